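# Evaluation protocol: the ranked list is truncated to the query's own
# annotation count, a prediction is correct when the GO ID matches exactly
# (binary criterion, no semantic similarity), and genome-level figures are
# the macro average over evaluated proteins. A node is predictable when at
# least one neighbor carries at least one GO annotation under the mode's
# annotation source; predictable nodes that are themselves annotated and
# receive a non-empty prediction are the evaluated set, and coverage is the
# evaluated fraction of all nodes.

#' Truth sets derived from domain annotations
#'
#' Under the InterPro-style protocol the reference annotation of a protein
#' is the combination (union) of the GO terms of all its domains.
#'
#' @param pon A `pon` object.
#' @param domain2go Domain-to-GO mapping (tibble or named list).
#' @param queries Protein IDs (default: all nodes).
#' @return Named list mapping each protein to its GO truth set (possibly
#'   empty).
#' @export
truth_from_domains <- function(pon, domain2go,
                               queries = names(pon$protein_index)) {
  map <- as_d2g_list(domain2go)
  setNames(lapply(queries, function(q) {
    sort(unique(unlist(map[pon$protein_index[[q]]], use.names = FALSE)))
  }), queries)
}

#' Evaluate one ranked prediction against a truth set
#'
#' The ranked list is truncated to `k = |truth|` terms with
#' [rank_and_truncate()] (ties at the cut-off resolved by the prediction's
#' seeded permutation); the success rate is the fraction of the truncated
#' list found in the truth set, and the recall is the fraction of the truth
#' set recovered. Top-1/top-3 hits are judged on the first one/three ranked
#' terms (or fewer when the list is shorter).
#'
#' @param prediction A `pon_prediction` for a single query (rows of a
#'   combined prediction table for one protein also work).
#' @param truth Character vector of reference GO IDs. If empty, the protein
#'   is excluded from evaluation and `NULL` is returned.
#' @param seed Tie-break seed; defaults to the prediction's own seed.
#' @return A one-row tibble (`protein_id`, `n_truth`, `n_predicted`,
#'   `n_correct`, `success_rate`, `top1_hit`, `top3_hit`, `recall`), or
#'   `NULL` when `truth` is empty.
#' @export
evaluate_protein <- function(prediction, truth, seed = NULL) {
  truth <- unique(truth)
  if (length(truth) == 0L) return(NULL)
  pid <- if (nrow(prediction) > 0L) prediction$protein_id[[1]] else NA_character_
  seed <- seed %||% attr(prediction, "seed_used") %||% 1L
  ranked <- rank_and_truncate(prediction, k = nrow(prediction), seed = seed)
  predicted <- head(ranked, min(length(truth), length(ranked)))
  n_correct <- length(intersect(predicted, truth))
  tibble::tibble(
    protein_id = pid,
    n_truth = length(truth),
    n_predicted = length(predicted),
    n_correct = n_correct,
    success_rate = if (length(predicted) == 0L) 0 else n_correct / length(predicted),
    top1_hit = length(ranked) >= 1L && ranked[[1]] %in% truth,
    top3_hit = any(head(ranked, 3L) %in% truth),
    recall = n_correct / length(truth)
  )
}

#' Predictable nodes under an annotation source
#'
#' A protein is predictable when at least one of its (eligible) neighbors
#' carries at least one GO annotation: an annotated domain for the
#' domain-based modes (radius-2 nodes for the second-layer mode), a
#' non-empty GOA entry for the GOA mode.
#'
#' @param pon A `pon` object.
#' @param annotation Domain-to-GO mapping (domain modes) or protein-to-GO
#'   map (GOA mode).
#' @param mode Prediction mode.
#' @param queries Protein IDs to classify (default: all nodes).
#' @param exclude Genome labels removed from neighborhoods (GOA mode).
#' @return Character vector of predictable protein IDs.
#' @export
predictable_proteins <- function(pon, annotation,
                                 mode = c("domain_direct",
                                          "domain_second_layer", "goa"),
                                 queries = names(pon$protein_index),
                                 exclude = character(0)) {
  mode <- match.arg(mode)
  if (mode == "goa") {
    map <- as_goa_list(annotation)
    annotated <- names(map)[lengths(map) > 0L]
    ok <- vapply(queries, function(q) {
      nb <- direct_neighbors(pon, q)
      if (length(exclude) > 0L) nb <- nb[!pon$genome_of[nb] %in% exclude]
      any(nb %in% annotated)
    }, logical(1))
  } else {
    map <- as_d2g_list(annotation)
    ann_domains <- names(map)[lengths(map) > 0L]
    carries <- vapply(pon$protein_index, function(d) any(d %in% ann_domains),
                      logical(1))
    radius <- if (mode == "domain_direct") 1 else 2
    ok <- vapply(queries, function(q) {
      nb <- pon_neighbors(pon, q, radius = radius)
      any(carries[nb])
    }, logical(1))
  }
  queries[ok]
}

#' Evaluate predictions for a whole genome
#'
#' Aggregates [evaluate_protein()] over all queries. The evaluated set is
#' the proteins with a non-empty truth set and a non-empty prediction;
#' genome-level success rate, top-1/top-3 accuracy and recall are unweighted
#' (macro) means over evaluated proteins, with the pooled (micro) success
#' rate also reported. Coverage is `n_evaluated / n_total`.
#'
#' @param pon A `pon` object.
#' @param predictions A combined prediction table from [predict_genome()]
#'   (or any `pon_prediction`).
#' @param truths Named list of truth GO sets (e.g. [truth_from_domains()] or
#'   a GOA map), or a tibble with `protein_id`, `go_id`.
#' @param seed Tie-break master seed; defaults to the prediction table's
#'   seed so truncation reproduces the prediction's stored order.
#' @param predictable Character vector of predictable proteins (from
#'   [predictable_proteins()]); defaults to the proteins with a non-empty
#'   prediction.
#' @param universe Protein IDs forming the denominator of coverage
#'   (default: every node of the network).
#' @return A `pon_evaluation` object: list with `per_protein` (tibble) and
#'   `summary` (one-row tibble).
#' @export
evaluate_genome <- function(pon, predictions, truths, seed = NULL,
                            predictable = NULL,
                            universe = names(pon$protein_index)) {
  truths <- as_goa_list(truths)
  seed <- seed %||% attr(predictions, "seed") %||% 1L
  tbl <- tibble::as_tibble(predictions)
  by_query <- if (nrow(tbl) > 0L) split(tbl, tbl$protein_id) else list()
  nonempty <- intersect(names(by_query), universe)
  predictable <- union(intersect(predictable, universe), nonempty)
  annotated <- universe[vapply(
    universe, function(q) length(truths[[q]]) > 0L, logical(1)
  )]
  evaluated <- intersect(nonempty, annotated)
  per <- dplyr::bind_rows(lapply(evaluated, function(q) {
    evaluate_protein(by_query[[q]], truths[[q]],
                     seed = derive_seed(seed, "tie", q))
  }))
  if (nrow(per) == 0L) {
    per <- tibble::tibble(
      protein_id = character(0), n_truth = integer(0),
      n_predicted = integer(0), n_correct = integer(0),
      success_rate = numeric(0), top1_hit = logical(0),
      top3_hit = logical(0), recall = numeric(0)
    )
  }
  n_total <- length(universe)
  summary <- tibble::tibble(
    n_total = n_total,
    n_predictable = length(predictable),
    n_evaluated = nrow(per),
    success_rate = mean(per$success_rate),
    success_rate_micro = if (sum(per$n_predicted) > 0L)
      sum(per$n_correct) / sum(per$n_predicted) else NaN,
    top1_accuracy = mean(per$top1_hit),
    top3_accuracy = mean(per$top3_hit),
    mean_recall = mean(per$recall),
    predictable_fraction = length(predictable) / n_total,
    coverage = nrow(per) / n_total
  )
  structure(list(per_protein = per, summary = summary),
            class = "pon_evaluation")
}

#' @export
print.pon_evaluation <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0(
      "<pon_evaluation> %d evaluated / %d predictable / %d nodes\n",
      "  success rate %.3f (micro %.3f), top-1 %.3f, top-3 %.3f\n",
      "  recall %.3f, predictable fraction %.3f, coverage %.3f\n"
    ),
    s$n_evaluated, s$n_predictable, s$n_total, s$success_rate,
    s$success_rate_micro, s$top1_accuracy, s$top3_accuracy, s$mean_recall,
    s$predictable_fraction, s$coverage
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pon_evaluation <- function(x, ...) x$per_protein

#' @exportS3Method generics::glance
glance.pon_evaluation <- function(x, ...) x$summary

#' Histogram of per-protein success rates
#'
#' @param object A `pon_evaluation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pon_evaluation <- function(object, ...) {
  ggplot2::ggplot(object$per_protein,
                  ggplot2::aes(x = .data$success_rate)) +
    ggplot2::geom_histogram(bins = 21, boundary = 0) +
    ggplot2::labs(x = "per-protein success rate", y = "proteins",
                  title = "Prediction success over evaluated proteins")
}

#' Randomize the domain-to-GO mapping
#'
#' The GO-term sets attached to the domains are permuted uniformly at random
#' among the domains: the multiset of annotation sets (hence the number of
#' annotated domains and the total assignment count) is conserved, domain
#' identities and network topology are untouched, and only the association
#' between a specific domain and its terms is destroyed. This is the null
#' model for the random-prediction control.
#'
#' @param domain2go Domain-to-GO mapping (tibble or named list).
#' @param seed Integer seed.
#' @return A mapping of the same form as the input.
#' @export
randomize_annotations <- function(domain2go, seed) {
  map <- as_d2g_list(domain2go)
  if (length(map) > 1L) {
    perm <- withr::with_seed(seed, sample.int(length(map)))
    map <- setNames(map[perm], names(map))
  }
  if (is.data.frame(domain2go)) d2g_tibble(map) else map
}

#' Random-prediction control for the domain-based method
#'
#' Repeats: permute the domain annotations with [randomize_annotations()],
#' re-run domain-based direct prediction, and evaluate against the truth
#' sets derived from the permuted mapping (the reference annotations move
#' with the permutation, exactly as when GO terms are switched between
#' proteins and their domains genome-wide). The spread of the resulting
#' success rates is the random baseline against which the real prediction
#' is judged.
#'
#' @param pon A `pon` object.
#' @param domain2go The real domain-to-GO mapping.
#' @param config A [prediction_config()].
#' @param n_reps Number of permutation repetitions.
#' @param seed Master seed; each repetition draws its own permutation and
#'   tie-break substreams from it.
#' @param queries Queries to evaluate (default: all nodes).
#' @return A `pon_control` object: list with `reps` (one summary row per
#'   repetition) and the aggregate `mean_success_rate`.
#' @export
run_control <- function(pon, domain2go, config = prediction_config(),
                        n_reps = 100, seed = 1L,
                        queries = names(pon$protein_index)) {
  stopifnot(n_reps >= 1)
  map <- as_d2g_list(domain2go)
  rows <- lapply(seq_len(n_reps), function(r) {
    rep_seed <- derive_seed(seed, "control", r)
    map_r <- randomize_annotations(map, rep_seed)
    config_r <- config
    config_r$seed <- derive_seed(rep_seed, "tie-stream")
    ev <- run_genome_evaluation(
      pon, domain2go = map_r, mode = "domain_direct",
      queries = queries, config = config_r
    )
    dplyr::mutate(ev$summary, rep = r, .before = 1)
  })
  reps <- dplyr::bind_rows(rows)
  structure(list(
    reps = reps,
    n_reps = n_reps,
    mean_success_rate = mean(reps$success_rate),
    sd_success_rate = stats::sd(reps$success_rate)
  ), class = "pon_control")
}

#' @export
print.pon_control <- function(x, ...) {
  cat(sprintf(
    "<pon_control> %d permutations: mean success rate %.4f (sd %.4f)\n",
    x$n_reps, x$mean_success_rate, x$sd_success_rate
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pon_control <- function(x, ...) x$reps

#' @exportS3Method generics::glance
glance.pon_control <- function(x, ...) {
  tibble::tibble(
    n_reps = x$n_reps,
    mean_success_rate = x$mean_success_rate,
    sd_success_rate = x$sd_success_rate,
    mean_coverage = mean(x$reps$coverage)
  )
}

#' Distribution plot of control success rates
#'
#' @param object A `pon_control`.
#' @param observed Optional observed (un-randomized) success rate drawn as a
#'   vertical line.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pon_control <- function(object, observed = NULL, ...) {
  p <- ggplot2::ggplot(object$reps, ggplot2::aes(x = .data$success_rate)) +
    ggplot2::geom_histogram(bins = 30, boundary = 0) +
    ggplot2::labs(x = "control success rate", y = "permutations",
                  title = "Randomization control")
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_vline(xintercept = observed, linetype = 2)
  }
  p
}

#' Predict and evaluate a genome in one call
#'
#' Convenience wrapper chaining [predictable_proteins()], [predict_genome()]
#' and [evaluate_genome()] under one configuration. The truth source follows
#' `config$truth_source`: the union of the query's domain annotations
#' (`"interpro"`) or the curated protein annotations (`"goa"`).
#'
#' @param pon A `pon` object.
#' @param domain2go Domain-to-GO mapping (required for domain modes and for
#'   the `"interpro"` truth source).
#' @param goa Protein-to-GO map (required for GOA mode / `"goa"` truth).
#' @param mode Prediction mode.
#' @param queries Queries to predict and evaluate (default: all nodes; use
#'   the proteins of one genome to score that genome inside a composite
#'   network).
#' @param exclude Genomes excluded from neighborhoods (GOA mode).
#' @param config A [prediction_config()].
#' @return A `pon_evaluation` with the prediction table attached as
#'   `$predictions`.
#' @export
run_genome_evaluation <- function(pon, domain2go = NULL, goa = NULL,
                                  mode = c("domain_direct",
                                           "domain_second_layer", "goa"),
                                  queries = names(pon$protein_index),
                                  exclude = character(0),
                                  config = prediction_config()) {
  mode <- match.arg(mode)
  annotation <- if (mode == "goa") as_goa_list(goa) else as_d2g_list(domain2go)
  truths <- if (config$truth_source == "goa") {
    as_goa_list(goa)
  } else {
    truth_from_domains(pon, domain2go, queries)
  }
  predictable <- predictable_proteins(pon, annotation, mode, queries, exclude)
  preds <- predict_genome(pon, annotation, mode, queries, exclude, config)
  ev <- evaluate_genome(pon, preds, truths, seed = config$seed,
                        predictable = predictable, universe = queries)
  ev$predictions <- preds
  ev
}
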