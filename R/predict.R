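# GO-term prediction by neighbor counting. A candidate term's score is its
# occurrence frequency: the number of distinct supporting items annotated
# with it -- domain types in the domain-based modes, neighbor proteins in the
# GOA mode. In the default test protocol the query's own domains are treated
# as functionally unknown, so domains shared between the query and a
# neighbor never contribute to the counts.

#' Prediction configuration
#'
#' @param min_domain_types Keep only GO terms supported by at least this many
#'   items (the domain-type diversity threshold; 1 keeps everything).
#' @param include_shared_domains If `TRUE`, domains shared between the query
#'   and its neighbors also contribute to the counts (the favorable-common-
#'   domain variant); the default `FALSE` is the test protocol, in which the
#'   query's domain functions are treated as unknown.
#' @param truth_source `"interpro"` (truth = union of the GO terms of the
#'   query's domains) or `"goa"` (truth = curated per-protein annotations).
#' @param seed Integer master seed for tie-breaking.
#' @return A `prediction_config` list.
#' @export
prediction_config <- function(min_domain_types = 1L,
                              include_shared_domains = FALSE,
                              truth_source = c("interpro", "goa"),
                              seed = 1L) {
  stopifnot(min_domain_types >= 1L)
  structure(list(
    min_domain_types = as.integer(min_domain_types),
    include_shared_domains = isTRUE(include_shared_domains),
    truth_source = match.arg(truth_source),
    seed = as.integer(seed)
  ), class = "prediction_config")
}

new_prediction <- function(protein_id, mode, go_id, frequency, supporting,
                           seed_used) {
  ord <- order_entries(go_id, frequency, seed_used)
  out <- tibble::tibble(
    protein_id = if (length(ord)) protein_id else character(0),
    mode = if (length(ord)) mode else character(0),
    rank = seq_along(ord),
    go_id = go_id[ord],
    frequency = as.integer(frequency[ord]),
    supporting = lapply(supporting[ord], function(s) sort(unique(s)))
  )
  attr(out, "seed_used") <- seed_used
  class(out) <- c("pon_prediction", class(out))
  out
}

# Count, for each GO term attached to any of `items`' annotation sets, the
# number of distinct items carrying it.
count_terms <- function(items, sets) {
  hit <- sets[items]
  hit <- hit[!vapply(hit, is.null, logical(1))]
  if (length(hit) == 0L) {
    return(list(go_id = character(0), frequency = integer(0),
                supporting = list()))
  }
  long <- tibble::tibble(
    item = rep(names(hit), lengths(hit)),
    go_id = unlist(hit, use.names = FALSE)
  )
  by_term <- split(long$item, long$go_id)
  list(
    go_id = names(by_term),
    frequency = lengths(by_term),
    supporting = unname(by_term)
  )
}

finish_domain_prediction <- function(query, mode, cand, shared_kept, map,
                                     config) {
  cnt <- count_terms(cand, map)
  keep <- cnt$frequency >= config$min_domain_types
  new_prediction(
    query, mode,
    cnt$go_id[keep], cnt$frequency[keep], cnt$supporting[keep],
    seed_used = derive_seed(config$seed, "tie", query)
  )
}

#' Domain-based prediction from direct neighbors
#'
#' Collects the domains present in the query's direct neighbors and ranks GO
#' terms by the number of distinct domain types annotated with each term.
#' Under the default configuration the common domains (present in the query
#' itself) are excluded from the candidate set: a term annotated only on
#' common domains is dropped, and a term annotated on both a common and a
#' non-shared domain is kept but the common domain does not add to its
#' count. With `include_shared_domains = TRUE` the common domains are
#' counted as well.
#'
#' @param pon A `pon` object.
#' @param domain2go Domain-to-GO mapping (tibble or named list).
#' @param query Protein ID of the query (must be in the network).
#' @param config A [prediction_config()].
#' @return A `pon_prediction` tibble with columns `protein_id`, `mode`,
#'   `rank`, `go_id`, `frequency` and `supporting` (list of contributing
#'   domain accessions). A query with no neighbors yields zero rows.
#' @export
predict_domain_direct <- function(pon, domain2go, query,
                                  config = prediction_config()) {
  check_protein(pon, query)
  map <- as_d2g_list(domain2go)
  s <- pon$protein_index[[query]]
  nb <- direct_neighbors(pon, query)
  dstar <- unique(unlist(pon$protein_index[nb], use.names = FALSE))
  cand <- if (config$include_shared_domains) dstar else setdiff(dstar, s)
  finish_domain_prediction(query, "domain_direct", cand, NULL, map, config)
}

#' Domain-based prediction from second-layer neighbors
#'
#' Counts GO terms over the domains found in the radius-2 nodes (proteins at
#' shortest-path distance exactly 2), excluding every domain already present
#' in the query or in any direct neighbor. This isolates genuinely new
#' domain information two steps away: a domain that also occurs in a direct
#' neighbor (equivalently, that co-occurs with a query domain in some
#' protein of the network) is never counted.
#'
#' @inheritParams predict_domain_direct
#' @return A `pon_prediction` tibble (mode `"domain_second_layer"`).
#' @export
predict_domain_second_layer <- function(pon, domain2go, query,
                                        config = prediction_config()) {
  check_protein(pon, query)
  map <- as_d2g_list(domain2go)
  s <- pon$protein_index[[query]]
  nb <- direct_neighbors(pon, query)
  s1 <- unique(unlist(pon$protein_index[nb], use.names = FALSE))
  layer2 <- pon_neighbors(pon, query, radius = 2)
  d2 <- setdiff(
    unique(unlist(pon$protein_index[layer2], use.names = FALSE)),
    union(s, s1)
  )
  finish_domain_prediction(query, "domain_second_layer", d2, NULL, map, config)
}

#' Prediction from curated GO annotations of neighbor proteins
#'
#' Ranks GO terms by the number of neighbor proteins annotated with each
#' term in a GOA-style protein-to-GO map. The query's own annotations are
#' never used. With `exclude`, proteins of the listed genomes are removed
#' from the neighborhood (leave-one-genome-out evaluation: the query stays
#' in the network as a node, but its edges to removed proteins vanish with
#' them). Neighbors absent from the map simply contribute nothing.
#'
#' @inheritParams predict_domain_direct
#' @param goa Protein-to-GO map (tibble with `protein_id`, `go_id` columns,
#'   or named list), e.g. from [read_gaf()].
#' @param exclude Character vector of genome labels whose proteins are
#'   removed from the neighborhood.
#' @return A `pon_prediction` tibble (mode `"goa"`, `supporting` = neighbor
#'   protein IDs). `min_domain_types` applies to the neighbor-protein counts.
#' @export
predict_goa <- function(pon, goa, query, exclude = character(0),
                        config = prediction_config()) {
  check_protein(pon, query)
  map <- as_goa_list(goa)
  nb <- direct_neighbors(pon, query)
  if (length(exclude) > 0L) {
    nb <- nb[!pon$genome_of[nb] %in% exclude]
  }
  cnt <- count_terms(nb, map)
  keep <- cnt$frequency >= config$min_domain_types
  new_prediction(
    query, "goa", cnt$go_id[keep], cnt$frequency[keep], cnt$supporting[keep],
    seed_used = derive_seed(config$seed, "tie", query)
  )
}

#' Truncate a ranked candidate list to k terms
#'
#' Terms are sorted by occurrence frequency, descending. All terms strictly
#' above the cut-off frequency are included; among terms tied exactly at the
#' cut-off, a uniform random (seeded) subset fills the remaining slots. If
#' fewer than `k` terms exist, all of them constitute the prediction.
#'
#' @param entries A tibble with columns `go_id` and `frequency` (e.g. a
#'   `pon_prediction`), or a named integer vector of frequencies.
#' @param k Number of terms to keep (the query's annotation count during
#'   evaluation).
#' @param seed Integer seed for the tie-break permutation. For a
#'   `pon_prediction` the default reuses the prediction's own seed, so
#'   truncation agrees with the stored rank order.
#' @return Character vector of GO IDs, length `min(k, available)`.
#' @export
rank_and_truncate <- function(entries, k, seed = NULL) {
  stopifnot(k >= 0)
  if (is.data.frame(entries)) {
    go <- entries$go_id
    freq <- entries$frequency
    seed <- seed %||% attr(entries, "seed_used") %||% 1L
  } else {
    go <- names(entries)
    freq <- as.integer(entries)
    seed <- seed %||% 1L
  }
  ord <- order_entries(go, freq, seed)
  head(go[ord], min(k, length(ord)))
}

#' Predict GO terms for many query proteins
#'
#' Maps one of the three prediction modes over a set of queries and binds
#' the ranked results into one prediction table, suitable for
#' [write_predictions()] and [evaluate_genome()].
#'
#' @param pon A `pon` object.
#' @param annotation The mode's annotation source: a domain-to-GO mapping
#'   for the domain modes, a protein-to-GO (GOA) map for `mode = "goa"`.
#' @param mode `"domain_direct"`, `"domain_second_layer"` or `"goa"`.
#' @param queries Protein IDs to predict (default: every node).
#' @param exclude Genomes excluded from neighborhoods (GOA mode only).
#' @param config A [prediction_config()].
#' @return A `pon_prediction` tibble covering all queries (queries with an
#'   empty prediction contribute no rows).
#' @export
predict_genome <- function(pon, annotation,
                           mode = c("domain_direct", "domain_second_layer",
                                    "goa"),
                           queries = names(pon$protein_index),
                           exclude = character(0),
                           config = prediction_config()) {
  mode <- match.arg(mode)
  map <- if (mode == "goa") as_goa_list(annotation) else as_d2g_list(annotation)
  preds <- lapply(queries, function(q) {
    switch(mode,
      domain_direct = predict_domain_direct(pon, map, q, config),
      domain_second_layer = predict_domain_second_layer(pon, map, q, config),
      goa = predict_goa(pon, map, q, exclude, config)
    )
  })
  out <- dplyr::bind_rows(preds)
  attr(out, "queries") <- queries
  attr(out, "mode") <- mode
  attr(out, "seed") <- config$seed
  class(out) <- c("pon_prediction", setdiff(class(out), "pon_prediction"))
  out
}

#' @export
print.pon_prediction <- function(x, ...) {
  nq <- length(unique(x$protein_id))
  cat(sprintf("<pon_prediction> %d ranked terms for %d quer%s\n",
              nrow(x), nq, if (nq == 1) "y" else "ies"))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Bar chart of the top-ranked GO terms of a prediction
#'
#' @param object A `pon_prediction` for a single query.
#' @param n_terms Number of top terms to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pon_prediction <- function(object, n_terms = 15, ...) {
  pid <- object$protein_id[1]
  tbl <- tibble::as_tibble(object) |>
    dplyr::filter(.data$protein_id == pid) |>
    head(n_terms)
  ggplot2::ggplot(tbl, ggplot2::aes(
    x = stats::reorder(.data$go_id, .data$frequency), y = .data$frequency
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "occurrence frequency",
                  title = paste("Ranked GO terms:", tbl$protein_id[1]))
}
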