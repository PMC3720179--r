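# Readers and writers for the three annotation inputs (protein-domain TSV,
# domain->GO mapping, GAF) and the prediction/evaluation outputs. All writers
# emit canonically sorted rows with "\n" line endings so identical in-memory
# objects always produce byte-identical files.

#' Read a protein-domain annotation table
#'
#' The canonical input is a two-column UTF-8 TSV with header
#' `protein_id<TAB>domains`, one row per protein, domain accessions
#' semicolon-separated (the `domains` field may be empty for a protein with
#' no domain annotation). Duplicate rows for the same protein union their
#' domain sets; identifiers are whitespace-stripped and treated
#' case-sensitively.
#'
#' @param path Path to the TSV file.
#' @param genome Genome label attached to every protein (e.g. `"yeast"`).
#' @return A tibble with columns `protein_id` (character), `genome`
#'   (character) and `domains` (list of character vectors, sorted), one row
#'   per distinct protein, sorted by `protein_id`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("protein_id\tdomains", "P1\tPF00001;PF00002", "P2\t"), tf)
#' read_protein_domains(tf, genome = "toy")
#' @export
read_protein_domains <- function(path, genome) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L) {
    rlang::abort(sprintf("'%s' is empty; expected a header line", path))
  }
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L || strip_ws(header[[1]]) != "protein_id") {
    rlang::abort(sprintf(
      "line 1 of '%s': expected header 'protein_id\\tdomains'", path
    ))
  }
  ids <- character(0)
  doms <- list()
  for (i in seq_along(lines)[-1]) {
    if (lines[[i]] == "") next
    fields <- strsplit(paste0(lines[[i]], "\x01"), "\t", fixed = TRUE)[[1]]
    # sentinel keeps a trailing empty field visible to strsplit
    fields[length(fields)] <- sub("\x01$", "", fields[length(fields)])
    if (length(fields) != 2L) {
      rlang::abort(sprintf(
        "line %d of '%s': expected 2 tab-separated fields, found %d",
        i, path, length(fields)
      ))
    }
    id <- strip_ws(fields[[1]])
    if (id == "") {
      rlang::abort(sprintf("line %d of '%s': empty protein_id", i, path))
    }
    d <- strip_ws(strsplit(fields[[2]], ";", fixed = TRUE)[[1]])
    d <- d[d != ""]
    ids <- c(ids, id)
    doms <- c(doms, list(d))
  }
  tibble::tibble(protein_id = ids, domains = doms) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      domains = list(sort(unique(unlist(.data$domains)))),
      .groups = "drop"
    ) |>
    dplyr::mutate(genome = genome, .after = "protein_id") |>
    dplyr::arrange(.data$protein_id)
}

#' Write a protein-domain annotation table
#'
#' Inverse of [read_protein_domains()]: rows sorted by `protein_id`, domain
#' accessions sorted and semicolon-joined, so writing is deterministic and
#' write -> read -> write is byte-stable.
#'
#' @param proteins Tibble as returned by [read_protein_domains()] (the
#'   `genome` column is not written; the format carries no genome field).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_domains <- function(proteins, path) {
  rows <- proteins |>
    dplyr::arrange(.data$protein_id) |>
    dplyr::mutate(dom = purrr::map_chr(
      .data$domains, function(d) paste(sort(unique(d)), collapse = ";")
    ))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(
    "protein_id\tdomains",
    paste0(rows$protein_id, "\t", rows$dom)
  ), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a domain-to-GO mapping
#'
#' Accepts either a two-column TSV (`domain_accession<TAB>go_id`, optional
#' header) or the Pfam2GO text dialect, whose mapping lines look like
#' `Pfam:PF05773 RWD > GO:protein binding ; GO:0005515`. Comment lines
#' starting with `!` are ignored; repeated pairs are deduplicated. The
#' mapping is genome-independent: the same domain always carries the same GO
#' terms.
#'
#' @param path Path to the mapping file.
#' @return A tibble with columns `domain` and `go_id`, one row per distinct
#'   pair, sorted.
#' @export
read_domain2go <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  body <- lines[!startsWith(lines, "!") & lines != ""]
  pfam2go <- length(body) > 0L && all(startsWith(body, "Pfam:"))
  domains <- character(0)
  gos <- character(0)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (ln == "" || startsWith(ln, "!")) next
    if (pfam2go) {
      m <- regmatches(ln, regexec("^Pfam:([^ \t]+).*;[ \t]*(GO:[0-9]+)[ \t]*$", ln))[[1]]
      if (length(m) != 3L) {
        rlang::abort(sprintf(
          "line %d of '%s': not a Pfam2GO mapping line", i, path
        ))
      }
      dom <- strip_ws(m[[2]])
      go <- strip_ws(m[[3]])
    } else {
      fields <- strip_ws(strsplit(ln, "\t", fixed = TRUE)[[1]])
      if (length(fields) != 2L) {
        rlang::abort(sprintf(
          "line %d of '%s': expected 2 tab-separated fields, found %d",
          i, path, length(fields)
        ))
      }
      if (i == 1L && !is_go_id(fields[[2]]) &&
          tolower(fields[[2]]) %in% c("go_id", "go", "go_term")) {
        next # header row
      }
      dom <- fields[[1]]
      go <- fields[[2]]
    }
    if (!is_go_id(go)) {
      rlang::abort(sprintf(
        "line %d of '%s': '%s' is not a valid GO ID (GO: + 7 digits)",
        i, path, go
      ))
    }
    domains <- c(domains, dom)
    gos <- c(gos, go)
  }
  tibble::tibble(domain = domains, go_id = gos) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$domain, .data$go_id)
}

#' Write a domain-to-GO mapping as a two-column TSV
#'
#' @param domain2go Tibble with columns `domain`, `go_id` (or a named list of
#'   GO character vectors).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain2go <- function(domain2go, path) {
  tbl <- d2g_tibble(as_d2g_list(domain2go))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0(tbl$domain, "\t", tbl$go_id), con, sep = "\n",
             useBytes = TRUE)
  invisible(path)
}

#' Read protein GO annotations from a GAF 2.x file
#'
#' Column 2 (DB object ID) and column 5 (GO ID) are used; comment lines start
#' with `!`; rows whose qualifier (column 4) contains `NOT` are skipped, since
#' negated annotations would corrupt neighbor counting. GO IDs for a protein
#' are unioned across rows.
#'
#' @param path Path to the GAF file.
#' @param genome Genome label attached to every protein.
#' @return A tibble with columns `protein_id`, `genome`, `go_id`, one row per
#'   distinct (protein, term) pair, sorted.
#' @export
read_gaf <- function(path, genome) {
  lines <- readLines(path, encoding = "UTF-8")
  ids <- character(0)
  gos <- character(0)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (ln == "" || startsWith(ln, "!")) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 15L) {
      rlang::abort(sprintf(
        "line %d of '%s': expected >= 15 tab-separated GAF columns, found %d",
        i, path, length(fields)
      ))
    }
    qualifier <- fields[[4]]
    if (grepl("(^|\\|)NOT(\\||$)", qualifier)) next
    go <- strip_ws(fields[[5]])
    if (!is_go_id(go)) {
      rlang::abort(sprintf(
        "line %d of '%s': '%s' is not a valid GO ID", i, path, go
      ))
    }
    ids <- c(ids, strip_ws(fields[[2]]))
    gos <- c(gos, go)
  }
  tibble::tibble(protein_id = ids, genome = genome, go_id = gos) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$protein_id, .data$go_id)
}

#' Write protein GO annotations as a minimal GAF 2.2 file
#'
#' Emits one row per (protein, GO term) pair with fixed filler metadata
#' columns, canonically sorted, so the file is deterministic and survives
#' write -> read -> write byte-identically.
#'
#' @param goa Tibble with columns `protein_id`, `go_id` (a `genome` column is
#'   ignored), or a named list of GO character vectors.
#' @param path Output path.
#' @param db Value for the DB column (default `"PON"`).
#' @return `path`, invisibly.
#' @export
write_gaf <- function(goa, path, db = "PON") {
  map <- as_goa_list(goa)
  tbl <- tibble::tibble(
    protein_id = rep(names(map), lengths(map)),
    go_id = unlist(map, use.names = FALSE)
  ) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$protein_id, .data$go_id)
  rows <- paste(
    db, tbl$protein_id, tbl$protein_id, "involved_in", tbl$go_id,
    "GO_REF:0000002", "IEA", "", "P", "", "", "protein", "taxon:0",
    "20200101", db, "", "",
    sep = "\t"
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("!gaf-version: 2.2", rows), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write ranked predictions to a TSV file
#'
#' Columns: `protein_id`, `rank`, `go_id`, `occurrence_frequency`,
#' `n_supporting_items`; rows ordered by `protein_id` then `rank`, so
#' identical predictions always produce byte-identical files.
#'
#' @param predictions A prediction tibble from [predict_domain_direct()],
#'   [predict_domain_second_layer()], [predict_goa()] or [predict_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  tbl <- tibble::as_tibble(predictions)
  if (nrow(tbl) > 0L) {
    tbl <- tbl |>
      dplyr::mutate(n_supporting_items = purrr::map_int(.data$supporting, length)) |>
      dplyr::arrange(.data$protein_id, .data$rank)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  header <- "protein_id\trank\tgo_id\toccurrence_frequency\tn_supporting_items"
  body <- if (nrow(tbl) == 0L) character(0) else paste(
    tbl$protein_id, tbl$rank, tbl$go_id, tbl$frequency,
    tbl$n_supporting_items, sep = "\t"
  )
  writeLines(c(header, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a prediction TSV written by [write_predictions()]
#'
#' @param path Path to the prediction TSV.
#' @return A tibble with columns `protein_id`, `rank`, `go_id`, `frequency`,
#'   `n_supporting_items`, in file order (ranked).
#' @export
read_predictions <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L || !startsWith(lines[[1]], "protein_id\t")) {
    rlang::abort(sprintf("'%s' is not a prediction TSV", path))
  }
  if (length(lines) == 1L) {
    return(tibble::tibble(
      protein_id = character(0), rank = integer(0), go_id = character(0),
      frequency = integer(0), n_supporting_items = integer(0)
    ))
  }
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 5L)
  if (length(bad) > 0L) {
    rlang::abort(sprintf(
      "line %d of '%s': expected 5 fields", bad[[1]] + 1L, path
    ))
  }
  m <- do.call(rbind, fields)
  tibble::tibble(
    protein_id = m[, 1], rank = as.integer(m[, 2]), go_id = m[, 3],
    frequency = as.integer(m[, 4]), n_supporting_items = as.integer(m[, 5])
  )
}

#' Write per-protein evaluation records and a one-row summary
#'
#' The per-protein TSV has columns `protein_id`, `n_truth`, `n_predicted`,
#' `n_correct`, `success_rate`, `top1`, `top3`, `recall`; the summary file
#' (at `paste0(path, ".summary.tsv")` unless given) holds the genome-level
#' aggregate.
#'
#' @param evaluation A `pon_evaluation` object from [evaluate_genome()].
#' @param path Output path for the per-protein table.
#' @param summary_path Output path for the one-row summary.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(evaluation, path,
                             summary_path = paste0(path, ".summary.tsv")) {
  per <- dplyr::arrange(evaluation$per_protein, .data$protein_id)
  fmt <- function(x) formatC(x, digits = 6, format = "g")
  con <- file(path, open = "wb")
  writeLines(c(
    "protein_id\tn_truth\tn_predicted\tn_correct\tsuccess_rate\ttop1\ttop3\trecall",
    if (nrow(per)) paste(
      per$protein_id, per$n_truth, per$n_predicted, per$n_correct,
      fmt(per$success_rate), as.integer(per$top1_hit),
      as.integer(per$top3_hit), fmt(per$recall), sep = "\t"
    )
  ), con, sep = "\n", useBytes = TRUE)
  close(con)
  s <- evaluation$summary
  con <- file(summary_path, open = "wb")
  writeLines(c(
    paste(names(s), collapse = "\t"),
    paste(vapply(s, function(v) {
      if (is.numeric(v)) fmt(v) else as.character(v)
    }, character(1)), collapse = "\t")
  ), con, sep = "\n", useBytes = TRUE)
  close(con)
  invisible(path)
}
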