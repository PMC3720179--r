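# Internal helpers: identifier hygiene, seeded tie-breaking, map coercions.

GO_PATTERN <- "^GO:[0-9]{7}$"

is_go_id <- function(x) grepl(GO_PATTERN, x)

strip_ws <- function(x) {
  gsub("^[ \t\r\n]+|[ \t\r\n]+$", "", x)
}

# Deterministic 31-bit string hash (polynomial rolling hash). Used only to
# derive per-query RNG substreams; not cryptographic.
hash_string <- function(x) {
  h <- 0
  for (cp in utf8ToInt(x)) h <- (h * 131 + cp) %% 2147483647
  h
}

#' Derive a reproducible sub-seed from a master seed and string labels
#'
#' All randomness in the package (tie-breaking, sampling, the synthetic
#' generator's substreams, control repetitions) flows from one integer seed
#' through this function, so that independent stages draw from independent
#' but reproducible streams. The result always fits in a 32-bit signed
#' integer.
#'
#' @param seed Integer master seed.
#' @param ... Character or numeric labels naming the substream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483647
  for (s in vapply(list(...), as.character, character(1))) {
    h <- (h * 131071 + hash_string(s)) %% 2147483647
  }
  as.integer(h)
}

# Order prediction entries: occurrence frequency descending, ties shuffled by
# a seeded uniform key. Entries are first put in canonical (alphabetical)
# order so the permutation is independent of input row order.
order_entries <- function(go_id, frequency, seed) {
  if (length(go_id) == 0L) return(integer(0))
  base <- order(go_id)
  key <- withr::with_seed(seed, runif(length(go_id)))
  base[order(-frequency[base], key)]
}

# Accept a domain->GO mapping as a long tibble (domain, go_id) or as a named
# list of character vectors; return the named-list form.
as_d2g_list <- function(domain2go) {
  if (is.list(domain2go) && !is.data.frame(domain2go)) {
    return(domain2go)
  }
  stopifnot(is.data.frame(domain2go))
  if (nrow(domain2go) == 0L) return(structure(list(), names = character(0)))
  split(domain2go$go_id, domain2go$domain)
}

# Inverse of as_d2g_list(): canonical long tibble, sorted for reproducible
# output.
d2g_tibble <- function(map) {
  if (length(map) == 0L) {
    return(tibble::tibble(domain = character(0), go_id = character(0)))
  }
  out <- tibble::tibble(
    domain = rep(names(map), lengths(map)),
    go_id = unlist(map, use.names = FALSE)
  )
  dplyr::arrange(dplyr::distinct(out), .data$domain, .data$go_id)
}

# Accept a protein->GO map as long tibble (protein_id, go_id) or named list.
as_goa_list <- function(goa) {
  if (is.list(goa) && !is.data.frame(goa)) return(goa)
  stopifnot(is.data.frame(goa))
  if (nrow(goa) == 0L) return(structure(list(), names = character(0)))
  split(goa$go_id, goa$protein_id)
}
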