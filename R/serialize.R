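# Network serialization: a versioned JSON document holding the two inverted
# indices implicitly, as one record per protein (id, genome, sorted
# domains). Canonical ordering makes write -> read -> write byte-stable.

PON_FORMAT <- "pon-json/1"

#' Write a protein overlap network to a JSON file
#'
#' @param pon A `pon` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pon <- function(pon, path) {
  ids <- sort(names(pon$protein_index))
  doc <- list(
    format = PON_FORMAT,
    proteins = lapply(ids, function(id) {
      list(
        id = id,
        genome = unname(pon$genome_of[[id]]),
        domains = as.list(sort(pon$protein_index[[id]]))
      )
    })
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a protein overlap network from a JSON file
#'
#' @param path Path written by [write_pon()].
#' @return A `pon` object.
#' @export
read_pon <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$format, PON_FORMAT)) {
    rlang::abort(sprintf("'%s' is not a %s file", path, PON_FORMAT))
  }
  tbl <- tibble::tibble(
    protein_id = vapply(doc$proteins, function(p) p$id, character(1)),
    genome = vapply(doc$proteins, function(p) p$genome, character(1)),
    domains = lapply(doc$proteins, function(p) {
      unlist(p$domains, use.names = FALSE) %||% character(0)
    })
  )
  build_pon(tbl)
}
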