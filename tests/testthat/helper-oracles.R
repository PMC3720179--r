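# Independent brute-force oracles. The network oracle materializes every
# O(n^2) protein pair and hands the explicit edge list to igraph; the
# counting oracles are plain nested loops over neighbors and domains. None
# of them touch the package's inverted-index code paths.

# All unordered edges by pairwise domain-set intersection.
oracle_edges <- function(tbl) {
  n <- nrow(tbl)
  from <- character(0)
  to <- character(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (length(intersect(tbl$domains[[i]], tbl$domains[[j]])) > 0) {
        from <- c(from, tbl$protein_id[[i]])
        to <- c(to, tbl$protein_id[[j]])
      }
    }
  }
  data.frame(from = from, to = to)
}

oracle_graph <- function(tbl) {
  edges <- oracle_edges(tbl)
  igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = tbl$protein_id)
  )
}

oracle_components <- function(tbl) {
  g <- oracle_graph(tbl)
  comp <- igraph::components(g)
  comps <- split(names(comp$membership), comp$membership)
  comps <- lapply(comps, sort)
  ord <- order(-lengths(comps), vapply(comps, `[[`, character(1), 1L))
  unname(comps[ord])
}

oracle_degree <- function(tbl) {
  g <- oracle_graph(tbl)
  d <- igraph::degree(g)
  d[tbl$protein_id]
}

oracle_clustering <- function(tbl) {
  g <- oracle_graph(tbl)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "NaN")
  names(cc) <- igraph::V(g)$name
  cc[tbl$protein_id]
}

# Exact mean shortest path over ordered pairs of one component.
oracle_mean_path <- function(tbl, component) {
  g <- oracle_graph(tbl)
  sub <- igraph::induced_subgraph(g, component)
  d <- igraph::distances(sub)
  sum(d) / (length(component) * (length(component) - 1))
}

# Nested-loop recount of the direct domain-based mode.
oracle_count_direct <- function(tbl, d2g, query, include_shared = FALSE) {
  rows <- setNames(tbl$domains, tbl$protein_id)
  s <- rows[[query]]
  nb_domains <- character(0)
  for (p in tbl$protein_id) {
    if (p == query) next
    if (length(intersect(rows[[p]], s)) > 0) {
      nb_domains <- union(nb_domains, rows[[p]])
    }
  }
  cand <- if (include_shared) nb_domains else setdiff(nb_domains, s)
  counts <- list()
  for (d in cand) {
    for (g in d2g[[d]]) counts[[g]] <- union(counts[[g]], d)
  }
  v <- vapply(counts, length, integer(1))
  if (length(v) == 0L) return(setNames(integer(0), character(0)))
  v[order(names(v))]
}

# Nested-loop recount of the second-layer mode.
oracle_count_second <- function(tbl, d2g, query) {
  rows <- setNames(tbl$domains, tbl$protein_id)
  s <- rows[[query]]
  nb1 <- character(0)
  for (p in tbl$protein_id) {
    if (p != query && length(intersect(rows[[p]], s)) > 0) nb1 <- c(nb1, p)
  }
  s1 <- unique(unlist(rows[nb1]))
  nb2 <- character(0)
  for (p in tbl$protein_id) {
    if (p == query || p %in% nb1) next
    for (q in nb1) {
      if (length(intersect(rows[[p]], rows[[q]])) > 0) {
        nb2 <- c(nb2, p)
        break
      }
    }
  }
  d2 <- setdiff(unique(unlist(rows[nb2])), union(s, s1))
  counts <- list()
  for (d in d2) {
    for (g in d2g[[d]]) counts[[g]] <- union(counts[[g]], d)
  }
  v <- vapply(counts, length, integer(1))
  if (length(v) == 0L) return(setNames(integer(0), character(0)))
  v[order(names(v))]
}

# Nested-loop recount of the GOA mode (neighbor-protein counting).
oracle_count_goa <- function(tbl, goa, query, exclude = character(0)) {
  rows <- setNames(tbl$domains, tbl$protein_id)
  genome_of <- setNames(tbl$genome, tbl$protein_id)
  s <- rows[[query]]
  counts <- list()
  for (p in tbl$protein_id) {
    if (p == query || genome_of[[p]] %in% exclude) next
    if (length(intersect(rows[[p]], s)) == 0) next
    for (g in goa[[p]]) counts[[g]] <- union(counts[[g]], p)
  }
  v <- vapply(counts, length, integer(1))
  if (length(v) == 0L) return(setNames(integer(0), character(0)))
  v[order(names(v))]
}

# Package prediction as a name-sorted frequency vector, for comparison.
pred_freqs <- function(prediction) {
  v <- setNames(as.integer(prediction$frequency), prediction$go_id)
  if (length(v) == 0L) return(setNames(integer(0), character(0)))
  v[order(names(v))]
}
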