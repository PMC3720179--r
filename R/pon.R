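# Protein overlap network (PON): proteins are nodes, and two proteins are
# joined by an edge when they share at least one domain accession. Edges are
# never materialized pairwise: the network is stored as the pair of inverted
# indices protein -> domains and domain -> proteins, because real PONs
# contain very large cliques of proteins with identical domain composition
# and an explicit edge list is quadratic in clique size.

new_pon <- function(protein_index, domain_index, genome_of) {
  structure(
    list(
      protein_index = protein_index,
      domain_index = domain_index,
      genome_of = genome_of
    ),
    class = "pon"
  )
}

#' Build a protein overlap network from protein-domain annotations
#'
#' Two proteins are connected iff their domain sets intersect; sharing
#' several domains still yields a single edge, and a protein with no domains
#' is an isolated node. Protein IDs must be unique across the input; if the
#' same ID occurs in two different genomes it is disambiguated by prefixing
#' the genome label (`"genome:protein"`). The same ID occurring twice within
#' one genome is an error (union duplicate rows at read time instead).
#'
#' @param proteins A protein-domain tibble (`protein_id`, `genome`, `domains`
#'   list-column) as returned by [read_protein_domains()], a
#'   `genome_annotation` object from [generate_genome()], or a list of
#'   either (multiple genomes are concatenated).
#' @return A `pon` object.
#' @examples
#' prot <- tibble::tibble(
#'   protein_id = c("P1", "P2", "P3"),
#'   genome = "toy",
#'   domains = list("PF00001", c("PF00001", "PF00002"), "PF00002")
#' )
#' net <- build_pon(prot)
#' pon_neighbors(net, "P2")
#' @export
build_pon <- function(proteins) {
  tbl <- collect_protein_tables(proteins)
  if (nrow(tbl) == 0L) {
    rlang::abort("cannot build a PON from an empty protein table")
  }
  dup_within <- tbl |>
    dplyr::count(.data$protein_id, .data$genome) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup_within) > 0L) {
    rlang::abort(sprintf(
      "duplicate protein_id within genome '%s': %s",
      dup_within$genome[[1]], dup_within$protein_id[[1]]
    ))
  }
  clash <- unique(tbl$protein_id[duplicated(tbl$protein_id)])
  if (length(clash) > 0L) {
    hit <- tbl$protein_id %in% clash
    tbl$protein_id[hit] <- paste0(tbl$genome[hit], ":", tbl$protein_id[hit])
  }
  protein_index <- setNames(
    lapply(tbl$domains, function(d) sort(unique(d))),
    tbl$protein_id
  )
  genome_of <- setNames(tbl$genome, tbl$protein_id)
  pairs <- tibble::tibble(
    domain = unlist(protein_index, use.names = FALSE),
    protein_id = rep(names(protein_index), lengths(protein_index))
  )
  domain_index <- if (nrow(pairs)) split(pairs$protein_id, pairs$domain)
                  else structure(list(), names = character(0))
  new_pon(protein_index, domain_index, genome_of)
}

# Normalize build_pon() input to one tibble(protein_id, genome, domains).
collect_protein_tables <- function(x) {
  if (inherits(x, "genome_annotation")) return(x$proteins)
  if (is.data.frame(x)) return(x)
  if (is.list(x)) {
    return(dplyr::bind_rows(lapply(x, collect_protein_tables)))
  }
  rlang::abort("unsupported input type for build_pon()")
}

#' Merge protein overlap networks into a composite network
#'
#' The composite PON of several genomes is the union of their indices;
#' cross-genome edges arise automatically wherever two genomes use the same
#' domain accession. Protein ID sets must be disjoint, except that a protein
#' repeated with an identical genome and domain set is kept once; the same ID
#' with a different domain set is an error.
#'
#' @param ... `pon` objects (or a single list of them).
#' @return The composite `pon`.
#' @export
merge_pons <- function(...) {
  pons <- list(...)
  if (length(pons) == 1L && !inherits(pons[[1]], "pon")) pons <- pons[[1]]
  stopifnot(length(pons) >= 1L, all(vapply(pons, inherits, logical(1), "pon")))
  protein_index <- list()
  genome_of <- character(0)
  for (p in pons) {
    for (id in names(p$protein_index)) {
      if (!is.null(protein_index[[id]])) {
        if (!identical(protein_index[[id]], p$protein_index[[id]]) ||
            genome_of[[id]] != p$genome_of[[id]]) {
          rlang::abort(sprintf(
            "protein_id '%s' occurs in two networks with conflicting records", id
          ))
        }
      } else {
        protein_index[[id]] <- p$protein_index[[id]]
        genome_of[[id]] <- p$genome_of[[id]]
      }
    }
  }
  pairs <- tibble::tibble(
    domain = unlist(protein_index, use.names = FALSE),
    protein_id = rep(names(protein_index), lengths(protein_index))
  )
  domain_index <- if (nrow(pairs)) split(pairs$protein_id, pairs$domain)
                  else structure(list(), names = character(0))
  new_pon(protein_index, domain_index, genome_of)
}

check_protein <- function(pon, protein_id) {
  if (!protein_id %in% names(pon$protein_index)) {
    rlang::abort(sprintf("protein '%s' is not in the network", protein_id))
  }
}

#' Network neighbors of a protein at radius 1 or 2
#'
#' Radius 1 returns the direct neighbors (proteins sharing at least one
#' domain with the query). Radius 2 returns the second-layer nodes: proteins
#' at shortest-path distance exactly 2, i.e. neighbors-of-neighbors that are
#' neither the query nor its direct neighbors.
#'
#' @param pon A `pon` object.
#' @param protein_id Query protein ID.
#' @param radius 1 (default) or 2.
#' @return Sorted character vector of protein IDs.
#' @export
pon_neighbors <- function(pon, protein_id, radius = 1) {
  check_protein(pon, protein_id)
  stopifnot(radius %in% c(1, 2))
  n1 <- direct_neighbors(pon, protein_id)
  if (radius == 1) return(n1)
  d2 <- as.character(unique(unlist(pon$domain_index[
    as.character(unique(unlist(pon$protein_index[n1], use.names = FALSE)))
  ], use.names = FALSE)))
  sort(setdiff(d2, c(protein_id, n1)))
}

direct_neighbors <- function(pon, protein_id) {
  doms <- pon$protein_index[[protein_id]]
  if (length(doms) == 0L) return(character(0))
  sort(setdiff(
    unique(unlist(pon$domain_index[doms], use.names = FALSE)),
    protein_id
  ))
}

#' Node degrees
#'
#' @param pon A `pon` object.
#' @param protein_ids Proteins to report (default: all).
#' @return Named integer vector of degrees.
#' @export
pon_degree <- function(pon, protein_ids = names(pon$protein_index)) {
  vapply(protein_ids, function(p) length(direct_neighbors(pon, p)),
         integer(1))
}

#' Connected components of the network
#'
#' Traversal runs over the domain index (all co-members of each domain are
#' visited at once), so huge cliques are crossed in time linear in their
#' size. Components are returned sorted by decreasing size; equal-sized
#' components are ordered by their lexicographically smallest member, and the
#' first component is the main sub-graph.
#'
#' @param pon A `pon` object.
#' @return A list of sorted character vectors of protein IDs.
#' @export
pon_components <- function(pon) {
  ids <- names(pon$protein_index)
  comp <- setNames(rep(NA_integer_, length(ids)), ids)
  seen_domain <- setNames(
    rep(FALSE, length(pon$domain_index)), names(pon$domain_index)
  )
  k <- 0L
  for (start in ids) {
    if (!is.na(comp[[start]])) next
    k <- k + 1L
    queue <- start
    comp[[start]] <- k
    while (length(queue) > 0L) {
      p <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      doms <- pon$protein_index[[p]]
      doms <- doms[!seen_domain[doms]]
      if (length(doms) == 0L) next
      seen_domain[doms] <- TRUE
      members <- unique(unlist(pon$domain_index[doms], use.names = FALSE))
      fresh <- members[is.na(comp[members])]
      comp[fresh] <- k
      queue <- c(queue, fresh)
    }
  }
  comps <- split(ids, comp)
  comps <- lapply(comps, sort)
  ord <- order(-lengths(comps), vapply(comps, `[[`, character(1), 1L))
  unname(comps[ord])
}

#' Clustering coefficient of a node
#'
#' For a node with `k` neighbors of which `n` pairs are themselves connected,
#' the coefficient is `2 n / (k (k - 1))`. Nodes with fewer than two
#' neighbors have no defined coefficient and return `NA`; they are excluded
#' from network means.
#'
#' @param pon A `pon` object.
#' @param protein_id Query protein ID.
#' @return A number in `[0, 1]`, or `NA` when the degree is below 2.
#' @export
clustering_coefficient <- function(pon, protein_id) {
  check_protein(pon, protein_id)
  nb <- direct_neighbors(pon, protein_id)
  k <- length(nb)
  if (k < 2L) return(NA_real_)
  2 * edges_among(pon, nb) / (k * (k - 1))
}

# Number of edges among a node set: for each domain, take its members inside
# the set and collect the implied pairs, deduplicated across domains.
edges_among <- function(pon, nodes) {
  idx <- seq_along(nodes)
  names(idx) <- nodes
  doms <- unique(unlist(pon$protein_index[nodes], use.names = FALSE))
  m <- length(nodes)
  keys <- unlist(lapply(doms, function(d) {
    members <- idx[pon$domain_index[[d]]]
    members <- sort(members[!is.na(members)])
    if (length(members) < 2L) return(numeric(0))
    cb <- utils::combn(members, 2L)
    cb[1L, ] * m + cb[2L, ]
  }), use.names = FALSE)
  length(unique(keys))
}

#' Mean shortest path length within a connected component
#'
#' Unweighted shortest paths by breadth-first traversal over the domain
#' index (equivalent to Dijkstra with unit edge weights). The mean is taken
#' over ordered source-target pairs, excluding self-pairs; for an undirected
#' graph this equals the unordered-pair mean. With `sample_sources = "all"`
#' (default) every node is a source and the value is exact; an integer
#' subsamples sources reproducibly for very large components.
#'
#' @param pon A `pon` object.
#' @param component Character vector of protein IDs forming one connected
#'   component (e.g. an element of [pon_components()]).
#' @param sample_sources `"all"` for the exact mean, or a source count.
#' @param seed Integer seed used only when sources are sampled.
#' @return Mean shortest path length (0 for a single-node component).
#' @export
shortest_path_stats <- function(pon, component, sample_sources = "all",
                                seed = 1L) {
  component <- sort(component)
  n <- length(component)
  if (n <= 1L) return(0)
  sources <- if (identical(sample_sources, "all") || sample_sources >= n) {
    component
  } else {
    withr::with_seed(seed, sample(component, sample_sources))
  }
  in_comp <- setNames(rep(TRUE, n), component)
  total <- 0
  count <- 0
  for (s in sources) {
    dist <- bfs_distances(pon, s)
    if (length(dist) != n || !all(names(dist) %in% component)) {
      rlang::abort("'component' is not a connected component of the network")
    }
    total <- total + sum(dist)
    count <- count + n - 1L
  }
  total / count
}

# Single-source BFS over the bipartite protein/domain incidence structure;
# each domain is expanded at most once, so a clique costs linear time.
bfs_distances <- function(pon, source) {
  dist <- setNames(0L, source)
  frontier <- source
  seen_domain <- character(0)
  d <- 0L
  while (length(frontier) > 0L) {
    d <- d + 1L
    doms <- unique(unlist(pon$protein_index[frontier], use.names = FALSE))
    doms <- setdiff(doms, seen_domain)
    seen_domain <- c(seen_domain, doms)
    nxt <- unique(unlist(pon$domain_index[doms], use.names = FALSE))
    nxt <- nxt[!nxt %in% names(dist)]
    if (length(nxt) > 0L) dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Topology summary of a protein overlap network
#'
#' Collects the node/domain/GO-term counts, the connected-component size
#' distribution, the degree histogram, and the main-sub-graph means of
#' degree, shortest path length, and clustering coefficient.
#'
#' @param pon A `pon` object.
#' @param domain2go Optional domain-to-GO mapping (tibble or named list);
#'   used only to count distinct GO terms annotating domains present in the
#'   network.
#' @param sample_sources Passed to [shortest_path_stats()] for the main
#'   sub-graph (default exact).
#' @param seed Seed for path-length source sampling.
#' @return A `pon_summary` object: a list with counts, `subgraph_sizes`,
#'   `degree_histogram` (tibble), `mean_degree`, `mean_path_length` and
#'   `mean_clustering` (main sub-graph).
#' @export
network_summary <- function(pon, domain2go = NULL, sample_sources = "all",
                            seed = 1L) {
  comps <- pon_components(pon)
  main <- comps[[1]]
  deg <- pon_degree(pon)
  n_go <- 0L
  if (!is.null(domain2go)) {
    map <- as_d2g_list(domain2go)
    present <- intersect(names(map), names(pon$domain_index))
    n_go <- length(unique(unlist(map[present], use.names = FALSE)))
  }
  cc <- vapply(main, function(p) clustering_coefficient(pon, p), numeric(1))
  structure(list(
    n_proteins = length(pon$protein_index),
    n_domains = length(pon$domain_index),
    n_go_terms = n_go,
    subgraph_sizes = lengths(comps),
    degree_histogram = tibble::as_tibble(table(degree = deg)) |>
      dplyr::mutate(degree = as.integer(.data$degree)) |>
      dplyr::rename(n_nodes = "n"),
    main_size = length(main),
    mean_degree = mean(deg[main]),
    mean_path_length = shortest_path_stats(pon, main, sample_sources, seed),
    mean_clustering = if (all(is.na(cc))) NA_real_ else mean(cc, na.rm = TRUE)
  ), class = "pon_summary")
}

#' @export
print.pon <- function(x, ...) {
  cat(sprintf(
    "<pon> %d proteins, %d domains, %d genome(s)\n",
    length(x$protein_index), length(x$domain_index),
    length(unique(x$genome_of))
  ))
  invisible(x)
}

#' @export
print.pon_summary <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<pon_summary> %d proteins, %d domains, %d GO terms\n",
      "  components: %d (main sub-graph: %d nodes)\n",
      "  main sub-graph means: degree %.2f, path length %.3f, clustering %.3f\n"
    ),
    x$n_proteins, x$n_domains, x$n_go_terms, length(x$subgraph_sizes),
    x$main_size, x$mean_degree, x$mean_path_length, x$mean_clustering
  ))
  invisible(x)
}

#' Tidy a protein overlap network into a node table
#'
#' @param x A `pon` object.
#' @param ... Unused.
#' @return A tibble with one row per protein: `protein_id`, `genome`,
#'   `degree`, `n_domains`, `component` (1 = main sub-graph) and
#'   `component_size`.
#' @exportS3Method generics::tidy
tidy.pon <- function(x, ...) {
  comps <- pon_components(x)
  comp_of <- rep(seq_along(comps), lengths(comps))
  names(comp_of) <- unlist(comps, use.names = FALSE)
  ids <- names(x$protein_index)
  tibble::tibble(
    protein_id = ids,
    genome = unname(x$genome_of[ids]),
    degree = unname(pon_degree(x)),
    n_domains = unname(lengths(x$protein_index)),
    component = unname(comp_of[ids]),
    component_size = lengths(comps)[unname(comp_of[ids])]
  )
}

#' One-row topology summary of a network
#'
#' @param x A `pon` object.
#' @param domain2go Optional domain-to-GO mapping for the GO-term count.
#' @param ... Passed to [network_summary()].
#' @return A one-row tibble with the [network_summary()] scalars.
#' @exportS3Method generics::glance
glance.pon <- function(x, domain2go = NULL, ...) {
  s <- network_summary(x, domain2go, ...)
  tibble::tibble(
    n_proteins = s$n_proteins, n_domains = s$n_domains,
    n_go_terms = s$n_go_terms, n_components = length(s$subgraph_sizes),
    main_size = s$main_size, mean_degree = s$mean_degree,
    mean_path_length = s$mean_path_length,
    mean_clustering = s$mean_clustering
  )
}

#' Degree-distribution plot of a network
#'
#' Log-log scatter of the number of nodes at each degree value, the
#' standard diagnostic for PONs (which show large same-degree clusters from
#' cliques of proteins with identical domain composition).
#'
#' @param object A `pon` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pon <- function(object, ...) {
  h <- tibble::as_tibble(table(degree = pon_degree(object))) |>
    dplyr::mutate(degree = as.integer(.data$degree)) |>
    dplyr::filter(.data$degree > 0)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$degree, y = .data$n)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree", y = "number of nodes",
                  title = "PON degree distribution")
}
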