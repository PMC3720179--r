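# Fixture builders shared across test files. Everything is generated in
# code; no fixture files are stored.

protein_table <- function(ids, domains, genome = "toy") {
  tibble::tibble(protein_id = ids, genome = genome, domains = domains)
}

# Path graph P1 - P2 - ... - Pn: consecutive proteins share one domain.
chain_table <- function(n, genome = "chain") {
  domains <- lapply(seq_len(n), function(i) {
    d <- character(0)
    if (i > 1) d <- c(d, sprintf("D%03d", i - 1))
    if (i < n) d <- c(d, sprintf("D%03d", i))
    d
  })
  protein_table(sprintf("P%03d", seq_len(n)), domains, genome)
}

# k proteins all sharing one domain: a complete graph.
clique_table <- function(k, genome = "clique") {
  protein_table(sprintf("P%03d", seq_len(k)),
                rep(list("DALL"), k), genome)
}

# Star: center holds one private domain per leaf.
star_table <- function(n_leaves, genome = "star") {
  leaf_doms <- sprintf("D%03d", seq_len(n_leaves))
  protein_table(
    c("CTR", sprintf("L%02d", seq_len(n_leaves))),
    c(list(leaf_doms), as.list(leaf_doms)),
    genome
  )
}

# Unstructured random protein-domain table (independent of the package's
# module-structured generator) for oracle-equivalence tests.
random_table <- function(n_proteins, n_domains, seed, max_per = 4,
                         p_empty = 0.05, genome = "rnd") {
  withr::with_seed(seed, {
    domains <- sprintf("R%03d", seq_len(n_domains))
    sets <- lapply(seq_len(n_proteins), function(i) {
      if (runif(1) < p_empty) return(character(0))
      sort(sample(domains, sample.int(max_per, 1)))
    })
    protein_table(sprintf("P%04d", seq_len(n_proteins)), sets, genome)
  })
}

# Random domain->GO map over the domains of a protein table.
random_d2g <- function(tbl, n_go, seed, p_annotated = 0.8, max_per = 3) {
  doms <- sort(unique(unlist(tbl$domains)))
  withr::with_seed(seed, {
    gos <- sprintf("GO:%07d", seq_len(n_go))
    sets <- lapply(doms, function(d) {
      if (runif(1) > p_annotated) return(character(0))
      sort(sample(gos, sample.int(max_per, 1)))
    })
    names(sets) <- doms
    sets[lengths(sets) > 0]
  })
}

# Random protein->GO (GOA-style) map.
random_goa <- function(tbl, n_go, seed, p_annotated = 0.8, max_per = 4) {
  withr::with_seed(seed, {
    gos <- sprintf("GO:%07d", seq_len(n_go))
    sets <- lapply(tbl$protein_id, function(p) {
      if (runif(1) > p_annotated) return(character(0))
      sort(sample(gos, sample.int(max_per, 1)))
    })
    names(sets) <- tbl$protein_id
    sets[lengths(sets) > 0]
  })
}
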