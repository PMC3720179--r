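# Synthetic genome generator. Emulates the three annotation inputs
# (protein-domain table, domain->GO mapping, GAF) with planted module
# structure: domains are partitioned into modules, proteins draw their
# domain combinations from one module (with power-law domain popularity and
# an occasional cross-module domain providing long-distance connections),
# and every domain of a module shares the module's GO-term pool, blurred by
# a configurable noise rate. With zero noise and no cross-module draws the
# modules are perfectly coherent: every GO term reachable through the
# neighborhood of a query belongs to the query's own truth set, which gives
# the generator a known perfect-information limit.

#' Specification of a synthetic genome
#'
#' @param n_proteins Number of proteins.
#' @param n_domains Number of distinct domain accessions.
#' @param n_go_terms Size of the GO-term universe.
#' @param domains_per_protein Mean number of domains per protein; per-protein
#'   counts are drawn as `1 + Geometric`, truncated to the module size
#'   (mean 2.5 by default, matching the few-domain architecture of real
#'   eukaryotic proteins).
#' @param domain_popularity Power-law exponent of domain reuse within a
#'   module: the weight of the r-th domain is `r^-exponent`, so larger
#'   values concentrate edges on a few hub domains (0 = uniform).
#' @param go_per_domain Size of each module's GO pool; with zero noise every
#'   domain of a module is annotated with exactly this pool.
#' @param module_structure Number of planted modules into which domains (and
#'   GO pools) are partitioned.
#' @param cross_module_rate Probability that a drawn domain is replaced by a
#'   uniformly random domain from any module, creating the sparse
#'   long-distance connections between otherwise dense modules.
#' @param noise_rate Fraction of domain-GO assignments replaced by a random
#'   term from the whole universe; the same rate governs extra per-protein
#'   GOA terms not explained by any domain.
#' @param genome Genome label.
#' @param seed Integer seed; topology, annotation and noise use independent
#'   substreams derived from it.
#' @return A `synthetic_genome_spec` list.
#' @export
synthetic_genome_spec <- function(n_proteins = 200, n_domains = 100,
                                  n_go_terms = 60, domains_per_protein = 2.5,
                                  domain_popularity = 0.8, go_per_domain = 3,
                                  module_structure = 12,
                                  cross_module_rate = 0.02, noise_rate = 0.05,
                                  genome = "synthetic", seed = 1L) {
  spec <- list(
    n_proteins = as.integer(n_proteins), n_domains = as.integer(n_domains),
    n_go_terms = as.integer(n_go_terms),
    domains_per_protein = domains_per_protein,
    domain_popularity = domain_popularity,
    go_per_domain = as.integer(go_per_domain),
    module_structure = as.integer(module_structure),
    cross_module_rate = cross_module_rate, noise_rate = noise_rate,
    genome = genome, seed = as.integer(seed)
  )
  stopifnot(
    spec$n_proteins > 0, spec$n_domains > 0, spec$n_go_terms > 0,
    spec$go_per_domain > 0, spec$module_structure > 0,
    spec$domains_per_protein >= 1,
    spec$noise_rate >= 0, spec$noise_rate <= 1,
    spec$cross_module_rate >= 0, spec$cross_module_rate <= 1
  )
  if (spec$module_structure > spec$n_domains) {
    rlang::abort("more modules than domains")
  }
  if (spec$domains_per_protein > spec$n_domains) {
    rlang::abort("infeasible spec: domains_per_protein exceeds n_domains")
  }
  if (spec$go_per_domain > spec$n_go_terms) {
    rlang::abort("go_per_domain exceeds the GO-term universe")
  }
  structure(spec, class = "synthetic_genome_spec")
}

#' Generate a synthetic annotated genome
#'
#' Produces a `genome_annotation`: the protein-domain table, the
#' domain-to-GO mapping and a GOA-style protein-to-GO table (the union of
#' each protein's domain terms plus per-protein noise terms, emulating
#' functions acquired independently of domain content). Fully reproducible
#' from the spec's seed.
#'
#' @param spec A [synthetic_genome_spec()] (or arguments passed to it via
#'   `...` when `spec` is missing).
#' @param ... Convenience: spec fields forwarded to
#'   [synthetic_genome_spec()].
#' @return A `genome_annotation` object: list with `genome`, `proteins`
#'   (tibble `protein_id`, `genome`, `domains`), `domain2go` (tibble),
#'   `goa` (tibble `protein_id`, `genome`, `go_id`) and `spec`.
#' @examples
#' g <- generate_genome(synthetic_genome_spec(n_proteins = 30, seed = 7))
#' g$proteins
#' @export
generate_genome <- function(spec = synthetic_genome_spec(...), ...) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  domains <- sprintf("PF9%04d", seq_len(spec$n_domains))
  go_universe <- sprintf("GO:%07d", seq_len(spec$n_go_terms))
  modules <- rep_len(seq_len(spec$module_structure), spec$n_domains)

  # -- topology substream: module membership, popularity, protein draws
  topo <- withr::with_seed(derive_seed(spec$seed, "topology"), {
    module_of <- sample(modules)
    by_module <- split(domains, module_of)
    weights <- lapply(by_module, function(d) {
      r <- sample(seq_along(d)) # random popularity ranks within the module
      (r^-spec$domain_popularity) / sum(r^-spec$domain_popularity)
    })
    p_geo <- min(1, 1 / spec$domains_per_protein)
    prot_domains <- lapply(seq_len(spec$n_proteins), function(i) {
      m <- sample.int(spec$module_structure, 1L)
      pool <- by_module[[m]]
      k <- min(1L + rgeom(1L, p_geo), length(pool))
      drawn <- sample(pool, k, prob = weights[[m]])
      cross <- runif(k) < spec$cross_module_rate
      if (any(cross)) {
        drawn[cross] <- sample(domains, sum(cross))
      }
      sort(unique(drawn))
    })
    list(module_of = setNames(module_of, domains), prot_domains = prot_domains)
  })

  # -- annotation substream: module GO pools, coherent domain annotation
  ann <- withr::with_seed(derive_seed(spec$seed, "annotation"), {
    need <- spec$module_structure * spec$go_per_domain
    pool_terms <- if (need <= spec$n_go_terms) {
      sample(go_universe, need)
    } else {
      c(sample(go_universe), sample(go_universe, need - spec$n_go_terms,
                                    replace = TRUE))
    }
    pools <- split(pool_terms, rep_len(seq_len(spec$module_structure),
                                       length(pool_terms)))
    setNames(lapply(domains, function(d) {
      sort(unique(pools[[topo$module_of[[d]]]]))
    }), domains)
  })

  # -- noise substream: assignment noise + per-protein GOA noise
  protein_ids <- sprintf("%s-P%04d", spec$genome, seq_len(spec$n_proteins))
  noisy <- withr::with_seed(derive_seed(spec$seed, "noise"), {
    d2g <- lapply(ann, function(terms) {
      flip <- runif(length(terms)) < spec$noise_rate
      if (any(flip)) terms[flip] <- sample(go_universe, sum(flip),
                                           replace = TRUE)
      sort(unique(terms))
    })
    goa_sets <- lapply(seq_len(spec$n_proteins), function(i) {
      base <- unique(unlist(d2g[topo$prot_domains[[i]]], use.names = FALSE))
      extra <- rpois(1L, spec$noise_rate)
      if (extra > 0L) base <- c(base, sample(go_universe, min(extra,
                                             spec$n_go_terms)))
      sort(unique(base))
    })
    list(d2g = d2g, goa = setNames(goa_sets, protein_ids))
  })

  proteins <- tibble::tibble(
    protein_id = protein_ids,
    genome = spec$genome,
    domains = topo$prot_domains
  )
  goa_tbl <- tibble::tibble(
    protein_id = rep(protein_ids, lengths(noisy$goa)),
    genome = spec$genome,
    go_id = unlist(noisy$goa, use.names = FALSE)
  )
  structure(list(
    genome = spec$genome,
    proteins = proteins,
    domain2go = d2g_tibble(noisy$d2g),
    goa = goa_tbl,
    spec = spec
  ), class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf(
    "<genome_annotation> '%s': %d proteins, %d annotated domains, %d GOA rows\n",
    x$genome, nrow(x$proteins), length(unique(x$domain2go$domain)),
    nrow(x$goa)
  ))
  invisible(x)
}

#' Mask a protein's annotations to create an evaluation case
#'
#' Emulates a query of unknown function: the GO associations of the query's
#' own domains are removed from the mapping handed to the prediction path,
#' while the ground truth (the union of those associations, untouched) is
#' returned alongside. Equivalent to the common-domain exclusion rule, but
#' expressed as data so any predictor can be tested against it.
#'
#' @param genome A `genome_annotation`.
#' @param held_out_protein Protein ID to mask.
#' @return A list with `query`, `truth` (character vector) and
#'   `domain2go_masked` (tibble without the query's domains).
#' @export
plant_query_case <- function(genome, held_out_protein) {
  stopifnot(inherits(genome, "genome_annotation"))
  row <- which(genome$proteins$protein_id == held_out_protein)
  if (length(row) != 1L) {
    rlang::abort(sprintf("protein '%s' is not in genome '%s'",
                         held_out_protein, genome$genome))
  }
  doms <- genome$proteins$domains[[row]]
  truth <- sort(unique(
    genome$domain2go$go_id[genome$domain2go$domain %in% doms]
  ))
  list(
    query = held_out_protein,
    truth = truth,
    domain2go_masked = dplyr::filter(genome$domain2go,
                                     !.data$domain %in% doms)
  )
}
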