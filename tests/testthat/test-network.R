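test_that("the edge rule connects exactly the domain-sharing protein pairs", {
  net <- build_pon(protein_table(
    c("P1", "P2", "P3"), list("A", c("A", "B"), "B")
  ))
  expect_equal(pon_neighbors(net, "P1"), "P2")
  expect_equal(pon_neighbors(net, "P2"), c("P1", "P3"))
  expect_equal(pon_neighbors(net, "P3"), "P2")

  # k proteins with one common domain: complete sub-graph, single edges
  k <- 6
  net <- build_pon(clique_table(k))
  expect_true(all(pon_degree(net) == k - 1))

  # protein with no domains is isolated
  net <- build_pon(protein_table(c("P1", "P4"), list("A", character(0))))
  expect_equal(pon_neighbors(net, "P4"), character(0))
  expect_equal(unname(pon_degree(net, "P4")), 0L)

  expect_error(build_pon(protein_table(character(0), list())), "empty")
})

test_that("index consistency holds after build and merge", {
  check_indices <- function(net) {
    for (p in names(net$protein_index)) {
      for (d in net$protein_index[[p]]) {
        expect_true(p %in% net$domain_index[[d]])
      }
    }
    for (d in names(net$domain_index)) {
      for (p in net$domain_index[[d]]) {
        expect_true(d %in% net$protein_index[[p]])
      }
    }
  }
  net <- build_pon(random_table(50, 20, seed = 1))
  check_indices(net)
  other <- build_pon(random_table(30, 10, seed = 2, genome = "rnd2"))
  # rename to keep ids disjoint
  names(other$protein_index) <- sub("^P", "Q", names(other$protein_index))
  names(other$genome_of) <- sub("^P", "Q", names(other$genome_of))
  other$domain_index <- lapply(other$domain_index, function(v) sub("^P", "Q", v))
  check_indices(merge_pons(net, other))
})

test_that("neighbors at radius 1 and 2 follow shortest-path distance", {
  net <- build_pon(protein_table(
    c("P1", "P2", "P3", "P4"),
    list("A", c("A", "B"), c("B", "C"), "C")
  ))
  expect_equal(pon_neighbors(net, "P2", 1), c("P1", "P3"))
  expect_equal(pon_neighbors(net, "P2", 2), "P4")
  expect_equal(pon_neighbors(net, "P1", 2), "P3")

  iso <- build_pon(protein_table(c("I", "J"), list(character(0), "Z")))
  expect_equal(pon_neighbors(iso, "I", 1), character(0))
  expect_equal(pon_neighbors(iso, "I", 2), character(0))

  tri <- build_pon(clique_table(3))
  expect_equal(pon_neighbors(tri, "P001", 2), character(0))

  expect_error(pon_neighbors(net, "nope"), "not in the network")
})

test_that("connected components partition the nodes, largest first", {
  net <- build_pon(protein_table(
    c("P1", "P2", "P3"), list("A", "A", "B")
  ))
  expect_equal(pon_components(net), list(c("P1", "P2"), "P3"))

  iso <- build_pon(protein_table(sprintf("P%d", 1:5), rep(list(character(0)), 5)))
  comps <- pon_components(iso)
  expect_length(comps, 5L)
  expect_true(all(lengths(comps) == 1L))
})

test_that("merging networks creates cross-genome edges and is order-insensitive", {
  yeast <- build_pon(protein_table("Y1", list("A"), genome = "yeast"))
  fly <- build_pon(protein_table("F1", list("A"), genome = "fly"))
  comp <- merge_pons(yeast, fly)
  expect_equal(pon_neighbors(comp, "Y1"), "F1")
  expect_equal(unname(comp$genome_of[c("Y1", "F1")]), c("yeast", "fly"))

  # identity and node-count additivity
  expect_equal(merge_pons(yeast, yeast), yeast)
  worm <- build_pon(protein_table("W1", list("B"), genome = "worm"))
  m <- merge_pons(yeast, fly, worm)
  expect_equal(length(m$protein_index), 3L)

  # associative and commutative up to index equality
  left <- merge_pons(merge_pons(yeast, fly), worm)
  right <- merge_pons(yeast, merge_pons(fly, worm))
  perm <- merge_pons(worm, yeast, fly)
  norm <- function(p) {
    ids <- sort(names(p$protein_index))
    list(p$protein_index[ids], p$domain_index[sort(names(p$domain_index))],
         p$genome_of[ids])
  }
  expect_equal(norm(left), norm(right))
  expect_equal(norm(left), norm(perm))

  clash <- build_pon(protein_table("Y1", list("Z"), genome = "yeast"))
  expect_error(merge_pons(yeast, clash), "conflicting")
})

test_that("clustering coefficient matches closed forms on cliques, stars, trees", {
  tri <- build_pon(clique_table(3))
  expect_equal(clustering_coefficient(tri, "P001"), 1)

  star <- build_pon(star_table(3))
  expect_equal(clustering_coefficient(star, "CTR"), 0)
  expect_true(is.na(clustering_coefficient(star, "L01"))) # degree 1

  for (k in c(4, 7)) {
    cl <- build_pon(clique_table(k))
    cc <- vapply(sprintf("P%03d", 1:k), function(p)
      clustering_coefficient(cl, p), numeric(1))
    expect_equal(unname(cc), rep(1, k))
  }
  # trees have clustering 0 wherever defined
  ch <- build_pon(chain_table(8))
  cc <- vapply(sprintf("P%03d", 2:7), function(p)
    clustering_coefficient(ch, p), numeric(1))
  expect_equal(unname(cc), rep(0, 6))
})

test_that("mean shortest path length of a path graph is (n+1)/3 exactly", {
  for (n in 3:50) {
    net <- build_pon(chain_table(n))
    comp <- pon_components(net)[[1]]
    expect_equal(shortest_path_stats(net, comp), (n + 1) / 3)
  }
  cl <- build_pon(clique_table(9))
  expect_equal(shortest_path_stats(cl, pon_components(cl)[[1]]), 1)
  expect_error(
    shortest_path_stats(build_pon(protein_table(c("A1", "B1"), list("A", "B"))),
                        c("A1", "B1")),
    "connected"
  )
})

test_that("degree, components, clustering and paths match the brute-force oracle", {
  skip_if_not_installed("igraph")
  for (seed in 1:6) {
    tbl <- random_table(n_proteins = 60 + 20 * seed, n_domains = 25, seed = seed)
    net <- build_pon(tbl)

    expect_equal(pon_degree(net)[tbl$protein_id], oracle_degree(tbl))
    expect_equal(pon_components(net), oracle_components(tbl))

    cc_pkg <- vapply(tbl$protein_id, function(p)
      clustering_coefficient(net, p), numeric(1))
    cc_orc <- oracle_clustering(tbl)
    expect_equal(is.na(cc_pkg), is.na(cc_orc) | is.nan(cc_orc))
    ok <- !is.na(cc_pkg)
    expect_equal(cc_pkg[ok], cc_orc[ok])

    main <- pon_components(net)[[1]]
    expect_equal(shortest_path_stats(net, main), oracle_mean_path(tbl, main))
  }
})

test_that("network summary assembles counts and main-sub-graph means", {
  tbl <- clique_table(3)
  net <- build_pon(tbl)
  s <- network_summary(net, list(DALL = "GO:0000001"))
  expect_equal(s$n_proteins, 3L)
  expect_equal(s$n_domains, 1L)
  expect_equal(s$n_go_terms, 1L)
  expect_equal(s$mean_degree, 2)
  expect_equal(s$mean_path_length, 1)
  expect_equal(s$mean_clustering, 1)
  expect_equal(sum(s$subgraph_sizes), s$n_proteins)

  expect_equal(network_summary(net, list())$n_go_terms, 0L)

  skip_if_not_installed("igraph")
  tbl <- random_table(80, 30, seed = 99)
  net <- build_pon(tbl)
  s <- network_summary(net)
  expect_equal(sum(s$subgraph_sizes), nrow(tbl))
  expect_equal(unname(s$subgraph_sizes), lengths(oracle_components(tbl)))
  main <- oracle_components(tbl)[[1]]
  expect_equal(s$mean_path_length, oracle_mean_path(tbl, main))
  cc <- oracle_clustering(tbl)[main]
  expect_equal(s$mean_clustering, mean(cc[!is.nan(cc)]))
  expect_equal(s$mean_degree, mean(oracle_degree(tbl)[main]))
})

test_that("tidy and glance expose the node table and topology scalars", {
  tbl <- random_table(40, 15, seed = 3)
  net <- build_pon(tbl)
  td <- tidy(net)
  expect_equal(nrow(td), 40L)
  expect_true(all(td$component_size[td$component == 1] ==
                    max(td$component_size)))
  expect_equal(sort(td$degree), sort(unname(oracle_degree(tbl))))
  gl <- glance(net)
  expect_equal(gl$n_proteins, 40L)
  expect_true(gl$mean_clustering >= 0 && gl$mean_clustering <= 1)
})
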