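d2g_toy <- list(
  C = "GO:0000001",
  D = c("GO:0000001", "GO:0000002"),
  A = "GO:0000003"
)
toy_net <- build_pon(protein_table(
  c("Q", "N1", "N2"), list(c("A", "B"), c("A", "C"), c("A", "D"))
))

test_that("direct mode counts distinct domain types and excludes shared domains", {
  p <- predict_domain_direct(toy_net, d2g_toy, "Q")
  expect_equal(setNames(p$frequency, p$go_id),
               c("GO:0000001" = 2L, "GO:0000002" = 1L))
  expect_equal(p$supporting[[1]], c("C", "D"))
  expect_false("GO:0000003" %in% p$go_id) # only on the shared domain A

  # common-domain rule: a term on both a shared and a non-shared domain is
  # kept, but the shared domain does not add to its count
  d2g2 <- modifyList(d2g_toy, list(A = c("GO:0000003", "GO:0000001")))
  p2 <- predict_domain_direct(toy_net, d2g2, "Q")
  expect_equal(p2$frequency[p2$go_id == "GO:0000001"], 2L)
  expect_false("A" %in% p2$supporting[[which(p2$go_id == "GO:0000001")]])

  # favorable mode counts the shared domains too
  p3 <- predict_domain_direct(toy_net, d2g2, "Q",
                              prediction_config(include_shared_domains = TRUE))
  expect_equal(p3$frequency[p3$go_id == "GO:0000001"], 3L)
  expect_equal(p3$frequency[p3$go_id == "GO:0000003"], 1L)
})

test_that("queries without usable neighbors give empty predictions, not errors", {
  net <- build_pon(protein_table(c("S", "T"), list("X", "Y")))
  p <- predict_domain_direct(net, list(X = "GO:0000009"), "S")
  expect_equal(nrow(p), 0L)
  expect_error(predict_domain_direct(net, list(), "nope"), "not in the network")
})

test_that("second-layer mode uses only domains absent from query and neighbors", {
  chain <- build_pon(protein_table(
    c("Q", "N1", "N2"), list(c("A", "B"), c("B", "C"), c("C", "D"))
  ))
  p <- predict_domain_second_layer(chain, list(D = "GO:0000004"), "Q")
  expect_equal(setNames(p$frequency, p$go_id), c("GO:0000004" = 1L))

  # a second immediate neighbor carrying D removes D from the candidates
  chain2 <- build_pon(protein_table(
    c("Q", "N1", "N2", "N3"),
    list(c("A", "B"), c("B", "C"), c("C", "D"), c("A", "D"))
  ))
  p2 <- predict_domain_second_layer(chain2, list(D = "GO:0000004"), "Q")
  expect_equal(nrow(p2), 0L)
})

test_that("GOA mode counts neighbor proteins and honors genome exclusion", {
  net <- build_pon(protein_table(
    c("Q", "P1", "P2", "P3"),
    list("A", c("A", "B"), c("A", "C"), c("A", "D"))
  ))
  goa <- list(P1 = "GO:0000001", P2 = c("GO:0000001", "GO:0000002"),
              Q = "GO:0000007")
  p <- predict_goa(net, goa, "Q")
  expect_equal(setNames(p$frequency, p$go_id),
               c("GO:0000001" = 2L, "GO:0000002" = 1L))
  expect_equal(p$supporting[[1]], c("P1", "P2"))
  expect_false("GO:0000007" %in% p$go_id) # own annotations never used

  # leave-one-genome-out removes every neighbor of that genome
  p2 <- predict_goa(net, goa, "Q", exclude = "toy")
  expect_equal(nrow(p2), 0L)
})

test_that("frequencies in all three modes equal the nested-loop oracle", {
  for (seed in 1:8) {
    tbl <- random_table(50, 18, seed = seed, max_per = 3)
    d2g <- random_d2g(tbl, 25, seed = seed + 100)
    goa <- random_goa(tbl, 25, seed = seed + 200)
    net <- build_pon(tbl)
    queries <- withr::with_seed(seed, sample(tbl$protein_id, 8))
    for (q in queries) {
      expect_equal(
        pred_freqs(predict_domain_direct(net, d2g, q)),
        oracle_count_direct(tbl, d2g, q),
        info = sprintf("direct seed=%d q=%s", seed, q)
      )
      expect_equal(
        pred_freqs(predict_domain_direct(
          net, d2g, q, prediction_config(include_shared_domains = TRUE)
        )),
        oracle_count_direct(tbl, d2g, q, include_shared = TRUE),
        info = sprintf("direct-shared seed=%d q=%s", seed, q)
      )
      expect_equal(
        pred_freqs(predict_domain_second_layer(net, d2g, q)),
        oracle_count_second(tbl, d2g, q),
        info = sprintf("second seed=%d q=%s", seed, q)
      )
      expect_equal(
        pred_freqs(predict_goa(net, goa, q)),
        oracle_count_goa(tbl, goa, q),
        info = sprintf("goa seed=%d q=%s", seed, q)
      )
    }
  }
})

test_that("occurrence frequency always equals the supporting-set size", {
  tbl <- random_table(60, 20, seed = 31)
  d2g <- random_d2g(tbl, 30, seed = 32)
  net <- build_pon(tbl)
  preds <- predict_genome(net, d2g, "domain_direct")
  expect_true(all(preds$frequency == lengths(preds$supporting)))
  # supporting sets never intersect the query's own domains in default mode
  for (i in seq_len(nrow(preds))) {
    expect_length(
      intersect(preds$supporting[[i]],
                net$protein_index[[preds$protein_id[[i]]]]),
      0
    )
  }
})

test_that("rank_and_truncate keeps certain terms and fills ties reproducibly", {
  entries <- tibble::tibble(go_id = c("GO:0000001", "GO:0000002"),
                            frequency = c(3L, 1L))
  expect_equal(rank_and_truncate(entries, 1, seed = 5), "GO:0000001")
  expect_equal(rank_and_truncate(tibble::tibble(
    go_id = "GO:0000001", frequency = 1L
  ), 5, seed = 5), "GO:0000001") # fewer terms than k: all returned

  tied <- tibble::tibble(
    go_id = sprintf("GO:%07d", 1:3), frequency = rep(2L, 3)
  )
  first <- rank_and_truncate(tied, 2, seed = 11)
  expect_length(first, 2L)
  expect_identical(rank_and_truncate(tied, 2, seed = 11), first)
  # input row order must not matter
  expect_identical(rank_and_truncate(tied[c(3, 1, 2), ], 2, seed = 11), first)
  # some seed yields a different tied subset/order
  alts <- vapply(1:40, function(s)
    paste(rank_and_truncate(tied, 2, seed = s), collapse = ","), character(1))
  expect_gt(length(unique(alts)), 1L)
})

test_that("raising min_domain_types only ever removes candidate terms", {
  tbl <- random_table(80, 20, seed = 55, max_per = 4)
  d2g <- random_d2g(tbl, 20, seed = 56)
  net <- build_pon(tbl)
  cfgs <- lapply(c(1, 4, 16), function(m)
    prediction_config(min_domain_types = m))
  for (q in withr::with_seed(57, sample(tbl$protein_id, 12))) {
    ps <- lapply(cfgs, function(cf) predict_domain_direct(net, d2g, q, cf))
    expect_true(all(ps[[2]]$go_id %in% ps[[1]]$go_id))
    expect_true(all(ps[[3]]$go_id %in% ps[[2]]$go_id))
    expect_true(nrow(ps[[1]]) >= nrow(ps[[2]]))
    expect_true(nrow(ps[[2]]) >= nrow(ps[[3]]))
  }
})

test_that("identical seeds give byte-identical outputs, different seeds may differ", {
  tbl <- random_table(40, 10, seed = 77, max_per = 3)
  d2g <- random_d2g(tbl, 6, seed = 78) # few GO terms: many ties
  net <- build_pon(tbl)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_predictions(predict_genome(net, d2g, "domain_direct",
                                   config = prediction_config(seed = 9)), f1)
  write_predictions(predict_genome(net, d2g, "domain_direct",
                                   config = prediction_config(seed = 9)), f2)
  expect_identical(readBin(f1, "raw", 1e6), readBin(f2, "raw", 1e6))
})
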