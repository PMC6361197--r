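test_that("correlation P values follow the exact t-transform", {
  # boundary behaviours
  expect_equal(pearson_pvalue(0, 10), 1)
  expect_warning(p1 <- pearson_pvalue(1, 5), "\\|r\\| = 1")
  expect_equal(p1, .Machine$double.xmin)

  # r = 0.9 at n = 10 sits just below a 5e-4 cutoff
  p09 <- pearson_pvalue(0.9, 10)
  tstat <- 0.9 * sqrt(8 / (1 - 0.81))
  expect_equal(p09, oracle_t_pvalue(tstat, 8), tolerance = 1e-9)
  expect_lt(p09, 5e-4)
  expect_gt(p09, 3e-4)
  # while r = 0.7 at n = 10 is rejected by the same cutoff
  expect_gt(pearson_pvalue(0.7, 10), 5e-4)

  # independent cross-check against cor.test over a grid
  set.seed(7)
  for (i in 1:20) {
    n <- sample(4:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    r <- cor(x, y)
    expect_equal(pearson_pvalue(r, n), cor.test(x, y)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("correlation P is strictly decreasing in |r| and in n", {
  rs <- seq(0.1, 0.95, by = 0.05)
  ps <- vapply(rs, pearson_pvalue, numeric(1), n = 10)
  expect_true(all(diff(ps) < 0))
  ns <- 3:30
  pn <- vapply(ns, function(n) pearson_pvalue(0.5, n), numeric(1))
  expect_true(all(diff(pn) < 0))
})

test_that("correlation P agrees with a permutation null within Monte-Carlo error", {
  set.seed(123)
  x <- rnorm(10)
  y <- 0.6 * x + rnorm(10, 0, 0.8)   # moderate |r|
  r <- cor(x, y)
  p_analytic <- pearson_pvalue(r, 10)
  B <- 2e4
  p_perm <- perm_pvalue_cor(x, y, B = B, seed = 99)
  # MC error plus a small allowance for the finite-sample gap between the
  # conditional permutation distribution of r and the t distribution at
  # n = 10 (a few percent relative; see the methods vignette)
  mc_se <- sqrt(p_analytic * (1 - p_analytic) / B)
  expect_lt(abs(p_perm - p_analytic), 4 * mc_se + 0.05 * p_analytic + 1 / B)
})

test_that("pearson correlation matches the raw product-moment formula and its symmetries", {
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  expect_equal(cor(x, y), oracle_pearson(x, y), tolerance = 1e-12)
  expect_equal(oracle_pearson(x, y), 0.8, tolerance = 1e-12)  # exact: 16/20
  expect_equal(cor(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(cor(c(1, 2, 3), c(6, 4, 2)), -1)
  set.seed(5)
  a <- rnorm(8); b <- rnorm(8)
  expect_equal(cor(a, b), cor(b, a))
  expect_equal(cor(a, -b), -cor(a, b))
  expect_equal(cor(a, 3 * b + 7), cor(a, b), tolerance = 1e-12)
})

test_that("a noise-free planted block yields exactly its lncRNA x mRNA pairs as edges", {
  # all-positive loadings: y is proportional to x on the linear scale, so
  # the linear-intensity screen recovers the blocks exactly
  run <- recovery_run(17, noise_sd = 1e-6, neg_member = FALSE)
  expect_setequal(run$detected, run$planted)
  expect_true(all(run$net$edges$sign == "POSITIVE"))
  expect_equal(run$net$n_pairs_tested, 800)

  # an anti-correlated member is exactly linear on the log2 scale (it is a
  # reciprocal curve on the linear scale); the log-scale screen recovers it
  run_neg <- recovery_run(17, noise_sd = 1e-6, neg_member = TRUE,
                          log_scale = TRUE)
  expect_setequal(run_neg$detected, run_neg$planted)
  key <- paste(run_neg$net$edges$lncrna_id, run_neg$net$edges$mrna_id)
  tkey <- paste(run_neg$truth$edge_table$lncrna_id,
                run_neg$truth$edge_table$mrna_id)
  expect_identical(run_neg$net$edges$sign[match(tkey, key)],
                   run_neg$truth$edge_table$expected_sign)
})

test_that("relaxing either threshold never removes an edge", {
  design <- synthetic_design(n_lncrna = 6, n_mrna = 40, de_fraction = 0.3,
                             seed = 23)
  em <- simulate_expression(design)$matrix
  lnc <- transcripts_of(em, "LNCRNA"); mr <- transcripts_of(em, "MRNA")
  strict <- coexpression_network(em, lnc, mr, pcc_min = 0.9, p_max = 5e-4)
  loose <- coexpression_network(em, lnc, mr, pcc_min = 0.8, p_max = 5e-3)
  k_s <- paste(strict$edges$lncrna_id, strict$edges$mrna_id)
  k_l <- paste(loose$edges$lncrna_id, loose$edges$mrna_id)
  expect_true(all(k_s %in% k_l))
  expect_true(all(abs(strict$edges$pcc) > 0.9))
  expect_true(all(strict$edges$p_value < 5e-4))
  expect_identical(strict$edges$sign, ifelse(strict$edges$pcc > 0,
                                             "POSITIVE", "NEGATIVE"))
})

test_that("zero-variance transcripts are skipped with a warning, not fatal", {
  em <- small_em()
  em$values["M2", ] <- 4  # constant
  expect_warning(
    net <- coexpression_network(em, "L1", c("M1", "M2"), pcc_min = 0.5,
                                p_max = 0.99),
    "zero-variance.*M2")
  expect_equal(net$n_pairs_skipped, 1)
  expect_equal(net$n_pairs_tested, 2)
  expect_error(coexpression_network(em, "L9", "M1"), "absent")
})

test_that("degree summary reports per-node degrees and all tied argmaxes", {
  net <- toy_net(edge_df(c("L1", "L1"), c("M1", "M2")))
  ds <- degree_summary(net)
  expect_equal(ds$table$degree[ds$table$node == "L1"], 2)
  expect_equal(ds$table$degree[ds$table$node == "M1"], 1)
  expect_identical(ds$max_lncrna, "L1")
  expect_equal(ds$max_lncrna_degree, 2)
  expect_identical(ds$max_mrna, c("M1", "M2"))  # tie reported in full

  empty <- toy_net(edge_df(character(0), character(0), numeric(0)))
  ds0 <- degree_summary(empty)
  expect_equal(nrow(ds0$table), 0)
  expect_length(ds0$max_lncrna, 0)
})

test_that("negative edges are exactly the sign-NEGATIVE subset", {
  e <- edge_df(c("L1", "L2", "L2"), c("M1", "M1", "M2"),
               pcc = c(0.95, -0.93, 0.91))
  net <- toy_net(e)
  neg <- negative_edges(net)
  expect_equal(nrow(neg), 1)
  expect_identical(neg$lncrna_id, "L2")
  expect_identical(neg$mrna_id, "M1")
  all_pos <- toy_net(edge_df("L1", "M1", 0.95))
  expect_equal(nrow(negative_edges(all_pos)), 0)
})

test_that("planted anti-correlated members always come out as NEGATIVE edges", {
  for (seed in 1:5) {
    run <- recovery_run(seed, log_scale = TRUE)
    tkey <- paste(run$truth$edge_table$lncrna_id, run$truth$edge_table$mrna_id)
    neg_planted <- tkey[run$truth$edge_table$expected_sign == "NEGATIVE"]
    ekey <- paste(run$net$edges$lncrna_id, run$net$edges$mrna_id)
    found <- intersect(neg_planted, ekey)
    if (length(found) > 0)
      expect_true(all(run$net$edges$sign[match(found, ekey)] == "NEGATIVE"))
  }
})

test_that("connected components partition the node set, largest first", {
  net <- toy_net(edge_df(c("L1", "L2"), c("M1", "M2")))
  comps <- network_components(net)
  expect_length(comps, 2)
  expect_equal(lengths(comps), c(2L, 2L))
  expect_identical(comps[[1]], c("L1", "M1"))  # tie broken by smallest id

  one <- network_components(toy_net(edge_df("L1", "M1")))
  expect_identical(one, list(c("L1", "M1")))

  # satellite: a block disconnected from a larger one
  net2 <- toy_net(edge_df(c("L1", "L1", "L1", "L2"),
                          c("M1", "M2", "M3", "M9")))
  comps2 <- network_components(net2)
  expect_equal(lengths(comps2), c(4L, 2L))
  expect_identical(comps2[[2]], c("L2", "M9"))
  # union = node set, pairwise disjoint
  allnodes <- unlist(comps2)
  expect_identical(sort(allnodes),
                   sort(c(net2$lncrna_nodes, net2$mrna_nodes)))
  expect_false(anyDuplicated(allnodes) > 0)
})
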