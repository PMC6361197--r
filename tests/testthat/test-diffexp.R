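test_that("fold change is the unsigned mean ratio with a signed log2 companion", {
  f <- fold_change(c(16, 16), c(2, 2))
  expect_equal(f$fold_change, 8)
  expect_equal(f$log2_fold_change, 3)
  f <- fold_change(c(2, 2), c(16, 16))
  expect_equal(f$fold_change, 8)
  expect_equal(f$log2_fold_change, -3)
  f <- fold_change(c(3, 5), c(3, 5))
  expect_equal(f$fold_change, 1)
  expect_equal(f$log2_fold_change, 0)
  expect_error(fold_change(c(1, -1), c(1, 1)), "strictly positive")
})

test_that("fold change identities hold on random positive data", {
  set.seed(101)
  for (i in 1:50) {
    xt <- 2^rnorm(5, 8); xn <- 2^rnorm(5, 8)
    f <- fold_change(xt, xn)
    expect_gte(f$fold_change, 1)
    expect_equal(f$fold_change, 2^abs(f$log2_fold_change), tolerance = 1e-12)
  }
})

test_that("t-test P matches numerical integration of the t density", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 6)
  p <- t_test_pvalue(a, b, log_scale = FALSE)
  # pooled-variance Student's t by hand, then the independent CDF oracle
  sp2 <- (4 * var(a) + 4 * var(b)) / 8
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  expect_equal(p, oracle_t_pvalue(tstat, 8), tolerance = 1e-9)

  expect_equal(t_test_pvalue(c(1, 2, 3), c(1, 2, 3), log_scale = FALSE), 1)

  shifted <- c(10, 11, 12, 13, 14)
  p_sep <- t_test_pvalue(shifted + 100 + rnorm(5, 0, 1e-3), shifted,
                         log_scale = FALSE)
  expect_lt(p_sep, 1e-6)
})

test_that("t-test P tracks the exhaustive 5v5 label-permutation null", {
  # all choose(10, 5) = 252 relabelings; the permutation P is exact for the
  # data at hand, the t P assumes normality - they agree up to the usual
  # percent-level finite-sample gap at this n
  set.seed(61)
  for (rep in 1:5) {
    pooled <- rnorm(10, mean = 8, sd = 1) + rep(c(0.8, 0), each = 5)
    obs_t <- abs(stats::t.test(pooled[1:5], pooled[6:10],
                               var.equal = TRUE)$statistic)
    combos <- utils::combn(10, 5)
    t_perm <- apply(combos, 2, function(idx)
      abs(stats::t.test(pooled[idx], pooled[-idx],
                        var.equal = TRUE)$statistic))
    p_perm <- mean(t_perm >= obs_t - 1e-12)
    p_t <- t_test_pvalue(2^pooled[1:5], 2^pooled[6:10])  # log2 undone inside
    expect_lt(abs(p_perm - p_t), 0.02 + 0.1 * p_t)
  }
})

test_that("degenerate zero-variance inputs resolve to 1 or the smallest positive P", {
  expect_equal(t_test_pvalue(c(2, 2), c(2, 2), log_scale = FALSE), 1)
  expect_warning(p <- t_test_pvalue(c(4, 4), c(2, 2), log_scale = FALSE),
                 "zero within-group variance")
  expect_equal(p, .Machine$double.xmin)
})

test_that("volcano boundaries: fold change inclusive, P strict", {
  # t1: exactly 2-fold up with tight within-group spread -> UP
  # t2: 1.99-fold with tiny P -> UNCHANGED (below the FC threshold)
  v <- rbind(
    t1 = c(1.9, 2.0, 2.1, 0.95, 1.00, 1.05) * 10,
    t2 = c(1.99, 1.99, 1.99, 1, 1, 1) * 10 + rep(c(0.001, 0, -0.001), 2),
    t3 = c(5, 5.1, 4.9, 5, 5.1, 4.9))
  colnames(v) <- c("T1", "T2", "T3", "N1", "N2", "N3")
  em <- expression_matrix(
    v, sample_group = setNames(rep(c("TUMOR", "NORMAL"), each = 3),
                               colnames(v)),
    transcript_class = c(t1 = "MRNA", t2 = "MRNA", t3 = "LNCRNA"))
  screen <- volcano_screen(em, fc_min = 2, alpha = 0.05)
  r <- screen$records
  expect_equal(r$fold_change[r$transcript_id == "t1"], 2, tolerance = 1e-12)
  expect_identical(r$regulation[r$transcript_id == "t1"], "UP")
  expect_lt(r$p_value[r$transcript_id == "t2"], 1e-4)
  expect_lt(r$fold_change[r$transcript_id == "t2"], 2)
  expect_identical(r$regulation[r$transcript_id == "t2"], "UNCHANGED")
  # counts tallied per class
  expect_equal(screen$counts["UP", "MRNA"], 1)
  expect_equal(sum(screen$counts), 1)
})

test_that("swapping group labels flips log2 fold changes and UP/DOWN, P unchanged", {
  design <- synthetic_design(n_lncrna = 10, n_mrna = 40, de_fraction = 0.3,
                             seed = 21)
  em <- simulate_expression(design)$matrix
  flipped <- em
  flipped$sample_group <- factor(
    ifelse(em$sample_group == "TUMOR", "NORMAL", "TUMOR"),
    levels = c("TUMOR", "NORMAL"))
  names(flipped$sample_group) <- names(em$sample_group)
  s1 <- volcano_screen(em)
  s2 <- volcano_screen(flipped)
  expect_equal(s2$records$log2_fold_change, -s1$records$log2_fold_change)
  expect_equal(s2$records$p_value, s1$records$p_value)
  expect_identical(s2$records$regulation == "UP", s1$records$regulation == "DOWN")
  expect_equal(s2$counts["UP", ], s1$counts["DOWN", ])
})

test_that("well-separated groups split at the top of the sample dendrogram", {
  design <- synthetic_design(n_lncrna = 10, n_mrna = 90, de_fraction = 0.3,
                             fc_range = c(4, 10), noise_sd = 0.2, seed = 31)
  sim <- simulate_expression(design)
  cl <- cluster_expression(sim$matrix, de_transcripts(volcano_screen(sim$matrix)))
  split <- top_split(cl)
  split <- split[order(vapply(split, `[`, character(1), 1))]
  expect_setequal(split[[grep("^N", vapply(split, `[`, character(1), 1))]],
                  samples_of(sim$matrix, "NORMAL"))
  expect_setequal(split[[grep("^T", vapply(split, `[`, character(1), 1))]],
                  samples_of(sim$matrix, "TUMOR"))
})

test_that("clustering handles a singleton transcript axis and rejects unknown ids", {
  em <- small_em()
  cl <- cluster_expression(em, "L1")
  expect_identical(cl$transcript_order, "L1")
  expect_null(cl$transcript_hclust)
  expect_length(cl$sample_order, 6)
  expect_error(cluster_expression(em, c("L1", "nope")), "nope")
})

test_that("BH-adjusted column is monotone and bounded", {
  design <- synthetic_design(n_lncrna = 5, n_mrna = 45, de_fraction = 0.2,
                             seed = 41)
  screen <- volcano_screen(simulate_expression(design)$matrix)
  r <- screen$records
  expect_true(all(r$p_adj_bh >= r$p_value - 1e-15))
  expect_true(all(r$p_adj_bh <= 1))
  ord <- order(r$p_value)
  expect_true(all(diff(r$p_adj_bh[ord]) >= -1e-15))
})
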