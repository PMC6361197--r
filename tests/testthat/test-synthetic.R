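test_that("simulation is reproducible from the seed and responsive to it", {
  design <- synthetic_design(n_lncrna = 10, n_mrna = 80, seed = 11,
                             blocks = list(coexpression_block(
                               c("lnc001", "GENE001", "GENE002"))))
  a <- simulate_expression(design)
  b <- simulate_expression(design)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth, b$truth)

  design2 <- synthetic_design(n_lncrna = 10, n_mrna = 80, seed = 12)
  expect_false(identical(simulate_expression(design2)$matrix$values,
                         a$matrix$values))
})

test_that("near-zero noise recovers planted log2 fold changes exactly", {
  design <- synthetic_design(n_lncrna = 5, n_mrna = 95, de_fraction = 0.2,
                             fc_range = c(8, 8), noise_sd = 1e-9, seed = 3)
  sim <- simulate_expression(design)
  screen <- volcano_screen(sim$matrix)
  truth <- sim$truth$de_table
  expect_equal(nrow(truth), 20)
  expect_setequal(de_transcripts(screen), truth$transcript_id)
  rec <- screen$records[match(truth$transcript_id, screen$records$transcript_id), ]
  expect_equal(abs(rec$log2_fold_change), rep(3, 20), tolerance = 1e-6)
  expect_identical(rec$regulation, truth$direction)
})

test_that("a single all-positive block drives within-block correlations to 1", {
  ids <- c("lnc001", paste0("GENE00", 1:5))
  design <- synthetic_design(n_lncrna = 1, n_mrna = 5, de_fraction = 0,
                             noise_sd = 1e-6,
                             blocks = list(coexpression_block(
                               ids, loadings = rep(1, 6), factor_sd = 2)),
                             seed = 5)
  sim <- simulate_expression(design)
  cc <- cor(t(log2(sim$matrix$values)))
  expect_true(all(cc > 0.999))
})

test_that("block members must exist among generated transcripts", {
  design <- synthetic_design(n_lncrna = 2, n_mrna = 3,
                             blocks = list(coexpression_block(
                               c("lnc001", "GENE999"))))
  expect_error(simulate_expression(design), "GENE999")
})

test_that("planted edge table joins block members with the loading-product sign", {
  run <- recovery_run(1)
  tr <- run$truth$edge_table
  expect_true(all(grepl("^lnc", tr$lncrna_id)))
  expect_true(all(grepl("^GENE", tr$mrna_id)))
  # block 1 has one negative-loading mRNA member -> its lncRNA pairs negative
  expect_true(any(tr$expected_sign == "NEGATIVE"))
  expect_true(all(tr$expected_sign %in% c("POSITIVE", "NEGATIVE")))
})

test_that("synthetic Ct tables reproduce planted fold changes at zero noise", {
  design <- synthetic_design(n_lncrna = 4, n_mrna = 16, de_fraction = 0.5,
                             fc_range = c(2, 10), seed = 9)
  sim <- simulate_expression(design)
  ct <- simulate_ct_table(sim$truth, design, ct_noise_sd = 0)
  for (i in seq_len(nrow(sim$truth$de_table))) {
    g <- sim$truth$de_table$transcript_id[i]
    r <- ddct(ct, g)
    expect_equal(max(r$ratio, 1 / r$ratio),
                 sim$truth$de_table$true_fold_change[i], tolerance = 1e-12)
    expect_identical(r$direction, sim$truth$de_table$direction[i])
  }
  # reference gene quantifies to exactly 1
  expect_equal(ddct(ct, "ACTB")$ratio, 1)
  # deterministic given the seed
  ct2 <- simulate_ct_table(sim$truth, design, ct_noise_sd = 0)
  expect_identical(ct$rows, ct2$rows)
})
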