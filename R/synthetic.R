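#' Describe a synthetic two-group expression study
#'
#' Captures the design the simulator realizes: two groups of samples
#' (defaults 5 tumor + 5 normal, the usual scale of FFPE microarray
#' comparisons), lncRNA and mRNA counts, a fraction of transcripts planted
#' as differentially expressed with linear fold changes drawn from
#' `fc_range`, log2-scale Gaussian noise, and optional co-expression blocks
#' driven by shared latent factors (see [coexpression_block()]).
#'
#' @param n_tumor,n_normal samples per group (each >= 2).
#' @param n_lncrna,n_mrna transcript counts per class.
#' @param de_fraction fraction of transcripts planted as DE (in \[0,1\]).
#' @param fc_range length-2 numeric, min/max planted linear fold change;
#'   min >= 1 (default `c(2, 10)` so every planted transcript clears a
#'   2-fold screen).
#' @param noise_sd SD of i.i.d. Gaussian noise on the log2 scale (> 0).
#' @param blocks list of [coexpression_block()] objects.
#' @param seed integer seed; all randomness in the simulator flows from it.
#' @return object of class `synthetic_design`.
#' @export
synthetic_design <- function(n_tumor = 5, n_normal = 5,
                             n_lncrna = 10, n_mrna = 90,
                             de_fraction = 0.2,
                             fc_range = c(2, 10),
                             noise_sd = 0.1,
                             blocks = list(),
                             seed = 1L) {
  stopifnot(n_tumor >= 2, n_normal >= 2,
            n_lncrna >= 0, n_mrna >= 1,
            de_fraction >= 0, de_fraction <= 1,
            length(fc_range) == 2, fc_range[1] >= 1,
            fc_range[2] >= fc_range[1],
            noise_sd > 0)
  if (length(blocks) > 0 &&
      !all(vapply(blocks, inherits, logical(1), "coexpression_block")))
    stop("`blocks` must be a list of coexpression_block objects")
  structure(list(n_tumor = n_tumor, n_normal = n_normal,
                 n_lncrna = n_lncrna, n_mrna = n_mrna,
                 de_fraction = de_fraction, fc_range = fc_range,
                 noise_sd = noise_sd, blocks = blocks,
                 seed = as.integer(seed)),
            class = "synthetic_design")
}

#' Define a planted co-expression block
#'
#' Each block owns one latent factor, drawn per sample from
#' `Normal(0, factor_sd)`. Every member transcript adds
#' `loading * factor` to its log2 intensity, so within-block pairs are
#' linearly correlated; a negative loading plants an anti-correlated member
#' (its pairs with positive-loading members get negative Pearson r).
#'
#' @param member_ids >= 2 transcript ids; blocks meant to yield
#'   lncRNA-mRNA edges should contain at least one of each class.
#' @param loadings signed numeric per member, `|loading|` in (0, 1].
#' @param factor_sd SD of the shared latent factor on the log2 scale.
#' @return object of class `coexpression_block`.
#' @export
coexpression_block <- function(member_ids, loadings = rep(1, length(member_ids)),
                               factor_sd = 2) {
  stopifnot(length(member_ids) >= 2,
            length(loadings) == length(member_ids),
            all(abs(loadings) > 0), all(abs(loadings) <= 1),
            factor_sd > 0)
  structure(list(member_ids = as.character(member_ids),
                 loadings = as.numeric(loadings),
                 factor_sd = factor_sd),
            class = "coexpression_block")
}

#' Default transcript id scheme for the simulator
#' @noRd
.synth_ids <- function(design) {
  list(lnc = sprintf("lnc%03d", seq_len(design$n_lncrna)),
       mrna = sprintf("GENE%03d", seq_len(design$n_mrna)))
}

#' Simulate an expression matrix with ground truth
#'
#' Generates log2 intensities as
#' `baseline(t) + de_shift(t) * [sample is TUMOR] + loading(t) * factor(block(t), sample) + eps`,
#' with `eps ~ Normal(0, noise_sd)`, then returns the matrix on the linear
#' scale (`2^log2`). Planted DE transcripts are a simple random sample of
#' size `round(de_fraction * n_transcripts)`; their log2 shifts are
#' `+/- log2(U)` with `U ~ Uniform(fc_range)` and random sign. Ground truth
#' records every planted fold change/direction and every planted
#' lncRNA-mRNA edge (all within-block lncRNA x mRNA pairs, expected sign =
#' sign of the loading product). Fully reproducible from `design$seed`.
#'
#' @param design a [synthetic_design()]. Block member ids must use the
#'   generated id scheme (`lnc001...`, `GENE001...`) or an error is raised.
#' @return list with `matrix` (an `expr_matrix`) and `truth`, a list of
#'   `de_table` (transcript_id, true_fold_change, direction) and
#'   `edge_table` (lncrna_id, mrna_id, expected_sign).
#' @export
simulate_expression <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  set.seed(design$seed)

  ids <- .synth_ids(design)
  transcripts <- c(ids$lnc, ids$mrna)
  n_t <- length(transcripts)
  samples <- c(sprintf("T%02d", seq_len(design$n_tumor)),
               sprintf("N%02d", seq_len(design$n_normal)))
  is_tumor <- rep(c(TRUE, FALSE), c(design$n_tumor, design$n_normal))

  for (b in design$blocks) {
    missing <- setdiff(b$member_ids, transcripts)
    if (length(missing) > 0)
      stop(sprintf("block member(s) not among generated transcripts: %s",
                   paste(missing, collapse = ", ")))
  }

  baseline <- stats::rnorm(n_t, mean = 8, sd = 1)

  n_de <- round(design$de_fraction * n_t)
  de_ids <- if (n_de > 0) sort(sample(transcripts, n_de)) else character(0)
  de_shift <- setNames(numeric(n_t), transcripts)
  true_fc <- direction <- NULL
  if (n_de > 0) {
    fc <- stats::runif(n_de, design$fc_range[1], design$fc_range[2])
    up <- sample(c(TRUE, FALSE), n_de, replace = TRUE)
    de_shift[de_ids] <- ifelse(up, log2(fc), -log2(fc))
    true_fc <- fc
    direction <- ifelse(up, "UP", "DOWN")
  }

  log2v <- matrix(baseline, n_t, length(samples),
                  dimnames = list(transcripts, samples))
  log2v <- log2v + outer(de_shift, as.numeric(is_tumor))

  edge_tab <- list()
  for (b in design$blocks) {
    f <- stats::rnorm(length(samples), 0, b$factor_sd)
    log2v[b$member_ids, ] <- log2v[b$member_ids, , drop = FALSE] +
      outer(b$loadings, f)
    lnc_m <- intersect(b$member_ids, ids$lnc)
    mr_m <- intersect(b$member_ids, ids$mrna)
    if (length(lnc_m) > 0 && length(mr_m) > 0) {
      pairs <- expand.grid(lncrna_id = lnc_m, mrna_id = mr_m,
                           stringsAsFactors = FALSE)
      ld <- setNames(b$loadings, b$member_ids)
      pairs$expected_sign <- ifelse(
        ld[pairs$lncrna_id] * ld[pairs$mrna_id] > 0, "POSITIVE", "NEGATIVE")
      edge_tab[[length(edge_tab) + 1]] <- pairs
    }
  }
  edge_table <- if (length(edge_tab) > 0)
    unique(do.call(rbind, edge_tab))
  else
    data.frame(lncrna_id = character(0), mrna_id = character(0),
               expected_sign = character(0), stringsAsFactors = FALSE)
  rownames(edge_table) <- NULL

  log2v <- log2v + matrix(stats::rnorm(length(log2v), 0, design$noise_sd),
                          nrow = n_t)

  em <- expression_matrix(
    2^log2v,
    sample_group = setNames(ifelse(is_tumor, "TUMOR", "NORMAL"), samples),
    transcript_class = setNames(rep(c("LNCRNA", "MRNA"),
                                    c(design$n_lncrna, design$n_mrna)),
                                transcripts))

  de_table <- data.frame(transcript_id = de_ids,
                         true_fold_change = if (n_de > 0) true_fc else numeric(0),
                         direction = if (n_de > 0) direction else character(0),
                         stringsAsFactors = FALSE)

  list(matrix = em, truth = list(de_table = de_table, edge_table = edge_table))
}

#' Simulate a qRT-PCR Ct table matching planted fold changes
#'
#' Cycle thresholds are generated so that the Livak `2^-ddCt` estimator
#' recovers each gene's planted fold change up to Gaussian Ct noise: the
#' reference gene has zero group shift, and each target gene's tumor Ct is
#' shifted by `-log2(fold change)` (one cycle earlier per doubling) for UP
#' genes, `+log2(fold change)` for DOWN genes. At `ct_noise_sd = 0` the
#' recovery is exact.
#'
#' @param truth ground truth from [simulate_expression()] (needs `de_table`).
#' @param design the [synthetic_design()] that produced it (sample layout
#'   and seed).
#' @param genes gene ids to measure; default all transcripts in `de_table`.
#' @param reference_gene id of the reference (internal control), default
#'   `"ACTB"`; it is added to the table with zero group shift.
#' @param ct_noise_sd SD of Gaussian noise added to every Ct, in cycles.
#' @return a `ct_table` (see [ct_table()]).
#' @export
simulate_ct_table <- function(truth, design, genes = NULL,
                              reference_gene = "ACTB", ct_noise_sd = 0) {
  stopifnot(inherits(design, "synthetic_design"))
  de <- truth$de_table
  if (is.null(genes)) genes <- de$transcript_id
  if (length(genes) == 0) stop("no genes to simulate")
  unknown <- setdiff(genes, de$transcript_id)
  if (length(unknown) > 0)
    stop(sprintf("gene(s) without planted direction: %s",
                 paste(unknown, collapse = ", ")))
  set.seed(design$seed + 1L)  # distinct stream from the matrix

  samples <- c(sprintf("T%02d", seq_len(design$n_tumor)),
               sprintf("N%02d", seq_len(design$n_normal)))
  is_tumor <- rep(c(TRUE, FALSE), c(design$n_tumor, design$n_normal))

  shift <- setNames(numeric(length(genes)), genes)
  idx <- match(genes, de$transcript_id)
  shift[] <- ifelse(de$direction[idx] == "UP", 1, -1) *
    log2(de$true_fold_change[idx])

  all_genes <- c(reference_gene, genes)
  base_ct <- setNames(c(18, stats::runif(length(genes), 22, 30)), all_genes)

  rows <- expand.grid(sample_id = samples, gene_id = all_genes,
                      stringsAsFactors = FALSE)
  tumor_of <- setNames(is_tumor, samples)
  g_shift <- c(setNames(0, reference_gene), shift)
  rows$ct <- base_ct[rows$gene_id] -
    g_shift[rows$gene_id] * as.numeric(tumor_of[rows$sample_id]) +
    stats::rnorm(nrow(rows), 0, ct_noise_sd)

  ct_table(rows,
           reference_gene = reference_gene,
           sample_group = setNames(ifelse(is_tumor, "TUMOR", "NORMAL"), samples))
}
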