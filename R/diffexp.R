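#' Linear fold change between two groups
#'
#' Fold change is the ratio of arithmetic group means of linear intensities,
#' reported two ways: `fold_change`, the unsigned ratio
#' `max(m_t/m_n, m_n/m_t) >= 1`, and `log2_fold_change`, the signed
#' `log2(m_t/m_n)` (tumor over normal).
#'
#' @param x_tumor,x_normal nonempty vectors of strictly positive linear
#'   intensities.
#' @return list with `fold_change` and `log2_fold_change`;
#'   `fold_change == 2^abs(log2_fold_change)`.
#' @examples
#' fold_change(c(16, 16), c(2, 2))  # fold 8, log2fc +3
#' @export
fold_change <- function(x_tumor, x_normal) {
  stopifnot(length(x_tumor) >= 1, length(x_normal) >= 1)
  if (any(x_tumor <= 0) || any(x_normal <= 0))
    stop("intensities must be strictly positive")
  m_t <- mean(x_tumor)
  m_n <- mean(x_normal)
  if (m_t <= 0 || m_n <= 0) stop("non-positive group mean")
  list(fold_change = max(m_t / m_n, m_n / m_t),
       log2_fold_change = log2(m_t / m_n))
}

#' Two-sample Student's t-test P value
#'
#' Two-sided t-test of equal group means. By default the pooled
#' (equal-variance) Student statistic is used on log2-transformed
#' intensities — the conventional volcano-plot configuration, where the log
#' transform stabilizes microarray variance. `var_equal = FALSE` switches to
#' Welch; `log_scale = FALSE` tests the linear intensities.
#'
#' Degenerate input is resolved rather than propagated: when both groups
#' are constant, equal means give P = 1 and unequal means give the smallest
#' representable positive P with a warning (perfect separation has no
#' finite t statistic).
#'
#' @param x_tumor,x_normal vectors of length >= 2, strictly positive when
#'   `log_scale = TRUE`.
#' @param log_scale test on log2 intensities (default `TRUE`).
#' @param var_equal pooled-variance Student's t (default `TRUE`).
#' @return two-sided P value in (0, 1].
#' @export
t_test_pvalue <- function(x_tumor, x_normal, log_scale = TRUE,
                          var_equal = TRUE) {
  stopifnot(length(x_tumor) >= 2, length(x_normal) >= 2)
  if (log_scale) {
    if (any(x_tumor <= 0) || any(x_normal <= 0))
      stop("log-scale testing needs strictly positive intensities")
    x_tumor <- log2(x_tumor)
    x_normal <- log2(x_normal)
  }
  if (stats::var(x_tumor) == 0 && stats::var(x_normal) == 0) {
    if (isTRUE(all.equal(mean(x_tumor), mean(x_normal)))) return(1)
    warning("zero within-group variance with unequal means; returning smallest positive P")
    return(.Machine$double.xmin)
  }
  stats::t.test(x_tumor, x_normal, var.equal = var_equal)$p.value
}

#' Volcano-filter differential-expression screen
#'
#' Screens every transcript of a two-group matrix with the joint
#' fold-change / P-value rule used for volcano plots: a transcript is
#' called `UP` when its fold change is at least `fc_min` (inclusive, so a
#' transcript at exactly 2.0 passes a 2-fold screen), its t-test P value is
#' strictly below `alpha`, and its tumor mean exceeds its normal mean;
#' `DOWN` symmetrically; everything else is `UNCHANGED`. P values are raw —
#' the screen does not adjust for multiple testing — but a
#' Benjamini-Hochberg column is reported alongside for inspection.
#'
#' @param em an [expression_matrix()].
#' @param fc_min minimum linear fold change (default 2).
#' @param alpha P-value cutoff (default 0.05, strict).
#' @param log_scale,var_equal passed to [t_test_pvalue()].
#' @return object of class `de_screen`: list with `records` (data frame:
#'   transcript_id, class, fold_change, log2_fold_change, p_value,
#'   p_adj_bh, regulation), `thresholds`, and `counts` (matrix of UP/DOWN
#'   per transcript class).
#' @export
volcano_screen <- function(em, fc_min = 2, alpha = 0.05,
                           log_scale = TRUE, var_equal = TRUE) {
  stopifnot(inherits(em, "expr_matrix"), fc_min >= 1, alpha > 0, alpha <= 1)
  t_idx <- em$sample_group == "TUMOR"
  n_idx <- em$sample_group == "NORMAL"

  n <- nrow(em$values)
  fc <- l2 <- p <- numeric(n)
  for (i in seq_len(n)) {
    xt <- em$values[i, t_idx]
    xn <- em$values[i, n_idx]
    f <- fold_change(xt, xn)
    fc[i] <- f$fold_change
    l2[i] <- f$log2_fold_change
    p[i] <- t_test_pvalue(xt, xn, log_scale = log_scale,
                          var_equal = var_equal)
  }
  regulation <- rep("UNCHANGED", n)
  hit <- fc >= fc_min & p < alpha
  regulation[hit & l2 > 0] <- "UP"
  regulation[hit & l2 < 0] <- "DOWN"

  records <- data.frame(
    transcript_id = rownames(em$values),
    class = as.character(em$transcript_class),
    fold_change = fc,
    log2_fold_change = l2,
    p_value = p,
    p_adj_bh = stats::p.adjust(p, method = "BH"),
    regulation = regulation,
    stringsAsFactors = FALSE)

  counts <- vapply(c("LNCRNA", "MRNA"), function(cl)
    c(UP = sum(regulation == "UP" & records$class == cl),
      DOWN = sum(regulation == "DOWN" & records$class == cl)),
    numeric(2))

  structure(list(records = records,
                 thresholds = list(fc_min = fc_min, alpha = alpha),
                 counts = counts,
                 settings = list(log_scale = log_scale,
                                 var_equal = var_equal)),
            class = "de_screen")
}

#' Transcript ids called differentially expressed
#'
#' @param x a `de_screen`.
#' @param class restrict to a transcript class (`"LNCRNA"`, `"MRNA"`) or
#'   `NULL` for all.
#' @param direction `"UP"`, `"DOWN"`, or `NULL` for both.
#' @return character vector of transcript ids.
#' @export
de_transcripts <- function(x, class = NULL, direction = NULL) {
  stopifnot(inherits(x, "de_screen"))
  r <- x$records
  keep <- r$regulation != "UNCHANGED"
  if (!is.null(class)) keep <- keep & r$class == class
  if (!is.null(direction)) keep <- keep & r$regulation == direction
  r$transcript_id[keep]
}

#' @export
print.de_screen <- function(x, ...) {
  cat(sprintf("de_screen: %d transcripts, thresholds FC >= %g, P < %g\n",
              nrow(x$records), x$thresholds$fc_min, x$thresholds$alpha))
  cat(sprintf("  LNCRNA: %d up, %d down\n",
              x$counts["UP", "LNCRNA"], x$counts["DOWN", "LNCRNA"]))
  cat(sprintf("  MRNA:   %d up, %d down\n",
              x$counts["UP", "MRNA"], x$counts["DOWN", "MRNA"]))
  invisible(x)
}

#' @export
summary.de_screen <- function(object, ...) {
  r <- object$records[object$records$regulation != "UNCHANGED", ]
  r <- r[order(r$p_value, -r$fold_change, r$transcript_id), ]
  rownames(r) <- NULL
  structure(list(screen = object, hits = r), class = "summary.de_screen")
}

#' @export
print.summary.de_screen <- function(x, ...) {
  print(x$screen)
  cat(sprintf("%d differentially expressed transcript(s); strongest first:\n",
              nrow(x$hits)))
  print(utils::head(x$hits, 10), digits = 4)
  invisible(x)
}

#' @export
as.data.frame.de_screen <- function(x, ...) x$records

#' Volcano plot of a differential-expression screen
#'
#' log2 fold change against -log10 P; threshold guide lines at
#' `+/- log2(fc_min)` and `alpha`; UP calls red, DOWN calls blue.
#'
#' @param x a `de_screen`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.de_screen <- function(x, ...) {
  r <- x$records
  col <- ifelse(r$regulation == "UP", "red3",
                ifelse(r$regulation == "DOWN", "blue3", "grey60"))
  graphics::plot(r$log2_fold_change, -log10(r$p_value), col = col, pch = 15,
                 xlab = expression(log[2] ~ "fold change"),
                 ylab = expression(-log[10] ~ italic(P)), ...)
  graphics::abline(v = c(-1, 1) * log2(x$thresholds$fc_min),
                   h = -log10(x$thresholds$alpha),
                   col = "green4", lty = 2)
  invisible(x)
}

#' Hierarchical clustering of samples and transcripts
#'
#' Agglomerative clustering with correlation distance
#' (`1 - Pearson r` across the chosen transcripts) and average linkage —
#' the usual configuration behind two-way expression heatmaps. The
#' clustering is deterministic for a given input ordering. Intensities are
#' log2-transformed before computing correlations.
#'
#' @param em an [expression_matrix()].
#' @param transcripts nonempty subset of transcript ids to cluster on
#'   (typically the DE calls); all must be present in the matrix.
#' @param method linkage passed to [stats::hclust()] (default
#'   `"average"`).
#' @return object of class `expr_clustering`: `sample_order` and
#'   `transcript_order` (leaf orders as ids), plus the two
#'   [stats::hclust()] merge records (`NULL` for a singleton axis).
#' @export
cluster_expression <- function(em, transcripts, method = "average") {
  stopifnot(inherits(em, "expr_matrix"), length(transcripts) >= 1)
  missing <- setdiff(transcripts, rownames(em$values))
  if (length(missing) > 0)
    stop(sprintf("transcript id(s) absent from matrix: %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  m <- log2(em$values[transcripts, , drop = FALSE])

  cl_axis <- function(mat, ids) {
    if (length(ids) == 1) return(list(order = ids, hclust = NULL))
    d <- stats::as.dist(1 - stats::cor(t(mat)))
    d[!is.finite(d)] <- 1  # zero-variance rows: treated as uncorrelated
    h <- stats::hclust(d, method = method)
    list(order = ids[h$order], hclust = h)
  }
  s <- cl_axis(t(m), colnames(m))
  t_ <- cl_axis(m, rownames(m))

  structure(list(sample_order = s$order, transcript_order = t_$order,
                 sample_hclust = s$hclust, transcript_hclust = t_$hclust),
            class = "expr_clustering")
}

#' Sample membership of the two top-level clusters
#'
#' Cuts the sample dendrogram into two clusters, e.g. to check whether the
#' clustering separates tumor from normal samples.
#'
#' @param x an `expr_clustering` with >= 2 samples.
#' @return list of two character vectors of sample ids.
#' @export
top_split <- function(x) {
  stopifnot(inherits(x, "expr_clustering"))
  if (is.null(x$sample_hclust)) stop("need >= 2 samples for a split")
  grp <- stats::cutree(x$sample_hclust, k = 2)
  unname(split(names(grp), grp))
}

#' @export
print.expr_clustering <- function(x, ...) {
  cat(sprintf("expr_clustering: %d samples, %d transcripts (average linkage, 1 - r distance)\n",
              length(x$sample_order), length(x$transcript_order)))
  cat("  sample order:", paste(x$sample_order, collapse = " "), "\n")
  invisible(x)
}
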