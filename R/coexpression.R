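#' Exact P value for a Pearson correlation
#'
#' Two-sided P under the null of zero correlation, via the exact
#' t-transform for bivariate-normal samples:
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom.
#' At the study scale (n = 10) this ties the two network thresholds
#' together: r = 0.9 gives P just below 5e-4.
#'
#' @param r sample Pearson correlation in \[-1, 1\].
#' @param n sample count (>= 3).
#' @return P value in (0, 1]. `|r| = 1` returns the smallest representable
#'   positive value with a warning (the t statistic diverges).
#' @examples
#' pearson_pvalue(0.9, 10)  # ~3.9e-4, just under a 5e-4 cutoff
#' @export
pearson_pvalue <- function(r, n) {
  stopifnot(n >= 3, abs(r) <= 1)
  if (abs(r) == 1) {
    warning("|r| = 1: returning smallest positive P")
    return(.Machine$double.xmin)
  }
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
}

#' Build a thresholded lncRNA-mRNA co-expression network
#'
#' For every (lncRNA, mRNA) candidate pair, computes the sample Pearson
#' correlation of their intensities across ALL samples pooled (both
#' groups), and keeps the pair as an edge when `|r| > pcc_min` and
#' `P < p_max`, both strict. Edge signs record the direction of the
#' correlation. Correlations are computed on the linear normalized
#' intensities by default; `log_scale = TRUE` correlates log2 intensities
#' instead.
#'
#' Pairs involving a zero-variance transcript have no defined correlation;
#' they are skipped with a warning and counted in `n_pairs_skipped` rather
#' than failing the run.
#'
#' @param em an [expression_matrix()].
#' @param lncrna_ids,mrna_ids candidate transcript ids; all must be present
#'   in the matrix (an absent id is an error).
#' @param pcc_min minimum absolute Pearson correlation (default 0.9).
#' @param p_max P-value cutoff (default 5e-4).
#' @param log_scale correlate log2 intensities instead of linear.
#' @return object of class `coexpr_net`: list with `edges` (data frame:
#'   lncrna_id, mrna_id, pcc, p_value, sign), `lncrna_nodes` /
#'   `mrna_nodes` (connected nodes only), `thresholds`, `n_pairs_tested`
#'   (= candidates lncRNAs x candidate mRNAs), `n_pairs_skipped`, and `n`
#'   (sample count).
#' @export
coexpression_network <- function(em, lncrna_ids, mrna_ids,
                                 pcc_min = 0.9, p_max = 5e-4,
                                 log_scale = FALSE) {
  stopifnot(inherits(em, "expr_matrix"),
            length(lncrna_ids) >= 1, length(mrna_ids) >= 1,
            pcc_min >= 0, pcc_min <= 1, p_max > 0, p_max <= 1)
  missing <- setdiff(c(lncrna_ids, mrna_ids), rownames(em$values))
  if (length(missing) > 0)
    stop(sprintf("id(s) absent from matrix: %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  .check_no_dups(lncrna_ids, "candidate lncRNA")
  .check_no_dups(mrna_ids, "candidate mRNA")

  v <- em$values
  if (log_scale) v <- log2(v)
  n <- ncol(v)
  if (n < 3) stop("need >= 3 samples for correlation P values")

  lv <- t(v[lncrna_ids, , drop = FALSE])
  mv <- t(v[mrna_ids, , drop = FALSE])
  sd0_l <- apply(lv, 2, stats::sd) == 0
  sd0_m <- apply(mv, 2, stats::sd) == 0
  n_skip <- sum(sd0_l) * length(mrna_ids) +
    sum(!sd0_l) * sum(sd0_m)
  if (n_skip > 0)
    warning(sprintf("%d pair(s) skipped: zero-variance transcript(s): %s",
                    n_skip,
                    paste(c(lncrna_ids[sd0_l], mrna_ids[sd0_m]),
                          collapse = ", ")))

  cc <- suppressWarnings(stats::cor(lv, mv))  # lnc x mrna

  keep_l <- which(!sd0_l)
  keep_m <- which(!sd0_m)
  edges <- data.frame(lncrna_id = character(0), mrna_id = character(0),
                      pcc = numeric(0), p_value = numeric(0),
                      sign = character(0), stringsAsFactors = FALSE)
  if (length(keep_l) > 0 && length(keep_m) > 0) {
    sub <- cc[keep_l, keep_m, drop = FALSE]
    hit <- which(abs(sub) > pcc_min, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      r <- sub[hit]
      p <- vapply(r, pearson_pvalue, numeric(1), n = n)
      ok <- p < p_max
      if (any(ok)) {
        edges <- data.frame(
          lncrna_id = lncrna_ids[keep_l][hit[ok, 1]],
          mrna_id = mrna_ids[keep_m][hit[ok, 2]],
          pcc = r[ok],
          p_value = p[ok],
          sign = ifelse(r[ok] > 0, "POSITIVE", "NEGATIVE"),
          stringsAsFactors = FALSE)
        edges <- edges[order(edges$lncrna_id, edges$mrna_id), ]
        rownames(edges) <- NULL
      }
    }
  }

  structure(list(edges = edges,
                 lncrna_nodes = sort(unique(edges$lncrna_id)),
                 mrna_nodes = sort(unique(edges$mrna_id)),
                 thresholds = list(pcc_min = pcc_min, p_max = p_max),
                 n_pairs_tested = length(lncrna_ids) * length(mrna_ids),
                 n_pairs_skipped = n_skip,
                 n = n),
            class = "coexpr_net")
}

#' @export
print.coexpr_net <- function(x, ...) {
  cat(sprintf("coexpr_net: %d edge(s) over %d pair(s) tested (|r| > %g, P < %g, n = %d)\n",
              nrow(x$edges), x$n_pairs_tested,
              x$thresholds$pcc_min, x$thresholds$p_max, x$n))
  cat(sprintf("  %d lncRNA node(s), %d mRNA node(s); %d negative edge(s)\n",
              length(x$lncrna_nodes), length(x$mrna_nodes),
              sum(x$edges$sign == "NEGATIVE")))
  if (x$n_pairs_skipped > 0)
    cat(sprintf("  %d pair(s) skipped (zero variance)\n", x$n_pairs_skipped))
  invisible(x)
}

#' @export
summary.coexpr_net <- function(object, ...) {
  deg <- degree_summary(object)
  comp <- network_components(object)
  structure(list(net = object, degrees = deg, components = comp),
            class = "summary.coexpr_net")
}

#' @export
print.summary.coexpr_net <- function(x, ...) {
  print(x$net)
  if (nrow(x$degrees$table) > 0) {
    cat(sprintf("  max-degree lncRNA: %s (%d); max-degree mRNA: %s (%d)\n",
                paste(x$degrees$max_lncrna, collapse = "/"),
                x$degrees$max_lncrna_degree,
                paste(x$degrees$max_mrna, collapse = "/"),
                x$degrees$max_mrna_degree))
    cat(sprintf("  %d connected component(s), sizes: %s\n",
                length(x$components),
                paste(lengths(x$components), collapse = ", ")))
  }
  invisible(x)
}

#' Node degrees of a co-expression network
#'
#' @param net a `coexpr_net`.
#' @return list with `table` (data frame: node, class, degree, sorted by
#'   degree descending then id) and, when the network is nonempty,
#'   `max_lncrna` / `max_mrna` (all argmax nodes per class, ties reported
#'   together) with their degrees.
#' @export
degree_summary <- function(net) {
  stopifnot(inherits(net, "coexpr_net"))
  e <- net$edges
  if (nrow(e) == 0) {
    return(list(table = data.frame(node = character(0), class = character(0),
                                   degree = integer(0),
                                   stringsAsFactors = FALSE),
                max_lncrna = character(0), max_lncrna_degree = NA_integer_,
                max_mrna = character(0), max_mrna_degree = NA_integer_))
  }
  d_l <- table(e$lncrna_id)
  d_m <- table(e$mrna_id)
  tab <- data.frame(
    node = c(names(d_l), names(d_m)),
    class = rep(c("LNCRNA", "MRNA"), c(length(d_l), length(d_m))),
    degree = as.integer(c(d_l, d_m)),
    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$degree, tab$node), ]
  rownames(tab) <- NULL
  list(table = tab,
       max_lncrna = sort(names(d_l)[d_l == max(d_l)]),
       max_lncrna_degree = as.integer(max(d_l)),
       max_mrna = sort(names(d_m)[d_m == max(d_m)]),
       max_mrna_degree = as.integer(max(d_m)))
}

#' Negatively correlated edges of a network
#'
#' @param net a `coexpr_net`.
#' @return the subset of the edge table with `sign == "NEGATIVE"`.
#' @export
negative_edges <- function(net) {
  stopifnot(inherits(net, "coexpr_net"))
  e <- net$edges[net$edges$sign == "NEGATIVE", ]
  rownames(e) <- NULL
  e
}

#' Connected components of a co-expression network
#'
#' Components of the undirected bipartite graph, ordered largest first
#' (ties broken by the lexicographically smallest member id), so that
#' "satellite" sub-networks disconnected from the main component are easy
#' to pick out.
#'
#' @param net a `coexpr_net`.
#' @return list of character vectors (sorted node ids), largest first.
#' @export
network_components <- function(net) {
  stopifnot(inherits(net, "coexpr_net"))
  if (nrow(net$edges) == 0) return(list())
  g <- as_igraph(net)
  comp <- igraph::components(g)
  sets <- split(igraph::V(g)$name, comp$membership)
  sets <- lapply(sets, sort)
  ord <- order(-lengths(sets),
               vapply(sets, `[`, character(1), 1))
  unname(sets[ord])
}

#' Plot a co-expression network
#'
#' lncRNAs as green squares, mRNAs as blue circles; negative edges dashed
#' red.
#'
#' @param x a `coexpr_net`.
#' @param ... passed to [igraph::plot.igraph()].
#' @return invisibly, `x`.
#' @export
plot.coexpr_net <- function(x, ...) {
  if (nrow(x$edges) == 0) {
    graphics::plot.new()
    graphics::title("empty co-expression network")
    return(invisible(x))
  }
  g <- as_igraph(x)
  is_lnc <- igraph::V(g)$type == "lncRNA"
  neg <- igraph::E(g)$pcc < 0
  igraph::plot.igraph(
    g,
    vertex.shape = ifelse(is_lnc, "square", "circle"),
    vertex.color = ifelse(is_lnc, "palegreen3", "skyblue2"),
    vertex.size = 8, vertex.label.cex = 0.6,
    edge.color = ifelse(neg, "red3", "grey50"),
    edge.lty = ifelse(neg, 2, 1), ...)
  invisible(x)
}
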