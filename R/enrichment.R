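#' Hypergeometric upper-tail probability (over-representation P)
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n_selected)`: the chance that
#' a random draw of `n_selected` genes from a universe of `N` (of which `K`
#' belong to the set) overlaps the set in at least `k` genes. This
#' one-sided tail is the standard over-representation test (identical to a
#' one-sided Fisher exact test on the 2x2 overlap table). Computation goes
#' through the numerically stable base distribution function.
#'
#' @param k observed overlap (0 <= k <= min(n_selected, K)).
#' @param n_selected query-list size.
#' @param K set size in the universe.
#' @param N universe size.
#' @return P value in (0, 1]; `k = 0` gives exactly 1.
#' @examples
#' hypergeom_tail(5, 5, 5, 20)  # 1 / choose(20, 5)
#' @export
hypergeom_tail <- function(k, n_selected, K, N) {
  stopifnot(length(k) == 1, length(n_selected) == 1,
            length(K) == 1, length(N) == 1)
  if (k < 0 || n_selected < 0 || K < 0 || N < 1 ||
      n_selected > N || K > N || k > min(n_selected, K))
    stop("inconsistent hypergeometric counts")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n_selected, lower.tail = FALSE)
}

#' Over-representation analysis of a gene list
#'
#' Tests every set of a collection for over-representation of the query
#' list via [hypergeom_tail()], keeping sets with at least one overlapping
#' gene. Query genes outside the universe are dropped with a warning (and
#' counted). Records are ranked by ascending raw P value — the ranking used
#' for "top enriched terms" bar charts — with ties broken by descending
#' overlap then set name; Benjamini-Hochberg adjusted P values are reported
#' as an extra column but do not drive the ranking or the `top_k` cut.
#'
#' @param query nonempty character vector of gene ids.
#' @param sets a [gene_sets()] collection.
#' @param top_k number of top records to return (default 20); `Inf` for
#'   all.
#' @return object of class `enrich_result`: a data frame with columns
#'   set_name, k (overlap), n_selected, K (set size), N (universe size),
#'   p_value, p_adj_bh, neg_log10_p; attribute `n_dropped` counts query
#'   genes outside the universe.
#' @export
enrich <- function(query, sets, top_k = 20) {
  stopifnot(inherits(sets, "gene_sets"), top_k >= 1)
  query <- unique(as.character(query))
  if (length(query) == 0) stop("empty query")
  eff <- intersect(query, sets$universe)
  n_dropped <- length(query) - length(eff)
  if (n_dropped > 0)
    warning(sprintf("%d query gene(s) outside the universe dropped", n_dropped))
  if (length(eff) == 0)
    stop("no query genes left after universe restriction")

  N <- length(sets$universe)
  n_sel <- length(eff)
  k <- vapply(sets$sets, function(s) length(intersect(s, eff)), integer(1))
  K <- lengths(sets$sets)
  keep <- k >= 1

  res <- data.frame(set_name = names(sets$sets)[keep],
                    k = k[keep],
                    n_selected = rep(n_sel, sum(keep)),
                    K = K[keep],
                    N = rep(N, sum(keep)),
                    stringsAsFactors = FALSE)
  res$p_value <- if (nrow(res) > 0)
    mapply(hypergeom_tail, res$k, res$n_selected, res$K,
           MoreArgs = list(N = N))
  else numeric(0)
  res$p_adj_bh <- stats::p.adjust(res$p_value, method = "BH")
  res$neg_log10_p <- -log10(res$p_value)
  res <- res[order(res$p_value, -res$k, res$set_name), ]
  res <- utils::head(res, top_k)
  rownames(res) <- NULL
  structure(res, class = c("enrich_result", "data.frame"),
            n_dropped = n_dropped)
}

#' @export
print.enrich_result <- function(x, ...) {
  cat(sprintf("enrich_result: %d set(s) with overlap (query n = %s, universe N = %s)\n",
              nrow(x), if (nrow(x)) x$n_selected[1] else "?",
              if (nrow(x)) x$N[1] else "?"))
  if (nrow(x) > 0)
    print.data.frame(utils::head(x, 10), digits = 4)
  invisible(x)
}

#' Bar chart of top enriched sets
#'
#' Horizontal bars of `-log10(P)`, most enriched at the top — the usual
#' presentation of top GO terms / KEGG pathways.
#'
#' @param x an `enrich_result`.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, `x`.
#' @export
plot.enrich_result <- function(x, ...) {
  if (nrow(x) == 0) {
    graphics::plot.new()
    graphics::title("no enriched sets")
    return(invisible(x))
  }
  op <- graphics::par(mar = c(4, 12, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(x$neg_log10_p), names.arg = rev(x$set_name),
                    horiz = TRUE, las = 1,
                    xlab = expression(-log[10] ~ italic(P)), ...)
  invisible(x)
}
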