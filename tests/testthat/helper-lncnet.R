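# Shared fixtures and independent oracles for the test suite.

# Small deterministic two-group matrix: values chosen by hand, no RNG.
small_em <- function() {
  v <- rbind(
    L1 = c(16, 18, 14, 2.0, 2.2, 1.8),   # ~8-fold up
    M1 = c(2.0, 2.2, 1.8, 16, 18, 14),   # ~8-fold down
    M2 = c(5.0, 5.2, 4.8, 5.1, 4.9, 5.0) # flat
  )
  colnames(v) <- c("T1", "T2", "T3", "N1", "N2", "N3")
  expression_matrix(
    v,
    sample_group = setNames(rep(c("TUMOR", "NORMAL"), each = 3), colnames(v)),
    transcript_class = c(L1 = "LNCRNA", M1 = "MRNA", M2 = "MRNA"))
}

# Hand-built network object for topology operations (edges only matter).
toy_net <- function(edges) {
  structure(list(edges = edges,
                 lncrna_nodes = sort(unique(edges$lncrna_id)),
                 mrna_nodes = sort(unique(edges$mrna_id)),
                 thresholds = list(pcc_min = 0.9, p_max = 5e-4),
                 n_pairs_tested = nrow(edges), n_pairs_skipped = 0L,
                 n = 10L),
            class = "coexpr_net")
}

edge_df <- function(lnc, mrna, pcc = rep(0.95, length(lnc))) {
  data.frame(lncrna_id = lnc, mrna_id = mrna, pcc = pcc,
             p_value = rep(1e-5, length(lnc)),
             sign = ifelse(pcc > 0, "POSITIVE", "NEGATIVE"),
             stringsAsFactors = FALSE)
}

# --- independent oracles -------------------------------------------------

# Two-sided t P value by numerical integration of the t density
# (gamma-function form), independent of pt().
oracle_t_pvalue <- function(tstat, df) {
  dens <- function(u) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + u^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, abs(tstat), Inf, rel.tol = 1e-12)$value
}

# Pearson r from raw integer-arithmetic sums (textbook product-moment
# formula), independent of cor().
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

# Permutation P value for a correlation: fraction of label permutations of
# y giving |r| at least as extreme as observed.
perm_pvalue_cor <- function(x, y, B = 1e5, seed = 42) {
  set.seed(seed)
  r_obs <- abs(stats::cor(x, y))
  perm <- replicate(B, sample(y))
  r_perm <- abs(as.numeric(stats::cor(x, perm)))
  mean(r_perm >= r_obs - 1e-12)
}

# Hypergeometric upper tail by direct combinatorial sum over the support.
oracle_hyper_tail <- function(k, n_sel, K, N) {
  if (k == 0) return(1)
  j <- k:min(n_sel, K)
  sum(choose(K, j) * choose(N - K, n_sel - j)) / choose(N, n_sel)
}

# Hypergeometric upper tail by exhaustive enumeration of all draws of size
# n_sel from a universe of N with K marked elements.
enum_hyper_tail <- function(k, n_sel, K, N) {
  if (k == 0) return(1)
  draws <- utils::combn(N, n_sel)
  overlap <- colSums(draws <= K)  # first K elements are the marked set
  mean(overlap >= k)
}

# Edge recovery experiment: planted blocks, no DE, candidates = all
# lncRNA x mRNA pairs. Returns detected and planted edge keys.
recovery_run <- function(seed, noise_sd = 0.1, factor_sd = 2,
                         neg_member = TRUE, log_scale = FALSE) {
  ids <- list(lnc = sprintf("lnc%03d", 1:10), mrna = sprintf("GENE%03d", 1:80))
  blocks <- list(
    coexpression_block(c(ids$lnc[1:2], ids$mrna[1:6]),
                       loadings = c(rep(1, 7), if (neg_member) -1 else 1),
                       factor_sd = factor_sd),
    coexpression_block(c(ids$lnc[3], ids$mrna[7:12]),
                       loadings = rep(1, 7), factor_sd = factor_sd),
    coexpression_block(c(ids$lnc[4:5], ids$mrna[13:16]),
                       loadings = rep(1, 6), factor_sd = factor_sd))
  design <- synthetic_design(n_lncrna = 10, n_mrna = 80, de_fraction = 0,
                             noise_sd = noise_sd, blocks = blocks,
                             seed = seed)
  sim <- simulate_expression(design)
  net <- coexpression_network(sim$matrix, ids$lnc, ids$mrna,
                              log_scale = log_scale)
  list(detected = paste(net$edges$lncrna_id, net$edges$mrna_id),
       planted = paste(sim$truth$edge_table$lncrna_id,
                       sim$truth$edge_table$mrna_id),
       net = net, truth = sim$truth)
}
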