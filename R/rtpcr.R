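#' Construct a qRT-PCR Ct table
#'
#' Long-format cycle-threshold measurements, one row per (sample, gene),
#' with a declared reference gene (internal control) and the tumor/normal
#' group of every sample. Technical replicates are expected to be averaged
#' upstream: duplicate (sample, gene) pairs are an error.
#'
#' @param rows data frame with columns `sample_id`, `gene_id`, `ct`
#'   (cycles, finite).
#' @param reference_gene id of the reference gene; must be measured in
#'   every sample.
#' @param sample_group named character vector mapping every sample id to
#'   `"TUMOR"` or `"NORMAL"`.
#' @return object of class `ct_table`.
#' @export
ct_table <- function(rows, reference_gene, sample_group) {
  stopifnot(is.data.frame(rows),
            all(c("sample_id", "gene_id", "ct") %in% colnames(rows)))
  rows <- rows[, c("sample_id", "gene_id", "ct")]
  rows$sample_id <- as.character(rows$sample_id)
  rows$gene_id <- as.character(rows$gene_id)
  rows$ct <- as.numeric(rows$ct)
  if (any(!is.finite(rows$ct))) stop("non-finite Ct value")
  key <- paste(rows$sample_id, rows$gene_id, sep = "\r")
  if (anyDuplicated(key))
    stop(sprintf("duplicate (sample, gene) measurement: %s",
                 sub("\r", " / ", key[duplicated(key)][1])))

  samples <- unique(rows$sample_id)
  ref_samples <- rows$sample_id[rows$gene_id == reference_gene]
  missing_ref <- setdiff(samples, ref_samples)
  if (length(missing_ref) > 0)
    stop(sprintf("reference gene '%s' not measured in sample(s): %s",
                 reference_gene, paste(missing_ref, collapse = ", ")))

  sample_group <- .check_annotation(sample_group, samples,
                                    c("TUMOR", "NORMAL"), "sample")
  structure(list(rows = rows, reference_gene = reference_gene,
                 sample_group = sample_group),
            class = "ct_table")
}

#' Read a Ct table from TSV
#'
#' @param path TSV with header columns `sample_id`, `gene_id`, `ct`.
#' @param groups_path two-column TSV: sample id, group.
#' @param reference_gene reference gene id (default `"ACTB"`).
#' @return a [ct_table()].
#' @export
read_ct_table <- function(path, groups_path, reference_gene = "ACTB") {
  for (p in c(path, groups_path))
    if (!file.exists(p)) stop(sprintf("file not found: %s", p))
  rows <- utils::read.delim(path, stringsAsFactors = FALSE)
  ct_table(rows, reference_gene = reference_gene,
           sample_group = .read_two_col(groups_path))
}

#' Write a Ct table (and its group map) to TSV
#' @param ct a `ct_table`.
#' @param path,groups_path output paths.
#' @return invisibly, `path`.
#' @export
write_ct_table <- function(ct, path, groups_path) {
  utils::write.table(ct$rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(id = names(ct$sample_group),
               group = as.character(ct$sample_group)),
    groups_path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  invisible(path)
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf("ct_table: %d measurement(s), %d sample(s), %d gene(s); reference '%s'\n",
              nrow(x$rows), length(unique(x$rows$sample_id)),
              length(unique(x$rows$gene_id)), x$reference_gene))
  invisible(x)
}

#' Livak 2^-ddCt relative quantification for one gene
#'
#' Per-sample `dCt = Ct(gene) - Ct(reference)`; `ddCt = mean dCt(tumor) -
#' mean dCt(normal)`; relative expression ratio `2^-ddCt` (tumor over
#' normal, assuming perfect doubling per cycle). Direction is `UP` when the
#' ratio exceeds 1, `DOWN` below 1, `UNCHANGED` at exactly 1. Because dCt
#' subtracts the reference within each sample, a constant Ct offset applied
#' to any one sample (e.g. input-amount differences) cancels out.
#'
#' @param ct a [ct_table()].
#' @param gene gene id, measured in at least one tumor and one normal
#'   sample.
#' @return list of class `relative_expression`: `gene_id`, `ddct`, `ratio`
#'   (`= 2^-ddct`), `log2_ratio` (`= -ddct`), `direction`, and
#'   `per_sample_dct` (named vector, for inspection).
#' @export
ddct <- function(ct, gene) {
  stopifnot(inherits(ct, "ct_table"))
  rows <- ct$rows
  if (!gene %in% rows$gene_id)
    stop(sprintf("gene '%s' absent from Ct table", gene))

  g <- rows[rows$gene_id == gene, ]
  ref <- rows[rows$gene_id == ct$reference_gene, ]
  ref_ct <- setNames(ref$ct, ref$sample_id)
  if (any(!g$sample_id %in% names(ref_ct)))
    stop(sprintf("reference '%s' missing in sample(s) measuring '%s'",
                 ct$reference_gene, gene))
  dct <- setNames(g$ct - ref_ct[g$sample_id], g$sample_id)

  grp <- ct$sample_group[g$sample_id]
  if (sum(grp == "TUMOR") < 1 || sum(grp == "NORMAL") < 1)
    stop(sprintf("gene '%s' needs >= 1 tumor and >= 1 normal measurement", gene))

  dd <- mean(dct[grp == "TUMOR"]) - mean(dct[grp == "NORMAL"])
  ratio <- 2^(-dd)
  structure(list(gene_id = gene, ddct = dd, ratio = ratio,
                 log2_ratio = -dd,
                 direction = if (ratio > 1) "UP" else if (ratio < 1) "DOWN" else "UNCHANGED",
                 per_sample_dct = dct),
            class = "relative_expression")
}

#' @export
print.relative_expression <- function(x, ...) {
  cat(sprintf("%s: ddCt = %.3f, ratio 2^-ddCt = %.3g (%s)\n",
              x$gene_id, x$ddct, x$ratio, x$direction))
  invisible(x)
}

#' Relative expression for several genes
#'
#' @param ct a [ct_table()].
#' @param genes gene ids; defaults to every measured gene except the
#'   reference.
#' @return data frame (gene_id, ddct, ratio, log2_ratio, direction).
#' @export
relative_expression <- function(ct, genes = NULL) {
  stopifnot(inherits(ct, "ct_table"))
  if (is.null(genes))
    genes <- setdiff(unique(ct$rows$gene_id), ct$reference_gene)
  res <- lapply(genes, function(g) {
    r <- ddct(ct, g)
    data.frame(gene_id = r$gene_id, ddct = r$ddct, ratio = r$ratio,
               log2_ratio = r$log2_ratio, direction = r$direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Direction concordance between qPCR and array calls
#'
#' Compares the up/down direction of qPCR relative-expression ratios with
#' the regulation calls of a differential-expression screen, gene by gene.
#'
#' @param pcr data frame from [relative_expression()] (needs `gene_id`,
#'   `direction`), or a list of `relative_expression` objects.
#' @param screen a [volcano_screen()] result; every qPCR gene must appear
#'   in it.
#' @return list with `fraction` (concordant / total) and `table` (per-gene
#'   directions and agreement).
#' @export
concordance <- function(pcr, screen) {
  stopifnot(inherits(screen, "de_screen"))
  if (is.list(pcr) && !is.data.frame(pcr) &&
      all(vapply(pcr, inherits, logical(1), "relative_expression"))) {
    pcr <- do.call(rbind, lapply(pcr, function(r)
      data.frame(gene_id = r$gene_id, direction = r$direction,
                 stringsAsFactors = FALSE)))
  }
  if (!is.data.frame(pcr) || nrow(pcr) == 0)
    stop("nothing to compare: empty qPCR result")
  idx <- match(pcr$gene_id, screen$records$transcript_id)
  if (anyNA(idx))
    stop(sprintf("gene(s) absent from array screen: %s",
                 paste(pcr$gene_id[is.na(idx)], collapse = ", ")))
  tab <- data.frame(gene_id = pcr$gene_id,
                    pcr_direction = pcr$direction,
                    array_direction = screen$records$regulation[idx],
                    stringsAsFactors = FALSE)
  tab$concordant <- tab$pcr_direction == tab$array_direction
  list(fraction = mean(tab$concordant), table = tab)
}
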