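#' Construct a validated two-group expression matrix
#'
#' The central container of the package: a transcripts x samples matrix of
#' normalized intensities (linear scale, strictly positive), together with a
#' sample-group annotation (`TUMOR` / `NORMAL`) and a transcript-class
#' annotation (`LNCRNA` / `MRNA`).
#'
#' Intensities are stored on the linear scale. If the source data are log2
#' intensities, pass `scale = "log2"` and they are exponentiated on input;
#' any log transformation downstream (e.g. for t-tests) is then explicit.
#'
#' @param values numeric matrix with transcript ids as rownames and sample
#'   ids as colnames; all entries finite and strictly positive (after
#'   unlogging when `scale = "log2"`).
#' @param sample_group named character vector mapping every sample id to
#'   `"TUMOR"` or `"NORMAL"`; at least two samples per group.
#' @param transcript_class named character vector mapping every transcript id
#'   to `"LNCRNA"` or `"MRNA"`.
#' @param scale scale of `values` on input: `"linear"` (default) or `"log2"`.
#' @return an object of class `expr_matrix`: a list with elements `values`
#'   (linear-scale matrix), `sample_group` and `transcript_class` (factors
#'   named by id, in matrix order).
#' @examples
#' v <- matrix(2^rnorm(12, 8), 3, 4,
#'             dimnames = list(c("L1", "M1", "M2"), paste0("S", 1:4)))
#' em <- expression_matrix(
#'   v,
#'   sample_group = setNames(c("TUMOR", "TUMOR", "NORMAL", "NORMAL"),
#'                           paste0("S", 1:4)),
#'   transcript_class = c(L1 = "LNCRNA", M1 = "MRNA", M2 = "MRNA"))
#' em
#' @export
expression_matrix <- function(values, sample_group, transcript_class,
                              scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry transcript ids as rownames and sample ids as colnames")

  .check_no_dups(rownames(values), "transcript")
  .check_no_dups(colnames(values), "sample")

  if (scale == "log2") values <- 2^values

  bad <- which(!is.finite(values) | values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-positive or non-finite intensity at transcript '%s', sample '%s'",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))

  sample_group <- .check_annotation(sample_group, colnames(values),
                                    c("TUMOR", "NORMAL"), "sample")
  transcript_class <- .check_annotation(transcript_class, rownames(values),
                                        c("LNCRNA", "MRNA"), "transcript")

  n_per <- table(sample_group)
  if (any(n_per < 2) || length(n_per) < 2)
    stop("each group (TUMOR, NORMAL) needs at least 2 samples")

  structure(list(values = values,
                 sample_group = sample_group,
                 transcript_class = transcript_class),
            class = "expr_matrix")
}

.check_no_dups <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0)
    stop(sprintf("duplicate %s id(s): %s", what,
                 paste(dup, collapse = ", ")))
  invisible(ids)
}

.check_annotation <- function(map, ids, levels, what) {
  if (is.factor(map)) map <- setNames(as.character(map), names(map))
  if (is.null(names(map)))
    stop(sprintf("%s annotation must be a named vector", what))
  missing <- setdiff(ids, names(map))
  if (length(missing) > 0)
    stop(sprintf("unmapped %s id(s): %s", what,
                 paste(utils::head(missing, 5), collapse = ", ")))
  map <- map[ids]
  bad <- setdiff(unique(map), levels)
  if (length(bad) > 0)
    stop(sprintf("invalid %s label(s): %s (allowed: %s)", what,
                 paste(bad, collapse = ", "), paste(levels, collapse = ", ")))
  factor(map, levels = levels)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d transcripts x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  samples:     %s\n",
              paste(sprintf("%s=%d", names(table(x$sample_group)),
                            table(x$sample_group)), collapse = ", ")))
  cat(sprintf("  transcripts: %s\n",
              paste(sprintf("%s=%d", names(table(x$transcript_class)),
                            table(x$transcript_class)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Sample ids of one group
#' @param em an `expr_matrix`.
#' @param group `"TUMOR"` or `"NORMAL"`.
#' @return character vector of sample ids.
#' @export
samples_of <- function(em, group = c("TUMOR", "NORMAL")) {
  group <- match.arg(group)
  names(em$sample_group)[em$sample_group == group]
}

#' Transcript ids of one class
#' @param em an `expr_matrix`.
#' @param class `"LNCRNA"` or `"MRNA"`.
#' @return character vector of transcript ids.
#' @export
transcripts_of <- function(em, class = c("LNCRNA", "MRNA")) {
  class <- match.arg(class)
  names(em$transcript_class)[em$transcript_class == class]
}
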