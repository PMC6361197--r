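#' Read an expression matrix with its sidecar annotations
#'
#' The matrix file is tab-delimited with a mandatory header row of sample ids
#' and transcript ids in the first column. Group and class annotations live
#' in two-column tab-delimited sidecar files (id, label), matching how
#' supplementary tables of normalized intensities are usually distributed.
#' Decimal points only; no locale-dependent parsing.
#'
#' @param path path to the TSV expression table.
#' @param groups_path two-column TSV: sample id, group (`TUMOR`/`NORMAL`).
#' @param classes_path two-column TSV: transcript id, class (`LNCRNA`/`MRNA`).
#' @param scale `"linear"` (default) or `"log2"`: the scale the file's
#'   intensities are on. The returned object is always linear.
#' @return a validated [expression_matrix()] preserving file order.
#' @export
read_expression_matrix <- function(path, groups_path, classes_path,
                                   scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  for (p in c(path, groups_path, classes_path))
    if (!file.exists(p)) stop(sprintf("file not found: %s", p))

  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(tab) < 2) stop("expression table needs >= 1 sample column")
  ids <- tab[[1]]
  .check_no_dups(ids, "transcript")
  .check_no_dups(colnames(tab)[-1], "sample")

  num <- suppressWarnings(
    vapply(tab[-1], as.numeric, numeric(nrow(tab))))
  if (nrow(tab) == 1) num <- matrix(num, nrow = 1)
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(as.matrix(bad)) > 0) {
    bad <- matrix(bad, ncol = 2)
    stop(sprintf("non-numeric intensity at row %d ('%s'), column '%s'",
                 bad[1, 1], ids[bad[1, 1]], colnames(tab)[-1][bad[1, 2]]))
  }
  rownames(num) <- ids
  colnames(num) <- colnames(tab)[-1]

  expression_matrix(num,
                    sample_group = .read_two_col(groups_path),
                    transcript_class = .read_two_col(classes_path),
                    scale = scale)
}

.read_two_col <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#")
  if (ncol(tab) < 2) stop(sprintf("annotation file %s needs two columns", path))
  # tolerate an optional header line with non-label second column
  setNames(tab[[2]], tab[[1]])
}

#' Write an expression matrix and its annotations to TSV files
#'
#' Inverse of [read_expression_matrix()]: a write-then-read round trip
#' reproduces values, ordering and annotations exactly.
#'
#' @param em an `expr_matrix`.
#' @param path,groups_path,classes_path output file paths.
#' @return invisibly, the matrix path.
#' @export
write_expression_matrix <- function(em, path, groups_path, classes_path) {
  tab <- data.frame(transcript_id = rownames(em$values),
                    em$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(id = names(em$sample_group), group = as.character(em$sample_group)),
    groups_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(id = names(em$transcript_class),
               class = as.character(em$transcript_class)),
    classes_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate members
#' within a set are dropped with a warning. The universe defaults to the
#' union of all members; pass `universe` to restrict or extend it (e.g. to
#' the measured genes).
#'
#' @param path path to the GMT file.
#' @param universe optional character vector of gene ids to use as the
#'   universe; sets are intersected with it.
#' @return an object of class `gene_sets`: list with `sets` (named list of
#'   character vectors) and `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("no gene sets in GMT file")

  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("GMT line %d has %d field(s); need name, description, members",
                   i, length(fields)))
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0)
      stop(sprintf("GMT line %d ('%s') has an empty member list", i, fields[1]))
    if (anyDuplicated(members)) {
      warning(sprintf("GMT set '%s': duplicate members deduplicated", fields[1]))
      members <- unique(members)
    }
    sets[[fields[1]]] <- members
  }
  gene_sets(sets, universe = universe)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (nonempty sets).
#' @param universe optional universe; defaults to the union of all members.
#'   Sets are restricted to the universe; a set left empty by the
#'   restriction is dropped with a warning.
#' @return object of class `gene_sets`.
#' @export
gene_sets <- function(sets, universe = NULL) {
  if (length(sets) == 0 || is.null(names(sets)))
    stop("`sets` must be a nonempty named list")
  if (is.null(universe)) {
    universe <- sort(unique(unlist(sets, use.names = FALSE)))
  } else {
    universe <- sort(unique(as.character(universe)))
    sets <- lapply(sets, intersect, y = universe)
    empty <- names(sets)[lengths(sets) == 0]
    if (length(empty) > 0) {
      warning(sprintf("dropping %d set(s) empty after universe restriction: %s",
                      length(empty), paste(utils::head(empty, 3), collapse = ", ")))
      sets <- sets[lengths(sets) > 0]
      if (length(sets) == 0) stop("no gene sets left after universe restriction")
    }
  }
  structure(list(sets = sets, universe = universe), class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("gene_sets: %d sets over a universe of %d genes\n",
              length(x$sets), length(x$universe)))
  cat(sprintf("  set sizes: min %d, median %g, max %d\n",
              min(lengths(x$sets)), stats::median(lengths(x$sets)),
              max(lengths(x$sets))))
  invisible(x)
}

#' Export a co-expression network in Cytoscape-loadable formats
#'
#' Writes a SIF file (relation token `coexp`), an edge-attribute TSV
#' (`lncrna`, `mrna`, `pcc`, `p_value`, `sign`) and a GraphML file with node
#' attribute `type` (`lncRNA` / `mRNA`) and edge attributes `pcc`, `p_value`.
#'
#' @param net a `coexpr_net` (see [coexpression_network()]), or a data frame
#'   of edges with columns `lncrna_id`, `mrna_id`, `pcc`, `p_value`, `sign`.
#' @param sif_path,attrs_path,graphml_path output paths; any may be `NULL`
#'   to skip that format.
#' @return invisibly, a character vector of the files written.
#' @export
write_network <- function(net, sif_path = NULL, attrs_path = NULL,
                          graphml_path = NULL) {
  edges <- if (inherits(net, "coexpr_net")) net$edges else net
  stopifnot(is.data.frame(edges))
  written <- character(0)

  if (!is.null(sif_path)) {
    lines <- if (nrow(edges) > 0)
      sprintf("%s\tcoexp\t%s", edges$lncrna_id, edges$mrna_id) else character(0)
    writeLines(lines, sif_path)
    written <- c(written, sif_path)
  }
  if (!is.null(attrs_path)) {
    out <- data.frame(lncrna = edges$lncrna_id, mrna = edges$mrna_id,
                      pcc = edges$pcc, p_value = edges$p_value,
                      sign = edges$sign, stringsAsFactors = FALSE)
    utils::write.table(out, attrs_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, attrs_path)
  }
  if (!is.null(graphml_path)) {
    g <- as_igraph(edges)
    igraph::write_graph(g, graphml_path, format = "graphml")
    written <- c(written, graphml_path)
  }
  invisible(written)
}

#' Convert a network (or edge table) to an igraph object
#'
#' Bipartite undirected graph; node attribute `type` is `"lncRNA"` or
#' `"mRNA"`, edge attributes `pcc` and `p_value` are carried over.
#'
#' @param net a `coexpr_net` or an edge data frame (see [write_network()]).
#' @return an [igraph::graph] object.
#' @export
as_igraph <- function(net) {
  edges <- if (inherits(net, "coexpr_net")) net$edges else net
  lnc <- unique(edges$lncrna_id)
  mr <- unique(edges$mrna_id)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(lnc) + length(mr),
                            name = c(lnc, mr),
                            type = c(rep("lncRNA", length(lnc)),
                                     rep("mRNA", length(mr))))
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, rbind(edges$lncrna_id, edges$mrna_id),
                           pcc = edges$pcc, p_value = edges$p_value)
  }
  g
}
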