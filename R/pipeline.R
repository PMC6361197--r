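#' Assemble (or load) a pipeline configuration
#'
#' A configuration is a flat named list of input paths, thresholds and
#' flags. When `config` is a path to a YAML file, relative input paths are
#' resolved against the YAML file's directory, so a config travels with its
#' data. Unset fields take the defaults below (the conventional screen and
#' network thresholds: fold change >= 2, P < 0.05; |r| > 0.9, P < 5e-4).
#'
#' Fields: `matrix`, `groups`, `classes` (required paths); `gmt`, `ct`,
#' `lncrna_list` (optional paths); `out_dir` (required); `scale`
#' (`"linear"`/`"log2"` of the matrix file); `fc_min`, `alpha`, `pcc_min`,
#' `p_max`, `top_k`; `ttest_log_scale`, `ttest_var_equal`,
#' `cor_log_scale`, `auto_lncrna` (use all DE lncRNAs as network
#' candidates instead of a supplied shortlist); `reference_gene`; `seed`.
#'
#' @param config named list or path to a YAML file.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config))
    base <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
    for (f in c("matrix", "groups", "classes", "gmt", "ct", "lncrna_list",
                "out_dir"))
      if (!is.null(config[[f]]) && !grepl("^(/|[A-Za-z]:)", config[[f]]))
        config[[f]] <- file.path(base, config[[f]])
  }
  stopifnot(is.list(config))
  defaults <- list(scale = "linear", fc_min = 2, alpha = 0.05,
                   pcc_min = 0.9, p_max = 5e-4, top_k = 20,
                   ttest_log_scale = TRUE, ttest_var_equal = TRUE,
                   cor_log_scale = FALSE, auto_lncrna = FALSE,
                   reference_gene = "ACTB", seed = 1L)
  for (f in names(defaults))
    if (is.null(config[[f]])) config[[f]] <- defaults[[f]]

  for (f in c("matrix", "groups", "classes", "out_dir"))
    if (is.null(config[[f]]))
      stop(sprintf("config field '%s' is required", f))
  for (f in c("matrix", "groups", "classes", "gmt", "ct", "lncrna_list"))
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop(sprintf("config: %s file not found: %s", f, config[[f]]))
  with(config, stopifnot(fc_min >= 1, alpha > 0, pcc_min >= 0, p_max > 0,
                         top_k >= 1))
  class(config) <- "pipeline_config"
  config
}

#' Run the full analysis pipeline
#'
#' Stages: differential-expression screen, hierarchical clustering on the
#' DE transcripts, lncRNA-mRNA co-expression network (candidates: the
#' supplied lncRNA shortlist — or all DE lncRNAs when `auto_lncrna` — by
#' all DE mRNAs), over-representation analysis of the up- and
#' down-regulated mRNA lists separately, and, when a Ct table is supplied,
#' 2^-ddCt quantification with array concordance. All tables, network
#' exports and a JSON run manifest (input hashes, thresholds, seed,
#' package version) are written under `out_dir`; identical inputs and
#' config produce identical outputs. Any stage failure aborts with a
#' stage-tagged error.
#'
#' @param config a [pipeline_config()], a bare list, or a YAML path.
#' @param quiet suppress progress messages.
#' @return invisibly, a list of class `lncnet_run` with elements `screen`,
#'   `clustering`, `network`, `enrichment` (list `up`/`down`, possibly
#'   NULL), `pcr` (or NULL), `concordance` (or NULL), `manifest`, and
#'   `files` (paths written).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  out <- function(name) {
    p <- file.path(cfg$out_dir, name)
    files[[length(files) + 1]] <<- p
    p
  }

  say("[io] reading expression matrix: %s", cfg$matrix)
  em <- stage("io", read_expression_matrix(cfg$matrix, cfg$groups,
                                           cfg$classes, scale = cfg$scale))

  say("[diffexp] volcano screen (FC >= %g, P < %g)", cfg$fc_min, cfg$alpha)
  screen <- stage("diffexp",
                  volcano_screen(em, fc_min = cfg$fc_min, alpha = cfg$alpha,
                                 log_scale = cfg$ttest_log_scale,
                                 var_equal = cfg$ttest_var_equal))
  utils::write.table(screen$records, out("diffexp.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  de_all <- de_transcripts(screen)
  clustering <- NULL
  if (length(de_all) >= 1) {
    say("[diffexp] clustering %d DE transcript(s)", length(de_all))
    clustering <- stage("diffexp", cluster_expression(em, de_all))
    utils::write.table(
      data.frame(axis = c(rep("sample", length(clustering$sample_order)),
                          rep("transcript", length(clustering$transcript_order))),
                 position = c(seq_along(clustering$sample_order),
                              seq_along(clustering$transcript_order)),
                 id = c(clustering$sample_order, clustering$transcript_order)),
      out("clustering_order.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }

  de_mrna <- de_transcripts(screen, class = "MRNA")
  lnc_cand <- if (!is.null(cfg$lncrna_list) && !cfg$auto_lncrna)
    readLines(cfg$lncrna_list)
  else
    de_transcripts(screen, class = "LNCRNA")
  lnc_cand <- lnc_cand[nzchar(trimws(lnc_cand))]

  network <- NULL
  if (length(lnc_cand) >= 1 && length(de_mrna) >= 1) {
    say("[coexpression] %d lncRNA x %d mRNA candidates (|r| > %g, P < %g)",
        length(lnc_cand), length(de_mrna), cfg$pcc_min, cfg$p_max)
    network <- stage("coexpression",
                     coexpression_network(em, lnc_cand, de_mrna,
                                          pcc_min = cfg$pcc_min,
                                          p_max = cfg$p_max,
                                          log_scale = cfg$cor_log_scale))
    stage("io", write_network(network,
                              sif_path = out("network.sif"),
                              attrs_path = out("network_edges.tsv"),
                              graphml_path = out("network.graphml")))
    say("[coexpression] %d edge(s) kept over %d pair(s)",
        nrow(network$edges), network$n_pairs_tested)
  } else {
    say("[coexpression] skipped: no candidate lncRNAs or no DE mRNAs")
  }

  enrichment <- NULL
  if (!is.null(cfg$gmt)) {
    sets <- stage("enrichment", read_gmt(cfg$gmt))
    enrichment <- list(up = NULL, down = NULL)
    for (dir in c("up", "down")) {
      q <- de_transcripts(screen, class = "MRNA", direction = toupper(dir))
      if (length(intersect(q, sets$universe)) > 0) {
        say("[enrichment] %s mRNA list: %d gene(s)", dir, length(q))
        enrichment[[dir]] <- stage("enrichment",
                                   suppressWarnings(enrich(q, sets,
                                                           top_k = cfg$top_k)))
        utils::write.table(enrichment[[dir]],
                           out(sprintf("enrichment_%s.tsv", dir)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      } else {
        say("[enrichment] %s mRNA list: nothing in universe, skipped", dir)
      }
    }
  }

  pcr <- conc <- NULL
  if (!is.null(cfg$ct)) {
    say("[rtpcr] 2^-ddCt quantification (reference %s)", cfg$reference_gene)
    ct <- stage("rtpcr", read_ct_table(cfg$ct, cfg$groups,
                                       reference_gene = cfg$reference_gene))
    pcr <- stage("rtpcr", relative_expression(ct))
    utils::write.table(pcr, out("rtpcr.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    shared <- pcr[pcr$gene_id %in% screen$records$transcript_id, ]
    if (nrow(shared) > 0) {
      conc <- stage("rtpcr", concordance(shared, screen))
      utils::write.table(conc$table, out("concordance.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      say("[rtpcr] direction concordance: %.0f%%", 100 * conc$fraction)
    }
  }

  manifest <- list(
    package = "lncnet",
    version = as.character(utils::packageVersion("lncnet")),
    seed = cfg$seed,
    thresholds = cfg[c("fc_min", "alpha", "pcc_min", "p_max", "top_k")],
    flags = cfg[c("scale", "ttest_log_scale", "ttest_var_equal",
                  "cor_log_scale", "auto_lncrna")],
    inputs = lapply(
      Filter(Negate(is.null),
             cfg[c("matrix", "groups", "classes", "gmt", "ct", "lncrna_list")]),
      function(p) list(path = basename(p),
                       md5 = unname(tools::md5sum(p)))),
    outputs = basename(unlist(files)))
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("[done] %d file(s) written to %s", length(files), cfg$out_dir)

  invisible(structure(list(screen = screen, clustering = clustering,
                           network = network, enrichment = enrichment,
                           pcr = pcr, concordance = conc,
                           manifest = manifest, files = unlist(files)),
                      class = "lncnet_run"))
}

#' @export
print.lncnet_run <- function(x, ...) {
  cat("lncnet_run\n")
  print(x$screen)
  if (!is.null(x$network)) print(x$network)
  if (!is.null(x$concordance))
    cat(sprintf("  qPCR/array concordance: %.0f%%\n",
                100 * x$concordance$fraction))
  invisible(x)
}

#' Write a seeded synthetic demo dataset
#'
#' Generates a study-scale synthetic dataset (5 tumor + 5 normal samples,
#' 100 transcripts: 10 lncRNAs + 90 mRNAs, ~20% planted DE at 2-10 fold,
#' three planted co-expression blocks including one anti-correlated member)
#' and writes everything the pipeline consumes: expression matrix with
#' sidecar annotations, a GMT collection over the mRNA universe (one set
#' concentrated on a planted block, the rest random), a Ct table for the
#' planted DE lncRNAs with an ACTB reference, the lncRNA shortlist, the
#' machine-readable ground truth, and a ready-to-run `config.yaml`. All
#' file contents are a pure function of `seed`.
#'
#' @param seed integer seed.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `config` (path to the YAML), `design`,
#'   `truth`, and `files`.
#' @export
make_demo <- function(seed, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)

  ids <- .synth_ids(list(n_lncrna = 10, n_mrna = 90))
  blocks <- list(
    coexpression_block(c(ids$lnc[1:2], ids$mrna[1:8]),
                       loadings = c(rep(1, 9), -1)),
    coexpression_block(c(ids$lnc[3], ids$mrna[9:14]),
                       loadings = rep(1, 7)),
    coexpression_block(c(ids$lnc[4:5], ids$mrna[15:18]),
                       loadings = rep(1, 6)))
  design <- synthetic_design(n_tumor = 5, n_normal = 5,
                             n_lncrna = 10, n_mrna = 90,
                             de_fraction = 0.2, fc_range = c(2, 10),
                             noise_sd = 0.1, blocks = blocks, seed = seed)
  sim <- simulate_expression(design)

  p <- function(name) file.path(out_dir, name)
  write_expression_matrix(sim$matrix, p("matrix.tsv"), p("groups.tsv"),
                          p("classes.tsv"))

  # gene sets over the mRNA universe: one concentrated on block 1, rest random
  set.seed(seed + 2L)
  sets <- list(BLOCK1_PATHWAY = ids$mrna[1:8])
  for (i in 1:9)
    sets[[sprintf("RANDOM_SET_%02d", i)]] <-
      sort(sample(ids$mrna, sample(8:20, 1)))
  gmt_lines <- vapply(names(sets), function(nm)
    paste(c(nm, "synthetic gene set", sets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(gmt_lines, p("gene_sets.gmt"))

  # qPCR genes mirror the study procedure: validate transcripts the array
  # screen itself calls DE (planted lncRNAs first, then any planted call)
  called <- de_transcripts(volcano_screen(sim$matrix))
  planted <- sim$truth$de_table$transcript_id
  ct_genes <- intersect(intersect(planted, ids$lnc), called)
  if (length(ct_genes) == 0) ct_genes <- intersect(planted, called)
  if (length(ct_genes) == 0) ct_genes <- utils::head(planted, 3)
  ct <- simulate_ct_table(sim$truth, design, genes = ct_genes,
                          ct_noise_sd = 0.05)
  write_ct_table(ct, p("ct_table.tsv"), p("ct_groups.tsv"))

  writeLines(ct_genes, p("lncrna_list.txt"))
  utils::write.table(sim$truth$de_table, p("truth_de.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$edge_table, p("truth_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  cfg <- list(matrix = "matrix.tsv", groups = "groups.tsv",
              classes = "classes.tsv", gmt = "gene_sets.gmt",
              ct = "ct_table.tsv", lncrna_list = "lncrna_list.txt",
              out_dir = "results", seed = seed)
  yaml::write_yaml(cfg, p("config.yaml"))

  files <- c("matrix.tsv", "groups.tsv", "classes.tsv", "gene_sets.gmt",
             "ct_table.tsv", "ct_groups.tsv", "lncrna_list.txt",
             "truth_de.tsv", "truth_edges.tsv", "config.yaml")
  invisible(list(config = p("config.yaml"), design = design,
                 truth = sim$truth, files = file.path(out_dir, files)))
}
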