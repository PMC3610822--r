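#' Assemble a pipeline configuration
#'
#' @param scan_dir Directory of \code{*.scan.tsv} arrays.
#' @param annotation_file Probe annotation TSV.
#' @param output_dir Where result TSVs and the run log go.
#' @param gene_annotation_file Optional gene annotation TSV (\code{gene_id},
#'   \code{category}, \code{known_function}, \code{conservation}) enabling
#'   the candidate cascade.
#' @param loess_span,loess_iterations,loess_degree Normalization settings.
#' @param alpha,sig_abs,candidate_abs,top_abs,conservation_min Filter
#'   thresholds (see [filter_criteria()]).
#' @param p_type Which p-value feeds the reliability filter.
#' @param normalize Run the normalization stage (disable only for
#'   noise-free validation runs).
#' @param conditions Optional ordered condition labels.
#' @param seed Seed recorded in the run log (the pipeline itself is
#'   deterministic).
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(scan_dir, annotation_file, output_dir,
                            gene_annotation_file = NULL,
                            loess_span = 0.3, loess_iterations = 3,
                            loess_degree = 1,
                            alpha = 0.05, sig_abs = 1, candidate_abs = 2,
                            top_abs = 3, conservation_min = 75,
                            p_type = "raw", normalize = TRUE,
                            conditions = NULL, seed = 1) {
  structure(list(scan_dir = scan_dir, annotation_file = annotation_file,
                 output_dir = output_dir,
                 gene_annotation_file = gene_annotation_file,
                 loess_span = loess_span,
                 loess_iterations = loess_iterations,
                 loess_degree = loess_degree,
                 alpha = alpha, sig_abs = sig_abs,
                 candidate_abs = candidate_abs, top_abs = top_abs,
                 conservation_min = conservation_min,
                 p_type = p_type, normalize = isTRUE(normalize),
                 conditions = conditions, seed = seed),
            class = "pipeline_config")
}

#' Run the full quantification and selection pipeline
#'
#' Probe processing (background correction, Mg, weights) -> weighted
#' cyclic-loess + median normalization -> gene summaries -> moderated
#' contrast statistics -> filter cascade. Writes
#' \code{normalized_matrix.tsv}, \code{results.tsv},
#' \code{filter_report.tsv} (when gene annotation is available) and a
#' \code{run.log} recording every parameter and the cascade counts.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with \code{matrix} (normalized probe-level
#'   [mg_matrix()]), \code{gene_matrix}, \code{results}
#'   (\code{contrast_result}), \code{report} (or NULL) and \code{status}
#'   (0 on success).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c(config$annotation_file, config$gene_annotation_file)) {
    if (!is.null(f) && !file.exists(f)) stop("missing input file: ", f)
  }
  if (!dir.exists(config$scan_dir)) {
    stop("missing scan directory: ", config$scan_dir)
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$output_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    writeLines(msg, log_con)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  for (k in setdiff(names(config), "conditions")) {
    say("param ", k, "=", paste(config[[k]], collapse = ","))
  }

  ann <- stage("probe_processing", read_annotation(config$annotation_file))
  scans <- stage("probe_processing", read_scan_dir(config$scan_dir))
  weights <- assign_weights(ann)
  cw <- attr(weights, "counts")
  say("probes: ", sum(cw), " total, ", cw["valid"], " valid (weight 1), ",
      cw["invalid"], " non-valid (weight 1e-6)")
  mat <- stage("probe_processing", build_matrix(scans, ann, weights))
  say("built ", nrow(mat$M), " x ", ncol(mat$M), " probe Mg matrix")

  if (config$normalize) {
    lc <- loess_config(config$loess_span, config$loess_iterations,
                       config$loess_degree)
    mat <- stage("normalization", normalize_matrix(mat, lc))
    say("normalized: cyclic loess (span ", lc$span, ", ", lc$iterations,
        " iterations, degree ", lc$degree, ") + weighted median")
  } else {
    say("normalization skipped by configuration")
  }
  write_matrix_tsv(mat, file.path(config$output_dir,
                                  "normalized_matrix.tsv"))

  design <- stage("diffexp",
                  design_from_labels(colnames(mat$M), config$conditions))
  gene_mat <- stage("diffexp", summarize_genes(mat, ann))
  say("summarized to ", nrow(gene_mat$M), " genes (",
      length(attr(gene_mat, "dropped")), " dropped: no valid probe)")
  fit <- stage("diffexp", fit_gene_model(gene_mat, design))
  results <- stage("diffexp", moderate_statistics(fit))
  say("moderated statistics: df_prior=",
      format(attr(results, "df_prior"), digits = 4), ", s0=",
      format(attr(results, "s0"), digits = 4))
  write_tsv(results, file.path(config$output_dir, "results.tsv"))

  report <- NULL
  if (!is.null(config$gene_annotation_file)) {
    gene_ann <- stage("filters", read_tsv(config$gene_annotation_file))
    gene_ann$known_function <- as.logical(gene_ann$known_function)
    criteria <- filter_criteria(config$alpha, config$sig_abs,
                                config$candidate_abs, config$top_abs,
                                config$conservation_min)
    report <- stage("filters",
                    filter_report(results, gene_ann, criteria,
                                  config$p_type))
    counts <- attr(report, "stage_counts")
    say("cascade: ", paste(names(counts), counts, sep = "=",
                           collapse = ", "))
    path <- file.path(config$output_dir, "filter_report.tsv")
    hdr <- paste0("# criteria: alpha=", criteria$alpha, " sig_abs=",
                  criteria$sig_abs, " candidate_abs=",
                  criteria$candidate_abs, " top_abs=", criteria$top_abs,
                  " conservation_min=", criteria$conservation_min,
                  " p_type=", config$p_type)
    writeLines(hdr, path)
    suppressWarnings(
      utils::write.table(report, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = TRUE,
                         append = TRUE))
  }
  say("seed=", config$seed, "; done")
  invisible(list(matrix = mat, gene_matrix = gene_mat, results = results,
                 report = report, status = 0L))
}

cli_usage <- function() {
  paste(
    "usage: mycodiff <subcommand> [options]",
    "",
    "subcommands:",
    "  simulate  --out DIR [--seed N] [--n-genes N] [--probes-per-gene N]",
    "            [--noise-sd X] [--dye-bias X] [--replicates N]",
    "  normalize --scans DIR --annotation FILE --out FILE",
    "            [--span X] [--iterations N] [--degree N]",
    "  diffexp   --scans DIR --annotation FILE --out FILE [--no-normalize]",
    "  filter    --table FILE [--top-abs X] [--candidate-abs X]",
    "            [--sig-abs X] [--annotation FILE] [--out FILE]",
    "  qpcr      --ct FILE --target GENE --reference GENE",
    "            --calibrator COND [--out FILE]",
    "  report    --config FILE",
    sep = "\n")
}

parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      out[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      out[[key]] <- TRUE
      i <- i + 1L
    }
  }
  out
}

opt <- function(opts, key, default = NULL, required = FALSE) {
  if (!is.null(opts[[key]])) return(opts[[key]])
  if (required) stop("missing required option --", key)
  default
}

#' Command-line entry point
#'
#' Subcommand dispatcher usable from \code{Rscript -e
#' 'mycodiff::cli()'} or programmatically with an argument vector. Errors
#' are reported on stderr and turned into a non-zero status rather than
#' thrown.
#'
#' @param args Character vector of arguments (defaults to the command
#'   line).
#' @return Exit status, invisibly (0 = success).
#' @export
cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message(cli_usage())
    return(invisible(1L))
  }
  sub_cmd <- args[1]
  status <- tryCatch({
    opts <- parse_cli_args(args[-1])
    switch(sub_cmd,
      simulate = cli_simulate(opts),
      normalize = cli_normalize(opts),
      diffexp = cli_diffexp(opts),
      filter = cli_filter(opts),
      qpcr = cli_qpcr(opts),
      report = cli_report(opts),
      {
        message("unknown subcommand: ", sub_cmd)
        message(cli_usage())
        1L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(as.integer(status))
}

cli_simulate <- function(opts) {
  out <- opt(opts, "out", required = TRUE)
  config <- sim_config(
    n_genes = as.integer(opt(opts, "n-genes", 200)),
    probes_per_gene = as.integer(opt(opts, "probes-per-gene", 3)),
    replicates = as.integer(opt(opts, "replicates", 3)),
    noise_sd = as.numeric(opt(opts, "noise-sd", 0.2)),
    dye_bias = as.numeric(opt(opts, "dye-bias", 0)),
    seed = as.integer(opt(opts, "seed", 1)))
  write_array_dataset(generate_array_dataset(config), out, config)
  message("simulated dataset written to ", out)
  0L
}

cli_normalize <- function(opts) {
  scans <- read_scan_dir(opt(opts, "scans", required = TRUE))
  ann <- read_annotation(opt(opts, "annotation", required = TRUE))
  mat <- build_matrix(scans, ann)
  lc <- loess_config(as.numeric(opt(opts, "span", 0.3)),
                     as.integer(opt(opts, "iterations", 3)),
                     as.integer(opt(opts, "degree", 1)))
  write_matrix_tsv(normalize_matrix(mat, lc),
                   opt(opts, "out", required = TRUE))
  0L
}

cli_diffexp <- function(opts) {
  scans <- read_scan_dir(opt(opts, "scans", required = TRUE))
  ann <- read_annotation(opt(opts, "annotation", required = TRUE))
  mat <- build_matrix(scans, ann)
  if (is.null(opts[["no-normalize"]])) mat <- normalize_matrix(mat)
  design <- design_from_labels(colnames(mat$M))
  results <- moderate_statistics(fit_gene_model(summarize_genes(mat, ann),
                                                design))
  write_tsv(results, opt(opts, "out", required = TRUE))
  0L
}

cli_filter <- function(opts) {
  table <- read_tsv(opt(opts, "table", required = TRUE))
  criteria <- filter_criteria(
    sig_abs = as.numeric(opt(opts, "sig-abs", 1)),
    candidate_abs = as.numeric(opt(opts, "candidate-abs", 2)),
    top_abs = as.numeric(opt(opts, "top-abs", 3)))
  kept <- top_filter(table, criteria)
  if (!is.null(opts[["annotation"]])) {
    ann <- read_tsv(opts[["annotation"]])
    ann$known_function <- as.logical(ann$known_function)
    kept <- intersect(kept, candidate_filter(table, ann, criteria))
  }
  message(length(kept), " gene(s) pass |Mc| >= ", criteria$top_abs)
  out <- opt(opts, "out")
  listing <- data.frame(gene_id = kept, stringsAsFactors = FALSE)
  if (is.null(out)) {
    if (length(kept)) writeLines(kept)
  } else {
    write_tsv(listing, out)
  }
  0L
}

cli_qpcr <- function(opts) {
  ct <- read_tsv(opt(opts, "ct", required = TRUE))
  res <- delta_delta_ct(ct, opt(opts, "target", required = TRUE),
                        opt(opts, "reference", required = TRUE),
                        opt(opts, "calibrator", required = TRUE))
  out <- opt(opts, "out")
  if (is.null(out)) {
    print(res)
  } else {
    write_tsv(res, out)
  }
  0L
}

cli_report <- function(opts) {
  cfg <- read_flat_config(opt(opts, "config", required = TRUE))
  config <- pipeline_config(
    scan_dir = cfg$scan_dir, annotation_file = cfg$annotation_file,
    output_dir = cfg$output_dir,
    gene_annotation_file = cfg$gene_annotation_file,
    loess_span = as.numeric(cfg$loess_span %||% 0.3),
    loess_iterations = as.integer(cfg$loess_iterations %||% 3),
    loess_degree = as.integer(cfg$loess_degree %||% 1),
    alpha = as.numeric(cfg$alpha %||% 0.05),
    sig_abs = as.numeric(cfg$sig_abs %||% 1),
    candidate_abs = as.numeric(cfg$candidate_abs %||% 2),
    top_abs = as.numeric(cfg$top_abs %||% 3),
    conservation_min = as.numeric(cfg$conservation_min %||% 75),
    p_type = cfg$p_type %||% "raw",
    seed = as.integer(cfg$seed %||% 1))
  run_pipeline(config)$status
}

`%||%` <- function(a, b) if (is.null(a)) b else a
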