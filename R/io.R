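# Tab-separated, header-bearing text for all tabular I/O, matching the
# FeatureExtraction lineage of the raw inputs and keeping fixtures
# diff-able.

SCAN_COLUMNS <- c("ProbeName", "gMeanSignal", "gBGMedianSignal",
                  "gBGPixSDev", "rMeanSignal", "rBGMedianSignal",
                  "rBGPixSDev")

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a simulated dataset as FeatureExtraction-style TSV files
#'
#' One \code{<label>.scan.tsv} per array plus \code{annotation.tsv},
#' \code{truth.tsv} and \code{config.txt} (flat key=value).
#'
#' @param dataset Result of [generate_array_dataset()].
#' @param dir Output directory (created if needed).
#' @param config The [sim_config()] used, echoed to \code{config.txt}.
#' @return The directory, invisibly.
#' @export
write_array_dataset <- function(dataset, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (label in names(dataset$scans)) {
    write_tsv(dataset$scans[[label]][SCAN_COLUMNS],
              file.path(dir, paste0(label, ".scan.tsv")))
  }
  write_tsv(dataset$annotation, file.path(dir, "annotation.tsv"))
  write_tsv(dataset$truth, file.path(dir, "truth.tsv"))
  if (!is.null(config)) {
    write_flat_config(unclass(config)[!vapply(config, is.data.frame, TRUE)],
                      file.path(dir, "config.txt"))
  }
  invisible(dir)
}

#' Read all array scans from a directory
#' @param dir Directory holding \code{*.scan.tsv} files.
#' @return Named list of scan data.frames (names = array labels).
#' @export
read_scan_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.scan\\.tsv$", full.names = TRUE)
  if (!length(files)) stop("no *.scan.tsv files in ", dir)
  scans <- lapply(files, function(f) {
    s <- read_tsv(f)
    missing <- setdiff(SCAN_COLUMNS, names(s))
    if (length(missing)) {
      stop(f, " lacks scan column(s): ", paste(missing, collapse = ", "))
    }
    s
  })
  names(scans) <- sub("\\.scan\\.tsv$", "", basename(files))
  scans
}

#' Read a probe annotation TSV (probe_id, class, gene_ids)
#' @param path File path.
#' @return data.frame.
#' @export
read_annotation <- function(path) {
  ann <- read_tsv(path)
  need <- c("probe_id", "class", "gene_ids")
  missing <- setdiff(need, names(ann))
  if (length(missing)) {
    stop(path, " lacks annotation column(s): ",
         paste(missing, collapse = ", "))
  }
  ann$gene_ids[is.na(ann$gene_ids)] <- ""
  ann
}

#' Write / read an Mg matrix as TSV (first column row ids)
#' @param mat An [mg_matrix()].
#' @param path File path.
#' @return \code{path} invisibly / the matrix as data.frame.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(id = rownames(mat$M), mat$M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_matrix_tsv
#' @param weights Per-row weights to attach (defaults to 1).
#' @export
read_matrix_tsv <- function(path, weights = 1) {
  df <- read_tsv(path)
  M <- as.matrix(df[-1])
  rownames(M) <- df[[1]]
  mg_matrix(M, weights)
}

#' Flat key=value configuration files
#' @param config Named list of scalar values.
#' @param path File path.
#' @return \code{path} invisibly / named character list.
#' @export
write_flat_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    paste0(k, "=", paste(config[[k]], collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_flat_config
#' @export
read_flat_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  out <- lapply(kv, function(x) trimws(x[2]))
  names(out) <- vapply(kv, function(x) trimws(x[1]), "")
  out
}
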