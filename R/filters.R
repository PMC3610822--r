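#' Selection thresholds of the gene-filter cascade
#'
#' @param alpha Significance level of the all-contrast reliability filter.
#' @param sig_abs Log2 threshold below which an abundance change is "flat"
#'   (the published plots draw this limit at +/- 1).
#' @param candidate_abs Log2 threshold of the candidate cascade (+/- 2,
#'   i.e. more than 4-fold).
#' @param top_abs Log2 threshold of the top tier (+/- 3, more than 8-fold).
#' @param conservation_min Minimum percent similarity across the genus for
#'   a gene to count as conserved (strict >).
#' @return A list of class \code{filter_criteria}.
#' @export
filter_criteria <- function(alpha = 0.05, sig_abs = 1, candidate_abs = 2,
                            top_abs = 3, conservation_min = 75) {
  stopifnot(alpha > 0, alpha < 1,
            sig_abs <= candidate_abs, candidate_abs <= top_abs)
  structure(list(alpha = alpha, sig_abs = sig_abs,
                 candidate_abs = candidate_abs, top_abs = top_abs,
                 conservation_min = conservation_min),
            class = "filter_criteria")
}

# Extract the genes x contrasts Mc matrix from a contrast_result or a
# printed abundance table (columns Mc_* or mc_*).
mc_columns <- function(table) {
  cols <- grep("^[Mm]c_", names(table), value = TRUE)
  if (!length(cols)) stop("no Mc_* columns found in table")
  m <- as.matrix(table[cols])
  rownames(m) <- table$gene_id
  m
}

p_columns <- function(table, type = c("raw", "fdr")) {
  type <- match.arg(type)
  prefix <- if (type == "raw") "^p_" else "^fdr_"
  cols <- grep(prefix, names(table), value = TRUE)
  if (!length(cols)) stop("no ", prefix, "* columns found in table")
  m <- as.matrix(table[cols])
  rownames(m) <- table$gene_id
  m
}

#' All-contrast reliability filter
#'
#' The conservative selection rule of the study: a gene is kept only when
#' its differential-abundance p-value is below alpha in every contrast
#' against the reference stage; a single unreliable contrast discards it.
#'
#' @param results A \code{contrast_result} (or data.frame with p_* / fdr_*
#'   columns and \code{gene_id}).
#' @param criteria A [filter_criteria()].
#' @param p_type Which p-value feeds the filter: \code{"raw"} (default, as
#'   published) or \code{"fdr"}.
#' @return Character vector of kept gene ids.
#' @export
select_reliable <- function(results, criteria = filter_criteria(),
                            p_type = c("raw", "fdr")) {
  p <- p_columns(results, match.arg(p_type))
  if (anyNA(p)) {
    stop("missing contrast p-value for gene(s): ",
         paste(utils::head(rownames(p)[apply(is.na(p), 1, any)], 5),
               collapse = ", "))
  }
  rownames(p)[apply(p < criteria$alpha, 1, all)]
}

# round a fold magnitude the way the narrative reports it: nearest integer
# from 5-fold up, one decimal below
round_fold <- function(magnitude) {
  ifelse(magnitude >= 5, round(magnitude), round(magnitude, 1))
}

#' Convert a log2 abundance difference to direction and fold change
#'
#' @param mc Log2 differential abundance (Mc), vectorised.
#' @param sig_abs Threshold below which the change counts as flat.
#' @return data.frame with \code{direction} (\code{up-in-MII},
#'   \code{up-in-MI}, \code{flat}) and \code{fold} = 2^|mc| rounded to the
#'   reported precision (integer from 5-fold, one decimal below).
#' @export
fold_change <- function(mc, sig_abs = 1) {
  stopifnot(all(is.finite(mc)))
  direction <- ifelse(abs(mc) < sig_abs, "flat",
                      ifelse(mc > 0, "up-in-MII", "up-in-MI"))
  data.frame(direction = direction, fold = round_fold(2^abs(mc)),
             stringsAsFactors = FALSE)
}

#' Maximum fold change over a gene set
#'
#' The "up to N-fold" summary used in the narrative: the maximum of
#' 2^|Mc| over the listed genes and all contrasts, rounded to the reported
#' precision.
#'
#' @param genes Gene ids, all present in \code{table}.
#' @param table Abundance table with \code{gene_id} and Mc columns.
#' @return A single number.
#' @export
max_fold_change <- function(genes, table) {
  m <- mc_columns(table)
  missing <- setdiff(genes, rownames(m))
  if (length(missing)) {
    stop("gene(s) not in table: ", paste(missing, collapse = ", "))
  }
  round_fold(max(2^abs(m[genes, , drop = FALSE])))
}

#' Candidate cascade: unknown, conserved, strongly regulated genes
#'
#' Keeps genes with no characterized function, conservation (percent
#' similarity across the genus) strictly above the minimum, and an absolute
#' Mc of at least \code{candidate_abs} in some contrast (more than 4-fold
#' up or down at the default).
#'
#' @param table Abundance table or \code{contrast_result}.
#' @param annotations Gene annotation data.frame with \code{gene_id},
#'   \code{known_function} (logical), \code{conservation} (percent).
#' @param criteria A [filter_criteria()].
#' @return Character vector of candidate gene ids.
#' @export
candidate_filter <- function(table, annotations,
                             criteria = filter_criteria()) {
  m <- mc_columns(table)
  ann <- annotations[match(rownames(m), annotations$gene_id), ]
  if (anyNA(ann$gene_id)) {
    stop("annotations do not cover gene(s): ",
         paste(utils::head(rownames(m)[is.na(ann$gene_id)], 5),
               collapse = ", "))
  }
  keep <- !ann$known_function &
    ann$conservation > criteria$conservation_min &
    apply(abs(m), 1, max) >= criteria$candidate_abs
  rownames(m)[keep]
}

#' Top tier: genes past the +/- 3 log2 threshold
#'
#' Keeps genes whose absolute Mc reaches \code{top_abs} in at least one
#' contrast (more than 8-fold at the default). The comparison is >= so
#' that printed one-decimal values sitting exactly on the threshold are
#' kept.
#'
#' @inheritParams candidate_filter
#' @return Character vector of kept gene ids.
#' @export
top_filter <- function(table, criteria = filter_criteria()) {
  m <- mc_columns(table)
  rownames(m)[apply(abs(m), 1, max) >= criteria$top_abs]
}

#' Fraction of genes with a consistent MII expression pattern
#'
#' A gene is consistent when its Mc values share one sign across all MII
#' contrasts; zero entries are ignored, so a gene is consistent iff its
#' non-zero entries agree (an all-zero gene is trivially consistent).
#'
#' @param results Abundance table or \code{contrast_result}.
#' @return Fraction in [0, 1].
#' @export
mii_consistency <- function(results) {
  m <- mc_columns(results)
  consistent <- apply(m, 1, function(x) {
    s <- sign(x[x != 0])
    length(s) == 0 || all(s == s[1])
  })
  mean(consistent)
}

#' Transcript vs protein concordance classes
#'
#' Classifies each gene's transcript Mc and protein log2 ratio as up
#' (>= sig_abs), down (<= -sig_abs) or flat; both flat is "no-variation",
#' matching non-flat classes are "similar", anything else "different".
#'
#' @param transcript_mc,protein_ratio Named (gene id) numeric vectors on
#'   the log2 scale, same genes.
#' @param sig_abs Flatness threshold.
#' @return data.frame \code{gene_id}, \code{class}; attribute
#'   \code{"counts"} with the three class totals.
#' @export
proteome_concordance <- function(transcript_mc, protein_ratio, sig_abs = 1) {
  stopifnot(length(transcript_mc) == length(protein_ratio))
  classify <- function(x) {
    ifelse(x >= sig_abs, "up", ifelse(x <= -sig_abs, "down", "flat"))
  }
  ct <- classify(transcript_mc); cp <- classify(protein_ratio)
  cls <- ifelse(ct == "flat" & cp == "flat", "no-variation",
                ifelse(ct == cp, "similar", "different"))
  out <- data.frame(
    gene_id = if (!is.null(names(transcript_mc))) names(transcript_mc)
              else seq_along(transcript_mc),
    class = cls, stringsAsFactors = FALSE)
  counts <- vapply(c("similar", "no-variation", "different"),
                   function(k) sum(cls == k), 0L)
  attr(out, "counts") <- counts
  out
}

#' Group Mc triplets by functional category
#'
#' @param table Abundance table or \code{contrast_result}.
#' @param annotations Gene annotation with \code{gene_id},
#'   \code{category}.
#' @return Named list of per-category data.frames (gene_id + Mc columns);
#'   category sizes sum to the number of input genes. Unannotated genes go
#'   to category \code{"unknown"} with a warning.
#' @export
category_summary <- function(table, annotations) {
  m <- mc_columns(table)
  if (nrow(m) == 0) return(structure(list(), names = character(0)))
  cat_ <- annotations$category[match(rownames(m), annotations$gene_id)]
  if (anyNA(cat_)) {
    warning(sum(is.na(cat_)), " gene(s) without annotation assigned to ",
            "category 'unknown'")
    cat_[is.na(cat_)] <- "unknown"
  }
  df <- data.frame(gene_id = rownames(m), m, row.names = NULL,
                   stringsAsFactors = FALSE)
  split(df, cat_)
}

#' Run the whole selection cascade and tabulate it
#'
#' @param results A \code{contrast_result}.
#' @param annotations Gene annotation table (see [candidate_filter()]).
#' @param criteria A [filter_criteria()].
#' @param p_type Which p-value feeds the reliability filter.
#' @return data.frame per gene: flags \code{reliable}, \code{candidate},
#'   \code{top}; per-contrast \code{direction_*} and \code{fold_*};
#'   attribute \code{"stage_counts"}.
#' @export
filter_report <- function(results, annotations,
                          criteria = filter_criteria(),
                          p_type = c("raw", "fdr")) {
  p_type <- match.arg(p_type)
  m <- mc_columns(results)
  reliable <- select_reliable(results, criteria, p_type)
  rel_results <- results[results$gene_id %in% reliable, , drop = FALSE]
  candidate <- candidate_filter(rel_results, annotations, criteria)
  top <- intersect(top_filter(rel_results, criteria), candidate)
  out <- data.frame(gene_id = rownames(m), stringsAsFactors = FALSE)
  out$reliable <- out$gene_id %in% reliable
  out$candidate <- out$gene_id %in% candidate
  out$top <- out$gene_id %in% top
  suffix <- sub("^[Mm]c_", "", colnames(m))
  for (i in seq_along(suffix)) {
    fc <- fold_change(m[, i], criteria$sig_abs)
    out[[paste0("direction_", suffix[i])]] <- fc$direction
    out[[paste0("fold_", suffix[i])]] <- fc$fold
  }
  attr(out, "stage_counts") <- c(total = nrow(out),
                                 reliable = length(reliable),
                                 candidate = length(candidate),
                                 top = length(top))
  out
}
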