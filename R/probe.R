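#' Background-correct one channel of a spot
#'
#' Net fluorescence is the mean foreground minus the median background of
#' the spot's pixels. When that subtraction is negative, or smaller than the
#' standard deviation of the background pixels, the background SD itself is
#' used as a surrogate intensity, so the net signal is always strictly
#' positive and the downstream log-ratio is defined for every probe.
#'
#' A difference exactly equal to \code{bg_pixel_sd} keeps the difference:
#' the surrogate fires only when the subtraction is strictly below the SD.
#'
#' @param fg_mean Mean of foreground pixels (vectorised).
#' @param bg_median Median of background pixels.
#' @param bg_pixel_sd Standard deviation of background pixels; must be
#'   strictly positive.
#' @return Net intensity, same length as the inputs; always
#'   \code{>= bg_pixel_sd > 0}.
#' @examples
#' correct_background(100, 40, 5)  # 60
#' correct_background(42, 40, 5)   # 5: difference 2 < SD 5
#' correct_background(30, 40, 5)   # 5: negative difference
#' @export
correct_background <- function(fg_mean, bg_median, bg_pixel_sd) {
  if (any(!is.finite(bg_pixel_sd)) || any(bg_pixel_sd <= 0)) {
    stop("bg_pixel_sd must be strictly positive: the surrogate rule and the ",
         "downstream log-ratio are undefined otherwise")
  }
  net <- fg_mean - bg_median
  ifelse(net < bg_pixel_sd, bg_pixel_sd, net)
}

#' Log2 cDNA/gDNA abundance of a probe
#'
#' Mg is the log2 ratio of the Cy3-labelled sample cDNA net intensity over
#' the Cy5-labelled genomic-DNA reference net intensity. Because every array
#' shares the same copy-number-flat gDNA channel, Mg values are comparable
#' across arrays.
#'
#' @param cy3_net,cy5_net Background-corrected intensities, strictly
#'   positive (guaranteed when they come from [correct_background()]).
#' @return \code{log2(cy3_net / cy5_net)}.
#' @export
compute_mg <- function(cy3_net, cy5_net) {
  if (any(!is.finite(cy3_net)) || any(!is.finite(cy5_net)) ||
      any(cy3_net <= 0) || any(cy5_net <= 0)) {
    stop("compute_mg requires strictly positive finite intensities")
  }
  log2(cy3_net / cy5_net)
}

WEIGHT_VALID <- 1
WEIGHT_INVALID <- 1e-6

#' Assign validity weights to probes
#'
#' Probes flagged as cross-hybridizing (matching more than one gene) or as
#' intergenic receive a negligible weight of 1e-6; all other probes receive
#' weight 1. Non-valid probes stay in the matrix so that every array keeps
#' an identical probe set, but they have essentially no influence on
#' normalization or gene summaries.
#'
#' @param annotations A probe annotation data.frame with columns
#'   \code{probe_id}, \code{class} (one of \code{"GENE"}, \code{"CROSSHYB"},
#'   \code{"INTERGENIC"}) and \code{gene_ids} (semicolon-separated).
#' @return A data.frame \code{probe_id}, \code{weight} in the annotation's
#'   row order, with attribute \code{"counts"} giving the number of valid
#'   and non-valid probes.
#' @export
assign_weights <- function(annotations) {
  stopifnot(is.data.frame(annotations),
            all(c("probe_id", "class") %in% names(annotations)))
  if (anyDuplicated(annotations$probe_id)) {
    stop("every probe must appear exactly once in the annotation table")
  }
  invalid <- annotations$class %in% c("CROSSHYB", "INTERGENIC")
  out <- data.frame(
    probe_id = annotations$probe_id,
    weight = ifelse(invalid, WEIGHT_INVALID, WEIGHT_VALID),
    stringsAsFactors = FALSE
  )
  attr(out, "counts") <- c(valid = sum(!invalid), invalid = sum(invalid))
  out
}

#' Construct an Mg expression matrix
#'
#' An \code{mg_matrix} bundles a probes-or-genes x arrays matrix of log2
#' cDNA/gDNA abundances with per-row validity weights. It is the container
#' passed between the processing, normalization and modelling steps.
#'
#' @param M Numeric matrix with row names (probe or gene ids) and column
#'   names (array labels).
#' @param weights Numeric vector of positive per-row weights, recycled if
#'   length 1.
#' @return An object of class \code{mg_matrix}.
#' @export
mg_matrix <- function(M, weights = 1) {
  stopifnot(is.matrix(M), is.numeric(M),
            !is.null(rownames(M)), !is.null(colnames(M)))
  if (length(weights) == 1L) weights <- rep(weights, nrow(M))
  stopifnot(length(weights) == nrow(M))
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("weights must be positive and finite")
  }
  if (anyNA(M)) stop("Mg matrix must have no missing cells")
  structure(list(M = M, weights = as.numeric(weights)), class = "mg_matrix")
}

#' @export
print.mg_matrix <- function(x, ...) {
  cat(sprintf("mg_matrix: %d rows x %d arrays (%d at weight 1, %d at 1e-6)\n",
              nrow(x$M), ncol(x$M),
              sum(x$weights == WEIGHT_VALID),
              sum(x$weights == WEIGHT_INVALID)))
  invisible(x)
}

#' @export
dim.mg_matrix <- function(x) dim(x$M)

#' Build the probe-level Mg matrix from raw scans
#'
#' Applies [correct_background()] to each channel of every probe on every
#' array and then [compute_mg()], producing a probes x arrays matrix with
#' the validity weights attached.
#'
#' @param scans Named list of per-array scan data.frames with columns
#'   \code{ProbeName}, \code{gMeanSignal}, \code{gBGMedianSignal},
#'   \code{gBGPixSDev} (Cy3 sample channel) and \code{rMeanSignal},
#'   \code{rBGMedianSignal}, \code{rBGPixSDev} (Cy5 gDNA channel); names
#'   become array labels.
#' @param annotations Probe annotation table (see [assign_weights()]).
#' @param weights Optional precomputed weight table; computed from
#'   \code{annotations} when omitted.
#' @return An [mg_matrix()] at probe level.
#' @export
build_matrix <- function(scans, annotations, weights = NULL) {
  stopifnot(is.list(scans), length(scans) >= 1, !is.null(names(scans)))
  if (is.null(weights)) weights <- assign_weights(annotations)
  ref_probes <- scans[[1]]$ProbeName
  for (label in names(scans)) {
    probes <- scans[[label]]$ProbeName
    if (!identical(sort(probes), sort(ref_probes))) {
      bad <- union(setdiff(probes, ref_probes), setdiff(ref_probes, probes))
      stop("arrays do not share an identical probe set; offending probes: ",
           paste(utils::head(bad, 10), collapse = ", "))
    }
  }
  M <- vapply(names(scans), function(label) {
    s <- scans[[label]]
    s <- s[match(ref_probes, s$ProbeName), ]
    cy3 <- correct_background(s$gMeanSignal, s$gBGMedianSignal, s$gBGPixSDev)
    cy5 <- correct_background(s$rMeanSignal, s$rBGMedianSignal, s$rBGPixSDev)
    compute_mg(cy3, cy5)
  }, numeric(length(ref_probes)))
  rownames(M) <- ref_probes
  w <- weights$weight[match(ref_probes, weights$probe_id)]
  if (anyNA(w)) stop("weight table does not cover all probes")
  mg_matrix(M, w)
}
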