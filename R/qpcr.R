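#' Relative expression by the delta-delta-Ct method
#'
#' Livak relative quantification against an internal-control gene and a
#' calibrator condition, assuming doubling per cycle. Technical replicate
#' wells are averaged within each biological replicate first; the
#' delta-delta-Ct of each biological replicate is then averaged, and the
#' replicate-to-replicate SD is reported as the dispersion.
#'
#' @param ct_table data.frame with columns \code{gene_id},
#'   \code{condition}, \code{bio_rep}, \code{tech_rep}, \code{ct}.
#' @param target Target gene id.
#' @param reference Internal-control gene id (constant expression; the
#'   study used SCO3878, a DNA polymerase III beta-chain).
#' @param calibrator Condition every other condition is expressed relative
#'   to (the vegetative MI stage in the study).
#' @return data.frame of class \code{qpcr_result}: \code{gene_id},
#'   \code{condition}, \code{delta_ct}, \code{delta_delta_ct},
#'   \code{rel_expr} = 2^(-ddCt), \code{log2_rel_expr} = -ddCt,
#'   \code{dispersion} (SD of ddCt across biological replicates).
#' @export
delta_delta_ct <- function(ct_table, target, reference, calibrator) {
  need <- c("gene_id", "condition", "bio_rep", "tech_rep", "ct")
  stopifnot(is.data.frame(ct_table), all(need %in% names(ct_table)))
  if (any(ct_table$ct <= 0)) stop("Ct values must be positive")
  conditions <- unique(ct_table$condition)
  if (!calibrator %in% conditions) {
    stop("calibrator condition '", calibrator, "' absent from table")
  }
  sub <- ct_table[ct_table$gene_id %in% c(target, reference), ]
  # mean over technical wells within (gene, condition, biological replicate)
  agg <- stats::aggregate(ct ~ gene_id + condition + bio_rep, data = sub,
                          FUN = mean)
  dct <- NULL
  for (cond in conditions) {
    t_ct <- agg[agg$gene_id == target & agg$condition == cond, ]
    r_ct <- agg[agg$gene_id == reference & agg$condition == cond, ]
    if (nrow(r_ct) == 0) {
      stop("reference gene '", reference, "' missing in condition '",
           cond, "'")
    }
    if (nrow(t_ct) == 0) {
      stop("target gene '", target, "' missing in condition '", cond, "'")
    }
    reps <- intersect(t_ct$bio_rep, r_ct$bio_rep)
    d <- t_ct$ct[match(reps, t_ct$bio_rep)] -
      r_ct$ct[match(reps, r_ct$bio_rep)]
    dct <- rbind(dct, data.frame(condition = cond, bio_rep = reps,
                                 delta_ct = d))
  }
  cal <- dct[dct$condition == calibrator, ]
  out <- do.call(rbind, lapply(conditions, function(cond) {
    d <- dct[dct$condition == cond, ]
    reps <- intersect(d$bio_rep, cal$bio_rep)
    dd <- d$delta_ct[match(reps, d$bio_rep)] -
      cal$delta_ct[match(reps, cal$bio_rep)]
    data.frame(gene_id = target, condition = cond,
               delta_ct = mean(d$delta_ct),
               delta_delta_ct = mean(dd),
               rel_expr = 2^(-mean(dd)),
               log2_rel_expr = -mean(dd),
               dispersion = stats::sd(dd),
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("qpcr_result", "data.frame")
  out
}

#' Array vs qPCR concordance
#'
#' Ordinary least-squares regression of qPCR log2 relative expression on
#' the array Mc values for the same gene/condition pairs, plus the Pearson
#' correlation.
#'
#' @param array_mc,qpcr_log2 Paired numeric vectors (>= 3 points).
#' @return list(slope, intercept, correlation, n).
#' @export
platform_concordance <- function(array_mc, qpcr_log2) {
  stopifnot(length(array_mc) == length(qpcr_log2))
  if (length(array_mc) < 3) stop("need at least 3 paired points")
  fit <- stats::lm.fit(cbind(1, array_mc), qpcr_log2)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       correlation = stats::cor(array_mc, qpcr_log2),
       n = length(array_mc))
}
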