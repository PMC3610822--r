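#' Study design description
#'
#' Maps array labels to developmental condition and biological replicate.
#' The first label in \code{conditions} is the reference stage every
#' contrast is taken against (MI_16h in the published design).
#'
#' @param array Array labels (matrix column names).
#' @param condition Condition label per array.
#' @param replicate Replicate index per array.
#' @param conditions Ordered condition levels; first is the reference.
#' @return A data.frame of class \code{design_info}.
#' @export
design_info <- function(array, condition, replicate,
                        conditions = unique(condition)) {
  stopifnot(length(array) == length(condition),
            length(array) == length(replicate),
            all(condition %in% conditions))
  tab <- table(factor(condition, levels = conditions))
  if (any(tab < 2)) {
    stop("every condition needs at least 2 replicate arrays; short: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  structure(data.frame(array = array,
                       condition = factor(condition, levels = conditions),
                       replicate = as.integer(replicate),
                       stringsAsFactors = FALSE),
            class = c("design_info", "data.frame"))
}

#' Infer the design from array labels of the form "<condition>_r<rep>"
#' @param labels Array labels.
#' @param conditions Optional ordered condition levels.
#' @return A [design_info()].
#' @export
design_from_labels <- function(labels, conditions = NULL) {
  parts <- regmatches(labels, regexec("^(.+)_r([0-9]+)$", labels))
  bad <- labels[vapply(parts, length, 1L) != 3L]
  if (length(bad)) {
    stop("array labels not of the form <condition>_r<replicate>: ",
         paste(bad, collapse = ", "))
  }
  cond <- vapply(parts, `[`, "", 2L)
  rep_ <- as.integer(vapply(parts, `[`, "", 3L))
  if (is.null(conditions)) conditions <- unique(cond)
  design_info(labels, cond, rep_, conditions)
}

# Short contrast suffixes for output column names: MII24 -> "24" in the
# published design; arbitrary labels fall back to the label itself.
contrast_suffix <- function(cond) {
  suf <- sub("^MII", "", cond)
  ifelse(grepl("^[0-9]+$", suf), suf, cond)
}

#' Average probes of the same gene into gene-level Mg values
#'
#' Per gene and array, the weighted mean of its probes' Mg using the
#' 1 / 1e-6 validity weights, so cross-hybridizing probes are carried in
#' the bookkeeping but contribute essentially nothing. Genes whose probes
#' are all non-valid are dropped and reported in the \code{"dropped"}
#' attribute. Intergenic probes belong to no gene and are never summarized.
#'
#' @param mat Probe-level [mg_matrix()].
#' @param annotations Probe annotation table (\code{probe_id}, \code{class},
#'   \code{gene_ids}); for CROSSHYB probes the first listed gene is used for
#'   bookkeeping.
#' @return Gene-level \code{mg_matrix} (weight 1 per gene), with attributes
#'   \code{"dropped"} (genes whose probes were all non-valid).
#' @export
summarize_genes <- function(mat, annotations) {
  stopifnot(inherits(mat, "mg_matrix"))
  ann <- annotations[match(rownames(mat$M), annotations$probe_id), ]
  if (anyNA(ann$probe_id)) stop("annotation table does not cover all probes")
  first_gene <- vapply(strsplit(ann$gene_ids, ";", fixed = TRUE),
                       function(g) if (length(g)) g[1] else NA_character_, "")
  keep <- ann$class %in% c("GENE", "CROSSHYB") & !is.na(first_gene)
  gene <- first_gene[keep]
  M <- mat$M[keep, , drop = FALSE]
  w <- mat$weights[keep]
  wsum <- rowsum(w, gene)
  S <- rowsum(M * w, gene)
  G <- S / as.vector(wsum)
  # a gene summarized only by weight-1e-6 probes is unreliable: drop it
  has_valid <- rowsum(as.numeric(w == WEIGHT_VALID), gene) > 0
  dropped <- rownames(G)[!has_valid]
  if (length(dropped)) {
    message(length(dropped), " gene(s) had no valid probe and were dropped")
  }
  G <- G[has_valid, , drop = FALSE]
  out <- mg_matrix(G, 1)
  attr(out, "dropped") <- dropped
  out
}

#' Per-gene one-way linear model over the developmental stages
#'
#' Ordinary least squares with one coefficient per condition (group means).
#' The contrast Mc for condition c is mean(c) - mean(reference); the
#' residual variance pools within-condition scatter with
#' \code{n_arrays - n_conditions} degrees of freedom.
#'
#' @param mat Gene-level [mg_matrix()].
#' @param design A [design_info()] covering every column of \code{mat}.
#' @return A list of class \code{gene_fit}: \code{coef} (genes x
#'   conditions), \code{Mc} (genes x contrasts), \code{sigma2},
#'   \code{df_residual}, \code{stdev_unscaled} (per contrast), condition
#'   labels and contrast names.
#' @export
fit_gene_model <- function(mat, design) {
  stopifnot(inherits(mat, "mg_matrix"), inherits(design, "design_info"))
  idx <- match(colnames(mat$M), design$array)
  if (anyNA(idx)) {
    stop("design does not cover arrays: ",
         paste(colnames(mat$M)[is.na(idx)], collapse = ", "))
  }
  design <- design[idx, ]
  cond <- design$condition
  levels_ <- levels(cond)
  n_per <- table(cond)
  if (any(n_per < 2)) {
    stop("condition with fewer than 2 replicates: ",
         paste(names(n_per)[n_per < 2], collapse = ", "))
  }
  Mt <- t(mat$M)                                     # arrays x genes
  means <- rowsum(Mt, cond) / as.vector(n_per)       # conditions x genes
  resid <- Mt - means[as.integer(cond), , drop = FALSE]
  df <- nrow(Mt) - length(levels_)
  sigma2 <- colSums(resid^2) / df
  ref <- levels_[1]
  contrasts <- levels_[-1]
  Mc <- t(means[contrasts, , drop = FALSE] -
            rep(means[ref, ], each = length(contrasts)))
  colnames(Mc) <- paste0(contrasts, "-", ref)
  su <- sqrt(1 / as.vector(n_per[contrasts]) + 1 / as.vector(n_per[ref]))
  names(su) <- colnames(Mc)
  structure(list(coef = t(means), Mc = Mc, sigma2 = sigma2,
                 df_residual = df, stdev_unscaled = su,
                 conditions = levels_, contrasts = contrasts,
                 genes = rownames(mat$M)),
            class = "gene_fit")
}

# Inverse of the trigamma function by Newton iteration (monotone
# decreasing, so convergence is global from the standard start value).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) < 1e-10 * x) break
  }
  x
}

# Method-of-moments fit of the scaled-inverse-chi-square prior for
# residual variances: on z = log(s^2), Var(z) exceeds trigamma(d/2) by
# trigamma(d0/2), and the mean locates log(s0^2).
estimate_variance_prior <- function(sigma2, df, d0_cap = 1e6) {
  z <- log(sigma2[sigma2 > 0 & is.finite(sigma2)])
  if (length(z) < 2) return(list(df_prior = d0_cap, s0 = sqrt(mean(sigma2))))
  evar <- stats::var(z) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    d0 <- d0_cap
  } else {
    d0 <- min(2 * trigamma_inverse(evar), d0_cap)
  }
  log_s0sq <- mean(z) - digamma(df / 2) + log(df / 2) +
    digamma(d0 / 2) - log(d0 / 2)
  list(df_prior = d0, s0 = sqrt(exp(log_s0sq)))
}

#' Empirical-Bayes moderated contrast statistics
#'
#' Shrinks each gene's residual variance toward a prior value s0^2
#' estimated from all genes, with prior degrees of freedom d0 set by the
#' method of moments on the log residual variances. The posterior variance
#' is (d0 s0^2 + d s^2) / (d0 + d) and the moderated t for a contrast is
#' Mc / (s_post * stdev_unscaled), referred to a t distribution on d0 + d
#' degrees of freedom. Raw p-values are two-sided; FDR columns apply
#' Benjamini-Hochberg within each contrast.
#'
#' @param fit A [fit_gene_model()] result over at least 10 genes (for
#'   stable hyperparameter estimation), unless both hyperparameters are
#'   supplied.
#' @param df_prior,s0 Optional hyperparameter overrides; \code{df_prior =
#'   0} reproduces the ordinary t-test exactly.
#' @return A data.frame of class \code{contrast_result} with columns
#'   \code{gene_id}, then per contrast suffix s: \code{Mc_s}, \code{t_s},
#'   \code{p_s}, \code{fdr_s}; plus \code{residual_sd}. Attributes
#'   \code{df_residual}, \code{df_prior}, \code{s0}, \code{contrasts}.
#' @export
moderate_statistics <- function(fit, df_prior = NULL, s0 = NULL) {
  stopifnot(inherits(fit, "gene_fit"))
  if (all(fit$sigma2 == 0)) {
    warning("all residual variances are zero; falling back to ordinary t")
    df_prior <- 0; s0 <- 0
  }
  manual <- !is.null(df_prior) && !is.null(s0)
  if (!manual && length(fit$genes) < 10) {
    stop("need >= 10 genes to estimate the variance prior; pass df_prior ",
         "and s0 explicitly for smaller problems")
  }
  if (is.null(df_prior) || is.null(s0)) {
    prior <- estimate_variance_prior(fit$sigma2, fit$df_residual)
    if (is.null(df_prior)) df_prior <- prior$df_prior
    if (is.null(s0)) s0 <- prior$s0
  }
  d <- fit$df_residual
  s2_post <- if (df_prior == 0) fit$sigma2 else
    (df_prior * s0^2 + d * fit$sigma2) / (df_prior + d)
  df_total <- d + df_prior
  suffix <- contrast_suffix(fit$contrasts)
  out <- data.frame(gene_id = fit$genes, stringsAsFactors = FALSE)
  for (i in seq_along(fit$contrasts)) {
    mc <- fit$Mc[, i]
    se <- sqrt(s2_post) * fit$stdev_unscaled[i]
    tstat <- ifelse(se > 0, mc / se, ifelse(mc == 0, 0, sign(mc) * Inf))
    p <- 2 * stats::pt(-abs(tstat), df = df_total)
    out[[paste0("Mc_", suffix[i])]] <- mc
    out[[paste0("t_", suffix[i])]] <- tstat
    out[[paste0("p_", suffix[i])]] <- p
  }
  for (i in seq_along(fit$contrasts)) {
    out[[paste0("fdr_", suffix[i])]] <-
      adjust_fdr(out[[paste0("p_", suffix[i])]])
  }
  out$residual_sd <- sqrt(fit$sigma2)
  attr(out, "df_residual") <- d
  attr(out, "df_prior") <- df_prior
  attr(out, "s0") <- s0
  attr(out, "contrasts") <- suffix
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' p-values are ranked, scaled by m/rank, and monotonicity is enforced by a
#' running minimum from the largest rank down; results are clipped at 1.
#'
#' @param p Raw p-values in [0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
adjust_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (m <= 1L) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}
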