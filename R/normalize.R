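#' Loess configuration
#'
#' Parameters of the local regression used by the cyclic normalization:
#' the span (fraction of probes entering each local fit, the published
#' "window" of 0.3), the number of full pair-cycles, and the degree of the
#' local polynomial.
#'
#' @param span Fraction in (0, 1] of points in each local fit.
#' @param iterations Number of full cycles over all array pairs.
#' @param degree Local polynomial degree (1 = local linear).
#' @return A list of class \code{loess_config}.
#' @export
loess_config <- function(span = 0.3, iterations = 3, degree = 1) {
  stopifnot(span > 0, span <= 1, iterations >= 1, degree %in% 0:2)
  structure(list(span = span, iterations = as.integer(iterations),
                 degree = as.integer(degree)), class = "loess_config")
}

#' Weighted loess fit evaluated at the observed points
#'
#' Local polynomial regression with tricube distance weights multiplied by
#' the supplied probe weights, so that non-valid probes (weight 1e-6) have
#' essentially no leverage on the fitted trend.
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @param weights Non-negative probe weights, not all zero.
#' @param config A [loess_config()].
#' @return Fitted values at each \code{x}.
#' @export
loess_fit <- function(x, y, weights = NULL, config = loess_config()) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 2)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n)
  if (any(weights < 0)) stop("weights must be non-negative")
  if (all(weights == 0)) stop("all weights are zero")
  fit <- stats::loess(y ~ x, weights = weights, span = config$span,
                      degree = config$degree, family = "gaussian",
                      control = stats::loess.control(surface = "direct",
                                                     statistics = "none"))
  as.numeric(stats::predict(fit, data.frame(x = x)))
}

# Interpolation-surface variant for large probe sets: identical model, but
# the kd-tree surface makes the pairwise cyclic pass affordable at 40k+
# probes. Used internally by cyclic_loess_normalize.
loess_fit_fast <- function(x, y, weights, config) {
  fit <- stats::loess(y ~ x, weights = weights, span = config$span,
                      degree = config$degree, family = "gaussian",
                      control = stats::loess.control(surface = "interpolate",
                                                     statistics = "none"))
  as.numeric(stats::predict(fit, data.frame(x = x)))
}

#' Cyclic loess normalization with probe weights
#'
#' Removes intensity-dependent (dye) bias between arrays. For each of the
#' configured iterations and every unordered array pair (j, k), the
#' difference M = Mg_j - Mg_k is loess-regressed on the average abundance
#' A = (Mg_j + Mg_k)/2 using the probe weights; the fitted trend is split
#' symmetrically, array j receiving -1/n of it and array k +1/n (with two
#' arrays this is exactly half the trend to each side). Within one
#' iteration all pair trends are estimated from the same snapshot of the
#' matrix, which makes the procedure invariant to the order in which the
#' arrays are listed and removes the full pairwise trend (not half of it)
#' per cycle, so the published three iterations converge.
#'
#' @param mat An [mg_matrix()] with at least two arrays.
#' @param config A [loess_config()].
#' @param exact Use the exact O(n^2) loess surface (small matrices / tests)
#'   instead of the interpolated one.
#' @return The normalized \code{mg_matrix}; ids and weights are unchanged.
#' @export
cyclic_loess_normalize <- function(mat, config = loess_config(),
                                   exact = FALSE) {
  stopifnot(inherits(mat, "mg_matrix"))
  M <- mat$M
  n_arr <- ncol(M)
  if (n_arr < 2) stop("cyclic loess requires at least two arrays")
  w <- mat$weights
  fitter <- if (exact) loess_fit else loess_fit_fast
  for (iter in seq_len(config$iterations)) {
    adjust <- matrix(0, nrow(M), n_arr)
    for (j in seq_len(n_arr - 1)) {
      for (k in (j + 1):n_arr) {
        mjk <- M[, j] - M[, k]
        ajk <- (M[, j] + M[, k]) / 2
        trend <- fitter(ajk, mjk, w, config)
        adjust[, j] <- adjust[, j] - trend
        adjust[, k] <- adjust[, k] + trend
      }
    }
    M <- M + adjust / n_arr
  }
  mat$M <- M
  mat
}

#' Weighted median
#'
#' Linear-interpolation weighted median: with observations sorted, the
#' cumulative weight midpoints define an empirical quantile function which
#' is evaluated at half the total weight. Reduces to the usual interpolated
#' median under equal weights; an observation with negligible weight moves
#' the result by a negligible amount.
#'
#' @param x Numeric vector.
#' @param w Positive weights.
#' @return The weighted median.
#' @export
weighted_median <- function(x, w = rep(1, length(x))) {
  stopifnot(length(x) == length(w), all(w > 0))
  if (length(x) == 1L) return(x)
  o <- order(x)
  x <- x[o]; w <- w[o]
  mid <- cumsum(w) - w / 2
  target <- sum(w) / 2
  if (target <= mid[1]) return(x[1])
  if (target >= mid[length(mid)]) return(x[length(x)])
  stats::approx(mid, x, xout = target, ties = "ordered")$y
}

#' Median normalization with probe weights
#'
#' Shifts each array so that its weighted median Mg equals the global
#' weighted median of the matrix before shifting. Equalizing to the global
#' median (rather than to zero) preserves the absolute-abundance meaning Mg
#' carries against the genomic-DNA reference. Probes at weight 1e-6 have no
#' effective say in where the medians sit.
#'
#' @param mat An [mg_matrix()].
#' @param target Optional target median; defaults to the global weighted
#'   median of all arrays.
#' @return The shifted \code{mg_matrix}.
#' @export
median_normalize <- function(mat, target = NULL) {
  stopifnot(inherits(mat, "mg_matrix"))
  w <- mat$weights
  if (is.null(target)) {
    target <- weighted_median(as.vector(mat$M), rep(w, ncol(mat$M)))
  }
  med <- apply(mat$M, 2, weighted_median, w = w)
  mat$M <- sweep(mat$M, 2, med - target)
  mat
}

#' Full normalization: weighted cyclic loess, then weighted median
#'
#' @inheritParams cyclic_loess_normalize
#' @return The normalized \code{mg_matrix}.
#' @export
normalize_matrix <- function(mat, config = loess_config(), exact = FALSE) {
  median_normalize(cyclic_loess_normalize(mat, config, exact = exact))
}
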