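#' Z-scale a vector
#'
#' Centers to mean 0 and scales to standard deviation 1 (n-1 denominator).
#' Used to render spline estimates comparable across correction methods and
#' reference regions.
#'
#' @param v Numeric vector, length >= 2, non-constant.
#' @return Scaled vector.
#' @export
zscale <- function(v) {
  if (length(v) < 2) stop("need at least 2 values")
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) stop("cannot z-scale a constant vector")
  (v - mean(v)) / s
}

#' Tertile knots of a distribution
#'
#' Empirical 33.33% and 66.67% quantiles using the linear-interpolation
#' (type 7) definition. These are the default interior knots of the spline
#' model, splitting the SUVR scale into low / intermediate / high amyloid
#' ranges.
#'
#' @param x Numeric vector with at least 6 values, >= 3 distinct.
#' @return Numeric vector `c(k1, k2)`.
#' @export
tertile_knots <- function(x) {
  if (length(x) < 6 || length(unique(x)) < 3)
    stop("need >= 6 values with >= 3 distinct values")
  unname(stats::quantile(x, c(1, 2) / 3, type = 7))
}

## Truncated-power linear spline basis: columns x, (x-k1)+, (x-k2)+, ...
lspline_basis <- function(x, knots) {
  B <- cbind(x, vapply(knots, function(k) pmax(x - k, 0), numeric(length(x))))
  colnames(B) <- c("x", paste0("hinge", seq_along(knots)))
  B
}

#' Continuous piecewise-linear (linear spline) regression
#'
#' Least-squares fit of `y` on the continuous piecewise-linear basis
#' `{1, x, (x - k1)+, (x - k2)+}`. Segment slopes are the cumulative sums of
#' the basis coefficients; standard errors and 95% confidence intervals come
#' from the ordinary OLS covariance. Knot positions at or beyond the data
#' maximum contribute structurally zero columns and are dropped, so the fit
#' degrades gracefully to fewer segments (ultimately simple OLS); a design
#' made rank-deficient by an empty interior segment is rejected, naming the
#' segment.
#'
#' @param x,y Numeric vectors (z-scaled upstream by convention; not
#'   required).
#' @param knots Strictly increasing knot positions (default:
#'   [tertile_knots()] of `x`).
#' @return Object of class `linspline` with components `knots`,
#'   `segment_slopes`, `slope_se`, `intercept`, `coefficients`, `vcov`,
#'   `fitted`, `residuals`, and the underlying `lm` fit.
#' @export
fit_linear_spline <- function(x, y, knots = tertile_knots(x)) {
  stopifnot(length(x) == length(y))
  if (length(x) <= 5) stop("need n > 5 observations")
  if (is.unsorted(knots, strictly = TRUE))
    stop("knots must be strictly increasing")
  B <- lspline_basis(x, knots)
  ## structurally degenerate hinge columns: knot at/above the data maximum
  ## (column identically zero) or at/below the minimum (column affine in x)
  zero_col <- colSums(B != 0) == 0 | c(FALSE, knots <= min(x))
  fit <- stats::lm(y ~ B[, !zero_col, drop = FALSE])
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    bad <- which(is.na(beta)) - 1L      # basis column index
    stop("rank-deficient spline design: no data in segment ",
         paste(bad + 1L, collapse = ", "))
  }
  ## map back to the full coefficient vector (dropped hinges contribute 0)
  full <- stats::setNames(numeric(ncol(B) + 1L),
                          c("(Intercept)", colnames(B)))
  full[c(TRUE, !zero_col)] <- beta
  seg <- cumsum(full[-1L])
  ## zero-residual (interpolating) fits trigger a spurious precision
  ## warning inside summary.lm; the covariance itself is well defined
  V <- suppressWarnings(stats::vcov(fit))
  ## slope_j = sum of first j basis coefs -> se via linear combinations
  se <- vapply(seq_along(seg), function(j) {
    keep <- which(!zero_col[seq_len(j)]) + 1L  # +1 skips intercept
    if (!length(keep)) return(0)
    a <- rep(1, length(keep))
    sqrt(drop(a %*% V[keep, keep, drop = FALSE] %*% a))
  }, numeric(1))
  structure(list(
    knots = knots,
    segment_slopes = unname(seg),
    slope_se = se,
    slope_ci = cbind(lower = seg - stats::qnorm(0.975) * se,
                     upper = seg + stats::qnorm(0.975) * se),
    intercept = unname(full[1L]),
    coefficients = full,
    vcov = V,
    fitted = unname(stats::fitted(fit)),
    residuals = unname(stats::residuals(fit)),
    lm = fit, x = x, y = y
  ), class = "linspline")
}

#' @export
print.linspline <- function(x, ...) {
  cat("Linear spline fit with knots at",
      paste(signif(x$knots, 4), collapse = ", "), "\n")
  cat("Segment slopes:",
      paste(signif(x$segment_slopes, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.linspline <- function(object, ...) {
  cat("Continuous piecewise-linear regression\n")
  cat("  knots:", paste(signif(object$knots, 4), collapse = ", "), "\n")
  tab <- data.frame(slope = object$segment_slopes,
                    se = object$slope_se,
                    ci_lo = object$slope_ci[, "lower"],
                    ci_hi = object$slope_ci[, "upper"])
  rownames(tab) <- paste0("segment", seq_len(nrow(tab)))
  print(tab, digits = 4)
  invisible(object)
}

#' @export
coef.linspline <- function(object, ...) object$coefficients

#' @export
predict.linspline <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else newdata
  B <- lspline_basis(x, object$knots)
  drop(cbind(1, B) %*% object$coefficients)
}

#' @export
residuals.linspline <- function(object, ...) object$residuals

#' @export
plot.linspline <- function(x, ...) {
  graphics::plot(x$x, x$y, pch = 16, col = "grey50",
                 xlab = "x (scaled SUVR)", ylab = "y (scaled CSF Abeta42)",
                 ...)
  xs <- seq(min(x$x), max(x$x), length.out = 200)
  graphics::lines(xs, predict(x, xs), lwd = 2, col = "firebrick")
  graphics::abline(v = x$knots, lty = 3)
  invisible(x)
}

#' First-segment slope with a sliding first knot
#'
#' Refits the linear spline for each first-knot position on a uniform grid
#' of quantile levels from `q_lo` to `q_hi` (default 16.6% to the first
#' tertile, 100 steps, endpoints included), holding the second knot fixed,
#' and records the first-segment slope — a sensitivity analysis of the
#' low-amyloid association that does not depend on a single knot choice.
#'
#' @param x,y Data vectors.
#' @param q_lo,q_hi Quantile-level range for the first knot (defaults 0.166
#'   and 1/3).
#' @param steps Number of grid points (default 100).
#' @param k2 Second knot position (default: second tertile of `x`).
#' @return Object of class `sliding_knot`: data frame with `level`, `knot`,
#'   `slope1`.
#' @export
sliding_first_knot <- function(x, y, q_lo = 0.166, q_hi = 1 / 3,
                               steps = 100, k2 = tertile_knots(x)[2]) {
  if (q_lo >= q_hi) stop("q_lo must be < q_hi")
  levels <- seq(q_lo, q_hi, length.out = steps)
  knots1 <- unname(stats::quantile(x, levels, type = 7))
  slopes <- vapply(knots1, function(k1) {
    fit_linear_spline(x, y, knots = c(k1, k2))$segment_slopes[1L]
  }, numeric(1))
  structure(data.frame(level = levels, knot = knots1, slope1 = slopes),
            class = c("sliding_knot", "data.frame"))
}
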