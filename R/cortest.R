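#' Pearson product-moment correlation
#'
#' Thin wrapper over [stats::cor()] with the input validation the pipeline
#' relies on (non-constant inputs, n >= 3).
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  stats::cor(x, y)
}

#' Fisher z transform
#'
#' @param r Correlation(s) with `|r| < 1`.
#' @return `atanh(r)`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1")
  atanh(r)
}

#' Overall and tertile-wise correlations
#'
#' Partitions subjects into tertiles of the SUVR distribution (type-7
#' quantile boundaries, the same rule as [tertile_knots()]; membership is
#' `suvr <= q1`, `q1 < suvr <= q2`, `suvr > q2`) and returns the Pearson
#' correlation between SUVR and CSF Abeta42 within each tertile and overall.
#' Within-tertile correlations are range-restricted and therefore
#' attenuated relative to the overall value; their comparison across
#' correction methods is the point of the analysis.
#'
#' @param suvr,csf Numeric vectors of equal length, n >= 9.
#' @return List with `r_low`, `r_mid`, `r_high`, `r_total`, `boundaries`,
#'   `n` (per-tertile counts).
#' @export
tertile_correlations <- function(suvr, csf) {
  stopifnot(length(suvr) == length(csf))
  if (length(suvr) < 9) stop("need n >= 9")
  q <- stats::quantile(suvr, c(1, 2) / 3, type = 7)
  grp <- cut(suvr, c(-Inf, q[1], q[2], Inf),
             labels = c("low", "mid", "high"))
  ns <- table(grp)
  if (any(ns < 3)) stop("a tertile has fewer than 3 subjects")
  r_in <- vapply(levels(grp), function(g)
    pearson(suvr[grp == g], csf[grp == g]), numeric(1))
  list(r_low = r_in[["low"]], r_mid = r_in[["mid"]], r_high = r_in[["high"]],
       r_total = pearson(suvr, csf), boundaries = unname(q),
       n = as.integer(ns))
}

## determinant of the 3x3 correlation matrix of (1,2,3)
cor3_det <- function(r12, r13, r23)
  1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23

#' Williams t test for two dependent correlations sharing one variable
#'
#' Compares `r12 = cor(X1, X2)` with `r13 = cor(X1, X3)` measured on the same
#' n subjects (`r23 = cor(X2, X3)`), e.g. the correlation of CSF Abeta42
#' with SUVR under two processing methods. The statistic is
#' \deqn{t = (r_{12}-r_{13}) \sqrt{\frac{(n-1)(1+r_{23})}
#'   {2 |R| (n-1)/(n-3) + \bar r^2 (1-r_{23})^3}}}
#' with \eqn{|R|} the determinant of the 3x3 correlation matrix and
#' \eqn{\bar r = (r_{12}+r_{13})/2}; it is referred to a t distribution with
#' `n - 3` degrees of freedom (two-sided).
#'
#' @param r12,r13,r23 Correlations; the triple must form a positive
#'   semidefinite correlation matrix.
#' @param n Sample size (>= 4).
#' @return An object of class `htest`.
#' @export
williams_t <- function(r12, r13, r23, n) {
  if (n < 4) stop("need n >= 4")
  if (any(abs(c(r12, r13, r23)) > 1)) stop("correlations must be in [-1, 1]")
  detR <- cor3_det(r12, r13, r23)
  if (detR < -1e-12) stop("correlation triple is not positive semidefinite")
  detR <- max(detR, 0)
  rbar <- (r12 + r13) / 2
  tval <- (r12 - r13) * sqrt((n - 1) * (1 + r23) /
    (2 * detR * (n - 1) / (n - 3) + rbar^2 * (1 - r23)^3))
  df <- n - 3
  p <- 2 * stats::pt(-abs(tval), df)
  structure(list(
    statistic = c(t = tval), parameter = c(df = df), p.value = p,
    estimate = c(r12 = r12, r13 = r13, r23 = r23),
    method = "Williams t test for two dependent correlations sharing one variable",
    data.name = sprintf("r12 = %.3f vs r13 = %.3f (r23 = %.3f, n = %d)",
                        r12, r13, r23, as.integer(n)),
    alternative = "two.sided"
  ), class = "htest")
}

#' Steiger Z test for two dependent correlations (Fisher-z form)
#'
#' The asymptotic Z variant of the dependent-correlation comparison, based
#' on Fisher-z transformed coefficients with Steiger's pooled-correlation
#' covariance term. Provided as a cross-check of [williams_t()].
#'
#' @inheritParams williams_t
#' @return An object of class `htest`.
#' @export
steiger_z <- function(r12, r13, r23, n) {
  if (n < 4) stop("need n >= 4")
  if (cor3_det(r12, r13, r23) < -1e-12)
    stop("correlation triple is not positive semidefinite")
  z12 <- fisher_z(r12); z13 <- fisher_z(r13)
  rbar <- (r12 + r13) / 2
  psi <- r23 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r23^2)
  cov_z <- psi / (1 - rbar^2)^2
  zval <- (z12 - z13) * sqrt((n - 3) / (2 - 2 * cov_z))
  structure(list(
    statistic = c(Z = zval), p.value = 2 * stats::pnorm(-abs(zval)),
    estimate = c(r12 = r12, r13 = r13, r23 = r23),
    method = "Steiger Z test for two dependent correlations (Fisher z)",
    data.name = sprintf("r12 = %.3f vs r13 = %.3f (r23 = %.3f, n = %d)",
                        r12, r13, r23, as.integer(n)),
    alternative = "two.sided"
  ), class = "htest")
}

#' Compare the CSF association of two SUVR variants
#'
#' Convenience wrapper: computes the three correlations from a
#' [compute_suvr_table()]-style table and runs [williams_t()].
#'
#' @param tab A `suvr_table`.
#' @param method_a,method_b Column names, e.g. `"suvr_pvc3_wc"` and
#'   `"suvr_none_wc"`.
#' @param subset Optional logical vector of rows to use.
#' @return An `htest` from [williams_t()].
#' @export
compare_methods <- function(tab, method_a = "suvr_pvc3_wc",
                            method_b = "suvr_none_wc", subset = NULL) {
  if (!is.null(subset)) tab <- tab[subset, , drop = FALSE]
  williams_t(pearson(tab$csf_ab42, tab[[method_a]]),
             pearson(tab$csf_ab42, tab[[method_b]]),
             pearson(tab[[method_a]], tab[[method_b]]),
             nrow(tab))
}

#' Tertile-wise comparison of two SUVR variants against CSF
#'
#' Dependent correlations can only be compared on a common sample, so the
#' tertile membership for a method comparison is defined once, on the
#' reference processing (by default the standard no-PVC, whole-cerebellum
#' SUVR), and both methods' correlations with CSF Abeta42 are computed on
#' those shared subsets and compared with [williams_t()].
#'
#' @param tab A `suvr_table`.
#' @param method_a,method_b SUVR column names to compare.
#' @param ref Column defining the tertile membership (default `method_b`,
#'   the standard processing).
#' @return Data frame with one row per stratum (`low`, `mid`, `high`,
#'   `total`): `r_a`, `r_b`, `t`, `df`, `p`, `n`.
#' @export
tertile_method_comparison <- function(tab, method_a = "suvr_pvc3_wc",
                                      method_b = "suvr_none_wc",
                                      ref = method_b) {
  x <- tab[[ref]]
  q <- stats::quantile(x, c(1, 2) / 3, type = 7)
  grp <- cut(x, c(-Inf, q[1], q[2], Inf), labels = c("low", "mid", "high"))
  strata <- c(as.list(stats::setNames(levels(grp), levels(grp))),
              list(total = NULL))
  rows <- lapply(names(strata), function(s) {
    sel <- if (s == "total") rep(TRUE, nrow(tab)) else grp == s
    ht <- compare_methods(tab, method_a, method_b, subset = sel)
    data.frame(stratum = s,
               r_a = unname(ht$estimate["r12"]),
               r_b = unname(ht$estimate["r13"]),
               t = unname(ht$statistic), df = unname(ht$parameter),
               p = ht$p.value, n = sum(sel))
  })
  do.call(rbind, rows)
}
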