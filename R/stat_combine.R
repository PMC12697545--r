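# Shared statistical kernels: one-sided variance-ratio (F) test, weighted
# aggregated-Cauchy p-value combination, Benjamini-Hochberg FDR.

#' One-sided variance-ratio (F) test p-value
#'
#' For two pooled sample variances with known degrees of freedom, the ratio
#' `s2_num / s2_den` follows an F distribution under the null of equal
#' variances. The lower tail tests "numerator smaller" (loop calling: the
#' tested pair against its local background); the upper tail tests
#' "numerator larger" (TAD calling: inter-domain against intra-domain).
#'
#' @param s2_num,s2_den Sample variances (`s2_num >= 0`, `s2_den > 0`;
#'   `s2_den == 0` yields `NaN`, untestable).
#' @param df_num,df_den Degrees of freedom (>= 1).
#' @param tail `"lower"` or `"upper"`.
#' @return The p-value (scalar).
#' @export
variance_ratio_pvalue <- function(s2_num, df_num, s2_den, df_den,
                                  tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  if (any(c(df_num, df_den) < 1)) stop("degrees of freedom must be >= 1")
  if (is.na(s2_num) || is.na(s2_den)) return(NaN)
  if (s2_num < 0 || s2_den < 0) stop("variances must be non-negative")
  if (s2_den == 0) return(NaN)
  stats::pf(s2_num / s2_den, df_num, df_den, lower.tail = tail == "lower")
}

# vectorized internal version (no argument checking)
.vr_pvalue <- function(r, df1, df2, lower) {
  out <- stats::pf(r, df1, df2, lower.tail = lower)
  out[!is.finite(r) | df1 < 1 | df2 < 1] <- NaN
  out
}

#' Weighted aggregated Cauchy combination of axis p-values
#'
#' Combines per-axis p-values with the aggregated Cauchy (ACAT) rule: each
#' p-value is mapped to a standard Cauchy quantile, `tan((0.5 - p) * pi)`,
#' the quantiles are averaged with the axis weights, and the weighted sum
#' `T` is converted back through the Cauchy tail, `0.5 - atan(T) / pi`.
#' The transform is its own inverse for a single axis, and is robust to
#' dependence between axes.
#'
#' `NaN` p-values (untestable axes) are dropped and the remaining weights
#' renormalized; if all axes are untestable the result is `NaN`. P-values
#' are clipped to `[1e-15, 1 - 1e-15]` before the tangent transform to
#' avoid overflow.
#'
#' @param p Length-3 numeric of per-axis p-values (x, y, z order).
#' @param w An `axis_weights` object or a length-3 positive numeric.
#' @return The combined p-value, with the weighted Cauchy statistic `T`
#'   attached as attribute `"statistic"`.
#' @export
cauchy_combine <- function(p, w) {
  if (inherits(w, "axis_weights")) w <- w$w
  stopifnot(length(p) == length(w))
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive")
  ok <- !is.na(p)
  if (!any(ok)) return(structure(NaN, statistic = NaN))
  w <- w[ok] / sum(w[ok])
  pc <- pmin(pmax(p[ok], 1e-15), 1 - 1e-15)
  T <- sum(w * tan((0.5 - pc) * pi))
  structure(0.5 - atan(T) / pi, statistic = T)
}

# vectorized internal version: P is a matrix (rows = tests, cols = axes),
# w a positive length-ncol vector. Returns list(p, stat).
.cauchy_combine_mat <- function(P, w) {
  W <- matrix(rep(w, each = nrow(P)), nrow = nrow(P))
  W[is.na(P)] <- 0
  sw <- rowSums(W)
  W <- W / ifelse(sw > 0, sw, 1)
  PC <- pmin(pmax(P, 1e-15), 1 - 1e-15)
  TT <- tan((0.5 - PC) * pi)
  TT[is.na(P)] <- 0
  T <- rowSums(W * TT)
  p <- 0.5 - atan(T) / pi
  p[sw == 0] <- NaN
  T[sw == 0] <- NaN
  list(p = p, stat = T)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up BH adjustment (via [stats::p.adjust()]), capped at 1 and
#' monotone. `NaN`/`NA` entries pass through unchanged and are excluded
#' from the number of tests.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA/NaN allowed).
#' @return Vector of FDR-adjusted values, same length and order.
#' @export
bh_fdr <- function(p) {
  out <- rep(NaN, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}
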