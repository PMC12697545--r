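# Per-axis p x p variance fields from pairwise coordinate differences:
# robust raw variance, lowess expected-variance by genomic distance, 4-SD
# outlier filtering, and distance normalization. The resulting (V, C, E)
# triplets are the sufficient statistics consumed by all downstream tests.

# Gaussian-consistency constant for the median-of-squared-deviations scale
ROBUST_C <- 1 / stats::qnorm(0.75)^2  # ~2.1981

# per-gap slice of pairwise differences: n x (p - g) matrix of
# x[, j] - x[, j + g] for j = 1..p-g (columns indexed by the left anchor)
.gap_diffs <- function(X, g) {
  p <- ncol(X)
  X[, seq_len(p - g), drop = FALSE] - X[, g + seq_len(p - g), drop = FALSE]
}

#' Robust raw pairwise-difference variance matrix
#'
#' Entry (j, k) is a robust variance of the pairwise differences
#' `d_i = x_ij - x_ik` over traces observing both spots:
#' `c * median_i[(d_i - median_i d_i)^2]` with the Gaussian-consistency
#' constant `c = 1 / qnorm(0.75)^2` (~2.1981), so the result is on the
#' ordinary variance scale for Gaussian data. Entries with fewer than 3
#' complete pairs, and the diagonal, are `NaN`.
#'
#' @param ds A centered `trace_dataset`.
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @return A symmetric `p x p` matrix (nm^2).
#' @export
robust_variance_matrix <- function(ds, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  if (!isTRUE(ds$centered)) stop("dataset must be centered first")
  X <- ds$coords[, , match(axis, AXES), drop = FALSE]
  dim(X) <- dim(ds$coords)[1:2]
  p <- ncol(X)
  V <- matrix(NaN, p, p)
  for (g in seq_len(p - 1)) {
    D <- .gap_diffs(X, g)
    cnt <- colSums(!is.na(D))
    med <- apply(D, 2, stats::median, na.rm = TRUE)
    dev2 <- sweep(D, 2, med, "-")^2
    v <- ROBUST_C * apply(dev2, 2, stats::median, na.rm = TRUE)
    v[cnt < 3] <- NaN
    j <- seq_len(p - g)
    V[cbind(j, j + g)] <- v
    V[cbind(j + g, j)] <- v
  }
  V
}

#' Expected-variance curve by genomic distance
#'
#' Fits a lowess curve (smoother span 0.3, 3 robustifying iterations; each
#' finite matrix entry is one point) of variance against 1D genomic
#' distance `s = |j - k| * resolution`, returning an evaluator defined on
#' the observed distance range, linearly extrapolated at the ends and
#' floored at 1 nm^2. With fewer than 5 finite entries or fewer than 3
#' distinct distances, the fit degenerates to interpolated per-distance
#' stratum means (a single stratum gives a constant curve).
#'
#' @param raw A `p x p` variance matrix (e.g. from
#'   [robust_variance_matrix()]).
#' @param bins Bin table from [genomic_bins()] (only the resolution is
#'   used).
#' @return A function `E(s)` mapping genomic distance (bp) to expected
#'   variance (nm^2).
#' @export
expected_variance_curve <- function(raw, bins) {
  res <- attr(bins, "resolution")
  p <- nrow(raw)
  ut <- which(upper.tri(raw), arr.ind = TRUE)
  v <- raw[ut]
  s <- (ut[, 2] - ut[, 1]) * res
  ok <- is.finite(v)
  if (!any(ok)) stop("cannot estimate an expected-variance curve: all entries are NaN")
  v <- v[ok]; s <- s[ok]
  if (length(v) < 5 || length(unique(s)) < 3) {
    xs <- sort(unique(s))
    ys <- vapply(xs, function(si) mean(v[s == si]), 0)
  } else {
    lo <- stats::lowess(s, v, f = 0.3, iter = 3)
    xs <- sort(unique(lo$x))
    ys <- vapply(xs, function(si) mean(lo$y[lo$x == si]), 0)
  }
  .linear_evaluator(xs, ys, floor = 1)
}

# piecewise-linear evaluator with end-slope extrapolation and a floor
.linear_evaluator <- function(xs, ys, floor = 1) {
  force(xs); force(ys); force(floor)
  k <- length(xs)
  function(s) {
    if (k == 1L) return(pmax(rep(ys, length(s)), floor))
    out <- stats::approx(xs, ys, xout = s, rule = 2)$y
    lo <- s < xs[1]
    if (any(lo))
      out[lo] <- ys[1] + (s[lo] - xs[1]) * (ys[2] - ys[1]) / (xs[2] - xs[1])
    hi <- s > xs[k]
    if (any(hi))
      out[hi] <- ys[k] + (s[hi] - xs[k]) * (ys[k] - ys[k - 1]) / (xs[k] - xs[k - 1])
    pmax(out, floor)
  }
}

#' Outlier mask for pairwise differences
#'
#' A pairwise difference `d = x_ij - x_ik` is retained iff
#' `|d| <= 4 * sqrt(E(s_jk))`, i.e. within four expected standard
#' deviations of 0 at its genomic distance. The Z-score is taken about 0
#' because pairwise differences are symmetric about zero under random
#' chromosome orientation.
#'
#' Intended for inspection at moderate problem sizes; [build_field()]
#' applies the same rule streamed per distance stratum without
#' materializing the full tensor.
#'
#' @param ds A centered `trace_dataset`.
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @param E Expected-variance curve from [expected_variance_curve()].
#' @return Logical `n x p x p` array; `FALSE` for missing spots and on the
#'   diagonal.
#' @export
outlier_mask <- function(ds, axis = c("x", "y", "z"), E) {
  axis <- match.arg(axis)
  X <- ds$coords[, , match(axis, AXES), drop = FALSE]
  dim(X) <- dim(ds$coords)[1:2]
  n <- nrow(X); p <- ncol(X)
  res <- bin_resolution(ds)
  M <- array(FALSE, c(n, p, p))
  for (g in seq_len(p - 1)) {
    D <- .gap_diffs(X, g)
    thr <- 4 * sqrt(E(g * res))
    keep <- !is.na(D) & abs(D) <= thr
    for (j in seq_len(p - g)) {
      M[, j, j + g] <- keep[, j]
      M[, j + g, j] <- keep[, j]
    }
  }
  M
}

#' Build the normalized per-axis variance field
#'
#' For each axis: (1) robust raw variance matrix; (2) lowess
#' expected-variance curve against genomic distance; (3) 4-SD outlier
#' filtering of the pairwise differences; (4) ordinary (mean-based) sample
#' variance of the surviving differences per entry, with the surviving
#' counts `C`; (5) a second lowess fit of the filtered variance against
#' distance; (6) normalization `V = filtered / second-fit prediction`,
#' removing the 1D genomic distance bias. Computation is streamed one
#' distance stratum at a time, so the `n x p x p` difference tensor is
#' never held in memory.
#'
#' @param ds A centered `trace_dataset`.
#' @return An object of class `variance_field`: per-axis lists `V`
#'   (normalized variance, `NaN` where fewer than 2 surviving
#'   differences), `C` (surviving counts), `E` (first-pass expected-
#'   variance curves, used by the outlier filter), `E2` (second-pass
#'   curves), `raw`, `filtered` and `expected` (second-fit predictions per
#'   entry), plus `bins`, `resolution` and `n`.
#' @export
build_field <- function(ds) {
  if (!isTRUE(ds$centered)) stop("dataset must be centered first")
  p <- n_bins(ds)
  res <- bin_resolution(ds)
  out <- list(V = list(), C = list(), E = list(), E2 = list(),
              raw = list(), filtered = list(), expected = list())
  for (a in AXES) {
    X <- ds$coords[, , match(a, AXES), drop = FALSE]
    dim(X) <- dim(ds$coords)[1:2]
    raw <- robust_variance_matrix(ds, a)
    E1 <- expected_variance_curve(raw, ds$bins)
    Fv <- matrix(NaN, p, p)
    Cm <- matrix(0L, p, p)
    for (g in seq_len(p - 1)) {
      D <- .gap_diffs(X, g)
      thr <- 4 * sqrt(E1(g * res))
      keep <- !is.na(D) & abs(D) <= thr
      Dk <- ifelse(keep, D, 0)
      cnt <- colSums(keep)
      s1 <- colSums(Dk)
      s2 <- colSums(Dk^2)
      v <- (s2 - s1^2 / pmax(cnt, 1)) / (cnt - 1)
      v[cnt < 2] <- NaN
      v <- pmax(v, 0)  # guard tiny negative round-off
      j <- seq_len(p - g)
      Fv[cbind(j, j + g)] <- v; Fv[cbind(j + g, j)] <- v
      Cm[cbind(j, j + g)] <- cnt; Cm[cbind(j + g, j)] <- cnt
    }
    E2 <- expected_variance_curve(Fv, ds$bins)
    S <- abs(outer(seq_len(p), seq_len(p), "-")) * res
    Ex <- matrix(E2(as.vector(S)), p, p)
    V <- Fv / Ex
    diag(V) <- NaN
    out$V[[a]] <- V; out$C[[a]] <- Cm; out$E[[a]] <- E1; out$E2[[a]] <- E2
    out$raw[[a]] <- raw; out$filtered[[a]] <- Fv; out$expected[[a]] <- Ex
  }
  out$bins <- ds$bins
  out$resolution <- res
  out$n <- n_traces(ds)
  class(out) <- "variance_field"
  out
}

#' @export
print.variance_field <- function(x, ...) {
  p <- nrow(x$V$x)
  cat(sprintf("Normalized variance field: %d x %d bins, 3 axes, %d traces\n",
              p, p, x$n))
  for (a in AXES)
    cat(sprintf("  %s: %.1f%% testable entries (C >= 2)\n", a,
                100 * mean(x$C[[a]][upper.tri(x$C[[a]])] >= 2)))
  invisible(x)
}

#' Count-weighted pooled variance from the field's sufficient statistics
#'
#' Pools normalized variances over a set of entries with weights `C - 1`:
#' `s2 = sum((C - 1) * V) / sum(C - 1)`, `df = sum(C - 1)`. Entries with
#' non-finite `V` or `C < 2` are skipped. This is the pooling used for
#' loop backgrounds and TAD inter/intra variances; it equals the pooled
#' sample variance computed directly from the surviving raw differences
#' (after per-entry normalization).
#'
#' @param field A `variance_field`.
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @param pairs Two-column matrix of (j, k) bin indices (1-based).
#' @return List with `s2` (pooled variance), `df` (pooled degrees of
#'   freedom) and `n_valid` (number of entries used).
#' @export
pooled_variance <- function(field, axis, pairs) {
  if (length(pairs) == 0 || nrow(pairs) == 0)
    return(list(s2 = NaN, df = 0, n_valid = 0L))
  v <- field$V[[axis]][pairs]
  cc <- field$C[[axis]][pairs]
  ok <- is.finite(v) & cc >= 2
  df <- sum(cc[ok] - 1)
  s2 <- if (df > 0) sum((cc[ok] - 1) * v[ok]) / df else NaN
  list(s2 = s2, df = df, n_valid = sum(ok))
}
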