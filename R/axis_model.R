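#' Estimate per-axis measurement-noise variance
#'
#' Under the spiked-covariance trace model, the observed coordinate on one
#' axis is a low-rank signal plus isotropic Gaussian noise. Because the
#' signal inflates only a minority of the per-bin variances when its rank is
#' small, the median over bins of the per-bin sample variance (across
#' traces, pairwise-complete) is a robust estimator of the noise variance.
#'
#' @param ds A centered `trace_dataset` (see [center_traces()]).
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @return Estimated noise variance in nm^2.
#' @export
estimate_noise_variance <- function(ds, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  if (!isTRUE(ds$centered)) stop("dataset must be centered first")
  X <- ds$coords[, , match(axis, AXES), drop = TRUE]
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  m <- colSums(!is.na(X))
  v <- rep(NA_real_, ncol(X))
  ok <- m >= 2
  v[ok] <- apply(X[, ok, drop = FALSE], 2, stats::var, na.rm = TRUE)
  if (sum(ok) < 3)
    stop("fewer than 3 bins with a computable variance on axis ", axis)
  stats::median(v[ok])
}

#' Estimate axis weights
#'
#' Estimates the three per-axis noise variances with
#' [estimate_noise_variance()] and converts them to normalized
#' inverse-variance weights, `w_a = (1/sigma2_a) / sum_b (1/sigma2_b)`,
#' so that more accurately measured axes receive more weight when axis-wise
#' statistics are combined.
#'
#' @param ds A centered `trace_dataset`.
#' @return An object of class `axis_weights`: a list with `sigma2` (named
#'   noise variances, nm^2) and `w` (named weights summing to one).
#' @export
compute_axis_weights <- function(ds) {
  if (n_bins(ds) < 10)
    warning("fewer than 10 bins: the low-rank identifiability assumption ",
            "behind the noise estimator is fragile here")
  sigma2 <- vapply(AXES, function(a) estimate_noise_variance(ds, a), 0)
  if (any(sigma2 == 0))
    stop("degenerate data: estimated noise variance is zero on axis ",
         paste(AXES[sigma2 == 0], collapse = ", "))
  w <- (1 / sigma2) / sum(1 / sigma2)
  structure(list(sigma2 = sigma2, w = w), class = "axis_weights")
}

#' Construct axis weights directly
#'
#' Builds an `axis_weights` object from given noise variances (or from
#' weights, for e.g. an equal-weights comparison run).
#'
#' @param sigma2 Optional length-3 noise variances (x, y, z order).
#' @param w Optional length-3 weights; normalized to sum to one.
#' @return An `axis_weights` object.
#' @export
axis_weights <- function(sigma2 = NULL, w = NULL) {
  if (is.null(w)) {
    stopifnot(length(sigma2) == 3, all(sigma2 > 0))
    w <- 1 / sigma2
  } else {
    stopifnot(length(w) == 3, all(w > 0))
    if (is.null(sigma2)) sigma2 <- 1 / w
  }
  w <- w / sum(w)
  names(w) <- names(sigma2) <- AXES
  structure(list(sigma2 = sigma2, w = w), class = "axis_weights")
}

#' @export
print.axis_weights <- function(x, ...) {
  cat("Axis noise variances (nm^2):\n")
  print(round(x$sigma2, 2))
  cat("Normalized inverse-variance weights:\n")
  print(round(x$w, 4))
  invisible(x)
}
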