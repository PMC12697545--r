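#' Fit the axis-aware chromatin trace model
#'
#' The main fitting function. Centers the traces (if needed), estimates
#' per-axis measurement-noise variances and inverse-variance weights, and
#' builds the normalized per-axis variance field that all feature callers
#' consume. Loops, TAD boundaries and A/B compartments are then obtained
#' with [call_loops()], [call_tads()] and [call_compartments()].
#'
#' @param ds A `trace_dataset` (e.g. from [read_fofct()] or
#'   [simulate_planted()]).
#' @param weights Optional `axis_weights` to use instead of estimating
#'   them (e.g. `axis_weights(w = c(1, 1, 1))` for an equal-weights run).
#' @param max_missing_frac Traces missing more than this fraction of spots
#'   are dropped before fitting (default 1: keep all).
#' @return An object of class `axistrace`: a list with elements `data`
#'   (the centered dataset), `weights` (`axis_weights`), `field`
#'   (`variance_field`) and `call`.
#' @examples
#' sim <- simulate_planted(simulation_spec(n = 60, p = 20, seed = 1))
#' fit <- axistrace(sim$data)
#' coef(fit)
#' @export
axistrace <- function(ds, weights = NULL, max_missing_frac = 1) {
  stopifnot(inherits(ds, "trace_dataset"))
  cl <- match.call()
  if (max_missing_frac < 1) {
    miss <- rowMeans(is.na(ds$coords[, , 1, drop = FALSE]))
    keep <- miss <= max_missing_frac
    if (!all(keep)) {
      ds$coords <- ds$coords[keep, , , drop = FALSE]
      ds$trace_ids <- ds$trace_ids[keep]
    }
  }
  if (!isTRUE(ds$centered)) ds <- center_traces(ds)
  if (is.null(weights)) weights <- compute_axis_weights(ds)
  stopifnot(inherits(weights, "axis_weights"))
  field <- build_field(ds)
  structure(list(data = ds, weights = weights, field = field, call = cl),
            class = "axistrace")
}

#' @export
print.axistrace <- function(x, ...) {
  cat("Axis-aware chromatin trace model\n")
  cat("Call: ", deparse(x$call), "\n\n")
  print(x$data)
  cat("\n")
  print(x$weights)
  invisible(x)
}

#' @export
summary.axistrace <- function(object, ...) {
  V <- object$field$V
  s <- list(
    n = n_traces(object$data), p = n_bins(object$data),
    chrom = object$data$bins$chrom[1],
    resolution = bin_resolution(object$data),
    sigma2 = object$weights$sigma2, w = object$weights$w,
    testable = vapply(AXES, function(a)
      mean(is.finite(V[[a]][upper.tri(V[[a]])])), 0),
    v_mean = vapply(AXES, function(a)
      mean(V[[a]][upper.tri(V[[a]])], na.rm = TRUE), 0))
  class(s) <- "summary.axistrace"
  s
}

#' @export
print.summary.axistrace <- function(x, ...) {
  cat(sprintf("Axis-aware trace model: %d traces x %d bins on %s (%g bp/bin)\n",
              x$n, x$p, x$chrom, x$resolution))
  cat("\nEstimated noise SD (nm) and weights:\n")
  print(data.frame(axis = AXES, noise_sd = round(sqrt(x$sigma2), 1),
                   weight = round(x$w, 4), row.names = NULL))
  cat("\nNormalized variance field (upper triangle):\n")
  print(data.frame(axis = AXES, frac_testable = round(x$testable, 3),
                   mean_V = round(x$v_mean, 3), row.names = NULL))
  invisible(x)
}

#' @export
coef.axistrace <- function(object, ...) object$weights$w

#' @export
weights.axistrace <- function(object, ...) object$weights$w

#' Diagnostic plot: variance against genomic distance
#'
#' Plots, per axis, the filtered per-entry variances against 1D genomic
#' distance with the fitted lowess expectation overlaid — the fit whose
#' predictions normalize the field. A flat normalized field near 1
#' indicates the distance bias has been removed.
#'
#' @param x An `axistrace` fit.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.axistrace <- function(x, ...) {
  fld <- x$field
  p <- n_bins(x$data); res <- fld$resolution
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (a in AXES) {
    Fv <- fld$filtered[[a]]
    ut <- which(upper.tri(Fv), arr.ind = TRUE)
    s <- (ut[, 2] - ut[, 1]) * res / 1000
    v <- Fv[ut]
    graphics::plot(s, v, pch = ".", col = "grey40",
                   xlab = "genomic distance (kb)",
                   ylab = "filtered variance (nm^2)",
                   main = paste0(a, "-axis"), ...)
    sg <- sort(unique(s))
    graphics::lines(sg, fld$E2[[a]](sg * 1000), col = "red3", lwd = 2)
  }
  invisible(x)
}
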