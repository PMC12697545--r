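# Simulators: real-data resampling with axis-noise injection (the
# uniform-noise benchmark design), a spiked low-rank generator for noise-
# estimator validation, and a fully synthetic Gaussian trace generator
# with planted loops, TAD blocks and compartment blocks.

# run expr with a locally seeded RNG, restoring the caller's stream
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  expr
}

#' Specification for the synthetic trace generator
#'
#' Defines the Gaussian trace model the generator draws from. The signal
#' covariance starts from a cumulative random-walk kernel
#' `K0(j, k) = scale^2 * min(j, k)` (1-based bins), so pairwise-difference
#' variance grows linearly with genomic separation, emulating polymer
#' distance decay; planted features then perturb `K0`:
#'
#' * a boundary at bin b (insulation f > 1) divides the covariance of all
#'   pairs straddling b by `f`, inflating cross-boundary differences;
#' * compartment blocks (labels, affinity c in nm) add the rank-1 block
#'   term `c^2 * u u'` (u = +/-1 by label) on the chosen axes, spatially
#'   separating the two compartment clusters: cross-label pair
#'   differences gain `4 c^2` nm^2 of variance, same-label pairs none;
#' * a loop (anchors j, k, proximity rho < 1) contracts the two anchor
#'   coordinates toward their midpoint (a congruence `A K A'`), shrinking
#'   the implied pair-difference variance to exactly `rho` times its
#'   pre-loop value while keeping the kernel positive semidefinite.
#'
#' If the insulation perturbation breaks positive semidefiniteness the
#' kernel is eigenvalue-clipped at zero (with a warning), so extreme
#' planted effects can be realized only approximately.
#'
#' An optional `arm_shift` adds, per trace, a random rigid offset (per-axis
#' SD in nm) to all bins after a split point — emulating the relative
#' placement of two chromosome arms, a whole-region confounder for
#' compartment calling.
#'
#' @param n Number of traces.
#' @param p Number of bins.
#' @param resolution Bin width in bp.
#' @param scale Backbone scale: per-axis SD (nm) of the coordinate step
#'   between adjacent bins.
#' @param noise_sd Length-3 per-axis measurement-noise SD in nm (x, y, z).
#' @param missing_rate Probability that a spot is unobserved.
#' @param loops `data.frame(j, k, proximity)` or `NULL`.
#' @param boundaries `data.frame(pos, insulation)` or `NULL` (`pos` is the
#'   last bin of the upstream block).
#' @param compartments `list(labels, affinity, axes)` or `NULL`; `labels`
#'   is a length-p vector of two values, `axes` the axes carrying the
#'   compartment signal (default all three).
#' @param arm_shift `list(split, sd)` or `NULL`; `sd` is a length-3
#'   per-axis SD in nm of the per-trace offset added to bins > `split`.
#' @param seed RNG seed.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(n, p = 60, resolution = 25000, scale = 85,
                            noise_sd = c(100, 100, 100), missing_rate = 0,
                            loops = NULL, boundaries = NULL,
                            compartments = NULL, arm_shift = NULL,
                            seed = 1) {
  stopifnot(n >= 1, p >= 3, resolution > 0, scale >= 0,
            length(noise_sd) == 3, all(noise_sd >= 0),
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(loops)) {
    stopifnot(all(c("j", "k", "proximity") %in% names(loops)),
              all(loops$j < loops$k), all(loops$k <= p),
              all(loops$proximity > 0))
  }
  if (!is.null(boundaries))
    stopifnot(all(c("pos", "insulation") %in% names(boundaries)),
              all(boundaries$pos >= 1), all(boundaries$pos < p),
              all(boundaries$insulation > 0))
  if (!is.null(compartments)) {
    stopifnot(length(compartments$labels) == p,
              length(unique(compartments$labels)) <= 2,
              compartments$affinity > 0)
    if (is.null(compartments$axes)) compartments$axes <- AXES
    stopifnot(all(compartments$axes %in% AXES))
  }
  if (!is.null(arm_shift))
    stopifnot(arm_shift$split >= 1, arm_shift$split < p,
              length(arm_shift$sd) == 3, all(arm_shift$sd >= 0))
  structure(list(n = n, p = p, resolution = resolution, scale = scale,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 loops = loops, boundaries = boundaries,
                 compartments = compartments, arm_shift = arm_shift,
                 seed = seed),
            class = "simulation_spec")
}

# signal kernel for one axis, with planted perturbations and PSD clip
.build_kernel <- function(spec, axis) {
  p <- spec$p
  K <- spec$scale^2 * outer(seq_len(p), seq_len(p), pmin)
  if (!is.null(spec$boundaries)) {
    for (r in seq_len(nrow(spec$boundaries))) {
      b <- spec$boundaries$pos[r]; f <- spec$boundaries$insulation[r]
      cross <- outer(seq_len(p) <= b, seq_len(p) > b, "&")
      cross <- cross | t(cross)
      K[cross] <- K[cross] / f
    }
  }
  if (!is.null(spec$compartments) && axis %in% spec$compartments$axes) {
    L <- spec$compartments$labels
    u <- ifelse(L == L[1], 1, -1)
    # rank-1 block term: same-label covariance up, cross-label down, so
    # cross-label pair differences gain 4 * affinity^2 nm^2 of variance
    # (a spatial separation of the two compartment clusters); PSD-safe
    K <- K + spec$compartments$affinity^2 * tcrossprod(u)
  }
  if (!is.null(spec$loops)) {
    # anchor contraction: blend the two anchor coordinates toward their
    # midpoint with a linear map A, K <- A K A'. The pair difference is
    # scaled by exactly sqrt(rho), so its variance shrinks to rho times
    # the pre-loop value, and the congruence keeps K positive
    # semidefinite by construction. Loops sharing an anchor compose
    # sequentially in row order.
    for (r in seq_len(nrow(spec$loops))) {
      j <- spec$loops$j[r]; k <- spec$loops$k[r]
      alpha <- 1 - sqrt(spec$loops$proximity[r])
      A <- diag(p)
      A[j, j] <- A[k, k] <- 1 - alpha / 2
      A[j, k] <- A[k, j] <- alpha / 2
      K <- A %*% K %*% t(A)
    }
  }
  ed <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(ed$values) < -1e-8 * max(abs(ed$values), 1))
    warning("planted perturbations broke positive semidefiniteness on axis ",
            axis, "; kernel clipped (realized effects may be weaker)")
  list(U = ed$vectors, lambda = pmax(ed$values, 0))
}

#' Generate synthetic chromatin traces with planted 3D genome features
#'
#' Draws each axis independently from `N_p(0, K_axis)` (see
#' [simulation_spec()]), adds per-axis Gaussian measurement noise, an
#' optional per-trace arm offset, and masks spots at the missing rate.
#' Every source of randomness flows from `spec$seed`, so the output
#' is reproducible.
#'
#' @param spec A [simulation_spec()].
#' @return A list with `data` (an uncentered [trace_dataset()]) and
#'   `truth` (the planted loop/boundary/compartment tables and the noise
#'   SDs).
#' @export
simulate_planted <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  n <- spec$n; p <- spec$p
  co <- .with_seed(spec$seed, {
    co <- array(NA_real_, c(n, p, 3))
    for (a in 1:3) {
      kern <- .build_kernel(spec, AXES[a])
      Z <- matrix(stats::rnorm(n * p), n, p)
      co[, , a] <- Z %*% (diag(sqrt(kern$lambda), p) %*% t(kern$U))
    }
    if (!is.null(spec$arm_shift)) {
      after <- seq_len(p) > spec$arm_shift$split
      for (a in 1:3) {
        if (spec$arm_shift$sd[a] == 0) next
        off <- stats::rnorm(n, 0, spec$arm_shift$sd[a])
        co[, after, a] <- co[, after, a] + off
      }
    }
    for (a in 1:3)
      if (spec$noise_sd[a] > 0)
        co[, , a] <- co[, , a] + stats::rnorm(n * p, 0, spec$noise_sd[a])
    if (spec$missing_rate > 0) {
      miss <- matrix(stats::runif(n * p) < spec$missing_rate, n, p)
      for (a in 1:3) co[, , a][miss] <- NA_real_
    }
    co
  })
  bins <- genomic_bins("chrS", (seq_len(p) - 1) * spec$resolution,
                       seq_len(p) * spec$resolution)
  ds <- trace_dataset(co, sprintf("T%04d", seq_len(n)), bins)
  list(data = ds,
       truth = list(loops = spec$loops, boundaries = spec$boundaries,
                    compartments = spec$compartments,
                    noise_sd = stats::setNames(spec$noise_sd, AXES)))
}

#' Generate a sparse spiked-covariance dataset
#'
#' Coordinates are a rank-`rank` Gaussian signal confined to a small
#' subset of bins plus isotropic per-axis noise — the regime in which the
#' median-diagonal noise estimator is consistent (the signal inflates
#' only a minority of per-bin variances). The same signal covariance is
#' shared by the three axes; draws are independent per axis.
#'
#' @param n,p Number of traces / bins.
#' @param rank Signal rank.
#' @param n_support Number of bins carrying signal.
#' @param loading_sd SD (nm) of the signal loadings.
#' @param noise_sd Length-3 per-axis noise SD (nm).
#' @param resolution Bin width (bp).
#' @param seed RNG seed.
#' @return A list with `data` (uncentered [trace_dataset()]) and `truth`
#'   (`noise_sd`, `support` bins).
#' @export
simulate_spiked <- function(n, p = 60, rank = 3, n_support = 10,
                            loading_sd = 300, noise_sd = c(100, 100, 200),
                            resolution = 25000, seed = 1) {
  stopifnot(rank >= 1, n_support <= p, length(noise_sd) == 3)
  out <- .with_seed(seed, {
    support <- sort(sample.int(p, n_support))
    B <- matrix(0, p, rank)
    B[support, ] <- stats::rnorm(n_support * rank, 0, loading_sd)
    # remove the loadings' center-of-mass component: traces are analyzed
    # after per-trace centering, so signal along the all-ones direction
    # is not part of the model and would only smear variance across bins
    B[support, ] <- sweep(B[support, , drop = FALSE], 2,
                          colMeans(B[support, , drop = FALSE]))
    co <- array(0, c(n, p, 3))
    for (a in 1:3) {
      U <- matrix(stats::rnorm(n * rank), n, rank)
      co[, , a] <- U %*% t(B) + stats::rnorm(n * p, 0, noise_sd[a])
    }
    list(co = co, support = support)
  })
  bins <- genomic_bins("chrS", (seq_len(p) - 1) * resolution,
                       seq_len(p) * resolution)
  ds <- trace_dataset(out$co, sprintf("T%04d", seq_len(n)), bins)
  list(data = ds, truth = list(noise_sd = stats::setNames(noise_sd, AXES),
                               support = out$support))
}

#' Resample a dataset into uniform-noise traces
#'
#' Builds each output trace from three x-axis profiles sampled (with
#' replacement across output traces, from three distinct source traces
#' within each output trace) of the input data; the three profiles become
#' the new x, y and z coordinates. Because all three axes then originate
#' from the x-axis of the source, they share one level of measurement
#' uncertainty — the uniform-noise baseline onto which axis-specific
#' noise can be injected with [add_axis_noise()]. A spot is missing in
#' the output when any of its three sampled profiles lacks it (keeping
#' spots all-or-none across axes).
#'
#' @param ds Source `trace_dataset` (>= 3 traces).
#' @param n_out Number of output traces.
#' @param seed RNG seed.
#' @return A `trace_dataset` with `n_out` traces.
#' @export
resample_uniform_noise <- function(ds, n_out, seed = 1) {
  n <- n_traces(ds); p <- n_bins(ds)
  if (n < 3) stop("at least 3 source traces are required")
  if (n_out <= 0) stop("n_out must be positive")
  co <- .with_seed(seed, {
    co <- array(NA_real_, c(n_out, p, 3))
    for (i in seq_len(n_out)) {
      src <- sample.int(n, 3, replace = FALSE)
      prof <- t(ds$coords[src, , 1])       # p x 3, x-axis profiles
      prof[rowSums(is.na(prof)) > 0, ] <- NA_real_
      co[i, , ] <- prof
    }
    co
  })
  trace_dataset(co, sprintf("S%04d", seq_len(n_out)), ds$bins,
                centered = FALSE)
}

#' Inject axis-specific Gaussian noise
#'
#' Adds independent centered Gaussian noise to every observed spot, with
#' a separate SD per axis; missing spots are unchanged. Used to emulate
#' heterogeneous measurement error (e.g. extra z-axis noise).
#'
#' @param ds A `trace_dataset`.
#' @param sd_by_axis Length-3 noise SD in nm (x, y, z).
#' @param seed RNG seed.
#' @return The noisy `trace_dataset`.
#' @export
add_axis_noise <- function(ds, sd_by_axis, seed = 1) {
  stopifnot(length(sd_by_axis) == 3, all(sd_by_axis >= 0))
  if (all(sd_by_axis == 0)) return(ds)
  co <- .with_seed(seed, {
    co <- ds$coords
    for (a in 1:3) {
      if (sd_by_axis[a] == 0) next
      obs <- !is.na(co[, , a])
      co[, , a][obs] <- co[, , a][obs] +
        stats::rnorm(sum(obs), 0, sd_by_axis[a])
    }
    co
  })
  trace_dataset(co, ds$trace_ids, ds$bins, centered = FALSE)
}
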