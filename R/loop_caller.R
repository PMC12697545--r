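# Chromatin loop calling: per-pair variance-ratio tests against a pooled
# 25-50 Kb local background ring, weighted Cauchy combination across axes,
# BH screening, candidate clustering and summit filters.

#' Loop-calling configuration
#'
#' @param background_min_kb,background_max_kb Ring radii: the local
#'   background of a tested pair contains pairs whose anchors are
#'   displaced by 25-50 Kb (Chebyshev distance in genomic units).
#' @param min_separation_kb Smallest tested anchor separation; keeps the
#'   background ring off the diagonal.
#' @param fdr_threshold Candidate screen on BH FDR.
#' @param cluster_radius_kb Candidates within this anchor distance are
#'   grouped; each group's smallest-p member is its summit.
#' @param summit_p_cutoff Final p-value filter on summits.
#' @param contact_cutoff_nm 3D distance below which two bins count as in
#'   contact for the population contact frequency.
#' @param cluster_freq_min,singleton_freq_min Minimum contact frequency
#'   for cluster summits / singleton summits when the frequency filter is
#'   enabled.
#' @param apply_frequency_filter Whether to apply the contact-frequency
#'   filter (off by default; its use is dataset-specific).
#' @return A list of class `loop_config`.
#' @export
loop_config <- function(background_min_kb = 25, background_max_kb = 50,
                        min_separation_kb = 100, fdr_threshold = 0.1,
                        cluster_radius_kb = 50, summit_p_cutoff = 1e-5,
                        contact_cutoff_nm = 500, cluster_freq_min = 1/3,
                        singleton_freq_min = 1/2,
                        apply_frequency_filter = FALSE) {
  stopifnot(background_min_kb > 0, background_min_kb <= background_max_kb,
            fdr_threshold > 0, fdr_threshold <= 1,
            summit_p_cutoff > 0, summit_p_cutoff <= 1)
  structure(list(background_min_kb = background_min_kb,
                 background_max_kb = background_max_kb,
                 min_separation_kb = min_separation_kb,
                 fdr_threshold = fdr_threshold,
                 cluster_radius_kb = cluster_radius_kb,
                 summit_p_cutoff = summit_p_cutoff,
                 contact_cutoff_nm = contact_cutoff_nm,
                 cluster_freq_min = cluster_freq_min,
                 singleton_freq_min = singleton_freq_min,
                 apply_frequency_filter = apply_frequency_filter),
            class = "loop_config")
}

#' Local background ring of a bin pair
#'
#' All pairs (j', k') with `j' < k'`, both in range, distinct from
#' (j, k), whose anchor displacement `max(|j' - j|, |k' - k|)` falls
#' between `background_min_kb` and `background_max_kb` in genomic units
#' (a square Chebyshev ring), and which are themselves off-diagonal by at
#' least `background_min_kb`.
#'
#' @param j,k Bin indices (1-based, `j < k`).
#' @param p Number of bins.
#' @param resolution Bin width in bp.
#' @param config A [loop_config()].
#' @return Two-column integer matrix of (j', k') pairs.
#' @export
background_ring <- function(j, k, p, resolution, config = loop_config()) {
  stopifnot(j < k)
  res_kb <- resolution / 1000
  rmin <- ceiling(config$background_min_kb / res_kb)
  rmax <- floor(config$background_max_kb / res_kb)
  if (rmax < rmin) return(matrix(integer(0), 0, 2))
  d <- -rmax:rmax
  grid <- expand.grid(dj = d, dk = d)
  cheb <- pmax(abs(grid$dj), abs(grid$dk))
  grid <- grid[cheb >= rmin & cheb <= rmax, ]
  jp <- j + grid$dj; kp <- k + grid$dk
  keep <- jp >= 1 & kp <= p & jp < kp & (kp - jp) >= rmin
  cbind(j = as.integer(jp[keep]), k = as.integer(kp[keep]))
}

#' Test one bin pair against its local background
#'
#' Per axis, the pooled background variance over the ring (weights
#' `C - 1`; see [pooled_variance()]) is compared to the entry's
#' normalized variance with a lower-tail F test: a loop has a
#' significantly *smaller* pairwise-difference variance than its
#' neighborhood. Axes with fewer than 3 valid ring entries or entry
#' count `C < 3` are untestable (`NaN`); the combined p-value drops them
#' and renormalizes the weights.
#'
#' @param field A `variance_field`.
#' @param w An `axis_weights` object.
#' @param j,k Bin indices (1-based, `j < k`).
#' @param config A [loop_config()].
#' @return One-row data.frame with `j`, `k`, per-axis p-values, combined
#'   `stat` and `p`.
#' @export
test_pair <- function(field, w, j, k, config = loop_config()) {
  p <- nrow(field$V$x)
  ring <- background_ring(j, k, p, field$resolution, config)
  px <- vapply(AXES, function(a) .test_pair_axis(field, a, j, k, ring), 0)
  cc <- cauchy_combine(px, w)
  data.frame(j = j, k = k, p_x = px[1], p_y = px[2], p_z = px[3],
             stat = attr(cc, "statistic"), p = as.numeric(cc))
}

.test_pair_axis <- function(field, a, j, k, ring) {
  cjk <- field$C[[a]][j, k]
  vjk <- field$V[[a]][j, k]
  if (cjk < 3 || !is.finite(vjk)) return(NaN)
  bg <- pooled_variance(field, a, ring)
  if (bg$n_valid < 3 || !is.finite(bg$s2) || bg$s2 <= 0) return(NaN)
  .vr_pvalue(vjk / bg$s2, cjk - 1, bg$df, lower = TRUE)
}

#' Test all eligible pairs and flag loop candidates
#'
#' Tests every pair with anchor separation at least `min_separation_kb`,
#' converts the combined p-values to BH FDRs over the tested pairs, and
#' flags candidates with FDR below the threshold.
#'
#' @param field A `variance_field`.
#' @param w An `axis_weights` object.
#' @param config A [loop_config()].
#' @return A data.frame of class `loop_calls` with one row per eligible
#'   pair: `j`, `k`, `p_x`, `p_y`, `p_z`, `stat`, `p`, `fdr`,
#'   `is_candidate`.
#' @export
call_candidates <- function(field, w, config = loop_config()) {
  p <- nrow(field$V$x)
  res <- field$resolution
  min_sep <- ceiling(config$min_separation_kb * 1000 / res)
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  pairs <- pairs[pairs[, 2] - pairs[, 1] >= min_sep, , drop = FALSE]
  if (nrow(pairs) == 0) {
    warning("no testable pairs at this separation")
    out <- data.frame(j = integer(0), k = integer(0), p_x = numeric(0),
                      p_y = numeric(0), p_z = numeric(0), stat = numeric(0),
                      p = numeric(0), fdr = numeric(0),
                      is_candidate = logical(0))
    return(structure(out, class = c("loop_calls", "data.frame"),
                     config = config, bins = field$bins))
  }
  P <- matrix(NaN, nrow(pairs), 3, dimnames = list(NULL, AXES))
  for (i in seq_len(nrow(pairs))) {
    ring <- background_ring(pairs[i, 1], pairs[i, 2], p, res, config)
    for (a in AXES)
      P[i, a] <- .test_pair_axis(field, a, pairs[i, 1], pairs[i, 2], ring)
  }
  cc <- .cauchy_combine_mat(P, w$w)
  fdr <- bh_fdr(cc$p)
  out <- data.frame(j = pairs[, 1], k = pairs[, 2],
                    p_x = P[, 1], p_y = P[, 2], p_z = P[, 3],
                    stat = cc$stat, p = cc$p, fdr = fdr,
                    is_candidate = !is.na(fdr) & fdr < config$fdr_threshold)
  if (!any(out$is_candidate) && all(is.na(out$p)))
    warning("no pair could be tested")
  structure(out, class = c("loop_calls", "data.frame"),
            config = config, bins = field$bins)
}

#' Group loop candidates and pick summits
#'
#' Builds a graph on candidates with edges between pairs whose anchor
#' displacement (Chebyshev, genomic units) is at most
#' `cluster_radius_kb`; connected components are clusters (so chains are
#' merged transitively), and each cluster's minimum-p member is its
#' summit (ties broken lexicographically on (j, k)).
#'
#' @param calls A `loop_calls` data.frame from [call_candidates()].
#' @param config A [loop_config()].
#' @return `calls` with `cluster_id` (NA for non-candidates) and
#'   `is_summit` columns.
#' @export
cluster_summits <- function(calls, config = attr(calls, "config")) {
  res <- attr(attr(calls, "bins"), "resolution")
  rad <- floor(config$cluster_radius_kb * 1000 / res)
  calls$cluster_id <- NA_integer_
  calls$is_summit <- FALSE
  idx <- which(calls$is_candidate)
  if (length(idx) == 0) return(calls)
  jj <- calls$j[idx]; kk <- calls$k[idx]
  m <- length(idx)
  lab <- seq_len(m)
  # union-find over candidate pairs (m is small)
  find <- function(i) { while (lab[i] != i) i <- lab[i]; i }
  for (i in seq_len(m)) for (l in seq_len(m)) {
    if (l <= i) next
    if (max(abs(jj[i] - jj[l]), abs(kk[i] - kk[l])) <= rad) {
      ri <- find(i); rl <- find(l)
      if (ri != rl) lab[max(ri, rl)] <- min(ri, rl)
    }
  }
  roots <- vapply(seq_len(m), find, 0L)
  cid <- match(roots, sort(unique(roots)))
  calls$cluster_id[idx] <- cid
  for (cl in unique(cid)) {
    members <- idx[cid == cl]
    o <- order(calls$p[members], calls$j[members], calls$k[members])
    calls$is_summit[members[o[1]]] <- TRUE
  }
  calls
}

#' Population contact frequency of a bin pair
#'
#' Fraction of traces, among those observing both spots, whose 3D
#' Euclidean distance between bins `j` and `k` is below `cutoff_nm`.
#'
#' @param ds A `trace_dataset`.
#' @param j,k Bin indices (1-based).
#' @param cutoff_nm Contact distance cutoff in nm.
#' @return A fraction in `[0, 1]`, or `NaN` with no co-observed trace.
#' @export
contact_frequency <- function(ds, j, k, cutoff_nm = 500) {
  d2 <- (ds$coords[, j, 1] - ds$coords[, k, 1])^2 +
    (ds$coords[, j, 2] - ds$coords[, k, 2])^2 +
    (ds$coords[, j, 3] - ds$coords[, k, 3])^2
  d2 <- d2[!is.na(d2)]
  if (length(d2) == 0) return(NaN)
  mean(sqrt(d2) < cutoff_nm)
}

#' Apply the final summit filters
#'
#' Keeps summits with combined p below `summit_p_cutoff`. When the
#' contact-frequency filter is enabled, cluster summits (cluster size
#' > 1) additionally need a population contact frequency of at least 1/3
#' and singleton summits at least 1/2.
#'
#' @param calls A `loop_calls` data.frame with summit flags (from
#'   [cluster_summits()]).
#' @param ds The `trace_dataset` the field was built from (for contact
#'   frequencies).
#' @param config A [loop_config()].
#' @return `calls` with `contact_freq` (computed for summits) and
#'   `is_final` columns.
#' @export
finalize_loops <- function(calls, ds, config = attr(calls, "config")) {
  calls$contact_freq <- NA_real_
  calls$is_final <- FALSE
  s <- which(calls$is_summit)
  if (length(s) == 0) return(calls)
  for (i in s)
    calls$contact_freq[i] <-
      contact_frequency(ds, calls$j[i], calls$k[i], config$contact_cutoff_nm)
  keep <- calls$p[s] < config$summit_p_cutoff
  if (config$apply_frequency_filter) {
    csize <- table(calls$cluster_id[calls$is_candidate])
    singleton <- csize[as.character(calls$cluster_id[s])] == 1
    fmin <- ifelse(singleton, config$singleton_freq_min, config$cluster_freq_min)
    keep <- keep & !(calls$contact_freq[s] < fmin)
  }
  calls$is_final[s[keep]] <- TRUE
  calls
}

#' Call chromatin loops from a fitted model
#'
#' Runs the full loop pipeline on an [axistrace()] fit: per-pair tests
#' against the 25-50 Kb background ring, BH candidate screen, candidate
#' clustering with summit selection, and the final p-value (and optional
#' contact-frequency) filters.
#'
#' @param fit An `axistrace` fit.
#' @param config A [loop_config()]; individual fields can also be passed
#'   through `...`.
#' @param ... Overrides for [loop_config()] fields.
#' @return A `loop_calls` data.frame (one row per tested pair) with
#'   columns `j`, `k`, per-axis and combined p-values, `fdr`,
#'   `is_candidate`, `cluster_id`, `is_summit`, `contact_freq`,
#'   `is_final`.
#' @export
call_loops <- function(fit, config = NULL, ...) {
  stopifnot(inherits(fit, "axistrace"))
  if (is.null(config)) config <- loop_config(...)
  calls <- call_candidates(fit$field, fit$weights, config)
  calls <- cluster_summits(calls, config)
  finalize_loops(calls, fit$data, config)
}

#' @export
`[.loop_calls` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}

#' @export
print.loop_calls <- function(x, ...) {
  cat(sprintf("Loop calls: %d tested pairs, %d candidates, %d summits, %d final\n",
              nrow(x), sum(x$is_candidate, na.rm = TRUE),
              sum(x$is_summit, na.rm = TRUE), sum(x$is_final, na.rm = TRUE)))
  cols <- intersect(c("j", "k", "p", "fdr", "contact_freq"), names(x))
  fin <- as.data.frame(x)[which(x$is_final), cols]
  if (nrow(fin) > 0) print(fin, row.names = FALSE)
  invisible(x)
}

#' Write loop calls as BEDPE
#'
#' One record per row of `calls` (or per final loop), with the test
#' columns appended after the six BEDPE coordinates.
#'
#' @param calls A `loop_calls` data.frame.
#' @param path Output path.
#' @param final_only Write only final loops (default) or all tested pairs.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(calls, path, final_only = TRUE) {
  bins <- attr(calls, "bins")
  rows <- if (final_only) calls[which(calls$is_final), ] else calls
  df <- data.frame(chrom1 = bins$chrom[rows$j], start1 = bins$start[rows$j],
                   end1 = bins$end[rows$j], chrom2 = bins$chrom[rows$k],
                   start2 = bins$start[rows$k], end2 = bins$end[rows$k],
                   p_x = rows$p_x, p_y = rows$p_y, p_z = rows$p_z,
                   p = rows$p, fdr = rows$fdr,
                   cluster_id = rows$cluster_id,
                   is_summit = rows$is_summit,
                   contact_freq = rows$contact_freq)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
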