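# TAD boundary calling: per-bin inter- vs intra-domain variance F-tests in
# a fixed window, weighted Cauchy combination, peak finding on an
# F(1,1)-approximated FDR profile, and hierarchical TAD assembly.

#' TAD-calling configuration
#'
#' @param window_kb Window length on *each side* of the tested bin
#'   (default 200 Kb, i.e. 8 bins at 25 Kb resolution).
#' @param fdr_threshold Boundary screen on BH FDR.
#' @param min_side_fraction Minimum fraction of window bins that must be
#'   available on each side; edge bins failing this are excluded.
#' @return A list of class `tad_config`.
#' @export
tad_config <- function(window_kb = 200, fdr_threshold = 0.1,
                       min_side_fraction = 0.5) {
  stopifnot(window_kb > 0, fdr_threshold > 0, fdr_threshold <= 1,
            min_side_fraction > 0, min_side_fraction <= 1)
  structure(list(window_kb = window_kb, fdr_threshold = fdr_threshold,
                 min_side_fraction = min_side_fraction),
            class = "tad_config")
}

#' Upstream/downstream window partition of a tested bin
#'
#' With `w = window_kb / resolution` bins per side, the upstream set is
#' `{i-w, ..., i-1}` and the downstream set `{i+1, ..., i+w}`, clipped to
#' the region; the tested bin belongs to neither. The bin is excluded
#' when either side retains fewer than `min_side_fraction * w` bins.
#' Intra-domain pairs are the pairs within each side; inter-domain pairs
#' are upstream x downstream.
#'
#' @param i Bin index (1-based).
#' @param p Number of bins.
#' @param resolution Bin width (bp).
#' @param config A [tad_config()].
#' @return `NULL` if excluded, else a list with `U`, `D` (bin indices)
#'   and two-column pair matrices `inter` and `intra`.
#' @export
domain_partition <- function(i, p, resolution, config = tad_config()) {
  w <- round(config$window_kb * 1000 / resolution)
  U <- intersect((i - w):(i - 1), seq_len(p))
  D <- intersect((i + 1):(i + w), seq_len(p))
  if (length(U) < config$min_side_fraction * w ||
      length(D) < config$min_side_fraction * w) return(NULL)
  side_pairs <- function(s) {
    if (length(s) < 2) return(matrix(integer(0), 0, 2))
    t(utils::combn(s, 2))
  }
  intra <- rbind(side_pairs(U), side_pairs(D))
  inter <- cbind(j = rep(U, each = length(D)), k = rep(D, length(U)))
  list(U = U, D = D, inter = inter, intra = intra)
}

#' Inter- vs intra-domain variance test at one bin
#'
#' Per axis, the count-weighted pooled inter-domain variance is compared
#' to the pooled intra-domain variance with an upper-tail F test: at a
#' TAD boundary, cross-window differences have a significantly *larger*
#' variance than within-window differences. Also reports the
#' F(1,1)-approximated p-values used for numerically stable peak finding
#' at large sample sizes.
#'
#' @param field A `variance_field`.
#' @param w An `axis_weights` object.
#' @param i Bin index (1-based).
#' @param config A [tad_config()].
#' @return One-row data.frame with `i`, per-axis p-values, combined
#'   `stat`, `p`, and `approx_p` (combined from per-axis F(1,1)
#'   p-values); or `NULL` when the bin is excluded by the window rule.
#' @export
boundary_test <- function(field, w, i, config = tad_config()) {
  part <- domain_partition(i, nrow(field$V$x), field$resolution, config)
  if (is.null(part)) return(NULL)
  px <- pa <- rep(NaN, 3); names(px) <- names(pa) <- AXES
  for (a in AXES) {
    inter <- pooled_variance(field, a, part$inter)
    intra <- pooled_variance(field, a, part$intra)
    if (inter$df < 1 || intra$df < 1 ||
        !is.finite(inter$s2) || !is.finite(intra$s2) || intra$s2 <= 0) next
    r <- inter$s2 / intra$s2
    px[a] <- .vr_pvalue(r, inter$df, intra$df, lower = FALSE)
    pa[a] <- .vr_pvalue(r, 1, 1, lower = FALSE)
  }
  cc <- cauchy_combine(px, w)
  ca <- cauchy_combine(pa, w)
  data.frame(i = i, p_x = px[1], p_y = px[2], p_z = px[3],
             stat = attr(cc, "statistic"), p = as.numeric(cc),
             approx_p = as.numeric(ca))
}

#' Per-bin TAD boundary profile
#'
#' Runs [boundary_test()] at every non-excluded bin and BH-adjusts both
#' the exact p-values (`fdr`, which gates the final calls) and the
#' F(1,1)-approximated ones (`approx_fdr`, on which peaks are located:
#' with thousands of traces the exact FDRs saturate at 0/1 while the
#' approximation stays graded).
#'
#' @param field A `variance_field`.
#' @param w An `axis_weights` object.
#' @param config A [tad_config()].
#' @return A data.frame of class `tad_profile` with one row per bin
#'   (excluded bins carry `NaN`): `i`, per-axis p-values, `stat`, `p`,
#'   `fdr`, `approx_p`, `approx_fdr`.
#' @export
boundary_profile <- function(field, w, config = tad_config()) {
  p <- nrow(field$V$x)
  rows <- lapply(seq_len(p), function(i) {
    r <- boundary_test(field, w, i, config)
    if (is.null(r))
      r <- data.frame(i = i, p_x = NaN, p_y = NaN, p_z = NaN, stat = NaN,
                      p = NaN, approx_p = NaN)
    r
  })
  prof <- do.call(rbind, rows)
  prof$fdr <- bh_fdr(prof$p)
  prof$approx_fdr <- bh_fdr(prof$approx_p)
  structure(prof, class = c("tad_profile", "data.frame"),
            config = config, bins = field$bins)
}

# local minima with plateau handling: a plateau flanked by larger values
# on both sides is one minimum reported at its leftmost bin; NaNs and the
# profile ends do not qualify as flanks.
.local_minima <- function(x) {
  n <- length(x)
  out <- integer(0)
  i <- 1
  while (i <= n) {
    if (!is.finite(x[i])) { i <- i + 1; next }
    l <- i
    while (l + 1 <= n && is.finite(x[l + 1]) && x[l + 1] == x[i]) l <- l + 1
    left_ok <- i > 1 && is.finite(x[i - 1]) && x[i - 1] > x[i]
    right_ok <- l < n && is.finite(x[l + 1]) && x[l + 1] > x[i]
    if (left_ok && right_ok) out <- c(out, i)
    i <- l + 1
  }
  out
}

#' Call TAD boundaries from a profile
#'
#' Boundaries are local minima of the F(1,1)-approximated significance
#' profile (a plateau counts once, at its leftmost bin; profile ends are
#' not minima) whose raw `fdr` is below the threshold. Peaks are located
#' on the approximated *p-values*: the BH adjustment is monotone in them,
#' but because F(1,1) p-values are compressed the adjustment collapses
#' them to ties, so the unadjusted profile is the numerically stable one
#' to scan; the raw FDR still gates every call.
#'
#' @param profile A `tad_profile` from [boundary_profile()].
#' @param config A [tad_config()].
#' @return Integer vector of boundary bin indices (1-based).
#' @export
call_boundaries <- function(profile, config = attr(profile, "config")) {
  minima <- .local_minima(profile$approx_p)
  minima[!is.na(profile$fdr[minima]) &
           profile$fdr[minima] < config$fdr_threshold]
}

#' Hierarchical TAD intervals
#'
#' Level-0 TADs tile the region between consecutive boundaries (and the
#' region ends). Boundaries are then removed one at a time, least
#' significant first (smallest combined Cauchy statistic), and each
#' removal adds the interval between the removed boundary's surviving
#' neighbors (or region ends) with the level incremented by one per
#' removal, until no boundaries remain.
#'
#' @param boundaries Sorted boundary bin indices.
#' @param stats Combined Cauchy statistics of the boundaries (same
#'   order); larger means more significant.
#' @param region Length-2 vector: first and last bin of the region.
#' @return A data.frame with columns `start`, `end` (bin indices) and
#'   `level` (0 = finest). With no boundaries, one level-0 interval
#'   covering the region.
#' @export
hierarchical_tads <- function(boundaries, stats, region) {
  stopifnot(length(boundaries) == length(stats), length(region) == 2)
  if (length(boundaries) == 0)
    return(data.frame(start = region[1], end = region[2], level = 0))
  o <- order(boundaries)
  boundaries <- boundaries[o]; stats <- stats[o]
  edges <- c(region[1], boundaries, region[2])
  out <- data.frame(start = edges[-length(edges)], end = edges[-1], level = 0)
  level <- 0
  active <- seq_along(boundaries)
  while (length(active) > 0) {
    rm_i <- active[which.min(stats[active])]
    level <- level + 1
    lower <- active[active < rm_i]
    upper <- active[active > rm_i]
    lo <- if (length(lower)) boundaries[max(lower)] else region[1]
    hi <- if (length(upper)) boundaries[min(upper)] else region[2]
    out <- rbind(out, data.frame(start = lo, end = hi, level = level))
    active <- setdiff(active, rm_i)
  }
  out
}

#' Call TADs from a fitted model
#'
#' Runs the full domain pipeline on an [axistrace()] fit: the per-bin
#' inter/intra variance profile, FDR peak finding, and hierarchical TAD
#' assembly.
#'
#' @param fit An `axistrace` fit.
#' @param config A [tad_config()]; fields can also be passed via `...`.
#' @param ... Overrides for [tad_config()] fields.
#' @return An object of class `tad_calls`: a list with `profile` (the
#'   per-bin `tad_profile`), `boundaries` (bin indices) and `intervals`
#'   (hierarchical TADs).
#' @export
call_tads <- function(fit, config = NULL, ...) {
  stopifnot(inherits(fit, "axistrace"))
  if (is.null(config)) config <- tad_config(...)
  prof <- boundary_profile(fit$field, fit$weights, config)
  bd <- call_boundaries(prof, config)
  iv <- hierarchical_tads(bd, prof$stat[bd], c(1, n_bins(fit$data)))
  structure(list(profile = prof, boundaries = bd, intervals = iv,
                 config = config, bins = fit$data$bins),
            class = "tad_calls")
}

#' @export
print.tad_calls <- function(x, ...) {
  cat(sprintf("TAD calls: %d boundaries over %d bins\n",
              length(x$boundaries), nrow(x$profile)))
  if (length(x$boundaries) > 0) {
    b <- x$boundaries
    cat("  boundary bins:", paste(b, collapse = ", "), "\n")
    cat(sprintf("  %d hierarchical intervals (levels 0-%d)\n",
                nrow(x$intervals), max(x$intervals$level)))
  }
  invisible(x)
}

#' Write TAD results as BED / bedGraph
#'
#' Writes a boundary BED (score = -log10 combined p), a bedGraph of the
#' FDR profile, and a TAD-interval BED with a level column.
#'
#' @param tads A `tad_calls` object.
#' @param prefix Output path prefix; files `<prefix>.boundaries.bed`,
#'   `<prefix>.fdr.bedgraph` and `<prefix>.tads.bed` are written.
#' @return The written paths, invisibly.
#' @export
write_tads <- function(tads, prefix) {
  bins <- tads$bins
  b <- tads$boundaries
  paths <- paste0(prefix, c(".boundaries.bed", ".fdr.bedgraph", ".tads.bed"))
  bb <- data.frame(chrom = bins$chrom[b], start = bins$start[b],
                   end = bins$end[b], name = paste0("boundary_", seq_along(b)),
                   score = round(-log10(pmax(tads$profile$p[b], 1e-300)), 3))
  utils::write.table(bb, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ok <- is.finite(tads$profile$fdr)
  gg <- data.frame(chrom = bins$chrom[ok], start = bins$start[ok],
                   end = bins$end[ok], value = tads$profile$fdr[ok])
  utils::write.table(gg, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  iv <- tads$intervals
  tt <- data.frame(chrom = bins$chrom[iv$start], start = bins$start[iv$start],
                   end = bins$end[iv$end], level = iv$level)
  utils::write.table(tt, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
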