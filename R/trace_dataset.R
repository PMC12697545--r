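#' Genomic bin table for a traced region
#'
#' Builds the ordered, fixed-width bin table underlying a chromatin trace
#' dataset. Coordinates are 0-based half-open base pairs, taken verbatim from
#' the input; bins must be non-overlapping, sorted and all on one chromosome,
#' with a common width (the resolution).
#'
#' @param chrom Chromosome name (single string).
#' @param start,end Integer vectors of bin boundaries (bp, 0-based half-open).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, ordered by
#'   `start`, with attribute `resolution` (bp per bin).
#' @export
genomic_bins <- function(chrom, start, end) {
  stopifnot(length(chrom) == 1L, length(start) == length(end))
  o <- order(start)
  start <- as.numeric(start[o]); end <- as.numeric(end[o])
  if (length(start) < 3L)
    stop("at least 3 bins are required (got ", length(start), ")")
  widths <- end - start
  if (length(unique(widths)) != 1L)
    stop("bins have inconsistent widths: ", paste(unique(widths), collapse = ", "))
  if (any(start[-1] < end[-length(end)]))
    stop("bins overlap")
  bins <- data.frame(chrom = chrom, start = start, end = end,
                     stringsAsFactors = FALSE)
  attr(bins, "resolution") <- widths[1]
  bins
}

#' Bin resolution of a bin table or dataset
#' @param x A bin table from [genomic_bins()] or a `trace_dataset`.
#' @return Resolution in bp per bin.
#' @export
bin_resolution <- function(x) {
  if (inherits(x, "trace_dataset")) return(attr(x$bins, "resolution"))
  attr(x, "resolution")
}

#' Chromatin trace dataset
#'
#' Container for n traces x p genomic bins x 3 axes of nm coordinates.
#' Missing spots are `NA` in all three axes (a spot is either fully observed
#' or fully absent).
#'
#' @param coords Numeric array `n x p x 3` (axes ordered x, y, z), in nm.
#'   `NA` marks missing spots.
#' @param trace_ids Character vector of n trace identifiers.
#' @param bins Bin table from [genomic_bins()].
#' @param centered Logical; whether per-trace per-axis means have been
#'   subtracted (see [center_traces()]).
#' @return An object of class `trace_dataset`: a list with elements
#'   `coords`, `trace_ids`, `bins`, `centered`.
#' @export
trace_dataset <- function(coords, trace_ids, bins, centered = FALSE) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  n <- dim(coords)[1]; p <- dim(coords)[2]
  if (p != nrow(bins))
    stop("coords has ", p, " bins but the bin table has ", nrow(bins))
  if (n < 1L) stop("at least one trace is required")
  if (length(trace_ids) != n) stop("trace_ids length must equal n")
  # a spot is missing on all 3 axes or on none
  na_count <- is.na(coords[, , 1, drop = FALSE]) +
    is.na(coords[, , 2, drop = FALSE]) + is.na(coords[, , 3, drop = FALSE])
  if (any(na_count %in% c(1, 2)))
    stop("spots must be missing on all three axes or on none")
  dimnames(coords) <- list(trace_ids, NULL, AXES)
  structure(list(coords = coords, trace_ids = as.character(trace_ids),
                 bins = bins, centered = isTRUE(centered)),
            class = "trace_dataset")
}

#' @export
print.trace_dataset <- function(x, ...) {
  d <- dim(x$coords)
  obs <- mean(!is.na(x$coords[, , 1]))
  cat(sprintf("Chromatin trace dataset: %d traces x %d bins (%s, %g bp/bin)\n",
              d[1], d[2], x$bins$chrom[1], bin_resolution(x)))
  cat(sprintf("  observed spots: %.1f%%; centered: %s\n",
              100 * obs, x$centered))
  invisible(x)
}

#' @export
dim.trace_dataset <- function(x) dim(x$coords)

#' Number of traces / bins
#' @param ds A `trace_dataset`.
#' @return Integer count.
#' @export
n_traces <- function(ds) dim(ds$coords)[1]

#' @rdname n_traces
#' @export
n_bins <- function(ds) dim(ds$coords)[2]

#' Remove duplicate spot records
#'
#' Chromatin tracing tables can record several 3D coordinates for the same
#' (trace, bin) combination, e.g. after allele misalignment. Only the first
#' record in file order is kept; the others are dropped and counted.
#'
#' For a long spot table (as parsed from FOF-CT) the duplicates are actually
#' removed. An assembled `trace_dataset` is already unique by construction,
#' so the method returns it unchanged with a zero count.
#'
#' @param x A spot `data.frame` with columns `trace_id` and `bin`, or a
#'   `trace_dataset`.
#' @return Same class as `x`, with attribute `duplicates_removed` giving the
#'   number of dropped records.
#' @export
deduplicate_spots <- function(x) UseMethod("deduplicate_spots")

#' @export
deduplicate_spots.data.frame <- function(x) {
  key <- paste(x$trace_id, x$bin, sep = "\r")
  dup <- duplicated(key)
  out <- x[!dup, , drop = FALSE]
  attr(out, "duplicates_removed") <- sum(dup)
  if (sum(dup) > 0)
    message(sum(dup), " duplicate spot record(s) removed (first occurrence kept)")
  out
}

#' @export
deduplicate_spots.trace_dataset <- function(x) {
  attr(x, "duplicates_removed") <- 0L
  x
}

#' Center traces
#'
#' Subtracts, per trace and per axis, the mean over observed spots, so that
#' each trace's per-axis mean is zero. Missing entries stay missing. Traces
#' with no observed spot are dropped with a warning. Pairwise coordinate
#' differences, on which all downstream statistics are based, are invariant
#' under this operation.
#'
#' @param ds A `trace_dataset`.
#' @return The centered `trace_dataset` (`centered = TRUE`).
#' @export
center_traces <- function(ds) {
  co <- ds$coords
  n_obs <- rowSums(!is.na(co[, , 1, drop = FALSE]))
  if (any(n_obs == 0)) {
    warning(sum(n_obs == 0), " trace(s) with zero observed spots dropped")
    keep <- n_obs > 0
    co <- co[keep, , , drop = FALSE]
    ds$trace_ids <- ds$trace_ids[keep]
  }
  for (a in 1:3) {
    m <- rowMeans(co[, , a, drop = FALSE], na.rm = TRUE)
    co[, , a] <- co[, , a] - m
  }
  trace_dataset(co, ds$trace_ids, ds$bins, centered = TRUE)
}
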