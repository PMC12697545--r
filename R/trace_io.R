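#' Read a FOF-CT chromatin tracing table
#'
#' Parses a 4DN FISH Omics Format for Chromatin Tracing (FOF-CT) core CSV,
#' or a plain CSV with the same columns. `##`-prefixed header lines are
#' tolerated; a `##columns=(...)` line, if present, names the columns,
#' otherwise the first non-`##` line is taken as the column header. The
#' mandatory columns are `Trace_ID`, `X`, `Y`, `Z`, `Chrom`, `Chrom_Start`
#' and `Chrom_End` (case-insensitive).
#'
#' Coordinates are converted to nm. The unit is taken from the file header
#' (a `##`-line mentioning `micron`/`um`/`µm` declares micrometres) unless
#' overridden by `unit`.
#'
#' Duplicate records for the same (trace, bin) are resolved by keeping the
#' first in file order (see [deduplicate_spots()]); bins are the sorted
#' union of the (Chrom_Start, Chrom_End) values and must share one width.
#' Spots absent from a trace are missing (`NA`).
#'
#' @param path Path to the file.
#' @param chrom Optional chromosome filter. If `NULL` and the file holds a
#'   single chromosome, that chromosome is used; with several chromosomes a
#'   named list of datasets is returned.
#' @param unit One of `"auto"`, `"nm"`, `"um"`.
#' @return A [trace_dataset()] (or a named list of them when `chrom` is
#'   `NULL` and the file spans several chromosomes), with attribute
#'   `duplicates_removed`.
#' @export
read_fofct <- function(path, chrom = NULL, unit = c("auto", "nm", "um")) {
  unit <- match.arg(unit)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(trimws(lines))))
    stop("empty input: ", path)
  hdr <- grepl("^##", lines)
  header_lines <- lines[hdr]
  body <- lines[!hdr]
  body <- body[nzchar(trimws(body))]

  cols_line <- grep("^##columns\\s*=", header_lines, ignore.case = TRUE, value = TRUE)
  if (length(cols_line) >= 1) {
    spec <- sub("^##columns\\s*=\\s*", "", cols_line[1], ignore.case = TRUE)
    spec <- gsub("[()]", "", spec)
    col_names <- trimws(strsplit(spec, ",")[[1]])
  } else {
    if (length(body) == 0) stop("empty input: ", path)
    col_names <- trimws(strsplit(body[1], ",")[[1]])
    body <- body[-1]
  }
  if (length(body) == 0) stop("empty input: no data rows in ", path)

  tab <- utils::read.csv(text = paste(body, collapse = "\n"), header = FALSE,
                         stringsAsFactors = FALSE, strip.white = TRUE)
  if (ncol(tab) < length(col_names))
    stop("fewer data columns than named columns in ", path)
  names(tab)[seq_along(col_names)] <- col_names

  need <- c("Trace_ID", "X", "Y", "Z", "Chrom", "Chrom_Start", "Chrom_End")
  idx <- match(tolower(need), tolower(names(tab)))
  if (anyNA(idx))
    stop("missing mandatory column(s): ", paste(need[is.na(idx)], collapse = ", "))
  spots <- data.frame(trace_id = as.character(tab[[idx[1]]]),
                      x = as.numeric(tab[[idx[2]]]),
                      y = as.numeric(tab[[idx[3]]]),
                      z = as.numeric(tab[[idx[4]]]),
                      chrom = as.character(tab[[idx[5]]]),
                      start = as.numeric(tab[[idx[6]]]),
                      end = as.numeric(tab[[idx[7]]]),
                      stringsAsFactors = FALSE)

  if (unit == "auto") {
    um <- any(grepl("micron|micrometer|µm|\\bum\\b", header_lines,
                    ignore.case = TRUE))
    unit <- if (um) "um" else "nm"
  }
  if (unit == "um") spots[c("x", "y", "z")] <- spots[c("x", "y", "z")] * 1000

  chroms <- unique(spots$chrom)
  if (!is.null(chrom)) {
    if (!chrom %in% chroms) stop("chromosome ", chrom, " not present in ", path)
    return(.assemble_fofct(spots[spots$chrom == chrom, , drop = FALSE]))
  }
  if (length(chroms) == 1L) return(.assemble_fofct(spots))
  out <- lapply(chroms, function(ch)
    .assemble_fofct(spots[spots$chrom == ch, , drop = FALSE]))
  names(out) <- chroms
  out
}

# assemble one chromosome's long spot table into a trace_dataset
.assemble_fofct <- function(spots) {
  ub <- unique(spots[c("start", "end")])
  bins <- genomic_bins(spots$chrom[1], ub$start, ub$end)
  spots$bin <- match(paste(spots$start, spots$end),
                     paste(bins$start, bins$end))
  spots <- deduplicate_spots(spots)
  ndup <- attr(spots, "duplicates_removed")

  # canonical order by (trace, bin) makes parsing row-order independent
  ids <- sort(unique(spots$trace_id))
  ti <- match(spots$trace_id, ids)
  co <- array(NA_real_, c(length(ids), nrow(bins), 3))
  for (a in 1:3)
    co[cbind(ti, spots$bin, a)] <- spots[[AXES[a]]]
  ds <- trace_dataset(co, ids, bins, centered = FALSE)
  attr(ds, "duplicates_removed") <- ndup
  ds
}

#' Write a trace dataset as FOF-CT
#'
#' Writes observed spots (one row per trace/bin with coordinates, in nm) in
#' FOF-CT core CSV layout. Reading the file back with [read_fofct()]
#' reproduces the coordinates, missing mask and bin table exactly.
#'
#' @param ds A `trace_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fofct <- function(ds, path) {
  co <- ds$coords
  n <- dim(co)[1]; p <- dim(co)[2]
  obs <- which(!is.na(co[, , 1]), arr.ind = TRUE)
  if (n == 1) obs <- cbind(row = 1L, col = which(!is.na(co[1, , 1])))
  df <- data.frame(
    Spot_ID = seq_len(nrow(obs)),
    Trace_ID = ds$trace_ids[obs[, 1]],
    X = formatC(co[cbind(obs[, 1], obs[, 2], 1L)], digits = 17, format = "g"),
    Y = formatC(co[cbind(obs[, 1], obs[, 2], 2L)], digits = 17, format = "g"),
    Z = formatC(co[cbind(obs[, 1], obs[, 2], 3L)], digits = 17, format = "g"),
    Chrom = ds$bins$chrom[obs[, 2]],
    Chrom_Start = ds$bins$start[obs[, 2]],
    Chrom_End = ds$bins$end[obs[, 2]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##FOF-CT_version=v0.1",
               "##XYZ_unit=nm",
               paste0("##columns=(", paste(names(df), collapse = ","), ")")),
             con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
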