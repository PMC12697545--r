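# Interval utilities backing compartment labeling and evaluation: TSS
# counting per bin, log2 peak enrichment, and reference-loop consensus.
# Genomic coordinates are 0-based half-open throughout.

#' Read a TSS table from BED or GTF
#'
#' BED: each record's start (0-based) is taken as a TSS position.
#' GTF: features of type `transcript` or `gene` contribute their 5' end
#' (start for `+` strand, `end - 1` for `-`), converted to 0-based.
#' Parsing goes through [rtracklayer::import()].
#'
#' @param path Path to a `.bed`, `.gtf` or `.gff` file.
#' @param format Override the extension-based format guess.
#' @return A data.frame with columns `chrom`, `pos` (bp, 0-based) and
#'   `strand`.
#' @export
read_tss <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.g[tf]f[0-9]?$", path, ignore.case = TRUE)) "gtf" else "bed"
  gr <- as.data.frame(rtracklayer::import(path, format = format))
  if (format == "gtf") {
    gr <- gr[as.character(gr$type) %in% c("transcript", "gene"), , drop = FALSE]
    pos <- ifelse(gr$strand == "-",
                  gr$end - 1L,    # 1-based inclusive end -> 0-based 5' end
                  gr$start - 1L)  # 1-based start -> 0-based
  } else {
    pos <- gr$start - 1L
  }
  tss_table(as.character(gr$seqnames), pos, as.character(gr$strand))
}

#' Construct a TSS table
#'
#' @param chrom Chromosome names.
#' @param pos TSS positions (bp, 0-based).
#' @param strand Strand (`"+"`, `"-"` or `"."`).
#' @return A data.frame of class `tss_table`.
#' @export
tss_table <- function(chrom, pos, strand = ".") {
  stopifnot(all(pos >= 0), all(strand %in% c("+", "-", "*", ".")))
  strand[strand == "*"] <- "."
  structure(data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                       strand = rep_len(strand, length(pos)),
                       stringsAsFactors = FALSE),
            class = c("tss_table", "data.frame"))
}

#' Count TSSs per genomic bin
#'
#' Half-open convention: a TSS at position `pos` falls in the bin with
#' `start <= pos < end` (so a TSS exactly at a bin start belongs to that
#' bin, and one at the shared boundary belongs to the following bin).
#'
#' @param bins Bin table from [genomic_bins()].
#' @param tss A TSS table (see [tss_table()]).
#' @return Integer vector of per-bin counts.
#' @export
count_tss <- function(bins, tss) {
  # a non-empty single-chromosome table on a different chromosome is a
  # mismatch; a multi-chromosome or empty table simply yields zero counts
  if (nrow(tss) > 0 && length(unique(tss$chrom)) == 1 &&
      unique(tss$chrom) != bins$chrom[1])
    stop("chromosome mismatch: TSS table is on ", unique(tss$chrom),
         " but bins are on ", bins$chrom[1])
  pos <- tss$pos[tss$chrom == bins$chrom[1]]
  vapply(seq_len(nrow(bins)), function(i)
    sum(pos >= bins$start[i] & pos < bins$end[i]), 0L)
}

#' Log2 enrichment of a peak overlap in a bin subset
#'
#' With `p1` the overlap proportion among the selected bins and `p` the
#' proportion among all bins, returns `log2(p1 / p)`. `p1 = 0` yields
#' `-Inf` with a warning.
#'
#' @param selected Indices (or logical mask) of the selected bins.
#' @param overlap Logical per-bin peak-overlap vector.
#' @return The log2 fold change.
#' @export
log2_enrichment <- function(selected, overlap) {
  sel <- if (is.logical(selected)) which(selected) else selected
  if (length(sel) == 0) stop("empty bin selection")
  p <- mean(overlap)
  if (p == 0) stop("overall overlap proportion is zero")
  p1 <- mean(overlap[sel])
  if (p1 == 0) {
    warning("no overlap among selected bins: enrichment is -Inf")
    return(-Inf)
  }
  log2(p1 / p)
}

#' Read a BEDPE loop list
#'
#' Plain-text BEDPE: the first six columns are
#' chrom1,start1,end1,chrom2,start2,end2 (0-based half-open).
#'
#' @param path Path to the file.
#' @return A data.frame with the six anchor columns.
#' @export
read_bedpe <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 6) stop("BEDPE needs at least 6 columns")
  stats::setNames(tab[, 1:6],
                  c("chrom1", "start1", "end1", "chrom2", "start2", "end2"))
}

#' Consensus bin pairs from reference loop lists
#'
#' Maps each reference loop to bin pairs: a loop marks the pair (j, k)
#' if its first anchor overlaps bin j and its second anchor overlaps bin
#' k (half-open interval intersection, either anchor order); an anchor
#' spanning several bins marks them all. Within one list a pair counts
#' at most once; pairs supported by at least `min_support` lists are
#' returned.
#'
#' @param loop_lists A list of BEDPE data.frames (see [read_bedpe()]).
#' @param bins Bin table from [genomic_bins()].
#' @param min_support Minimum number of supporting lists (default 2).
#' @return A data.frame with columns `j`, `k` (bin indices, `j < k`) and
#'   `support`.
#' @export
reference_consensus <- function(loop_lists, bins, min_support = 2) {
  stopifnot(length(loop_lists) >= 1)
  overlap_bins <- function(s, e)
    which(bins$start < e & bins$end > s)  # half-open intersection
  support <- new.env(parent = emptyenv())
  for (ll in loop_lists) {
    seen <- character(0)
    ll <- ll[ll$chrom1 == bins$chrom[1] & ll$chrom2 == bins$chrom[1], ,
             drop = FALSE]
    for (r in seq_len(nrow(ll))) {
      b1 <- overlap_bins(ll$start1[r], ll$end1[r])
      b2 <- overlap_bins(ll$start2[r], ll$end2[r])
      for (j in b1) for (k in b2) {
        lo <- min(j, k); hi <- max(j, k)
        if (lo == hi) next
        seen <- c(seen, paste(lo, hi))
      }
    }
    for (key in unique(seen))
      assign(key, (if (exists(key, support)) get(key, support) else 0L) + 1L,
             support)
  }
  keys <- ls(support)
  cnt <- vapply(keys, function(k) get(k, support), 0L)
  keep <- cnt >= min_support
  if (!any(keep))
    return(data.frame(j = integer(0), k = integer(0), support = integer(0)))
  jk <- do.call(rbind, strsplit(keys[keep], " "))
  out <- data.frame(j = as.integer(jk[, 1]), k = as.integer(jk[, 2]),
                    support = as.integer(cnt[keep]))
  out[order(out$j, out$k), , drop = FALSE]
}

#' Match called loops against a reference with a bin-shift tolerance
#'
#' A called pair matches a reference pair when both anchors are within
#' `tol_bins` bins of the reference anchors (the benchmarking convention
#' "allow one bin shift").
#'
#' @param called Data.frame with columns `j`, `k`.
#' @param reference Data.frame with columns `j`, `k`.
#' @param tol_bins Allowed per-anchor shift in bins (default 1).
#' @return A list with `recall`, `precision`, and logical vectors
#'   `called_matched`, `reference_matched`.
#' @export
match_loops <- function(called, reference, tol_bins = 1) {
  cm <- rep(FALSE, nrow(called)); rm_ <- rep(FALSE, nrow(reference))
  for (i in seq_len(nrow(called))) {
    hit <- abs(called$j[i] - reference$j) <= tol_bins &
      abs(called$k[i] - reference$k) <= tol_bins
    cm[i] <- any(hit)
    rm_[hit] <- TRUE
  }
  list(recall = if (nrow(reference)) mean(rm_) else NaN,
       precision = if (nrow(called)) mean(cm) else NaN,
       called_matched = cm, reference_matched = rm_)
}
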