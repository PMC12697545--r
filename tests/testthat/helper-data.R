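# shared fixtures and independent oracles, built in code at test time

# trace_dataset from an n x p x 3 array; optionally mark as centered
# without re-centering (for fixtures whose per-bin statistics are exact)
toy_ds <- function(coords, centered = FALSE, resolution = 25000,
                   chrom = "chr1") {
  n <- dim(coords)[1]; p <- dim(coords)[2]
  bins <- genomic_bins(chrom, (seq_len(p) - 1) * resolution,
                       seq_len(p) * resolution)
  ds <- trace_dataset(coords, sprintf("T%03d", seq_len(n)), bins)
  ds$centered <- centered
  ds
}

# write a small FOF-CT file; rows = list of c(trace, x, y, z, start, end)
write_toy_fofct <- function(rows, path, unit_line = "##XYZ_unit=nm",
                            chrom = "chr1", plain_header = FALSE) {
  cols <- "Trace_ID,X,Y,Z,Chrom,Chrom_Start,Chrom_End"
  body <- vapply(rows, function(r)
    paste(r[1], r[2], r[3], r[4], chrom, r[5], r[6], sep = ","), "")
  if (plain_header) {
    writeLines(c(cols, body), path)
  } else {
    writeLines(c("##FOF-CT_version=v0.1", unit_line,
                 paste0("##columns=(", cols, ")"), body), path)
  }
  path
}

# minimal variance_field stand-in for kernel-level tests
fake_field <- function(V, C, resolution = 25000, chrom = "chr1") {
  p <- nrow(V)
  bins <- genomic_bins(chrom, (seq_len(p) - 1) * resolution,
                       seq_len(p) * resolution)
  structure(list(V = list(x = V, y = V, z = V),
                 C = list(x = C, y = C, z = C),
                 bins = bins, resolution = resolution, n = max(C)),
            class = "variance_field")
}

# independent brute-force pooled variance over a set of entries: recompute
# each entry's surviving differences from the raw coordinates, its sample
# variance, normalize by the field's second-pass expectation, and pool
# with weights (count - 1)
brute_pooled <- function(ds, field, axis, pairs) {
  a <- match(axis, c("x", "y", "z"))
  res <- bin_resolution(ds)
  num <- 0; df <- 0
  for (r in seq_len(nrow(pairs))) {
    j <- pairs[r, 1]; k <- pairs[r, 2]
    d <- ds$coords[, j, a] - ds$coords[, k, a]
    d <- d[!is.na(d)]
    thr <- 4 * sqrt(field$E[[axis]](abs(k - j) * res))
    d <- d[abs(d) <= thr]
    if (length(d) < 2) next
    v <- stats::var(d) / field$expected[[axis]][j, k]
    num <- num + (length(d) - 1) * v
    df <- df + length(d) - 1
  }
  list(s2 = if (df > 0) num / df else NaN, df = df)
}

# brute-force BH step-up: adj_i = min_{j >= i} p_(j) * m / j, capped at 1
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# accuracy of a 2-group partition against planted labels (label-switching
# resolved by taking the better of the two matchings)
partition_accuracy <- function(partition, labels) {
  ref <- labels == labels[1]
  max(mean((partition == 1) == ref), mean((partition == 2) == ref))
}
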