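# A/B compartment calling: second eigenvectors of the per-axis normalized
# variance matrices, weight-scaled 2-means clustering, and A/B labeling by
# TSS density (or a within-group variance fallback).

#' Per-axis second-eigenvector embedding
#'
#' Each axis's normalized variance matrix is eigendecomposed (after
#' imputing missing entries with their genomic-distance stratum mean and
#' setting the diagonal to 1, the normalization's expected value);
#' eigenpairs are ordered by decreasing absolute eigenvalue and the second
#' eigenvector kept — the first tracks residual distance decay, the
#' second carries the two-block compartment contrast. The sign is fixed
#' so the first nonzero component is positive.
#'
#' @param field A `variance_field`.
#' @param max_na_frac Maximum tolerated fraction of missing off-diagonal
#'   entries per axis (default 0.2).
#' @return A `p x 3` matrix (columns x, y, z), with a logical attribute
#'   `"degenerate"` flagging axes whose second eigenvalue is ~0.
#' @export
axis_embedding <- function(field, max_na_frac = 0.2) {
  p <- nrow(field$V$x)
  if (p < 4) stop("at least 4 bins are required for the eigen-embedding")
  res <- field$resolution
  emb <- matrix(NA_real_, p, 3, dimnames = list(NULL, AXES))
  degen <- logical(3); names(degen) <- AXES
  S <- abs(outer(seq_len(p), seq_len(p), "-"))
  for (a in AXES) {
    V <- field$V[[a]]
    off <- upper.tri(V)
    na_frac <- mean(!is.finite(V[off]))
    if (na_frac > max_na_frac)
      stop(sprintf("axis %s: %.0f%% of entries are missing (max %.0f%%)",
                   a, 100 * na_frac, 100 * max_na_frac))
    # stratum-mean imputation
    for (g in sort(unique(S[off & !is.finite(V)]))) {
      sel <- S == g
      fill <- mean(V[sel][is.finite(V[sel])])
      if (!is.finite(fill)) fill <- mean(V[off][is.finite(V[off])])
      V[sel & !is.finite(V)] <- fill
    }
    diag(V) <- 1
    V <- (V + t(V)) / 2
    ed <- eigen(V, symmetric = TRUE)
    o <- order(abs(ed$values), decreasing = TRUE)
    vec <- ed$vectors[, o[2]]
    degen[a] <- abs(ed$values[o[2]]) < 1e-10 * max(abs(ed$values))
    nz <- which(abs(vec) > 1e-12)[1]
    if (!is.na(nz) && vec[nz] < 0) vec <- -vec
    emb[, a] <- vec
  }
  attr(emb, "degenerate") <- degen
  emb
}

#' Weighted 2-means partition of the embedding
#'
#' Scales each embedding column by its axis weight and runs 2-means
#' (multiple restarts, best inertia kept), so eigenvectors from more
#' accurately measured axes dominate the partition.
#'
#' @param embedding `p x 3` matrix from [axis_embedding()].
#' @param w An `axis_weights` object (or length-3 weights).
#' @param seed RNG seed for the restarts.
#' @param nstart Number of k-means restarts (>= 10).
#' @return Integer vector of group labels (1/2).
#' @export
cluster_ab <- function(embedding, w, seed = 0, nstart = 25) {
  if (inherits(w, "axis_weights")) w <- w$w
  stopifnot(ncol(embedding) == 3, length(w) == 3, nstart >= 10)
  Xw <- embedding %*% diag(w)
  if (all(apply(Xw, 2, function(c) diff(range(c)) == 0)))
    stop("degenerate embedding: all rows identical, no 2-group structure")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  km <- stats::kmeans(Xw, centers = 2, nstart = nstart)
  km$cluster
}

#' Assign A/B identities to the two groups
#'
#' With a TSS table, the group with the higher total TSS count becomes
#' the A compartment (transcriptionally active chromatin carries more
#' promoters); ties fall back to the variance rule. Without TSS, the
#' group with the lower within-group normalized variance (weight-averaged
#' over axes, over within-group bin pairs) becomes B, since condensed
#' heterochromatin keeps its loci comparatively close.
#'
#' @param partition Group labels from [cluster_ab()].
#' @param bins Bin table.
#' @param tss Optional TSS table (see [read_tss()]), same chromosome.
#' @param field The `variance_field` (for the variance fallback).
#' @param w An `axis_weights` object.
#' @return A character vector of per-bin `"A"`/`"B"` labels with
#'   attribute `"assignment_basis"` (`"tss"` or `"variance"`).
#' @export
assign_ab <- function(partition, bins, tss = NULL, field, w) {
  if (inherits(w, "axis_weights")) w <- w$w
  basis <- "variance"
  a_group <- NA_integer_
  if (!is.null(tss)) {
    counts <- count_tss(bins, tss)
    t1 <- sum(counts[partition == 1]); t2 <- sum(counts[partition == 2])
    if (t1 != t2) {
      a_group <- if (t1 > t2) 1L else 2L
      basis <- "tss"
    }
  }
  if (is.na(a_group)) {
    gv <- vapply(1:2, function(g) {
      idx <- which(partition == g)
      if (length(idx) < 2) return(Inf)
      pr <- t(utils::combn(idx, 2))
      vals <- vapply(AXES, function(a) {
        v <- field$V[[a]][pr]
        mean(v[is.finite(v)])
      }, 0)
      sum(w * vals)
    }, 0)
    a_group <- which.max(gv)  # higher within-group variance -> A; lower -> B
  }
  labels <- ifelse(partition == a_group, "A", "B")
  attr(labels, "assignment_basis") <- basis
  labels
}

#' Call A/B compartments from a fitted model
#'
#' Runs the full compartment pipeline on an [axistrace()] fit: per-axis
#' second-eigenvector embedding, weight-scaled 2-means partition, and
#' A/B assignment by TSS density (or the variance fallback).
#'
#' @param fit An `axistrace` fit.
#' @param tss Optional TSS table from [read_tss()].
#' @param seed K-means seed.
#' @param weights Optional `axis_weights` override (e.g. equal weights
#'   for comparison).
#' @param centromere Optional centromere coordinate (bp). When given,
#'   bins are split into p and q arms at this position and the whole
#'   pipeline runs independently per arm, removing the arm-territory
#'   confounder at the cost of two smaller eigenproblems.
#' @return An object of class `compartment_calls`: a list with `labels`
#'   (per-bin A/B), `partition`, `embedding`, `weighted_embedding`,
#'   `assignment_basis` and `bins`.
#' @export
call_compartments <- function(fit, tss = NULL, seed = 0, weights = NULL,
                              centromere = NULL) {
  stopifnot(inherits(fit, "axistrace"))
  w <- if (is.null(weights)) fit$weights else weights
  if (!is.null(centromere)) {
    arm <- ifelse((fit$data$bins$start + fit$data$bins$end) / 2 < centromere,
                  1L, 2L)
    if (min(table(factor(arm, 1:2))) < 4)
      stop("each arm needs at least 4 bins; centromere at ", centromere,
           " leaves ", min(table(factor(arm, 1:2))))
    parts <- lapply(1:2, function(a)
      .call_compartments_once(.subset_field(fit$field, which(arm == a)),
                              fit$data$bins[arm == a, , drop = FALSE],
                              tss, seed, w))
    out <- list(labels = c(parts[[1]]$labels, parts[[2]]$labels),
                partition = c(parts[[1]]$partition,
                              parts[[2]]$partition + 2L),
                embedding = rbind(parts[[1]]$embedding,
                                  parts[[2]]$embedding),
                weighted_embedding = rbind(parts[[1]]$weighted_embedding,
                                           parts[[2]]$weighted_embedding),
                assignment_basis = parts[[1]]$assignment_basis,
                bins = fit$data$bins)
    return(structure(out, class = "compartment_calls"))
  }
  out <- .call_compartments_once(fit$field, fit$data$bins, tss, seed, w)
  structure(out, class = "compartment_calls")
}

.call_compartments_once <- function(field, bins, tss, seed, w) {
  emb <- axis_embedding(field)
  part <- cluster_ab(emb, w, seed = seed)
  labels <- assign_ab(part, bins, tss, field, w)
  list(labels = as.character(labels), partition = part, embedding = emb,
       weighted_embedding = emb %*% diag(w$w),
       assignment_basis = attr(labels, "assignment_basis"), bins = bins)
}

# restrict a variance field to a subset of bins (per-arm analysis)
.subset_field <- function(field, idx) {
  out <- field
  for (a in AXES) {
    out$V[[a]] <- field$V[[a]][idx, idx, drop = FALSE]
    out$C[[a]] <- field$C[[a]][idx, idx, drop = FALSE]
  }
  out$bins <- field$bins[idx, , drop = FALSE]
  attr(out$bins, "resolution") <- attr(field$bins, "resolution")
  out
}

#' @export
print.compartment_calls <- function(x, ...) {
  cat(sprintf("A/B compartments: %d A bins, %d B bins (assigned by %s)\n",
              sum(x$labels == "A"), sum(x$labels == "B"),
              x$assignment_basis))
  rl <- rle(x$labels)
  cat("  blocks:", paste0(rl$values, "(", rl$lengths, ")", collapse = " "), "\n")
  invisible(x)
}

#' Write compartment calls as BED
#'
#' Per-bin records with the A/B label as name and the three embedding
#' coordinates appended.
#'
#' @param comp A `compartment_calls` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_compartments <- function(comp, path) {
  df <- data.frame(chrom = comp$bins$chrom, start = comp$bins$start,
                   end = comp$bins$end, label = comp$labels,
                   ev_x = comp$embedding[, 1], ev_y = comp$embedding[, 2],
                   ev_z = comp$embedding[, 3])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
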