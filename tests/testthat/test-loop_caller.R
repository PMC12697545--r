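test_that("the background ring enumerates the 25-50 kb Chebyshev shell", {
  cfg <- loop_config()
  # interior pair at 25 kb: radii 1-2 bins, (2*2+1)^2 - 1 = 24 positions
  ring <- background_ring(11, 31, 60, 25000, cfg)
  expect_equal(nrow(ring), 24)
  cheb <- pmax(abs(ring[, 1] - 11), abs(ring[, 2] - 31))
  expect_true(all(cheb >= 1 & cheb <= 2))
  expect_true(all(ring[, 1] < ring[, 2]))
  expect_false(any(ring[, 1] == 11 & ring[, 2] == 31))
  # a pair at the matrix edge has a truncated ring
  ring_edge <- background_ring(1, 3, 60, 25000, cfg)
  expect_lt(nrow(ring_edge), 24)
  expect_true(all(ring_edge[, 1] >= 1))
  # 5 kb bins: radii become 5-10 bins
  ring5 <- background_ring(30, 60, 120, 5000, cfg)
  cheb5 <- pmax(abs(ring5[, 1] - 30), abs(ring5[, 2] - 60))
  expect_equal(range(cheb5), c(5, 10))
})

test_that("pair tests pool the background by counts and reduce to F", {
  # pooled example: V = {2.0 (C=3), 1.0 (C=5)} -> s2 = 4/3, df = 6
  V <- matrix(1, 20, 20); C <- matrix(5L, 20, 20)
  V[3, 10] <- V[10, 3] <- 2; C[3, 10] <- C[10, 3] <- 3L
  fld <- fake_field(V, C)
  got <- pooled_variance(fld, "x", cbind(c(3, 4), c(10, 11)))
  expect_equal(got$s2, 4 / 3)
  expect_equal(got$df, 6)

  # tested variance equal to its background: the F ratio is exactly 1,
  # so the p-value is the F CDF at 1 with the pooled dfs (0.5 when the
  # dfs match, as variance_ratio_pvalue shows directly)
  V1 <- matrix(1, 30, 30); diag(V1) <- NaN
  C1 <- matrix(11L, 30, 30); diag(C1) <- 0L
  fld1 <- fake_field(V1, C1)
  w <- axis_weights(w = c(1, 1, 1))
  res <- test_pair(fld1, w, 10, 20)
  expect_equal(res$p_x, pf(1, 10, 24 * 10))
  expect_equal(variance_ratio_pvalue(1, 240, 1, 240, "lower"), 0.5)

  # fewer than 3 valid background entries -> untested
  C2 <- matrix(1L, 30, 30); C2[10, 20] <- C2[20, 10] <- 11L
  fld2 <- fake_field(V1, C2)
  res2 <- test_pair(fld2, w, 10, 20)
  expect_true(is.nan(res2$p))
})

test_that("candidate clustering is transitive with lexicographic summits", {
  mk_calls <- function(j, k, p) {
    bins <- genomic_bins("chr1", (0:59) * 25000, (1:60) * 25000)
    structure(data.frame(j = j, k = k, p = p, fdr = p,
                         is_candidate = TRUE),
              class = c("loop_calls", "data.frame"),
              bins = bins, config = loop_config())
  }
  # neighbors within 50 kb: one cluster, smallest p is the summit
  cl <- cluster_summits(mk_calls(c(10, 10), c(20, 21), c(1e-6, 1e-3)))
  expect_equal(cl$cluster_id, c(1L, 1L))
  expect_equal(cl$is_summit, c(TRUE, FALSE))
  # 100 kb apart: two singleton clusters, both summits
  cl2 <- cluster_summits(mk_calls(c(10, 10), c(20, 24), c(1e-4, 1e-4)))
  expect_equal(length(unique(cl2$cluster_id)), 2)
  expect_true(all(cl2$is_summit))
  # chain A-B-C with 50 kb consecutive gaps merges transitively
  cl3 <- cluster_summits(mk_calls(c(10, 10, 10), c(20, 22, 24),
                                  c(1e-3, 1e-5, 1e-4)))
  expect_equal(cl3$cluster_id, rep(1L, 3))
  expect_equal(which(cl3$is_summit), 2)
  # exact p tie breaks to the lexicographically smaller pair
  cl4 <- cluster_summits(mk_calls(c(10, 10), c(21, 20), c(1e-4, 1e-4)))
  expect_equal(which(cl4$is_summit), 2)
})

test_that("contact frequency counts co-observed traces under the cutoff", {
  co <- array(0, c(3, 3, 3))
  co[, 2, 1] <- c(300, 600, 400)  # 3D distances to bin 1: 300, 600, 400
  ds <- toy_ds(co, centered = TRUE)
  expect_equal(contact_frequency(ds, 1, 2, 500), 2 / 3)
  expect_equal(contact_frequency(ds, 1, 2, 1000), 1)
  expect_equal(contact_frequency(ds, 1, 2, 0), 0)
  co[, 3, ] <- NA
  ds2 <- toy_ds(co, centered = TRUE)
  expect_true(is.nan(contact_frequency(ds2, 1, 3, 500)))
})

test_that("final summit filters apply the p and frequency cutoffs", {
  # 20 traces; per tested pair (j, k), bin k is placed so that a chosen
  # fraction of traces sits closer than the 500 nm contact cutoff
  set_freq <- function(co, k, n_close)
    { co[, k, 1] <- c(rep(100, n_close), rep(900, 20 - n_close)); co }
  co <- array(0, c(20, 60, 3))
  co <- set_freq(co, 10, 8)    # (2, 10): freq 0.40
  co <- set_freq(co, 20, 6)    # (4, 20): freq 0.30
  co <- set_freq(co, 30, 9)    # (6, 30): freq 0.45
  co <- set_freq(co, 40, 12)   # (8, 40): freq 0.60
  ds <- toy_ds(co, centered = TRUE)
  mk <- function(p_summit, cfg) {
    df <- data.frame(
      j = c(2, 4, 6, 8, 2, 4), k = c(10, 20, 30, 40, 11, 21),
      p = c(p_summit, rep(1e-3, 2)), fdr = 1e-3, is_candidate = TRUE,
      cluster_id = c(1L, 2L, 3L, 4L, 1L, 2L),
      is_summit = c(rep(TRUE, 4), FALSE, FALSE))
    structure(df, class = c("loop_calls", "data.frame"),
              bins = ds$bins, config = cfg)
  }
  # frequency filter off: only the p < 1e-5 cutoff applies
  cfg0 <- loop_config()
  out <- finalize_loops(mk(c(1e-7, 2e-5, 1e-8, 1e-9), cfg0), ds, cfg0)
  expect_equal(out$is_final[1:4], c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(out$contact_freq[1:4], c(0.40, 0.30, 0.45, 0.60))
  # frequency filter on: clusters (size > 1) need >= 1/3, singletons >= 1/2
  cfgf <- loop_config(apply_frequency_filter = TRUE)
  out2 <- finalize_loops(mk(rep(1e-9, 4), cfgf), ds, cfgf)
  expect_true(out2$is_final[1])    # cluster summit, 0.40 >= 1/3
  expect_false(out2$is_final[2])   # cluster summit, 0.30 < 1/3
  expect_false(out2$is_final[3])   # singleton, 0.45 < 1/2
  expect_true(out2$is_final[4])    # singleton, 0.60 >= 1/2
})

test_that("loop p-values are invariant to translation and axis reflection", {
  sim <- simulate_planted(simulation_spec(n = 80, p = 20, seed = 41))
  ds <- center_traces(sim$data)
  fit <- axistrace(ds)
  p0 <- call_candidates(fit$field, fit$weights)$p
  ds2 <- sim$data
  ds2$coords[3, , ] <- ds2$coords[3, , ] + rep(c(500, -200, 300), each = 20)
  ds2$coords[, , 2] <- -ds2$coords[, , 2]
  fit2 <- axistrace(ds2, weights = fit$weights)
  p2 <- call_candidates(fit2$field, fit2$weights)$p
  expect_equal(p2, p0, tolerance = 1e-9)
})

test_that("a planted loop is flagged as a candidate", {
  for (s in 1:2) {
    sim <- simulate_planted(simulation_spec(
      n = 400, p = 30, seed = 50 + s,
      loops = data.frame(j = 8, k = 22, proximity = 0.5)))
    fit <- axistrace(sim$data)
    lc <- call_candidates(fit$field, fit$weights)
    expect_true(lc$is_candidate[lc$j == 8 & lc$k == 22])
  }
})

test_that("an empty eligible set warns and returns no calls", {
  sim <- simulate_planted(simulation_spec(n = 30, p = 5, seed = 61))
  fit <- suppressWarnings(axistrace(sim$data))
  expect_warning(lc <- call_candidates(fit$field, fit$weights,
                                       loop_config(min_separation_kb = 500)),
                 "no testable")
  expect_equal(nrow(lc), 0)
})
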