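test_that("the window partition builds the stated inter/intra pair sets", {
  cfg <- tad_config()  # 200 kb per side -> w = 8 bins at 25 kb
  part <- domain_partition(21, 60, 25000, cfg)
  expect_equal(part$U, 13:20)
  expect_equal(part$D, 22:29)
  expect_equal(nrow(part$inter), 64)
  expect_equal(nrow(part$intra), 28 + 28)
  expect_false(21 %in% c(part$U, part$D))
  # per-side availability rule: bin 2 has |U| = 1 < 4 -> excluded
  expect_null(domain_partition(2, 60, 25000, cfg))
  # bin 5 has |U| = 4 >= 4 -> tested
  expect_false(is.null(domain_partition(5, 60, 25000, cfg)))
})

test_that("equal inter and intra variance gives p = 0.5 and F(1,1) = 0.5", {
  V <- matrix(1, 40, 40); diag(V) <- NaN
  C <- matrix(9L, 40, 40); diag(C) <- 0L
  fld <- fake_field(V, C)
  w <- axis_weights(w = c(1, 1, 1))
  res <- boundary_test(fld, w, 20)
  # ratio exactly 1: p is the upper F tail at 1 with the pooled dfs
  # (64 inter and 56 intra pairs, each contributing C - 1 = 8)
  expect_equal(res$p_x, pf(1, 64 * 8, 56 * 8, lower.tail = FALSE))
  expect_equal(variance_ratio_pvalue(1, 512, 1, 512, "upper"), 0.5)
  # the F(1,1) approximation of the same unit ratio sits at its median
  expect_equal(res$approx_p, 0.5, tolerance = 1e-12)
})

test_that("pooled inter/intra statistics match brute-force recomputation", {
  sim <- simulate_planted(simulation_spec(n = 50, p = 20, seed = 71,
                                          missing_rate = 0.1))
  ds <- center_traces(sim$data)
  fld <- build_field(ds)
  part <- domain_partition(10, 20, 25000, tad_config(window_kb = 100))
  for (a in c("x", "y", "z")) {
    for (set in list(part$inter, part$intra)) {
      got <- pooled_variance(fld, a, set)
      want <- brute_pooled(ds, fld, a, set)
      expect_equal(got$df, want$df)
      expect_equal(got$s2, want$s2, tolerance = 1e-9)
    }
  }
})

test_that("boundary peaks are graded minima gated by the raw FDR", {
  mk_prof <- function(approx_p, fdr)
    structure(data.frame(i = seq_along(approx_p), approx_p = approx_p,
                         fdr = fdr, approx_fdr = bh_fdr(approx_p)),
              class = c("tad_profile", "data.frame"), config = tad_config())
  # two interior minima, both under the FDR gate
  prof <- mk_prof(c(0.9, 0.2, 0.9, 0.9, 0.05, 0.9),
                  c(1, 0.02, 1, 1, 0.01, 1))
  expect_equal(call_boundaries(prof), c(2, 5))
  # the FDR gate removes one of them
  prof2 <- mk_prof(c(0.9, 0.2, 0.9, 0.9, 0.05, 0.9),
                   c(1, 0.5, 1, 1, 0.01, 1))
  expect_equal(call_boundaries(prof2), 5)
  # a monotone profile has no interior minimum
  expect_equal(length(call_boundaries(mk_prof(seq(0.1, 0.9, length.out = 6),
                                              rep(0, 6)))), 0)
  # a plateau counts once, at its leftmost bin
  prof3 <- mk_prof(c(0.9, 0.05, 0.05, 0.9), rep(0.01, 4))
  expect_equal(call_boundaries(prof3), 2)
  # NaN edges (excluded bins) do not qualify as flanks
  prof4 <- mk_prof(c(NaN, 0.05, 0.9, 0.05, NaN), rep(0.01, 5))
  expect_equal(call_boundaries(prof4), integer(0))
})

test_that("hierarchical TADs replay the removal algorithm exactly", {
  # boundaries at 11, 21, 31 over bins 1..60; significance 11 < 31 < 21
  iv <- hierarchical_tads(c(11, 21, 31), stats = c(1, 3, 2), region = c(1, 60))
  expect_equal(iv[iv$level == 0, c("start", "end")],
               data.frame(start = c(1, 11, 21, 31), end = c(11, 21, 31, 60)),
               ignore_attr = TRUE)
  expect_equal(iv[iv$level == 1, c("start", "end")],
               data.frame(start = 1, end = 21), ignore_attr = TRUE)
  expect_equal(iv[iv$level == 2, c("start", "end")],
               data.frame(start = 21, end = 60), ignore_attr = TRUE)
  expect_equal(iv[iv$level == 3, c("start", "end")],
               data.frame(start = 1, end = 60), ignore_attr = TRUE)
  # single boundary: level 0 pair then the merged region
  iv2 <- hierarchical_tads(30, stats = 5, region = c(1, 60))
  expect_equal(iv2$level, c(0, 0, 1))
  expect_equal(iv2$start, c(1, 30, 1))
  expect_equal(iv2$end, c(30, 60, 60))
  # no boundaries: one level-0 interval covering the region
  iv3 <- hierarchical_tads(integer(0), numeric(0), c(1, 60))
  expect_equal(iv3, data.frame(start = 1, end = 60, level = 0))
})

test_that("hierarchical intervals nest and tile on random configurations", {
  set.seed(55)
  for (rep in 1:10) {
    nb <- sample(1:6, 1)
    b <- sort(sample(5:55, nb))
    iv <- hierarchical_tads(b, stats = runif(nb), region = c(1, 60))
    lvl0 <- iv[iv$level == 0, ]
    # level-0 intervals tile the region
    expect_equal(lvl0$start, c(1, b))
    expect_equal(lvl0$end, c(b, 60))
    # every higher-level interval is a union of contiguous lower intervals
    for (l in seq_len(max(iv$level))) {
      ivl <- iv[iv$level == l, ]
      expect_true(all(ivl$start %in% c(1, b)) && all(ivl$end %in% c(b, 60)))
      expect_true(all(ivl$end > ivl$start))
    }
    # the top level spans the whole region
    expect_equal(iv[iv$level == max(iv$level), c("start", "end")],
                 data.frame(start = 1, end = 60), ignore_attr = TRUE)
  }
})

test_that("a planted two-block boundary attains the minimum combined p", {
  for (s in 1:2) {
    sim <- simulate_planted(simulation_spec(
      n = 300, p = 30, seed = 80 + s,
      boundaries = data.frame(pos = 15, insulation = 2)))
    fit <- axistrace(sim$data)
    prof <- boundary_profile(fit$field, fit$weights)
    best <- prof$i[which.min(prof$p)]
    expect_true(abs(best - 15) <= 1)
  }
})
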