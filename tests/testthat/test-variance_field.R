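test_that("the robust variance matrix follows the stated median formula", {
  # constant differences have zero spread
  co <- array(0, c(4, 3, 3))
  co[, 1, ] <- 5; co[, 2, ] <- 105; co[, 3, ] <- 305
  V <- robust_variance_matrix(toy_ds(co, centered = TRUE), "x")
  expect_equal(V[1, 2], 0)
  expect_true(is.nan(V[1, 1]))

  # hand evaluation: d = (-100, 0, 100, 0, 0): median 0, squared deviations
  # (1e4, 0, 1e4, 0, 0), median 0 -> robust variance 0 (breakdown point)
  co2 <- array(0, c(5, 3, 3))
  co2[, 1, 1] <- c(-100, 0, 100, 0, 0)  # bin 2 stays 0 so d = x_1 - x_2
  V2 <- robust_variance_matrix(toy_ds(co2, centered = TRUE), "x")
  expect_equal(V2[1, 2], 0)

  # Gaussian consistency: sd-100 differences give ~1e4 nm^2
  set.seed(31)
  co3 <- array(0, c(2000, 3, 3))
  co3[, 1, 1] <- rnorm(2000, sd = 100)   # d_12 ~ N(0, 100^2)
  V3 <- robust_variance_matrix(toy_ds(co3, centered = TRUE), "x")
  expect_lt(abs(V3[1, 2] - 1e4) / 1e4, 0.1)

  # fewer than 3 complete pairs -> NaN
  co4 <- array(rnorm(4 * 3 * 3), c(4, 3, 3))
  co4[1:2, 1, ] <- NA
  V4 <- robust_variance_matrix(toy_ds(co4, centered = TRUE), "x")
  expect_true(is.nan(V4[1, 2]))
  expect_false(is.nan(V4[2, 3]))
})

test_that("the expected-variance curve tracks distance trends", {
  p <- 20
  bins <- genomic_bins("chr1", (0:(p - 1)) * 25000, (1:p) * 25000)
  S <- abs(outer(1:p, 1:p, "-")) * 25000
  # entries exactly linear in distance: lowess is near identity inside
  raw <- 2 * S; diag(raw) <- NaN
  E <- expected_variance_curve(raw, bins)
  for (s in c(5, 8, 12) * 25000)
    expect_lt(abs(E(s) - 2 * s) / (2 * s), 0.05)
  # constant entries give a constant curve
  raw2 <- matrix(7000, p, p); diag(raw2) <- NaN
  E2 <- expected_variance_curve(raw2, bins)
  expect_equal(E2(3 * 25000), 7000, tolerance = 1e-6)
  # single observed stratum degenerates to that stratum's mean
  raw3 <- matrix(NaN, 3, 3)
  raw3[1, 2] <- raw3[2, 1] <- 4000; raw3[2, 3] <- raw3[3, 2] <- 6000
  bins3 <- genomic_bins("chr1", (0:2) * 25000, (1:3) * 25000)
  E3 <- expected_variance_curve(raw3, bins3)
  expect_equal(E3(25000), 5000)
  # all-NaN input errors
  expect_error(expected_variance_curve(matrix(NaN, 3, 3), bins3), "NaN")
})

test_that("the 4-SD filter removes exactly the stated differences", {
  # stratum with expected variance 2500 (sd 50): threshold 200
  co <- array(0, c(3, 3, 3))
  co[, 1, 1] <- c(210, 199, 0)  # d_12 = 210 (|Z| = 4.2), 199, 0
  ds <- toy_ds(co, centered = TRUE)
  Ec <- function(s) rep(2500, length(s))
  M <- outlier_mask(ds, "x", Ec)
  expect_false(M[1, 1, 2])  # 210 removed
  expect_true(M[2, 1, 2])   # 199 retained
  expect_true(M[3, 1, 2])
  expect_equal(M[, 1, 2], M[, 2, 1])

  # standard-normal differences scaled to sd 50: removal fraction ~ 2 Phi(-4)
  set.seed(17)
  d <- rnorm(1e6, sd = 50)
  removed <- mean(abs(d) > 4 * 50)
  expected <- 2 * pnorm(-4)
  se <- sqrt(expected / 1e6)
  expect_lt(abs(removed - expected), 4 * se)
})

test_that("noise-only fields normalize to 1 at every distance stratum", {
  sim <- simulate_planted(simulation_spec(n = 1000, p = 30, scale = 0,
                                          noise_sd = c(80, 80, 80), seed = 5))
  fld <- build_field(center_traces(sim$data))
  V <- fld$V$x
  S <- abs(outer(1:30, 1:30, "-"))
  for (g in c(1, 5, 10, 20)) {
    vals <- V[S == g]
    expect_lt(abs(mean(vals, na.rm = TRUE) - 1), 0.05)
  }
  # re-fitting a lowess curve to V vs distance stays within 10% of 1
  ut <- which(upper.tri(V), arr.ind = TRUE)
  lo <- lowess((ut[, 2] - ut[, 1]) * 25000, V[ut], f = 0.3, iter = 3)
  inner <- lo$x > 25000 & lo$x < 29 * 25000
  expect_true(all(abs(lo$y[inner] - 1) < 0.1))
})

test_that("a planted proximity pair is the minimum of its row", {
  sim <- simulate_planted(simulation_spec(
    n = 1500, p = 30, seed = 9,
    loops = data.frame(j = 8, k = 22, proximity = 0.5)))
  fld <- build_field(center_traces(sim$data))
  V <- fld$V$x
  # clearly reduced below the stratum level (1 after normalization), and
  # the smallest entry among same-row entries at comparable separation
  expect_lt(V[8, 22], 0.75)
  far <- setdiff(which(abs((1:30) - 8) >= 10 & (1:30) != 22), 22)
  expect_true(V[8, 22] < min(V[8, far], na.rm = TRUE))
})

test_that("one wild outlier difference barely moves the filtered field", {
  sim <- simulate_planted(simulation_spec(n = 400, p = 12, scale = 0,
                                          noise_sd = c(70, 70, 70), seed = 13))
  ds <- center_traces(sim$data)
  fld0 <- build_field(ds)
  ds2 <- ds
  # push one spot 20 expected SDs away on x: the (3, 9) difference becomes
  # a wild outlier and must be filtered, not absorbed
  ds2$coords[1, 3, 1] <- ds2$coords[1, 3, 1] + 20 * sqrt(fld0$E$x(6 * 25000))
  fld2 <- build_field(ds2)
  expect_lt(abs(fld2$V$x[3, 9] - fld0$V$x[3, 9]) / fld0$V$x[3, 9], 0.05)
})

test_that("field matrices are symmetric with consistent counts", {
  sim <- simulate_planted(simulation_spec(n = 60, p = 15, seed = 21,
                                          missing_rate = 0.1))
  fld <- build_field(center_traces(sim$data))
  for (a in c("x", "y", "z")) {
    expect_identical(fld$V[[a]], t(fld$V[[a]]))
    expect_identical(fld$C[[a]], t(fld$C[[a]]))
    expect_true(all(fld$C[[a]] >= 0 & fld$C[[a]] <= 60))
    off <- upper.tri(fld$V[[a]])
    expect_true(all(is.finite(fld$V[[a]][off]) == (fld$C[[a]][off] >= 2)))
  }
})

test_that("pooled statistics from (V, C) match brute-force recomputation", {
  sim <- simulate_planted(simulation_spec(n = 50, p = 20, seed = 33,
                                          missing_rate = 0.15))
  ds <- center_traces(sim$data)
  fld <- build_field(ds)
  set.seed(34)
  for (rep in 1:5) {
    pairs <- which(upper.tri(matrix(0, 20, 20)), arr.ind = TRUE)
    pairs <- pairs[sample(nrow(pairs), 12), , drop = FALSE]
    for (a in c("x", "y", "z")) {
      got <- pooled_variance(fld, a, pairs)
      want <- brute_pooled(ds, fld, a, pairs)
      expect_equal(got$df, want$df)
      expect_equal(got$s2, want$s2, tolerance = 1e-9)
    }
  }
})
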