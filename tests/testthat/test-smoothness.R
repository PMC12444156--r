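test_that("velocity ratio measures speed evenness", {
  expect_equal(velocity_ratio(rep(42, 5)), 1.0)
  expect_equal(velocity_ratio(c(0, 100, 0)), 1 / 3)
  expect_error(velocity_ratio(rep(0, 5)), "undefined ratio")
  # minimum-jerk: MV/PV = 8/15
  expect_equal(velocity_ratio(ref_speed), 8 / 15, tolerance = 0.005)
})

test_that("velocity-peak count detects submovements", {
  expect_equal(count_velocity_peaks(ref_speed), 1L)

  # two non-overlapping submovements half a second apart
  bi <- sub_reach(D = 150, T = 0.5, k = 2L, offsets = c(0, 0.5))
  bs <- seg_path(bi)
  expect_equal(count_velocity_peaks(speed_profile(bs$path)), 2L)

  # a ripple whose local maximum exceeds its preceding minimum by only
  # 10 mm/s is not counted at delta = 20
  t <- seq(0, 1, by = 0.005)
  key_t <- c(0, 0.5, 0.7, 0.75, 0.8, 1)
  key_v <- c(0, 100, 30, 40, 28, 0)
  p <- scalar_profile(t, stats::approx(key_t, key_v, xout = t)$y)
  raw <- count_velocity_peaks(p, peak_params(delta = 1e-9, tau = 0))
  expect_gt(raw, 1L)
  expect_equal(count_velocity_peaks(p, peak_params()), 1L)
})

test_that("the refractory interval suppresses nearby peaks without resetting", {
  t <- seq(0, 0.4, by = 0.01)
  v <- rep(5, length(t))
  v[t %in% c(0.10, 0.20, 0.30)] <- c(100, 90, 95)
  p <- scalar_profile(t, v)
  # tau = 0.15: peak at 0.10 accepted, 0.20 rejected (0.10 s gap), 0.30
  # accepted (0.20 s since last *accepted*) -- a rejected candidate must
  # not reset the clock
  expect_equal(count_velocity_peaks(p, peak_params(delta = 20, tau = 0.15)), 2L)
  expect_equal(count_velocity_peaks(p, peak_params(delta = 20, tau = 0)), 3L)
})

test_that("with thresholds off, the count equals the raw local-maximum count", {
  set.seed(17)
  for (i in 1:40) {
    n <- sample(5:50, 1)
    v <- as.numeric(sample(0:5, n, replace = TRUE))  # integer values force plateaus
    p <- scalar_profile(seq_len(n) / 100, v)
    expect_equal(count_velocity_peaks(p, peak_params(delta = 0, tau = 0)),
                 brute_peak_count(v))
  }
})

test_that("acceleration zero-crossings count sign changes", {
  expect_equal(zero_crossings_accel(c(1, -1, 2)), 2L)
  expect_equal(zero_crossings_accel(rep(3, 10)), 0L)
  # exact zeros: crossing through zero counts once, touching counts zero
  expect_equal(zero_crossings_accel(c(1, 0, -1)), 1L)
  expect_equal(zero_crossings_accel(c(1, 0, 2)), 0L)
  expect_error(zero_crossings_accel(numeric(0)), "empty")
  # positive scaling invariance
  set.seed(23)
  a <- rnorm(50)
  expect_equal(zero_crossings_accel(a), zero_crossings_accel(3.7 * a))

  # minimum-jerk tangential acceleration changes sign once (interior)
  acc <- differentiate(ref_speed, 1)
  n <- length(acc$values)
  expect_equal(zero_crossings_accel(acc$values[2:(n - 1)]), 1L)
})

test_that("log dimensionless jerk matches the minimum-jerk closed form", {
  expect_equal(log_dimensionless_jerk(ref_seg$path, ref_seg$seg), -log(720),
               tolerance = 0.05)
  # independent of amplitude and duration: D = 120 mm, T = 0.6 s
  g2 <- sub_reach(D = 120, T = 0.6)
  s2 <- seg_path(g2)
  expect_equal(log_dimensionless_jerk(s2$path, s2$seg), -log(720),
               tolerance = 0.05)
})

test_that("LDJ is invariant under spatial and temporal scaling", {
  base <- log_dimensionless_jerk(ref_seg$path)
  sp <- path3d(ref_seg$path$times, ref_seg$path$points * 4.2)
  expect_equal(log_dimensionless_jerk(sp), base, tolerance = 1e-6)
  t0 <- ref_seg$path$times[1]
  tp <- path3d(t0 + (ref_seg$path$times - t0) * 2.5, ref_seg$path$points)
  expect_equal(log_dimensionless_jerk(tp), base, tolerance = 1e-3)
  expect_error(log_dimensionless_jerk(path3d(1:5 / 10, matrix(1, 5, 3))),
               "zero path length")
})

test_that("SPARC is amplitude-invariant and bounded by -1", {
  base <- sparc(ref_speed)
  scaled <- scalar_profile(ref_speed$times, ref_speed$values * 17.3)
  expect_equal(sparc(scaled), base, tolerance = 1e-12)
  expect_lte(base, -1 + 1e-6)

  set.seed(29)
  for (i in 1:10) {
    v <- abs(100 + cumsum(rnorm(64, sd = 10)))
    p <- scalar_profile(seq_along(v) / 100, v)
    expect_lte(sparc(p), -1 + 1e-6)
  }
  expect_error(sparc(scalar_profile(1:8 / 10, rep(0, 8))), "V\\(0\\)")
})

test_that("SPARC agrees with a dense-grid spectral oracle on smooth reaches", {
  impl <- sparc(ref_speed)
  oracle <- sparc_oracle(ref_speed$values, fs = 200)
  expect_equal(impl, oracle, tolerance = 0.01)

  # a second smooth reach with different amplitude and duration
  g2 <- sub_reach(D = 150, T = 0.8)
  sp2 <- speed_profile(seg_path(g2)$path)
  expect_equal(sparc(sp2), sparc_oracle(sp2$values, fs = 200), tolerance = 0.01)
})

test_that("SPARC resamples jittered profiles before the FFT", {
  set.seed(37)
  t <- ref_speed$times + c(0, runif(length(ref_speed$times) - 2, -1e-3, 1e-3), 0)
  jit <- scalar_profile(sort(t), ref_speed$values)
  expect_equal(sparc(jit), sparc(ref_speed), tolerance = 0.05)
})

test_that("composed submovements degrade NPV and SPARC monotonically", {
  n_pass <- 0L
  n_trials <- 20L
  for (seed in seq_len(n_trials)) {
    set.seed(seed)
    sep <- runif(1, 1.0, 1.3)
    D <- runif(1, 180, 230)
    res <- sapply(1:3, function(k) {
      g <- sub_reach(D = D, k = k, offsets = (0:(k - 1)) * sep, seed = seed)
      sp <- speed_profile(seg_path(g)$path)
      c(count_velocity_peaks(sp), sparc(sp))
    })
    if (all(diff(res[1, ]) >= 0) && all(diff(res[2, ]) <= 0)) n_pass <- n_pass + 1L
  }
  expect_gte(n_pass / n_trials, 0.95)
})
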