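test_that("population-vector azimuth: one-hot, adjacent pair, undefined cases", {
  one <- rep(0, 8); one[3] <- 10
  expect_equal(bump_azimuth(one), 90) # octant 3 center
  pair <- rep(0, 8); pair[3:4] <- 10
  expect_equal(bump_azimuth(pair), 112.5) # midpoint of octants 3 and 4
  expect_true(is.na(bump_azimuth(rep(0, 8))))
  expect_true(is.na(bump_azimuth(rep(7, 8)))) # uniform: zero resultant
  # rotating rates by one octant rotates the azimuth by exactly 45 deg
  r <- spatial_profile(30, peak_rate = 80, background_rate = 2)
  expect_equal(bump_azimuth(r[c(8, 1:7)]),
               (bump_azimuth(r) + 45) %% 360, tolerance = 1e-9)
})

test_that("bump width: generate-then-measure round trip and edge cases", {
  r <- spatial_profile(0, fwhm = 90, peak_rate = 100, background_rate = 0)
  expect_equal(bump_fwhm(r), 90, tolerance = 0.15) # interpolation error only
  one <- rep(0, 8); one[5] <- 10
  expect_lte(bump_fwhm(one), 45)
  expect_true(is.na(bump_fwhm(rep(3, 8))))
  # peak centered off-octant still recovers about the nominal width
  r2 <- spatial_profile(22.5, fwhm = 90, peak_rate = 100, background_rate = 0)
  expect_equal(bump_fwhm(r2), 90, tolerance = 0.2)
})

test_that("tracking error is the absolute wrapped difference", {
  expect_equal(tracking_error(c(0, 90, 350), c(0, 90, 350)), c(0, 0, 0))
  expect_equal(tracking_error(rep(0, 3), rep(180, 3)), rep(180, 3))
  expect_equal(tracking_error(10, 350), 20)
  expect_error(tracking_error(1:3, 1:4), "length mismatch")
  # a decode lagging a ramp by tau yields error rate * tau
  t <- seq(0, 5, 0.01)
  true <- (t * 100) %% 360
  lagged <- ((t - 0.05) * 100) %% 360
  expect_equal(unique(round(tracking_error(true, lagged)[10:400], 6)), 5)
})

test_that("success criterion counts the sub-threshold fraction", {
  expect_true(success_criterion(rep(0, 100)))
  expect_false(success_criterion(rep(20, 100)))
  expect_true(success_criterion(c(rep(5, 60), rep(90, 40)))) # 60% under 10
  expect_false(success_criterion(c(rep(5, 40), rep(90, 60))))
  expect_error(success_criterion(numeric(0)), "empty")
})

test_that("lag estimation recovers constructed shifts and phases", {
  dt <- 0.01
  t <- seq(0, 20, dt)
  set.seed(11)
  base <- 120 * sin(2 * pi * 0.5 * t) + 40 * sin(2 * pi * 1.3 * t + 1)
  for (shift in c(0, 0.1, 0.2, 0.3)) {
    dec <- 120 * sin(2 * pi * 0.5 * (t - shift)) +
      40 * sin(2 * pi * 1.3 * (t - shift) + 1)
    lg <- lag_estimate(t, base %% 360, dec %% 360)
    expect_equal(lg$lag_s, shift, tolerance = dt + 1e-9)
  }
  # single sinusoid with a known phase offset at f: lag = phi / (2 pi f)
  f0 <- 1; phi <- 0.8
  x <- 90 * sin(2 * pi * f0 * t)
  y <- 90 * sin(2 * pi * f0 * t - phi)
  lg <- lag_estimate(t, x %% 360, y %% 360, bands = c(0.5, 2))
  expect_equal(lg$by_frequency$lag_s[1], phi / (2 * pi * f0), tolerance = 0.01)
  expect_error(lag_estimate(t, rep(1, length(t)), rep(1, length(t))),
               "degenerate")
})

test_that("dominant period: sinusoid, generator round trip, white noise", {
  dt <- 0.01
  t <- seq(0, 30, dt)
  x <- 100 * sin(2 * pi * 0.916 * t)
  dp <- dominant_period(x, dt)
  expect_equal(dp$period_psd_s, 1 / 0.916, tolerance = 0.04)
  expect_equal(dp$period_acov_s, 1 / 0.916, tolerance = 0.04)
  expect_true(dp$significant)
  set.seed(2)
  wn <- dominant_period(rnorm(2000), dt)
  expect_false(wn$significant)
  expect_true(is.na(wn$period_psd_s))
})

test_that("decoded bump trace from a simulation has sane ranges", {
  cir <- fly_circuit()
  M <- connectivity_matrix(cir, working_weights())
  sim <- simulate_protocol(M, step_protocol(90, 90, t_stim = 0.4,
                                            t_dark = 0.2, t_pre = 0),
                           seed = 9)
  bt <- decode_bump(sim)
  expect_s3_class(bt, "cx_bump_trace")
  late <- bt$t > 0.2 & bt$t <= 0.4
  expect_true(all(abs(((bt$azimuth_deg[late] - 90 + 180) %% 360) - 180) < 45))
  expect_true(all(bt$fwhm_deg > 0 & bt$fwhm_deg < 360, na.rm = TRUE))
  f <- tempfile(fileext = ".csv")
  write_bump_trace_csv(bt, f)
  expect_named(read.csv(f), c("t", "azimuth_deg", "fwhm_deg", "amplitude"))
})
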