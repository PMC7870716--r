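test_that("spatial profile peaks at the cue and has the requested FWHM", {
  r <- spatial_profile(0, fwhm = 90, peak_rate = 100, background_rate = 5)
  expect_equal(which.max(r), 1L)
  expect_equal(max(r), 100)
  expect_equal(min(r), 5, tolerance = 1e-6)
  # at +-45 deg the above-background rate is half the peak's
  th <- seq(0, 315, by = 45)
  r45 <- spatial_profile(45, fwhm = 90, peak_rate = 100, background_rate = 5)
  expect_equal(r45[2], 100) # octant 2 center = 45 deg
  # half-maximum condition, checked at octants 45 deg from the peak
  expect_equal(r[2], 5 + (100 - 5) / 2, tolerance = 1e-6)
  expect_equal(r[8], 5 + (100 - 5) / 2, tolerance = 1e-6)
  # rotating by one octant cyclically shifts the rate vector
  expect_equal(unname(r45), unname(r[c(8, 1:7)]), tolerance = 1e-10)
  # total rate is conserved under rotation of the azimuth
  expect_equal(sum(spatial_profile(17)), sum(spatial_profile(17 + 45)),
               tolerance = 1e-8)
})

test_that("Poisson encoding matches target rates and rejects undersampling", {
  tr <- poisson_encode(rep(100, 2), duration = 10, dt = 1e-4, seed = 1)
  counts <- colSums(tr)
  expect_true(all(abs(counts - 1000) < 3 * sqrt(1000)))
  expect_equal(sum(poisson_encode(0, duration = 1, dt = 1e-4, seed = 1)), 0L)
  expect_error(poisson_encode(2e4, duration = 0.1, dt = 1e-4), "undersampled")
  expect_error(poisson_encode(-1, duration = 0.1), "negative")
  # seed reproducibility; different seeds agree within Poisson error
  a <- poisson_encode(50, duration = 5, dt = 1e-4, seed = 7)
  b <- poisson_encode(50, duration = 5, dt = 1e-4, seed = 7)
  expect_identical(a, b)
  d <- poisson_encode(50, duration = 5, dt = 1e-4, seed = 8)
  expect_lt(abs(sum(d) - sum(a)), 4 * sqrt(250))
})

test_that("step protocol lays out the dark/stimulus schedule", {
  p <- step_protocol(0, 180, t_stim = 0.5, t_dark = 1, t_pre = 0.5)
  expect_equal(p$segments$t_start, c(0, 0.5, 1, 2, 2.5))
  expect_equal(p$segments$azimuth, c(NA, 0, NA, 180, NA))
  expect_equal(p$duration, 3.5)
  # zero-length leading darkness drops the first segment
  p0 <- step_protocol(10, 10, t_pre = 0)
  expect_equal(p0$segments$azimuth[1], 10)
  expect_equal(protocol_azimuth(p, c(0.7, 1.5, 2.2)), c(0, NA, 180))
})

test_that("encoded darkness emits background rate only", {
  p <- step_protocol(0, 180, t_stim = 0.3, t_dark = 0.3, t_pre = 0.3,
                     background_rate = 5, peak_rate = 200)
  enc <- encode_protocol(p, seed = 3)
  t <- (seq_len(nrow(enc$rates)) - 1) * 1e-4
  dark <- t < 0.3
  expect_true(all(enc$rates[dark, ] == 5))
  n_dark <- sum(enc$spikes[dark, ])
  lambda <- 5 * sum(dark) * 1e-4 * 8
  expect_lt(abs(n_dark - lambda), 4 * sqrt(lambda))
  stim <- t >= 0.3 & t < 0.6
  expect_equal(max(enc$rates[stim, 1]), 200)
})

test_that("trajectory protocols resample headings at simulation resolution", {
  # constant heading behaves like a single step segment
  const <- trajectory_protocol(data.frame(t = c(0, 1), heading_deg = 90))
  expect_equal(protocol_azimuth(const, c(0.1, 0.9)), c(90, 90))
  # uniform rotation at 360 deg/s advances one octant every 125 ms
  tr <- data.frame(t = seq(0, 2, 0.01),
                   heading_deg = (seq(0, 2, 0.01) * 360) %% 360)
  p <- trajectory_protocol(tr)
  az <- protocol_azimuth(p, c(0, 0.125, 0.25))
  expect_equal(az, c(0, 45, 90), tolerance = 1e-6)
})

test_that("protocols round-trip through YAML", {
  p <- step_protocol(30, 210, t_stim = 0.4, peak_rate = 150)
  f <- tempfile(fileext = ".yaml")
  write_protocol_yaml(p, f)
  q <- read_protocol_yaml(f)
  expect_equal(q$segments, p$segments)
  expect_equal(q$peak_rate, 150)
  tp <- trajectory_protocol(data.frame(t = c(0, 0.5, 1),
                                       heading_deg = c(0, 90, 180)))
  g <- tempfile(fileext = ".yaml")
  write_protocol_yaml(tp, g)
  tq <- read_protocol_yaml(g)
  expect_equal(tq$headings, tp$headings)
})
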