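times84 <- seq(0, 84, by = 1 / 12)

test_that("first-cycle period doubles the trough-to-peak distance", {
  # construct a signal with first trough at 10 h and first peak at 23 h
  y <- -80 * cos(2 * pi * (times84 - 10) / 26)
  # trough at 10 h, next peak at 23 h -> period estimate 2 * 13 = 26
  expect_equal(first_cycle_period(y, times84, peak_params(150, 50)), 26,
               tolerance = 1e-6)

  # noiseless damped cosine: trough precedes peak by half the period
  p <- well_sim_params(amplitude = 80, period = 24, phase = pi - 0.3,
                       damping = 0.01)
  yd <- simulate_well(p, times84)
  expect_equal(first_cycle_period(yd, times84, peak_params(150, 20)), 24,
               tolerance = 2 * (1 / 12) / 24)

  # the estimate is order-agnostic (absolute value): peak first works too
  y2 <- 80 * cos(2 * pi * (times84 - 9) / 26)
  expect_equal(first_cycle_period(y2, times84, peak_params(150, 50)), 26,
               tolerance = 1e-6)

  expect_error(first_cycle_period(rep(0, 1009), times84, peak_params(150, 50)),
               class = "feature_error")
})

test_that("first-peak features return the earliest qualifying peak", {
  # single broad cosine peak at 25 h, height 90
  y <- 90 * cos(2 * pi * (times84 - 25) / 30)
  f <- first_peak_features(y, times84)
  expect_equal(f$time, 25, tolerance = 1e-6)
  expect_equal(f$height, 90, tolerance = 1e-6)

  # narrow spike before the broad peak is rejected by the width filter
  spike <- 200 * exp(-(times84 - 8)^2 / (2 * 0.25^2))
  f2 <- first_peak_features(y + spike, times84)
  expect_equal(f2$time, 25, tolerance = 0.01)

  # nothing above the data-dependent height threshold
  expect_error(first_peak_features(rep(1, 1009), times84),
               class = "feature_error")
})

test_that("strain summaries use arithmetic mean and n-1 standard deviation", {
  s <- summarize_strain("WT", c(21, 22, 23), c(80, 90, 100))
  expect_equal(s$peak_time_mean, 22)
  expect_equal(s$peak_time_sd, 1)
  expect_equal(s$peak_height_mean, 90)
  expect_equal(s$peak_height_sd, 10)

  s1 <- summarize_strain("WT", 21, 80)
  expect_equal(s1$peak_time_sd, 0)
  expect_equal(s1$peak_height_sd, 0)

  set.seed(4)
  x <- stats::rnorm(7); h <- stats::rnorm(7)
  s2 <- summarize_strain("WT", x, h)
  expect_equal(s2$peak_time_sd,
               sqrt(sum((x - mean(x))^2) / 6), tolerance = 1e-12)
})

test_that("phase shift and relative amplitude follow the published formulas", {
  mut <- summarize_strain("mut", 21, 30)
  ref <- summarize_strain("WT", 28, 90)
  ps <- phase_shift(mut, ref)
  expect_equal(ps$shift, -7)
  expect_equal(ps$error, 0)

  ra <- relative_amplitude(mut, ref)
  expect_equal(ra$ratio, 1 / 3)

  # against itself: shift 0, ratio 1
  expect_equal(phase_shift(ref, ref)$shift, 0)
  expect_equal(relative_amplitude(ref, ref)$ratio, 1)

  # error boundaries: sums of SDs / relative SDs, as printed
  mut2 <- summarize_strain("mut", c(20.5, 21.5), c(27, 33))
  ref2 <- summarize_strain("WT", c(27.6, 28.4), c(81, 99))
  expect_equal(phase_shift(mut2, ref2)$error,
               stats::sd(c(20.5, 21.5)) + stats::sd(c(27.6, 28.4)))
  expect_equal(relative_amplitude(mut2, ref2)$error,
               stats::sd(c(27, 33)) / 30 + stats::sd(c(81, 99)) / 90)
  # explicit worked case: SDs 3 and 9 on heights 30 and 90 -> 0.2
  mut3 <- list(strain = "m", n_wells = 2, peak_time_mean = 21, peak_time_sd = 0.5,
               peak_height_mean = 30, peak_height_sd = 3)
  ref3 <- list(strain = "r", n_wells = 2, peak_time_mean = 28, peak_time_sd = 0.4,
               peak_height_mean = 90, peak_height_sd = 9)
  class(mut3) <- class(ref3) <- "strain_first_peak"
  expect_equal(phase_shift(mut3, ref3)$error, 0.9)
  expect_equal(relative_amplitude(mut3, ref3)$error, 0.2)

  # degenerate reference
  ref0 <- summarize_strain("zero", 10, 0)
  expect_error(relative_amplitude(mut, ref0), class = "domain_error")
})

test_that("comparison properties: antisymmetry and reciprocality", {
  set.seed(11)
  for (i in 1:10) {
    a <- summarize_strain("a", stats::rnorm(5, 22, 1), stats::rnorm(5, 60, 5))
    b <- summarize_strain("b", stats::rnorm(4, 25, 2), stats::rnorm(4, 90, 8))
    expect_equal(phase_shift(a, b)$shift, -phase_shift(b, a)$shift)
    expect_equal(relative_amplitude(a, b)$ratio * relative_amplitude(b, a)$ratio, 1)
    expect_gte(phase_shift(a, b)$error, 0)
    expect_gte(relative_amplitude(a, b)$error, 0)
  }
})

test_that("per-strain first-period statistics aggregate wells and report failures", {
  # three synthetic wells of one strain, no noise, slightly different phases
  mk <- function(phase) {
    simulate_well(well_sim_params(amplitude = 80, period = 26, phase = phase),
                  times84)
  }
  m <- cbind(w1 = mk(2.5), w2 = mk(2.7), w3 = mk(2.9))
  st <- first_period_stats(m, times84, peak_params(150, 50), strain = "WT")
  expect_equal(length(st$periods), 3)
  expect_equal(st$mean, 26, tolerance = 2 * (1 / 12) / 26)
  expect_equal(st$median, unname(sort(st$periods)[2]))
  expect_equal(st$failed, character(0))

  # a flat well is reported, not fatal
  m2 <- cbind(m, flat = rep(0, length(times84)))
  st2 <- first_period_stats(m2, times84, peak_params(150, 50), strain = "WT")
  expect_equal(st2$failed, "flat")
  expect_equal(length(st2$periods), 3)

  # single well: sd 0
  st3 <- first_period_stats(m[, 1, drop = FALSE], times84, peak_params(150, 50))
  expect_equal(st3$sd, 0)

  # everything fails
  expect_error(
    first_period_stats(cbind(rep(0, 1009)), times84, peak_params(150, 50)),
    class = "feature_error"
  )
  # explicit worked aggregate
  expect_equal(mean(c(20, 22, 24)), 22)
})
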