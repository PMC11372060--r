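times84 <- seq(0, 84, by = 1 / 12)

test_that("fit_trend recovers polynomials exactly and matches normal equations", {
  # constant trace
  cf <- fit_trend(rep(100, 1009), times84)
  expect_equal(cf, c(100, 0, 0, 0, 0), tolerance = 1e-8)

  # exact quadratic recovered by a quartic fit
  y <- 2 + 3 * times84 - 0.1 * times84^2
  expect_equal(fit_trend(y, times84), c(2, 3, -0.1, 0, 0), tolerance = 1e-8)

  # quartic + cosine: equals the normal-equations solution on included points
  y2 <- 150 + 8 * times84 + 0.3 * times84^2 - 0.004 * times84^3 +
    1e-5 * times84^4 + 80 * cos(2 * pi * times84 / 26 + 1)
  expect_equal(fit_trend(y2, times84),
               oracle_polyfit(y2, times84, 4, 3), tolerance = 1e-8)

  # random small instances, several degrees
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(10:50, 1)
    deg <- sample(0:4, 1)
    t <- sort(stats::runif(n, 0, 84))
    y <- stats::rnorm(n, 50, 20)
    cfg <- detrend_config(degree = deg, exclude_before = 3)
    expect_equal(fit_trend(y, t, cfg), oracle_polyfit(y, t, deg, 3),
                 tolerance = 1e-8)
  }
})

test_that("fit_trend rejects underdetermined inputs", {
  expect_error(fit_trend(1:4, c(0, 1, 2, 3), detrend_config(degree = 4)),
               class = "fit_error")
  # all points before the exclusion window
  expect_error(fit_trend(1:5, seq(0, 2, length.out = 5), detrend_config()),
               class = "fit_error")
  expect_error(fit_trend(1:5, 1:4, detrend_config()), class = "shape_error")
})

test_that("detrend_normalize subtracts trend everywhere and centers the residual", {
  # trace equal to its own trend -> all zeros
  y <- 5 + 2 * times84
  cf <- fit_trend(y, times84, detrend_config(degree = 1))
  dn <- detrend_normalize(y, times84, cf)
  expect_equal(dn$normalized, rep(0, length(y)), tolerance = 1e-10)

  # zero mean by construction, even for arbitrary coefficients
  set.seed(3)
  y2 <- stats::rnorm(1009, 500, 50)
  dn2 <- detrend_normalize(y2, times84, c(400, 1, 0.01, 0, 0))
  expect_lt(abs(mean(dn2$normalized)), 1e-9 * max(abs(y2)))
  # residual is raw - polynomial at ALL points (early window included)
  expect_equal(dn2$normalized + dn2$subtracted_mean +
                 (400 + times84 + 0.01 * times84^2), y2)
  expect_error(detrend_normalize(1:5, 1:4, c(0, 1)), class = "shape_error")
})

test_that("smooth_uniform implements zero-padded 'same' convolution", {
  expect_identical(smooth_uniform(c(4, 7, 1), 1), c(4, 7, 1))
  expect_equal(smooth_uniform(c(1, 2, 3), 3), c(1, 2, 5 / 3))
  # even kernel alignment: centre at floor(k/2) (kernel exceeds the series,
  # which warns but still computes)
  expect_warning(sm4 <- smooth_uniform(c(1, 2, 3), 4), class = "kernel_warning")
  expect_equal(sm4, c(0.75, 1.5, 1.5))

  # constant series: interior exact, first/last floor(k/2) samples damped
  x <- rep(1, 100)
  for (k in c(5, 40)) {
    sm <- smooth_uniform(x, k)
    half <- k %/% 2
    fwd <- k - 1 - half # forward reach of the kernel
    interior <- (half + 1):(100 - fwd)
    expect_equal(sm[interior], rep(1, length(interior)))
    expect_true(all(sm[1:half] < 1))
    expect_true(all(sm[(100 - fwd + 1):100] < 1))
  }

  # linearity to 1e-12
  set.seed(8)
  x1 <- stats::rnorm(200); x2 <- stats::rnorm(200)
  expect_equal(smooth_uniform(2.5 * x1 - 1.3 * x2, 7),
               2.5 * smooth_uniform(x1, 7) - 1.3 * smooth_uniform(x2, 7),
               tolerance = 1e-12)

  # oversized kernel warns but computes
  expect_warning(sm <- smooth_uniform(c(1, 2, 3), 5), class = "kernel_warning")
  expect_length(sm, 3)
  expect_error(smooth_uniform(1:5, 0), class = "param_error")
})

test_that("full preprocess keeps an in-bounds cosine recognizable", {
  # a quartic OLS fit absorbs part of a 3.2-cycle cosine, so the processed
  # trace is a distorted cosine: strong but not perfect correlation away from
  # the smoothing edges (the distortion is characterized in the vignette)
  trend <- c(150, 8, 0.3, -0.004, 1e-5)
  p <- well_sim_params(trend = trend, amplitude = 80, period = 26, phase = 1)
  sim <- simulate_well(p, times84)
  pp <- preprocess_plate(
    plate_series(times84, matrix(sim), data.frame(well = "A1", strain = "WT"))
  )
  truth <- 80 * cos(2 * pi * times84 / 26 + 1)
  win <- times84 >= 3 & times84 <= 81
  expect_gt(stats::cor(pp$smoothed[win, 1], truth[win]), 0.9)
  # the trend-coefficient distortion is exactly trend-independent: the fitted
  # coefficients equal true trend + quartic projection of the cosine
  cos_proj <- oracle_polyfit(truth, times84, 4, 3)
  expect_equal(pp$trend_coeffs[, 1], trend + cos_proj, tolerance = 1e-6)
})
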