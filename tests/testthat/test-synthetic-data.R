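times84 <- seq(0, 84, by = 1 / 12)

test_that("noiseless wells follow the closed-form signal model", {
  p <- well_sim_params(amplitude = 80, period = 26, phase = 1)
  y <- simulate_well(p, times84)
  expect_equal(y[1], 80 * cos(1))
  expect_equal(y, 80 * cos(2 * pi * times84 / 26 + 1))

  # amplitude 0, sigma 0 -> trace equals the trend exactly
  p2 <- well_sim_params(trend = c(2, 3, -0.1))
  expect_equal(simulate_well(p2, times84), 2 + 3 * times84 - 0.1 * times84^2)

  # damping multiplies the cosine by exp(-lambda t)
  p3 <- well_sim_params(amplitude = 10, period = 24, phase = 0.5, damping = 0.03)
  expect_equal(simulate_well(p3, times84),
               10 * exp(-0.03 * times84) * cos(2 * pi * times84 / 24 + 0.5))

  # transient decays as exp(-t / 1h)
  p4 <- well_sim_params(transient_amplitude = 30)
  expect_equal(simulate_well(p4, times84), 30 * exp(-times84))

  # logistic trend option
  p5 <- well_sim_params(trend = list(type = "logistic", K = 400, r = 0.1, t_mid = 40))
  expect_equal(simulate_well(p5, times84), 400 / (1 + exp(-0.1 * (times84 - 40))))
})

test_that("simulation is deterministic per seed and parameters validated", {
  p <- well_sim_params(amplitude = 5, period = 24, noise_sd = 2)
  expect_identical(simulate_well(p, times84, seed = 11),
                   simulate_well(p, times84, seed = 11))
  expect_false(identical(simulate_well(p, times84, seed = 11),
                         simulate_well(p, times84, seed = 12)))
  expect_error(well_sim_params(period = -1), class = "param_error")
  expect_error(well_sim_params(noise_sd = -0.1), class = "param_error")
  expect_error(well_sim_params(damping = -1), class = "param_error")
  expect_error(well_sim_params(trend = 1:6), class = "param_error")
})

test_that("experiments lay out one grid and derived per-well seeds", {
  spec <- experiment_spec(
    strains = list(WT = well_sim_params(amplitude = 1, period = 26),
                   mut = well_sim_params(amplitude = 1, period = 20)),
    replicates = 4, duration = 84, dt = 1 / 12, seed = 5
  )
  sim <- simulate_experiment(spec)
  expect_equal(n_wells(sim), 8)
  expect_equal(length(sim$times), 84 * 12 + 1) # 1009 samples
  expect_setequal(unique(sim$wells$strain), c("mut", "WT"))
  # reproducible end to end
  expect_identical(simulate_experiment(spec)$values, sim$values)
  # per-well seed derivation is stable and in 32-bit range
  expect_identical(well_seed(5, 3), well_seed(5, 3))
  expect_true(well_seed(2147483646, 10000) < 2^31)
  expect_error(
    experiment_spec(strains = list(well_sim_params()), replicates = 2),
    class = "spec_error"
  )
})

test_that("noise is zero-mean i.i.d. Gaussian at the requested sd", {
  p <- well_sim_params(noise_sd = 1)
  t_long <- seq(0, 1e4, by = 0.1) # > 1e5 draws
  eps <- simulate_well(p, t_long, seed = 99)
  n <- length(eps)
  expect_lt(abs(mean(eps)), 4 / sqrt(n))
  expect_equal(stats::sd(eps), 1, tolerance = 0.02)
})

test_that("generator-fit closed loop recovers clean parameters to 1e-3", {
  # noiseless, undamped cosines strictly inside generous bounds: the harmonic
  # fit must identify them essentially exactly
  b <- fit_bounds(a_max = 120, min_period = 18, max_period = 45)
  for (P in c(19, 26, 40)) {
    for (phi in c(0.6, 3)) {
      p <- well_sim_params(amplitude = 80, period = P, phase = phi)
      y <- simulate_well(p, times84)
      f <- fit_cosine(times84, y, b)
      expect_equal(f$period, P, tolerance = 1e-3)
      expect_equal(f$a, 80, tolerance = 1e-3 * 80)
      expect_equal(f$phi, phi, tolerance = 1e-3 * phi)
    }
  }
})

test_that("damped presets realize their target first-peak observables", {
  ref <- well_sim_params(amplitude = 80, period = 26, phase = 1)
  mut <- damped_offset_params(ref, phase_offset = -7, rel_amplitude = 1 / 3,
                              damping = 0.02)
  ext_ref <- damped_first_extrema(ref$period, ref$phase, 0)
  ext_mut <- damped_first_extrema(mut$period, mut$phase, mut$damping)
  expect_equal(ext_mut$peak - ext_ref$peak, -7, tolerance = 1e-9)
  # realized height at the damped first peak is 1/3 the reference amplitude
  h <- mut$amplitude * exp(-mut$damping * ext_mut$peak) *
    cos(2 * pi * ext_mut$peak / mut$period + mut$phase)
  expect_equal(h, 80 / 3, tolerance = 1e-9)
  # closed form matches a dense numerical argmax of the oscillation
  tt <- seq(0, 30, by = 1e-4)
  osc <- mut$amplitude * exp(-mut$damping * tt) *
    cos(2 * pi * tt / mut$period + mut$phase)
  expect_equal(tt[which.max(osc)], ext_mut$peak, tolerance = 1e-3)
})
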