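#' Per-well simulation parameters
#'
#' Describes one well's signal as the sum of a smooth growth trend, a start-up
#' transient decaying within the first hours, a (possibly exponentially damped)
#' cosine, and i.i.d. Gaussian noise:
#'
#' \deqn{y(t) = trend(t) + c\,e^{-t/1h} + A_0 e^{-\lambda t}
#'   \cos(2\pi t / P + \varphi_0) + \varepsilon,\quad
#'   \varepsilon \sim N(0, \sigma^2).}
#'
#' The trend is either a polynomial (coefficients lowest order first, degree
#' <= 4, in backscatter units per hour^k) or a logistic curve
#' `K / (1 + exp(-r (t - t_mid)))`.
#'
#' @param trend numeric vector of polynomial coefficients (lowest order first),
#'   or `list(type = "logistic", K=, r=, t_mid=)`. Default `0` (flat).
#' @param amplitude oscillation amplitude A0 >= 0, backscatter units.
#' @param period oscillation period P > 0, hours.
#' @param phase phase angle phi0, radians.
#' @param damping exponential damping rate lambda >= 0, per hour.
#' @param noise_sd Gaussian noise SD sigma >= 0, backscatter units.
#' @param transient_amplitude start-up artifact amplitude c >= 0; the artifact
#'   decays as `exp(-t / 1h)`, i.e. essentially gone after 3 h (the window the
#'   detrending stage excludes).
#' @return object of class `well_sim_params`.
#' @export
well_sim_params <- function(trend = 0, amplitude = 0, period = 24, phase = 0,
                            damping = 0, noise_sd = 0, transient_amplitude = 0) {
  if (!is_number(period) || period <= 0) cr_abort("period must be > 0", "param_error")
  if (!is_number(amplitude) || amplitude < 0) cr_abort("amplitude must be >= 0", "param_error")
  if (!is_number(damping) || damping < 0) cr_abort("damping must be >= 0", "param_error")
  if (!is_number(noise_sd) || noise_sd < 0) cr_abort("noise_sd must be >= 0", "param_error")
  if (!is_number(transient_amplitude) || transient_amplitude < 0) {
    cr_abort("transient_amplitude must be >= 0", "param_error")
  }
  if (!is_number(phase)) cr_abort("phase must be a finite number", "param_error")
  if (is.list(trend)) {
    if (!identical(trend$type, "logistic") ||
        !all(c("K", "r", "t_mid") %in% names(trend))) {
      cr_abort("list trend must be list(type='logistic', K=, r=, t_mid=)", "param_error")
    }
  } else {
    trend <- as.numeric(trend)
    if (length(trend) < 1L || length(trend) > 5L || anyNA(trend)) {
      cr_abort("polynomial trend needs 1..5 finite coefficients (degree <= 4)",
               "param_error")
    }
  }
  structure(
    list(trend = trend, amplitude = amplitude, period = period, phase = phase,
         damping = damping, noise_sd = noise_sd,
         transient_amplitude = transient_amplitude),
    class = "well_sim_params"
  )
}

eval_trend <- function(trend, times) {
  if (is.list(trend)) {
    trend$K / (1 + exp(-trend$r * (times - trend$t_mid)))
  } else {
    # Horner evaluation, coefficients lowest order first
    acc <- rep(trend[length(trend)], length(times))
    if (length(trend) > 1L) {
      for (k in rev(seq_len(length(trend) - 1L))) acc <- acc * times + trend[k]
    }
    acc
  }
}

#' Simulate one well trace
#'
#' Deterministic given `(params, times, seed)`: the same seed reproduces the
#' trace bitwise. Noise is drawn with R's default RNG after `set.seed(seed)`.
#'
#' @param params a [well_sim_params()].
#' @param times time grid in hours.
#' @param seed integer RNG seed.
#' @return numeric vector of backscatter values on `times`.
#' @export
simulate_well <- function(params, times, seed = 1L) {
  stopifnot(inherits(params, "well_sim_params"))
  times <- as.numeric(times)
  deterministic <-
    eval_trend(params$trend, times) +
    params$transient_amplitude * exp(-times / 1) +
    params$amplitude * exp(-params$damping * times) *
      cos(2 * pi * times / params$period + params$phase)
  if (params$noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    deterministic <- deterministic + stats::rnorm(length(times), 0, params$noise_sd)
  }
  deterministic
}

#' Experiment specification for a synthetic plate
#'
#' @param strains named list of [well_sim_params()], one entry per strain.
#' @param replicates wells per strain (single value or one per strain); the
#'   study design this emulates used 4-5 replicate wells per strain.
#' @param duration total duration in hours (default 84).
#' @param dt sampling interval in hours (default 1/12, i.e. 5 min).
#' @param seed integer experiment seed; per-well seeds are derived from it.
#' @return object of class `experiment_spec`.
#' @export
experiment_spec <- function(strains, replicates = 5L, duration = 84, dt = 1 / 12,
                            seed = 1L) {
  if (!is.list(strains) || length(strains) == 0L || is.null(names(strains)) ||
      any(names(strains) == "")) {
    cr_abort("strains must be a named list of well_sim_params", "spec_error")
  }
  if (anyDuplicated(names(strains))) cr_abort("duplicate strain names", "spec_error")
  ok <- vapply(strains, inherits, logical(1), "well_sim_params")
  if (!all(ok)) cr_abort("every strain entry must be a well_sim_params", "spec_error")
  replicates <- as.integer(rep_len(replicates, length(strains)))
  if (any(replicates < 1L)) cr_abort("replicates must be >= 1", "spec_error")
  if (!is_number(duration) || !is_number(dt) || dt <= 0 || duration / dt < 1) {
    cr_abort("duration/dt must yield at least 2 samples", "spec_error")
  }
  structure(
    list(strains = strains, replicates = replicates, duration = duration,
         dt = dt, seed = as.integer(seed)),
    class = "experiment_spec"
  )
}

#' Derive a per-well RNG seed from the experiment seed
#'
#' Stable across runs and platforms: `(seed + 1000003 * well_index) mod
#' (2^31 - 1)` in double arithmetic (exact for these magnitudes).
#'
#' @param seed experiment seed.
#' @param well_index 1-based well index within the experiment.
#' @return integer seed.
#' @export
well_seed <- function(seed, well_index) {
  as.integer((as.double(seed) + 1000003 * as.double(well_index)) %% 2147483647)
}

#' Simulate a full plate experiment
#'
#' Generates `replicates` wells per strain on a single shared grid
#' `seq(0, duration, by = dt)`. Well ids are `<strain>_<replicate>`.
#'
#' @param spec an [experiment_spec()].
#' @return a [plate_series()].
#' @examples
#' spec <- experiment_spec(
#'   strains = list(WT = well_sim_params(amplitude = 80, period = 26, phase = 1)),
#'   replicates = 4, duration = 84, dt = 1 / 12, seed = 7
#' )
#' sim <- simulate_experiment(spec)
#' @export
simulate_experiment <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  times <- seq(0, spec$duration, by = spec$dt)
  strain_names <- names(spec$strains)
  well_ids <- character(0)
  strains <- character(0)
  for (i in seq_along(strain_names)) {
    reps <- spec$replicates[i]
    well_ids <- c(well_ids, sprintf("%s_%d", strain_names[i], seq_len(reps)))
    strains <- c(strains, rep(strain_names[i], reps))
  }
  if (anyDuplicated(well_ids)) cr_abort("duplicate well ids in spec", "spec_error")
  values <- matrix(NA_real_, nrow = length(times), ncol = length(well_ids))
  for (j in seq_along(well_ids)) {
    values[, j] <- simulate_well(spec$strains[[strains[j]]], times,
                                 seed = well_seed(spec$seed, j))
  }
  plate_series(times, values,
               data.frame(well = well_ids, strain = strains,
                          stringsAsFactors = FALSE))
}

#' First-extremum times of a damped cosine
#'
#' For `A0 exp(-lambda t) cos(2 pi t / P + phi)`, extrema satisfy
#' `tan(omega t + phi) = -lambda / omega`; the envelope pulls every extremum
#' earlier than the undamped cosine by `atan(lambda / omega) / omega`. Used to
#' place a mutant preset's first peak at a chosen phase offset from a
#' reference.
#'
#' @param period P in hours.
#' @param phase phi in radians.
#' @param damping lambda per hour.
#' @return list with `peak` and `trough`: times (hours, >= 0) of the first
#'   maximum and first minimum.
#' @export
damped_first_extrema <- function(period, phase, damping = 0) {
  omega <- 2 * pi / period
  lag <- atan(damping / omega)
  # maxima at omega t + phi = 2 pi k - lag; minima at 2 pi k + pi - lag
  first_time <- function(target) {
    k <- ceiling((phase + lag - target) / (2 * pi))
    (2 * pi * k + target - lag - phase) / omega
  }
  list(peak = first_time(0), trough = first_time(pi))
}

#' Preset experiment mirroring the published strain panel
#'
#' Three strain archetypes on a quartic growth trend:
#' * `WT`: robust ~26 h cosine, no damping.
#' * `dKaiA1B1C1`: very low amplitude, long ~33 h period, no damping.
#' * `dKaiA3B3C3`: damped oscillation whose *measured* first peak is 7 h
#'   earlier and one third the height of the WT first peak (the generator's
#'   nominal amplitude/phase are back-computed from the damped-extremum
#'   closed form, see [damped_first_extrema()]).
#'
#' @param noise_sd Gaussian noise SD applied to every strain (default 8).
#' @param replicates wells per strain (default 5).
#' @param seed experiment seed.
#' @param duration,dt grid (defaults 84 h at 5 min).
#' @return an [experiment_spec()].
#' @export
preset_panel_spec <- function(noise_sd = 8, replicates = 5L, seed = 1L,
                              duration = 84, dt = 1 / 12) {
  trend <- c(150, 8, 0.3, -0.004, 1e-5) # gentle quartic growth
  wt <- well_sim_params(trend = trend, amplitude = 80, period = 26, phase = 1,
                        noise_sd = noise_sd)
  a1 <- well_sim_params(trend = trend, amplitude = 8, period = 33, phase = 1,
                        noise_sd = noise_sd)
  a3 <- damped_offset_params(wt, phase_offset = -7, rel_amplitude = 1 / 3,
                             damping = 0.02, noise_sd = noise_sd)
  experiment_spec(
    strains = list(WT = wt, dKaiA1B1C1 = a1, dKaiA3B3C3 = a3),
    replicates = replicates, duration = duration, dt = dt, seed = seed
  )
}

#' Damped-mutant parameters realizing a target first-peak offset and ratio
#'
#' Given a reference (undamped) preset, builds a damped variant whose first
#' peak of the oscillatory component occurs `phase_offset` hours from the
#' reference first peak and whose height there is `rel_amplitude` times the
#' reference amplitude. Compensates analytically for the damping envelope:
#' the nominal amplitude is `A_ref * rel_amplitude * exp(lambda t_peak)` and
#' the nominal phase places the damped extremum (not the bare cosine maximum)
#' at the target time.
#'
#' @param reference a [well_sim_params()] with `damping = 0`.
#' @param phase_offset hours (negative = earlier than reference).
#' @param rel_amplitude target first-peak height ratio.
#' @param damping lambda per hour for the variant.
#' @param noise_sd noise SD for the variant (default: reference's).
#' @param period period of the variant (default: reference's).
#' @return a [well_sim_params()].
#' @export
damped_offset_params <- function(reference, phase_offset, rel_amplitude,
                                 damping, noise_sd = reference$noise_sd,
                                 period = reference$period) {
  stopifnot(inherits(reference, "well_sim_params"))
  if (reference$damping != 0) {
    cr_abort("reference preset must be undamped", "param_error")
  }
  ref_peak <- damped_first_extrema(reference$period, reference$phase, 0)$peak
  t_peak <- ref_peak + phase_offset
  if (t_peak < 0) cr_abort("target first peak lies before t = 0", "param_error")
  omega <- 2 * pi / period
  lag <- atan(damping / omega)
  # place the damped extremum at t_peak: omega t_peak + phi = 2 pi k - lag
  phi <- (2 * pi - lag - omega * t_peak) %% (2 * pi)
  # cos value at the damped extremum is cos(-lag) = cos(lag)
  a0 <- reference$amplitude * rel_amplitude *
    exp(damping * t_peak) / cos(lag)
  well_sim_params(
    trend = reference$trend, amplitude = a0, period = period, phase = phi,
    damping = damping, noise_sd = noise_sd,
    transient_amplitude = reference$transient_amplitude
  )
}
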