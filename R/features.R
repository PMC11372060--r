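#' First-cycle period from the first trough and first peak
#'
#' For dampened oscillators that a single cosine does not describe well, the
#' first-cycle period is estimated as twice the absolute time difference
#' between the earliest detected trough and the earliest detected peak
#' (trough-to-peak is half a cycle; the absolute value makes the estimate
#' order-agnostic). Default detection settings: distance 150 samples, height
#' 50 signal units, applied to the smoothed signal.
#'
#' @param signal smoothed, normalized signal.
#' @param times time grid, hours.
#' @param params a [peak_params()] (default `peak_params(150, 50)`).
#' @return period in hours.
#' @export
first_cycle_period <- function(signal, times, params = peak_params()) {
  peaks <- find_peaks(signal, params, times)
  troughs <- find_troughs(signal, params, times)
  if (nrow(peaks) == 0L || nrow(troughs) == 0L) {
    cr_abort("no qualifying trough/peak pair for first-cycle period",
             "feature_error")
  }
  2 * abs(peaks$time[1] - troughs$time[1])
}

#' Time and height of the first qualifying peak
#'
#' The phase/amplitude feature of the first oscillation cycle: the earliest
#' peak passing the distance/width/height criteria (defaults: distance 150
#' samples, width 65 samples at half prominence, height
#' `mean(signal) + 0.2 * max(signal)`).
#'
#' @param signal smoothed, normalized signal.
#' @param times time grid, hours.
#' @param params a [peak_params()]; default [first_peak_params()] computed
#'   from `signal`.
#' @return list with `time` (hours) and `height` (signal units).
#' @export
first_peak_features <- function(signal, times, params = NULL) {
  if (is.null(params)) params <- first_peak_params(signal)
  peaks <- find_peaks(signal, params, times)
  if (nrow(peaks) == 0L) {
    cr_abort("no peak satisfies the first-peak criteria", "feature_error")
  }
  list(time = peaks$time[1], height = peaks$height[1])
}

#' Summarize first-peak features across replicate wells of one strain
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator; 0 for a
#' single well) of per-well first-peak times and heights.
#'
#' @param strain strain label.
#' @param peak_times per-well first-peak times, hours.
#' @param peak_heights per-well first-peak heights, signal units.
#' @return object of class `strain_first_peak`: `strain`, `n_wells`,
#'   `peak_time_mean`, `peak_time_sd`, `peak_height_mean`, `peak_height_sd`.
#' @export
summarize_strain <- function(strain, peak_times, peak_heights) {
  if (length(peak_times) < 1L || length(peak_times) != length(peak_heights)) {
    cr_abort("need matching non-empty feature vectors", "shape_error")
  }
  sd0 <- function(v) if (length(v) > 1L) stats::sd(v) else 0
  structure(
    list(strain = strain, n_wells = length(peak_times),
         peak_time_mean = mean(peak_times), peak_time_sd = sd0(peak_times),
         peak_height_mean = mean(peak_heights),
         peak_height_sd = sd0(peak_heights)),
    class = "strain_first_peak"
  )
}

#' First-peak phase shift of a mutant versus a reference strain
#'
#' `shift = mean peak time(mutant) - mean peak time(reference)`, with error
#' boundary `SD(mutant) + SD(reference)` (the published error formula: a sum
#' of the replicate SDs, not a propagated quadrature).
#'
#' @param mutant,reference [summarize_strain()] results.
#' @return list with `shift` (hours) and `error` (hours).
#' @export
phase_shift <- function(mutant, reference) {
  stopifnot(inherits(mutant, "strain_first_peak"),
            inherits(reference, "strain_first_peak"))
  list(shift = mutant$peak_time_mean - reference$peak_time_mean,
       error = mutant$peak_time_sd + reference$peak_time_sd)
}

#' First-peak relative amplitude of a mutant versus a reference strain
#'
#' `ratio = mean peak height(mutant) / mean peak height(reference)`, with the
#' published error boundary implemented literally as printed:
#' `SD(mutant)/height(mutant) + SD(reference)/height(reference)` (a sum of
#' relative SDs). `propagate = TRUE` multiplies that sum by the ratio,
#' yielding the conventional first-order propagated error instead.
#'
#' @param mutant,reference [summarize_strain()] results.
#' @param propagate scale the error by the ratio (default `FALSE`).
#' @return list with `ratio` (dimensionless) and `error`.
#' @export
relative_amplitude <- function(mutant, reference, propagate = FALSE) {
  stopifnot(inherits(mutant, "strain_first_peak"),
            inherits(reference, "strain_first_peak"))
  if (reference$peak_height_mean == 0) {
    cr_abort("reference peak height is zero", "domain_error")
  }
  ratio <- mutant$peak_height_mean / reference$peak_height_mean
  err <- abs(mutant$peak_height_sd / mutant$peak_height_mean) +
    abs(reference$peak_height_sd / reference$peak_height_mean)
  if (propagate) err <- err * abs(ratio)
  list(ratio = ratio, error = err)
}

#' Per-strain first-cycle period statistics
#'
#' Applies [first_cycle_period()] to each replicate well and returns the
#' per-well values with their mean, median and sample SD. Wells where no
#' trough/peak pair qualifies are dropped (and named in `failed`); if every
#' well fails, a `feature_error` is signalled.
#'
#' @param smoothed matrix of smoothed traces (columns = wells of one strain).
#' @param times time grid, hours.
#' @param params a [peak_params()] (default `peak_params(150, 50)`).
#' @param strain strain label carried through to the result.
#' @return object of class `first_period_stats`: `strain`, `periods`
#'   (named per-well vector), `mean`, `median`, `sd`, `failed`.
#' @export
first_period_stats <- function(smoothed, times, params = peak_params(),
                               strain = "") {
  smoothed <- as.matrix(smoothed)
  wells <- colnames(smoothed)
  if (is.null(wells)) wells <- as.character(seq_len(ncol(smoothed)))
  periods <- numeric(0)
  failed <- character(0)
  for (j in seq_len(ncol(smoothed))) {
    p <- tryCatch(first_cycle_period(smoothed[, j], times, params),
                  feature_error = function(e) NA_real_)
    if (is.na(p)) failed <- c(failed, wells[j])
    else periods <- c(periods, stats::setNames(p, wells[j]))
  }
  if (length(periods) == 0L) {
    cr_abort(sprintf("first-cycle period failed in all %d wells", ncol(smoothed)),
             "feature_error")
  }
  structure(
    list(strain = strain, periods = periods, mean = mean(periods),
         median = stats::median(periods),
         sd = if (length(periods) > 1L) stats::sd(periods) else 0,
         failed = failed),
    class = "first_period_stats"
  )
}
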