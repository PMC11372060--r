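#' Detrending/smoothing configuration
#'
#' Defaults reproduce the published processing: a fourth-degree polynomial
#' growth trend fitted while excluding the first 3 h (start-up artifacts), and
#' a 40-sample uniform smoothing kernel (3 h 20 min at 5-min sampling).
#'
#' @param degree polynomial degree >= 0 (default 4).
#' @param exclude_before_h hours excluded from the *trend fit* (default 3); the
#'   fitted trend is still subtracted at all time points.
#' @param kernel_samples uniform smoothing kernel size in samples (default 40).
#' @param edge_trim if `TRUE`, downstream peak search drops
#'   `floor(kernel_samples / 2)` samples at each end, where zero-padded
#'   smoothing biases the signal toward zero (default `FALSE`, faithful to the
#'   original processing).
#' @return object of class `detrend_config`.
#' @export
detrend_config <- function(degree = 4L, exclude_before_h = 3, kernel_samples = 40L,
                           edge_trim = FALSE) {
  if (!is_number(degree) || degree < 0 || degree != round(degree)) {
    cr_abort("degree must be a nonnegative integer", "param_error")
  }
  if (!is_number(exclude_before_h) || exclude_before_h < 0) {
    cr_abort("exclude_before_h must be >= 0", "param_error")
  }
  if (!is_number(kernel_samples) || kernel_samples < 1 ||
      kernel_samples != round(kernel_samples)) {
    cr_abort("kernel_samples must be a positive integer", "param_error")
  }
  structure(
    list(degree = as.integer(degree), exclude_before_h = exclude_before_h,
         kernel_samples = as.integer(kernel_samples),
         edge_trim = isTRUE(edge_trim)),
    class = "detrend_config"
  )
}

#' Fit the polynomial growth trend of one trace
#'
#' Ordinary least squares polynomial of the configured degree, fitted only to
#' time points with `t >= exclude_before_h`. For conditioning, the fit runs on
#' a scaled time axis internally (a raw degree-4 monomial basis on t up to
#' 84 h is badly conditioned); returned coefficients are in the monomial basis
#' on the original axis, lowest order first.
#'
#' @param values raw backscatter values.
#' @param times time grid, hours.
#' @param cfg a [detrend_config()].
#' @return numeric vector of `degree + 1` coefficients, lowest order first.
#' @export
fit_trend <- function(values, times, cfg = detrend_config()) {
  values <- as.numeric(values)
  times <- as.numeric(times)
  if (length(values) != length(times)) {
    cr_abort("values and times differ in length", "shape_error")
  }
  keep <- times >= cfg$exclude_before_h
  n_in <- sum(keep)
  if (n_in <= cfg$degree) {
    cr_abort(sprintf(
      "only %d points at t >= %g h; need more than degree (%d)",
      n_in, cfg$exclude_before_h, cfg$degree
    ), "fit_error")
  }
  s <- max(abs(times[keep]))
  if (s == 0) s <- 1
  ts <- times[keep] / s
  X <- outer(ts, 0:cfg$degree, `^`)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) cr_abort("rank-deficient polynomial design", "fit_error")
  beta_scaled <- qr.coef(qr_x, values[keep])
  beta_scaled / s^(0:cfg$degree)
}

eval_poly <- function(coeffs, times) {
  acc <- rep(coeffs[length(coeffs)], length(times))
  if (length(coeffs) > 1L) {
    for (k in rev(seq_len(length(coeffs) - 1L))) acc <- acc * times + coeffs[k]
  }
  acc
}

#' Detrend and normalize one trace
#'
#' Subtracts the polynomial trend prediction at *all* time points (including
#' the early window excluded from the fit), then subtracts the arithmetic mean
#' of the residual so the normalized signal has zero mean.
#'
#' @param values raw backscatter values.
#' @param times time grid, hours.
#' @param coeffs coefficients from [fit_trend()], lowest order first.
#' @return list with `normalized` (zero-mean residual) and `subtracted_mean`.
#' @export
detrend_normalize <- function(values, times, coeffs) {
  values <- as.numeric(values)
  if (length(values) != length(times)) {
    cr_abort("values and times differ in length", "shape_error")
  }
  residual <- values - eval_poly(coeffs, times)
  m <- mean(residual)
  list(normalized = residual - m, subtracted_mean = m)
}

#' Uniform-kernel smoothing, zero-padded "same" convolution
#'
#' Discrete convolution with a kernel of `kernel_size` equal weights summing
#' to 1, zero-padded so the output has the input length. Output sample `i` is
#' centred on input sample `i` with the kernel centre at offset
#' `floor(kernel_size / 2)`; the first and last `floor(kernel_size / 2)`
#' samples are biased toward zero by the padding (reproduced deliberately, see
#' [detrend_config()]'s `edge_trim`).
#'
#' @param x numeric signal.
#' @param kernel_size window length in samples, >= 1.
#' @return smoothed signal, same length as `x`.
#' @export
smooth_uniform <- function(x, kernel_size) {
  x <- as.numeric(x)
  n <- length(x)
  k <- as.integer(kernel_size)
  if (k < 1L) cr_abort("kernel_size must be >= 1", "param_error")
  if (k > n) {
    cr_warn(sprintf("kernel size %d exceeds series length %d", k, n),
            "kernel_warning")
  }
  if (k == 1L) return(x)
  half <- k %/% 2L
  xp <- c(rep(0, k), x, rep(0, k))
  # window for output i: input indices (i - half) .. (i - half + k - 1)
  s <- cumsum(xp)
  lo <- seq_len(n) - half + k # index into xp of window start
  (s[lo + k - 1L] - s[lo - 1L]) / k
}

#' Preprocess every well of a plate
#'
#' Runs trend fit, detrend/normalize and smoothing per well and returns a
#' `processed_plate`: the shared grid plus matrices of normalized and smoothed
#' values, the per-well trend coefficients and subtracted means.
#'
#' @param series a [plate_series()].
#' @param cfg a [detrend_config()].
#' @return object of class `processed_plate` with elements `times`, `wells`,
#'   `normalized`, `smoothed` (matrices, one column per well), `trend_coeffs`
#'   (matrix, one column per well), `subtracted_mean`, `cfg`.
#' @export
preprocess_plate <- function(series, cfg = detrend_config()) {
  stopifnot(inherits(series, "plate_series"))
  nw <- n_wells(series)
  nt <- length(series$times)
  normalized <- matrix(NA_real_, nt, nw, dimnames = list(NULL, series$wells$well))
  smoothed <- normalized
  coeffs <- matrix(NA_real_, cfg$degree + 1L, nw,
                   dimnames = list(NULL, series$wells$well))
  means <- numeric(nw)
  for (j in seq_len(nw)) {
    cf <- fit_trend(series$values[, j], series$times, cfg)
    dn <- detrend_normalize(series$values[, j], series$times, cf)
    normalized[, j] <- dn$normalized
    smoothed[, j] <- smooth_uniform(dn$normalized, cfg$kernel_samples)
    coeffs[, j] <- cf
    means[j] <- dn$subtracted_mean
  }
  structure(
    list(times = series$times, wells = series$wells, normalized = normalized,
         smoothed = smoothed, trend_coeffs = coeffs, subtracted_mean = means,
         cfg = cfg),
    class = "processed_plate"
  )
}

#' @export
print.processed_plate <- function(x, ...) {
  cat(sprintf(
    "<processed_plate> %d wells, degree-%d detrend (t >= %g h), kernel %d\n",
    ncol(x$normalized), x$cfg$degree, x$cfg$exclude_before_h,
    x$cfg$kernel_samples
  ))
  invisible(x)
}

#' Export processed traces to long CSV
#'
#' Columns `well,strain,time_h,normalized,smoothed`.
#'
#' @param processed a [preprocess_plate()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_processed_long <- function(processed, path) {
  nt <- length(processed$times)
  df <- data.frame(
    well = rep(processed$wells$well, each = nt),
    strain = rep(processed$wells$strain, each = nt),
    time_h = rep(processed$times, times = nrow(processed$wells)),
    normalized = as.vector(processed$normalized),
    smoothed = as.vector(processed$smoothed)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
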