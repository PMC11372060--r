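#' Peak-detection parameters
#'
#' Defaults follow the published settings, expressed in *samples* on the
#' 5-min reference grid: for first-cycle period detection a minimum peak
#' separation of 150 samples (12.5 h) and a minimum height of 50
#' normalized-backscatter units; for first-peak phase/amplitude features a
#' separation of 150 samples, a minimum width of 65 samples (~5.4 h) at half
#' prominence, and a minimum height of `mean(signal) + 0.2 * max(signal)`
#' (set via [first_peak_params()]). Heights are in normalized units (trend
#' and mean removed, amplitude unscaled), so `min_height` must be adapted
#' when the data scale differs. When a grid's sampling interval differs from
#' `reference_dt`, sample-denominated settings are rescaled by
#' [scale_peak_params()] so the time-domain meaning is preserved.
#'
#' @param min_distance minimum separation between retained peaks, samples
#'   (>= 1).
#' @param min_height minimum peak height, signal units (`-Inf` disables).
#' @param min_width minimum full width at half prominence, samples, or `NULL`
#'   to disable.
#' @param reference_dt sampling interval (hours) at which the sample counts
#'   are denominated; default 1/12 h (5 min).
#' @return object of class `peak_params`.
#' @export
peak_params <- function(min_distance = 150L, min_height = 50,
                        min_width = NULL, reference_dt = 1 / 12) {
  if (!is_number(min_distance) || min_distance < 1) {
    cr_abort("min_distance must be >= 1 sample", "param_error")
  }
  if (!is.null(min_width) && (!is_number(min_width) || min_width < 0)) {
    cr_abort("min_width must be >= 0 or NULL", "param_error")
  }
  structure(
    list(min_distance = min_distance, min_height = min_height,
         min_width = min_width, reference_dt = reference_dt),
    class = "peak_params"
  )
}

#' First-peak feature parameters with data-dependent height
#'
#' The published first-peak criterion: distance 150 samples, width 65 samples,
#' minimum height `mean(signal) + 0.2 * max(signal)`.
#'
#' @param signal the signal the threshold is computed from.
#' @param min_distance,min_width,reference_dt see [peak_params()].
#' @return a [peak_params()].
#' @export
first_peak_params <- function(signal, min_distance = 150L, min_width = 65,
                              reference_dt = 1 / 12) {
  peak_params(
    min_distance = min_distance,
    min_height = mean(signal) + 0.2 * max(signal),
    min_width = min_width, reference_dt = reference_dt
  )
}

#' Rescale sample-denominated peak parameters to another grid
#'
#' @param params a [peak_params()].
#' @param dt sampling interval of the target grid, hours.
#' @return a [peak_params()] with `min_distance`/`min_width` scaled by
#'   `reference_dt / dt` (distance rounded, kept >= 1).
#' @export
scale_peak_params <- function(params, dt) {
  stopifnot(inherits(params, "peak_params"))
  f <- params$reference_dt / dt
  peak_params(
    min_distance = max(1, round(params$min_distance * f)),
    min_height = params$min_height,
    min_width = if (is.null(params$min_width)) NULL else params$min_width * f,
    reference_dt = dt
  )
}

# --- local maxima with plateau handling ------------------------------------

# returns matrix with columns index (plateau floor-midpoint), left, right
local_maxima <- function(x) {
  n <- length(x)
  out <- list()
  i <- 2L
  while (i <= n - 1L) {
    if (x[i - 1L] < x[i]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) {
        out[[length(out) + 1L]] <- c((i + j) %/% 2L, i, j)
        i <- j
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(out) == 0L) {
    matrix(integer(0), ncol = 3, dimnames = list(NULL, c("index", "left", "right")))
  } else {
    m <- do.call(rbind, out)
    dimnames(m) <- list(NULL, c("index", "left", "right"))
    m
  }
}

# greedy distance thinning: repeatedly keep the highest remaining peak
# (ties -> earlier index) and drop peaks closer than min_distance samples
thin_by_distance <- function(indices, heights, min_distance) {
  keep <- rep(TRUE, length(indices))
  ord <- order(-heights, indices)
  for (j in ord) {
    if (!keep[j]) next
    clash <- keep & abs(indices - indices[j]) < min_distance
    clash[j] <- FALSE
    keep[clash] <- FALSE
  }
  keep
}

# prominence of peak at p: scan outward until a sample higher than x[p] (or
# the signal end); the flanking base on each side is the minimum of the
# scanned range nearest the peak; prominence = x[p] - max(left min, right min)
peak_prominence <- function(x, p) {
  n <- length(x)
  left_min <- x[p]; left_base <- p
  i <- p - 1L
  while (i >= 1L && x[i] <= x[p]) {
    if (x[i] < left_min) { left_min <- x[i]; left_base <- i }
    i <- i - 1L
  }
  right_min <- x[p]; right_base <- p
  i <- p + 1L
  while (i <= n && x[i] <= x[p]) {
    if (x[i] < right_min) { right_min <- x[i]; right_base <- i }
    i <- i + 1L
  }
  list(prominence = x[p] - max(left_min, right_min),
       left_base = left_base, right_base = right_base)
}

# full width at a fraction of prominence below the peak, linearly
# interpolated, bounded by the prominence bases; width in samples
peak_width <- function(x, p, prom, rel_height = 0.5) {
  h_eval <- x[p] - rel_height * prom$prominence
  i <- p
  while (i > prom$left_base && x[i] > h_eval) i <- i - 1L
  left_ip <- as.numeric(i)
  if (x[i] < h_eval) left_ip <- i + (h_eval - x[i]) / (x[i + 1L] - x[i])
  i <- p
  while (i < prom$right_base && x[i] > h_eval) i <- i + 1L
  right_ip <- as.numeric(i)
  if (x[i] < h_eval) right_ip <- i - (h_eval - x[i]) / (x[i - 1L] - x[i])
  right_ip - left_ip
}

#' Detect peaks in a signal
#'
#' Local maxima (strictly higher than both neighbours; flat-topped plateaus
#' collapse to their floor-midpoint sample), filtered by minimum height,
#' thinned so retained peaks are at least `min_distance` samples apart
#' (iteratively keeping the highest remaining peak), then - when `min_width`
#' is set - filtered by full width at half prominence. Prominence is measured
#' against the higher of the two flanking minima within the peak's base.
#' Signal ends never count as peaks.
#'
#' @param signal numeric vector, length >= 3.
#' @param params a [peak_params()].
#' @param times optional time grid (hours); adds peak times to the result and
#'   triggers [scale_peak_params()] when the grid's spacing differs from the
#'   params' `reference_dt`.
#' @return object of class `peak_set`: data.frame with columns `index`
#'   (1-based sample), `time` (hours, `NA` without a grid), `height`,
#'   `prominence`, `width` (samples). Zero rows when nothing qualifies.
#' @examples
#' find_peaks(c(0, 3, 0, 5, 0), peak_params(min_distance = 1, min_height = 1))
#' @export
find_peaks <- function(signal, params = peak_params(), times = NULL) {
  stopifnot(inherits(params, "peak_params"))
  x <- as.numeric(signal)
  if (length(x) < 3L) cr_abort("signal must have at least 3 samples", "shape_error")
  if (!is.null(times)) {
    dt <- sampling_interval(times)
    if (abs(dt - params$reference_dt) > 1e-9) {
      params <- scale_peak_params(params, dt)
    }
  }
  lm <- local_maxima(x)
  idx <- lm[, "index"]
  heights <- x[idx]
  ok <- heights >= params$min_height
  idx <- idx[ok]; heights <- heights[ok]
  if (length(idx) > 1L) {
    keep <- thin_by_distance(idx, heights, params$min_distance)
    idx <- idx[keep]; heights <- heights[keep]
  }
  proms <- numeric(length(idx))
  widths <- numeric(length(idx))
  for (k in seq_along(idx)) {
    pr <- peak_prominence(x, idx[k])
    proms[k] <- pr$prominence
    widths[k] <- peak_width(x, idx[k], pr)
  }
  if (!is.null(params$min_width) && length(idx) > 0L) {
    ok <- widths >= params$min_width
    idx <- idx[ok]; heights <- heights[ok]
    proms <- proms[ok]; widths <- widths[ok]
  }
  structure(
    data.frame(
      index = as.integer(idx),
      time = if (is.null(times)) rep(NA_real_, length(idx)) else as.numeric(times)[idx],
      height = heights, prominence = proms, width = widths
    ),
    class = c("peak_set", "data.frame")
  )
}

#' Detect troughs in a signal
#'
#' Runs [find_peaks()] on the negated signal (`min_height` therefore applies
#' to the negated values) and reports heights on the original scale, i.e.
#' trough heights are the original (negative) minima.
#'
#' @inheritParams find_peaks
#' @return a `peak_set` whose `height` column holds the original signal
#'   values at the troughs.
#' @export
find_troughs <- function(signal, params = peak_params(), times = NULL) {
  out <- find_peaks(-as.numeric(signal), params, times)
  out$height <- -out$height
  out
}
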