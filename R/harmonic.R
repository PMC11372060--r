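#' Box constraints for the harmonic fit
#'
#' The model is `y(t) = A cos(omega t + phi)` with amplitude A (backscatter
#' units), angular frequency omega (rad/h) and phase angle phi (rad). The
#' published bound recipe is `0 <= A <= max(data) - mean(data)`,
#' `2 pi / max_period <= omega <= 2 pi / min_period`, and
#' `2 pi / 12 <= phi <= 2 pi`.
#'
#' @param a_max amplitude upper bound (>= 0).
#' @param min_period,max_period period window in hours, `0 < min < max`;
#'   converted to omega bounds.
#' @param phi_min,phi_max phase bounds in radians (defaults `2 pi / 12`,
#'   `2 pi`).
#' @return object of class `fit_bounds` with fields `a_min`, `a_max`,
#'   `omega_min`, `omega_max`, `phi_min`, `phi_max`.
#' @export
fit_bounds <- function(a_max, min_period = 18, max_period = 45,
                       phi_min = 2 * pi / 12, phi_max = 2 * pi) {
  if (!is_number(a_max) || a_max < 0) cr_abort("a_max must be >= 0", "param_error")
  if (!is_number(min_period) || !is_number(max_period) ||
      min_period <= 0 || max_period <= min_period) {
    cr_abort("need 0 < min_period < max_period", "param_error")
  }
  if (phi_min > phi_max) cr_abort("phi_min must be <= phi_max", "param_error")
  structure(
    list(a_min = 0, a_max = a_max,
         omega_min = 2 * pi / max_period, omega_max = 2 * pi / min_period,
         phi_min = phi_min, phi_max = phi_max,
         min_period = min_period, max_period = max_period),
    class = "fit_bounds"
  )
}

#' Default bounds from the data, following the published recipe
#'
#' `A_max = max(values) - mean(values)`; omega bounds from the estimated
#' period window (the published analysis used minimum estimated periods of
#' 18-35 h and maximum estimated periods of 26-45 h depending on the strain;
#' the widest envelope, 18-45 h, is the default); phase in
#' `[2 pi / 12, 2 pi]`.
#'
#' @param values signal the model will be fitted to (normally the smoothed,
#'   zero-mean trace).
#' @param min_period,max_period period window in hours.
#' @return a [fit_bounds()]. Warns (class `degenerate_bounds_warning`) when
#'   the series is constant so `A_max = 0`.
#' @export
default_bounds <- function(values, min_period = 18, max_period = 45) {
  a_max <- max(values) - mean(values)
  if (a_max == 0) {
    cr_warn("constant series: amplitude bound is degenerate (A_max = 0)",
            "degenerate_bounds_warning")
  }
  fit_bounds(a_max = a_max, min_period = min_period, max_period = max_period)
}

#' Fit a bounded simple-harmonic oscillation
#'
#' Least-squares fit of `A cos(omega t + phi)` under box constraints, by
#' Levenberg-Marquardt with multi-start: initial omega values from
#' `n_starts` equally spaced periods across the period window, initial
#' `A = A_max / 2`, initial phi at the midpoint of the phase bounds (the
#' objective is multimodal in omega, so a single start is unreliable). The
#' best start wins by residual sum of squares; exact ties break toward the
#' smaller fitted period.
#'
#' @param times time grid in hours.
#' @param values signal values (zero-mean smoothed trace, usually).
#' @param bounds a [fit_bounds()].
#' @param n_starts number of period starts (default 8).
#' @param tolerance convergence tolerance passed to the optimizer (default
#'   1e-10).
#' @return object of class `harmonic_fit`: `a`, `omega`, `phi`, `period`
#'   (= 2 pi / omega), `rss`, `converged`, `degenerate` (amplitude stuck at
#'   0), `n_points`, `r_squared` (1 - rss / total sum of squares, a
#'   report-only goodness-of-fit so callers can decide whether the strain is
#'   adequately described by a single cosine).
#' @examples
#' t <- seq(0, 84, by = 1 / 12)
#' y <- 80 * cos(2 * pi * t / 26 + 1)
#' fit_cosine(t, y, fit_bounds(a_max = 100))
#' @export
fit_cosine <- function(times, values, bounds, n_starts = 8L, tolerance = 1e-10) {
  stopifnot(inherits(bounds, "fit_bounds"))
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    cr_abort("times and values differ in length", "shape_error")
  }
  if (length(values) < 4L) cr_abort("need at least 4 points to fit 3 parameters",
                                    "fit_error")
  lower <- c(bounds$a_min, bounds$omega_min, bounds$phi_min)
  upper <- c(bounds$a_max, bounds$omega_max, bounds$phi_max)

  resid_fn <- function(p) values - p[1] * cos(p[2] * times + p[3])
  # starts equally spaced in angular frequency: uniform coverage of the
  # objective's oscillatory ridge (period spacing would undersample short
  # periods, where neighbouring modes are closest)
  start_periods <- 2 * pi / seq(bounds$omega_min, bounds$omega_max,
                                length.out = max(1L, as.integer(n_starts)))
  phi_mid <- (bounds$phi_min + bounds$phi_max) / 2
  a_mid <- min(max(bounds$a_max / 2, bounds$a_min), bounds$a_max)

  # warm start per trial period: A cos(wt + phi) = B cos(wt) + C sin(wt) is
  # linear in (B, C), so a least-squares solve gives good (A, phi) guesses,
  # with the phase wrapped into the bounds before projection
  warm_start <- function(w0) {
    cb <- cos(w0 * times); sb <- sin(w0 * times)
    coefs <- tryCatch(stats::lm.fit(cbind(cb, sb), values)$coefficients,
                      error = function(e) c(NA_real_, NA_real_))
    if (anyNA(coefs)) return(NULL)
    a0 <- sqrt(sum(coefs^2))
    phi0 <- atan2(-coefs[2], coefs[1]) %% (2 * pi)
    if (phi0 < bounds$phi_min) phi0 <- phi0 + 2 * pi
    c(min(max(a0, bounds$a_min), bounds$a_max),
      w0,
      min(max(phi0, bounds$phi_min), bounds$phi_max))
  }

  starts <- list()
  for (p0 in start_periods) {
    w0 <- min(max(2 * pi / p0, bounds$omega_min), bounds$omega_max)
    ws <- warm_start(w0)
    if (!is.null(ws)) starts[[length(starts) + 1L]] <- ws
    starts[[length(starts) + 1L]] <- c(a_mid, w0, phi_mid)
  }
  # profiled start: dense scan over omega with the amplitude/phase pair
  # solved linearly at each frequency (the objective conditional on omega is
  # linear in A cos(phi), -A sin(phi)), then start from the best frequency
  w_grid <- seq(bounds$omega_min, bounds$omega_max,
                length.out = max(50L, 25L * as.integer(n_starts)))
  prof_rss <- vapply(w_grid, function(w0) {
    cb <- cos(w0 * times); sb <- sin(w0 * times)
    fitl <- tryCatch(stats::lm.fit(cbind(cb, sb), values),
                     error = function(e) NULL)
    if (is.null(fitl)) Inf else sum(fitl$residuals^2)
  }, numeric(1))
  ws_prof <- warm_start(w_grid[which.min(prof_rss)])
  if (!is.null(ws_prof)) starts[[length(starts) + 1L]] <- ws_prof

  best <- NULL
  any_ok <- FALSE
  for (par0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = par0, lower = lower, upper = upper, fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          ftol = tolerance, ptol = tolerance, maxiter = 500
        )
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    any_ok <- TRUE
    rss <- sum(fit$fvec^2)
    period <- 2 * pi / fit$par[2]
    if (is.null(best) || rss < best$rss - 1e-12 ||
        (abs(rss - best$rss) <= 1e-12 && period < best$period)) {
      best <- list(par = fit$par, rss = rss, period = period, info = fit$info)
    }
  }
  if (!any_ok) cr_abort("all multi-start fits failed", "fit_error")

  par <- pmin(pmax(best$par, lower), upper)
  tss <- sum((values - mean(values))^2)
  degenerate <- par[1] <= bounds$a_min + 1e-12
  structure(
    list(a = par[1], omega = par[2], phi = par[3],
         period = 2 * pi / par[2], rss = best$rss,
         converged = best$info %in% 1:3 && !degenerate,
         degenerate = degenerate,
         n_points = length(values),
         r_squared = if (tss > 0) 1 - best$rss / tss else NA_real_),
    class = "harmonic_fit"
  )
}

#' @export
print.harmonic_fit <- function(x, ...) {
  cat(sprintf(
    "<harmonic_fit> A = %.4g, period = %.4g h, phi = %.4g rad (rss %.4g, R^2 %.3f%s)\n",
    x$a, x$period, x$phi, x$rss, x$r_squared,
    if (x$converged) "" else ", NOT converged"
  ))
  invisible(x)
}

#' Free-running period from a harmonic fit
#'
#' @param fit a [fit_cosine()] result, or an angular frequency in rad/h.
#' @return period in hours, `2 pi / omega`.
#' @export
period_of <- function(fit) {
  omega <- if (inherits(fit, "harmonic_fit")) fit$omega else as.numeric(fit)
  if (!is_number(omega) || omega <= 0) {
    cr_abort("angular frequency must be > 0", "domain_error")
  }
  2 * pi / omega
}

#' Per-well and per-strain harmonic fits of a processed plate
#'
#' Fits the bounded cosine to each well's smoothed trace and, per strain, to
#' the replicate-averaged smoothed trace (the mode used for the published
#' strain periods); both result tables are returned.
#'
#' @param processed a [preprocess_plate()] result.
#' @param min_period,max_period period window in hours (may be a named vector
#'   keyed by strain for strain-specific windows).
#' @param n_starts,tolerance passed to [fit_cosine()].
#' @return list of data.frames `wells` (one row per well) and `strains` (one
#'   row per strain, fitted on the replicate mean).
#' @export
fit_plate <- function(processed, min_period = 18, max_period = 45,
                      n_starts = 8L, tolerance = 1e-10) {
  window_for <- function(strain, w, default) {
    if (!is.null(names(w))) {
      if (strain %in% names(w)) unname(w[[strain]]) else default
    } else w
  }
  fit_one <- function(y, strain) {
    b <- default_bounds(
      y,
      min_period = window_for(strain, min_period, 18),
      max_period = window_for(strain, max_period, 45)
    )
    fit_cosine(processed$times, y, b, n_starts = n_starts, tolerance = tolerance)
  }
  row_of <- function(f) {
    data.frame(amplitude = f$a, period_h = f$period, phase_rad = f$phi,
               rss = f$rss, r_squared = f$r_squared, converged = f$converged)
  }
  wells <- do.call(rbind, lapply(seq_len(nrow(processed$wells)), function(j) {
    f <- fit_one(processed$smoothed[, j], processed$wells$strain[j])
    cbind(processed$wells[j, , drop = FALSE], row_of(f))
  }))
  rownames(wells) <- NULL
  strain_names <- unique(processed$wells$strain)
  strains <- do.call(rbind, lapply(strain_names, function(s) {
    cols <- processed$wells$strain == s
    avg <- rowMeans(processed$smoothed[, cols, drop = FALSE])
    f <- fit_one(avg, s)
    cbind(data.frame(strain = s, n_wells = sum(cols)), row_of(f))
  }))
  rownames(strains) <- NULL
  list(wells = wells, strains = strains)
}
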