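#' Construct a plate time-series object
#'
#' A `plate_series` holds a single, strictly increasing, uniform time grid (in
#' hours) shared by every well, plus one backscatter trace per well with its
#' strain label. This mirrors a microbioreactor export where all wells of one
#' plate are sampled on the same clock (typically every 5 min for 84 h).
#'
#' @param times numeric vector of time points in hours; strictly increasing,
#'   uniformly spaced (spacing constant to 1e-9 h), length >= 2.
#' @param values numeric matrix of backscatter values (arbitrary units), one
#'   column per well, `length(times)` rows. No missing values.
#' @param wells data.frame with columns `well` (unique ids) and `strain`.
#' @return An object of class `plate_series` with elements `times`, `values`,
#'   `wells`.
#' @examples
#' ps <- plate_series(
#'   times = seq(0, 1, by = 1 / 12),
#'   values = matrix(rnorm(26), ncol = 2),
#'   wells = data.frame(well = c("A1", "A2"), strain = "WT")
#' )
#' sampling_interval(ps)
#' @export
plate_series <- function(times, values, wells) {
  times <- as.numeric(times)
  if (length(times) < 2L) {
    cr_abort("a plate series needs at least 2 time points", "grid_error")
  }
  if (anyNA(times)) cr_abort("time grid contains missing values", "grid_error")
  check_uniform_grid(times)
  values <- as.matrix(values)
  if (!is.numeric(values)) cr_abort("backscatter values must be numeric", "parse_error")
  if (anyNA(values)) cr_abort("backscatter values contain NA; traces must be complete", "parse_error")
  if (nrow(values) != length(times)) {
    cr_abort(sprintf(
      "values have %d rows but the grid has %d time points",
      nrow(values), length(times)
    ), "shape_error")
  }
  wells <- as.data.frame(wells, stringsAsFactors = FALSE)
  if (!all(c("well", "strain") %in% names(wells))) {
    cr_abort("wells must have columns 'well' and 'strain'", "shape_error")
  }
  if (nrow(wells) != ncol(values)) {
    cr_abort("one wells row per value column required", "shape_error")
  }
  if (anyDuplicated(wells$well)) cr_abort("duplicate well ids", "spec_error")
  colnames(values) <- wells$well
  structure(
    list(times = times, values = values,
         wells = data.frame(well = as.character(wells$well),
                            strain = as.character(wells$strain),
                            stringsAsFactors = FALSE)),
    class = "plate_series"
  )
}

# grid must be uniform: spacing constant within 1e-9 h
check_uniform_grid <- function(times) {
  dt <- diff(times)
  if (any(dt <= 0)) cr_abort("time grid must be strictly increasing", "grid_error")
  if (max(dt) - min(dt) > 1e-9) {
    cr_abort(sprintf(
      "non-uniform time grid: spacing ranges from %.3g to %.3g h",
      min(dt), max(dt)
    ), "grid_error")
  }
  invisible(times)
}

#' @export
print.plate_series <- function(x, ...) {
  cat(sprintf(
    "<plate_series> %d wells x %d time points, t = %.3g..%.3g h (dt = %.4g h)\n",
    ncol(x$values), length(x$times), x$times[1],
    x$times[length(x$times)], sampling_interval(x)
  ))
  st <- table(x$wells$strain)
  cat("  strains:", paste(sprintf("%s (%d)", names(st), st), collapse = ", "), "\n")
  invisible(x)
}

#' Number of wells in a plate series
#' @param series a [plate_series()].
#' @return integer count of wells.
#' @export
n_wells <- function(series) ncol(series$values)

#' Sampling interval of a plate series
#'
#' Returns the constant grid spacing in hours, computed as
#' `(t_last - t_first) / (n - 1)` after validating uniformity.
#'
#' @param series a [plate_series()] (or a bare numeric time grid).
#' @return spacing in hours.
#' @export
sampling_interval <- function(series) {
  times <- if (inherits(series, "plate_series")) series$times else as.numeric(series)
  if (length(times) < 2L) {
    cr_abort("sampling interval undefined for fewer than 2 time points", "grid_error")
  }
  check_uniform_grid(times)
  (times[length(times)] - times[1]) / (length(times) - 1L)
}

#' Read plate time series from long-format delimited text
#'
#' Expects a header-keyed table with columns `well`, `strain`, `time_h`,
#' `backscatter` (column order irrelevant). All wells must share one uniform
#' time grid. A `time_unit = "min"` flag accepts a grid in minutes and converts
#' to hours, the canonical unit of every downstream formula.
#'
#' @param path file path.
#' @param sep field delimiter (default comma).
#' @param time_unit `"h"` (default) or `"min"`.
#' @return a [plate_series()].
#' @export
read_plate_long <- function(path, sep = ",", time_unit = c("h", "min")) {
  time_unit <- match.arg(time_unit)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = NA)
  need <- c("well", "strain", "time_h", "backscatter")
  if (!all(need %in% names(df))) {
    cr_abort(paste0(
      "missing required columns: ",
      paste(setdiff(need, names(df)), collapse = ", ")
    ), "parse_error")
  }
  if (!is.numeric(df$time_h)) cr_abort("time column is not numeric", "parse_error")
  if (!is.numeric(df$backscatter)) cr_abort("backscatter column is not numeric", "parse_error")
  if (anyNA(df$time_h) || anyNA(df$backscatter)) {
    cr_abort("missing values in time or backscatter column", "parse_error")
  }
  if (time_unit == "min") df$time_h <- df$time_h / 60

  well_ids <- unique(df$well)
  grid <- sort(unique(df$time_h))
  rows <- split(seq_len(nrow(df)), df$well)
  values <- matrix(NA_real_, nrow = length(grid), ncol = length(well_ids))
  strains <- character(length(well_ids))
  for (j in seq_along(well_ids)) {
    idx <- rows[[well_ids[j]]]
    tw <- df$time_h[idx]
    if (length(tw) != length(grid) || !isTRUE(all.equal(sort(tw), grid, tolerance = 1e-12))) {
      cr_abort(sprintf("well '%s' is not on the shared time grid", well_ids[j]),
               "shape_error")
    }
    ord <- order(tw)
    values[, j] <- df$backscatter[idx][ord]
    strains[j] <- df$strain[idx[1]]
  }
  plate_series(grid, values,
               data.frame(well = well_ids, strain = strains,
                          stringsAsFactors = FALSE))
}

#' Write plate time series to long-format delimited text
#'
#' One row per (well, time point), header `well,strain,time_h,backscatter`.
#' An empty well list yields a header-only file. Numbers are written with full
#' double precision so that `read_plate_long(write_plate_long(x))` round-trips
#' values to 1e-12.
#'
#' @param series a [plate_series()].
#' @param path output file path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_plate_long <- function(series, path, sep = ",") {
  stopifnot(inherits(series, "plate_series"))
  nw <- n_wells(series)
  nt <- length(series$times)
  df <- data.frame(
    well = rep(series$wells$well, each = nt),
    strain = rep(series$wells$strain, each = nt),
    time_h = rep(series$times, times = nw),
    backscatter = as.vector(series$values),
    stringsAsFactors = FALSE
  )
  con <- tryCatch(file(path, "w"), error = function(e) {
    cr_abort(sprintf("cannot open '%s' for writing", path), "io_error")
  })
  on.exit(close(con))
  writeLines(paste(c("well", "strain", "time_h", "backscatter"), collapse = sep), con)
  if (nrow(df) > 0L) {
    lines <- paste(df$well, df$strain,
                   formatC(df$time_h, format = "g", digits = 17),
                   formatC(df$backscatter, format = "g", digits = 17),
                   sep = sep)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Subset a plate series by strain
#' @param series a [plate_series()].
#' @param strain strain label(s) to keep.
#' @return a [plate_series()] with matching wells.
#' @export
subset_strain <- function(series, strain) {
  keep <- series$wells$strain %in% strain
  if (!any(keep)) cr_abort(sprintf("no wells with strain '%s'", paste(strain, collapse = ",")),
                           "key_error")
  plate_series(series$times, series$values[, keep, drop = FALSE],
               series$wells[keep, , drop = FALSE])
}
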