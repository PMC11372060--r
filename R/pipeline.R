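#' Run configuration for the backscatter analysis
#'
#' Bundles every stage's parameters with defaults equal to the published
#' processing: degree-4 detrend excluding the first 3 h, 40-sample smoothing
#' kernel, period window 18-45 h, period peaks (distance 150 / height 50),
#' first-peak features (distance 150 / width 65 / height mean + 0.2 max),
#' alpha 0.05.
#'
#' @param reference_strain strain all mutants are compared against.
#' @param detrend a [detrend_config()].
#' @param min_period_h,max_period_h cosine-fit period window (scalars or named
#'   per-strain vectors).
#' @param period_peaks [peak_params()] for first-cycle period detection.
#' @param first_peak_height `NULL` for the data-dependent default
#'   (`mean + 0.2 max`, per well) or a fixed height in signal units.
#' @param first_peak_distance,first_peak_width sample-denominated settings for
#'   the first-peak detector.
#' @param alpha significance level of the strain-comparison cascade.
#' @param n_starts,tolerance cosine-fit optimizer settings.
#' @param seed integer seed recorded in the manifest (the analysis itself is
#'   deterministic; the seed matters when the input is simulated here).
#' @return object of class `run_config`.
#' @export
run_config <- function(reference_strain,
                       detrend = detrend_config(),
                       min_period_h = 18, max_period_h = 45,
                       period_peaks = peak_params(min_distance = 150, min_height = 50),
                       first_peak_height = NULL,
                       first_peak_distance = 150L, first_peak_width = 65,
                       alpha = 0.05, n_starts = 8L, tolerance = 1e-10,
                       seed = 1L) {
  if (!is.character(reference_strain) || length(reference_strain) != 1L) {
    cr_abort("reference_strain must be a single strain name", "config_error")
  }
  structure(
    list(reference_strain = reference_strain, detrend = detrend,
         min_period_h = min_period_h, max_period_h = max_period_h,
         period_peaks = period_peaks, first_peak_height = first_peak_height,
         first_peak_distance = first_peak_distance,
         first_peak_width = first_peak_width, alpha = alpha,
         n_starts = n_starts, tolerance = tolerance, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the [run_config()] arguments; nested `detrend:` keys are
#' `degree`, `exclude_before_h`, `kernel_samples`, `edge_trim`.
#'
#' @param path YAML file path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    cr_abort("the 'yaml' package is required to read YAML configs", "config_error")
  }
  y <- yaml::read_yaml(path)
  det <- do.call(detrend_config, if (is.null(y$detrend)) list() else y$detrend)
  args <- y[setdiff(names(y), "detrend")]
  args$detrend <- det
  do.call(run_config, args)
}

#' End-to-end backscatter rhythm analysis
#'
#' Orchestrates preprocess -> harmonic fit -> peak features -> strain
#' comparisons for one plate. Per-well feature failures (e.g. no qualifying
#' peak in a low-amplitude mutant) are logged and reported, not fatal; the
#' affected well is simply absent from the feature tables. When `out_dir` is
#' given, every stage's table is written as CSV along with a JSON manifest of
#' parameters and package version, and re-running the same config on the same
#' input reproduces the files byte for byte.
#'
#' @param series a [plate_series()] (or path to a long CSV readable by
#'   [read_plate_long()]).
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return object of class `rhythm_analysis`: `processed`, `fits` (list of
#'   `wells`/`strains` data.frames), `first_peaks` (per well),
#'   `strain_summaries` (per strain), `comparisons` (per mutant vs
#'   reference), `first_periods` (per strain), `period_tests` (pairwise
#'   cascade on first-cycle periods), `log` (character).
#' @export
run_backscatter_analysis <- function(series, config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(series)) series <- read_plate_long(series)
  stopifnot(inherits(series, "plate_series"))
  strains <- unique(series$wells$strain)
  if (!config$reference_strain %in% strains) {
    cr_abort(sprintf("reference strain '%s' not present in the input",
                     config$reference_strain), "config_error")
  }
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  dt <- sampling_interval(series)
  note("input: %d wells, %d strains, dt = %.5f h", n_wells(series),
       length(strains), dt)

  processed <- preprocess_plate(series, config$detrend)
  trim <- if (config$detrend$edge_trim) config$detrend$kernel_samples %/% 2L else 0L
  keep_idx <- if (trim > 0) {
    seq_len(length(processed$times) - 2L * trim) + trim
  } else {
    seq_along(processed$times)
  }
  times_pk <- processed$times[keep_idx]

  fits <- fit_plate(processed, config$min_period_h, config$max_period_h,
                    n_starts = config$n_starts, tolerance = config$tolerance)

  # per-well first-peak features
  fp_rows <- list()
  for (j in seq_len(nrow(processed$wells))) {
    sig <- processed$smoothed[keep_idx, j]
    params <- if (is.null(config$first_peak_height)) {
      first_peak_params(sig, min_distance = config$first_peak_distance,
                        min_width = config$first_peak_width)
    } else {
      peak_params(min_distance = config$first_peak_distance,
                  min_height = config$first_peak_height,
                  min_width = config$first_peak_width)
    }
    feat <- tryCatch(first_peak_features(sig, times_pk, params),
                     feature_error = function(e) NULL)
    if (is.null(feat)) {
      note("well %s (%s): no qualifying first peak",
           processed$wells$well[j], processed$wells$strain[j])
      next
    }
    fp_rows[[length(fp_rows) + 1L]] <- data.frame(
      well = processed$wells$well[j], strain = processed$wells$strain[j],
      peak_time_h = feat$time, peak_height = feat$height
    )
  }
  first_peaks <- if (length(fp_rows)) do.call(rbind, fp_rows) else
    data.frame(well = character(0), strain = character(0),
               peak_time_h = numeric(0), peak_height = numeric(0))

  # per-strain first-peak summaries and mutant-vs-reference comparisons
  summaries <- list()
  for (s in strains) {
    rows <- first_peaks[first_peaks$strain == s, , drop = FALSE]
    if (nrow(rows) == 0L) {
      note("strain %s: first-peak summary unavailable", s)
      next
    }
    summaries[[s]] <- summarize_strain(s, rows$peak_time_h, rows$peak_height)
  }
  comp_rows <- list()
  ref <- summaries[[config$reference_strain]]
  if (is.null(ref)) {
    note("reference strain has no first-peak summary; comparisons skipped")
  } else {
    for (s in setdiff(names(summaries), config$reference_strain)) {
      ps <- phase_shift(summaries[[s]], ref)
      ra <- relative_amplitude(summaries[[s]], ref)
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        strain = s, reference = config$reference_strain,
        phase_shift_h = ps$shift, phase_shift_err_h = ps$error,
        relative_amplitude = ra$ratio, relative_amplitude_err = ra$error
      )
    }
  }
  comparisons <- if (length(comp_rows)) do.call(rbind, comp_rows) else
    data.frame(strain = character(0), reference = character(0),
               phase_shift_h = numeric(0), phase_shift_err_h = numeric(0),
               relative_amplitude = numeric(0),
               relative_amplitude_err = numeric(0))

  # per-strain first-cycle periods + pairwise statistics cascade
  fps_list <- list()
  for (s in strains) {
    cols <- processed$wells$strain == s
    st <- tryCatch(
      first_period_stats(processed$smoothed[keep_idx, cols, drop = FALSE],
                         times_pk, config$period_peaks, strain = s),
      feature_error = function(e) NULL
    )
    if (is.null(st)) {
      note("strain %s: first-cycle period failed in every well", s)
      next
    }
    if (length(st$failed)) {
      note("strain %s: first-cycle period failed in wells %s", s,
           paste(st$failed, collapse = ","))
    }
    fps_list[[s]] <- st
  }
  first_periods <- do.call(rbind, lapply(fps_list, function(st) {
    data.frame(strain = st$strain, n_wells = length(st$periods),
               period_mean_h = st$mean, period_median_h = st$median,
               period_sd_h = st$sd)
  }))
  groups <- lapply(fps_list, function(st) unname(st$periods))
  period_tests <- if (length(groups) >= 2L &&
                      all(vapply(groups, length, 1L) >= 2L)) {
    compare_all_strains(groups, alpha = config$alpha)
  } else {
    note("fewer than two strains with >= 2 period values; cascade skipped")
    NULL
  }

  result <- structure(
    list(processed = processed, fits = fits, first_peaks = first_peaks,
         strain_summaries = summaries, comparisons = comparisons,
         first_periods = first_periods, period_tests = period_tests,
         log = log, config = config),
    class = "rhythm_analysis"
  )
  if (!is.null(out_dir)) write_analysis(result, out_dir)
  result
}

#' @export
print.rhythm_analysis <- function(x, ...) {
  cat(sprintf("<rhythm_analysis> %d wells, %d strains\n",
              nrow(x$processed$wells), length(unique(x$processed$wells$strain))))
  if (!is.null(x$fits$strains)) {
    cat("strain-average cosine fits:\n")
    print(x$fits$strains, row.names = FALSE)
  }
  invisible(x)
}

write_analysis <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    if (!is.null(df)) {
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    }
  }
  w(result$fits$wells, "fits_wells.csv")
  w(result$fits$strains, "fits_strains.csv")
  w(result$first_peaks, "first_peaks.csv")
  w(result$comparisons, "comparisons.csv")
  w(result$first_periods, "first_periods.csv")
  w(result$period_tests, "period_tests.csv")
  writeLines(result$log, file.path(out_dir, "run_log.txt"))
  cfg <- result$config
  manifest <- list(
    package = "cyanorhythm",
    version = as.character(utils::packageVersion("cyanorhythm")),
    reference_strain = cfg$reference_strain,
    detrend = cfg$detrend[c("degree", "exclude_before_h", "kernel_samples",
                            "edge_trim")],
    fit = list(min_period_h = cfg$min_period_h, max_period_h = cfg$max_period_h,
               n_starts = cfg$n_starts, tolerance = cfg$tolerance),
    period_peaks = cfg$period_peaks[c("min_distance", "min_height")],
    first_peak = list(distance = cfg$first_peak_distance,
                      width = cfg$first_peak_width,
                      height = if (is.null(cfg$first_peak_height))
                        "mean+0.2*max" else cfg$first_peak_height),
    alpha = cfg$alpha, seed = cfg$seed
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' End-to-end co-occurrence analysis
#'
#' Reads (or accepts) a presence/absence matrix, restricts to the anchor
#' universe, computes right-sided Fisher's exact tests for all protein pairs,
#' applies the Benjamini-Hochberg correction and thresholds the network.
#'
#' @param m logical presence matrix or path to a delimited matrix file.
#' @param anchor anchor protein id.
#' @param q FDR level / edge threshold (default 0.01).
#' @param use_raw threshold raw instead of adjusted p-values.
#' @param out_dir optional output directory (writes edge/node CSVs and a
#'   manifest).
#' @return a [build_network()] result with the pair table attached as
#'   `pairs`.
#' @export
run_cooccurrence <- function(m, anchor, q = 0.01, use_raw = FALSE,
                             out_dir = NULL) {
  if (is.character(m)) m <- read_presence_matrix(m)
  if (length(m) == 0L || ncol(m) < 2L) {
    cr_abort("presence matrix must contain at least two proteins", "config_error")
  }
  pairs <- pairwise_cooccurrence(m, anchor)
  net <- build_network(pairs, q = q, use_raw = use_raw)
  net$pairs <- pairs
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_network(net, file.path(out_dir, "edges.csv"),
                  file.path(out_dir, "nodes.csv"))
    jsonlite::write_json(
      list(package = "cyanorhythm",
           version = as.character(utils::packageVersion("cyanorhythm")),
           anchor = anchor, q = q, use_raw = use_raw,
           n_genomes = nrow(m), n_proteins = ncol(m)),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA
    )
  }
  net
}
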