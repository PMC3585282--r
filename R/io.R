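#' Read and write frequency-scan CSV files
#'
#' The scan dialect has the header
#' `electrode_id,role,phase_label,frequency_hz,z_real_ohm,z_imag_ohm`
#' (UTF-8, '.' decimal). Each (electrode, role, phase) group becomes one
#' [complex_spectrum()]. Numbers are written with 15 significant
#' digits, so a write/read round trip is lossless at that precision.
#' Malformed rows are reported with their line numbers.
#'
#' @param path File path.
#' @return `read_scan_csv`: a list of [complex_spectrum()] objects.
#' @export
read_scan_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("electrode_id", "role", "phase_label", "frequency_hz",
            "z_real_ohm", "z_imag_ohm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing columns in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) stop("no data rows in ", path, call. = FALSE)
  num <- c("frequency_hz", "z_real_ohm", "z_imag_ohm")
  for (col in num) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]))
    if (length(bad)) {
      stop(sprintf("non-numeric '%s' at line(s) %s of %s", col,
                   paste(bad + 1, collapse = ", "), path), call. = FALSE)
    }
    df[[col]] <- vals
  }
  key <- interaction(df$electrode_id, df$role, df$phase_label, drop = TRUE)
  lapply(split(df, key), function(g) {
    g <- g[order(g$frequency_hz), , drop = FALSE]
    if (any(diff(g$frequency_hz) <= 0)) {
      stop(sprintf("duplicate frequencies for electrode '%s' (%s, %s) in %s",
                   g$electrode_id[1], g$role[1], g$phase_label[1], path),
           call. = FALSE)
    }
    complex_spectrum(g$frequency_hz,
                     z_real_ohm = g$z_real_ohm, z_imag_ohm = g$z_imag_ohm,
                     electrode_id = g$electrode_id[1],
                     role = g$role[1], phase_label = g$phase_label[1])
  })
}

#' @rdname read_scan_csv
#' @param spectra A [complex_spectrum()] or list of them.
#' @export
write_scan_csv <- function(spectra, path) {
  if (inherits(spectra, "complex_spectrum")) spectra <- list(spectra)
  df <- do.call(rbind, lapply(spectra, as.data.frame))
  for (col in c("frequency_hz", "z_real_ohm", "z_imag_ohm")) {
    df[[col]] <- sprintf("%.15g", df[[col]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write timecourse CSV files
#'
#' Dialect: `electrode_id,frequency_hz,time_s,z_real_ohm,z_imag_ohm`.
#'
#' @param path File path.
#' @param stimulus_time_s Optional stimulus annotation applied to every
#'   trace on read.
#' @return `read_timecourse_csv`: list of [timecourse_trace()] objects.
#' @export
read_timecourse_csv <- function(path, stimulus_time_s = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("electrode_id", "frequency_hz", "time_s", "z_real_ohm",
            "z_imag_ohm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing columns in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  lapply(split(df, df$electrode_id), function(g) {
    g <- g[order(g$time_s), , drop = FALSE]
    timecourse_trace(g$time_s,
                     z_real_ohm = g$z_real_ohm, z_imag_ohm = g$z_imag_ohm,
                     frequency_hz = g$frequency_hz[1],
                     electrode_id = g$electrode_id[1],
                     stimulus_time_s = stimulus_time_s)
  })
}

#' @rdname read_timecourse_csv
#' @param traces A [timecourse_trace()] or list of them.
#' @export
write_timecourse_csv <- function(traces, path) {
  if (inherits(traces, "timecourse_trace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(electrode_id = tr$electrode_id,
               frequency_hz = tr$frequency_hz,
               time_s = tr$times_s,
               z_real_ohm = Re(tr$z_ohm),
               z_imag_ohm = Im(tr$z_ohm),
               stringsAsFactors = FALSE)
  }))
  for (col in c("time_s", "z_real_ohm", "z_imag_ohm")) {
    df[[col]] <- sprintf("%.15g", df[[col]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit every cell-covered scan of a simulated bundle
#'
#' Runs [fit_monolayer()] against each experiment's reference scan for
#' every electrode and phase, and joins the generating ground truth.
#'
#' @param bundle An `ecis_bundle` from [generate_experiment()].
#' @param options [fit_options()]; the per-electrode fit seed is derived
#'   from `options$seed` deterministically.
#' @return data.frame with fitted and true parameters, rms, convergence
#'   and QC flags per (experiment, electrode, phase).
#' @export
fit_bundle <- function(bundle, options = fit_options()) {
  stopifnot(inherits(bundle, "ecis_bundle"))
  rows <- list()
  idx <- 0
  for (exp in bundle$experiments) {
    for (el in exp$electrodes) {
      for (phase in c("pre", "post")) {
        idx <- idx + 1
        opt <- options
        opt$seed <- child_seed(options$seed, idx)
        fit <- fit_monolayer(el[[phase]], exp$reference,
                             geometry = bundle$geometry, options = opt)
        tr <- bundle$truth
        tr <- tr[tr$electrode_id == el$electrode_id &
                   tr$phase_label == phase, , drop = FALSE]
        rows[[idx]] <- data.frame(
          experiment_id = exp$experiment_id,
          electrode_id = el$electrode_id,
          phase_label = phase,
          alpha = fit$params$alpha, rb = fit$params$rb,
          cm = fit$params$cm,
          alpha_true = tr$alpha, rb_true = tr$rb, cm_true = tr$cm,
          rms = fit$rms_relative_residual,
          converged = fit$converged,
          qc = paste(fit$qc, collapse = "|"),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pipeline run configuration
#'
#' @param scenario_name A [scenario_preset()] name.
#' @param seed Integer master seed (drives simulation and fitting).
#' @param output_dir Output directory, created if needed; `NULL`
#'   disables file output.
#' @param geometry [electrode_geometry()].
#' @param options [fit_options()].
#' @param noise_sd Optional scenario noise override.
#' @return An object of class `run_config`.
#' @export
run_config <- function(scenario_name = "007AM", seed = 1L,
                       output_dir = NULL,
                       geometry = electrode_geometry(),
                       options = fit_options(), noise_sd = NULL) {
  if (options$f_min_hz >= options$f_max_hz) {
    stop("invalid window in options", call. = FALSE)
  }
  structure(list(scenario_name = scenario_name, seed = as.integer(seed),
                 output_dir = output_dir, geometry = geometry,
                 options = options, noise_sd = noise_sd),
            class = "run_config")
}

#' Run the simulate -> fit -> aggregate -> report pipeline
#'
#' Simulates the configured scenario, fits every electrode's pre and
#' post scan against its experiment's reference electrode, averages the
#' fitted constants over electrodes within each experiment, and reports
#' the replicate statistics (one-way ANOVA across pre/post rendered as
#' "A(F;P)", plus a paired two-tailed t-test on per-experiment means)
#' for Rb, alpha and Cm. Given identical configuration the run is
#' bit-identical, and all outputs carry the seed, window and modelling
#' conventions as provenance.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `bundle`, `fits`, `aggregates`,
#'   `stats` and `run_info`; written as CSV/JSON into
#'   `config$output_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  scn_args <- list(name = config$scenario_name, seed = config$seed)
  if (!is.null(config$noise_sd)) scn_args$noise_sd <- config$noise_sd
  scn <- do.call(scenario_preset, scn_args)
  bundle <- generate_experiment(scn, geometry = config$geometry)
  opt <- config$options
  opt$seed <- child_seed(config$seed, 77)
  fits <- fit_bundle(bundle, opt)

  aggregates <- list(); stats_rows <- list()
  for (param in c("rb", "alpha", "cm")) {
    tab <- experiment_table(
      data.frame(experiment_id = fits$experiment_id,
                 condition = fits$phase_label,
                 electrode_id = fits$electrode_id,
                 value = fits[[param]], stringsAsFactors = FALSE),
      value_kind = param)
    agg <- aggregate_electrodes(tab)
    agg$parameter <- param
    aggregates[[param]] <- agg
    pre <- agg$mean_value[agg$condition == "pre"]
    post <- agg$mean_value[agg$condition == "post"]
    an <- anova_oneway(list(pre = pre, post = post))
    tt <- ttest(post, pre, mode = "paired")
    stats_rows[[param]] <- data.frame(
      parameter = param,
      n_experiments = length(pre),
      pre_mean = mean(pre), post_mean = mean(post),
      post_pre_ratio = mean(post) / mean(pre),
      anova = an$label, t = tt$t, p_t = tt$p,
      stringsAsFactors = FALSE)
  }
  aggregates <- do.call(rbind, aggregates)
  rownames(aggregates) <- NULL
  stats_tab <- do.call(rbind, stats_rows)
  rownames(stats_tab) <- NULL

  run_info <- list(
    scenario = config$scenario_name, seed = config$seed,
    window_hz = c(opt$f_min_hz, opt$f_max_hz),
    residual_weighting = opt$weighting,
    membrane_convention =
      "Cm is one membrane; two identical membranes in series",
    electrode_area_cm2 = config$geometry$area_cm2,
    package_version = as.character(utils::packageVersion("ecisbarrier")))

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(fits, file.path(config$output_dir, "fits.csv"),
                     row.names = FALSE)
    utils::write.csv(aggregates,
                     file.path(config$output_dir, "aggregates.csv"),
                     row.names = FALSE)
    utils::write.csv(stats_tab, file.path(config$output_dir, "stats.csv"),
                     row.names = FALSE)
    jsonlite::write_json(run_info,
                         file.path(config$output_dir, "run_info.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(bundle = bundle, fits = fits, aggregates = aggregates,
                 stats = stats_tab, run_info = run_info))
}
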