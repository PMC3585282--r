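#' Single-frequency impedance timecourse
#'
#' Complex impedance of one electrode recorded over time at a fixed
#' monitoring frequency (4000 Hz by default, the standard monolayer
#' monitoring frequency), optionally annotated with a stimulus time.
#' Gaps in sampling are permitted; times must be strictly increasing.
#'
#' @param times_s Strictly increasing sampling times, s.
#' @param z_ohm Complex impedance, Ohm, aligned with `times_s`;
#'   alternatively `z_real_ohm`/`z_imag_ohm`.
#' @param z_real_ohm,z_imag_ohm Real/imaginary parts if `z_ohm` is
#'   missing.
#' @param frequency_hz Monitoring frequency, Hz (> 0).
#' @param electrode_id Identifier.
#' @param stimulus_time_s Optional stimulus annotation, s.
#' @return An object of class `timecourse_trace`.
#' @export
timecourse_trace <- function(times_s, z_ohm = NULL, z_real_ohm = NULL,
                             z_imag_ohm = NULL, frequency_hz = 4000,
                             electrode_id = "E1",
                             stimulus_time_s = NULL) {
  if (is.null(z_ohm)) {
    if (is.null(z_real_ohm) || is.null(z_imag_ohm)) {
      stop("provide 'z_ohm' or both 'z_real_ohm' and 'z_imag_ohm'",
           call. = FALSE)
    }
    z_ohm <- complex(real = z_real_ohm, imaginary = z_imag_ohm)
  }
  times_s <- as.numeric(times_s)
  z_ohm <- as.complex(z_ohm)
  if (length(times_s) != length(z_ohm)) {
    stop("times and impedance must have equal length", call. = FALSE)
  }
  if (any(diff(times_s) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (!is.finite(frequency_hz) || frequency_hz <= 0) {
    stop("'frequency_hz' must be > 0", call. = FALSE)
  }
  structure(list(electrode_id = as.character(electrode_id),
                 frequency_hz = frequency_hz,
                 times_s = times_s, z_ohm = z_ohm,
                 stimulus_time_s = stimulus_time_s),
            class = "timecourse_trace")
}

#' @export
print.timecourse_trace <- function(x, ...) {
  cat(sprintf("Timecourse '%s' at %g Hz: %d samples, t = %g..%g s%s\n",
              x$electrode_id, x$frequency_hz, length(x$times_s),
              min(x$times_s), max(x$times_s),
              if (!is.null(x$stimulus_time_s))
                sprintf(", stimulus at %g s", x$stimulus_time_s) else ""))
  invisible(x)
}

#' Impedance magnitude over time
#'
#' @param trace A [timecourse_trace()].
#' @return data.frame with `time_s` and `z_mod_ohm` = |Z|.
#' @export
magnitude_trace <- function(trace) {
  stopifnot(inherits(trace, "timecourse_trace"))
  data.frame(time_s = trace$times_s, z_mod_ohm = Mod(trace$z_ohm))
}

#' Series-RC readout over time
#'
#' Applies [series_rc_equivalent()] pointwise: the legacy macroscopic
#' interpretation of each sample as one resistor and capacitor in
#' series.
#'
#' @param trace A [timecourse_trace()].
#' @return data.frame with `time_s`, `r_ohm`, `c_farad`.
#' @export
rc_trace <- function(trace) {
  stopifnot(inherits(trace, "timecourse_trace"))
  rc <- series_rc_equivalent(trace$z_ohm, trace$frequency_hz)
  cbind(data.frame(time_s = trace$times_s), rc)
}

#' Pre/post-stimulus summary of a timecourse
#'
#' Means of |Z| over a window before and a window after the stimulus,
#' plus their post/pre ratio. Default windows: the 30 samples ending at
#' the stimulus, and an equally long stretch starting after a settling
#' lag of 600 s (the transient immediately after compound addition is
#' excluded).
#'
#' @param trace A [timecourse_trace()] with `stimulus_time_s` set (or
#'   explicit windows given).
#' @param pre_window_s,post_window_s Optional `c(start, end)` windows
#'   in s (inclusive); samples with `start <= t <= end` are used.
#' @param settling_s Settling lag for the default post window, s.
#' @param n_samples Default window length in samples (30).
#' @return List with `pre_mean`, `post_mean`, `ratio` and the windows
#'   used.
#' @export
pre_post_summary <- function(trace, pre_window_s = NULL,
                             post_window_s = NULL, settling_s = 600,
                             n_samples = 30) {
  stopifnot(inherits(trace, "timecourse_trace"))
  t <- trace$times_s
  if (is.null(pre_window_s) || is.null(post_window_s)) {
    if (is.null(trace$stimulus_time_s)) {
      stop("default windows require 'stimulus_time_s'", call. = FALSE)
    }
    t0 <- trace$stimulus_time_s
    if (is.null(pre_window_s)) {
      before <- t[t <= t0]
      if (length(before) == 0) stop("no samples before the stimulus",
                                    call. = FALSE)
      k <- utils::tail(before, n_samples)
      pre_window_s <- c(min(k), max(k))
    }
    if (is.null(post_window_s)) {
      after <- t[t >= t0 + settling_s]
      if (length(after) == 0) stop("no samples after the settling lag",
                                   call. = FALSE)
      k <- utils::head(after, n_samples)
      post_window_s <- c(min(k), max(k))
    }
  }
  if (pre_window_s[2] > post_window_s[1]) {
    stop("pre and post windows must not overlap", call. = FALSE)
  }
  zmod <- Mod(trace$z_ohm)
  in_pre <- t >= pre_window_s[1] & t <= pre_window_s[2]
  in_post <- t >= post_window_s[1] & t <= post_window_s[2]
  if (!any(in_pre)) stop("pre window contains no samples", call. = FALSE)
  if (!any(in_post)) stop("post window contains no samples", call. = FALSE)
  pre_mean <- mean(zmod[in_pre])
  post_mean <- mean(zmod[in_post])
  list(pre_mean = pre_mean, post_mean = post_mean,
       ratio = post_mean / pre_mean,
       pre_window_s = pre_window_s, post_window_s = post_window_s,
       n_pre = sum(in_pre), n_post = sum(in_post))
}

#' Subset a timecourse in time
#'
#' @param trace A [timecourse_trace()].
#' @param from_s,to_s Inclusive time bounds, s.
#' @return The restricted [timecourse_trace()].
#' @export
subset_trace <- function(trace, from_s = -Inf, to_s = Inf) {
  stopifnot(inherits(trace, "timecourse_trace"))
  keep <- trace$times_s >= from_s & trace$times_s <= to_s
  if (!any(keep)) stop("no samples inside the requested range",
                       call. = FALSE)
  trace$times_s <- trace$times_s[keep]
  trace$z_ohm <- trace$z_ohm[keep]
  trace
}
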