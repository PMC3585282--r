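#' Constant-phase-element model of a cell-free electrode
#'
#' Stand-in for a measured gold-film reference electrode. The physical
#' (artifact-free) interface is a solution resistance in series with a
#' constant-phase element, Z_phys(f) = R_sol + 1/(Q (j 2 pi f)^beta).
#' The recording chain additionally contributes a high-frequency
#' inductive artifact: each electrode's lead adds
#' Z_lead(f) = j 2 pi f L / (1 + (f_gate/f)^8) to every *recorded*
#' spectrum. This is an empirical artifact shape, not a circuit model:
#' it reproduces the structure seen in measured scans -- clean spectra
#' up to the 16 kHz analysis ceiling, then a steeply growing inductive
#' component that flips Im(Z) positive inside the acquisition grid and
#' makes the high-frequency points unusable for model fitting. Lead
#' traces differ between the wells of an array, so generators accept a
#' per-electrode `lead_scale`. Default values are plausible for small
#' gold-film electrodes; they are package inventions, not measured
#' constants.
#'
#' @param cpe_q CPE magnitude Q in s^beta / (Ohm cm^2).
#' @param cpe_beta CPE exponent in (0, 1]; 1 is an ideal capacitor.
#' @param r_sol Solution (spreading) resistance, Ohm cm^2.
#' @param inductance Lead series inductance, H cm^2 (0 disables the
#'   artifact).
#' @param gate_hz Onset frequency of the artifact, Hz: the inductive
#   term is suppressed as (f/f_gate)^8 below it.
#' @return An object of class `electrode_model`.
#' @export
electrode_model <- function(cpe_q = 2e-5, cpe_beta = 0.95,
                            r_sol = 1.5, inductance = 6e-6,
                            gate_hz = 2.4e4) {
  if (cpe_beta <= 0 || cpe_beta > 1) stop("'cpe_beta' must be in (0, 1]",
                                          call. = FALSE)
  if (cpe_q <= 0 || r_sol < 0 || inductance < 0 || gate_hz <= 0) {
    stop("'cpe_q' must be > 0, 'gate_hz' > 0; 'r_sol' and 'inductance' >= 0",
         call. = FALSE)
  }
  structure(list(cpe_q = cpe_q, cpe_beta = cpe_beta, r_sol = r_sol,
                 inductance = inductance, gate_hz = gate_hz),
            class = "electrode_model")
}

# High-frequency inductive lead artifact on recorded spectra
# (specific units).
lead_artifact <- function(model, frequency_hz, lead_scale = 1) {
  if (model$inductance == 0 || lead_scale == 0) {
    return(rep(0 + 0i, length(frequency_hz)))
  }
  gate <- 1 / (1 + (model$gate_hz / frequency_hz)^8)
  1i * 2 * pi * frequency_hz * model$inductance * lead_scale * gate
}

#' Noise-free electrode-model impedance
#'
#' Specific impedance of the [electrode_model()] at the given
#' frequencies. `include_lead = FALSE` returns the artifact-free
#' interface impedance that the monolayer physics acts on;
#' `TRUE` (default) returns what the instrument records.
#'
#' @param model An [electrode_model()].
#' @param frequency_hz Frequencies in Hz.
#' @param include_lead Include the resonant lead artifact?
#' @param lead_scale Per-electrode multiplier on the lead inductance.
#' @return Complex specific impedance, Ohm cm^2.
#' @export
electrode_model_z <- function(model, frequency_hz,
                              include_lead = TRUE, lead_scale = 1) {
  stopifnot(inherits(model, "electrode_model"))
  w <- 2 * pi * frequency_hz
  z <- model$r_sol + 1 / (model$cpe_q * (1i * w)^model$cpe_beta)
  if (include_lead) z <- z + lead_artifact(model, frequency_hz, lead_scale)
  z
}

#' Default acquisition frequency grid
#'
#' Doubling series 31.25 Hz to 64 kHz (12 frequencies), so the default
#' analysis window 62.5--16000 Hz has out-of-window points on both
#' sides.
#'
#' @return Numeric vector of frequencies in Hz.
#' @export
default_frequency_grid <- function() 31.25 * 2^(0:11)

# Multiplicative complex Gaussian noise: the relative complex
# perturbation has rms magnitude noise_sd (each quadrature gets
# sd noise_sd/sqrt(2)).
apply_complex_noise <- function(z, noise_sd, seed) {
  if (noise_sd == 0) return(z)
  sd_q <- noise_sd / sqrt(2)
  with_seed(seed, {
    n <- length(z)
    z * (1 + complex(real = stats::rnorm(n, sd = sd_q),
                     imaginary = stats::rnorm(n, sd = sd_q)))
  })
}

#' Simulate a recorded cell-free reference scan
#'
#' @param model An [electrode_model()].
#' @param frequencies_hz Acquisition frequencies (default
#'   [default_frequency_grid()]).
#' @param geometry [electrode_geometry()] used to convert the specific
#'   model impedance to recorded whole-electrode Ohm.
#' @param noise_sd Relative (multiplicative complex Gaussian) noise sd.
#' @param seed Integer seed; identical seeds give identical scans.
#' @param lead_scale Per-electrode multiplier on the lead inductance.
#' @param electrode_id,phase_label Spectrum tags.
#' @return A [complex_spectrum()] with role `"reference"`.
#' @export
generate_reference <- function(model = electrode_model(),
                               frequencies_hz = default_frequency_grid(),
                               geometry = electrode_geometry(),
                               noise_sd = 0.01, seed = 1L,
                               lead_scale = 1,
                               electrode_id = "REF", phase_label = "pre") {
  z_spec <- electrode_model_z(model, frequencies_hz,
                              lead_scale = lead_scale)
  z_spec <- apply_complex_noise(z_spec, noise_sd, seed)
  complex_spectrum(frequencies_hz, from_specific(z_spec, geometry),
                   electrode_id = electrode_id, role = "reference",
                   phase_label = phase_label)
}

#' Simulate a recorded cell-covered scan
#'
#' The monolayer model acts on the artifact-free interface impedance of
#' the noise-free electrode model; the recording chain then adds the
#' electrode's resonant lead artifact, and multiplicative complex noise
#' is drawn independently of any reference realisation.
#'
#' @inheritParams generate_reference
#' @param params [monolayer_params()] generating the scan.
#' @return A [complex_spectrum()] with role `"cell_covered"`.
#' @export
generate_cell_scan <- function(model = electrode_model(),
                               params = monolayer_params(6, 4, 1.8),
                               frequencies_hz = default_frequency_grid(),
                               geometry = electrode_geometry(),
                               noise_sd = 0.01, seed = 1L,
                               lead_scale = 1,
                               electrode_id = "E1", phase_label = "pre") {
  zn_phys <- electrode_model_z(model, frequencies_hz,
                               include_lead = FALSE)
  zc <- cell_covered_impedance(frequencies_hz, zn_phys, params)
  zc <- zc + lead_artifact(model, frequencies_hz, lead_scale)
  zc <- apply_complex_noise(zc, noise_sd, seed)
  complex_spectrum(frequencies_hz, from_specific(zc, geometry),
                   electrode_id = electrode_id, role = "cell_covered",
                   phase_label = phase_label)
}

#' Experimental scenario
#'
#' Describes one simulated condition: baseline monolayer parameters,
#' the multiplicative effect of the condition (applied between the
#' "pre" and "post" phase of every electrode), the replicate structure
#' (electrodes nested in independent experiments) and the noise model.
#' `alpha` may alternatively be derived from a microscopic triple
#' (cell radius r_c in um, medium resistivity rho in Ohm cm,
#' cell-substrate separation h in nm) as alpha = r_c sqrt(rho / h).
#'
#' @param name Scenario label.
#' @param baseline [monolayer_params()] of the unperturbed monolayer.
#' @param rb_factor,alpha_factor,cm_factor Multipliers applied in the
#'   "post" phase (>= 0).
#' @param noise_sd Relative spectral noise sd (default 0.01).
#' @param n_electrodes Electrodes per experiment (default 4).
#' @param n_experiments Independent experiments (default 4).
#' @param cv_experiment,cv_electrode Lognormal coefficients of
#'   variation of the biological parameter spread between experiments
#'   (default 0.15) and between electrodes within an experiment (0.05).
#' @param seed Integer seed.
#' @param microscopic Optional `list(r_c_um=, rho_ohm_cm=, h_nm=)`
#'   overriding `baseline$alpha`.
#' @return An object of class `scenario`.
#' @export
scenario <- function(name = "control",
                     baseline = monolayer_params(6, 4, 1.8),
                     rb_factor = 1, alpha_factor = 1, cm_factor = 1,
                     noise_sd = 0.01, n_electrodes = 4,
                     n_experiments = 4, cv_experiment = 0.15,
                     cv_electrode = 0.05, seed = 1L,
                     microscopic = NULL) {
  stopifnot(inherits(baseline, "monolayer_params"))
  if (any(c(rb_factor, alpha_factor, cm_factor) < 0)) {
    stop("effect factors must be >= 0", call. = FALSE)
  }
  if (n_electrodes < 1 || n_experiments < 1) {
    stop("need at least one electrode and one experiment", call. = FALSE)
  }
  if (!is.null(microscopic)) {
    need <- c("r_c_um", "rho_ohm_cm", "h_nm")
    if (!all(need %in% names(microscopic))) {
      stop("'microscopic' needs r_c_um, rho_ohm_cm and h_nm", call. = FALSE)
    }
    r_c_cm <- microscopic$r_c_um * 1e-4
    h_cm <- microscopic$h_nm * 1e-7
    baseline$alpha <- r_c_cm * sqrt(microscopic$rho_ohm_cm / h_cm)
  }
  structure(list(name = name, baseline = baseline,
                 rb_factor = rb_factor, alpha_factor = alpha_factor,
                 cm_factor = cm_factor, noise_sd = noise_sd,
                 n_electrodes = as.integer(n_electrodes),
                 n_experiments = as.integer(n_experiments),
                 cv_experiment = cv_experiment,
                 cv_electrode = cv_electrode,
                 seed = as.integer(seed),
                 microscopic = microscopic),
            class = "scenario")
}

#' Scenario presets mirroring the studied conditions
#'
#' Effect directions and replicate counts follow the study designs the
#' generator emulates: Epac activation by 007-AM raises the barrier
#' resistance about 1.5-fold (8 experiments); Rap2 depletion doubles it
#' (6 experiments); Rap1 depletion lowers it (8); combined Rap1+Rap2
#' depletion leaves it at control level (4); VE-/P-cadherin depletion
#' collapses Rb to near zero while alpha is preserved and Cm is reduced
#' and unstable (4). Absolute baseline values are invented plausible
#' numbers, shared by all presets.
#'
#' @param name One of `"control"`, `"007AM"`, `"siRap1"`, `"siRap2"`,
#'   `"siRap1+siRap2"`, `"siCadherin"`.
#' @param ... Overrides passed to [scenario()].
#' @return A [scenario()].
#' @export
scenario_preset <- function(name = c("control", "007AM", "siRap1",
                                     "siRap2", "siRap1+siRap2",
                                     "siCadherin"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    "control"       = list(rb_factor = 1, n_experiments = 4),
    "007AM"         = list(rb_factor = 1.5, n_experiments = 8),
    "siRap1"        = list(rb_factor = 0.6, n_experiments = 8),
    "siRap2"        = list(rb_factor = 2, n_experiments = 6),
    "siRap1+siRap2" = list(rb_factor = 1, n_experiments = 4),
    "siCadherin"    = list(rb_factor = 0.005, alpha_factor = 1,
                           cm_factor = 0.4, n_experiments = 4))
  args$name <- name
  user <- list(...)
  args[names(user)] <- user
  do.call(scenario, args)
}

# Lognormal multiplier with unit mean and coefficient of variation cv.
lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a full multi-experiment scan bundle
#'
#' Draws per-experiment and per-electrode lognormal variation around the
#' scenario baseline, simulates a recorded reference scan per experiment
#' and pre/post cell-covered scans per electrode (the scenario's effect
#' factors applied in the post phase to the same electrode draw, i.e.
#' pre and post are paired), and emits the generating parameters as a
#' ground-truth table.
#'
#' @param scn A [scenario()].
#' @param geometry [electrode_geometry()].
#' @param model [electrode_model()].
#' @param frequencies_hz Acquisition grid.
#' @param cv_lead Lognormal coefficient of variation of the lead
#'   inductance between electrodes (wells have individual lead traces;
#'   default 0.1).
#' @return An object of class `ecis_bundle`: `experiments` (each with a
#'   `reference` spectrum and per-electrode `pre`/`post` spectra) and
#'   `truth` (data.frame of generating parameters per scan).
#' @export
generate_experiment <- function(scn, geometry = electrode_geometry(),
                                model = electrode_model(),
                                frequencies_hz = default_frequency_grid(),
                                cv_lead = 0.1) {
  stopifnot(inherits(scn, "scenario"))
  b <- scn$baseline
  mult <- c(scn$alpha_factor, scn$rb_factor, scn$cm_factor)
  experiments <- vector("list", scn$n_experiments)
  truth <- list()
  for (e in seq_len(scn$n_experiments)) {
    exp_id <- sprintf("exp%02d", e)
    exp_fac <- with_seed(child_seed(scn$seed, e * 1000),
                         lognormal_factor(3, scn$cv_experiment))
    leads <- with_seed(child_seed(scn$seed, e * 1000 + 2),
                       lognormal_factor(scn$n_electrodes + 1, cv_lead))
    ref <- generate_reference(model, frequencies_hz, geometry,
                              noise_sd = scn$noise_sd,
                              seed = child_seed(scn$seed, e * 1000 + 1),
                              lead_scale = leads[1],
                              electrode_id = paste0(exp_id, "_REF"))
    electrodes <- vector("list", scn$n_electrodes)
    for (i in seq_len(scn$n_electrodes)) {
      el_id <- sprintf("%s_E%d", exp_id, i)
      el_fac <- with_seed(child_seed(scn$seed, e * 1000 + 10 + i),
                          lognormal_factor(3, scn$cv_electrode))
      p_pre_v <- c(b$alpha, b$rb, b$cm) * exp_fac * el_fac
      p_post_v <- p_pre_v * mult
      p_pre <- monolayer_params(p_pre_v[1], p_pre_v[2], max(p_pre_v[3], 1e-6))
      p_post <- monolayer_params(p_post_v[1], p_post_v[2],
                                 max(p_post_v[3], 1e-6))
      pre <- generate_cell_scan(model, p_pre, frequencies_hz, geometry,
                                noise_sd = scn$noise_sd,
                                seed = child_seed(scn$seed,
                                                  e * 1000 + 100 + 2 * i),
                                lead_scale = leads[i + 1],
                                electrode_id = el_id, phase_label = "pre")
      post <- generate_cell_scan(model, p_post, frequencies_hz, geometry,
                                 noise_sd = scn$noise_sd,
                                 seed = child_seed(scn$seed,
                                                   e * 1000 + 101 + 2 * i),
                                 lead_scale = leads[i + 1],
                                 electrode_id = el_id, phase_label = "post")
      electrodes[[i]] <- list(electrode_id = el_id, pre = pre, post = post)
      truth[[length(truth) + 1]] <- data.frame(
        experiment_id = exp_id, electrode_id = el_id,
        phase_label = c("pre", "post"),
        alpha = c(p_pre$alpha, p_post$alpha),
        rb = c(p_pre$rb, p_post$rb),
        cm = c(p_pre$cm, p_post$cm),
        stringsAsFactors = FALSE)
    }
    experiments[[e]] <- list(experiment_id = exp_id, reference = ref,
                             electrodes = electrodes)
  }
  structure(list(scenario = scn, geometry = geometry, model = model,
                 frequencies_hz = frequencies_hz,
                 experiments = experiments,
                 truth = do.call(rbind, truth)),
            class = "ecis_bundle")
}

#' @export
print.ecis_bundle <- function(x, ...) {
  cat(sprintf("ECIS bundle '%s': %d experiments x %d electrodes, noise %.3g\n",
              x$scenario$name, x$scenario$n_experiments,
              x$scenario$n_electrodes, x$scenario$noise_sd))
  invisible(x)
}

#' Simulate a single-frequency impedance timecourse
#'
#' Monolayer parameters transition smoothly (logistic in time, time
#' constant `tau_s`) from the scenario baseline to baseline x effect
#' factors after the stimulus; the recorded complex impedance at
#' `frequency_hz` is computed from the noise-free electrode model plus
#' the inductive recording artifact, then noised.
#'
#' @param scn A [scenario()]; one trace per electrode is produced.
#' @param geometry [electrode_geometry()].
#' @param model [electrode_model()].
#' @param frequency_hz Monitoring frequency (default 4000 Hz).
#' @param times_s Sampling times, strictly increasing (default every
#'   60 s from -3600 s to 7200 s).
#' @param stimulus_time_s Stimulus time (default 0).
#' @param tau_s Logistic transition time constant (default 900 s).
#' @return List of [timecourse_trace()] objects, one per electrode.
#' @export
generate_timecourse <- function(scn, geometry = electrode_geometry(),
                                model = electrode_model(),
                                frequency_hz = 4000,
                                times_s = seq(-3600, 7200, by = 60),
                                stimulus_time_s = 0, tau_s = 900) {
  stopifnot(inherits(scn, "scenario"))
  b <- scn$baseline
  mult <- c(scn$alpha_factor, scn$rb_factor, scn$cm_factor)
  zn_phys <- electrode_model_z(model, frequency_hz, include_lead = FALSE)
  z_l <- lead_artifact(model, frequency_hz)
  sig <- stats::plogis((times_s - stimulus_time_s) / tau_s)
  sig[times_s <= stimulus_time_s] <- 0   # effect starts at the stimulus
  traces <- vector("list", scn$n_electrodes)
  for (i in seq_len(scn$n_electrodes)) {
    el_fac <- with_seed(child_seed(scn$seed, 5000 + i),
                        lognormal_factor(3, scn$cv_electrode))
    p0 <- c(b$alpha, b$rb, b$cm) * el_fac
    z <- vapply(seq_along(times_s), function(k) {
      fac <- 1 + (mult - 1) * sig[k]
      pk <- p0 * fac
      cell_covered_impedance(
        frequency_hz, zn_phys,
        monolayer_params(pk[1], pk[2], max(pk[3], 1e-6))) + z_l
    }, complex(1))
    z <- apply_complex_noise(z, scn$noise_sd,
                             child_seed(scn$seed, 6000 + i))
    traces[[i]] <- timecourse_trace(
      times_s = times_s, z_ohm = from_specific(z, geometry),
      frequency_hz = frequency_hz,
      electrode_id = sprintf("TC_E%d", i),
      stimulus_time_s = stimulus_time_s)
  }
  traces
}

#' Simulate a qPCR Ct table with known knockdowns
#'
#' Target-gene Ct values rise by -log2(fraction) cycles under a
#' knockdown to the given fraction of control expression; the reference
#' gene is unshifted. An untreated reference sample (all fractions 1)
#' is always included so delta-delta-Ct can be formed.
#'
#' @param knockdown_fractions Named numeric vector in (0, 1], remaining
#'   expression fraction per target gene.
#' @param n_replicates Knockdown replicate samples (default 3).
#' @param ct_sd Gaussian Ct noise sd in cycles (default 0.15).
#' @param baseline_ct Baseline Ct of each target gene (default 24).
#' @param reference_gene Housekeeping gene name (default "HPRT").
#' @param reference_ct Baseline Ct of the reference gene (default 20).
#' @param seed Integer seed.
#' @return A [ct_table()] whose reference sample is `"reference"`.
#' @export
generate_ct_table <- function(knockdown_fractions, n_replicates = 3,
                              ct_sd = 0.15, baseline_ct = 24,
                              reference_gene = "HPRT",
                              reference_ct = 20, seed = 1L) {
  if (is.null(names(knockdown_fractions)) ||
      any(!nzchar(names(knockdown_fractions)))) {
    stop("'knockdown_fractions' must be a named vector", call. = FALSE)
  }
  if (any(knockdown_fractions <= 0) || any(knockdown_fractions > 1)) {
    stop("knockdown fractions must lie in (0, 1]", call. = FALSE)
  }
  genes <- names(knockdown_fractions)
  baseline_ct <- rep_len(baseline_ct, length(genes))
  samples <- c("reference", sprintf("kd_%d", seq_len(n_replicates)))
  rows <- with_seed(seed, {
    out <- list()
    for (s in samples) {
      shift <- if (s == "reference") rep(0, length(genes)) else
        -log2(knockdown_fractions)
      for (gi in seq_along(genes)) {
        out[[length(out) + 1]] <- data.frame(
          sample_id = s, gene = genes[gi],
          ct_cycles = baseline_ct[gi] + shift[gi] +
            stats::rnorm(1, sd = ct_sd),
          stringsAsFactors = FALSE)
      }
      out[[length(out) + 1]] <- data.frame(
        sample_id = s, gene = reference_gene,
        ct_cycles = reference_ct + stats::rnorm(1, sd = ct_sd),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  ct_table(rows, reference_gene = reference_gene,
           reference_sample_id = "reference")
}

#' Simulate a two-channel junction/cytoskeleton image pair
#'
#' Renders a Voronoi mosaic of `n_cells` cells: channel A is the
#' junction marker (a smooth ridge along cell boundaries, where the
#' distances to the two nearest cell centres coincide); channel B is
#' F-actin, a weighted mixture of the same junctional component
#' (weight `w`, the "junctionality") and transverse stress fibres
#' (per-cell sinusoidal line patterns at random orientation, weight
#' `1 - w`). Both channels are Gaussian-blurred and carry additive
#' Gaussian noise. The generating junction mask is attached as
#' attribute `"truth_mask"`.
#'
#' @param w Junctionality in \[0, 1\]: 1 = all actin junctional,
#'   0 = all actin in transverse fibres.
#' @param dims Image dimensions, >= 128 x 128 (default 256 x 256).
#' @param n_cells Number of cells, >= 9 (default 25).
#' @param noise_sd Additive intensity noise sd (default 0.05; intensity
#'   scale is \[0, 1\]).
#' @param blur_sigma Gaussian blur sd in pixels (default 1).
#' @param seed Integer seed.
#' @return An [image_pair()] with attribute `"truth_mask"`.
#' @export
generate_images <- function(w, dims = c(256, 256), n_cells = 25,
                            noise_sd = 0.05, blur_sigma = 1, seed = 1L) {
  if (w < 0 || w > 1) stop("'w' must lie in [0, 1]", call. = FALSE)
  if (any(dims < 128)) stop("'dims' must be at least 128 x 128",
                            call. = FALSE)
  if (n_cells < 9) stop("'n_cells' must be >= 9", call. = FALSE)
  nx <- dims[1]; ny <- dims[2]
  with_seed(seed, {
    cx <- stats::runif(n_cells, 1, nx)
    cy <- stats::runif(n_cells, 1, ny)
    theta <- stats::runif(n_cells, 0, pi)
    phase <- stats::runif(n_cells, 0, 2 * pi)
    px <- matrix(rep(seq_len(nx), ny), nrow = nx)
    py <- matrix(rep(seq_len(ny), each = nx), nrow = nx)
    d1 <- matrix(Inf, nx, ny); d2 <- matrix(Inf, nx, ny)
    owner <- matrix(1L, nx, ny)
    for (k in seq_len(n_cells)) {
      d <- sqrt((px - cx[k])^2 + (py - cy[k])^2)
      closer <- d < d1
      d2 <- ifelse(closer, d1, pmin(d2, d))
      owner[closer] <- k
      d1 <- ifelse(closer, d, d1)
    }
    junction <- exp(-0.5 * ((d2 - d1) / 1.5)^2)   # ridge on boundaries
    period <- 8                                    # fibre spacing, px
    fibres <- matrix(0, nx, ny)
    for (k in seq_len(n_cells)) {
      sel <- owner == k
      u <- px[sel] * cos(theta[k]) + py[sel] * sin(theta[k])
      fibres[sel] <- 0.5 * (1 + cos(2 * pi * u / period + phase[k]))
    }
    channel_a <- junction
    channel_b <- w * junction + (1 - w) * fibres
    if (blur_sigma > 0) {
      channel_a <- EBImage::imageData(
        EBImage::gblur(EBImage::Image(channel_a), sigma = blur_sigma))
      channel_b <- EBImage::imageData(
        EBImage::gblur(EBImage::Image(channel_b), sigma = blur_sigma))
    }
    # ground truth: junction territory of the ideal (blurred, noise-free)
    # junction channel, at 30% of its unit peak intensity
    truth <- channel_a > 0.3
    if (noise_sd > 0) {
      channel_a <- channel_a + matrix(stats::rnorm(nx * ny, sd = noise_sd),
                                      nx, ny)
      channel_b <- channel_b + matrix(stats::rnorm(nx * ny, sd = noise_sd),
                                      nx, ny)
    }
    pair <- image_pair(pmax(channel_a, 0), pmax(channel_b, 0))
    attr(pair, "truth_mask") <- truth
    pair
  })
}
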