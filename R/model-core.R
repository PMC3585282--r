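#' Monolayer barrier parameters
#'
#' The three microscopic constants of the Lo--Ferrier--Giaever model of a
#' cell-covered electrode: the cell-substrate constriction parameter
#' `alpha` (Ohm^0.5 cm, set by cell radius, medium resistivity and
#' cell-substrate separation), the junctional barrier resistance `rb`
#' (Ohm cm^2, the resistance opposed to paracellular ion flow) and the
#' membrane capacitance `cm` (uF/cm^2, per single membrane; apical and
#' basal membranes act in series).
#'
#' @param alpha Constriction parameter, Ohm^0.5 cm. Non-negative.
#' @param rb Barrier resistance, Ohm cm^2. Non-negative.
#' @param cm Membrane capacitance, uF/cm^2. Strictly positive.
#' @return An object of class `monolayer_params`.
#' @examples
#' monolayer_params(alpha = 6, rb = 4, cm = 1.8)
#' @export
monolayer_params <- function(alpha, rb, cm) {
  vals <- c(alpha = alpha, rb = rb, cm = cm)
  if (!all(is.finite(vals))) {
    stop("monolayer parameters must be finite", call. = FALSE)
  }
  if (alpha < 0) stop("'alpha' must be >= 0", call. = FALSE)
  if (rb < 0) stop("'rb' must be >= 0", call. = FALSE)
  if (cm <= 0) stop("'cm' must be > 0", call. = FALSE)
  structure(list(alpha = alpha, rb = rb, cm = cm),
            class = "monolayer_params")
}

#' @export
print.monolayer_params <- function(x, ...) {
  cat(sprintf(
    "Monolayer parameters: alpha = %.4g Ohm^0.5 cm, Rb = %.4g Ohm cm^2, Cm = %.4g uF/cm^2\n",
    x$alpha, x$rb, x$cm))
  invisible(x)
}

#' Electrode geometry
#'
#' Working-electrode area used to convert between whole-electrode
#' impedance (Ohm, what the instrument records) and specific impedance
#' (Ohm cm^2, what the monolayer model is written in). The default is
#' the "8W10E" layout: ten circular 250-um electrodes per well,
#' 10 * pi * (0.0125 cm)^2 = 4.91e-3 cm^2 in total. The area is a
#' configurable modelling choice, not an instrument-supplied constant.
#'
#' @param area_cm2 Total working-electrode area in cm^2 (> 0).
#' @param label Free-text electrode layout label.
#' @return An object of class `electrode_geometry`.
#' @export
electrode_geometry <- function(area_cm2 = 10 * pi * 0.0125^2,
                               label = "8W10E") {
  if (!is.numeric(area_cm2) || length(area_cm2) != 1 ||
      !is.finite(area_cm2) || area_cm2 <= 0) {
    stop("'area_cm2' must be a single positive number", call. = FALSE)
  }
  structure(list(area_cm2 = area_cm2, label = as.character(label)),
            class = "electrode_geometry")
}

#' Frequency scan of one electrode
#'
#' Container for a complex impedance spectrum: strictly increasing
#' frequencies with aligned real and imaginary whole-electrode impedance
#' in Ohm, tagged by electrode, role (cell-covered or cell-free
#' reference) and measurement phase (e.g. "pre" / "post" stimulation).
#' The sign convention is e^{+j omega t}: capacitive impedance carries a
#' negative imaginary part.
#'
#' @param frequencies_hz Strictly increasing positive frequencies (>= 3).
#' @param z_ohm Complex impedance in Ohm, same length; alternatively pass
#'   `z_real_ohm` and `z_imag_ohm`.
#' @param z_real_ohm,z_imag_ohm Real/imaginary parts, used when `z_ohm`
#'   is missing.
#' @param electrode_id Identifier of the electrode.
#' @param role `"cell_covered"` or `"reference"`.
#' @param phase_label Free-text phase tag (default `"pre"`).
#' @return An object of class `complex_spectrum`.
#' @export
complex_spectrum <- function(frequencies_hz, z_ohm = NULL,
                             z_real_ohm = NULL, z_imag_ohm = NULL,
                             electrode_id = "E1",
                             role = c("cell_covered", "reference"),
                             phase_label = "pre") {
  role <- match.arg(role)
  if (is.null(z_ohm)) {
    if (is.null(z_real_ohm) || is.null(z_imag_ohm)) {
      stop("provide 'z_ohm' or both 'z_real_ohm' and 'z_imag_ohm'",
           call. = FALSE)
    }
    z_ohm <- complex(real = z_real_ohm, imaginary = z_imag_ohm)
  }
  frequencies_hz <- as.numeric(frequencies_hz)
  z_ohm <- as.complex(z_ohm)
  n <- length(frequencies_hz)
  if (n < 3) stop("a spectrum needs at least 3 frequencies", call. = FALSE)
  if (length(z_ohm) != n) {
    stop("impedance and frequency vectors must have equal length",
         call. = FALSE)
  }
  if (any(!is.finite(frequencies_hz)) || any(frequencies_hz <= 0)) {
    stop("frequencies must be finite and > 0", call. = FALSE)
  }
  if (any(diff(frequencies_hz) <= 0)) {
    stop("frequencies must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(z_ohm))) stop("impedance must be finite", call. = FALSE)
  structure(list(electrode_id = as.character(electrode_id),
                 role = role,
                 phase_label = as.character(phase_label),
                 frequencies_hz = frequencies_hz,
                 z_ohm = z_ohm),
            class = "complex_spectrum")
}

#' @export
print.complex_spectrum <- function(x, ...) {
  cat(sprintf("Complex spectrum '%s' (%s, %s): %d frequencies, %.4g-%.4g Hz\n",
              x$electrode_id, x$role, x$phase_label,
              length(x$frequencies_hz),
              min(x$frequencies_hz), max(x$frequencies_hz)))
  invisible(x)
}

#' @export
as.data.frame.complex_spectrum <- function(x, ...) {
  data.frame(electrode_id = x$electrode_id,
             role = x$role,
             phase_label = x$phase_label,
             frequency_hz = x$frequencies_hz,
             z_real_ohm = Re(x$z_ohm),
             z_imag_ohm = Im(x$z_ohm),
             stringsAsFactors = FALSE)
}

#' Specific impedance of the cell membranes
#'
#' Apical and basal membranes of capacitance `cm` each, in series:
#' Z_m(f) = 2 / (j 2 pi f C_m) = 1 / (j pi f C_m), purely capacitive
#' (negative imaginary part under the e^{+j omega t} convention).
#'
#' @param frequency_hz Frequency in Hz (> 0), vectorised.
#' @param cm Membrane capacitance in uF/cm^2 (> 0).
#' @return Complex specific impedance, Ohm cm^2.
#' @examples
#' membrane_impedance(1 / (pi * 1e-6), cm = 1)  # -1i Ohm cm^2
#' @export
membrane_impedance <- function(frequency_hz, cm) {
  if (any(!is.finite(frequency_hz)) || any(frequency_hz <= 0)) {
    stop("'frequency_hz' must be finite and > 0", call. = FALSE)
  }
  if (!is.finite(cm) || cm <= 0) stop("'cm' must be > 0", call. = FALSE)
  cm_f <- cm * 1e-6                      # uF/cm^2 -> F/cm^2
  1 / (1i * pi * frequency_hz * cm_f)
}

#' Ratio of modified Bessel functions I0(z)/I1(z)
#'
#' Numerical kernel of the cell-covered electrode model, evaluated for
#' complex argument in the right half plane. Uses the continued fraction
#' for I1/I0 obtained from the three-term recurrence of I_nu, evaluated
#' by backward iteration; this is stable from |z| ~ 0 through the large
#' arguments reached at high frequency, where a naive power-series
#' summation suffers catastrophic cancellation near arg(z) = pi/2.
#'
#' @param z Complex argument(s) with Re(z) > 0 (z = 0 must be handled by
#'   the caller through the small-argument limit z * I0/I1 -> 2).
#' @return Complex value(s) of I0(z)/I1(z).
#' @export
bessel_ratio <- function(z) {
  z <- as.complex(z)
  if (any(z == 0)) stop("'z' must be nonzero; use the small-argument limit",
                        call. = FALSE)
  if (any(Re(z) <= 0)) stop("'z' must satisfy Re(z) > 0 (|arg z| < pi/2)",
                            call. = FALSE)
  # t_nu = I_{nu+1}/I_nu; t_{nu-1} = 1 / (2 nu / z + t_nu), t_N -> 0
  depth <- ceiling(40 + 1.5 * max(Mod(z)))
  t <- rep(0 + 0i, length(z))
  for (nu in depth:1) t <- 1 / (2 * nu / z + t)
  1 / t
}

#' Specific impedance of a cell-covered electrode
#'
#' The Lo--Ferrier--Giaever model: current reaching the electrode under
#' a confluent monolayer either couples capacitively through the two
#' cell membranes or flows radially in the narrow cell-substrate channel
#' and out through the intercellular junctions. With Z_n the cell-free
#' (naked) electrode specific impedance, Z_m the two-membrane series
#' impedance and gamma = alpha * sqrt(1/Z_n + 1/Z_m) (principal root),
#'
#'   1/Z_c = (1/Z_n) * ( Z_n/(Z_n+Z_m) +
#'           (Z_m/(Z_n+Z_m)) / ( (gamma/2) I0(gamma)/I1(gamma)
#'                               + R_b (1/Z_n + 1/Z_m) ) )
#'
#' At alpha = 0 the Bessel factor takes its analytic small-argument
#' limit (gamma/2) I0/I1 -> 1, so alpha = R_b = 0 returns Z_n exactly,
#' and R_b -> Inf returns Z_n + Z_m (all current through the membranes).
#'
#' @param frequency_hz Frequency in Hz (> 0), vectorised.
#' @param zn Complex naked-electrode specific impedance, Ohm cm^2,
#'   recycled against `frequency_hz`.
#' @param params A [monolayer_params()] object.
#' @return Complex specific impedance Z_c, Ohm cm^2.
#' @export
cell_covered_impedance <- function(frequency_hz, zn, params) {
  stopifnot(inherits(params, "monolayer_params"))
  zn <- as.complex(zn)
  if (any(zn == 0)) stop("'zn' must be nonzero", call. = FALSE)
  zm <- membrane_impedance(frequency_hz, params$cm)
  s <- 1 / zn + 1 / zm
  if (params$alpha == 0) {
    spread <- 1                       # lim_{g->0} (g/2) I0(g)/I1(g) = 1
  } else {
    gam <- params$alpha * sqrt(s)     # principal branch, Re(gam) > 0
    spread <- (gam / 2) * bessel_ratio(gam)
  }
  inv_zc <- (1 / zn) * (zn / (zn + zm) +
                          (zm / (zn + zm)) / (spread + params$rb * s))
  1 / inv_zc
}

#' Series-RC equivalent of a complex impedance
#'
#' Legacy macroscopic readout: a measured impedance is interpreted as a
#' single resistor and capacitor in series, r = Re(Z) and
#' c = -1 / (2 pi f Im(Z)). A non-negative imaginary part has no
#' series-capacitance interpretation; the capacitance is then reported
#' as `NA` while the resistance is still returned.
#'
#' @param z Complex impedance (Ohm), vectorised.
#' @param frequency_hz Frequency in Hz (> 0).
#' @return A data.frame with columns `r_ohm` and `c_farad`.
#' @export
series_rc_equivalent <- function(z, frequency_hz) {
  if (any(!is.finite(frequency_hz)) || any(frequency_hz <= 0)) {
    stop("'frequency_hz' must be finite and > 0", call. = FALSE)
  }
  z <- as.complex(z)
  c_farad <- ifelse(Im(z) < 0, -1 / (2 * pi * frequency_hz * Im(z)),
                    NA_real_)
  data.frame(r_ohm = Re(z), c_farad = c_farad)
}

#' Convert whole-electrode impedance to specific impedance
#'
#' The monolayer model is written per unit area while the instrument
#' records whole-electrode Ohm; multiplying by the electrode area gives
#' Ohm cm^2. [from_specific()] is the inverse.
#'
#' @param z_ohm Complex impedance, Ohm.
#' @param geometry An [electrode_geometry()] object.
#' @return Complex specific impedance, Ohm cm^2.
#' @export
to_specific <- function(z_ohm, geometry) {
  stopifnot(inherits(geometry, "electrode_geometry"))
  as.complex(z_ohm) * geometry$area_cm2
}

#' @rdname to_specific
#' @param z_specific Complex specific impedance, Ohm cm^2.
#' @export
from_specific <- function(z_specific, geometry) {
  stopifnot(inherits(geometry, "electrode_geometry"))
  as.complex(z_specific) / geometry$area_cm2
}
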