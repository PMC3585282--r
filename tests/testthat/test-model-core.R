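test_that("membrane impedance is a pure series capacitance of two membranes", {
  # closed form: cm = 1 uF/cm^2 at f = 1/(pi * 1e-6) Hz gives exactly -1i
  f0 <- 1 / (pi * 1e-6)
  expect_equal(membrane_impedance(f0, cm = 1), -1i)
  # purely imaginary with negative imaginary part at arbitrary points
  z <- membrane_impedance(c(62.5, 4000, 16000), cm = 1.8)
  expect_true(all(Re(z) == 0))
  expect_true(all(Im(z) < 0))
  # inverse proportionality in cm, vanishing at high frequency
  expect_equal(Mod(membrane_impedance(250, 2)),
               Mod(membrane_impedance(250, 1)) / 2)
  expect_lt(Mod(membrane_impedance(1e12, 1)), 1e-5)
  expect_error(membrane_impedance(-5, 1))
  expect_error(membrane_impedance(100, 0))
})

test_that("bessel_ratio matches high-precision reference values to 1e-10", {
  ref <- utils::read.csv(test_path("bessel_ratio_reference.csv"))
  z <- complex(real = ref$z_real, imaginary = ref$z_imag)
  got <- bessel_ratio(z)
  want <- complex(real = ref$ratio_real, imaginary = ref$ratio_imag)
  expect_lt(max(Mod(got - want) / Mod(want)), 1e-10)
})

test_that("bessel_ratio agrees with the power-series oracle where it is stable", {
  # grid restricted to arguments where double-precision series summation
  # keeps >10 significant digits (moderate cancellation)
  grid <- expand.grid(mod = c(1e-3, 0.1, 1, 2, 5, 8),
                      arg = c(-1.2, -0.6, 0, 0.6, 1.2))
  z <- complex(modulus = grid$mod, argument = grid$arg)
  want <- oracle_bessel_i0(z) / oracle_bessel_i1(z)
  expect_lt(max(Mod(bessel_ratio(z) - want) / Mod(want)), 1e-10)
})

test_that("bessel_ratio limits and domain errors", {
  # z * I0/I1 -> 2 as z -> 0 (leading series terms)
  expect_equal(Re(1e-8 * bessel_ratio(1e-8 + 0i)), 2, tolerance = 1e-12)
  # I0/I1 -> 1 for large arguments
  expect_lt(Mod(bessel_ratio(1e4 + 0i) - 1), 1e-3)
  # value at z = 2 frozen from 40-digit arbitrary-precision evaluation
  expect_equal(bessel_ratio(2 + 0i), 1.4331274267223117583 + 0i,
               tolerance = 1e-14)
  expect_error(bessel_ratio(0), "nonzero")
  expect_error(bessel_ratio(-1 + 0.5i), "Re")
})

test_that("cell-covered impedance reduces to the naked electrode and membrane ceiling", {
  f <- default_frequency_grid()
  zn <- electrode_model_z(electrode_model(inductance = 0), f)
  # alpha = 0, rb = 0: bracket collapses, Zc = Zn for any cm
  for (cm in c(0.5, 1.8, 4)) {
    zc <- cell_covered_impedance(f, zn, monolayer_params(0, 0, cm))
    expect_lt(max(Mod(zc - zn) / Mod(zn)), 1e-12)
  }
  # rb -> Inf: all current through the membranes, Zc -> Zn + Zm. The
  # finite-rb correction is ~|Zm|/rb, so at rb = 1e9 the 1e-6 agreement
  # holds where |Zm| <= 1 kOhm cm^2 (f >= 250 Hz for cm = 1.8).
  fa <- f[f >= 250]
  zna <- zn[f >= 250]
  p <- monolayer_params(6, 1e9, 1.8)
  zm <- membrane_impedance(fa, 1.8)
  zc <- cell_covered_impedance(fa, zna, p)
  expect_lt(max(Mod(zc - (zna + zm)) / Mod(zna + zm)), 1e-6)
  # and the approach to the limit scales as 1/rb
  zc10 <- cell_covered_impedance(fa, zna, monolayer_params(6, 1e10, 1.8))
  dev9 <- max(Mod(zc - (zna + zm)) / Mod(zna + zm))
  dev10 <- max(Mod(zc10 - (zna + zm)) / Mod(zna + zm))
  expect_equal(dev10 / dev9, 0.1, tolerance = 0.01)
})

test_that("cell-covered impedance matches an independent direct evaluation", {
  zn <- electrode_model_z(electrode_model(inductance = 0), 4000)
  got <- cell_covered_impedance(4000, zn, monolayer_params(6, 4, 1.8))
  want <- oracle_cell_covered(4000, zn, 6, 4, 1.8)
  expect_lt(Mod(got - want) / Mod(want), 1e-12)
})

test_that("cell-covered impedance is monotone in rb and smooth in all parameters", {
  f <- exp(seq(log(62.5), log(16000), length.out = 12))
  zn <- electrode_model_z(electrode_model(inductance = 0), f)
  rbs <- c(0, 0.5, 1, 2, 5, 10, 30, 100)
  mods <- sapply(rbs, function(rb) {
    Mod(cell_covered_impedance(f, zn, monolayer_params(6, rb, 1.8)))
  })
  # |Zc| non-decreasing in rb at every frequency over rb in [0, 100];
  # the membrane ceiling |Zn + Zm| is approached (from either side) as
  # rb -> Inf -- at finite rb the constriction path can push |Zc| above
  # it, so the ceiling is asymptotic, not a finite-rb bound
  expect_true(all(diff(t(mods)) >= -1e-12))
  ceiling_mod <- Mod(zn + membrane_impedance(f, 1.8))
  mod_inf <- Mod(cell_covered_impedance(f, zn, monolayer_params(6, 1e12, 1.8)))
  expect_equal(mod_inf, ceiling_mod, tolerance = 1e-8)
  # finite central-difference derivatives (the fitter relies on them)
  p0 <- c(alpha = 6, rb = 4, cm = 1.8)
  for (k in 1:3) {
    h <- 1e-6 * p0[k]
    up <- p0; up[k] <- up[k] + h
    dn <- p0; dn[k] <- dn[k] - h
    d <- (cell_covered_impedance(f, zn, monolayer_params(up[1], up[2], up[3])) -
            cell_covered_impedance(f, zn, monolayer_params(dn[1], dn[2], dn[3]))) /
      (2 * h)
    expect_true(all(is.finite(Re(d)) & is.finite(Im(d))))
  }
  expect_error(cell_covered_impedance(4000, 0 + 0i, monolayer_params(6, 4, 1.8)))
})

test_that("series-RC equivalent is the closed-form decomposition with round trip", {
  rc <- series_rc_equivalent(100 - 50i, 4000)
  expect_equal(rc$r_ohm, 100)
  expect_equal(rc$c_farad, 1 / (2 * pi * 4000 * 50))
  # purely real (or inductive) impedance has no series capacitance
  rc2 <- series_rc_equivalent(c(80 + 0i, 80 + 5i), 4000)
  expect_equal(rc2$r_ohm, c(80, 80))
  expect_true(all(is.na(rc2$c_farad)))
  # build from (r, c, f) and decompose back exactly
  r <- 120; cf <- 2e-9; f <- 4000
  z <- r - 1i / (2 * pi * f * cf)
  back <- series_rc_equivalent(z, f)
  expect_equal(back$r_ohm, r)
  expect_equal(back$c_farad, cf)
})

test_that("specific-impedance conversion scales by area and round-trips", {
  g <- electrode_geometry(area_cm2 = 5e-3)
  expect_equal(to_specific(1000 + 0i, g), 5 + 0i)
  g1 <- electrode_geometry(area_cm2 = 1)
  expect_equal(to_specific(42 - 7i, g1), 42 - 7i)
  z <- complex(real = rnorm(5, 100), imaginary = -abs(rnorm(5, 50)))
  expect_equal(from_specific(to_specific(z, g), g), z)
})

test_that("domain types validate their invariants", {
  expect_error(monolayer_params(-1, 4, 1.8), "alpha")
  expect_error(monolayer_params(6, -1, 1.8), "rb")
  expect_error(monolayer_params(6, 4, 0), "cm")
  expect_error(monolayer_params(6, Inf, 1.8), "finite")
  expect_error(electrode_geometry(area_cm2 = 0))
  expect_error(complex_spectrum(c(100, 200), z_ohm = c(1 + 0i, 2 + 0i)),
               "at least 3")
  expect_error(complex_spectrum(c(100, 50, 200),
                                z_ohm = c(1 + 0i, 2 + 0i, 3 + 0i)),
               "increasing")
  expect_error(complex_spectrum(c(100, 200, 300), z_ohm = c(1 + 0i, 2 + 0i)),
               "equal length")
  # default 8W10E area: ten 250-um circular electrodes
  expect_equal(electrode_geometry()$area_cm2, 10 * pi * 0.0125^2)
})
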