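test_that("electrode model degenerates to an ideal RC without artifact", {
  em <- electrode_model(cpe_beta = 1, inductance = 0)
  f <- c(100, 400, 1600, 6400)
  z <- electrode_model_z(em, f)
  # beta = 1: Im(Z) * 2 pi f is the constant -1/Q
  expect_equal(Im(z) * 2 * pi * f, rep(-1 / em$cpe_q, 4))
  expect_equal(Re(z), rep(em$r_sol, 4))
})

test_that("recorded reference spectra show the high-frequency inductive flip", {
  # noiseless default model: capacitive (Im < 0) throughout the fit
  # window, inductive (Im > 0) before the top of the acquisition grid
  em <- electrode_model()
  f <- default_frequency_grid()
  z <- electrode_model_z(em, f)
  expect_true(all(Im(z)[f <= 16000] < 0))
  expect_gt(Im(z)[f == 64000], 0)
  # the sign change lies strictly above the analysis window
  flip <- stats::uniroot(function(fx) Im(electrode_model_z(em, fx)),
                         c(16000, 64000))$root
  expect_gt(flip, 16000)
  # artifact-free interface impedance stays capacitive everywhere
  z0 <- electrode_model_z(em, f, include_lead = FALSE)
  expect_true(all(Im(z0) < 0))
})

test_that("generators are deterministic under a fixed seed and decorrelate across seeds", {
  r1 <- generate_reference(seed = 7)
  r2 <- generate_reference(seed = 7)
  expect_identical(r1, r2)
  r3 <- generate_reference(seed = 8)
  expect_false(identical(r1$z_ohm, r3$z_ohm))
  c1 <- generate_cell_scan(seed = 7)
  c2 <- generate_cell_scan(seed = 7)
  expect_identical(c1, c2)
  p1 <- generate_images(0.5, seed = 7)
  p2 <- generate_images(0.5, seed = 7)
  expect_identical(p1, p2)
  t1 <- generate_ct_table(c(g = 0.5), seed = 7)
  t2 <- generate_ct_table(c(g = 0.5), seed = 7)
  expect_identical(t1, t2)
  b1 <- generate_experiment(scenario_preset("control", n_experiments = 1, seed = 7))
  b2 <- generate_experiment(scenario_preset("control", n_experiments = 1, seed = 7))
  expect_identical(b1, b2)
  # seeded generation does not disturb the session RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(generate_reference(seed = 5)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("zero-effect parameters reproduce the reference electrode", {
  em <- electrode_model()
  geom <- electrode_geometry()
  ref <- generate_reference(em, geometry = geom, noise_sd = 0)
  cell <- generate_cell_scan(em, monolayer_params(0, 0, 1.8),
                             geometry = geom, noise_sd = 0)
  expect_equal(cell$z_ohm, ref$z_ohm, tolerance = 1e-12)
  # doubling rb raises |Z| at the monitoring frequency
  z1 <- generate_cell_scan(em, monolayer_params(6, 4, 1.8),
                           geometry = geom, noise_sd = 0)
  z2 <- generate_cell_scan(em, monolayer_params(6, 8, 1.8),
                           geometry = geom, noise_sd = 0)
  at4k <- function(s) Mod(s$z_ohm[s$frequencies_hz == 4000])
  expect_gt(at4k(z2), at4k(z1))
})

test_that("a degenerate generator (no noise, no spread) is recovered exactly", {
  scn <- scenario_preset("control", n_experiments = 1, noise_sd = 0,
                         cv_experiment = 0, cv_electrode = 0, seed = 3)
  bundle <- generate_experiment(scn, model = electrode_model(inductance = 0),
                                cv_lead = 0)
  fits <- fit_bundle(bundle)
  expect_equal(fits$alpha, rep(6, nrow(fits)), tolerance = 1e-6)
  expect_equal(fits$rb, rep(4, nrow(fits)), tolerance = 1e-6)
  expect_equal(fits$cm, rep(1.8, nrow(fits)), tolerance = 1e-6)
})

test_that("experiment bundles carry ground truth aligned with their spectra", {
  scn <- scenario_preset("007AM", n_experiments = 2, seed = 5)
  bundle <- generate_experiment(scn)
  expect_equal(length(bundle$experiments), 2)
  expect_equal(nrow(bundle$truth), 2 * 4 * 2)  # exp x electrode x phase
  # the post/pre ratio of generating rb is exactly the preset factor
  tr <- bundle$truth
  pre <- tr$rb[tr$phase_label == "pre"]
  post <- tr$rb[tr$phase_label == "post"]
  expect_equal(post / pre, rep(1.5, 8))
  # alpha untouched by the stimulus
  expect_equal(tr$alpha[tr$phase_label == "post"],
               tr$alpha[tr$phase_label == "pre"])
})

test_that("scenario presets encode the study effect directions", {
  expect_equal(scenario_preset("007AM")$rb_factor, 1.5)
  expect_equal(scenario_preset("siRap2")$rb_factor, 2)
  expect_lt(scenario_preset("siRap1")$rb_factor, 1)
  expect_equal(scenario_preset("siRap1+siRap2")$rb_factor, 1)
  sic <- scenario_preset("siCadherin")
  expect_lt(sic$baseline$rb * sic$rb_factor, 0.05)  # barrier ~ 0
  expect_equal(sic$alpha_factor, 1)                 # alpha preserved
  expect_lt(sic$cm_factor, 1)                       # Cm reduced
  expect_equal(scenario_preset("007AM")$n_experiments, 8)
  expect_equal(scenario_preset("siRap2")$n_experiments, 6)
})

test_that("alpha can be derived from the microscopic triple", {
  # alpha = r_c * sqrt(rho / h): 15 um, 54 Ohm cm, 150 nm
  scn <- scenario(microscopic = list(r_c_um = 15, rho_ohm_cm = 54,
                                     h_nm = 150))
  expect_equal(scn$baseline$alpha, 1.5e-3 * sqrt(54 / 1.5e-5))
  expect_error(scenario(microscopic = list(r_c_um = 15)), "h_nm")
})

test_that("Ct generator encodes knockdowns as cycle shifts", {
  # noise-free: fraction 0.5 -> delta-delta-Ct exactly +1; fraction 1 -> 0
  tab <- generate_ct_table(c(kd50 = 0.5, none = 1), ct_sd = 0, seed = 2)
  d <- ddct(tab)
  kd <- d[d$sample_id != "reference", ]
  expect_equal(kd$delta_delta_ct[kd$gene == "kd50"], rep(1, 3))
  expect_equal(kd$delta_delta_ct[kd$gene == "none"], rep(0, 3))
  expect_equal(kd$fold_change[kd$gene == "kd50"], rep(0.5, 3))
  expect_error(generate_ct_table(c(g = 0)), "0, 1")
  expect_error(generate_ct_table(0.5), "named")
})

test_that("image generator validates inputs and emits ground truth", {
  expect_error(generate_images(1.5), "0, 1")
  expect_error(generate_images(0.5, dims = c(64, 64)), "128")
  expect_error(generate_images(0.5, n_cells = 4), "9")
  pair <- generate_images(0.5, seed = 1)
  expect_s3_class(pair, "image_pair")
  truth <- attr(pair, "truth_mask")
  expect_true(is.logical(truth))
  expect_equal(dim(truth), dim(pair$channel_a))
  frac <- mean(truth)
  expect_gt(frac, 0.02); expect_lt(frac, 0.5)
})
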