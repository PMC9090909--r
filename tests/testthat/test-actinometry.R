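test_that("actinometer calibration recovers exact lines and published slopes", {
  p0 <- c(0.5, 1, 2, 3, 4) * 1e-4
  pts <- data.frame(p0_tot = p0, k_eta = 700 * p0 + 2e-4)
  cal <- calibrate_actinometer(pts, "drug", "lampX")
  expect_equal(cal$beta_eta, 700)
  expect_equal(cal$intercept, 2e-4)
  expect_equal(cal$r2, 1)

  # points sampled from the published short-wavelength-lamp line
  pts1 <- data.frame(p0_tot = p0,
                     k_eta = 548.26 * p0 - 0.4e-3)
  cal1 <- calibrate_actinometer(pts1, "NIF", "lamp1")
  expect_equal(cal1$beta_eta, 548.26)

  expect_error(calibrate_actinometer(pts[1:3, ], "d", "l"), "4 distinct")
  same <- data.frame(p0_tot = rep(1e-4, 5), k_eta = rep(0.1, 5))
  expect_error(calibrate_actinometer(same, "d", "l"), "4 distinct")
  expect_error(calibrate_actinometer(pts, "d", ""), "mandatory")
})

test_that("calibration inversion reproduces the published cross-lamp worked example", {
  cals <- nif_lamp_calibrations()
  # the slope-1365.3 line and the mid-wavelength (#2) line
  cal_1365 <- Filter(function(c) c$beta_eta == 1365.3, cals)[[1]]
  p4 <- unknown_intensity(0.332, cal_1365)
  p2 <- unknown_intensity(0.332, cals$lamp2)
  expect_equal(p4, 2.42e-4, tolerance = 2e-3)
  expect_equal(p2, 2.98e-4, tolerance = 2e-3)
  disc <- cross_lamp_discrepancy(0.332, cals$lamp2, cal_1365)
  expect_equal(disc, 19, tolerance = 0.02)

  expect_equal(cross_lamp_discrepancy(0.332, cals$lamp2, cals$lamp2), 0)

  # k_eta equal to the intercept: intensity 0, flagged below range
  expect_warning(p0 <- unknown_intensity(cals$lamp2$intercept, cals$lamp2),
                 "below the")
  expect_equal(p0, 0)
})

test_that("lamp mismatch warns, and refuses in strict mode", {
  cals <- nif_lamp_calibrations()
  expect_warning(unknown_intensity(0.332, cals$lamp2, lamp_id = "lamp3"),
                 "lamp-specific")
  expect_error(unknown_intensity(0.332, cals$lamp2, lamp_id = "lamp3",
                                 strict = TRUE), "lamp mismatch")
  expect_silent(unknown_intensity(0.332, cals$lamp2, lamp_id = "lamp2"))
})

test_that("beta from attributes: scale invariance, single-wavelength cancellation", {
  poly <- toy_polychromatic()
  b1 <- beta_from_attributes(poly$species, poly$lamp)
  lamp3 <- lamp_profile(spectrum(poly$lamp$spectrum$wavelength,
                                 3 * poly$lamp$spectrum$value,
                                 unit = "einstein dm-3 s-1"), "toy-poly")
  expect_equal(beta_from_attributes(poly$species, lamp3), b1,
               tolerance = 1e-12)

  # eps_B = 0 and one wavelength: beta = Phi eps_A P / (P eps_A) = Phi
  toy <- toy_single_lambda(eps_A = 1e4, eps_B = 0, phi = 0.37, P0 = 2e-5)
  expect_equal(beta_from_attributes(toy$species, toy$lamp), 0.37)
})

test_that("predicted beta agrees with beta fitted from simulated calibrations", {
  sys <- make_system(synthetic_spec(noise_rsd = 0, seed = 5L))
  series <- make_intensity_series(sys, noise_rsd = 0)
  pts <- data.frame(
    p0_tot = vapply(series, `[[`, numeric(1), "p0_tot"),
    k_eta = vapply(series, function(e) {
      fit_eta_trace(e$trace, alpha2 = sys$params$alpha2, C0 = sys$C0)$k_eta
    }, numeric(1)))
  cal <- calibrate_actinometer(pts, "syn", "synthetic-lamp")
  expect_lt(abs(cal$beta_eta - sys$beta_true) / sys$beta_true, 0.05)
})

test_that("lamp specificity: different emission shapes give different betas", {
  uva_heavy <- toy_polychromatic(lamp_weights = c(0.05, 0.95))
  uvc_heavy <- toy_polychromatic(lamp_weights = c(0.70, 0.30))
  b_uva <- beta_from_attributes(uva_heavy$species, uva_heavy$lamp)
  b_uvc <- beta_from_attributes(uvc_heavy$species, uvc_heavy$lamp)
  # quantum yield rises with wavelength: UVA-weighted lamp drives it harder
  expect_gt(b_uva, b_uvc)

  # proportional profiles coincide
  prop <- toy_polychromatic(lamp_weights = c(0.05, 0.95),
                            total_flux_val = 3.3e-4)
  expect_equal(beta_from_attributes(prop$species, prop$lamp), b_uva,
               tolerance = 1e-10)
})

test_that("full protocol recovers a held-out intensity from noiseless traces", {
  sys <- make_system(synthetic_spec(noise_rsd = 0, seed = 3L))
  series <- make_intensity_series(sys, noise_rsd = 0)
  held_out <- scale_lamp(sys, 0.7)
  unk <- make_trace(held_out, noise_rsd = 0)
  report <- run_protocol(list(
    alpha2 = sys$params$alpha2, C0 = sys$C0,
    calibration = lapply(series, function(e) list(p0_tot = e$p0_tot,
                                                  trace = e$trace)),
    unknown_trace = unk,
    drug_id = "syn", lamp_id = "synthetic-lamp"))
  truth <- total_flux(held_out$lamp)
  expect_lt(abs(report$p0_tot_unknown - truth) / truth, 1e-3)
  expect_gt(report$calibration$r2, 0.999)
})

test_that("protocol validates its configuration", {
  sys <- make_system(synthetic_spec(noise_rsd = 0, seed = 3L))
  series <- make_intensity_series(sys, noise_rsd = 0)
  cal_entries <- lapply(series, function(e) list(p0_tot = e$p0_tot,
                                                 trace = e$trace))
  expect_error(run_protocol(list(alpha2 = 1e-5, C0 = sys$C0,
                                 calibration = cal_entries)),
               "lamp_id")
  expect_error(run_protocol(list(alpha2 = 1e-5, C0 = sys$C0,
                                 calibration = cal_entries[1:3],
                                 lamp_id = "l")),
               ">= 4 distinct")
})

test_that("calibration JSON round-trips through the io layer", {
  p0 <- c(0.5, 1, 2, 4) * 1e-4
  pts <- data.frame(p0_tot = p0, k_eta = 700 * p0 + 2e-4)
  cal <- calibrate_actinometer(pts, "drug", "lampX")
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration_json(cal, path)
  back <- read_calibration_json(path)
  expect_equal(back$beta_eta, cal$beta_eta)
  expect_equal(back$intercept, cal$intercept)
  expect_equal(back$points, cal$points)
  expect_identical(back$lamp_id, "lampX")
})
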