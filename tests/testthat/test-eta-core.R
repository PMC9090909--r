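test_that("total absorbance sums both species over the window", {
  wl <- c(300, 310)
  sp <- photo_species(spectrum(wl, c(1e4, 2e4), unit = "M-1cm-1"),
                      spectrum(wl, c(1e3, 2e3), unit = "M-1cm-1"),
                      spectrum(wl, c(0.1, 0.1), unit = "dimensionless"))
  geom <- reactor_geometry()
  expect_equal(total_absorbance(sp, geom, 0, 0), 0)
  # hand arithmetic: (1e4+2e4)*1e-5 + (1e3+2e3)*2e-5 = 0.30 + 0.06
  expect_equal(total_absorbance(sp, geom, 1e-5, 2e-5), 0.36)
  # linear in C_A at fixed C_B
  a <- total_absorbance(sp, geom, 1e-5, 2e-5)
  b <- total_absorbance(sp, geom, 2e-5, 2e-5)
  c3 <- total_absorbance(sp, geom, 3e-5, 2e-5)
  expect_equal(c3 - b, b - a)
  expect_error(total_absorbance(sp, geom, -1e-6, 0), "non-negative")
})

test_that("photokinetic factor: full form, reduced form, continuous limit", {
  expect_equal(photokinetic_factor(1), 0.9)
  expect_equal(photokinetic_factor(1e-14), log(10))
  expect_equal(photokinetic_factor(1e-6), log(10), tolerance = 1e-5)
  expect_equal(photokinetic_factor(3), (1 - 1e-3) / 3)
  expect_equal(photokinetic_factor(3, reduced = TRUE), 1 / 3)
  gap <- abs(photokinetic_factor(3, reduced = TRUE) - photokinetic_factor(3)) /
    photokinetic_factor(3)
  expect_lt(gap, 0.0011)
  expect_error(photokinetic_factor(0, reduced = TRUE), "undefined")
})

test_that("alpha constants reproduce the published summed-absorptivity arithmetic", {
  # species whose window sums equal the published DBZ totals
  n <- 100
  wl <- seq(300, 399, by = 1)
  sp <- photo_species(
    spectrum(wl, rep(1150028.96 / n, n), unit = "M-1cm-1"),
    spectrum(wl, rep(344785.15 / n, n), unit = "M-1cm-1"),
    spectrum(wl, rep(0.1, n), unit = "dimensionless"))
  expect_equal(alpha1(sp, reactor_geometry()), 1 / 805243.81,
               tolerance = 1e-10)
  expect_equal(alpha1(sp, reactor_geometry()), 1.2419e-6, tolerance = 1e-4)
  expect_equal(alpha2(sp, C0 = 5.41e-5), 5.41e-5 * 344785.15 / 805243.81,
               tolerance = 1e-10)
  expect_equal(alpha2(sp, C0 = 5.41e-5), 2.3165e-5, tolerance = 1e-4)

  # transparent photoproduct -> alpha2 = 0
  spB0 <- photo_species(sp$eps_A, spectrum(wl, rep(0, n), unit = "M-1cm-1"),
                        sp$qy)
  expect_equal(alpha2(spB0, C0 = 1e-5), 0)

  # degenerate window
  spEq <- photo_species(sp$eps_A, sp$eps_A, sp$qy)
  expect_error(alpha1(spEq, reactor_geometry()), "degenerate")
  expect_error(alpha2(spEq, 1e-5), "degenerate")
})

test_that("k_eta from attributes: value, homogeneity, C0/l_irr independence", {
  toy <- toy_single_lambda(eps_A = 1e4, eps_B = 0, phi = 0.5, P0 = 1e-5)
  expect_equal(k_eta_from_attributes(toy$species, toy$lamp), 5e-6)

  poly <- toy_polychromatic()
  k1 <- k_eta_from_attributes(poly$species, poly$lamp)
  lamp2 <- lamp_profile(spectrum(poly$lamp$spectrum$wavelength,
                                 2 * poly$lamp$spectrum$value,
                                 unit = "einstein dm-3 s-1"), "toy-poly")
  expect_equal(k_eta_from_attributes(poly$species, lamp2), 2 * k1)

  # k_eta carries no C0 or l_irr: identical params at different C0 / paths
  pA <- eta_params_from_system(poly$species, poly$lamp, reactor_geometry(), 1.5e-5)
  pB <- eta_params_from_system(poly$species, poly$lamp, reactor_geometry(), 10.5e-5)
  expect_equal(pA$k_eta, pB$k_eta)
  pC <- eta_params_from_system(poly$species, poly$lamp,
                               reactor_geometry(l_irr_cm = 2.5), 1.5e-5)
  expect_equal(pA$k_eta, pC$k_eta)
})

test_that("eta transform: identity at C0, zeroth-order limit, hand value", {
  p <- eta_params(1.2e-6, 2e-5, 1e-7, 1e-4)
  expect_equal(eta_of_t(1e-4, p), 0)
  p0 <- eta_params(1.2e-6, 0, 1e-7, 1e-4)
  expect_equal(eta_of_t(6e-5, p0), 6e-5 - 1e-4)
  expect_equal(eta_of_t(6.016e-5, p), -5.000e-5, tolerance = 1e-4)
  expect_error(eta_of_t(0, p), "positive")
})

test_that("closed-form inversion satisfies the implicit law and matches bisection", {
  p <- eta_params(1.2e-6, 2e-5, 1e-7, 1e-4)
  expect_equal(concentration_at_time(0, p), 1e-4)
  expect_equal(concentration_at_time(500, p),
               bisect_eta(500, 1e-4, 2e-5, 1e-7), tolerance = 1e-10)
  expect_equal(concentration_at_time(500, p), 6.016e-5, tolerance = 1e-4)

  # property-based: random valid params, residual of the implicit law
  set.seed(42)
  for (i in 1:25) {
    C0 <- 10^runif(1, -5.5, -3.5)
    a2 <- C0 * runif(1, 0.01, 3)
    k <- 10^runif(1, -9, -6)
    pp <- eta_params(1, a2, k, C0)
    tt <- seq(0, 6 * half_life(pp), length.out = 40)
    C <- concentration_at_time(tt, pp)
    expect_true(all(diff(C) <= 1e-15))      # monotone non-increasing
    expect_true(all(C >= 0 & C <= C0))
    pos <- C > 0
    resid <- abs((C[pos] - C0) + a2 * log(C[pos] / C0) + k * tt[pos])
    expect_lt(max(resid), 1e-10 * C0)
    expect_equal(C, bisect_eta(tt, C0, a2, k), tolerance = 1e-9)
  }
})

test_that("closed form survives the Lambert-W overflow regime", {
  # b/alpha2 ~ C0/alpha2 is huge when alpha2 << C0: exp() overflows, the
  # Newton fallback on w + log w must take over
  p <- eta_params(1, 1e-8, 1e-7, 1e-4)
  C <- concentration_at_time(c(0, 100, 500, 990), p)
  expect_equal(C, bisect_eta(c(0, 100, 500, 990), 1e-4, 1e-8, 1e-7),
               tolerance = 1e-9)
})

test_that("alpha2 <= 0 regimes fall back to bracketed root finding", {
  # alpha2 = 0: pure zeroth-order line, floored at zero
  p0 <- eta_params(1, 0, 1e-7, 1e-4)
  expect_equal(concentration_at_time(c(0, 200, 1000), p0),
               c(1e-4, 1e-4 - 2e-5, 0))
  # alpha2 < 0 with k < 0 (photoproduct out-absorbs the reactant)
  expect_warning(pn <- eta_params(-1, -2e-5, -1e-7, 1e-4), "alpha2 < 0")
  C <- concentration_at_time(c(0, 100, 400), pn)
  expect_equal(C[1], 1e-4)
  expect_true(all(diff(C) < 0))
  resid <- (C - 1e-4) + (-2e-5) * log(C / 1e-4) + (-1e-7) * c(0, 100, 400)
  expect_lt(max(abs(resid)), 1e-10 * 1e-4)
})

test_that("half-life formula, its concentration check, and flux scaling", {
  p <- eta_params(1.2e-6, 2e-5, 1e-7, 1e-4)
  t12 <- half_life(p)
  expect_equal(t12, (0.5e-4 + 2e-5 * log(2)) / 1e-7)
  expect_equal(t12, 638.63, tolerance = 1e-5)
  expect_equal(concentration_at_time(t12, p), 5e-5, tolerance = 1e-9)

  p0 <- eta_params(1.2e-6, 0, 1e-7, 1e-4)
  expect_equal(half_life(p0), 0.5 * 1e-4 / 1e-7)

  # doubling lamp flux doubles k_eta, halving the half-life
  poly <- toy_polychromatic()
  geom <- reactor_geometry()
  pa <- eta_params_from_system(poly$species, poly$lamp, geom, 2.3e-5)
  lamp2 <- lamp_profile(spectrum(poly$lamp$spectrum$wavelength,
                                 2 * poly$lamp$spectrum$value,
                                 unit = "einstein dm-3 s-1"), "toy-poly")
  pb <- eta_params_from_system(poly$species, lamp2, geom, 2.3e-5)
  expect_equal(half_life(pb), half_life(pa) / 2)
  expect_error(half_life(eta_params(1, 1e-5, 0, 1e-4)), "k_eta > 0")
})

test_that("initial velocity composes tested pieces and loses C0 dependence at high A", {
  poly <- toy_polychromatic()
  geom <- reactor_geometry()
  sp <- restrict_to_support(poly$species, poly$lamp)
  p <- eta_params_from_system(poly$species, poly$lamp, geom, 2.3e-5)
  d <- sum(sp$eps_A$value - sp$eps_B$value)
  A0 <- total_absorbance(sp, geom, 2.3e-5, 0)
  expect_gt(A0, 3)
  r0 <- initial_velocity(p, sp, geom)
  expect_equal(r0, -2.3e-5 * p$k_eta * 1 * d * photokinetic_factor(A0))
  expect_lt(r0, 0)

  # two C0 both with A_tot(0) > 3: |r0| within 0.1%
  p2 <- eta_params_from_system(poly$species, poly$lamp, geom, 4.6e-5)
  r0b <- initial_velocity(p2, sp, geom)
  expect_lt(abs(abs(r0b) - abs(r0)) / abs(r0), 1e-3)

  # zero flux: k_eta = 0 -> r0 = 0
  pz <- eta_params(p$alpha1, p$alpha2, 0, 2.3e-5)
  expect_equal(initial_velocity(pz, sp, geom), 0)
})

test_that("validity audit raises the documented flags", {
  poly <- toy_polychromatic()
  sp <- restrict_to_support(poly$species, poly$lamp)
  geom <- reactor_geometry()
  p <- eta_params_from_system(poly$species, poly$lamp, geom, 2.3e-5)
  ok <- validity_check(sp, geom, p, trace_end_absorbance = 5)
  expect_true(ok$ok)
  low <- validity_check(sp, geom, p, trace_end_absorbance = 0.5)
  expect_true(low$reduced_factor_invalid)
  rng <- validity_check(sp, geom, p, trace_end_absorbance = 5,
                        linearity_range = c(1.5e-5, 2e-5))
  expect_true(rng$linearity_exceeded)
})

test_that("first- and zeroth-order limits of the closed form", {
  # Sum eps_B -> Sum eps_A: trace converges to C0 exp(-(k/alpha2) t)
  wl <- 300:360
  epsA <- rep(2e4, length(wl))
  gap <- 1e-3
  epsB <- epsA * (1 - gap)
  sp <- photo_species(spectrum(wl, epsA, unit = "M-1cm-1"),
                      spectrum(wl, epsB, unit = "M-1cm-1"),
                      spectrum(wl, rep(0.3, length(wl)), "dimensionless"))
  lamp <- lamp_profile(spectrum(wl, rep(1e-6, length(wl)),
                                unit = "einstein dm-3 s-1"), "flat")
  p <- eta_params_from_system(sp, lamp, reactor_geometry(), 5e-5)
  tt <- seq(0, 3 * half_life(p) , length.out = 50)
  C <- concentration_at_time(tt, p)
  Cexp <- 5e-5 * exp(-(p$k_eta / p$alpha2) * tt)
  expect_lt(max(abs(C - Cexp) / Cexp), 0.01)

  # eps_B = 0 and F reduced: C = C0 - k t exactly in eta form with alpha2 = 0
  spB0 <- photo_species(sp$eps_A, spectrum(wl, rep(0, length(wl)), "M-1cm-1"),
                        sp$qy)
  p0 <- eta_params_from_system(spB0, lamp, reactor_geometry(), 5e-5)
  expect_equal(p0$alpha2, 0)
  tt0 <- seq(0, 0.9 * 5e-5 / p0$k_eta, length.out = 20)
  expect_equal(concentration_at_time(tt0, p0), 5e-5 - p0$k_eta * tt0)
})
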