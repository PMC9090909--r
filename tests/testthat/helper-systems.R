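# Shared in-code fixtures: tiny toy systems and independent oracles.

# A minimal single-wavelength system: one grid point, photoproduct dark.
toy_single_lambda <- function(wl = 254, eps_A = 1e4, eps_B = 0, phi = 0.5,
                              P0 = 1e-5) {
  species <- photo_species(
    spectrum(wl, eps_A, unit = "M-1cm-1"),
    spectrum(wl, eps_B, unit = "M-1cm-1"),
    spectrum(wl, phi, unit = "dimensionless"))
  lamp <- lamp_profile(spectrum(wl, P0, unit = "einstein dm-3 s-1"),
                       lamp_id = "toy")
  list(species = species, lamp = lamp)
}

# Two-band drug-like species + mixed lamp on a 200-400 nm grid with an
# eps_B/eps_A ratio keeping alpha2 > 0 over the lamp support.
toy_polychromatic <- function(eps_B_scale = 1, lamp_weights = c(0.15, 0.85),
                              total_flux_val = 1e-4) {
  wl <- 200:400
  epsA <- 16000 * exp(-0.5 * ((wl - 238) / 18)^2) +
          22000 * exp(-0.5 * ((wl - 330) / 28)^2)
  epsB <- eps_B_scale * (9000 * exp(-0.5 * ((wl - 240) / 20)^2) +
                         5200 * exp(-0.5 * ((wl - 320) / 30)^2))
  phi <- 0.005 + (0.30 - 0.005) / (1 + exp(-(wl - 310) / 18))
  rel <- lamp_weights[1] * exp(-0.5 * ((wl - 254) / 2)^2) +
         lamp_weights[2] * exp(-0.5 * ((wl - 365) / 14)^2)
  species <- photo_species(spectrum(wl, epsA, unit = "M-1cm-1"),
                           spectrum(wl, epsB, unit = "M-1cm-1"),
                           spectrum(wl, phi, unit = "dimensionless"))
  lamp0 <- lamp_profile(spectrum(wl, rel, unit = "einstein dm-3 s-1"), "toy-poly")
  scale <- total_flux_val / total_flux(lamp0)
  lamp <- lamp_profile(spectrum(wl, rel * scale, unit = "einstein dm-3 s-1"),
                       "toy-poly")
  list(species = species, lamp = lamp)
}

# Independent oracle: root of the implicit eta-order law by plain bisection
# (never calls concentration_at_time).
bisect_eta <- function(t, C0, a2, k, tol = 1e-12) {
  vapply(t, function(ti) {
    # g is strictly increasing in C (a2 >= 0): g(0+) = -Inf, g(C0) = k ti
    g <- function(C) (C - C0) + a2 * log(C / C0) + k * ti
    lo <- 1e-30 * C0; hi <- C0
    if (ti == 0) {
      C0
    } else if (g(lo) > 0) {
      0  # depleted beyond bracket resolution
    } else {
      for (i in 1:200) {
        mid <- 0.5 * (lo + hi)
        if (g(mid) > 0) hi <- mid else lo <- mid
        if (hi - lo < tol * C0) break
      }
      0.5 * (lo + hi)
    }
  }, numeric(1))
}

# Independent fixed-step RK4 integrator for a scalar ODE dC/dt = f(C).
rk4_trace <- function(f, C0, t_grid, n_sub = 50) {
  C <- numeric(length(t_grid))
  C[1] <- C0
  for (i in seq_along(t_grid)[-1]) {
    h <- (t_grid[i] - t_grid[i - 1]) / n_sub
    y <- C[i - 1]
    for (s in seq_len(n_sub)) {
      k1 <- f(y); k2 <- f(y + h / 2 * k1)
      k3 <- f(y + h / 2 * k2); k4 <- f(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    C[i] <- y
  }
  C
}

# Run a cli call with its stdout/messages captured (exit code only).
cli_quiet <- function(expr) {
  out <- utils::capture.output(code <- suppressMessages(expr))
  code
}
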