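# Reference numerical integration of the unapproximated per-wavelength rate
# law and of the lumped (Delta-lambda-summed) rate law. The closed-form
# eta-order solution is the analytic solution of the lumped/reduced ODE;
# the per-wavelength integration is the oracle quantifying the lumping error.

#' Kinetic trace
#'
#' A sampled concentration-versus-time record for the reactant (and,
#' optionally, the photoproduct reconstructed by mass balance).
#'
#' @param t time, s, non-decreasing.
#' @param C_A reactant concentration, M; `C_A[1] > 0`.
#' @param C_B optional photoproduct concentration, M.
#' @param provenance one of `"simulated"`, `"synthetic"`, `"measured"`.
#' @param noise_rsd relative noise level applied (fraction; 0 for exact).
#' @param seed integer seed used for any noise (NA when deterministic).
#' @return An object of class `kinetic_trace` (a data frame with metadata).
#' @export
kinetic_trace <- function(t, C_A, C_B = NULL,
                          provenance = c("simulated", "synthetic", "measured"),
                          noise_rsd = 0, seed = NA_integer_) {
  provenance <- match.arg(provenance)
  t <- as.numeric(t); C_A <- as.numeric(C_A)
  if (length(t) != length(C_A)) stop("t and C_A lengths differ", call. = FALSE)
  if (any(diff(t) < 0)) stop("time must be non-decreasing", call. = FALSE)
  if (C_A[1] <= 0) stop("C_A(0) must be positive", call. = FALSE)
  out <- data.frame(t = t, C_A = C_A)
  if (!is.null(C_B)) {
    if (length(C_B) != length(t)) stop("C_B length mismatch", call. = FALSE)
    out$C_B <- as.numeric(C_B)
  }
  attr(out, "provenance") <- provenance
  attr(out, "noise_rsd") <- noise_rsd
  attr(out, "seed") <- seed
  class(out) <- c("kinetic_trace", "data.frame")
  out
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("<kinetic_trace> %d points, t = 0-%g s, C_A(0) = %.4g M (%s%s)\n",
              nrow(x), max(x$t), x$C_A[1], attr(x, "provenance"),
              if (attr(x, "noise_rsd") > 0)
                sprintf(", %.1f%% rsd noise", 100 * attr(x, "noise_rsd"))
              else ""))
  invisible(x)
}

#' Default time grid through five estimated half-lives
#'
#' 200 log-spaced points (plus t = 0) out to five times the eta-order
#' half-life.
#'
#' @param params an [eta_params()].
#' @param n number of points.
#' @param n_half number of half-lives to cover.
#' @return Numeric time grid, s.
#' @export
default_time_grid <- function(params, n = 200, n_half = 5) {
  t_end <- n_half * half_life(params)
  c(0, exp(seq(log(t_end / 1e3), log(t_end), length.out = n - 1)))
}

#' Simulate the unapproximated per-wavelength rate law
#'
#' Integrates
#' dC_A/dt = -Sum_lambda Phi P0 (A_A / A_tot) (1 - 10^-A_tot)
#' with per-wavelength absorbances A = l_irr eps C, using adaptive lsoda at
#' rtol 1e-9. This is the reference against which the lumped closed form is
#' an approximation. The photoproduct follows by mass balance.
#'
#' @param species a [photo_species()].
#' @param lamp a [lamp_profile()].
#' @param geom a [reactor_geometry()].
#' @param C0 initial reactant concentration, M.
#' @param t_grid times, s (default: five half-lives from the eta-order
#'   parameterisation).
#' @param rtol,atol integrator tolerances.
#' @return A `kinetic_trace` with both species.
#' @export
simulate_perwavelength <- function(species, lamp, geom, C0, t_grid = NULL,
                                   rtol = 1e-9, atol = 1e-15 * C0) {
  w <- species_lamp_window(species, lamp)
  sp <- w$species
  epsA <- sp$eps_A$value; epsB <- sp$eps_B$value
  phi <- sp$qy$value; P0 <- w$flux
  l <- geom$l_irr_cm
  if (is.null(t_grid)) {
    t_grid <- default_time_grid(eta_params_from_system(species, lamp, geom, C0))
  }
  rhs <- function(t, y, parms) {
    CA <- max(y[1], 0)
    CB <- max(C0 - CA, 0)
    A_A <- l * epsA * CA
    A_tot <- A_A + l * epsB * CB
    Fl <- photokinetic_factor(A_tot, reduced = FALSE)
    list(-sum(phi * P0 * A_A * Fl))
  }
  sol <- deSolve::ode(y = c(C_A = C0), times = t_grid, func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop(sprintf("integration failed at t = %g s (last good state C_A = %g M)",
                 max(sol[, "time"]), sol[nrow(sol), "C_A"]), call. = FALSE)
  }
  CA <- pmin(pmax(sol[, "C_A"], 0), C0)
  kinetic_trace(t_grid, CA, C_B = C0 - CA, provenance = "simulated")
}

#' Simulate the lumped (Delta-lambda-summed) rate law
#'
#' Integrates dC_A/dt = -(Sum Phi eps_A P0) l_irr F(t) C_A, with the
#' photokinetic factor F built from the window-summed total absorbance, in
#' either its full or its reduced (1/A_tot) form. The reduced-form solution
#' is exactly the Lambert-W closed form of [concentration_at_time()].
#'
#' @inheritParams simulate_perwavelength
#' @param factor_form `"full"` or `"reduced"`.
#' @return A `kinetic_trace` with both species.
#' @export
simulate_lumped <- function(species, lamp, geom, C0, t_grid = NULL,
                            factor_form = c("full", "reduced"),
                            rtol = 1e-9, atol = 1e-15 * C0) {
  factor_form <- match.arg(factor_form)
  w <- species_lamp_window(species, lamp)
  sp <- w$species
  s <- sum_window(sp)
  rate_sum <- sum(sp$qy$value * sp$eps_A$value * w$flux)  # Sum Phi eps_A P0
  l <- geom$l_irr_cm
  if (is.null(t_grid)) {
    t_grid <- default_time_grid(eta_params_from_system(species, lamp, geom, C0))
  }
  reduced <- factor_form == "reduced"
  rhs <- function(t, y, parms) {
    CA <- max(y[1], 0)
    CB <- max(C0 - CA, 0)
    A_tot <- l * (s$eps_A * CA + s$eps_B * CB)
    Fd <- if (reduced && A_tot > 0) 1 / A_tot
          else photokinetic_factor(A_tot, reduced = FALSE)
    list(-rate_sum * l * Fd * CA)
  }
  sol <- deSolve::ode(y = c(C_A = C0), times = t_grid, func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop(sprintf("integration failed at t = %g s (last good state C_A = %g M)",
                 max(sol[, "time"]), sol[nrow(sol), "C_A"]), call. = FALSE)
  }
  CA <- pmin(pmax(sol[, "C_A"], 0), C0)
  kinetic_trace(t_grid, CA, C_B = C0 - CA, provenance = "simulated")
}

#' Compare two kinetic traces on a shared time grid
#'
#' @param a,b `kinetic_trace` objects on identical time grids.
#' @param threshold relative-deviation level above which the comparison is
#'   flagged.
#' @return A list with `max_rel`, `mean_rel` (pointwise relative deviations
#'   of C_A, taking `a` as reference) and logical `flagged`.
#' @export
compare_traces <- function(a, b, threshold = 0.01) {
  if (!isTRUE(all.equal(a$t, b$t))) {
    stop("traces are on different time grids", call. = FALSE)
  }
  denom <- pmax(abs(a$C_A), 1e-12 * a$C_A[1])
  rel <- abs(a$C_A - b$C_A) / denom
  list(max_rel = max(rel), mean_rel = mean(rel),
       flagged = max(rel) > threshold, threshold = threshold)
}
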