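# Closed-form eta-order kinetics for AB(1Phi) photoreactions with an
# absorbing photoproduct under polychromatic light.
#
# Rate law (reduced photokinetic factor):
#   dC_A/dt = -(Sum Phi eps_A P0) * l_irr * F(t) * C_A
# integrates to the implicit eta-order law
#   eta(t) = (C_A(t) - C0) + alpha2 * ln(C_A(t)/C0) = -k_eta * t
# with
#   alpha1 = 1 / (l_irr * Sum(eps_A - eps_B))
#   alpha2 = C0 * Sum(eps_B) / Sum(eps_A - eps_B)
#   k_eta  = Sum(Phi eps_A P0) / Sum(eps_A - eps_B)
# all sums running over the lamp's emission support.

sum_window <- function(species) {
  list(eps_A = sum(species$eps_A$value),
       eps_B = sum(species$eps_B$value),
       diff = sum(species$eps_A$value - species$eps_B$value))
}

#' Eta-order model parameters
#'
#' The complete parameterisation of one eta-order system: the two spectral
#' constants alpha1 and alpha2 (both in M), the overall rate constant k_eta
#' (M s^-1, the dimension of a zeroth-order rate constant), the initial
#' reactant concentration and the lamp emission window the sums were taken
#' over.
#'
#' @param alpha1,alpha2 spectral constants, M.
#' @param k_eta overall rate constant, M s^-1.
#' @param C0 initial reactant concentration, M (> 0).
#' @param window numeric length-2, \[lambda_a, lambda_b\] nm (optional
#'   bookkeeping).
#' @return An object of class `eta_params`.
#' @export
eta_params <- function(alpha1, alpha2, k_eta, C0, window = c(NA, NA)) {
  if (!is.finite(C0) || C0 <= 0) stop("C0 must be positive", call. = FALSE)
  if (!is.finite(alpha2)) stop("alpha2 must be finite", call. = FALSE)
  if (is.finite(alpha1) && is.finite(alpha2) && alpha1 * alpha2 < 0) {
    warning("alpha1 and alpha2 have opposite signs; both should share the ",
            "sign of Sum(eps_A - eps_B) over the window")
  }
  if (alpha2 < 0) {
    warning("alpha2 < 0 (Sum eps_B > Sum eps_A over the window): the ",
            "closed form is evaluated by root bracketing in this regime")
  }
  structure(list(alpha1 = alpha1, alpha2 = alpha2, k_eta = k_eta,
                 C0 = C0, window = window),
            class = "eta_params")
}

#' @export
print.eta_params <- function(x, ...) {
  cat(sprintf(paste0("<eta_params> alpha1 = %.4g M, alpha2 = %.4g M, ",
                     "k_eta = %.4g M s-1, C0 = %.4g M\n"),
              x$alpha1, x$alpha2, x$k_eta, x$C0))
  invisible(x)
}

#' Spectral constant alpha1
#'
#' alpha1 = 1 / (l_irr * Sum(eps_A - eps_B)) over the active window, in M.
#' The species should already be restricted to the lamp support
#' ([restrict_to_support()]).
#'
#' @param species a [photo_species()] on the active window.
#' @param geom a [reactor_geometry()].
#' @return alpha1 in M.
#' @export
alpha1 <- function(species, geom = reactor_geometry()) {
  d <- sum_window(species)$diff
  if (d == 0) {
    stop(paste("Sum(eps_A - eps_B) = 0 over the window: degenerate",
               "eta-order system; use the first-order limit",
               "(k1 = Sum(Phi eps_A P0)/(C0 Sum eps_B))"), call. = FALSE)
  }
  1 / (geom$l_irr_cm * d)
}

#' Spectral constant alpha2
#'
#' alpha2 = C0 * Sum(eps_B) / Sum(eps_A - eps_B) over the active window, in
#' M. Zero when the photoproduct is transparent over the window.
#'
#' @param species a [photo_species()] on the active window.
#' @param C0 initial reactant concentration, M.
#' @return alpha2 in M.
#' @export
alpha2 <- function(species, C0) {
  s <- sum_window(species)
  if (s$diff == 0) {
    stop(paste("Sum(eps_A - eps_B) = 0 over the window: degenerate",
               "eta-order system; use the first-order limit"), call. = FALSE)
  }
  C0 * s$eps_B / s$diff
}

#' Overall eta-order rate constant from per-wavelength attributes
#'
#' k_eta = Sum(Phi eps_A P0) / Sum(eps_A - eps_B) over the lamp support, in
#' M s^-1. Independent of the initial concentration and of the optical path;
#' proportional to the quantum yields and to the lamp flux.
#'
#' @param species a [photo_species()].
#' @param lamp a [lamp_profile()].
#' @return k_eta in M s^-1.
#' @export
k_eta_from_attributes <- function(species, lamp) {
  w <- species_lamp_window(species, lamp)
  sp <- w$species
  d <- sum_window(sp)$diff
  if (d == 0) {
    stop("Sum(eps_A - eps_B) = 0 over the window: degenerate eta-order system",
         call. = FALSE)
  }
  sum(sp$qy$value * sp$eps_A$value * w$flux) / d
}

#' Build eta-order parameters from spectra, lamp and geometry
#'
#' Convenience constructor evaluating alpha1, alpha2 and k_eta over the
#' lamp's emission support.
#'
#' @param species a [photo_species()].
#' @param lamp a [lamp_profile()].
#' @param geom a [reactor_geometry()].
#' @param C0 initial reactant concentration, M.
#' @return An [eta_params()] object.
#' @export
eta_params_from_system <- function(species, lamp, geom, C0) {
  sp <- restrict_to_support(species, lamp)
  eta_params(alpha1 = alpha1(sp, geom),
             alpha2 = alpha2(sp, C0),
             k_eta = k_eta_from_attributes(species, lamp),
             C0 = C0,
             window = lamp$support)
}

#' Total absorbance over the active window
#'
#' A_tot = Sum_lambda l_irr (eps_A C_A + eps_B C_B), dimensionless.
#'
#' @param species a [photo_species()] on the active window.
#' @param geom a [reactor_geometry()].
#' @param C_A,C_B concentrations, M (>= 0); vectorised.
#' @return Total absorbance (dimensionless).
#' @export
total_absorbance <- function(species, geom, C_A, C_B = 0) {
  if (any(C_A < 0) || any(C_B < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  s <- sum_window(species)
  geom$l_irr_cm * (s$eps_A * C_A + s$eps_B * C_B)
}

#' Photokinetic factor
#'
#' Full form F(A) = (1 - 10^-A)/A, with the continuous limit ln(10) at
#' A = 0; reduced form 1/A, valid when A >> 1 (the neglected 10^-A term is
#' below 1% for A >= 2).
#'
#' @param A_tot total absorbance, >= 0; vectorised.
#' @param reduced logical; use the high-absorbance reduced form.
#' @return The factor, dimensionless.
#' @export
photokinetic_factor <- function(A_tot, reduced = FALSE) {
  if (any(A_tot < 0)) stop("absorbance must be non-negative", call. = FALSE)
  if (reduced) {
    if (any(A_tot == 0)) {
      stop("reduced photokinetic factor undefined at A_tot = 0", call. = FALSE)
    }
    return(1 / A_tot)
  }
  out <- ifelse(A_tot < 1e-12, log(10), -expm1(-A_tot * log(10)) / A_tot)
  # guard the removable singularity elementwise without catastrophic cancellation
  out
}

#' Eta transform of a concentration
#'
#' eta(C) = (C - C0) + alpha2 * ln(C/C0), in M. Equals -k_eta * t along an
#' eta-order trace; zero at C = C0, non-positive and decreasing in
#' decreasing C when alpha2 > 0.
#'
#' @param C_t concentration(s) at time t, M, in (0, C0\].
#' @param params an [eta_params()] (only `alpha2` and `C0` used).
#' @return eta in M; vectorised over `C_t`.
#' @export
eta_of_t <- function(C_t, params) {
  if (any(C_t <= 0)) stop("concentration must be positive", call. = FALSE)
  (C_t - params$C0) + params$alpha2 * log(C_t / params$C0)
}

# Principal-branch Lambert W evaluated as W0(exp(x)): solves w + log(w) = x,
# w > 0, by Newton iteration on this log form, which never overflows however
# large x (= b/alpha2) gets. f(w) = w + log w - x is concave and strictly
# increasing on (0, Inf) with a unique root, so Newton converges from any
# positive start; iterations are bounded as a belt-and-braces guard.
lambert_w_of_exp <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi)) return(NA_real_)
    if (xi < -700) return(exp(xi))  # w = e^x to beyond double precision
    w <- if (xi > 1) xi - log(xi) else exp(xi)
    for (i in 1:100) {
      f <- w + log(w) - xi
      step <- f / (1 + 1 / w)
      w_new <- w - step
      if (w_new <= 0) w_new <- w / 2
      if (abs(w_new - w) <= 1e-16 * w_new) {
        w <- w_new
        break
      }
      w <- w_new
    }
    w
  }, numeric(1))
}

# Bracketed root of (C - C0) + a2*log(C/C0) + k*t = 0 in (0, C0]
eta_root_bisect <- function(t, C0, a2, k, lower_frac = 1e-18,
                            tol = 1e-14) {
  vapply(t, function(ti) {
    # for a2 > 0, g is strictly increasing with g(0+) = -Inf, g(C0) = k t;
    # for a2 < 0 (k < 0) it decreases from +Inf through the physical root
    g <- function(C) (C - C0) + a2 * log(C / C0) + k * ti
    if (ti == 0) return(C0)
    lo <- lower_frac * C0
    hi <- C0
    if (a2 > 0 && g(lo) > 0) return(0)  # depleted beyond bracket resolution
    r <- stats::uniroot(g, c(lo, hi), tol = tol * C0, maxiter = 2000)
    r$root
  }, numeric(1))
}

#' Reactant concentration at time t (explicit eta-order inversion)
#'
#' Inverts the implicit integrated rate law eta(C) = -k_eta t explicitly via
#' the principal branch of the Lambert W function:
#' C(t) = alpha2 * W0( (1/alpha2) * exp(b/alpha2) ),
#' b = C0 + alpha2 ln C0 - k_eta t (alpha2 > 0). The result is verified to
#' satisfy the implicit law to 1e-10 relative; if the check fails (or for
#' alpha2 <= 0, where the W branch structure changes) a bracketed bisection
#' on the implicit equation is used instead.
#'
#' @param t time(s), s, >= 0; vectorised.
#' @param params an [eta_params()].
#' @return C_A(t) in M, monotone non-increasing in t.
#' @export
concentration_at_time <- function(t, params) {
  if (any(t < 0)) stop("time must be non-negative", call. = FALSE)
  C0 <- params$C0
  a2 <- params$alpha2
  k <- params$k_eta
  if (a2 == 0) {
    # zeroth-order form: C = C0 - k t, floored at 0
    return(pmax(C0 - k * t, 0))
  }
  if (a2 < 0) {
    return(eta_root_bisect(t, C0, a2, k))
  }
  b <- C0 + a2 * log(C0) - k * t
  x <- b / a2 - log(a2)            # W argument is exp(x)
  C <- a2 * lambert_w_of_exp(x)
  C <- pmin(C, C0)
  # residual audit of the implicit law; fall back where it fails
  resid <- abs((C - C0) + a2 * log(pmax(C, .Machine$double.xmin) / C0) + k * t)
  bad <- which(!is.finite(C) | (C > 0 & resid > 1e-10 * C0))
  if (length(bad)) {
    C[bad] <- eta_root_bisect(t[bad], C0, a2, k)
  }
  C
}

#' Eta-order half-life
#'
#' t_1/2 = (0.5 C0 + alpha2 ln 2) / k_eta, s. Depends on the initial
#' concentration (unlike a first-order half-life) and on all spectral
#' attributes through alpha2 and k_eta; halves when the lamp flux doubles.
#'
#' @param params an [eta_params()] with `k_eta > 0`.
#' @return Half-life in s.
#' @export
half_life <- function(params) {
  if (params$k_eta <= 0) stop("half-life requires k_eta > 0", call. = FALSE)
  (0.5 * params$C0 + params$alpha2 * log(2)) / params$k_eta
}

#' Initial photoreaction velocity
#'
#' r0 = -C0 k_eta l_irr Sum(eps_A - eps_B) F(A_tot(0)) with the full-form
#' photokinetic factor, in M s^-1. Approximately independent of C0 whenever
#' A_tot(0) >> 1.
#'
#' @param params an [eta_params()].
#' @param species a [photo_species()] on the active window.
#' @param geom a [reactor_geometry()].
#' @return Initial velocity, M s^-1 (negative for a degrading reactant).
#' @export
initial_velocity <- function(params, species, geom = reactor_geometry()) {
  d <- sum_window(species)$diff
  A0 <- total_absorbance(species, geom, C_A = params$C0, C_B = 0)
  F0 <- photokinetic_factor(A0, reduced = FALSE)
  -params$C0 * params$k_eta * geom$l_irr_cm * d * F0
}

#' Validity audit of an eta-order analysis
#'
#' Checks the working assumptions of the reduced-factor closed form:
#' the total absorbance must stay in the high-absorbance regime
#' (A_tot >= `a_threshold`, default 2, keeping the neglected 10^-A term
#' under 1%), the initial concentration must sit inside the declared
#' Beer-Lambert linearity range, and Sum(eps_A - eps_B) over the window
#' should be positive (the only regime the model is demonstrated in).
#'
#' @param species a [photo_species()] on the active window.
#' @param geom a [reactor_geometry()].
#' @param params an [eta_params()].
#' @param trace_end_absorbance smallest A_tot reached along the trace
#'   (e.g. A_tot at full conversion).
#' @param linearity_range optional c(C_min, C_max) in M from the calibration
#'   graph.
#' @param a_threshold high-absorbance threshold, default 2.
#' @return A list of class `eta_validity` with logical flags
#'   `reduced_factor_invalid`, `linearity_exceeded`, `window_sign_negative`
#'   and an `ok` summary.
#' @export
validity_check <- function(species, geom, params, trace_end_absorbance,
                           linearity_range = NULL, a_threshold = 2) {
  flags <- list(
    reduced_factor_invalid = trace_end_absorbance < a_threshold,
    linearity_exceeded = !is.null(linearity_range) &&
      (params$C0 < linearity_range[1] || params$C0 > linearity_range[2]),
    window_sign_negative = sum_window(species)$diff <= 0
  )
  flags$ok <- !any(unlist(flags))
  class(flags) <- "eta_validity"
  flags
}

#' @export
print.eta_validity <- function(x, ...) {
  cat("<eta_validity>",
      if (x$ok) "all checks passed" else "flags raised:", "\n")
  if (x$reduced_factor_invalid)
    cat("  - A_tot drops below the high-absorbance threshold;",
        "reduced photokinetic factor unreliable\n")
  if (x$linearity_exceeded)
    cat("  - C0 outside the declared Beer-Lambert linearity range\n")
  if (x$window_sign_negative)
    cat("  - Sum(eps_A - eps_B) <= 0 over the window\n")
  invisible(x)
}
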