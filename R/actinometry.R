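# Drug-actinometry on eta-order kinetics. A drug-lamp pair is calibrated by
# regressing k_eta against the lamp's total photon flux P0,tot; the slope
# beta_eta converts a measured k_eta back into an unknown intensity.
# Calibrations are lamp-specific: beta_eta depends on the lamp's normalised
# emission shape through Sum(Phi eps_A P0)/P0,tot, so a calibration
# transferred to a lamp with a different profile gives a biased intensity.

#' Actinometer calibration for one drug-lamp pair
#'
#' Least-squares line k_eta = beta_eta * P0,tot (+ intercept), fitted over
#' at least four distinct lamp intensities. beta_eta is stored as the
#' literal ratio of k_eta (M s^-1) to P0,tot (einstein dm^-3 s^-1); its
#' conventional reporting unit is M^-1 s.
#'
#' @param points data frame with columns `p0_tot` and `k_eta` (one row per
#'   intensity), or a list of such pairs.
#' @param drug_id,lamp_id identities of the actinometer drug and of the lamp
#'   (both mandatory; the calibration is unusable without its lamp).
#' @param through_origin logical; the theoretical line has no intercept but
#'   experimental calibrations carry small ones, so the default keeps a free
#'   intercept.
#' @return An object of class `actinometer_calibration` with `beta_eta`,
#'   `intercept`, `r2`, `n`, `points`, `drug_id`, `lamp_id`.
#' @export
calibrate_actinometer <- function(points, drug_id, lamp_id,
                                  through_origin = FALSE) {
  if (!is.data.frame(points)) points <- do.call(rbind.data.frame, points)
  if (!all(c("p0_tot", "k_eta") %in% names(points))) {
    stop("points must have columns p0_tot and k_eta", call. = FALSE)
  }
  if (missing(drug_id) || missing(lamp_id) || !nzchar(lamp_id)) {
    stop("drug_id and lamp_id are mandatory", call. = FALSE)
  }
  n <- nrow(points)
  if (n < 4 || length(unique(points$p0_tot)) < 4) {
    stop(paste("actinometric calibration requires at least 4 distinct lamp",
               "intensities"), call. = FALSE)
  }
  fit <- if (through_origin) stats::lm(k_eta ~ 0 + p0_tot, data = points)
         else stats::lm(k_eta ~ p0_tot, data = points)
  sm <- suppressWarnings(summary(fit))
  slope_row <- if (through_origin) 1 else 2
  new_actinometer_calibration(
    beta_eta = sm$coefficients[slope_row, 1],
    intercept = if (through_origin) 0 else sm$coefficients[1, 1],
    r2 = sm$r.squared,
    n = n, points = points[, c("p0_tot", "k_eta")],
    drug_id = drug_id, lamp_id = lamp_id)
}

new_actinometer_calibration <- function(beta_eta, intercept, r2, n, points,
                                        drug_id, lamp_id) {
  structure(list(beta_eta = beta_eta, intercept = intercept, r2 = r2,
                 n = n, points = points, drug_id = drug_id,
                 lamp_id = lamp_id, beta_unit = "M-1 s"),
            class = "actinometer_calibration")
}

#' Actinometer calibration from published line coefficients
#'
#' @param beta_eta slope (M^-1 s as conventionally reported).
#' @param intercept intercept, M s^-1.
#' @param r2 published correlation coefficient.
#' @param drug_id,lamp_id identities.
#' @param n number of intensities behind the published line (NA if unknown).
#' @return An `actinometer_calibration`.
#' @export
actinometer_calibration <- function(beta_eta, intercept = 0, r2 = NA_real_,
                                    drug_id, lamp_id, n = NA_integer_) {
  new_actinometer_calibration(beta_eta, intercept, r2, n,
                              points = data.frame(p0_tot = numeric(0),
                                                  k_eta = numeric(0)),
                              drug_id = drug_id, lamp_id = lamp_id)
}

#' @export
print.actinometer_calibration <- function(x, ...) {
  cat(sprintf(
    "<actinometer_calibration> %s / %s: k_eta = %.6g x P0,tot %+.3g (r2 = %.4g, n = %s)\n",
    x$drug_id, x$lamp_id, x$beta_eta, x$intercept, x$r2, x$n))
  invisible(x)
}

#' Invert a calibration: unknown lamp intensity from a measured k_eta
#'
#' P0,tot = (k_eta - intercept) / beta_eta. Because beta_eta is specific to
#' the calibration lamp's emission shape, using a calibration from another
#' lamp biases the inferred intensity: pass the identity of the lamp
#' actually used via `lamp_id` to get a warning (default) or a refusal
#' (`strict = TRUE`) on mismatch.
#'
#' @param k_eta_unk measured overall rate constant, M s^-1 (> 0).
#' @param cal an [actinometer_calibration()].
#' @param lamp_id identity of the lamp that produced `k_eta_unk` (optional).
#' @param strict refuse on lamp mismatch instead of warning.
#' @return Total photon flux P0,tot, einstein dm^-3 s^-1. Zero or negative
#'   results (k_eta at or below the intercept) are returned with a warning:
#'   the measurement sits below the calibration range.
#' @export
unknown_intensity <- function(k_eta_unk, cal, lamp_id = NULL, strict = FALSE) {
  stopifnot(inherits(cal, "actinometer_calibration"))
  if (k_eta_unk <= 0) stop("k_eta must be positive", call. = FALSE)
  if (!is.null(lamp_id) && !identical(lamp_id, cal$lamp_id)) {
    msg <- sprintf(paste("lamp mismatch: calibration is for '%s' but the",
                         "measurement used '%s'; actinometers are",
                         "lamp-specific"), cal$lamp_id, lamp_id)
    if (strict) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  p <- (k_eta_unk - cal$intercept) / cal$beta_eta
  if (p <= 0) {
    warning("inferred intensity is not positive: k_eta at or below the ",
            "calibration intercept (below calibration range)", call. = FALSE)
  }
  p
}

#' Cross-lamp inversion discrepancy
#'
#' Percent error committed by inverting a k_eta measured under the `true`
#' calibration's lamp through a calibration built on a different lamp:
#' 100 |P_true - P_wrong| / P_true.
#'
#' @param k_eta measured rate constant, M s^-1.
#' @param cal_true calibration of the lamp actually used.
#' @param cal_wrong calibration wrongly applied.
#' @return Discrepancy in percent.
#' @export
cross_lamp_discrepancy <- function(k_eta, cal_true, cal_wrong) {
  p_true <- unknown_intensity(k_eta, cal_true)
  p_wrong <- unknown_intensity(k_eta, cal_wrong)
  100 * abs(p_true - p_wrong) / p_true
}

#' Predicted beta_eta from per-wavelength attributes
#'
#' beta_eta = Sum(Phi eps_A P0) / (P0,tot * Sum(eps_A - eps_B)) over the
#' lamp support. Invariant under uniform scaling of the lamp profile, so it
#' characterises the lamp's shape, not its intensity; when the individual
#' wavelength attributes are known this removes the need for experimental
#' calibration.
#'
#' @param species a [photo_species()].
#' @param lamp a [lamp_profile()].
#' @return Predicted beta_eta (ratio of M s^-1 to einstein dm^-3 s^-1;
#'   conventionally M^-1 s).
#' @export
beta_from_attributes <- function(species, lamp) {
  k_eta_from_attributes(species, lamp) / total_flux(lamp)
}

#' Run the full actinometric protocol
#'
#' Executes the calibration-then-measurement workflow on a set of kinetic
#' traces: per calibration intensity, compute eta(t), fit the eta-order
#' line and extract k_eta; regress k_eta against P0,tot to obtain beta_eta
#' (at least four intensities); fit the unknown-intensity trace the same
#' way and invert the calibration to report the unknown P0,tot.
#'
#' @param config a list with elements:
#'   \describe{
#'     \item{alpha2}{spectral constant, M (or supply `species`, `lamp`,
#'       `geom`, `C0` and it is computed).}
#'     \item{calibration}{list of `list(p0_tot = , trace = )` entries,
#'       >= 4 intensities; traces are `kinetic_trace` objects or CSV paths.}
#'     \item{unknown_trace}{`kinetic_trace` or CSV path (optional).}
#'     \item{drug_id, lamp_id}{identities (lamp_id mandatory).}
#'     \item{through_origin}{flag for both regression stages (default
#'       FALSE for the calibration line, TRUE for eta fits).}
#'   }
#' @return A list of class `actinometry_report`: per-intensity `eta_fits`,
#'   the `calibration`, and when an unknown trace is given, `k_eta_unknown`
#'   and `p0_tot_unknown`.
#' @export
run_protocol <- function(config) {
  req <- function(name) {
    if (is.null(config[[name]])) {
      stop(sprintf("protocol config is missing '%s'", name), call. = FALSE)
    }
    config[[name]]
  }
  lamp_id <- req("lamp_id")
  drug_id <- if (is.null(config$drug_id)) "actinometer" else config$drug_id
  a2 <- config$alpha2
  if (is.null(a2)) {
    sp <- restrict_to_support(req("species"), req("lamp"))
    a2 <- alpha2(sp, req("C0"))
  }
  cal_in <- req("calibration")
  if (length(cal_in) < 4) {
    stop("protocol requires traces at >= 4 distinct lamp intensities",
         call. = FALSE)
  }
  load_trace <- function(x) {
    if (inherits(x, "kinetic_trace")) x else read_trace_csv(x)
  }
  eta_fits <- lapply(cal_in, function(entry) {
    tr <- load_trace(entry$trace)
    fit <- fit_eta_trace(tr, alpha2 = a2, C0 = config$C0,
                         through_origin = TRUE)
    list(p0_tot = entry$p0_tot, fit = fit)
  })
  pts <- data.frame(
    p0_tot = vapply(eta_fits, `[[`, numeric(1), "p0_tot"),
    k_eta = vapply(eta_fits, function(e) e$fit$k_eta, numeric(1)))
  cal <- calibrate_actinometer(pts, drug_id = drug_id, lamp_id = lamp_id,
                               through_origin = isTRUE(config$through_origin))
  out <- list(eta_fits = eta_fits, calibration = cal, alpha2 = a2)
  if (!is.null(config$unknown_trace)) {
    tr <- load_trace(config$unknown_trace)
    fit_unk <- fit_eta_trace(tr, alpha2 = a2, C0 = config$C0,
                             through_origin = TRUE)
    out$k_eta_unknown <- fit_unk$k_eta
    out$p0_tot_unknown <- unknown_intensity(fit_unk$k_eta, cal,
                                            lamp_id = lamp_id)
  }
  class(out) <- "actinometry_report"
  out
}

#' @export
print.actinometry_report <- function(x, ...) {
  cat("<actinometry_report>\n")
  print(x$calibration)
  if (!is.null(x$p0_tot_unknown)) {
    cat(sprintf("  unknown lamp intensity: P0,tot = %.6g einstein dm-3 s-1 (k_eta = %.6g M s-1)\n",
                x$p0_tot_unknown, x$k_eta_unknown))
  }
  invisible(x)
}

#' Published NIF calibration lines for the four study lamps
#'
#' The four k_eta-versus-P0,tot correlation lines reported for Nifedipine
#' (2.69e-5 M in ethanol) on a 254-nm short-wavelength lamp (#1), a 302-nm
#' mid-wavelength lamp (#2), a 365-nm long-wavelength lamp (#3) and a
#' 254/365-nm mixed-wavelength lamp (#4): slopes 548.26, 1109.8, 1365.3 and
#' 779.26 with intercepts -0.4e-3, 1.2e-3, 1.3e-3 and 1.5e-3 M s^-1. The
#' lamp labels follow the published correlation table; note that the
#' accompanying discussion associates the 1365.3 slope with the
#' mixed-wavelength lamp, so when working by slope value select on
#' `beta_eta` rather than on the label.
#'
#' @return A named list of [actinometer_calibration()] objects
#'   (`lamp1`..`lamp4`).
#' @export
nif_lamp_calibrations <- function() {
  mk <- function(beta, icpt, lamp) {
    actinometer_calibration(beta_eta = beta, intercept = icpt, r2 = 0.99,
                            drug_id = "NIF", lamp_id = lamp)
  }
  list(lamp1 = mk(548.26, -0.4e-3, "lamp1"),
       lamp2 = mk(1109.8, 1.2e-3, "lamp2"),
       lamp3 = mk(1365.3, 1.3e-3, "lamp3"),
       lamp4 = mk(779.26, 1.5e-3, "lamp4"))
}

#' Published summed-absorptivity and Lamp #4 beta_eta reference values
#'
#' Reference constants for the two study drugs: total molar absorptivities
#' of reactant and photoproduct summed at 1 nm steps over the measured
#' range (M^-1 cm^-1), and the mixed-wavelength-lamp beta_eta values
#' (M^-1 s) for both actinometer drugs.
#'
#' @return A list with `dbz` (`sum_eps_A`, `sum_eps_B`), `nif` (idem) and
#'   `beta_lamp4` (`nif`, `dbz`).
#' @export
drug_reference_values <- function() {
  list(dbz = list(sum_eps_A = 1150028.96, sum_eps_B = 344785.15),
       nif = list(sum_eps_A = 1920219.56, sum_eps_B = 1936173.24),
       beta_lamp4 = list(nif = 1365, dbz = 211))
}
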