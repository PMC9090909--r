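# Physical constants (CODATA 2018, exact SI values)
PLANCK_H <- 6.62607015e-34   # J s
SPEED_C <- 2.99792458e8      # m s^-1
AVOGADRO <- 6.02214076e23    # mol^-1

#' Wavelength-indexed spectrum
#'
#' The basic carrier for every per-wavelength quantity in the package:
#' molar absorption coefficients, quantum yields, lamp spectral irradiance
#' and volumetric photon flux. Wavelengths are in nanometres on a strictly
#' increasing grid (1 nm native step throughout); the unit of the value
#' column is carried as metadata, never inferred.
#'
#' @param wavelength numeric, nm, strictly increasing.
#' @param value numeric, same length, all finite.
#' @param unit one of `"M-1cm-1"`, `"dimensionless"`, `"mW cm-2 nm-1"`,
#'   `"einstein dm-3 s-1"`.
#' @return An object of class `spectrum`: a data frame with columns
#'   `wavelength` and `value` and a `unit` attribute.
#' @export
spectrum <- function(wavelength, value,
                     unit = c("dimensionless", "M-1cm-1",
                              "mW cm-2 nm-1", "einstein dm-3 s-1")) {
  unit <- match.arg(unit)
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) != length(value)) {
    stop("wavelength and value must have the same length", call. = FALSE)
  }
  if (length(wavelength) < 1L) stop("empty spectrum", call. = FALSE)
  if (any(!is.finite(wavelength)) || any(!is.finite(value))) {
    stop("spectrum contains non-finite entries", call. = FALSE)
  }
  if (any(diff(wavelength) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  out <- data.frame(wavelength = wavelength, value = value)
  attr(out, "unit") <- unit
  class(out) <- c("spectrum", "data.frame")
  out
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %.0f-%.0f nm, unit: %s\n",
              nrow(x), min(x$wavelength), max(x$wavelength),
              spectrum_unit(x)))
  invisible(x)
}

#' Unit metadata of a spectrum
#' @param x a `spectrum`.
#' @return The unit string.
#' @export
spectrum_unit <- function(x) attr(x, "unit")

grid_step <- function(x) {
  if (nrow(x) < 2L) return(NA_real_)
  steps <- diff(x$wavelength)
  if (max(steps) - min(steps) > 1e-9) return(NA_real_)
  steps[1]
}

#' Align spectra onto a common wavelength grid
#'
#' Linearly interpolates each spectrum onto `grid`. Extrapolation is
#' forbidden: every spectrum must cover the full requested grid.
#'
#' @param spectra a list of `spectrum` objects (a single spectrum is
#'   accepted and wrapped).
#' @param grid numeric wavelength grid (nm), strictly increasing.
#' @return A list of aligned `spectrum` objects (units preserved).
#' @export
align_spectra <- function(spectra, grid) {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing", call. = FALSE)
  lapply(spectra, function(s) {
    if (min(grid) < min(s$wavelength) - 1e-9 ||
        max(grid) > max(s$wavelength) + 1e-9) {
      stop(sprintf(
        "requested grid [%g, %g] nm outside spectrum range [%g, %g] nm",
        min(grid), max(grid), min(s$wavelength), max(s$wavelength)),
        call. = FALSE)
    }
    v <- if (nrow(s) == 1L) rep(s$value, length(grid))  # grid == the one point
         else stats::approx(s$wavelength, s$value, xout = grid, rule = 1)$y
    spectrum(grid, v, unit = spectrum_unit(s))
  })
}

#' Reactor geometry
#'
#' Top-illuminated, collimated cuvette geometry: the optical path of the
#' irradiation light inside the medium, the irradiated surface area and the
#' irradiated solution volume. Defaults correspond to a standard 1-cm cuvette
#' holding 2 mL, lit from the top through its 1 cm^2 opening.
#'
#' @param l_irr_cm optical path of the irradiation beam, cm.
#' @param area_cm2 irradiated area, cm^2.
#' @param volume_dm3 irradiated volume, dm^3 (2e-3 dm^3 = 2 mL).
#' @return An object of class `reactor_geometry`.
#' @export
reactor_geometry <- function(l_irr_cm = 1, area_cm2 = 1, volume_dm3 = 2e-3) {
  if (any(c(l_irr_cm, area_cm2, volume_dm3) <= 0)) {
    stop("geometry dimensions must all be positive", call. = FALSE)
  }
  structure(list(l_irr_cm = l_irr_cm, area_cm2 = area_cm2,
                 volume_dm3 = volume_dm3),
            class = "reactor_geometry")
}

#' Convert spectral irradiance to volumetric photon flux
#'
#' Converts a lamp emission spectrum measured in mW cm^-2 nm^-1 (as delivered
#' by a spectroradiometer) into the photon flux per unit irradiated volume,
#' in einstein dm^-3 s^-1, required by photokinetic rate laws. Per
#' wavelength: flux = E * 1e-3 * lambda_m * area * step / (N_A h c * volume),
#' i.e. radiant power on the sample divided by the energy of one photon and
#' Avogadro's number, per irradiated volume.
#'
#' @param E a `spectrum` with unit `"mW cm-2 nm-1"`, non-negative.
#' @param geom a [reactor_geometry()].
#' @param step_nm wavelength bin width, nm; defaults to the grid step.
#' @return A `spectrum` with unit `"einstein dm-3 s-1"`.
#' @export
photon_flux_from_irradiance <- function(E, geom, step_nm = NULL) {
  stopifnot(inherits(E, "spectrum"), inherits(geom, "reactor_geometry"))
  if (spectrum_unit(E) != "mW cm-2 nm-1") {
    stop("irradiance spectrum must carry unit 'mW cm-2 nm-1'", call. = FALSE)
  }
  if (any(E$value < 0)) stop("irradiance must be non-negative", call. = FALSE)
  if (is.null(step_nm)) {
    step_nm <- grid_step(E)
    if (is.na(step_nm)) step_nm <- 1
  }
  lambda_m <- E$wavelength * 1e-9
  flux <- E$value * 1e-3 * lambda_m * geom$area_cm2 * step_nm /
    (AVOGADRO * PLANCK_H * SPEED_C * geom$volume_dm3)
  spectrum(E$wavelength, flux, unit = "einstein dm-3 s-1")
}

#' Lamp emission profile
#'
#' Wraps a photon-flux spectrum with a lamp identity and its emission
#' support: the contiguous wavelength span over which the flux is at least
#' `support_threshold` times the peak flux. All summed quantities of the
#' eta-order model (total absorptivities, sum of Phi*eps*P, total flux) are
#' restricted to this window.
#'
#' @param spec a `spectrum` in photon-flux units (`"einstein dm-3 s-1"`); a
#'   `"mW cm-2 nm-1"` spectrum is converted through `geom`.
#' @param lamp_id character lamp identity (mandatory; actinometric
#'   calibrations are lamp-specific).
#' @param support_threshold fraction of the peak flux defining the emission
#'   edges; default 1e-3.
#' @param geom geometry used only when `spec` is an irradiance spectrum.
#' @return An object of class `lamp_profile` with fields `spectrum`,
#'   `lamp_id`, `support` (c(lambda_a, lambda_b) in nm).
#' @export
lamp_profile <- function(spec, lamp_id, support_threshold = 1e-3,
                         geom = reactor_geometry()) {
  stopifnot(inherits(spec, "spectrum"))
  if (missing(lamp_id) || !nzchar(lamp_id)) {
    stop("lamp_id is mandatory: calibrations are lamp-specific", call. = FALSE)
  }
  if (spectrum_unit(spec) == "mW cm-2 nm-1") {
    spec <- photon_flux_from_irradiance(spec, geom)
  }
  if (spectrum_unit(spec) != "einstein dm-3 s-1") {
    stop("lamp spectrum must be in photon-flux units", call. = FALSE)
  }
  peak <- max(spec$value)
  if (peak <= 0) stop("lamp emits no light: empty support", call. = FALSE)
  idx <- which(spec$value >= support_threshold * peak)
  support <- c(spec$wavelength[min(idx)], spec$wavelength[max(idx)])
  structure(list(spectrum = spec, lamp_id = lamp_id, support = support),
            class = "lamp_profile")
}

#' @export
print.lamp_profile <- function(x, ...) {
  cat(sprintf("<lamp_profile> '%s', support %g-%g nm, P0,tot = %.4g einstein dm-3 s-1\n",
              x$lamp_id, x$support[1], x$support[2], total_flux(x)))
  invisible(x)
}

#' Total photon flux of a lamp over its emission support
#'
#' Sum of the per-wavelength volumetric photon flux over the lamp's support
#' window, P0,tot (einstein dm^-3 s^-1) -- the single intensity number used
#' throughout actinometry.
#'
#' @param lamp a [lamp_profile()].
#' @return Total flux, einstein dm^-3 s^-1.
#' @export
total_flux <- function(lamp) {
  stopifnot(inherits(lamp, "lamp_profile"))
  s <- lamp$spectrum
  in_sup <- s$wavelength >= lamp$support[1] & s$wavelength <= lamp$support[2]
  if (!any(in_sup)) stop("lamp support is empty", call. = FALSE)
  sum(s$value[in_sup])
}

#' Photoactive species: reactant, photoproduct and quantum yield
#'
#' Bundles the molar absorption coefficient spectra of the reactant A and of
#' its single photoproduct B together with the wavelength-dependent quantum
#' yield of the A -> B phototransformation. All three must share one grid
#' (use [align_spectra()] first if they do not).
#'
#' @param eps_A,eps_B `spectrum` objects, M^-1 cm^-1, non-negative.
#' @param qy `spectrum`, dimensionless, values in \[0, 1\].
#' @param name species label.
#' @return An object of class `photo_species`.
#' @export
photo_species <- function(eps_A, eps_B, qy, name = "species") {
  for (s in list(eps_A, eps_B, qy)) stopifnot(inherits(s, "spectrum"))
  if (!isTRUE(all.equal(eps_A$wavelength, eps_B$wavelength)) ||
      !isTRUE(all.equal(eps_A$wavelength, qy$wavelength))) {
    stop("eps_A, eps_B and qy must share one wavelength grid; align first",
         call. = FALSE)
  }
  if (any(eps_A$value < 0) || any(eps_B$value < 0)) {
    stop("absorption coefficients must be non-negative", call. = FALSE)
  }
  if (any(qy$value < 0) || any(qy$value > 1)) {
    stop("quantum yields must lie in [0, 1]", call. = FALSE)
  }
  structure(list(eps_A = eps_A, eps_B = eps_B, qy = qy, name = name),
            class = "photo_species")
}

#' @export
print.photo_species <- function(x, ...) {
  cat(sprintf("<photo_species> '%s', grid %g-%g nm (%d points)\n",
              x$name, min(x$eps_A$wavelength), max(x$eps_A$wavelength),
              nrow(x$eps_A)))
  invisible(x)
}

#' Restrict species spectra to a lamp's emission support
#'
#' Truncates the three species spectra to the lamp support window
#' \[lambda_a, lambda_b\]; every summed quantity downstream runs over this
#' window only. Idempotent.
#'
#' @param species a [photo_species()].
#' @param lamp a [lamp_profile()].
#' @return A `photo_species` on the truncated grid.
#' @export
restrict_to_support <- function(species, lamp) {
  stopifnot(inherits(species, "photo_species"), inherits(lamp, "lamp_profile"))
  wl <- species$eps_A$wavelength
  keep <- wl >= lamp$support[1] & wl <= lamp$support[2]
  if (!any(keep)) {
    stop("species grid does not overlap the lamp support", call. = FALSE)
  }
  sub <- function(s) spectrum(s$wavelength[keep], s$value[keep],
                              unit = spectrum_unit(s))
  photo_species(sub(species$eps_A), sub(species$eps_B), sub(species$qy),
                name = species$name)
}

# Align lamp flux onto the species grid restricted to the lamp support;
# returns list(species, flux_values) on the common window grid.
species_lamp_window <- function(species, lamp) {
  sp <- restrict_to_support(species, lamp)
  wl <- sp$eps_A$wavelength
  flux <- align_spectra(lamp$spectrum, wl)[[1]]
  list(species = sp, flux = flux$value, wavelength = wl)
}
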