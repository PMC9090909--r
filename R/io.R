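# Plain-text interchange: spectrum CSV (wavelength_nm,value), kinetic trace
# CSV (time_s,conc_A_M[,conc_B_M]), calibration JSON and geometry YAML.
# write o read is identity to full double precision.

parse_error <- function(fmt, ...) {
  stop(structure(class = c("etakin_parse_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}

read_strict_csv <- function(path, required_cols) {
  if (!file.exists(path)) parse_error("file not found: %s", path)
  df <- tryCatch(utils::read.csv(path, header = TRUE, check.names = FALSE),
                 error = function(e) parse_error("cannot parse %s: %s",
                                                 path, conditionMessage(e)))
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    parse_error("%s: missing required column(s) %s (line 1)", path,
                paste(missing, collapse = ", "))
  }
  for (col in names(df)) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      parse_error(paste0("%s: column '%s' is not numeric (first offending ",
                         "data line %d); note decimal commas are not ",
                         "accepted, use '.'"),
                  path, col, if (is.na(bad)) 2L else bad + 1L)
    }
  }
  df
}

#' Read a spectrum from CSV
#'
#' Expects columns `wavelength_nm,value` with a header, UTF-8, '.' decimal
#' separator. The unit is taken from a sidecar JSON (`<path>.json` with key
#' `unit`) when present, else from the `unit` argument.
#'
#' @param path CSV path.
#' @param unit fallback unit when no sidecar exists.
#' @return A [spectrum()].
#' @export
read_spectrum_csv <- function(path, unit = "dimensionless") {
  df <- read_strict_csv(path, c("wavelength_nm", "value"))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (!is.null(meta$unit)) unit <- meta$unit
  }
  if (any(diff(df$wavelength_nm) <= 0)) {
    parse_error("%s: wavelength_nm must be strictly increasing", path)
  }
  spectrum(df$wavelength_nm, df$value, unit = unit)
}

#' Write a spectrum to CSV (with unit sidecar)
#'
#' @param x a [spectrum()].
#' @param path CSV path; a `<path>.json` sidecar records the unit.
#' @param sidecar write the sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(x, path, sidecar = TRUE) {
  stopifnot(inherits(x, "spectrum"))
  df <- data.frame(wavelength_nm = x$wavelength, value = x$value)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    jsonlite::write_json(list(unit = spectrum_unit(x)), paste0(path, ".json"),
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a kinetic trace from CSV
#'
#' Expects columns `time_s,conc_A_M` and optionally `conc_B_M`. Provenance
#' metadata is read from a `<path>.json` sidecar when present.
#'
#' @param path CSV path.
#' @return A [kinetic_trace()].
#' @export
read_trace_csv <- function(path) {
  df <- read_strict_csv(path, c("time_s", "conc_A_M"))
  if (any(diff(df$time_s) < 0)) {
    parse_error("%s: time_s must be non-decreasing", path)
  }
  prov <- "measured"; noise <- 0; seed <- NA_integer_
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (!is.null(meta$provenance)) prov <- meta$provenance
    if (!is.null(meta$noise_rsd)) noise <- meta$noise_rsd
    if (!is.null(meta$seed)) seed <- as.integer(meta$seed)
  }
  kinetic_trace(df$time_s, df$conc_A_M,
                C_B = if ("conc_B_M" %in% names(df)) df$conc_B_M else NULL,
                provenance = prov, noise_rsd = noise, seed = seed)
}

#' Write a kinetic trace to CSV (with provenance sidecar)
#'
#' @param x a [kinetic_trace()].
#' @param path CSV path.
#' @param sidecar write `<path>.json` provenance metadata (default TRUE).
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(x, path, sidecar = TRUE) {
  stopifnot(inherits(x, "kinetic_trace"))
  df <- data.frame(time_s = x$t, conc_A_M = x$C_A)
  if (!is.null(x$C_B)) df$conc_B_M <- x$C_B
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    jsonlite::write_json(
      list(provenance = attr(x, "provenance"),
           noise_rsd = attr(x, "noise_rsd"),
           seed = if (is.na(attr(x, "seed"))) NULL else attr(x, "seed")),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write an actinometer calibration to JSON
#'
#' Schema: `{drug_id, lamp_id, beta_eta, intercept, r2, n,
#' points: [{p0_tot, k_eta}, ...]}`.
#'
#' @param cal an [actinometer_calibration()].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(cal, path) {
  stopifnot(inherits(cal, "actinometer_calibration"))
  jsonlite::write_json(
    list(drug_id = cal$drug_id, lamp_id = cal$lamp_id,
         beta_eta = cal$beta_eta, intercept = cal$intercept,
         r2 = cal$r2, n = cal$n,
         points = cal$points),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Read an actinometer calibration from JSON
#'
#' @param path JSON path written by [write_calibration_json()].
#' @return An [actinometer_calibration()].
#' @export
read_calibration_json <- function(path) {
  if (!file.exists(path)) parse_error("file not found: %s", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  pts <- if (!is.null(j$points) && NROW(j$points) > 0) {
    as.data.frame(j$points)
  } else {
    data.frame(p0_tot = numeric(0), k_eta = numeric(0))
  }
  new_actinometer_calibration(
    beta_eta = j$beta_eta, intercept = j$intercept,
    r2 = if (is.null(j$r2)) NA_real_ else j$r2,
    n = if (is.null(j$n)) NA_integer_ else j$n,
    points = pts, drug_id = j$drug_id, lamp_id = j$lamp_id)
}

#' Read reactor geometry from a YAML/JSON config
#'
#' Keys: `l_irr_cm`, `area_cm2`, `volume_dm3` (missing keys take the
#' package defaults).
#'
#' @param path YAML (or JSON) config path.
#' @return A [reactor_geometry()].
#' @export
read_geometry <- function(path) {
  if (!file.exists(path)) parse_error("file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  reactor_geometry(
    l_irr_cm = if (is.null(cfg$l_irr_cm)) 1 else cfg$l_irr_cm,
    area_cm2 = if (is.null(cfg$area_cm2)) 1 else cfg$area_cm2,
    volume_dm3 = if (is.null(cfg$volume_dm3)) 2e-3 else cfg$volume_dm3)
}

#' Serialise eta-order parameters to JSON
#'
#' Keys: `alpha1_M, alpha2_M, k_eta_M_per_s, C0_M, window_nm`.
#'
#' @param params an [eta_params()].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_eta_params_json <- function(params, path) {
  jsonlite::write_json(
    list(alpha1_M = params$alpha1, alpha2_M = params$alpha2,
         k_eta_M_per_s = params$k_eta, C0_M = params$C0,
         window_nm = params$window),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read eta-order parameters from JSON
#' @param path JSON path written by [write_eta_params_json()].
#' @return An [eta_params()].
#' @export
read_eta_params_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  eta_params(alpha1 = j$alpha1_M, alpha2 = j$alpha2_M,
             k_eta = j$k_eta_M_per_s, C0 = j$C0_M,
             window = if (is.null(j$window_nm)) c(NA, NA) else j$window_nm)
}
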