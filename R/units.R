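#' Unit conventions
#'
#' All internal quantities use a single consistent unit system: pressures in
#' kPa, volumes in ml, flows in ml/s, lengths and diameters in mm, times in s,
#' masses in kg, compliances in ml/kPa and resistances in kPa s/ml.
#' Conversions from clinical units (cmH2O for airway pressures, cm^2/s for
#' diffusivities) happen once, at the configuration boundary.
#'
#' @name neovent-units
#' @keywords internal
NULL

#' Conversion factor from cmH2O to kPa (exact, conventional)
#' @keywords internal
CMH2O_TO_KPA <- 0.0980665

#' Convert a pressure in cmH2O to kPa
#'
#' @param p pressure in cmH2O
#' @return pressure in kPa
#' @examples
#' cmh2o_to_kpa(8) # PEEP of 8 cmH2O ~ 0.7845 kPa
#' @export
cmh2o_to_kpa <- function(p) p * CMH2O_TO_KPA

#' Convert a diffusivity in cm^2/s to mm^2/s
#' @param d diffusivity in cm^2/s
#' @return diffusivity in mm^2/s
#' @export
cm2s_to_mm2s <- function(d) d * 100

# internal: stop with a field-named validation message
fail_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    fail_field(field, "must be a single positive finite number")
  invisible(x)
}

check_nonnegative <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    fail_field(field, "must be a single non-negative finite number")
  invisible(x)
}
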