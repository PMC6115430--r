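#' HFOV ventilator prescription
#'
#' High-frequency oscillatory ventilation settings: oscillation frequency,
#' tidal volume per kilogram, inspiratory:expiratory ratio, PEEP (given in
#' cmH2O as on the ventilator panel, stored internally in kPa) and the
#' inspired oxygen fraction. Defaults are the reference prescription for
#' the 0.76 kg patient: f = 10 Hz, V_T = 2.0 ml/kg, I:E = 1:2, PEEP =
#' 8 cmH2O, FiO2 = 0.35.
#'
#' @param frequency oscillation frequency (Hz)
#' @param tidal_volume_per_kg tidal volume (ml/kg)
#' @param ie_ratio length-2 numeric `c(I, E)`, both positive
#' @param peep_cmh2o positive end-expiratory pressure (cmH2O)
#' @param fio2 inspired oxygen fraction, in (0, 1]
#' @param n_cycles number of ventilation cycles to simulate
#' @return an object of class `neovent_hfov`; `peep_kpa` holds the
#'   converted PEEP
#' @export
hfov_settings <- function(frequency = 10,
                          tidal_volume_per_kg = 2.0,
                          ie_ratio = c(1, 2),
                          peep_cmh2o = 8,
                          fio2 = 0.35,
                          n_cycles = 6L) {
  check_positive(frequency, "frequency")
  check_positive(tidal_volume_per_kg, "tidal_volume_per_kg")
  if (length(ie_ratio) != 2L || any(ie_ratio <= 0))
    fail_field("ie_ratio", "must be two positive numbers c(I, E)")
  check_nonnegative(peep_cmh2o, "peep_cmh2o")
  if (fio2 <= 0 || fio2 > 1) fail_field("fio2", "must lie in (0, 1]")
  if (n_cycles < 1) fail_field("n_cycles", "must be >= 1")
  structure(list(frequency = frequency,
                 tidal_volume_per_kg = tidal_volume_per_kg,
                 ie_ratio = as.numeric(ie_ratio),
                 peep_cmh2o = peep_cmh2o,
                 peep_kpa = cmh2o_to_kpa(peep_cmh2o),
                 fio2 = fio2,
                 n_cycles = as.integer(n_cycles)),
            class = "neovent_hfov")
}

#' Phase timing of one HFOV cycle
#'
#' @param settings a `neovent_hfov`
#' @return list with `period`, `t_insp`, `t_exp` (s):
#'   `period = 1/f`, `t_insp = period * I/(I+E)`
#' @examples
#' inspiratory_times(hfov_settings())  # period 0.1 s, t_insp 1/30 s
#' @export
inspiratory_times <- function(settings) {
  stopifnot(inherits(settings, "neovent_hfov"))
  period <- 1 / settings$frequency
  t_insp <- period * settings$ie_ratio[1] / sum(settings$ie_ratio)
  list(period = period, t_insp = t_insp, t_exp = period - t_insp)
}

#' Prescribed ventilator flow waveform
#'
#' During inspiration the ventilator drives a half-sine flow,
#' `Q(t) = Q_peak sin(pi t / t_insp)` with
#' `Q_peak = pi V_T / (2 t_insp)` so that the inspiratory integral equals
#' the absolute tidal volume `V_T = tidal_volume_per_kg * body_mass`.
#' During expiration the prescribed source is zero: flow develops freely
#' from regional lung mechanics against the PEEP held at the airway
#' opening.
#'
#' @param settings a `neovent_hfov`
#' @param body_mass patient mass (kg)
#' @param t time(s) within one cycle (s); values are reduced modulo the
#'   period
#' @return prescribed flow (ml/s), vectorised over `t`
#' @export
flow_waveform <- function(settings, body_mass, t) {
  stopifnot(inherits(settings, "neovent_hfov"))
  check_positive(body_mass, "body_mass")
  tim <- inspiratory_times(settings)
  vt <- settings$tidal_volume_per_kg * body_mass
  q_peak <- pi * vt / (2 * tim$t_insp)
  tt <- t %% tim$period
  ifelse(tt <= tim$t_insp, q_peak * sin(pi * tt / tim$t_insp), 0)
}

#' Endotracheal tube model
#'
#' An uncuffed neonatal tube, by default 3.0 mm inner diameter and 100 mm
#' long, with laminar (Poiseuille) flow resistance.
#'
#' @param inner_diameter tube inner diameter (mm)
#' @param length tube length (mm)
#' @param air a `neovent_air`
#' @return an object of class `neovent_tube` with derived `resistance`
#'   (kPa s/ml)
#' @export
tube_model <- function(inner_diameter = 3.0, length = 100, air = air_properties()) {
  check_positive(inner_diameter, "inner_diameter")
  check_positive(length, "length")
  structure(list(inner_diameter = inner_diameter, length = length,
                 resistance = poiseuille_resistance(length, inner_diameter, air)),
            class = "neovent_tube")
}

#' Tube-leak model
#'
#' Uncuffed neonatal tubes leak around the tube wall between pharynx and
#' tube. Two regimes: `linear` (a fixed leak resistance, the default,
#' calibrated so that the leaked fraction of the supplied tidal volume
#' matches a clinical target) and `orifice` (inertial orifice outflow
#' through a given cross-sectional area). Exactly one of
#' `resistance`/`orifice_area` must be set, matching the regime.
#'
#' @param regime `"linear"` or `"orifice"`
#' @param resistance leak resistance (kPa s/ml), linear regime
#' @param orifice_area leak cross-sectional area (mm^2), orifice regime
#' @return an object of class `neovent_leak`
#' @export
leak_model <- function(regime = c("linear", "orifice"),
                       resistance = NULL, orifice_area = NULL) {
  regime <- match.arg(regime)
  if (regime == "linear") {
    if (is.null(resistance) || !is.null(orifice_area))
      fail_field("resistance", "linear regime requires 'resistance' only")
    check_positive(resistance, "resistance")
  } else {
    if (is.null(orifice_area) || !is.null(resistance))
      fail_field("orifice_area", "orifice regime requires 'orifice_area' only")
    check_positive(orifice_area, "orifice_area")
  }
  structure(list(regime = regime, resistance = resistance,
                 orifice_area = orifice_area),
            class = "neovent_leak")
}

#' Instantaneous leak flow
#'
#' Linear regime: `Q = p / R_leak`. Orifice regime:
#' `Q = sign(p) A sqrt(2 |p| / rho)` (Bernoulli orifice, discharge
#' coefficient 1). `p` is the opening pressure relative to ambient, so with
#' PEEP applied the leak flows outward in both phases.
#'
#' @param leak a `neovent_leak`
#' @param p_opening pressure at the airway opening relative to ambient (kPa)
#' @param air a `neovent_air` (used in the orifice regime)
#' @return leak flow (ml/s), positive out of the circuit; vectorised over
#'   `p_opening`
#' @export
leak_flow <- function(leak, p_opening, air = air_properties()) {
  stopifnot(inherits(leak, "neovent_leak"))
  if (leak$regime == "linear") {
    p_opening / leak$resistance
  } else {
    # p in kPa = 1e3 Pa; rho kg/m^3; v = sqrt(2 p / rho) m/s -> mm/s *1e3
    # Q [ml/s] = A[mm^2] * v[mm/s] / 1e3
    v_m_s <- sqrt(2 * abs(p_opening) * 1000 / air$density)
    sign(p_opening) * leak$orifice_area * v_m_s * 1000 / 1000
  }
}

#' Calibrate the linear leak resistance to a target leak fraction
#'
#' The leak area of an individual patient is image-derived and not portable,
#' so the linear leak is calibrated instead: bisection on log leak
#' resistance until the simulated leak fraction (leaked volume over one
#' steady-state cycle divided by the supplied tidal volume) is within
#' `tol` of `target_leak_fraction`. The leak fraction is monotone
#' decreasing in leak resistance, which guarantees bisection converges when
#' the target is bracketed.
#'
#' @param config a pipeline configuration from [neovent_config()]; its leak
#'   block is ignored and replaced by the candidate linear leak
#' @param target_leak_fraction target in (0, 1), e.g. 0.16
#' @param tol half-width of the acceptance band (fraction, default 0.005,
#'   i.e. +/- 0.5 percentage points)
#' @param bracket initial resistance bracket (kPa s/ml)
#' @param max_iter bisection iteration cap
#' @return list with `leak` (the calibrated `neovent_leak`),
#'   `achieved_fraction`, and `iterations`
#' @export
calibrate_leak <- function(config, target_leak_fraction = 0.16, tol = 0.005,
                           bracket = c(0.01, 100), max_iter = 60L) {
  if (target_leak_fraction <= 0 || target_leak_fraction >= 1)
    fail_field("target_leak_fraction", "must lie in (0, 1)")
  frac_at <- function(r) {
    cfg <- config
    cfg$leak <- leak_model("linear", resistance = r)
    leak_fraction(simulate_hfov(cfg))
  }
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- frac_at(lo); f_hi <- frac_at(hi)
  # fraction decreases with resistance: f_lo is the high fraction
  if (target_leak_fraction > f_lo || target_leak_fraction < f_hi)
    stop(sprintf(paste0("leak calibration: target %.3f outside achievable range ",
                        "[%.4f, %.4f] for resistance bracket [%g, %g]"),
                 target_leak_fraction, f_hi, f_lo, lo, hi), call. = FALSE)
  it <- 0L
  repeat {
    it <- it + 1L
    mid <- sqrt(lo * hi)
    f_mid <- frac_at(mid)
    if (abs(f_mid - target_leak_fraction) <= tol || it >= max_iter) {
      if (abs(f_mid - target_leak_fraction) > tol)
        stop("leak calibration did not converge within iteration cap", call. = FALSE)
      return(list(leak = leak_model("linear", resistance = mid),
                  achieved_fraction = f_mid, iterations = it))
    }
    if (f_mid > target_leak_fraction) lo <- mid else hi <- mid
  }
}
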