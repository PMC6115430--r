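#' Physical properties of the respired gas
#'
#' Defaults are humidified air at body temperature: kinematic viscosity
#' 17 mm^2/s and density 1.27 kg/m^3.
#'
#' @param kinematic_viscosity mm^2/s
#' @param density kg/m^3
#' @return an object of class `neovent_air`
#' @export
air_properties <- function(kinematic_viscosity = 17, density = 1.27) {
  check_positive(kinematic_viscosity, "kinematic_viscosity")
  check_positive(density, "density")
  structure(list(kinematic_viscosity = kinematic_viscosity, density = density),
            class = "neovent_air")
}

#' Estimate respiratory mechanics from a single-occlusion maneuver
#'
#' The standard single-occlusion analysis: total compliance is the exhaled
#' volume divided by the occlusion plateau pressure; the expiratory time
#' constant is minus the reciprocal of the least-squares slope of flow
#' against exhaled volume (a passive single-compartment expiration is a
#' straight line in the flow-volume plane); resistance is the time constant
#' divided by the compliance.
#'
#' @param maneuver a `neovent_sot` with at least 10 samples
#' @return an object of class `neovent_mechanics`: list with `crs` (ml/kPa),
#'   `resistance` (kPa s/ml), `time_constant` (s) and `fit_diagnostics`
#'   (list with `r_squared`, `n`, `exhaled_volume`)
#' @examples
#' p <- make_patient()
#' m <- make_sot_maneuver(p, 0.006, 10, noise_sd = 0, seed = 1)
#' estimate_crs_sot(m)$crs
#' @export
estimate_crs_sot <- function(maneuver) {
  stopifnot(inherits(maneuver, "neovent_sot"))
  if (length(maneuver$time) < 10)
    stop("SOT estimation needs at least 10 samples of passive expiration", call. = FALSE)
  if (!is.numeric(maneuver$plateau_pressure) || maneuver$plateau_pressure <= 0)
    stop("SOT estimation needs a positive plateau pressure", call. = FALSE)
  vol <- maneuver$volume
  # noise may produce small local dips; reject only a substantial reversal
  exhaled <- vol[length(vol)]
  drawdown <- max(cummax(vol) - vol)
  if (exhaled <= 0 || drawdown > 0.1 * exhaled)
    stop("exhaled volume must be non-decreasing during passive expiration", call. = FALSE)
  crs <- exhaled / maneuver$plateau_pressure
  fit <- stats::lm.fit(cbind(1, vol), maneuver$flow)
  slope <- unname(fit$coefficients[2])
  if (!is.finite(slope) || slope >= 0)
    stop("flow-volume relation has non-negative slope; not a passive expiration", call. = FALSE)
  tau <- -1 / slope
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((maneuver$flow - mean(maneuver$flow))^2)
  structure(list(
    crs = crs,
    resistance = tau / crs,
    time_constant = tau,
    fit_diagnostics = list(r_squared = 1 - ss_res / ss_tot,
                           n = length(vol), exhaled_volume = exhaled)
  ), class = "neovent_mechanics")
}

#' Partition total compliance among terminal units
#'
#' Regional compliances act in parallel, so they add: each terminal unit i
#' receives `c_eq_i = w_i * crs_total`, and the sum over units recovers the
#' total exactly.
#'
#' @param crs_total total respiratory compliance (ml/kPa)
#' @param tree a `neovent_tree`
#' @param weights positive weights, one per terminal, summing to 1 (default
#'   uniform)
#' @return named numeric vector of `c_eq` (ml/kPa), names = terminal ids in
#'   canonical order
#' @export
partition_compliance <- function(crs_total, tree, weights = NULL) {
  check_positive(crs_total, "crs_total")
  term <- terminal_ids(tree)
  n <- length(term)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n)
    stop(sprintf("got %d weights for %d terminals", length(weights), n), call. = FALSE)
  if (any(weights <= 0)) fail_field("weights", "must all be positive")
  if (abs(sum(weights) - 1) > 1e-8) fail_field("weights", "must sum to 1")
  stats::setNames(as.numeric(weights) * crs_total, term)
}

#' Poiseuille resistance of a cylindrical airway segment
#'
#' Fully developed laminar flow: R = 128 mu L / (pi d^4) with dynamic
#' viscosity mu = rho * nu, converted to kPa s/ml.
#'
#' @param length_mm segment length (mm)
#' @param diameter_mm segment inner diameter (mm)
#' @param air a `neovent_air`
#' @return resistance in kPa s/ml
#' @examples
#' poiseuille_resistance(100, 3)  # a 3.0 mm x 100 mm endotracheal tube
#' @export
poiseuille_resistance <- function(length_mm, diameter_mm, air = air_properties()) {
  stopifnot(inherits(air, "neovent_air"))
  mu_pa_s <- air$density * air$kinematic_viscosity * 1e-6  # kg/m^3 * m^2/s
  l_m <- length_mm * 1e-3
  d_m <- diameter_mm * 1e-3
  r_si <- 128 * mu_pa_s * l_m / (pi * d_m^4)               # Pa s / m^3
  r_si * 1e-9                                              # kPa s / ml
}

#' Equivalent resistance of the unresolved downstream subtree
#'
#' The conducting airways beyond the resolved tree (generations 8-16 by
#' default, continuing from each generation-7 outlet) are lumped into one
#' equivalent resistance per outlet: a virtual symmetric dichotomous subtree
#' continues the per-generation length and diameter ratios for
#' `extra_generations` levels and is reduced by series/parallel composition
#' (resistances add in series, conductances add in parallel). For the
#' symmetric case this reduces to the closed form
#' `sum_k R_seg(k) / 2^k`, k = 1..extra_generations.
#'
#' @param terminal_diameter diameter of the resolved terminal segment (mm)
#' @param terminal_length length of the resolved terminal segment (mm)
#' @param extra_generations number of virtual generations (default 9,
#'   spanning generations 8-16 beyond a generation-7 terminal)
#' @param diameter_ratio,length_ratio per-generation ratios in (0,1)
#' @param air a `neovent_air`
#' @return equivalent resistance (kPa s/ml)
#' @export
equivalent_downstream_resistance <- function(terminal_diameter, terminal_length,
                                             extra_generations = 9L,
                                             diameter_ratio = 0.79,
                                             length_ratio = 0.79,
                                             air = air_properties()) {
  check_positive(terminal_diameter, "terminal_diameter")
  check_positive(terminal_length, "terminal_length")
  if (extra_generations < 1) fail_field("extra_generations", "must be >= 1")
  for (nm in c("diameter_ratio", "length_ratio")) {
    v <- get(nm)
    if (v <= 0 || v >= 1) fail_field(nm, "must lie strictly in (0, 1)")
  }
  k <- seq_len(extra_generations)
  r_seg <- poiseuille_resistance(terminal_length * length_ratio^k,
                                 terminal_diameter * diameter_ratio^k, air)
  sum(r_seg / 2^k)
}

#' Construct a terminal resistance-compliance unit
#'
#' Each generation-seven outlet is closed by a lumped unit: the equivalent
#' resistance of its unresolved downstream airways in series with the
#' regional tissue compliance. The unit's state is the volume `delta_v`
#' stored above the PEEP-equilibrated functional residual capacity.
#'
#' @param outlet_id terminal segment id
#' @param r_eq equivalent downstream resistance (kPa s/ml), >= 0
#' @param c_eq regional compliance (ml/kPa), > 0
#' @param delta_v initial stored volume above baseline (ml)
#' @return an object of class `neovent_terminal_unit`
#' @export
terminal_unit <- function(outlet_id, r_eq, c_eq, delta_v = 0) {
  if (r_eq < 0) fail_field("r_eq", "must be non-negative")
  check_positive(c_eq, "c_eq")
  structure(list(outlet_id = outlet_id, r_eq = r_eq, c_eq = c_eq,
                 delta_v = delta_v, pressure = 0, flow = 0),
            class = "neovent_terminal_unit")
}

#' Advance a terminal unit under a known inflow
#'
#' The terminal closure: the pressure at the outlet is the resistive drop
#' across the unresolved airways plus the elastic recoil of the stored
#' volume, `P = R_eq * Q + delta_v / C_eq`, with `delta_v` the running time
#' integral of the inflow `Q` (trapezoidal update). Pressures are relative
#' to the PEEP baseline, so a unit at rest reads zero.
#'
#' @param unit a `neovent_terminal_unit`
#' @param q inflow during the step (ml/s); scalar (held constant) or the
#'   pair `c(q_old, q_new)` for the trapezoidal rule
#' @param dt step length (s), > 0
#' @return the updated unit, with `delta_v`, `pressure`, `flow` advanced
#' @export
terminal_pressure <- function(unit, q, dt) {
  stopifnot(inherits(unit, "neovent_terminal_unit"))
  check_positive(dt, "dt")
  if (length(q) == 1L) q <- c(unit$flow, q)
  if (length(q) != 2L) fail_field("q", "must be a scalar or a pair (q_old, q_new)")
  unit$delta_v <- unit$delta_v + dt * (q[1] + q[2]) / 2
  unit$flow <- q[2]
  unit$pressure <- unit$r_eq * q[2] + unit$delta_v / unit$c_eq
  unit
}

#' Serialise a compliance/resistance map to CSV
#'
#' Columns: `outlet_id`, `c_eq_ml_per_kPa`, `r_eq_kPa_s_per_ml`.
#'
#' @param c_eq named vector from [partition_compliance()]
#' @param r_eq named vector of equivalent downstream resistances (same names)
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_mechanics_map <- function(c_eq, r_eq, path) {
  stopifnot(identical(names(c_eq), names(r_eq)))
  utils::write.csv(
    data.frame(outlet_id = names(c_eq),
               c_eq_ml_per_kPa = as.numeric(c_eq),
               r_eq_kPa_s_per_ml = as.numeric(r_eq)),
    path, row.names = FALSE)
  invisible(path)
}
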