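#' Reynolds number of a segment at a given flow
#'
#' `Re = 4 |Q| / (pi d nu)`, equivalent to `u d / nu` with the mean
#' velocity `u = Q/A`. Used to flag airway segments prone to turbulence
#' during the oscillatory cycle.
#'
#' @param flow_ml_s volumetric flow (ml/s)
#' @param diameter_mm segment diameter (mm)
#' @param air a `neovent_air`
#' @return dimensionless Reynolds number (vectorised)
#' @export
reynolds_number <- function(flow_ml_s, diameter_mm, air = air_properties()) {
  stopifnot(inherits(air, "neovent_air"))
  4 * abs(flow_ml_s) * 1000 / (pi * diameter_mm * air$kinematic_viscosity)
}

#' Womersley number of a segment
#'
#' `alpha = (d/2) sqrt(2 pi f / nu)`: the ratio of oscillatory inertial to
#' viscous effects. Large alpha (blunted, phase-lagged velocity profiles)
#' is expected in the large airways at HFOV frequencies; alpha falls with
#' the square root of frequency and linearly with diameter towards the
#' periphery.
#'
#' @param diameter_mm segment diameter (mm)
#' @param frequency oscillation frequency (Hz)
#' @param air a `neovent_air`
#' @return dimensionless Womersley number (vectorised)
#' @export
womersley_number <- function(diameter_mm, frequency, air = air_properties()) {
  stopifnot(inherits(air, "neovent_air"))
  check_nonnegative(frequency, "frequency")
  (diameter_mm / 2) * sqrt(2 * pi * frequency / air$kinematic_viscosity)
}

#' Classify per-segment oscillatory flow regimes
#'
#' Computes each segment's peak-cycle Reynolds number from the recorded
#' flows and labels it `turbulent_prone`, `transitional` or `laminar`
#' against configurable thresholds. The thresholds are declared surrogates
#' for a full turbulence criterion (defaults 2000 and 500, the classic pipe
#' transition band) and are echoed in the report. The Womersley number at
#' the ventilation frequency is reported alongside.
#'
#' @param result a `neovent_sim` with recorded segment flows
#' @param thresholds list with `turbulent` and `transitional` Reynolds
#'   thresholds
#' @return an object of class `neovent_regimes`: data frame with
#'   `segment_id`, `generation`, `re_peak`, `alpha`, `label`, plus the
#'   thresholds as an attribute
#' @export
classify_regimes <- function(result,
                             thresholds = list(turbulent = 2000, transitional = 500)) {
  stopifnot(inherits(result, "neovent_sim"))
  if (is.null(result$segment_flows))
    stop("regime classification needs recorded segment flows", call. = FALSE)
  s <- result$network$tree$segments
  air <- result$network$air
  q_peak <- apply(abs(result$segment_flows), 2, max)
  re <- reynolds_number(q_peak, s$diameter_mm, air)
  alpha <- womersley_number(s$diameter_mm, result$network$settings$frequency, air)
  label <- ifelse(re >= thresholds$turbulent, "turbulent_prone",
                  ifelse(re >= thresholds$transitional, "transitional", "laminar"))
  out <- data.frame(segment_id = s$id, generation = s$generation,
                    re_peak = as.numeric(re), alpha = alpha, label = label,
                    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- thresholds
  class(out) <- c("neovent_regimes", class(out))
  out
}

#' Leaked fraction of the supplied tidal volume
#'
#' Integrates the recorded leak flow over one steady-state cycle (the first
#' steady cycle per [detect_steady_state()]; if no steady cycle exists, the
#' final cycle is used with a warning) and divides by the tidal volume
#' supplied by the ventilator during that cycle.
#'
#' @param result a `neovent_sim`
#' @param tol_fraction_of_vt steady-state tolerance passed to
#'   [detect_steady_state()]
#' @return leak fraction in `[0, 1]`
#' @export
leak_fraction <- function(result, tol_fraction_of_vt = 0.02) {
  stopifnot(inherits(result, "neovent_sim"))
  k <- detect_steady_state(result, tol_fraction_of_vt)
  if (is.na(k)) {
    warning("no steady-state cycle detected; using the final cycle", call. = FALSE)
    k <- length(result$cycle_ends)
  }
  i0 <- if (k == 1) 1L else result$cycle_ends[k - 1]
  i1 <- result$cycle_ends[k]
  idx <- i0:i1
  tt <- result$times[idx]
  leak_vol <- sum(diff(tt) * (result$leak_flow[idx][-1] +
                                result$leak_flow[idx][-length(idx)]) / 2)
  # supplied tidal volume: the prescribed inspiratory waveform only (the
  # expiratory bias supply that feeds the leak while the opening is clamped
  # at PEEP is not part of the tidal volume)
  src <- result$source_flow[idx] * (result$phase[idx] == 1L)
  supplied <- sum(diff(tt) * (src[-1] + src[-length(idx)]) / 2)
  leak_vol / supplied
}

#' Aggregate a run into a single summary
#'
#' Gathers the headline observables of a completed run: leak fraction,
#' steady-state cycle, pendelluft event count, oxygen delivery
#' classification counts and dead space per kilogram. Deterministic:
#' identical inputs give byte-identical JSON.
#'
#' @param result a `neovent_sim`
#' @param gas optional `neovent_gas` for delivery metrics
#' @param pendelluft_threshold threshold fraction for
#'   [detect_pendelluft()]
#' @param delivery_threshold oxygen fraction for
#'   [oxygen_delivery_metrics()]
#' @return an object of class `neovent_summary` (a named list)
#' @export
summarise_run <- function(result, gas = NULL,
                          pendelluft_threshold = 0.01,
                          delivery_threshold = 0.25) {
  stopifnot(inherits(result, "neovent_sim"))
  net <- result$network
  n_term <- length(net$term)
  ev <- if (!is.null(result$segment_flows))
    detect_pendelluft(result, pendelluft_threshold) else NULL
  delivery <- if (!is.null(gas)) oxygen_delivery_metrics(gas, delivery_threshold)
  counts <- if (!is.null(delivery)) {
    tab <- table(factor(delivery$classification,
                        levels = c("direct", "delayed", "unreached")))
    as.list(stats::setNames(as.integer(tab), names(tab)))
  } else list(direct = NA_integer_, delayed = NA_integer_,
              unreached = NA_integer_)
  missing <- character(0)
  if (is.null(result$segment_flows)) missing <- c(missing, "pendelluft_event_count")
  if (is.null(gas)) missing <- c(missing, "delivery_counts")
  structure(list(
    leak_fraction = leak_fraction(result),
    steady_state_cycle = detect_steady_state(result),
    pendelluft_event_count = if (is.null(ev)) NA_integer_ else nrow(ev),
    delivery_counts = counts,
    n_terminals = n_term,
    dead_space_per_kg = dead_space(net$tree, net$body_mass),
    tidal_volume_ml = net$settings$tidal_volume_per_kg * net$body_mass,
    n_cycles = net$settings$n_cycles,
    missing_inputs = missing
  ), class = "neovent_summary")
}

#' Write a run summary as JSON and a human-readable report
#'
#' @param summary a `neovent_summary`
#' @param json_path path for the JSON rendering (`NULL` to skip)
#' @param text_path path for the text report (`NULL` to skip)
#' @return the summary, invisibly
#' @export
write_summary <- function(summary, json_path = NULL, text_path = NULL) {
  stopifnot(inherits(summary, "neovent_summary"))
  if (!is.null(json_path))
    jsonlite::write_json(unclass(summary), json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  if (!is.null(text_path)) {
    lines <- c(
      "HFOV run summary",
      "================",
      sprintf("dead space:            %.3f ml/kg", summary$dead_space_per_kg),
      sprintf("tidal volume:          %.3f ml", summary$tidal_volume_ml),
      sprintf("cycles simulated:      %d", summary$n_cycles),
      sprintf("steady state at cycle: %s", summary$steady_state_cycle),
      sprintf("leak fraction:         %.1f%% of supplied tidal volume",
              100 * summary$leak_fraction),
      sprintf("pendelluft events:     %s", summary$pendelluft_event_count),
      sprintf("terminal regions:      %d (direct %s / delayed %s / unreached %s)",
              summary$n_terminals, summary$delivery_counts$direct,
              summary$delivery_counts$delayed, summary$delivery_counts$unreached))
    if (length(summary$missing_inputs) > 0)
      lines <- c(lines, paste("missing inputs:", paste(summary$missing_inputs,
                                                       collapse = ", ")))
    writeLines(lines, text_path)
  }
  invisible(summary)
}

#' Write a regime report to CSV
#'
#' Columns: `segment_id`, `generation`, `re_peak`, `alpha`, `label`.
#'
#' @param regimes a `neovent_regimes`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_regimes <- function(regimes, path) {
  stopifnot(inherits(regimes, "neovent_regimes"))
  utils::write.csv(as.data.frame(regimes), path, row.names = FALSE)
  invisible(path)
}
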