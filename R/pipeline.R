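# Default linear leak resistance (kPa s/ml). Calibrated with
# calibrate_leak() so that the default configuration leaks 16% of the
# supplied tidal volume per steady-state cycle, the clinically reported
# leak fraction for uncuffed neonatal tubes.
DEFAULT_LEAK_RESISTANCE <- 0.362

#' Assemble a full pipeline configuration
#'
#' Collects every block the pipeline needs: the patient, the tree
#' morphometry, the compliance partition, the ventilator prescription, tube
#' and leak models, solver and transport controls, and a single global seed
#' that fans out to the per-stage seeds (morphometry jitter uses `seed`,
#' the compliance partition `seed + 1000`, the SOT noise `seed + 2000`),
#' so each stage is independently reproducible.
#'
#' @param patient a `neovent_patient`
#' @param morphometry a `neovent_morphometry`; its seed is overridden by
#'   the global seed unless `morphometry_seed_fixed = TRUE`
#' @param partition list: `profile` ("uniform" or "bpd_patchy"),
#'   `severity`, `patch_fraction`
#' @param settings a `neovent_hfov`
#' @param tube a `neovent_tube`
#' @param leak a `neovent_leak`, or `NULL` for the packaged default linear
#'   leak (calibrated to a 16% leak fraction)
#' @param solver list: `steps_per_insp`, `scheme`, `inertance`,
#'   `nonlinearity_factor`
#' @param transport a `neovent_transport_params`
#' @param sot list: `resistance` (kPa s/ml), `occlusion_volume_per_kg`
#'   (ml/kg), `noise_sd` (ml/s) controlling the synthetic single-occlusion
#'   maneuver
#' @param target_deadspace_per_kg dead-space calibration target (ml/kg)
#' @param extra_generations virtual downstream generations lumped into each
#'   terminal resistance
#' @param air a `neovent_air`
#' @param seed global integer seed
#' @param morphometry_seed_fixed keep the seed stored in `morphometry`
#' @return an object of class `neovent_config`
#' @export
neovent_config <- function(patient = make_patient(),
                           morphometry = morphometry_params(),
                           partition = list(profile = "uniform",
                                            severity = 0.5,
                                            patch_fraction = 0.25),
                           settings = hfov_settings(),
                           tube = tube_model(),
                           leak = NULL,
                           solver = list(steps_per_insp = 200L,
                                         scheme = "trapezoidal",
                                         inertance = FALSE,
                                         nonlinearity_factor = 1),
                           transport = transport_params(),
                           sot = list(resistance = 0.006,
                                      occlusion_volume_per_kg = 6,
                                      noise_sd = 0),
                           target_deadspace_per_kg = 2.2,
                           extra_generations = 9L,
                           air = air_properties(),
                           seed = 1L,
                           morphometry_seed_fixed = FALSE) {
  stopifnot(inherits(patient, "neovent_patient"),
            inherits(morphometry, "neovent_morphometry"),
            inherits(settings, "neovent_hfov"),
            inherits(tube, "neovent_tube"),
            inherits(transport, "neovent_transport_params"),
            inherits(air, "neovent_air"))
  if (is.null(leak)) leak <- leak_model("linear", resistance = DEFAULT_LEAK_RESISTANCE)
  stopifnot(inherits(leak, "neovent_leak"))
  defaults_part <- list(profile = "uniform", severity = 0.5, patch_fraction = 0.25)
  defaults_part[names(partition)] <- partition
  defaults_solver <- list(steps_per_insp = 200L, scheme = "trapezoidal",
                          inertance = FALSE, nonlinearity_factor = 1)
  defaults_solver[names(solver)] <- solver
  defaults_sot <- list(resistance = 0.006, occlusion_volume_per_kg = 6,
                       noise_sd = 0)
  defaults_sot[names(sot)] <- sot
  if (!morphometry_seed_fixed) morphometry$seed <- as.integer(seed)
  structure(list(
    patient = patient, morphometry = morphometry, partition = defaults_part,
    settings = settings, tube = tube, leak = leak, solver = defaults_solver,
    transport = transport, sot = defaults_sot,
    target_deadspace_per_kg = target_deadspace_per_kg,
    extra_generations = as.integer(extra_generations),
    air = air, seed = as.integer(seed)
  ), class = "neovent_config")
}

# Build every derived piece of a configuration: tree, compliance partition,
# terminal resistances and the prefactorised network. Internal.
config_pieces <- function(config) {
  stopifnot(inherits(config, "neovent_config"))
  tree <- generate_tree(config$morphometry, config$patient$body_mass,
                        config$target_deadspace_per_kg)
  term <- terminal_ids(tree)
  weights <- make_compliance_heterogeneity(
    length(term), config$partition$profile,
    severity = config$partition$severity,
    seed = config$seed + 1000L,
    patch_fraction = config$partition$patch_fraction)
  c_eq <- partition_compliance(config$patient$crs_total, tree, weights)
  st <- tree$segments[tree$segments$is_terminal, ]
  r_eq <- stats::setNames(vapply(seq_len(nrow(st)), function(i)
    equivalent_downstream_resistance(
      st$diameter_mm[i], st$length_mm[i],
      extra_generations = config$extra_generations,
      diameter_ratio = config$morphometry$diameter_ratio,
      length_ratio = config$morphometry$length_ratio,
      air = config$air), numeric(1)), st$id)
  network <- build_network(tree, c_eq, r_eq, config$tube, config$leak,
                           config$settings, config$patient$body_mass,
                           air = config$air,
                           steps_per_insp = config$solver$steps_per_insp,
                           scheme = config$solver$scheme,
                           inertance = config$solver$inertance,
                           nonlinearity_factor = config$solver$nonlinearity_factor)
  list(tree = tree, weights = weights, c_eq = c_eq, r_eq = r_eq,
       network = network)
}

# ---- configuration files ----------------------------------------------------

parse_pressure_cmh2o <- function(x, field) {
  if (is.numeric(x)) return(x)
  if (is.character(x) && length(x) == 1L) {
    m <- regmatches(x, regexec("^\\s*([0-9.eE+-]+)\\s*(cmH2O|kPa)\\s*$", x))[[1]]
    if (length(m) == 3L) {
      val <- as.numeric(m[2])
      return(if (m[3] == "kPa") val / CMH2O_TO_KPA else val)
    }
  }
  fail_field(field, "must be a number (cmH2O) or a string like '8 cmH2O' or '0.785 kPa'")
}

check_known_keys <- function(block, allowed, block_name) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown) > 0)
    stop(sprintf("unknown key '%s' in config block '%s'", unknown[1], block_name),
         call. = FALSE)
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Reads a (possibly empty) YAML or JSON file, applies the packaged
#' defaults for every omitted field, normalises units (PEEP may be given in
#' cmH2O, optionally as a string with unit suffix), and rejects unknown
#' keys with an error naming the field. An empty file yields the full
#' default configuration (f = 10 Hz, V_T = 2.0 ml/kg, I:E = 1:2, PEEP =
#' 8 cmH2O, FiO2 = 0.35).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file
#' @return a `neovent_config`
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  check_known_keys(raw, c("patient", "morphometry", "partition", "ventilator",
                          "tube", "leak", "solver", "transport", "sot",
                          "target_deadspace_per_kg", "extra_generations",
                          "seed"), "(top level)")

  pat <- raw$patient
  check_known_keys(pat, c("body_mass", "crs_total", "frc", "bpd_grade",
                          "gestational_age"), "patient")
  patient <- make_patient(pat)

  mor <- raw$morphometry
  check_known_keys(mor, c("trachea_length", "trachea_diameter", "diameter_ratio",
                          "length_ratio", "asymmetry_factor", "jitter_sd",
                          "seed"), "morphometry")
  morphometry <- do.call(morphometry_params, if (is.null(mor)) list() else mor)

  par <- raw$partition
  check_known_keys(par, c("profile", "severity", "patch_fraction"), "partition")

  ven <- raw$ventilator
  check_known_keys(ven, c("frequency", "tidal_volume_per_kg", "ie_ratio",
                          "peep", "fio2", "n_cycles"), "ventilator")
  ven_args <- list()
  if (!is.null(ven)) {
    if (!is.null(ven$peep)) {
      ven_args$peep_cmh2o <- parse_pressure_cmh2o(ven$peep, "ventilator.peep")
      ven$peep <- NULL
    }
    ven_args <- c(ven_args, ven)
  }
  settings <- do.call(hfov_settings, ven_args)

  tb <- raw$tube
  check_known_keys(tb, c("inner_diameter", "length"), "tube")
  tube <- do.call(tube_model, if (is.null(tb)) list() else tb)

  lk <- raw$leak
  check_known_keys(lk, c("regime", "resistance", "orifice_area"), "leak")
  leak <- if (is.null(lk)) NULL else do.call(leak_model, lk)

  sol <- raw$solver
  check_known_keys(sol, c("steps_per_insp", "scheme", "inertance",
                          "nonlinearity_factor"), "solver")

  tr <- raw$transport
  check_known_keys(tr, c("diffusivity_cm2s", "inlet_concentration",
                         "cells_per_segment", "scheme",
                         "initial_concentration", "cfl", "include_tube"),
                   "transport")
  transport <- do.call(transport_params, if (is.null(tr)) list() else tr)

  sot <- raw$sot
  check_known_keys(sot, c("resistance", "occlusion_volume_per_kg", "noise_sd"),
                   "sot")

  args <- list(patient = patient, morphometry = morphometry,
               settings = settings, tube = tube, leak = leak,
               transport = transport, morphometry_seed_fixed = !is.null(mor$seed))
  if (!is.null(par)) args$partition <- par
  if (!is.null(sol)) args$solver <- sol
  if (!is.null(sot)) args$sot <- sot
  if (!is.null(raw$target_deadspace_per_kg))
    args$target_deadspace_per_kg <- raw$target_deadspace_per_kg
  if (!is.null(raw$extra_generations))
    args$extra_generations <- raw$extra_generations
  if (!is.null(raw$seed)) args$seed <- raw$seed
  do.call(neovent_config, args)
}

# 32-bit polynomial hash of the serialised configuration, as hex. Internal.
config_hash <- function(config) {
  bytes <- as.integer(serialize(unclass(config), NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full pipeline
#'
#' Executes the stages in order — synthetic fixtures, airway tree,
#' mechanics, flow solution, gas transport, diagnostics — and writes every
#' artefact to `outdir`: the tree CSV, the SOT maneuver and its mechanics
#' fit, the terminal compliance/resistance map, the tidy simulation CSV,
#' oxygen snapshots, the regime report, the run-summary JSON and text
#' report, an echo of the effective configuration and a log. Deterministic
#' given the configuration.
#'
#' @param config a `neovent_config`
#' @param outdir output directory (created if absent)
#' @param transport logical; run the oxygen-transport stage
#' @param sim_stride time-sample stride for the simulation CSV
#' @return invisibly, a list with the `summary`, the `result`, the `gas`
#'   stage output (or `NULL`) and the vector of written `paths`
#' @export
run_pipeline <- function(config, outdir, transport = TRUE, sim_stride = 5L) {
  stopifnot(inherits(config, "neovent_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  log_lines <- c(sprintf("neovent %s | R %s", as.character(utils::packageVersion("neovent")),
                         paste(R.version$major, R.version$minor, sep = ".")),
                 sprintf("config hash %s | seed %d", config_hash(config), config$seed))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    log_lines <<- c(log_lines, sprintf("stage %-14s %6.2f s", name,
                                       as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }
  paths <- character(0)
  emit <- function(name) {
    p <- file.path(outdir, name)
    paths <<- c(paths, p)
    p
  }

  pieces <- stage("airway_tree", config_pieces(config))
  write_tree(pieces$tree, emit("tree.csv"))

  maneuver <- stage("synthetic_sot", make_sot_maneuver(
    config$patient, config$sot$resistance,
    config$sot$occlusion_volume_per_kg * config$patient$body_mass,
    noise_sd = config$sot$noise_sd, seed = config$seed + 2000L))
  write_sot_maneuver(maneuver, emit("sot_maneuver.csv"))
  mech <- stage("mechanics", estimate_crs_sot(maneuver))
  jsonlite::write_json(unclass(mech), emit("mechanics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_mechanics_map(pieces$c_eq, pieces$r_eq, emit("mechanics_map.csv"))

  result <- stage("flow_solver", simulate_hfov(config))
  write_simulation(result, emit("simulation.csv"), stride = sim_stride)

  gas <- NULL
  if (transport) {
    gas <- stage("gas_transport", run_gas_transport(result, config$transport))
    write_gas_snapshots(gas, emit("gas_final.csv"))
    utils::write.csv(oxygen_budget(gas), emit("oxygen_budget.csv"),
                     row.names = FALSE)
    utils::write.csv(oxygen_delivery_metrics(gas), emit("oxygen_delivery.csv"),
                     row.names = FALSE)
  }

  regimes <- stage("diagnostics", classify_regimes(result))
  write_regimes(regimes, emit("regimes.csv"))
  summary <- summarise_run(result, gas)
  write_summary(summary, emit("run_summary.json"), emit("report.txt"))

  echo <- rapply(unclass(config), function(x) x, how = "list")
  yaml::write_yaml(list(config_hash = config_hash(config), config = echo),
                   emit("config_echo.yaml"))
  log_lines <- c(log_lines, sprintf("total %6.2f s",
                                    as.numeric(difftime(Sys.time(), t_start, units = "secs"))))
  writeLines(log_lines, emit("log.txt"))
  invisible(list(summary = summary, result = result, gas = gas, paths = paths))
}
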