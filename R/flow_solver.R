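#' Build the unsteady 0D airway network
#'
#' Assembles the resolved tree, endotracheal tube, terminal
#' resistance-compliance units and leak branch into a linear nodal-analysis
#' system, prefactorised for the two boundary-condition phases of an HFOV
#' cycle:
#' \itemize{
#'   \item inspiration: the prescribed half-sine source flow enters the
#'     airway-opening node, which floats; the leak branch connects it to
#'     ambient.
#'   \item expiration: the opening node is clamped at PEEP (pressure zero in
#'     the PEEP-relative convention) and flow develops freely from regional
#'     mechanics.
#' }
#' Terminal units are closed implicitly: with the trapezoidal scheme
#' (default) each unit contributes an effective conductance
#' `1 / (r_eq + dt/(2 c_eq))` towards a state-dependent source pressure;
#' `implicit_euler` uses `1 / (r_eq + dt/c_eq)`. Both are unconditionally
#' stable for the stiff R-C network; the trapezoidal variant is
#' second-order accurate in time.
#'
#' All pressures are relative to the PEEP baseline; `delta_v` is the volume
#' stored above the PEEP-equilibrated FRC. Segment pressure drops are
#' laminar (Poiseuille); an optional nonlinearity factor scales the
#' resistance of generations 0-1 (trachea and main bronchi), and an
#' optional inertance `rho L / A` per segment can be enabled
#' (backward-difference).
#'
#' @param tree a `neovent_tree`
#' @param c_eq named compliance vector (ml/kPa), one entry per terminal
#' @param r_eq named equivalent downstream resistance vector (kPa s/ml),
#'   same names as `c_eq`
#' @param tube a `neovent_tube`
#' @param leak a `neovent_leak`, or `NULL` for a leak-free circuit
#' @param settings a `neovent_hfov`
#' @param body_mass patient mass (kg)
#' @param air a `neovent_air`
#' @param steps_per_insp inspiratory steps; `dt = t_insp / steps_per_insp`
#' @param scheme `"trapezoidal"` (default) or `"implicit_euler"` terminal
#'   closure
#' @param inertance logical; include segment gas inertance
#' @param nonlinearity_factor resistance multiplier for generations 0-1
#' @return an object of class `neovent_network` holding the prefactorised
#'   phase systems and index maps
#' @export
build_network <- function(tree, c_eq, r_eq, tube, leak, settings, body_mass,
                          air = air_properties(),
                          steps_per_insp = 200L,
                          scheme = c("trapezoidal", "implicit_euler"),
                          inertance = FALSE,
                          nonlinearity_factor = 1) {
  stopifnot(inherits(tree, "neovent_tree"), inherits(tube, "neovent_tube"),
            inherits(settings, "neovent_hfov"), inherits(air, "neovent_air"))
  scheme <- match.arg(scheme)
  if (!is.null(leak)) stopifnot(inherits(leak, "neovent_leak"))
  if (steps_per_insp < 50)
    warning("dt exceeds t_insp/50; time resolution may be too coarse for ",
            "the oscillatory pressures", call. = FALSE)

  s <- tree$segments
  n_seg <- nrow(s)
  term <- which(s$is_terminal)
  if (!identical(names(c_eq), s$id[term]) || !identical(names(r_eq), s$id[term]))
    stop("c_eq / r_eq names must match the tree's terminal ids in order",
         call. = FALSE)
  if (any(c_eq <= 0))
    stop("terminal closure is singular: non-positive compliance in c_eq",
         call. = FALSE)
  if (any(r_eq < 0)) stop("r_eq must be non-negative", call. = FALSE)

  tim <- inspiratory_times(settings)
  dt_i <- tim$t_insp / steps_per_insp
  n_exp_steps <- max(1L, round(tim$t_exp / dt_i))
  dt_e <- tim$t_exp / n_exp_steps

  # nodes: 1 = airway opening (Y piece / tube proximal), 2 = tube distal
  # (trachea proximal), 2 + i = distal end of segment i
  n_nodes <- n_seg + 2L
  parent_idx <- match(s$parent_id, s$id)
  edge_from <- ifelse(is.na(parent_idx), 2L, parent_idx + 2L)
  edge_to <- seq_len(n_seg) + 2L

  r_seg <- poiseuille_resistance(s$length_mm, s$diameter_mm, air)
  r_seg[s$generation <= 1L] <- r_seg[s$generation <= 1L] * nonlinearity_factor
  area_mm2 <- pi * (s$diameter_mm / 2)^2
  # inertance rho L / A in kPa s^2 / ml: rho[kg/m^3] L[m] / A[m^2] = Pa s^2/m^3
  inert <- if (inertance) {
    air$density * (s$length_mm * 1e-3) / (area_mm2 * 1e-6) * 1e-9
  } else rep(0, n_seg)
  tube_inert <- if (inertance) {
    air$density * (tube$length * 1e-3) /
      (pi * (tube$inner_diameter / 2)^2 * 1e-6) * 1e-9
  } else 0

  lin_leak <- !is.null(leak) && leak$regime == "linear"
  g_leak <- if (lin_leak) 1 / leak$resistance else 0

  half <- if (scheme == "trapezoidal") 0.5 else 1
  make_phase <- function(dt, inspiratory, half) {
    r_edge <- c(tube$resistance + tube_inert / dt, r_seg + inert / dt)
    g_edge <- 1 / r_edge
    ef <- c(1L, edge_from)
    et <- c(2L, edge_to)
    A <- matrix(0, n_nodes, n_nodes)
    for (e in seq_along(g_edge)) {
      A[ef[e], ef[e]] <- A[ef[e], ef[e]] + g_edge[e]
      A[et[e], et[e]] <- A[et[e], et[e]] + g_edge[e]
      A[ef[e], et[e]] <- A[ef[e], et[e]] - g_edge[e]
      A[et[e], ef[e]] <- A[et[e], ef[e]] - g_edge[e]
    }
    g_term <- 1 / (r_eq + half * dt / c_eq)
    tn <- term + 2L
    A[cbind(tn, tn)] <- A[cbind(tn, tn)] + g_term
    if (inspiratory && lin_leak) A[1, 1] <- A[1, 1] + g_leak
    keep <- if (inspiratory) seq_len(n_nodes) else 2:n_nodes
    Ainv <- tryCatch(solve(A[keep, keep]),
                     error = function(e) stop(
                       "network system is singular (check terminal closure: ",
                       conditionMessage(e), ")", call. = FALSE))
    list(dt = dt, Ainv = Ainv, g_edge = g_edge, g_term = g_term,
         keep = keep, inspiratory = inspiratory, half = half)
  }

  structure(list(
    tree = tree, tube = tube, leak = leak, settings = settings,
    body_mass = body_mass, air = air, scheme = scheme, half = half,
    inertance = inertance, nonlinearity_factor = nonlinearity_factor,
    n_seg = n_seg, n_nodes = n_nodes, term = term,
    edge_from = c(1L, edge_from), edge_to = c(2L, edge_to),
    c_eq = c_eq, r_eq = r_eq, g_leak = g_leak,
    timing = tim, dt_i = dt_i, dt_e = dt_e, n_insp_steps = as.integer(steps_per_insp),
    n_exp_steps = n_exp_steps,
    phase_i = make_phase(dt_i, TRUE, half), phase_e = make_phase(dt_e, FALSE, half),
    # the boundary-condition switch makes flows discontinuous; the first
    # step of each phase uses implicit Euler so the trapezoidal memory
    # never straddles the jump
    phase_i_first = make_phase(dt_i, TRUE, 1),
    phase_e_first = make_phase(dt_e, FALSE, 1)
  ), class = "neovent_network")
}

#' Initial network state
#'
#' The lung starts at the PEEP-equilibrated FRC: all stored volumes, flows
#' and PEEP-relative pressures are zero.
#'
#' @param network a `neovent_network`
#' @return a `neovent_state` list: `time`, `delta_v`, `q_term`,
#'   `edge_flows` (tube first, then segments), `pressures` (nodal, incl.
#'   opening), `q_leak`, `q_source`, `cum_source`, `cum_leak`
#' @export
network_state_init <- function(network) {
  structure(list(
    time = 0,
    delta_v = stats::setNames(rep(0, length(network$term)), names(network$c_eq)),
    q_term = stats::setNames(rep(0, length(network$term)), names(network$c_eq)),
    edge_flows = rep(0, network$n_seg + 1L),
    pressures = rep(0, network$n_nodes),
    q_leak = if (is.null(network$leak)) 0 else
      leak_flow(network$leak, network$settings$peep_kpa, network$air),
    # at rest the ventilator's bias supply exactly feeds the PEEP-driven leak
    q_source = if (is.null(network$leak)) 0 else
      leak_flow(network$leak, network$settings$peep_kpa, network$air),
    cum_source = 0, cum_leak = 0
  ), class = "neovent_state")
}

# Advance the network by one step to time t_new. Internal core shared by
# assemble_and_step() and simulate_hfov().
network_advance <- function(network, state, t_new) {
  tim <- network$timing
  phase_t <- t_new %% tim$period
  # the instant t = t_insp belongs to inspiration; a time landing exactly on
  # a period boundary is the last expiratory step
  inspiratory <- phase_t > 1e-12 && phase_t <= tim$t_insp + 1e-12
  old_t <- state$time %% tim$period
  old_inspiratory <- old_t > 1e-12 && old_t <= tim$t_insp + 1e-12
  switched <- inspiratory != old_inspiratory
  ph <- if (inspiratory) {
    if (switched) network$phase_i_first else network$phase_i
  } else {
    if (switched) network$phase_e_first else network$phase_e
  }
  dt <- t_new - state$time
  half <- ph$half
  peep <- network$settings$peep_kpa

  # terminal source pressures for the implicit closure
  p_src <- state$delta_v / network$c_eq +
    (if (half == 0.5) half * dt * state$q_term / network$c_eq else 0)

  b <- rep(0, network$n_nodes)
  tn <- network$term + 2L
  b[tn] <- b[tn] + ph$g_term * p_src

  # inertance memory terms: edge law p_from - p_to = R_eff q - (I/dt) q_prev
  if (network$inertance) {
    # I/dt equals R_eff minus the resistive part; recover it from stored flows
    i_over_dt <- 1 / ph$g_edge - edge_resistive(network)
    emf <- i_over_dt * state$edge_flows
    b[network$edge_from] <- b[network$edge_from] - ph$g_edge * emf
    b[network$edge_to] <- b[network$edge_to] + ph$g_edge * emf
  }

  q_source_new <- 0
  orifice <- !is.null(network$leak) && network$leak$regime == "orifice"
  if (ph$inspiratory) {
    q_source_new <- flow_waveform(network$settings, network$body_mass, t_new)
    b[1] <- b[1] + q_source_new
    if (!is.null(network$leak) && network$leak$regime == "linear")
      b[1] <- b[1] - network$g_leak * peep
  }

  solve_nodal <- function(b_eff) {
    p <- rep(0, network$n_nodes)
    p[ph$keep] <- as.numeric(ph$Ainv %*% b_eff[ph$keep])
    p
  }

  if (ph$inspiratory && orifice) {
    # Picard iteration: orifice leak treated as a pressure-dependent sink
    p <- state$pressures
    for (iter in 1:12) {
      ql <- leak_flow(network$leak, p[1] + peep, network$air)
      p_new <- solve_nodal(`[<-`(b, 1, b[1] - ql))
      if (max(abs(p_new - p)) < 1e-10) { p <- p_new; break }
      p <- (p + p_new) / 2
    }
    q_leak_new <- leak_flow(network$leak, p[1] + peep, network$air)
  } else {
    p <- solve_nodal(b)
    q_leak_new <- if (is.null(network$leak)) 0 else
      leak_flow(network$leak, p[1] + peep, network$air)
  }

  edge_flows <- ph$g_edge * (p[network$edge_from] - p[network$edge_to])
  if (network$inertance) {
    i_over_dt <- 1 / ph$g_edge - edge_resistive(network)
    edge_flows <- edge_flows + ph$g_edge * (i_over_dt * state$edge_flows)
  }
  q_term_new <- ph$g_term * (p[tn] - p_src)
  delta_v_new <- state$delta_v +
    if (half == 0.5) half * dt * (state$q_term + q_term_new)
    else dt * q_term_new

  if (!ph$inspiratory) {
    # ventilator boundary flow balancing the clamped opening node
    q_source_new <- q_leak_new + edge_flows[1]
  }

  structure(list(
    time = t_new,
    delta_v = delta_v_new,
    q_term = q_term_new,
    edge_flows = edge_flows,
    pressures = p,
    q_leak = q_leak_new,
    q_source = q_source_new,
    # same quadrature as the delta_v update so the volume-closure identity
    # cum_source - cum_leak - sum(delta_v) = 0 holds to machine precision
    cum_source = state$cum_source +
      dt * ((1 - half) * state$q_source + half * q_source_new),
    cum_leak = state$cum_leak +
      dt * ((1 - half) * state$q_leak + half * q_leak_new)
  ), class = "neovent_state")
}

edge_resistive <- function(network) {
  s <- network$tree$segments
  r_seg <- poiseuille_resistance(s$length_mm, s$diameter_mm, network$air)
  r_seg[s$generation <= 1L] <- r_seg[s$generation <= 1L] * network$nonlinearity_factor
  c(network$tube$resistance, r_seg)
}

#' Advance the network state by one time step
#'
#' One implicit step of the coupled nodal-conservation / segment
#' pressure-drop / terminal-closure system, with the boundary condition
#' appropriate to the phase of the cycle containing the new time (prescribed
#' source flow during inspiration, PEEP-clamped opening during expiration).
#'
#' @param network a `neovent_network`
#' @param state a `neovent_state`
#' @param dt step length (s), > 0; must not cross a phase boundary
#' @return the advanced `neovent_state`
#' @export
assemble_and_step <- function(network, state, dt) {
  check_positive(dt, "dt")
  network_advance(network, state, state$time + dt)
}

#' Run an HFOV simulation
#'
#' Executes `n_cycles` ventilation periods of the assembled network at a
#' fixed inspiratory step `t_insp / steps_per_insp` (the expiratory step is
#' matched to divide the expiratory phase evenly), recording the full state
#' trajectory. Deterministic given the configuration.
#'
#' @param config a `neovent_config` from [neovent_config()]
#' @param record_segments logical; record the per-segment flow matrix
#'   (needed for pendelluft detection and gas transport)
#' @return an object of class `neovent_sim`: list with `times`,
#'   `source_flow` (ventilator boundary flow, ml/s), `inlet_flow` (flow at
#'   the proximal end of the endotracheal tube, ml/s), `leak_flow` (ml/s),
#'   `opening_pressure` (kPa above PEEP), `lung_volume` (ml above the
#'   PEEP-equilibrated FRC), `terminal_volumes` (matrix time x terminal),
#'   `segment_flows` (matrix time x segment, or `NULL`),
#'   `cum_source`, `cum_leak` (ml), `cycle_ends` (row indices of cycle
#'   ends), `phase` (1 inspiration, 2 expiration), plus the `network` and
#'   `config` used
#' @export
simulate_hfov <- function(config, record_segments = TRUE) {
  stopifnot(inherits(config, "neovent_config"))
  pieces <- config_pieces(config)
  network <- pieces$network
  settings <- network$settings
  n_cycles <- settings$n_cycles
  n_i <- network$n_insp_steps
  n_e <- network$n_exp_steps
  steps_per_cycle <- n_i + n_e
  n_rows <- n_cycles * steps_per_cycle + 1L

  n_term <- length(network$term)
  times <- numeric(n_rows)
  source_flow <- numeric(n_rows)
  inlet_flow <- numeric(n_rows)
  lk_flow <- numeric(n_rows)
  opening_pressure <- numeric(n_rows)
  lung_volume <- numeric(n_rows)
  cum_source <- numeric(n_rows)
  cum_leak <- numeric(n_rows)
  phase <- integer(n_rows)
  terminal_volumes <- matrix(0, n_rows, n_term,
                             dimnames = list(NULL, names(network$c_eq)))
  segment_flows <- if (record_segments)
    matrix(0, n_rows, network$n_seg,
           dimnames = list(NULL, network$tree$segments$id)) else NULL

  state <- network_state_init(network)
  lk_flow[1] <- state$q_leak
  row <- 1L
  tim <- network$timing
  for (cycle in seq_len(n_cycles)) {
    t0 <- (cycle - 1L) * tim$period
    step_times <- c(t0 + seq_len(n_i) * network$dt_i,
                    t0 + tim$t_insp + seq_len(n_e) * network$dt_e)
    for (k in seq_along(step_times)) {
      state <- network_advance(network, state, step_times[k])
      row <- row + 1L
      times[row] <- state$time
      source_flow[row] <- state$q_source
      inlet_flow[row] <- state$edge_flows[1]
      lk_flow[row] <- state$q_leak
      opening_pressure[row] <- state$pressures[1]
      lung_volume[row] <- sum(state$delta_v)
      cum_source[row] <- state$cum_source
      cum_leak[row] <- state$cum_leak
      phase[row] <- if (k <= n_i) 1L else 2L
      terminal_volumes[row, ] <- state$delta_v
      if (record_segments) segment_flows[row, ] <- state$edge_flows[-1]
    }
  }

  structure(list(
    times = times, source_flow = source_flow, inlet_flow = inlet_flow,
    leak_flow = lk_flow, opening_pressure = opening_pressure,
    lung_volume = lung_volume, terminal_volumes = terminal_volumes,
    segment_flows = segment_flows,
    cum_source = cum_source, cum_leak = cum_leak,
    cycle_ends = 1L + seq_len(n_cycles) * steps_per_cycle,
    phase = phase,
    network = network, config = config
  ), class = "neovent_sim")
}

#' First cycle at which end-expiratory volume has stabilised
#'
#' Scans end-expiratory volumes (EEV) cycle by cycle and returns the first
#' cycle `k >= 2` whose EEV differs from the previous cycle's by less than
#' `tol_fraction_of_vt` times the absolute tidal volume, i.e. the cycle at
#' which the respiratory system and the ventilator have reached a steady
#' state. Returns `NA` if never reached.
#'
#' @param result a `neovent_sim`
#' @param tol_fraction_of_vt tolerance as a fraction of tidal volume
#'   (default 0.02)
#' @return integer cycle index, or `NA`
#' @export
detect_steady_state <- function(result, tol_fraction_of_vt = 0.02) {
  stopifnot(inherits(result, "neovent_sim"))
  eev <- result$lung_volume[result$cycle_ends]
  if (length(eev) < 2) stop("need at least 2 complete cycles", call. = FALSE)
  vt <- result$network$settings$tidal_volume_per_kg * result$network$body_mass
  d <- abs(diff(eev))
  hit <- which(d < tol_fraction_of_vt * vt)
  if (length(hit) == 0) NA_integer_ else hit[1] + 1L
}

#' Detect pendelluft events
#'
#' Pendelluft is gas exchange between lung regions of unequal time
#' constants: at some instant, one sibling branch carries flow distally
#' while the other carries it proximally, so gas moves from one region into
#' the other rather than through the airway opening. An event is any
#' recorded sample at which two sibling segments carry opposite-signed
#' flows, both exceeding `threshold_fraction` times the peak flow at the
#' tube's proximal end in magnitude.
#'
#' @param result a `neovent_sim` with recorded segment flows
#' @param threshold_fraction magnitude threshold as a fraction of peak
#'   inlet flow (default 0.01)
#' @return data frame with one row per event: `time`, `parent_id`,
#'   `sibling_a`, `sibling_b`, `flow_a`, `flow_b` (ml/s)
#' @export
detect_pendelluft <- function(result, threshold_fraction = 0.01) {
  stopifnot(inherits(result, "neovent_sim"))
  if (is.null(result$segment_flows))
    stop("per-segment flows were not recorded; rerun with record_segments = TRUE",
         call. = FALSE)
  s <- result$network$tree$segments
  q <- result$segment_flows
  thr <- threshold_fraction * max(abs(result$inlet_flow))

  out <- list()
  parents <- unique(s$parent_id[!is.na(s$parent_id)])
  for (p in parents) {
    kids <- which(s$parent_id %in% p)
    if (length(kids) != 2L) next
    qa <- q[, kids[1]]; qb <- q[, kids[2]]
    hit <- which(qa * qb < 0 & abs(qa) > thr & abs(qb) > thr)
    if (length(hit) > 0) {
      out[[length(out) + 1L]] <- data.frame(
        time = result$times[hit], parent_id = p,
        sibling_a = s$id[kids[1]], sibling_b = s$id[kids[2]],
        flow_a = qa[hit], flow_b = qb[hit], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    data.frame(time = numeric(0), parent_id = character(0),
               sibling_a = character(0), sibling_b = character(0),
               flow_a = numeric(0), flow_b = numeric(0),
               stringsAsFactors = FALSE)
  } else {
    ev <- do.call(rbind, out)
    ev[order(ev$time, ev$parent_id), , drop = FALSE]
  }
}

#' Write a simulation result as tidy long-format CSV
#'
#' Columns `time`, `variable`, `id`, `value`. Global channels use an empty
#' `id`; per-terminal volumes and per-segment flows carry the segment id.
#'
#' @param result a `neovent_sim`
#' @param path output file path
#' @param stride keep every `stride`-th time sample (default 1 = all)
#' @return `path`, invisibly
#' @export
write_simulation <- function(result, path, stride = 1L) {
  stopifnot(inherits(result, "neovent_sim"))
  keep <- seq(1, length(result$times), by = stride)
  glob <- function(var, x) data.frame(time = result$times[keep], variable = var,
                                      id = "", value = x[keep],
                                      stringsAsFactors = FALSE)
  pieces <- list(glob("source_flow", result$source_flow),
                 glob("inlet_flow", result$inlet_flow),
                 glob("leak_flow", result$leak_flow),
                 glob("lung_volume", result$lung_volume))
  tv <- result$terminal_volumes[keep, , drop = FALSE]
  pieces <- c(pieces, list(data.frame(
    time = rep(result$times[keep], ncol(tv)),
    variable = "terminal_volume",
    id = rep(colnames(tv), each = length(keep)),
    value = as.vector(tv), stringsAsFactors = FALSE)))
  utils::write.csv(do.call(rbind, pieces), path, row.names = FALSE)
  invisible(path)
}
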