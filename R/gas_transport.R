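#' Oxygen-transport parameters
#'
#' Governs the 1D finite-volume solution of the oxygen advection-diffusion
#' equation on the airway tree,
#' `dPhi/dt + u dPhi/dx - d/dx(D dPhi/dx) = 0`,
#' with `u = Q/A` the per-segment mean velocity taken from the flow
#' solution and `D` the molecular diffusivity of oxygen in air. The inlet
#' concentration is the inspired oxygen fraction; generation-seven outlets
#' carry a zero-gradient condition (oxygen that leaves the resolved tree is
#' taken up by the subtended acinar region). The scheme is first-order
#' upwind in the advective fluxes and central in the diffusive ones,
#' explicit in time with automatic sub-cycling to respect the CFL bound.
#'
#' @param diffusivity_cm2s molecular diffusivity (cm^2/s); default 0.219
#'   for oxygen in air
#' @param inlet_concentration oxygen volume fraction of the delivered gas
#'   (defaults to 0.35, the prescription's FiO2)
#' @param cells_per_segment finite-volume cells per airway segment
#' @param scheme advection scheme (first-order upwind)
#' @param initial_concentration oxygen fraction filling the lung at start
#'   (0.21: room air)
#' @param cfl Courant number for the sub-cycled explicit steps
#' @param include_tube logical; include the endotracheal tube in the
#'   transport domain (needed to account for leak efflux)
#' @return an object of class `neovent_transport_params`
#' @export
transport_params <- function(diffusivity_cm2s = 0.219,
                             inlet_concentration = 0.35,
                             cells_per_segment = 20L,
                             scheme = "upwind",
                             initial_concentration = 0.21,
                             cfl = 0.9,
                             include_tube = TRUE) {
  check_nonnegative(diffusivity_cm2s, "diffusivity_cm2s") # 0 = pure advection
  if (inlet_concentration <= 0 || inlet_concentration > 1)
    fail_field("inlet_concentration", "must lie in (0, 1]")
  if (cells_per_segment < 2) fail_field("cells_per_segment", "must be >= 2")
  if (!identical(scheme, "upwind")) fail_field("scheme", "only 'upwind' is implemented")
  check_nonnegative(initial_concentration, "initial_concentration")
  if (cfl <= 0 || cfl > 1) fail_field("cfl", "must lie in (0, 1]")
  structure(list(diffusivity_cm2s = diffusivity_cm2s,
                 diffusivity = cm2s_to_mm2s(diffusivity_cm2s),
                 inlet_concentration = inlet_concentration,
                 cells_per_segment = as.integer(cells_per_segment),
                 scheme = scheme,
                 initial_concentration = initial_concentration,
                 cfl = cfl, include_tube = include_tube),
            class = "neovent_transport_params")
}

#' Initialise the oxygen field on a tree
#'
#' Discretises every airway segment (and, by default, the endotracheal
#' tube) into equal finite-volume cells and fills them with the initial
#' concentration.
#'
#' @param tree a `neovent_tree`
#' @param tube a `neovent_tube`, or `NULL` when `include_tube` is `FALSE`
#' @param params a `neovent_transport_params`
#' @return an object of class `neovent_gas_field`: the concentration matrix
#'   `phi` (`cells_per_segment` rows, one column per transport unit), unit
#'   geometry, junction maps and running budget accumulators
#' @export
gas_field_init <- function(tree, tube = NULL, params = transport_params()) {
  stopifnot(inherits(tree, "neovent_tree"),
            inherits(params, "neovent_transport_params"))
  s <- tree$segments
  n_seg <- nrow(s)
  off <- if (params$include_tube) 1L else 0L
  if (params$include_tube) stopifnot(inherits(tube, "neovent_tube"))

  unit_id <- c(if (off) "tube", s$id)
  length_mm <- c(if (off) tube$length, s$length_mm)
  diameter_mm <- c(if (off) tube$inner_diameter, s$diameter_mm)
  n_units <- n_seg + off
  area_mm2 <- pi * (diameter_mm / 2)^2
  n_c <- params$cells_per_segment
  dx <- length_mm / n_c
  v_cell <- area_mm2 * dx # mm^3

  # junction nodes: one per non-terminal segment (two children), plus the
  # tube-trachea node (single child) when the tube is included
  parent_idx <- match(s$parent_id, s$id)
  kids1 <- kids2 <- rep(NA_integer_, n_seg)
  for (i in seq_len(n_seg)) {
    k <- which(parent_idx == i)
    if (length(k) == 2L) { kids1[i] <- k[1]; kids2[i] <- k[2] }
  }
  nt <- which(!s$is_terminal)
  root <- which(is.na(parent_idx))

  phi <- matrix(params$initial_concentration, n_c, n_units,
                dimnames = list(NULL, unit_id))
  structure(list(
    phi = phi, time = 0,
    unit_id = unit_id, length_mm = length_mm, area_mm2 = area_mm2,
    dx = dx, v_cell = v_cell, n_c = n_c, n_units = n_units, off = off,
    terminal_units = which(c(if (off) FALSE, s$is_terminal)),
    node_parent = nt + off, node_child1 = kids1[nt] + off,
    node_child2 = kids2[nt] + off,
    root_unit = root + off,
    params = params,
    budget = list(source_in = 0, vent_out = 0, leak_out = 0,
                  outlet_out = 0, initial_content = sum(phi * rep(v_cell, each = n_c)))
  ), class = "neovent_gas_field")
}

# stable explicit step for given unit velocities (mm/s)
transport_stable_dt <- function(field, u) {
  d <- field$params$diffusivity
  adv <- ifelse(abs(u) > 0, field$dx / abs(u), Inf)
  dif <- field$dx^2 / (2 * d)
  field$params$cfl * min(c(adv, dif))
}

#' Advance the oxygen field over one flow step
#'
#' Advances the concentration field by `dt` under piecewise-constant
#' volumetric flows, sub-cycling the explicit upwind scheme so every
#' sub-step respects the CFL bound (set `subcycle = FALSE` to forbid
#' sub-cycling, in which case a `dt` above the bound is an error naming the
#' limiting segment). Junctions are zero-volume perfect mixers: the node
#' concentration is the flow-weighted average of the streams entering the
#' node, and every stream leaving carries it. The airway-opening node mixes
#' the ventilator source gas (at the inlet concentration, whenever the
#' ventilator flow is directed into the circuit) with any gas returning
#' from the tube; the leak stream leaves from this node. Terminal outlets
#' are zero-gradient.
#'
#' @param field a `neovent_gas_field`
#' @param unit_flows volumetric flow per transport unit (ml/s, tube first
#'   when included), positive distal-ward
#' @param q_source ventilator boundary flow at the opening (ml/s, positive
#'   into the circuit)
#' @param q_leak leak flow at the opening (ml/s, positive out)
#' @param dt flow-step length (s)
#' @param subcycle logical; sub-cycle to satisfy the CFL bound
#' @return the advanced `neovent_gas_field`
#' @export
advance_transport <- function(field, unit_flows, q_source, q_leak, dt,
                              subcycle = TRUE) {
  stopifnot(inherits(field, "neovent_gas_field"))
  check_positive(dt, "dt")
  if (length(unit_flows) != field$n_units)
    stop(sprintf("expected %d unit flows, got %d", field$n_units,
                 length(unit_flows)), call. = FALSE)
  q_mm3 <- unit_flows * 1000 # ml/s -> mm^3/s
  u <- q_mm3 / field$area_mm2
  dt_max <- transport_stable_dt(field, u)
  if (!subcycle && dt > dt_max) {
    lim <- which.min(ifelse(abs(u) > 0, field$dx / abs(u), Inf))
    stop(sprintf("CFL violation: dt = %.3g s exceeds stable %.3g s (limiting segment '%s')",
                 dt, dt_max, field$unit_id[lim]), call. = FALSE)
  }
  n_sub <- max(1L, ceiling(dt / dt_max))
  h <- dt / n_sub

  n_c <- field$n_c
  phi <- field$phi
  d <- field$params$diffusivity
  fio2 <- field$params$inlet_concentration

  # per-unit constants for this flow step
  upwind_pos <- q_mm3 > 0
  coef_diff_face <- d * field$area_mm2 / field$dx      # within-unit faces
  # junction diffusive coupling child-first <-> parent-last
  np <- field$node_parent; c1 <- field$node_child1; c2 <- field$node_child2
  gap1 <- (field$dx[np] + field$dx[c1]) / 2
  gap2 <- (field$dx[np] + field$dx[c2]) / 2
  coef_j1 <- d * field$area_mm2[c1] / gap1
  coef_j2 <- d * field$area_mm2[c2] / gap2
  ru <- field$root_unit
  has_tube <- field$off == 1L
  if (has_tube) {
    gap_t <- (field$dx[1] + field$dx[ru]) / 2
    coef_jt <- d * field$area_mm2[ru] / gap_t
  }
  inv_v <- 1 / field$v_cell
  term <- field$terminal_units

  b <- field$budget
  qs_in <- max(q_source, 0) * 1000
  qs_out <- max(-q_source, 0) * 1000
  ql <- q_leak * 1000
  q_open <- q_mm3[1] # tube (or root) flow at the opening

  for (sub in seq_len(n_sub)) {
    first <- phi[1, ]
    last <- phi[n_c, ]

    # opening node: incoming = ventilator source (fresh gas) and/or tube return
    w_in <- qs_in + max(-q_open, 0)
    phi_y <- if (w_in > 0) {
      (qs_in * fio2 + max(-q_open, 0) * first[1]) / w_in
    } else first[1]

    # internal junction nodes (two children) and the tube-trachea node
    wp <- pmax(q_mm3[np], 0)
    w1 <- pmax(-q_mm3[c1], 0)
    w2 <- pmax(-q_mm3[c2], 0)
    wsum <- wp + w1 + w2
    phi_node <- ifelse(wsum > 0,
                       (wp * last[np] + w1 * first[c1] + w2 * first[c2]) /
                         pmax(wsum, .Machine$double.xmin),
                       (last[np] + first[c1] + first[c2]) / 3)
    if (has_tube) {
      wt <- max(q_mm3[1], 0); wr <- max(-q_mm3[ru], 0)
      phi_tr <- if (wt + wr > 0) (wt * last[1] + wr * first[ru]) / (wt + wr)
                else (last[1] + first[ru]) / 2
    }

    # within-unit faces: advective upwind + central diffusion
    if (n_c > 1) {
      up <- phi[-n_c, , drop = FALSE]
      dn <- phi[-1, , drop = FALSE]
      face_adv <- sweep(up, 2, q_mm3 * upwind_pos, `*`) +
        sweep(dn, 2, q_mm3 * (!upwind_pos), `*`)
      face_diff <- -sweep(dn - up, 2, coef_diff_face, `*`)
      face <- face_adv + face_diff
    } else face <- matrix(0, 0, field$n_units)

    # proximal boundary flux per unit (positive = into the unit's first cell)
    b_prox <- numeric(field$n_units)
    # distal boundary flux per unit (positive = out of the unit's last cell)
    b_dist <- numeric(field$n_units)

    # opening <-> first unit
    b_prox[1] <- if (q_mm3[1] >= 0) q_mm3[1] * phi_y else q_mm3[1] * first[1]
    if (has_tube) {
      # tube distal face and root proximal face share the tube-trachea node
      adv_t <- if (q_mm3[1] >= 0) q_mm3[1] * last[1] else q_mm3[1] * phi_tr
      adv_r <- if (q_mm3[ru] >= 0) q_mm3[ru] * phi_tr else q_mm3[ru] * first[ru]
      dif_t <- -coef_jt * (first[ru] - last[1])
      b_dist[1] <- adv_t + dif_t
      b_prox[ru] <- adv_r + dif_t
    }

    # junction faces: parent distal / child proximal
    adv_p <- ifelse(q_mm3[np] >= 0, q_mm3[np] * last[np], q_mm3[np] * phi_node)
    adv_1 <- ifelse(q_mm3[c1] >= 0, q_mm3[c1] * phi_node, q_mm3[c1] * first[c1])
    adv_2 <- ifelse(q_mm3[c2] >= 0, q_mm3[c2] * phi_node, q_mm3[c2] * first[c2])
    dif_1 <- -coef_j1 * (first[c1] - last[np])
    dif_2 <- -coef_j2 * (first[c2] - last[np])
    b_dist[np] <- adv_p + dif_1 + dif_2
    b_prox[c1] <- adv_1 + dif_1
    b_prox[c2] <- adv_2 + dif_2

    # terminal outlets: zero-gradient ghost (flux carries the last cell's phi
    # in either direction)
    b_dist[term] <- q_mm3[term] * last[term]

    influx <- rbind(b_prox, face, deparse.level = 0)
    efflux <- rbind(face, b_dist, deparse.level = 0)
    phi <- phi + h * sweep(influx - efflux, 2, inv_v, `*`)

    # budget accumulation (same quadrature as the update: exactly conservative)
    b$source_in <- b$source_in + h * qs_in * fio2
    b$vent_out <- b$vent_out + h * qs_out * phi_y
    b$leak_out <- b$leak_out + h * ql * phi_y
    b$outlet_out <- b$outlet_out + h * sum(q_mm3[term] * last[term])
  }

  field$phi <- phi
  field$time <- field$time + dt
  field$budget <- b
  field
}

#' Transport oxygen through a completed flow simulation
#'
#' Replays the recorded flow history through the 1D transport scheme:
#' each recorded flow sample is held constant over its step and the oxygen
#' field is advanced with automatic CFL sub-cycling. Records the
#' concentration in the distal cell of every terminal segment at every flow
#' sample, the cumulative oxygen budget, and optional full-field snapshots.
#'
#' @param result a `neovent_sim` with recorded segment flows
#' @param params a `neovent_transport_params`
#' @param snapshot_stride record a full-field snapshot every this many flow
#'   steps (0 = final field only)
#' @return an object of class `neovent_gas`: `times`, `terminal_phi`
#'   (matrix time x terminal), `budget_trace` (data frame of cumulative
#'   budget terms plus stored content and residual), `field` (final
#'   `neovent_gas_field`), `snapshots` (list of phi matrices), and the
#'   `params` used
#' @export
run_gas_transport <- function(result, params = transport_params(),
                              snapshot_stride = 0L) {
  stopifnot(inherits(result, "neovent_sim"))
  if (is.null(result$segment_flows))
    stop("gas transport needs recorded segment flows", call. = FALSE)
  net <- result$network
  field <- gas_field_init(net$tree,
                          if (params$include_tube) net$tube else NULL,
                          params)
  n_rows <- length(result$times)
  term_names <- net$tree$segments$id[net$term]
  term_units <- match(term_names, field$unit_id)
  terminal_phi <- matrix(NA_real_, n_rows, length(term_units),
                         dimnames = list(NULL, term_names))
  terminal_phi[1, ] <- field$phi[field$n_c, term_units]
  budget_rows <- vector("list", n_rows)
  content0 <- field$budget$initial_content
  budget_rows[[1]] <- c(source_in = 0, vent_out = 0, leak_out = 0,
                        outlet_out = 0, stored_delta = 0, residual = 0)
  snapshots <- list()

  for (n in 2:n_rows) {
    dt <- result$times[n] - result$times[n - 1]
    flows <- c(if (params$include_tube) result$inlet_flow[n],
               result$segment_flows[n, ])
    field <- advance_transport(field, flows, result$source_flow[n],
                               result$leak_flow[n], dt)
    terminal_phi[n, ] <- field$phi[field$n_c, term_units]
    b <- field$budget
    stored <- sum(field$phi * rep(field$v_cell, each = field$n_c))
    budget_rows[[n]] <- c(
      source_in = b$source_in, vent_out = b$vent_out, leak_out = b$leak_out,
      outlet_out = b$outlet_out, stored_delta = stored - content0,
      residual = b$source_in - b$vent_out - b$leak_out - b$outlet_out -
        (stored - content0))
    if (snapshot_stride > 0 && (n - 1) %% snapshot_stride == 0)
      snapshots[[as.character(result$times[n])]] <- field$phi
  }

  budget_trace <- as.data.frame(do.call(rbind, budget_rows))
  budget_trace$time <- result$times
  structure(list(times = result$times, terminal_phi = terminal_phi,
                 budget_trace = budget_trace, field = field,
                 snapshots = snapshots, params = params, result = result),
            class = "neovent_gas")
}

#' First-arrival times and delivery classification per terminal
#'
#' For every terminal region, finds the first time its distal cell's oxygen
#' fraction exceeds `threshold` and classifies delivery as `direct` (within
#' the first inflation: regions adjacent to the major airways receive fresh
#' gas during the very first inspiratory phase), `delayed` (first arrival
#' later within the recorded cycles) or `unreached`.
#'
#' @param gas a `neovent_gas`
#' @param threshold oxygen fraction defining arrival (default 0.25)
#' @return data frame: `outlet_id`, `first_arrival_s`, `classification`
#' @export
oxygen_delivery_metrics <- function(gas, threshold = 0.25) {
  stopifnot(inherits(gas, "neovent_gas"))
  if (threshold <= 0)
    fail_field("threshold", "must be positive")
  t_insp <- gas$result$network$timing$t_insp
  out <- data.frame(outlet_id = colnames(gas$terminal_phi),
                    first_arrival_s = NA_real_,
                    classification = "unreached",
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(gas$terminal_phi))) {
    hit <- which(gas$terminal_phi[, j] > threshold)
    if (length(hit) > 0) {
      ta <- gas$times[hit[1]]
      out$first_arrival_s[j] <- ta
      out$classification[j] <- if (ta <= t_insp + 1e-12) "direct" else "delayed"
    }
  }
  out
}

#' Per-cycle oxygen budget audit
#'
#' Differences the cumulative budget trace at cycle boundaries: for each
#' cycle, the oxygen entering at the ventilator source, leaving through the
#' leak, returning to the ventilator line, leaving through the
#' generation-seven outlets (consumed by the acinar regions), the change in
#' stored content, and the residual of the discrete balance.
#'
#' @param gas a `neovent_gas`
#' @return data frame with one row per cycle (volumes in mm^3 of O2)
#' @export
oxygen_budget <- function(gas) {
  stopifnot(inherits(gas, "neovent_gas"))
  ends <- gas$result$cycle_ends
  bt <- gas$budget_trace
  at <- function(col) bt[[col]][ends]
  d <- function(x) diff(c(0, x))
  data.frame(
    cycle = seq_along(ends),
    source_in = d(at("source_in")),
    vent_out = d(at("vent_out")),
    leak_out = d(at("leak_out")),
    outlet_out = d(at("outlet_out")),
    stored_delta = d(at("stored_delta")),
    residual = d(at("source_in")) - d(at("vent_out")) - d(at("leak_out")) -
      d(at("outlet_out")) - d(at("stored_delta"))
  )
}

#' Write oxygen-field snapshots to CSV
#'
#' Long format: `time_s`, `segment_id`, `cell_index`, `position_mm`, `phi`.
#' Positions are cell centres measured from the proximal end of each
#' segment.
#'
#' @param gas a `neovent_gas` produced with a positive `snapshot_stride`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_gas_snapshots <- function(gas, path) {
  stopifnot(inherits(gas, "neovent_gas"))
  snaps <- gas$snapshots
  if (length(snaps) == 0)
    snaps <- stats::setNames(list(gas$field$phi), gas$field$time)
  f <- gas$field
  pos <- as.vector(outer(seq_len(f$n_c) - 0.5, f$dx))
  rows <- lapply(names(snaps), function(tm) {
    data.frame(time_s = as.numeric(tm),
               segment_id = rep(f$unit_id, each = f$n_c),
               cell_index = rep(seq_len(f$n_c), f$n_units),
               position_mm = pos,
               phi = as.vector(snaps[[tm]]),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
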