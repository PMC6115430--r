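# Shared fixtures. Everything is generated in code; small trees and short
# runs keep the suite fast while exercising every code path.

# a manual single-segment "tree": one cylinder acting as both trachea and
# terminal, for closed-form single-compartment checks
one_segment_tree <- function(length_mm = 25, diameter_mm = 3.3) {
  seg <- data.frame(id = "g0_1", parent_id = NA_character_, generation = 0L,
                    length_mm = length_mm, diameter_mm = diameter_mm,
                    lobe = "main", is_terminal = TRUE, stringsAsFactors = FALSE)
  structure(list(segments = seg, root_id = "g0_1"), class = "neovent_tree")
}

# a small (3-generation, 15-segment) calibrated tree for solver tests
small_tree <- function(asymmetry = 0, jitter = 0, seed = 1) {
  generate_tree(morphometry_params(asymmetry_factor = asymmetry,
                                   jitter_sd = jitter, seed = seed),
                body_mass = 0.76, target_deadspace_per_kg = 2.2,
                max_generation = 3L)
}

# build and run an HFOV simulation on an arbitrary hand-built tree,
# mirroring simulate_hfov() but without going through a full configuration
run_small <- function(tree, settings = hfov_settings(n_cycles = 4L),
                      leak = leak_model("linear", resistance = 0.362),
                      c_weights = NULL, steps_per_insp = 100L,
                      extra_generations = 9L, crs = 20.93,
                      record_segments = TRUE, scheme = "trapezoidal") {
  term <- terminal_ids(tree)
  w <- if (is.null(c_weights)) rep(1 / length(term), length(term)) else c_weights
  c_eq <- partition_compliance(crs, tree, w)
  st <- tree$segments[tree$segments$is_terminal, ]
  r_eq <- stats::setNames(vapply(seq_len(nrow(st)), function(i)
    equivalent_downstream_resistance(st$diameter_mm[i], st$length_mm[i],
                                     extra_generations = extra_generations),
    numeric(1)), st$id)
  net <- build_network(tree, c_eq, r_eq, tube_model(), leak, settings, 0.76,
                       steps_per_insp = steps_per_insp, scheme = scheme)
  run_network(net)
}

# drive a pre-built network step by step and assemble a neovent_sim
run_network <- function(net, record_segments = TRUE) {
  n_cycles <- net$settings$n_cycles
  n_i <- net$n_insp_steps; n_e <- net$n_exp_steps
  tim <- net$timing
  n_rows <- n_cycles * (n_i + n_e) + 1L
  out <- list(times = numeric(n_rows), source_flow = numeric(n_rows),
              inlet_flow = numeric(n_rows), leak_flow = numeric(n_rows),
              opening_pressure = numeric(n_rows),
              lung_volume = numeric(n_rows),
              cum_source = numeric(n_rows), cum_leak = numeric(n_rows),
              phase = integer(n_rows))
  out$terminal_volumes <- matrix(0, n_rows, length(net$term),
                                 dimnames = list(NULL, names(net$c_eq)))
  out$segment_flows <- if (record_segments)
    matrix(0, n_rows, net$n_seg, dimnames = list(NULL, net$tree$segments$id))
  state <- network_state_init(net)
  out$leak_flow[1] <- state$q_leak
  out$source_flow[1] <- state$q_source
  row <- 1L
  for (cycle in seq_len(n_cycles)) {
    t0 <- (cycle - 1L) * tim$period
    ts <- c(t0 + seq_len(n_i) * net$dt_i,
            t0 + tim$t_insp + seq_len(n_e) * net$dt_e)
    for (k in seq_along(ts)) {
      state <- neovent:::network_advance(net, state, ts[k])
      row <- row + 1L
      out$times[row] <- state$time
      out$source_flow[row] <- state$q_source
      out$inlet_flow[row] <- state$edge_flows[1]
      out$leak_flow[row] <- state$q_leak
      out$opening_pressure[row] <- state$pressures[1]
      out$lung_volume[row] <- sum(state$delta_v)
      out$cum_source[row] <- state$cum_source
      out$cum_leak[row] <- state$cum_leak
      out$phase[row] <- if (k <= n_i) 1L else 2L
      out$terminal_volumes[row, ] <- state$delta_v
      if (record_segments) out$segment_flows[row, ] <- state$edge_flows[-1]
    }
  }
  out$cycle_ends <- 1L + seq_len(n_cycles) * (n_i + n_e)
  out$network <- net
  out$config <- NULL
  class(out) <- "neovent_sim"
  out
}
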