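test_that("pure advection moves the oxygen front at the mean velocity", {
  # single segment, no tube, no diffusion: method-of-characteristics oracle
  tr <- one_segment_tree(length_mm = 100, diameter_mm = 2)
  pars <- transport_params(diffusivity_cm2s = 0, cells_per_segment = 50,
                           initial_concentration = 0.21, include_tube = FALSE)
  f <- gas_field_init(tr, NULL, pars)
  area <- pi * 1^2          # mm^2
  q <- 0.1                  # ml/s -> u = 100/area mm/s
  u <- q * 1000 / area
  t_total <- 0.4
  f <- advance_transport(f, q, q_source = q, q_leak = 0, dt = t_total)
  front_exact <- u * t_total
  # front position: last cell centre above the midpoint concentration
  xc <- (seq_len(f$n_c) - 0.5) * f$dx
  front_num <- max(xc[f$phi[, 1] > (0.35 + 0.21) / 2])
  expect_lt(abs(front_num - front_exact), f$dx * 1.5)
  # upstream of the front is fully fresh
  expect_equal(unname(f$phi[1, 1]), 0.35, tolerance = 1e-5)
})

test_that("pure diffusion conserves total oxygen content", {
  tr <- small_tree()
  pars <- transport_params(include_tube = FALSE)
  f <- gas_field_init(tr, NULL, pars)
  # a non-uniform initial field, zero flow everywhere, closed ends
  f$phi[] <- 0.21 + 0.1 * sin(seq_len(length(f$phi)) / 7)
  content0 <- sum(f$phi * rep(f$v_cell, each = f$n_c))
  f2 <- advance_transport(f, rep(0, f$n_units), 0, 0, dt = 0.05)
  content1 <- sum(f2$phi * rep(f2$v_cell, each = f2$n_c))
  expect_equal(content1, content0, tolerance = 1e-10)
})

test_that("a uniform field at the inlet concentration is a fixed point", {
  tr <- small_tree()
  pars <- transport_params(initial_concentration = 0.35)
  f <- gas_field_init(tr, tube_model(), pars)
  flows <- c(1, 2^-(tr$segments$generation)) # arbitrary distal-ward flows
  f2 <- advance_transport(f, flows, q_source = 1, q_leak = 0.5, dt = 0.02)
  expect_equal(max(abs(f2$phi - 0.35)), 0, tolerance = 1e-12)
})

test_that("diffusive variance grows at 2 D t on a single segment", {
  tr <- one_segment_tree(length_mm = 200, diameter_mm = 2)
  pars <- transport_params(cells_per_segment = 200, include_tube = FALSE,
                           initial_concentration = 0)
  f <- gas_field_init(tr, NULL, pars)
  mid <- 100L
  f$phi[mid, 1] <- 1 # a narrow pulse
  xc <- (seq_len(f$n_c) - 0.5) * f$dx
  var_of <- function(phi) {
    w <- phi[, 1] / sum(phi[, 1])
    sum(w * xc^2) - sum(w * xc)^2
  }
  v0 <- var_of(f$phi)
  t_total <- 0.1
  f2 <- advance_transport(f, 0, 0, 0, dt = t_total)
  d <- cm2s_to_mm2s(0.219)
  expect_equal(var_of(f2$phi) - v0, 2 * d * t_total, tolerance = 0.02)
})

test_that("the discrete maximum principle holds on a full oscillatory run", {
  tr <- small_tree()
  res <- run_small(tr, settings = hfov_settings(n_cycles = 2))
  gas <- run_gas_transport(res, transport_params(cells_per_segment = 8))
  expect_gte(min(gas$field$phi), 0.21 - 1e-12)
  expect_lte(max(gas$field$phi), 0.35 + 1e-12)
  expect_true(all(gas$terminal_phi >= 0.21 - 1e-12 &
                    gas$terminal_phi <= 0.35 + 1e-12))
})

test_that("the oxygen budget closes to well under 1% of the influx per cycle", {
  tr <- small_tree()
  res <- run_small(tr, settings = hfov_settings(n_cycles = 2))
  gas <- run_gas_transport(res, transport_params(cells_per_segment = 8))
  b <- oxygen_budget(gas)
  expect_true(all(abs(b$residual) < 0.01 * b$source_in))
  # doubling the inspired fraction doubles the influx (linearity)
  gas2 <- run_gas_transport(res, transport_params(cells_per_segment = 8,
                                                  inlet_concentration = 0.70))
  b2 <- oxygen_budget(gas2)
  expect_equal(b2$source_in, 2 * b$source_in, tolerance = 1e-10)
})

test_that("arrival times equal a brute-force scan and respect the threshold", {
  tr <- small_tree(asymmetry = 0.25)
  res <- run_small(tr, settings = hfov_settings(n_cycles = 2))
  gas <- run_gas_transport(res, transport_params(cells_per_segment = 8))
  del <- oxygen_delivery_metrics(gas, threshold = 0.25)
  # independent scan of the stored history
  for (j in seq_len(ncol(gas$terminal_phi))) {
    hit <- which(gas$terminal_phi[, j] > 0.25)
    if (length(hit) == 0) {
      expect_identical(del$classification[j], "unreached")
    } else {
      expect_equal(del$first_arrival_s[j], gas$times[hit[1]])
    }
  }
  # threshold above the inlet concentration: nothing ever arrives
  del_hi <- oxygen_delivery_metrics(gas, threshold = 0.99)
  expect_true(all(del_hi$classification == "unreached"))
})

test_that("asymmetric path lengths split terminals into direct and delayed", {
  tr <- small_tree(asymmetry = 0.3)
  res <- run_small(tr, settings = hfov_settings(n_cycles = 2))
  gas <- run_gas_transport(res, transport_params(cells_per_segment = 8))
  del <- oxygen_delivery_metrics(gas, threshold = 0.25)
  expect_true("direct" %in% del$classification)
  expect_true(any(del$classification != "direct"))
  # the direct terminals sit on wider, shorter-transit paths
  tim <- res$network$timing
  expect_true(all(del$first_arrival_s[del$classification == "direct"] <=
                    tim$t_insp + 1e-12))
})

test_that("grid refinement moves a clean front's arrival by under a coarse cell", {
  # constant distal-ward flow through a single segment: the front crossing
  # of the outlet is a monotone, well-separated event, so halving the cell
  # size must move its arrival time by less than one coarse-cell transit
  arrival <- function(n_cells) {
    tr <- one_segment_tree(length_mm = 100, diameter_mm = 2)
    pars <- transport_params(cells_per_segment = n_cells, include_tube = FALSE)
    f <- gas_field_init(tr, NULL, pars)
    q <- 0.1 # ml/s
    dt <- 0.02
    t <- 0
    repeat {
      f <- advance_transport(f, q, q_source = q, q_leak = 0, dt = dt)
      t <- t + dt
      if (f$phi[f$n_c, 1] > 0.28 || t > 10) break
    }
    t
  }
  t_coarse <- arrival(10)
  t_fine <- arrival(20)
  u <- 0.1 * 1000 / (pi * 1^2)                  # mm/s
  coarse_transit <- (100 / 10) / u              # s per coarse cell
  expect_lt(abs(t_coarse - t_fine), coarse_transit + 0.02)
})

test_that("CFL violations are refused when sub-cycling is disabled", {
  tr <- one_segment_tree(length_mm = 100, diameter_mm = 2)
  pars <- transport_params(cells_per_segment = 50, include_tube = FALSE)
  f <- gas_field_init(tr, NULL, pars)
  expect_error(advance_transport(f, 10, 10, 0, dt = 0.5, subcycle = FALSE),
               "CFL")
})

test_that("gas snapshots serialise to the documented CSV", {
  tr <- small_tree()
  res <- run_small(tr, settings = hfov_settings(n_cycles = 1))
  gas <- run_gas_transport(res, transport_params(cells_per_segment = 6),
                           snapshot_stride = 100)
  f <- withr::local_tempfile(fileext = ".csv")
  write_gas_snapshots(gas, f)
  tab <- read.csv(f)
  expect_named(tab, c("time_s", "segment_id", "cell_index", "position_mm", "phi"))
  expect_true(all(tab$phi >= 0.2 & tab$phi <= 0.36))
})
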