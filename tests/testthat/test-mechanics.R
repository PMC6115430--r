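test_that("SOT estimator inverts the generator in the noise-free limit", {
  p <- make_patient()
  m <- make_sot_maneuver(p, 0.006, 8, noise_sd = 0, seed = 1)
  est <- estimate_crs_sot(m)
  expect_lt(abs(est$crs - 20.93) / 20.93, 1e-3)
  expect_lt(abs(est$resistance - 0.006) / 0.006, 1e-3)
  # time constant consistent with R * C
  expect_equal(est$time_constant, est$resistance * est$crs, tolerance = 1e-6)
  # a maneuver generated with R*C = 0.2 s returns that time constant
  r2 <- 0.2 / 20.93
  est2 <- estimate_crs_sot(make_sot_maneuver(p, r2, 8, noise_sd = 0, seed = 1))
  expect_equal(est2$time_constant, 0.2, tolerance = 1e-3)
})

test_that("SOT estimator recovers the truth under noise (Monte Carlo)", {
  p <- make_patient()
  crs_hat <- vapply(1:100, function(seed) {
    m <- make_sot_maneuver(p, 0.006, 8, noise_sd = 2, seed = seed)
    estimate_crs_sot(m)$crs
  }, numeric(1))
  # mean estimate within 2 standard errors of the generating compliance
  expect_lt(abs(mean(crs_hat) - 20.93), 2 * sd(crs_hat) / sqrt(100) + 2 * sd(crs_hat))
  expect_lt(abs(mean(crs_hat) - 20.93), 2 * sd(crs_hat))
})

test_that("SOT estimator rejects degenerate maneuvers", {
  p <- make_patient()
  m <- make_sot_maneuver(p, 0.006, 8, noise_sd = 0, seed = 1)
  m$plateau_pressure <- 0
  expect_error(estimate_crs_sot(m), "plateau")
  m2 <- make_sot_maneuver(p, 0.006, 8, noise_sd = 0, seed = 1, n_samples = 20)
  m2$volume <- rev(m2$volume)
  expect_error(estimate_crs_sot(m2), "non-decreasing")
})

test_that("compliance partition conserves the total exactly", {
  tr <- generate_tree(body_mass = 0.76)
  c_eq <- partition_compliance(20.93, tr)
  expect_length(c_eq, 128L)
  expect_equal(unname(c_eq[1]), 20.93 / 128)
  expect_equal(sum(c_eq), 20.93, tolerance = 1e-14)
  # heterogeneous weights still conserve and follow the generator's ratio
  w <- make_compliance_heterogeneity(128, "bpd_patchy", severity = 0.5, seed = 2)
  c_h <- partition_compliance(20.93, tr, w)
  expect_equal(sum(c_h), 20.93, tolerance = 1e-12)
  patch <- attr(w, "patch")
  healthy <- setdiff(seq_along(w), patch)
  expect_equal(unname(c_h[patch[1]] / c_h[healthy[1]]), 0.5)
  expect_error(partition_compliance(20.93, tr, w[-1]), "weights")
})

test_that("Poiseuille resistance follows the 128 mu L / (pi d^4) law", {
  air <- air_properties()
  # independent unit-by-unit evaluation in SI
  mu <- air$density * air$kinematic_viscosity * 1e-6   # Pa s
  r_si <- 128 * mu * 0.040 / (pi * 0.004^4)            # Pa s / m^3
  expect_equal(poiseuille_resistance(40, 4, air), r_si * 1e-9, tolerance = 1e-12)
  # d^4 law and series additivity
  expect_equal(poiseuille_resistance(40, 8), poiseuille_resistance(40, 4) / 16)
  expect_equal(poiseuille_resistance(30, 4) + poiseuille_resistance(10, 4),
               poiseuille_resistance(40, 4), tolerance = 1e-12)
})

test_that("equivalent downstream resistance matches brute-force reduction", {
  # explicit enumeration: a branch is its segment in series with the
  # parallel pair of child branches; the unit's R_eq is the parallel pair
  # of the terminal's two child branches
  branch <- function(d, l, k, dr, lr) {
    r <- poiseuille_resistance(l, d)
    if (k == 0) return(r)
    r + branch(d * dr, l * lr, k - 1, dr, lr) / 2
  }
  for (ng in 1:4) {
    got <- equivalent_downstream_resistance(0.64, 4.8, ng,
                                            diameter_ratio = 0.79,
                                            length_ratio = 0.79)
    oracle <- branch(0.64 * 0.79, 4.8 * 0.79, ng - 1, 0.79, 0.79) / 2
    expect_equal(got, oracle, tolerance = 1e-12)
  }
  # one extra generation: two identical children in parallel
  expect_equal(equivalent_downstream_resistance(1, 10, 1,
                                                diameter_ratio = 0.5,
                                                length_ratio = 0.5),
               poiseuille_resistance(5, 0.5) / 2, tolerance = 1e-12)
  # ratios -> 1: the geometric series sum_k R_child / 2^k
  r_child <- poiseuille_resistance(4.8 * (1 - 1e-9), 0.64 * (1 - 1e-9))
  expect_equal(equivalent_downstream_resistance(0.64, 4.8, 9,
                                                diameter_ratio = 1 - 1e-9,
                                                length_ratio = 1 - 1e-9),
               r_child * sum(1 / 2^(1:9)), tolerance = 1e-6)
  expect_error(equivalent_downstream_resistance(0.64, 4.8, 9,
                                                diameter_ratio = 1.2),
               "diameter_ratio")
})

test_that("terminal closure reproduces P = R Q + dV/C", {
  u <- terminal_unit("t1", r_eq = 0.05, c_eq = 0.2)
  # rest is a fixed point
  u0 <- terminal_pressure(u, 0, 0.01)
  expect_equal(u0$pressure, 0)
  expect_equal(u0$delta_v, 0)
  # pure capacitor: constant inflow gives P = q t / C
  uc <- terminal_unit("t1", r_eq = 0, c_eq = 0.2)
  uc$flow <- 2 # constant from the start
  for (i in 1:100) uc <- terminal_pressure(uc, 2, 0.001)
  expect_equal(uc$pressure, 2 * 0.1 / 0.2, tolerance = 1e-10)
  # sinusoidal inflow against the symbolic integral of Eq-style closure:
  # q = sin(w t): dV = (1 - cos(w t))/w, P = R sin(w t) + dV/C
  w <- 2 * pi * 10
  us <- terminal_unit("t1", r_eq = 0.05, c_eq = 0.2)
  dt <- 1e-5
  ts <- seq(dt, 0.05, by = dt)
  for (t in ts) us <- terminal_pressure(us, sin(w * t), dt)
  t_end <- ts[length(ts)]
  p_exact <- 0.05 * sin(w * t_end) + (1 - cos(w * t_end)) / w / 0.2
  expect_equal(us$pressure, p_exact, tolerance = 1e-5)
})

test_that("mechanics maps serialise to the documented CSV", {
  tr <- small_tree()
  c_eq <- partition_compliance(20.93, tr)
  r_eq <- stats::setNames(rep(0.1, length(c_eq)), names(c_eq))
  f <- withr::local_tempfile(fileext = ".csv")
  write_mechanics_map(c_eq, r_eq, f)
  tab <- read.csv(f)
  expect_named(tab, c("outlet_id", "c_eq_ml_per_kPa", "r_eq_kPa_s_per_ml"))
  expect_equal(sum(tab$c_eq_ml_per_kPa), 20.93, tolerance = 1e-9)
})
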