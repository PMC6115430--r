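#' Default preterm patient fixture
#'
#' Builds the reference patient used throughout the package: an extremely
#' low-birth-weight preterm infant (0.76 kg) with severe bronchopulmonary
#' dysplasia (BPD grade 3) whose total respiratory compliance, 20.93 ml/kPa,
#' was measured by infant lung function testing with the single-occlusion
#' technique. Any field can be overridden.
#'
#' @param overrides named list of fields to override. Recognised fields:
#'   `body_mass` (kg), `crs_total` (ml/kPa), `frc` (ml, may be `NA` when the
#'   plethysmographic FRC is unknown), `bpd_grade` (integer 0-3),
#'   `gestational_age` (weeks).
#' @return an object of class `neovent_patient`: a named list with the fields
#'   above.
#' @examples
#' p <- make_patient()
#' p$body_mass   # 0.76 kg
#' p$crs_total   # 20.93 ml/kPa
#' make_patient(list(body_mass = 1.0))$body_mass
#' @export
make_patient <- function(overrides = NULL) {
  patient <- list(
    body_mass       = 0.76,   # kg
    crs_total       = 20.93,  # ml/kPa
    frc             = NA_real_, # ml; plethysmographic FRC not part of fixture
    bpd_grade       = 3L,
    gestational_age = 27.3    # weeks
  )
  if (!is.null(overrides)) {
    if (!is.list(overrides) || is.null(names(overrides)) || any(names(overrides) == ""))
      fail_field("overrides", "must be a named list")
    unknown <- setdiff(names(overrides), names(patient))
    if (length(unknown) > 0)
      fail_field("overrides", paste("unknown field(s):", paste(unknown, collapse = ", ")))
    patient[names(overrides)] <- overrides
  }
  check_positive(patient$body_mass, "body_mass")
  check_positive(patient$crs_total, "crs_total")
  if (!is.na(patient$frc)) check_nonnegative(patient$frc, "frc")
  if (!(patient$bpd_grade %in% 0:3)) fail_field("bpd_grade", "must be an integer in 0..3")
  check_positive(patient$gestational_age, "gestational_age")
  structure(patient, class = "neovent_patient")
}

#' Synthetic single-occlusion-technique (SOT) maneuver
#'
#' Emulates the passive-expiration phase of a single-occlusion maneuver used
#' in infant lung function testing: after a brief airway occlusion at volume
#' `occlusion_volume` above relaxation volume, the respiratory system empties
#' passively through resistance `resistance` against its compliance, so flow
#' decays exponentially with the time constant tau = R * C. A plateau
#' pressure equal to `occlusion_volume / crs_total` is recorded during the
#' occlusion. Optional additive Gaussian noise models sensor noise on the
#' flow channel; the volume channel is the running trapezoidal integral of
#' the noisy flow, as a real pneumotachograph pipeline would produce.
#'
#' @param patient a `neovent_patient` (provides the compliance)
#' @param resistance total respiratory resistance (kPa s/ml)
#' @param occlusion_volume volume above relaxation volume at occlusion (ml)
#' @param noise_sd standard deviation of additive flow noise (ml/s)
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and the seed
#' @param duration_tau maneuver length in units of the time constant
#'   (default 10, long enough that the exhaled volume equals the occluded
#'   volume to well below 0.1 percent)
#' @param n_samples number of samples over the maneuver
#' @return an object of class `neovent_sot`: list with `time` (s), `flow`
#'   (ml/s, positive = expiratory), `volume` (ml, exhaled), `plateau_pressure`
#'   (kPa), and the generating truth in `truth`
#' @examples
#' p <- make_patient()
#' m <- make_sot_maneuver(p, resistance = 0.006, occlusion_volume = 10,
#'                        noise_sd = 0, seed = 1)
#' m$plateau_pressure            # 10 / 20.93 kPa
#' @export
make_sot_maneuver <- function(patient, resistance, occlusion_volume,
                              noise_sd = 0, seed = 1L,
                              duration_tau = 10, n_samples = 500L) {
  stopifnot(inherits(patient, "neovent_patient"))
  check_positive(resistance, "resistance")
  check_positive(occlusion_volume, "occlusion_volume")
  check_nonnegative(noise_sd, "noise_sd")
  check_positive(duration_tau, "duration_tau")
  if (n_samples < 10) fail_field("n_samples", "need at least 10 samples")

  crs <- patient$crs_total
  tau <- resistance * crs
  time <- seq(0, duration_tau * tau, length.out = n_samples)
  flow_clean <- (occlusion_volume / tau) * exp(-time / tau)
  noise <- if (noise_sd > 0) {
    withr_seed_rnorm(seed, n_samples, sd = noise_sd)
  } else {
    numeric(n_samples)
  }
  flow <- flow_clean + noise
  volume <- cumtrapz(time, flow)

  structure(list(
    time = time,
    flow = flow,
    volume = volume,
    plateau_pressure = occlusion_volume / crs,
    truth = list(crs = crs, resistance = resistance, tau = tau,
                 occlusion_volume = occlusion_volume,
                 noise_sd = noise_sd, seed = as.integer(seed))
  ), class = "neovent_sot")
}

#' Regional compliance weights with optional BPD-like heterogeneity
#'
#' Produces one positive weight per terminal unit, summing to one, used to
#' apportion the total respiratory compliance among the acinar regions
#' subtended by the generation-seven outlets. The `uniform` profile gives
#' equal weights. The `bpd_patchy` profile emulates the patchy regional
#' disease of bronchopulmonary dysplasia: a seeded, contiguous block of
#' terminals (one quarter of them by default) has its weight multiplied by
#' `1 - severity`, after which all weights are renormalised; contiguity in
#' terminal order corresponds to an anatomically coherent diseased region of
#' the symmetric tree.
#'
#' @param n_terminals number of terminal units (>= 2)
#' @param profile `"uniform"` or `"bpd_patchy"`
#' @param severity fraction in `[0, 1)` by which the patch compliance is
#'   reduced; 0 reproduces the uniform profile
#' @param seed integer seed selecting the patch location
#' @param patch_fraction fraction of terminals in the diseased patch
#' @return numeric weight vector of length `n_terminals`, positive, summing
#'   to one, with attribute `"patch"` giving the down-weighted indices
#' @examples
#' w <- make_compliance_heterogeneity(128, "bpd_patchy", severity = 0.5, seed = 7)
#' sum(w)  # 1
#' @export
make_compliance_heterogeneity <- function(n_terminals,
                                          profile = c("uniform", "bpd_patchy"),
                                          severity = 0.5, seed = 1L,
                                          patch_fraction = 0.25) {
  profile <- match.arg(profile)
  if (n_terminals < 2) fail_field("n_terminals", "need at least 2 terminals")
  if (!is.numeric(severity) || severity < 0 || severity >= 1)
    fail_field("severity", "must lie in [0, 1)")
  w <- rep(1, n_terminals)
  patch <- integer(0)
  if (profile == "bpd_patchy" && severity > 0) {
    n_patch <- max(1L, floor(n_terminals * patch_fraction))
    start <- withr_seed_sample(seed, n_terminals - n_patch + 1L, 1L)
    patch <- seq.int(start, start + n_patch - 1L)
    w[patch] <- w[patch] * (1 - severity)
  }
  w <- w / sum(w)
  attr(w, "patch") <- patch
  w
}

# Seeded draws without touching the caller's global RNG state.
withr_seed_rnorm <- function(seed, n, sd = 1) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  stats::rnorm(n, sd = sd)
}

withr_seed_sample <- function(seed, n, size) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(n, size)
}

# cumulative trapezoidal integral
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}

#' Write an SOT maneuver to CSV
#'
#' Columns: `time_s`, `flow_ml_s`, `volume_ml`.
#'
#' @param maneuver a `neovent_sot`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_sot_maneuver <- function(maneuver, path) {
  stopifnot(inherits(maneuver, "neovent_sot"))
  utils::write.csv(
    data.frame(time_s = maneuver$time, flow_ml_s = maneuver$flow,
               volume_ml = maneuver$volume),
    path, row.names = FALSE)
  invisible(path)
}

#' Read an SOT maneuver from CSV
#'
#' Counterpart of [write_sot_maneuver()]. The plateau pressure is not stored
#' in the trace and must be supplied.
#'
#' @param path CSV file with columns `time_s`, `flow_ml_s`, `volume_ml`
#' @param plateau_pressure occlusion plateau pressure (kPa)
#' @return a `neovent_sot` (without generating truth)
#' @export
read_sot_maneuver <- function(path, plateau_pressure) {
  check_positive(plateau_pressure, "plateau_pressure")
  d <- utils::read.csv(path)
  need <- c("time_s", "flow_ml_s", "volume_ml")
  if (!all(need %in% names(d)))
    stop("SOT trace must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  structure(list(time = d$time_s, flow = d$flow_ml_s, volume = d$volume_ml,
                 plateau_pressure = plateau_pressure, truth = NULL),
            class = "neovent_sot")
}
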