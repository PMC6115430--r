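#' Morphometry parameters for the dichotomous airway tree
#'
#' The conducting tree is modelled as a regular dichotomous (Weibel-type)
#' branching structure: each parent bears two children whose lengths and
#' diameters shrink by fixed per-generation ratios. The classic homothety
#' ratio 0.79 (close to 2^(-1/3), which preserves total cross-sectional
#' behaviour across generations) is the default for both length and
#' diameter. An asymmetry factor splits the two children unevenly, and a
#' log-normal jitter adds seeded per-segment variability. The trachea
#' dimensions set the absolute scale before the global dead-space
#' calibration of [generate_tree()].
#'
#' @param trachea_length trachea length (mm)
#' @param trachea_diameter trachea inner diameter (mm)
#' @param diameter_ratio per-generation child/parent diameter ratio, in (0,1)
#' @param length_ratio per-generation child/parent length ratio, in (0,1)
#' @param asymmetry_factor in `[0, 0.5]`; child ratios become
#'   `ratio * (1 + a)` and `ratio * (1 - a)`
#' @param jitter_sd standard deviation of log-normal per-segment jitter
#' @param seed integer seed for the jitter
#' @return an object of class `neovent_morphometry`
#' @export
morphometry_params <- function(trachea_length = 30,
                               trachea_diameter = 4,
                               diameter_ratio = 0.79,
                               length_ratio = 0.79,
                               asymmetry_factor = 0,
                               jitter_sd = 0,
                               seed = 1L) {
  check_positive(trachea_length, "trachea_length")
  check_positive(trachea_diameter, "trachea_diameter")
  for (nm in c("diameter_ratio", "length_ratio")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1)
      fail_field(nm, "must lie strictly in (0, 1)")
  }
  if (asymmetry_factor < 0 || asymmetry_factor > 0.5)
    fail_field("asymmetry_factor", "must lie in [0, 0.5]")
  check_nonnegative(jitter_sd, "jitter_sd")
  structure(list(trachea_length = trachea_length,
                 trachea_diameter = trachea_diameter,
                 diameter_ratio = diameter_ratio,
                 length_ratio = length_ratio,
                 asymmetry_factor = asymmetry_factor,
                 jitter_sd = jitter_sd,
                 seed = as.integer(seed)),
            class = "neovent_morphometry")
}

#' Generate the resolved conducting airway tree
#'
#' Builds a dichotomous tree of generations 0 (trachea) through
#' `max_generation` (default 7, giving 255 segments when symmetric), with
#' per-generation geometric scaling, optional asymmetric child splitting and
#' seeded log-normal jitter. When `target_deadspace_per_kg` is given, every
#' length and diameter is multiplied by the single global factor that makes
#' the anatomical dead space per kilogram equal the target — since segment
#' volume is pi (d/2)^2 L, uniform linear rescaling by s scales total volume
#' by s^3, so the factor is the cube root of the volume ratio. The packaged
#' default calibrates to 2.2 ml/kg, the dead space of the reference preterm
#' patient's imaged tree.
#'
#' @param params a `neovent_morphometry` (default [morphometry_params()])
#' @param body_mass patient mass (kg)
#' @param target_deadspace_per_kg target anatomical dead space (ml/kg), or
#'   `NULL` to skip calibration
#' @param max_generation deepest resolved generation (terminals)
#' @return an object of class `neovent_tree`: list with `segments` (a
#'   data frame with columns `id`, `parent_id`, `generation`, `length_mm`,
#'   `diameter_mm`, `lobe`, `is_terminal`) and `root_id`
#' @examples
#' tr <- generate_tree(body_mass = 0.76, target_deadspace_per_kg = 2.2)
#' dead_space(tr, 0.76) # 2.2
#' @export
generate_tree <- function(params = morphometry_params(),
                          body_mass = 0.76,
                          target_deadspace_per_kg = 2.2,
                          max_generation = 7L) {
  stopifnot(inherits(params, "neovent_morphometry"))
  check_positive(body_mass, "body_mass")
  if (!is.null(target_deadspace_per_kg))
    check_positive(target_deadspace_per_kg, "target_deadspace_per_kg")
  if (max_generation < 1) fail_field("max_generation", "must be >= 1")

  n_seg <- 2L^(max_generation + 1L) - 1L
  # heap indexing: segment k has children 2k and 2k+1
  idx <- seq_len(n_seg)
  generation <- floor(log2(idx))
  parent <- ifelse(idx == 1L, NA_integer_, idx %/% 2L)
  # which child am I (1 = first, 2 = second)
  child_rank <- ifelse(idx == 1L, 0L, idx %% 2L + 1L)

  jitter <- if (params$jitter_sd > 0) {
    exp(withr_seed_rnorm(params$seed, 2L * n_seg, sd = params$jitter_sd))
  } else rep(1, 2L * n_seg)
  jit_len <- jitter[seq_len(n_seg)]
  jit_dia <- jitter[n_seg + seq_len(n_seg)]

  a <- params$asymmetry_factor
  split_factor <- ifelse(child_rank == 1L, 1 + a, ifelse(child_rank == 2L, 1 - a, 1))

  length_mm <- numeric(n_seg)
  diameter_mm <- numeric(n_seg)
  length_mm[1] <- params$trachea_length
  diameter_mm[1] <- params$trachea_diameter
  for (k in 2:n_seg) {
    p <- parent[k]
    length_mm[k] <- length_mm[p] * params$length_ratio * split_factor[k] * jit_len[k]
    diameter_mm[k] <- diameter_mm[p] * params$diameter_ratio * split_factor[k] * jit_dia[k]
  }

  lobe <- assign_lobes(idx, generation, parent, max_generation)

  segments <- data.frame(
    id = sprintf("g%d_%d", generation, idx - 2L^generation + 1L),
    parent_id = ifelse(is.na(parent), NA_character_,
                       sprintf("g%d_%d", generation - 1L,
                               parent - 2L^pmax(generation - 1L, 0L) + 1L)),
    generation = as.integer(generation),
    length_mm = length_mm,
    diameter_mm = diameter_mm,
    lobe = lobe,
    is_terminal = generation == max_generation,
    stringsAsFactors = FALSE
  )
  tree <- structure(list(segments = segments, root_id = segments$id[1]),
                    class = "neovent_tree")

  if (!is.null(target_deadspace_per_kg)) {
    current <- dead_space(tree, body_mass)
    s <- (target_deadspace_per_kg / current)^(1 / 3)
    tree$segments$length_mm <- tree$segments$length_mm * s
    tree$segments$diameter_mm <- tree$segments$diameter_mm * s
  }
  tree
}

# Lobe labels by subtree at generation 2: the four grandchildren map to
# RUL, right-lower subtree (split RML/RLL at generation 3), LUL, LLL.
# Generations 0-1 are labelled "main". Reporting only; no physics.
assign_lobes <- function(idx, generation, parent, max_generation) {
  lobe <- rep("main", length(idx))
  if (max_generation < 2) return(lobe)
  # ancestor at generation 2 for each segment of generation >= 2
  anc2 <- idx
  g <- generation
  while (any(g > 2L)) {
    move <- g > 2L
    anc2[move] <- anc2[move] %/% 2L
    g[move] <- g[move] - 1L
  }
  gen2 <- 4:7 # heap indices of the generation-2 segments
  labels <- c("RUL", "RLOW", "LUL", "LLL")
  for (j in seq_along(gen2)) {
    lobe[generation >= 2L & anc2 == gen2[j]] <- labels[j]
  }
  if (max_generation >= 3) {
    # split the right-lower subtree at generation 3 into RML / RLL
    anc3 <- idx
    g <- generation
    while (any(g > 3L)) {
      move <- g > 3L
      anc3[move] <- anc3[move] %/% 2L
      g[move] <- g[move] - 1L
    }
    rlow <- lobe == "RLOW" & generation >= 3L
    lobe[rlow & anc3 == 10L] <- "RML"
    lobe[rlow & anc3 == 11L] <- "RLL"
  }
  lobe[lobe == "RLOW"] <- "RML" # the generation-2 stem itself
  lobe
}

#' Anatomical dead space of a tree
#'
#' Sums cylindrical segment volumes pi (d/2)^2 L over all segments (mm^3,
#' converted to ml) and divides by body mass.
#'
#' @param tree a `neovent_tree`
#' @param body_mass patient mass (kg)
#' @return dead space in ml/kg
#' @export
dead_space <- function(tree, body_mass) {
  stopifnot(inherits(tree, "neovent_tree"))
  check_positive(body_mass, "body_mass")
  s <- tree$segments
  vol_ml <- sum(pi * (s$diameter_mm / 2)^2 * s$length_mm) / 1000
  vol_ml / body_mass
}

#' Validate airway-tree invariants
#'
#' Checks connectivity, acyclicity, a unique generation-0 root, dichotomous
#' branching of non-terminal segments, terminal flags confined to the
#' deepest generation, positive geometry, and parent-child generation
#' increments of exactly one. Returns a character vector of violations
#' (empty when the tree is valid); each violation names the offending
#' segment and the rule.
#'
#' @param tree a `neovent_tree`
#' @return character vector of violation messages
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "neovent_tree"))
  s <- tree$segments
  v <- character(0)
  if (anyDuplicated(s$id)) {
    # identity is ambiguous below this point; report and stop here
    return(sprintf("duplicate: segment id '%s' repeated", s$id[duplicated(s$id)][1]))
  }
  roots <- s$id[is.na(s$parent_id)]
  if (length(roots) != 1L) {
    v <- c(v, sprintf("root: expected exactly one root, found %d", length(roots)))
  } else if (s$generation[s$id == roots] != 0L) {
    v <- c(v, sprintf("root: segment '%s' is root but generation %d != 0",
                      roots, s$generation[s$id == roots]))
  }
  bad_geom <- s$id[s$length_mm <= 0 | s$diameter_mm <= 0]
  for (id in bad_geom) v <- c(v, sprintf("geometry: segment '%s' has non-positive length or diameter", id))

  known <- s$parent_id %in% s$id | is.na(s$parent_id)
  for (id in s$id[!known]) v <- c(v, sprintf("disconnected: segment '%s' has unknown parent", id))

  pidx <- match(s$parent_id, s$id)
  has_parent <- !is.na(pidx)
  gen_bad <- has_parent & (s$generation != s$generation[pidx] + 1L)
  for (id in s$id[gen_bad]) v <- c(v, sprintf("generation: segment '%s' is not its parent's generation + 1", id))

  # reachability from root (guards against cycles among non-root components)
  if (length(roots) == 1L) {
    reach <- s$id %in% roots
    repeat {
      newly <- !reach & has_parent & reach[pidx]
      if (!any(newly, na.rm = TRUE)) break
      reach <- reach | (newly %in% TRUE)
    }
    for (id in s$id[!reach & known]) {
      if (!id %in% roots) v <- c(v, sprintf("disconnected: segment '%s' unreachable from root", id))
    }
  }

  n_children <- table(factor(s$parent_id, levels = s$id))
  max_gen <- max(s$generation)
  for (i in seq_len(nrow(s))) {
    id <- s$id[i]
    nc <- as.integer(n_children[id])
    if (s$is_terminal[i]) {
      if (nc != 0L) v <- c(v, sprintf("terminal: segment '%s' flagged terminal but has children", id))
      if (s$generation[i] != max_gen)
        v <- c(v, sprintf("terminal: segment '%s' terminal at generation %d != max %d",
                          id, s$generation[i], max_gen))
    } else if (nc != 2L) {
      v <- c(v, sprintf("branching: segment '%s' has %d children, expected 2", id, nc))
    }
  }
  v
}

#' Write / read the airway-tree CSV dialect
#'
#' One row per segment; columns `id`, `parent_id`, `generation`,
#' `length_mm`, `diameter_mm`, `lobe`, `is_terminal`; header mandatory; the
#' root's parent is the empty field. `read_tree(write_tree(tree))` is the
#' identity.
#'
#' @param tree a `neovent_tree`
#' @param path file path
#' @return `write_tree` returns `path` invisibly; `read_tree` returns a
#'   `neovent_tree`
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "neovent_tree"))
  s <- tree$segments
  s$parent_id[is.na(s$parent_id)] <- ""
  utils::write.csv(s, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(id = "character", parent_id = "character",
                                      lobe = "character"))
  need <- c("id", "parent_id", "generation", "length_mm", "diameter_mm",
            "lobe", "is_terminal")
  missing_cols <- setdiff(need, names(s))
  if (length(missing_cols) > 0)
    stop("tree file missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(s) == 0) stop("tree file has no segments: no root", call. = FALSE)
  s$parent_id[s$parent_id == ""] <- NA_character_
  if (anyDuplicated(s$id)) {
    line <- which(duplicated(s$id))[1] + 1L # +1 for header
    stop(sprintf("duplicate segment id '%s' at line %d", s$id[duplicated(s$id)][1], line),
         call. = FALSE)
  }
  roots <- s$id[is.na(s$parent_id)]
  if (length(roots) == 0) stop("no root (every segment has a parent)", call. = FALSE)
  orphan <- !(s$parent_id %in% s$id) & !is.na(s$parent_id)
  if (any(orphan)) {
    line <- which(orphan)[1] + 1L
    stop(sprintf("segment '%s' at line %d references missing parent '%s'",
                 s$id[orphan][1], line, s$parent_id[orphan][1]), call. = FALSE)
  }
  s$generation <- as.integer(s$generation)
  s$is_terminal <- as.logical(s$is_terminal)
  structure(list(segments = s, root_id = roots[1]), class = "neovent_tree")
}

#' Terminal segment ids of a tree, in canonical order
#' @param tree a `neovent_tree`
#' @return character vector of terminal segment ids
#' @export
terminal_ids <- function(tree) {
  stopifnot(inherits(tree, "neovent_tree"))
  tree$segments$id[tree$segments$is_terminal]
}
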