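test_that("default calibrated tree has 255 segments and the target dead space", {
  tr <- generate_tree(body_mass = 0.76, target_deadspace_per_kg = 2.2)
  expect_equal(nrow(tr$segments), 255L)
  expect_equal(sum(tr$segments$is_terminal), 128L)
  expect_equal(dead_space(tr, 0.76), 2.2, tolerance = 1e-10)
  expect_length(validate_tree(tr), 0)
})

test_that("symmetric settings make all segments within a generation identical", {
  tr <- generate_tree(morphometry_params(jitter_sd = 0, asymmetry_factor = 0),
                      body_mass = 0.76)
  for (g in 0:7) {
    s <- tr$segments[tr$segments$generation == g, ]
    expect_equal(diff(range(s$length_mm)), 0)
    expect_equal(diff(range(s$diameter_mm)), 0)
  }
})

test_that("segment count is 2^(g+1)-1 for symmetric dichotomous trees", {
  for (g in 2:5) {
    tr <- generate_tree(body_mass = 0.76, target_deadspace_per_kg = NULL,
                        max_generation = g)
    expect_equal(nrow(tr$segments), 2L^(g + 1L) - 1L)
  }
})

test_that("dead-space calibration rescales by the cube root of the volume ratio", {
  params <- morphometry_params()
  raw <- generate_tree(params, 0.76, target_deadspace_per_kg = NULL)
  cal <- generate_tree(params, 0.76, target_deadspace_per_kg = 2.2)
  # brute-force volume re-summation on both trees
  vol <- function(tr) sum(pi * (tr$segments$diameter_mm / 2)^2 *
                            tr$segments$length_mm) / 1000
  s_expected <- (2.2 * 0.76 / vol(raw))^(1 / 3)
  expect_equal(cal$segments$length_mm, raw$segments$length_mm * s_expected,
               tolerance = 1e-12)
  expect_equal(cal$segments$diameter_mm, raw$segments$diameter_mm * s_expected,
               tolerance = 1e-12)
  expect_equal(vol(cal) / 0.76, 2.2, tolerance = 1e-12)
})

test_that("dead_space matches hand-computed cylinder volumes and scaling laws", {
  tr <- one_segment_tree(length_mm = 40, diameter_mm = 4)
  # pi r^2 L = pi * 4 * 40 mm^3 -> ml -> per kg
  expect_equal(dead_space(tr, 0.76), pi * 4 * 40 / 1000 / 0.76)
  tr2 <- tr
  tr2$segments$diameter_mm <- tr2$segments$diameter_mm * 2
  expect_equal(dead_space(tr2, 0.76), 4 * dead_space(tr, 0.76))
})

test_that("dead_space agrees with an independent sum over the exported table", {
  tr <- generate_tree(morphometry_params(jitter_sd = 0.05, seed = 11),
                      body_mass = 0.76, target_deadspace_per_kg = 2.2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_tree(tr, f)
  tab <- read.csv(f)
  oracle <- sum(pi * (tab$diameter_mm / 2)^2 * tab$length_mm) / 1000 / 0.76
  expect_equal(dead_space(tr, 0.76), oracle, tolerance = 1e-12)
})

test_that("tree generation is deterministic given the seed", {
  p <- morphometry_params(jitter_sd = 0.1, seed = 99)
  expect_identical(generate_tree(p, 0.76), generate_tree(p, 0.76))
  p2 <- morphometry_params(jitter_sd = 0.1, seed = 100)
  expect_false(identical(generate_tree(p, 0.76)$segments$length_mm,
                         generate_tree(p2, 0.76)$segments$length_mm))
})

test_that("validate_tree reports named violations", {
  tr <- small_tree()
  expect_length(validate_tree(tr), 0)
  # orphan segment
  bad <- tr
  bad$segments$parent_id[5] <- "nonexistent"
  expect_match(paste(validate_tree(bad), collapse = "; "), "disconnected")
  # generation gap
  bad2 <- tr
  bad2$segments$generation[5] <- bad2$segments$generation[5] + 1L
  expect_match(paste(validate_tree(bad2), collapse = "; "), "generation")
  # duplicate id
  bad3 <- tr
  bad3$segments$id[6] <- bad3$segments$id[5]
  expect_match(paste(validate_tree(bad3), collapse = "; "), "duplicate")
})

test_that("tree CSV dialect round-trips exactly and rejects malformed files", {
  tr <- generate_tree(morphometry_params(jitter_sd = 0.03, seed = 2),
                      body_mass = 0.76)
  f <- withr::local_tempfile(fileext = ".csv")
  write_tree(tr, f)
  tr2 <- read_tree(f)
  expect_equal(tr2$segments$length_mm, tr$segments$length_mm, tolerance = 1e-12)
  expect_identical(tr2$segments$id, tr$segments$id)
  expect_identical(tr2$segments$parent_id, tr$segments$parent_id)
  expect_identical(tr2$root_id, tr$root_id)

  # duplicate id names the line
  tab <- read.csv(f, colClasses = "character")
  tab$id[2] <- tab$id[1]
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, f2, row.names = FALSE, quote = FALSE)
  expect_error(read_tree(f2), "duplicate")
  # empty file: no root
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,parent_id,generation,length_mm,diameter_mm,lobe,is_terminal", f3)
  expect_error(read_tree(f3), "no root")
  # missing parent
  tab2 <- read.csv(f, colClasses = "character")
  tab2$parent_id[3] <- "ghost"
  f4 <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab2, f4, row.names = FALSE, quote = FALSE)
  expect_error(read_tree(f4), "missing parent")
})

test_that("lobe labels partition the tree below generation 2", {
  tr <- generate_tree(body_mass = 0.76)
  s <- tr$segments
  expect_setequal(unique(s$lobe[s$generation >= 3]),
                  c("RUL", "RML", "RLL", "LUL", "LLL"))
  expect_true(all(s$lobe[s$generation <= 1] == "main"))
})
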