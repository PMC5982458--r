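test_that("reading a minimal well-formed CSV keeps both phases", {
  path <- write_profile_csv(c("0,0.1,compression",
                              "1,0.5,compression",
                              "1,0.3,release"))
  prof <- read_profile(path)
  expect_s3_class(prof, "flexibility_profile")
  expect_false(prof$floppy)
  expect_equal(sum(prof$samples$phase == "compression"), 2)
  expect_equal(sum(prof$samples$phase == "release"), 1)
})

test_that("leading sub-trigger points are trimmed and distance re-zeroed", {
  path <- write_profile_csv(c("0,0.01,compression",
                              "0.5,0.03,compression",
                              "1,0.05,compression",
                              "2,0.8,compression"))
  prof <- read_profile(path)
  expect_equal(nrow(prof$samples), 2)
  expect_equal(prof$samples$distance_mm, c(0, 1))
  expect_equal(prof$samples$force_N[1], 0.05)
  expect_equal(prof$metadata$trigger_offset_mm, 1)
})

test_that("a curve that never reaches the trigger force is flagged floppy", {
  path <- write_profile_csv(c("0,0.01,compression",
                              "5,0.04,compression",
                              "10,0.02,compression"))
  prof <- read_profile(path)
  expect_true(prof$floppy)
  expect_equal(nrow(prof$samples), 0)
  expect_equal(prof$metadata$max_recorded_force_N, 0.04)
})

test_that("malformed inputs raise informative errors", {
  bad_num <- write_profile_csv(c("0,0.1,compression", "1,0.2,compression",
                                 "2,0.3,compression", "3,0.4,compression",
                                 "4,abc,compression"))
  expect_error(read_profile(bad_num), "row 5")
  empty <- write_profile_csv(character())
  expect_error(read_profile(empty), "empty")
  missing_col <- tempfile(fileext = ".csv")
  writeLines(c("distance_mm,force_N", "0,0.1"), missing_col)
  expect_error(read_profile(missing_col), "phase")
  bad_phase <- write_profile_csv(c("0,0.1,compress", "1,0.2,compress"))
  expect_error(read_profile(bad_phase), "phase")
})

test_that("filament id and replicate are parsed from the filename stem", {
  path <- file.path(tempdir(), "HP30__rep2.csv")
  writeLines(c("distance_mm,force_N,phase", "0,0.1,compression",
               "1,0.5,compression"), path)
  prof <- read_profile(path)
  expect_equal(prof$filament_id, "HP30")
  expect_equal(prof$replicate, 2L)
})

test_that("profile validation enforces the protocol invariants", {
  cfg <- protocol_config()
  good <- data.frame(distance_mm = c(0, 1), force_N = c(0.1, 0.5),
                     phase = "compression")
  expect_silent(flexibility_profile("a", good, config = cfg))
  expect_error(
    flexibility_profile("a", transform(good, force_N = c(-0.1, 0.5))),
    "negative")
  expect_error(
    flexibility_profile("a", transform(good, distance_mm = c(1, 0))),
    "non-decreasing")
  expect_error(
    flexibility_profile("a", transform(good, force_N = c(0.01, 0.5))),
    "trigger")
  expect_error(
    flexibility_profile("a", good[1, ]), "at least 2")
})

test_that("write-then-read round trip preserves the numbers bit for bit", {
  prof <- ramp_profile(slope = 1 / 3, recovery = 2 / 7)
  # first sample is at the trigger already? force at 0 mm is 0; make it valid
  prof$samples <- prof$samples[prof$samples$force_N >= 0.05 |
                                 prof$samples$phase == "release", ]
  prof$samples$distance_mm <- prof$samples$distance_mm -
    min(prof$samples$distance_mm[prof$samples$phase == "compression"])
  prof$samples <- prof$samples[prof$samples$distance_mm >= 0, ]
  path <- tempfile(fileext = ".csv")
  write_profile(prof, path)
  back <- read_profile(path)
  expect_identical(back$samples$distance_mm,
                   prof$samples$distance_mm)
  expect_identical(back$samples$force_N, prof$samples$force_N)
  path2 <- tempfile(fileext = ".csv")
  write_profile(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("resampling a straight ramp onto a coarse grid is exact", {
  cfg <- small_config(4L)
  prof <- ramp_profile(slope = 2, config = cfg, recovery = 0)
  v <- resample_profile(prof, cfg)
  comp <- v$grid$phase == "compression"
  expect_equal(v$grid$distance_mm[comp], c(0, 5, 10, 15))
  expect_equal(v$values[comp], c(0, 10, 20, 30))
})

test_that("post-fracture stations hold the last recorded force", {
  cfg <- small_config(16L)
  # rises to 4 N at 6 mm, drops, recording ends at 7 mm with 0.1 N residual
  d <- c(0, 2, 4, 6, 6.5, 7)
  f <- c(0.05, 1.5, 3, 4, 0.15, 0.1)
  prof <- flexibility_profile("frac", data.frame(
    distance_mm = d, force_N = f, phase = "compression"), config = cfg)
  v <- suppressWarnings(resample_profile(prof, cfg))
  comp_st <- v$grid$distance_mm[v$grid$phase == "compression"]
  # independent per-station step-function oracle
  oracle <- vapply(comp_st, function(s) {
    if (s <= 7) stats::approx(d, f, xout = s)$y else 0.1
  }, numeric(1))
  expect_equal(v$values[v$grid$phase == "compression"], oracle)
})

test_that("a recording that simply stops without a drop fills with zero", {
  cfg <- small_config(8L)
  prof <- flexibility_profile("stub", data.frame(
    distance_mm = c(0, 3), force_N = c(0.05, 0.06), phase = "compression"),
    config = cfg)
  v <- suppressWarnings(resample_profile(prof, cfg))
  comp <- v$grid$phase == "compression"
  expect_true(all(v$values[comp][v$grid$distance_mm[comp] > 3] == 0))
})

test_that("an absent release phase yields zero release stations and a warning", {
  cfg <- small_config(4L)
  prof <- flexibility_profile("noret", data.frame(
    distance_mm = c(0, 15), force_N = c(0.1, 30), phase = "compression"),
    config = cfg)
  expect_warning(v <- resample_profile(prof, cfg), "release")
  expect_equal(v$values[v$grid$phase == "release"], rep(0, 4))
})

test_that("degenerate profiles cannot be resampled", {
  cfg <- small_config(4L)
  floppy <- flexibility_profile("fl", data.frame(
    distance_mm = numeric(), force_N = numeric(), phase = character()),
    floppy = TRUE, config = cfg)
  expect_error(resample_profile(floppy, cfg), "not testable")
  one_rel <- flexibility_profile("r1", data.frame(
    distance_mm = c(0, 15, 15), force_N = c(0.1, 30, 20),
    phase = c("compression", "compression", "release")), config = cfg)
  expect_error(resample_profile(one_rel, cfg), "release")
})

test_that("resampling is idempotent on the protocol grid", {
  cfg <- small_config(32L)
  prof <- ramp_profile(slope = 1.3, config = cfg, recovery = 0.4)
  v1 <- resample_profile(prof, cfg)
  v2 <- resample_profile(v1, cfg)
  expect_identical(v1$values, v2$values)
})

test_that("data-range normalization matches the defining ratio", {
  expect_equal(normalize_profile(c(1, 2, 3, 4)), c(0.1, 0.2, 0.3, 0.4))
  expect_equal(normalize_profile(c(5, 5)), c(0.5, 0.5))
  expect_equal(normalize_profile(c(2, 3, 5)), c(0.2, 0.3, 0.5))
  expect_error(normalize_profile(c(0, 0, 0)), "degenerate")
  expect_error(normalize_profile(c(-1, 2)), "negative")
})

test_that("normalization sums to one, is scale-invariant and preserves correlation", {
  set.seed(11)
  for (i in 1:25) {
    v <- stats::runif(64, 0, 10)
    w <- stats::runif(64, 0, 10)
    k <- stats::runif(1, 1e-3, 1e3)
    expect_equal(sum(normalize_profile(v)), 1, tolerance = 1e-9)
    expect_equal(normalize_profile(k * v), normalize_profile(v),
                 tolerance = 1e-12)
    expect_equal(stats::cor(v, w),
                 stats::cor(normalize_profile(v), normalize_profile(w)),
                 tolerance = 1e-12)
  }
})

test_that("replicate aggregation averages pointwise and renormalizes", {
  cfg <- small_config(1L)  # 2-station grid
  a <- as_profile_vector(c(0.2, 0.8), config = cfg, normalized = TRUE)
  b <- as_profile_vector(c(0.4, 0.6), config = cfg, normalized = TRUE)
  expect_equal(aggregate_replicates(list(a))$values, a$values)
  expect_equal(aggregate_replicates(list(a, a))$values, a$values)
  agg <- aggregate_replicates(list(a, b))
  expect_equal(agg$values, c(0.3, 0.7))
  expect_equal(agg$metadata$n_replicates, 2)
  big <- as_profile_vector(rep(0.25, 8), config = small_config(4L),
                           normalized = TRUE)
  expect_error(aggregate_replicates(list(a, big)), "grid")
})

test_that("protocol config rejects non-positive constants and unknown keys", {
  expect_error(protocol_config(trigger_force = 0), "trigger_force")
  expect_error(protocol_config(compression_distance = -1),
               "compression_distance")
  cfg_file <- tempfile(fileext = ".json")
  writeLines('{"trigger_force": 0.1}', cfg_file)
  cfg <- read_protocol_config(cfg_file)
  expect_equal(cfg$trigger_force, 0.1)
  expect_equal(cfg$compression_speed, 3.15)
  writeLines('{"trigger": 0.1}', cfg_file)
  expect_error(read_protocol_config(cfg_file), "unknown key")
})
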