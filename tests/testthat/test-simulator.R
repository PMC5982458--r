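test_that("the Euler critical load matches the closed form for the rig geometry", {
  # hand computation: I = pi * (1.75e-3)^4 / 64 = 4.6039e-13 m^4,
  # F = pi^2 * 1e9 * I / 0.05^2 = 1.8175 N
  expect_equal(euler_critical_force(1e9), 1.8175, tolerance = 1e-4)
  # doubling the length quarters the load
  expect_equal(euler_critical_force(1e9, length = 100),
               euler_critical_force(1e9) / 4)
  # a fixed-fixed column (K = 0.5) carries four times the pinned load
  expect_equal(euler_critical_force(1e9, effective_length_factor = 0.5),
               4 * euler_critical_force(1e9))
  # a very soft filament never registers on the instrument
  expect_lt(euler_critical_force(0.001e9), protocol_config()$trigger_force)
})

test_that("mechanics validation enforces phenotype-parameter consistency", {
  expect_error(filament_mechanics("floppy", yield_force = 1),
               "below the trigger")
  expect_error(filament_mechanics("sharp_brittle", yield_force = 0.01),
               "exceed the trigger")
  expect_error(filament_mechanics("sharp_brittle", fracture_distance = 20),
               "fracture_distance")
  expect_error(filament_mechanics("sharp_brittle",
                                  residual_force_fraction = 0.1),
               "zero residual")
  expect_error(filament_mechanics("strain_bearing_brittle",
                                  residual_force_fraction = 0.5),
               "0, 0.3")
  expect_error(filament_mechanics("bouncy"), "arg")
})

test_that("noiseless sharp brittle fracture peaks at the yield force and drops to zero", {
  cfg <- protocol_config()
  mech <- filament_mechanics("sharp_brittle", yield_force = 4,
                             fracture_distance = 5, noise_sd = 0)
  prof <- simulate_profile(mech, cfg)
  comp <- prof$samples[prof$samples$phase == "compression", ]
  expect_equal(max(comp$force_N), 4)
  expect_equal(comp$distance_mm[which.max(comp$force_N)], 5)
  expect_true(all(comp$force_N[comp$distance_mm > 5] == 0))
  expect_true(all(prof$samples$force_N[prof$samples$phase == "release"] == 0))
  expect_equal(comp$force_N[1], cfg$trigger_force)
})

test_that("noiseless strain-bearing fracture keeps a creeping residual", {
  cfg <- protocol_config()
  mech <- filament_mechanics("strain_bearing_brittle", yield_force = 5,
                             fracture_distance = 4,
                             residual_force_fraction = 0.2,
                             recovery_fraction = 0.1, noise_sd = 0)
  prof <- simulate_profile(mech, cfg)
  comp <- prof$samples[prof$samples$phase == "compression", ]
  post <- comp[comp$distance_mm > 4, ]
  expect_equal(max(post$force_N), 0.2 * 5, tolerance = 0.01)
  expect_true(all(diff(post$force_N) <= 0))  # creeps downward
  expect_true(all(post$force_N > 0))
})

test_that("noiseless pliable profiles plateau at the Euler point and retrace on release", {
  cfg <- protocol_config()
  mech <- filament_mechanics("pliable", youngs_modulus = 2e9,
                             post_buckling_slope = 0.1,
                             recovery_fraction = 0.6, noise_sd = 0)
  prof <- simulate_profile(mech, cfg)
  f_cr <- prof$metadata$euler_force_N
  expect_equal(f_cr, euler_critical_force(2e9, cfg$specimen_diameter,
                                          cfg$specimen_length))
  comp <- prof$samples[prof$samples$phase == "compression", ]
  rel <- prof$samples[prof$samples$phase == "release", ]
  d_b <- prof$metadata$buckling_distance_mm
  # maximum force = Euler force + post-buckling contribution over the travel
  expect_equal(max(comp$force_N),
               f_cr + 0.1 * (cfg$compression_distance - d_b),
               tolerance = 1e-9)
  # release retraces compression at the recovery fraction, distance by distance
  m <- match(round(rel$distance_mm, 9), round(comp$distance_mm, 9))
  expect_equal(rel$force_N, 0.6 * comp$force_N[m], tolerance = 1e-9)
})

test_that("floppy phenotypes return a sub-trigger trace flagged floppy", {
  cfg <- protocol_config()
  mech <- filament_mechanics("floppy", yield_force = 0.03,
                             youngs_modulus = 1e6, noise_sd = 0.02, seed = 2)
  prof <- simulate_profile(mech, cfg)
  expect_true(prof$floppy)
  expect_true(all(prof$samples$force_N < cfg$trigger_force))
  expect_error(resample_profile(prof, cfg), "not testable")
})

test_that("profiles are reproducible from their seed", {
  mech1 <- filament_mechanics("pliable", seed = 77)
  mech2 <- filament_mechanics("pliable", seed = 77)
  mech3 <- filament_mechanics("pliable", seed = 78)
  p1 <- simulate_profile(mech1)
  p2 <- simulate_profile(mech2)
  p3 <- simulate_profile(mech3)
  expect_identical(p1$samples, p2$samples)
  expect_false(identical(p1$samples$force_N, p3$samples$force_N))
  # simulation does not disturb the session RNG stream
  set.seed(1); before <- stats::runif(1)
  set.seed(1); invisible(simulate_profile(mech1)); after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("the simulated reference library is mutually feedable with one odd member", {
  cfg <- protocol_config()
  refs <- make_reference_library(cfg, seed = 42)
  expect_named(refs$profiles, c("ABS_like", "PLA_like", "Dissolvable_like"))
  expect_true(all(refs$truth == "feedable"))
  vecs <- lapply(refs$profiles, function(p) {
    normalize_profile(resample_profile(p, cfg))
  })
  lib <- build_reference_library(vecs)
  # every reference scores feedable against the other two
  for (id in names(vecs)) {
    others <- lib
    others$references <- vecs[setdiff(names(vecs), id)]
    tab <- score_panel(vecs[id], build_reference_library(others$references))
    expect_true(tab$feedable)
  }
  # the dissolvable-like stand-in is the least consistent member
  cm <- lib$consistency_matrix
  mean_off <- (rowSums(cm) - 1) / 2
  expect_lt(mean_off["Dissolvable_like"], cm["ABS_like", "PLA_like"])
})

test_that("a stiff 120 N-scale preset is still feedable: scoring is scale-free", {
  cfg <- protocol_config()
  refs <- make_reference_library(cfg, seed = 42)
  mech <- filament_presets(noise_sd = 0.02)$mowiflex_like
  mech$seed <- 5L
  stiff <- simulate_profile(mech, cfg)
  stiff$filament_id <- "Mowiflex_like"
  expect_gt(max(stiff$samples$force_N), 100)  # ~120 N deformation force
  res <- screen_panel(list(stiff), refs, cfg)
  expect_equal(res$table$call, "feedable")
})

test_that("panels are labelled, jittered within ranges, and size-checked", {
  cfg <- protocol_config()
  panel <- make_panel(c(pliable = 2, sharp_brittle = 2), cfg, seed = 3)
  expect_length(panel$profiles, 4)
  expect_equal(unname(panel$truth),
               c("feedable", "feedable", "non-feedable", "non-feedable"))
  empty <- make_panel(c(pliable = 0, floppy = 0), cfg, seed = 3)
  expect_length(empty$profiles, 0)
  expect_error(make_panel(c(gooey = 2), cfg, seed = 3), "unknown phenotype")
  # reproducibility of the whole panel from the master seed
  again <- make_panel(c(pliable = 2, sharp_brittle = 2), cfg, seed = 3)
  expect_identical(lapply(panel$profiles, `[[`, "samples"),
                   lapply(again$profiles, `[[`, "samples"))
})

test_that("a panel written to disk round-trips through the CSV reader", {
  cfg <- protocol_config()
  panel <- make_panel(c(pliable = 1, sharp_brittle = 1, floppy = 1), cfg,
                      seed = 6)
  dir <- file.path(tempdir(), "panel_rt")
  write_panel(panel, dir)
  expect_true(file.exists(file.path(dir, "truth.json")))
  profs <- read_profile_dir(dir, cfg)
  ids <- vapply(profs, `[[`, character(1), "filament_id")
  expect_setequal(ids, names(panel$profiles))
  floppy_back <- profs[[which(ids == "floppy_01")]]
  expect_true(floppy_back$floppy)
})
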