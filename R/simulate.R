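#' Euler critical buckling load of a filament specimen
#'
#' Critical axial load of a slender circular column,
#' `F_cr = pi^2 E I / (K L)^2` with second moment of area
#' `I = pi d^4 / 64`. Above this load ("the Euler point") an infinitesimal
#' lateral perturbation makes the specimen bend rather than compress further,
#' which is the transition feedable filaments survive and exploit. Conical
#' end caps that allow end rotation correspond to the pinned-pinned case,
#' `K = 1`.
#'
#' @param youngs_modulus Young's modulus in Pa.
#' @param diameter Filament diameter in mm (default 1.75).
#' @param length Free specimen length in mm (default 50).
#' @param effective_length_factor Boundary-condition factor K (default 1,
#'   pinned-pinned).
#' @return Critical load in N.
#' @examples
#' euler_critical_force(1e9)  # ~1.82 N for a 1 GPa, 1.75 mm x 50 mm specimen
#' @export
euler_critical_force <- function(youngs_modulus, diameter = 1.75, length = 50,
                                 effective_length_factor = 1) {
  stopifnot(youngs_modulus > 0, diameter > 0, length > 0,
            effective_length_factor > 0)
  d <- diameter / 1000
  L <- effective_length_factor * length / 1000
  I <- pi * d^4 / 64
  pi^2 * youngs_modulus * I / L^2
}

phenotype_levels <- c("sharp_brittle", "strain_bearing_brittle", "pliable",
                      "floppy")

#' Mechanical parameter set of a simulated filament
#'
#' Describes one filament for the profile simulator. The four phenotypes
#' reproduce the curve morphologies seen on the instrument:
#' \describe{
#'   \item{sharp_brittle}{linear elastic ramp ending in an instantaneous
#'     fracture with no residual force (highly friable pure polymers).}
#'   \item{strain_bearing_brittle}{ramp over a longer travel, fracture to a
#'     small residual force that creeps downward (partially plasticized but
#'     still friable blends).}
#'   \item{pliable}{rise of an imperfect elastic column toward its Euler
#'     critical load, then a gently varying post-buckling plateau; on release
#'     the curve is retraced at a fixed recovery fraction (feedable
#'     filaments, which bend and partially straighten again).}
#'   \item{floppy}{the specimen never exerts the trigger force; the trace
#'     stays sub-trigger and the filament is not testable (over-plasticized,
#'     string-like filaments).}
#' }
#'
#' @param phenotype One of `"sharp_brittle"`, `"strain_bearing_brittle"`,
#'   `"pliable"`, `"floppy"`.
#' @param youngs_modulus Young's modulus in Pa (sets the Euler load of
#'   pliable/floppy specimens).
#' @param yield_force Peak force in N: fracture force of brittle phenotypes,
#'   force ceiling of floppy ones (must stay below the trigger).
#' @param fracture_distance Probe travel in mm at which brittle specimens
#'   fracture.
#' @param residual_force_fraction Post-fracture residual force as a fraction
#'   of the peak; 0 for `sharp_brittle`, in (0, 0.3] for
#'   `strain_bearing_brittle`.
#' @param post_buckling_slope Slope of the pliable post-buckling plateau in
#'   N/mm (may be slightly negative).
#' @param recovery_fraction Release-phase force as a fraction of the
#'   compression force at the same distance, in \[0, 1\].
#' @param imperfection Initial bow amplitude of the column in mm; larger
#'   values stretch the pre-buckling rise over a longer travel.
#' @param noise_sd Standard deviation of additive Gaussian force noise in N
#'   (default 0.02, small against the 0.05 N trigger).
#' @param seed Integer seed making the noise reproducible (`NULL` uses the
#'   session RNG stream).
#' @param config A [protocol_config()]; used to validate the parameters
#'   against the protocol (trigger force, travel).
#' @return An object of class `filament_mechanics`.
#' @export
filament_mechanics <- function(phenotype,
                               youngs_modulus = 2.2e9,
                               yield_force = 6,
                               fracture_distance = 2,
                               residual_force_fraction = 0,
                               post_buckling_slope = 0.08,
                               recovery_fraction = 0.6,
                               imperfection = 0.5,
                               noise_sd = 0.02,
                               seed = NULL,
                               config = protocol_config()) {
  phenotype <- match.arg(phenotype, phenotype_levels)
  mech <- structure(
    list(phenotype = phenotype,
         youngs_modulus = youngs_modulus,
         yield_force = yield_force,
         fracture_distance = fracture_distance,
         residual_force_fraction = residual_force_fraction,
         post_buckling_slope = post_buckling_slope,
         recovery_fraction = recovery_fraction,
         imperfection = imperfection,
         noise_sd = noise_sd,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "filament_mechanics"
  )
  stopifnot(youngs_modulus > 0, imperfection > 0, noise_sd >= 0,
            recovery_fraction >= 0, recovery_fraction <= 1)
  if (phenotype == "floppy") {
    if (yield_force >= config$trigger_force) {
      stop("filament_mechanics: a floppy filament must stay below the ",
           "trigger force (yield_force < ", config$trigger_force, " N)",
           call. = FALSE)
    }
  } else {
    if (yield_force <= config$trigger_force) {
      stop("filament_mechanics: yield_force must exceed the trigger force",
           call. = FALSE)
    }
  }
  if (phenotype %in% c("sharp_brittle", "strain_bearing_brittle")) {
    if (fracture_distance <= 0 ||
        fracture_distance > config$compression_distance) {
      stop("filament_mechanics: fracture_distance must lie in (0, ",
           config$compression_distance, "] mm", call. = FALSE)
    }
  }
  if (phenotype == "sharp_brittle" && residual_force_fraction != 0) {
    stop("filament_mechanics: sharp_brittle implies zero residual force",
         call. = FALSE)
  }
  if (phenotype == "strain_bearing_brittle" &&
      (residual_force_fraction <= 0 || residual_force_fraction > 0.3)) {
    stop("filament_mechanics: strain_bearing_brittle needs ",
         "residual_force_fraction in (0, 0.3]", call. = FALSE)
  }
  mech
}

# Pre-buckling rise of an imperfect pinned column: a half-sine initial bow of
# amplitude e0 is amplified as the load approaches F_cr, and the resulting
# bowing end-shortening (mm) inverts to F(delta)/F_cr = 1 - e0/sqrt(e0^2 + c*delta)
# with c = 4 L / pi^2. Dimensionless shape g in [0, 1).
imperfect_column_shape <- function(delta_mm, imperfection_mm, length_mm) {
  cc <- 4 * length_mm / pi^2
  1 - imperfection_mm / sqrt(imperfection_mm^2 + cc * delta_mm)
}

# Travel at which the rise reaches fraction q of F_cr (closed form inverse).
buckling_transition_distance <- function(imperfection_mm, length_mm,
                                         q = 0.95) {
  cc <- 4 * length_mm / pi^2
  imperfection_mm^2 * (1 / (1 - q)^2 - 1) / cc
}

#' Simulate a compress-and-release flexibility profile
#'
#' Generates the deterministic force-distance curve for the filament's
#' phenotype (see [filament_mechanics()]), samples it at `points_per_mm`
#' along both the compression and release strokes, adds seeded Gaussian
#' noise, clamps forces at zero, and applies the instrument's trigger
#' semantics. Distance is measured from the trigger point, so non-floppy
#' curves start at the trigger force at 0 mm.
#'
#' @param mech A `filament_mechanics`.
#' @param config A [protocol_config()].
#' @param points_per_mm Sampling density of the synthetic instrument
#'   (default 10).
#' @return A `flexibility_profile`; floppy phenotypes return a sub-trigger
#'   trace flagged floppy. Metadata records the phenotype, the Euler load and
#'   the buckling transition distance.
#' @export
simulate_profile <- function(mech, config = protocol_config(),
                             points_per_mm = 10) {
  stopifnot(inherits(mech, "filament_mechanics"))
  D <- config$compression_distance
  delta <- seq(0, D, by = 1 / points_per_mm)
  trig <- config$trigger_force
  f_cr <- euler_critical_force(mech$youngs_modulus,
                               config$specimen_diameter,
                               config$specimen_length)
  delta_b <- NA_real_

  if (mech$phenotype %in% c("sharp_brittle", "strain_bearing_brittle")) {
    df <- mech$fracture_distance
    ramp <- trig + (mech$yield_force - trig) * delta / df
    residual <- mech$residual_force_fraction * mech$yield_force
    # residual resistance of the fractured specimen creeps slowly downward
    creep <- 1 - 0.3 * (delta - df) / max(D - df, 1e-9)
    post <- residual * pmax(creep, 0)
    comp <- ifelse(delta <= df, ramp, post)
    rel <- mech$recovery_fraction *
      ifelse(delta >= df, post, residual * delta / df)
  } else if (mech$phenotype == "pliable") {
    g <- imperfect_column_shape(delta, mech$imperfection,
                                config$specimen_length)
    ramp <- trig + (f_cr - trig) * g
    delta_b <- buckling_transition_distance(mech$imperfection,
                                            config$specimen_length)
    plateau <- f_cr + mech$post_buckling_slope * (delta - delta_b)
    comp <- ifelse(delta < delta_b, ramp, pmax(plateau, 0))
    rel <- mech$recovery_fraction * comp
  } else { # floppy
    g <- imperfect_column_shape(delta, mech$imperfection,
                                config$specimen_length)
    comp <- mech$yield_force * g
    rel <- mech$recovery_fraction * comp
  }

  n_c <- length(delta)
  force <- c(comp, rev(rel))
  if (mech$noise_sd > 0) {
    noise_fun <- function() stats::rnorm(length(force), 0, mech$noise_sd)
    noise <- if (is.null(mech$seed)) noise_fun() else {
      withr::with_seed(mech$seed, noise_fun())
    }
    force <- force + noise
  }
  force <- pmax(force, 0)
  if (mech$phenotype == "floppy") {
    # the specimen cannot exert more than its force ceiling, so noise spikes
    # are capped below the trigger and the trace stays sub-trigger
    force <- pmin(force, mech$yield_force)
  }

  samples <- data.frame(
    distance_mm = c(delta, rev(delta)),
    force_N = force,
    phase = rep(c("compression", "release"), each = n_c),
    stringsAsFactors = FALSE
  )
  metadata <- list(phenotype = mech$phenotype,
                   euler_force_N = f_cr,
                   buckling_distance_mm = delta_b,
                   mechanics = mech)

  if (mech$phenotype == "floppy") {
    return(flexibility_profile("sim", samples, floppy = TRUE,
                               metadata = metadata, config = config))
  }

  # trigger semantics: drop leading sub-trigger compression samples (noise
  # can push the first few below the trigger)
  comp_idx <- which(samples$phase == "compression")
  trig_hit <- comp_idx[samples$force_N[comp_idx] >= trig]
  if (length(trig_hit) == 0) {
    return(flexibility_profile("sim", samples, floppy = TRUE,
                               metadata = metadata, config = config))
  }
  if (trig_hit[1] > 1) {
    samples <- samples[-seq_len(trig_hit[1] - 1L), , drop = FALSE]
    rownames(samples) <- NULL
  }
  flexibility_profile("sim", samples, metadata = metadata, config = config)
}

#' Built-in mechanical presets
#'
#' Named [filament_mechanics()] presets used by the reference-library and
#' panel generators. The three reference stand-ins are pliable with distinct
#' stiffness and plateau character; `dissolvable_like` is deliberately
#' dissimilar (soft, long pre-buckling rise, decaying plateau, weak recovery)
#' to exercise the library's outlier rule, and `mowiflex_like` has a ~120 N
#' force scale to exercise scale-freeness of the scoring.
#'
#' @param noise_sd Noise level applied to every preset (default 0.02 N).
#' @return Named list of `filament_mechanics`.
#' @export
filament_presets <- function(noise_sd = 0.02) {
  list(
    abs_like = filament_mechanics("pliable", youngs_modulus = 2.2e9,
                                  post_buckling_slope = 0.08,
                                  recovery_fraction = 0.65,
                                  imperfection = 0.5, noise_sd = noise_sd),
    pla_like = filament_mechanics("pliable", youngs_modulus = 3.5e9,
                                  post_buckling_slope = 0.10,
                                  recovery_fraction = 0.60,
                                  imperfection = 0.4, noise_sd = noise_sd),
    dissolvable_like = filament_mechanics("pliable", youngs_modulus = 1.1e9,
                                          post_buckling_slope = -0.03,
                                          recovery_fraction = 0.35,
                                          imperfection = 1.5,
                                          noise_sd = noise_sd),
    mowiflex_like = filament_mechanics("pliable", youngs_modulus = 6.6e10,
                                       post_buckling_slope = 1.5,
                                       recovery_fraction = 0.6,
                                       imperfection = 0.5,
                                       noise_sd = noise_sd)
  )
}

#' Simulate the commercial reference library
#'
#' Three pliable stand-ins for the commercial control filaments (ABS-like,
#' PLA-like, dissolvable-like), all feedable by construction. The
#' dissolvable-like preset is deliberately dissimilar to the other two so the
#' library's consistency matrix shows the asymmetric pattern of a real
#' control set containing one odd member.
#'
#' @param config A [protocol_config()].
#' @param seed Integer master seed.
#' @param noise_sd Noise level in N.
#' @return A `labeled_panel`: list with `profiles` (named list of
#'   `flexibility_profile`s) and `truth` (named character vector, all
#'   `"feedable"`).
#' @export
make_reference_library <- function(config = protocol_config(), seed = 1,
                                   noise_sd = 0.02) {
  presets <- filament_presets(noise_sd = noise_sd)[
    c("abs_like", "pla_like", "dissolvable_like")]
  ids <- c(abs_like = "ABS_like", pla_like = "PLA_like",
           dissolvable_like = "Dissolvable_like")
  seeds <- derive_seeds(seed, length(presets))
  profiles <- list()
  for (i in seq_along(presets)) {
    mech <- presets[[i]]
    mech$seed <- seeds[i]
    prof <- simulate_profile(mech, config)
    prof$filament_id <- ids[[names(presets)[i]]]
    profiles[[prof$filament_id]] <- prof
  }
  structure(
    list(profiles = profiles,
         truth = stats::setNames(rep("feedable", length(profiles)),
                                 names(profiles))),
    class = "labeled_panel"
  )
}

derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

jitter_ranges <- list(
  pliable = list(youngs_modulus = c(1.0e9, 4.0e9),
                 post_buckling_slope = c(0.02, 0.15),
                 recovery_fraction = c(0.4, 0.8),
                 imperfection = c(0.3, 1.0)),
  # brittle specimens fracture within the first few mm of the 15 mm stroke;
  # strain-bearing ones travel farther than sharp ones before breaking
  sharp_brittle = list(yield_force = c(2, 15),
                       fracture_distance = c(0.3, 1.5),
                       recovery_fraction = c(0, 0)),
  strain_bearing_brittle = list(yield_force = c(2, 15),
                                fracture_distance = c(1.5, 4.5),
                                residual_force_fraction = c(0.02, 0.12),
                                recovery_fraction = c(0.05, 0.15)),
  floppy = list(yield_force = c(0.005, 0.04),
                youngs_modulus = c(5e5, 5e6),
                recovery_fraction = c(0.2, 0.6))
)

truth_label <- c(pliable = "feedable",
                 sharp_brittle = "non-feedable",
                 strain_bearing_brittle = "non-feedable",
                 floppy = "not-testable")

#' Simulate a labelled panel of filaments
#'
#' Draws `counts[phenotype]` filaments per phenotype with parameters jittered
#' uniformly within phenotype-valid ranges, simulates each profile, and
#' attaches the ground-truth feedability label (pliable are feedable, brittle
#' phenotypes non-feedable, floppy not-testable). Fully reproducible from the
#' master seed.
#'
#' @param counts Named integer vector, e.g.
#'   `c(pliable = 5, sharp_brittle = 5)`.
#' @param config A [protocol_config()].
#' @param seed Integer master seed.
#' @param noise_sd Noise level in N (default 0.02).
#' @return A `labeled_panel`: `profiles` (named list) and `truth` (named
#'   character vector of `"feedable"`, `"non-feedable"`, `"not-testable"`).
#' @export
make_panel <- function(counts, config = protocol_config(), seed = 1,
                       noise_sd = 0.02) {
  bad <- setdiff(names(counts), phenotype_levels)
  if (length(bad) > 0 || is.null(names(counts))) {
    stop("make_panel: unknown phenotype(s): ",
         paste(if (length(bad)) bad else "<unnamed>", collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(counts >= 0))
  total <- sum(counts)
  profiles <- list()
  truth <- character()
  if (total == 0) {
    return(structure(list(profiles = profiles, truth = truth),
                     class = "labeled_panel"))
  }
  seeds <- derive_seeds(seed, 2L * total)
  k <- 0L
  for (ph in names(counts)) {
    for (i in seq_len(counts[[ph]])) {
      k <- k + 1L
      ranges <- jitter_ranges[[ph]]
      draws <- withr::with_seed(seeds[2L * k - 1L], {
        lapply(ranges, function(r) stats::runif(1, r[1], r[2]))
      })
      args <- c(list(phenotype = ph, noise_sd = noise_sd,
                     seed = seeds[2L * k], config = config), draws)
      mech <- do.call(filament_mechanics, args)
      prof <- simulate_profile(mech, config)
      id <- sprintf("%s_%02d", ph, i)
      prof$filament_id <- id
      profiles[[id]] <- prof
      truth[id] <- truth_label[[ph]]
    }
  }
  structure(list(profiles = profiles, truth = truth),
            class = "labeled_panel")
}

#' @export
print.labeled_panel <- function(x, ...) {
  cat(sprintf("Labelled panel of %d simulated filaments\n", length(x$profiles)))
  if (length(x$truth) > 0) print(table(x$truth))
  invisible(x)
}

#' Write a labelled panel to canonical CSVs plus a truth file
#'
#' @param panel A `labeled_panel`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(panel$profiles)) {
    write_profile(panel$profiles[[id]],
                  file.path(dir, paste0(id, "__rep1.csv")))
  }
  jsonlite::write_json(as.list(panel$truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
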