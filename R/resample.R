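#' Build the common distance grid for a protocol
#'
#' The comparison grid runs the compression stations from 0 mm out to the full
#' compression distance, followed by the release stations back from the full
#' distance to 0 mm, so one vector holds the whole compress-and-release cycle.
#'
#' @param config A [protocol_config()].
#' @return Data frame with columns `distance_mm` and `phase`.
#' @export
protocol_grid <- function(config = protocol_config()) {
  D <- config$compression_distance
  data.frame(
    distance_mm = c(seq(0, D, length.out = config$grid_points_compression),
                    seq(D, 0, length.out = config$grid_points_release)),
    phase = rep(c("compression", "release"),
                c(config$grid_points_compression, config$grid_points_release)),
    stringsAsFactors = FALSE
  )
}

new_profile_vector <- function(filament_id, grid, values, normalized,
                               metadata = list()) {
  structure(
    list(filament_id = as.character(filament_id), grid = grid,
         values = as.numeric(values), normalized = isTRUE(normalized),
         metadata = metadata),
    class = "profile_vector"
  )
}

#' Resample a flexibility profile onto the common grid
#'
#' Correlating curves requires equal-length vectors, so each recorded curve is
#' linearly interpolated onto the fixed protocol grid. Compression stations
#' beyond the recorded range (a fracture can end sampling early) are filled
#' with the last recorded force when the recording ended in a force drop --
#' fractured specimens keep exerting some minor residual resistance -- and
#' with zero otherwise. An absent release phase yields zero at all release
#' stations, with a warning.
#'
#' @param profile A non-floppy `flexibility_profile` whose compression phase
#'   spans a positive distance.
#' @param config A [protocol_config()].
#' @return A `profile_vector` of raw forces (N) on the common grid.
#' @export
resample_profile <- function(profile, config = protocol_config()) {
  if (inherits(profile, "profile_vector")) {
    return(profile)  # already on a grid; idempotent entry point
  }
  if (profile$floppy) {
    stop("resample_profile: '", profile$filament_id,
         "' is floppy (never reached the trigger force) and not testable",
         call. = FALSE)
  }
  s <- profile$samples
  comp <- s[s$phase == "compression", , drop = FALSE]
  rel <- s[s$phase == "release", , drop = FALSE]
  if (nrow(comp) < 2) {
    stop("resample_profile: '", profile$filament_id,
         "': degenerate compression phase (fewer than 2 samples)",
         call. = FALSE)
  }
  if (diff(range(comp$distance_mm)) <= 0) {
    stop("resample_profile: '", profile$filament_id,
         "': compression phase spans zero distance", call. = FALSE)
  }
  if (nrow(rel) == 1) {
    stop("resample_profile: '", profile$filament_id,
         "': degenerate release phase (single sample)", call. = FALSE)
  }

  grid <- protocol_grid(config)
  comp_st <- grid$distance_mm[grid$phase == "compression"]
  rel_st <- grid$distance_mm[grid$phase == "release"]

  comp_f <- stats::approx(comp$distance_mm, comp$force_N, xout = comp_st,
                          ties = mean, rule = 1)$y
  beyond <- comp_st > max(comp$distance_mm)
  if (any(beyond)) {
    last_force <- comp$force_N[nrow(comp)]
    # a recording that ended after a force drop keeps its residual level;
    # otherwise there is no evidence of contact beyond the recorded range
    ended_in_drop <- max(comp$force_N) - last_force > config$trigger_force
    comp_f[beyond] <- if (ended_in_drop) last_force else 0
  }
  before <- comp_st < min(comp$distance_mm)
  if (any(before)) comp_f[before] <- comp$force_N[1]

  if (nrow(rel) == 0) {
    warning("resample_profile: '", profile$filament_id,
            "': no release phase recorded; release stations set to 0",
            call. = FALSE)
    rel_f <- rep(0, length(rel_st))
  } else {
    ord <- order(rel$distance_mm)
    rel_f <- stats::approx(rel$distance_mm[ord], rel$force_N[ord],
                           xout = rel_st, ties = mean, rule = 2)$y
  }

  new_profile_vector(
    profile$filament_id, grid, c(comp_f, rel_f), normalized = FALSE,
    metadata = c(profile$metadata, list(replicate = profile$replicate))
  )
}

#' Data-range normalization of a profile vector
#'
#' Divides every point of the curve by the curve total, `y_n / sum(y)`, so
#' the normalized vector sums to one. This removes the absolute force scale:
#' a stiff filament and a soft one with the same curve shape normalize to the
#' same vector, which is what lets filaments of very different hardness be
#' compared by correlation.
#'
#' @param x A `profile_vector` of raw forces, or a plain non-negative numeric
#'   vector with positive sum.
#' @return The same type as `x`, rescaled to sum to 1.
#' @export
normalize_profile <- function(x) {
  if (inherits(x, "profile_vector")) {
    v <- normalize_profile(x$values)
    out <- x
    out$values <- v
    out$normalized <- TRUE
    return(out)
  }
  x <- as.numeric(x)
  if (any(x < 0)) {
    stop("normalize_profile: negative forces cannot be range-normalized",
         call. = FALSE)
  }
  total <- sum(x)
  if (!is.finite(total) || total <= 0) {
    stop("normalize_profile: degenerate input (curve total is zero)",
         call. = FALSE)
  }
  x / total
}

#' Average replicate profile vectors
#'
#' Replicate curves on the identical grid are combined by their pointwise
#' mean and renormalized to sum to one. The replicate count is recorded in
#' the result's metadata so downstream reports can show it.
#'
#' @param vectors List of normalized `profile_vector`s on one grid.
#' @return A single `profile_vector`.
#' @export
aggregate_replicates <- function(vectors) {
  if (length(vectors) == 0) {
    stop("aggregate_replicates: no vectors supplied", call. = FALSE)
  }
  ref <- vectors[[1]]
  for (v in vectors[-1]) {
    if (length(v$values) != length(ref$values) ||
        !isTRUE(all.equal(v$grid$distance_mm, ref$grid$distance_mm)) ||
        !identical(v$grid$phase, ref$grid$phase)) {
      stop("aggregate_replicates: replicate grids do not match", call. = FALSE)
    }
  }
  vals <- rowMeans(vapply(vectors, `[[`, numeric(length(ref$values)), "values"))
  out <- ref
  out$values <- normalize_profile(vals)
  out$normalized <- TRUE
  out$metadata$n_replicates <- length(vectors)
  out
}

#' Cumulative-area transform of a normalized profile
#'
#' Replaces each station's value by the running total up to that station, i.e.
#' the normalized area accumulated under the flexibility profile. This is the
#' alternative reading of "correlating normalized areas under the curve";
#' the point-by-point curve is the package default and the two options are
#' selectable wherever profiles are scored.
#'
#' @param x A normalized `profile_vector`.
#' @return A `profile_vector` of the cumulative curve (final station = 1).
#' @export
cumulative_profile <- function(x) {
  stopifnot(inherits(x, "profile_vector"))
  out <- x
  out$values <- cumsum(x$values) / sum(x$values)
  out$metadata$cumulative <- TRUE
  out
}

#' Restrict a profile vector to its compression phase
#'
#' @param x A `profile_vector`.
#' @param renormalize Rescale the retained stations to sum to 1 (default
#'   `TRUE` when `x` is normalized).
#' @return A `profile_vector` holding only the compression stations.
#' @export
compression_only <- function(x, renormalize = x$normalized) {
  stopifnot(inherits(x, "profile_vector"))
  keep <- x$grid$phase == "compression"
  out <- x
  out$grid <- x$grid[keep, , drop = FALSE]
  out$values <- x$values[keep]
  if (isTRUE(renormalize)) out$values <- normalize_profile(out$values)
  out
}

#' Resample, normalize and average a filament's replicate profiles
#'
#' Convenience wrapper running the whole preparation chain for one filament:
#' each replicate is resampled onto the protocol grid, range-normalized, and
#' the replicates averaged.
#'
#' @param profiles List of `flexibility_profile`s of one filament.
#' @param config A [protocol_config()].
#' @return A normalized `profile_vector`.
#' @export
prepare_profile <- function(profiles, config = protocol_config()) {
  if (inherits(profiles, "flexibility_profile")) profiles <- list(profiles)
  vecs <- lapply(profiles, function(p) {
    normalize_profile(resample_profile(p, config))
  })
  aggregate_replicates(vecs)
}

#' @export
print.profile_vector <- function(x, ...) {
  cat(sprintf("%s profile vector '%s': %d stations (%d compression + %d release)\n",
              if (x$normalized) "Normalized" else "Raw",
              x$filament_id, length(x$values),
              sum(x$grid$phase == "compression"),
              sum(x$grid$phase == "release")))
  invisible(x)
}
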