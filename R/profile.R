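#' Construct a flexibility profile
#'
#' A flexibility profile is one compress-and-release force-distance curve
#' recorded by the texture analyzer for a single filament replicate. Distance
#' is probe travel in mm measured from the trigger point; force is the
#' reaction force in N. Each sample is tagged with the phase
#' (`"compression"` or `"release"`) it was recorded in.
#'
#' A profile whose specimen never exerted the trigger force (too flexible to
#' stand in the rig) is flagged `floppy`; floppy profiles carry no testable
#' samples and are routed to a "not-testable" call rather than scored.
#'
#' @param filament_id Label of the filament the specimen was cut from.
#' @param samples Data frame with columns `distance_mm`, `force_N`, `phase`.
#' @param replicate Replicate index (default 1).
#' @param floppy Logical; `TRUE` when the specimen never reached the trigger
#'   force.
#' @param metadata Free-form named list.
#' @param config A [protocol_config()], used for validation.
#' @param validate Set to `FALSE` to skip invariant checks (useful for
#'   constructing deliberately irregular curves in simulations).
#'
#' @return An object of class `flexibility_profile`.
#' @export
flexibility_profile <- function(filament_id, samples, replicate = 1L,
                                floppy = FALSE, metadata = list(),
                                config = protocol_config(), validate = TRUE) {
  samples <- as.data.frame(samples)
  prof <- structure(
    list(filament_id = as.character(filament_id),
         replicate = as.integer(replicate),
         samples = samples,
         floppy = isTRUE(floppy),
         metadata = metadata),
    class = "flexibility_profile"
  )
  if (validate) validate_profile(prof, config)
  prof
}

#' Validate a flexibility profile against the protocol invariants
#'
#' Checks that the sample table has the canonical columns, that distances are
#' non-decreasing within the compression phase and non-increasing within the
#' release phase, that forces are non-negative, that the compression phase
#' holds at least two samples, and that the first compression sample is at or
#' above the trigger force. Floppy profiles are exempt from the sample-count
#' and trigger checks.
#'
#' @param profile A `flexibility_profile`.
#' @param config A [protocol_config()].
#' @return The profile, invisibly; errors describe the violated invariant.
#' @export
validate_profile <- function(profile, config = protocol_config()) {
  s <- profile$samples
  required <- c("distance_mm", "force_N", "phase")
  missing_cols <- setdiff(required, names(s))
  if (length(missing_cols) > 0) {
    stop("profile '", profile$filament_id, "': missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (profile$floppy) {
    return(invisible(profile))
  }
  if (!all(s$phase %in% c("compression", "release"))) {
    stop("profile '", profile$filament_id,
         "': phase must be 'compression' or 'release'", call. = FALSE)
  }
  comp <- s[s$phase == "compression", , drop = FALSE]
  rel <- s[s$phase == "release", , drop = FALSE]
  if (nrow(comp) < 2) {
    stop("profile '", profile$filament_id,
         "': compression phase needs at least 2 samples", call. = FALSE)
  }
  if (any(diff(comp$distance_mm) < 0)) {
    stop("profile '", profile$filament_id,
         "': compression distances must be non-decreasing", call. = FALSE)
  }
  if (nrow(rel) > 1 && any(diff(rel$distance_mm) > 0)) {
    stop("profile '", profile$filament_id,
         "': release distances must be non-increasing", call. = FALSE)
  }
  if (any(s$force_N < 0)) {
    stop("profile '", profile$filament_id, "': negative force recorded",
         call. = FALSE)
  }
  if (comp$force_N[1] < config$trigger_force) {
    stop("profile '", profile$filament_id,
         "': first compression sample is below the trigger force (",
         config$trigger_force, " N); trim sub-trigger points or flag floppy",
         call. = FALSE)
  }
  invisible(profile)
}

#' Read a flexibility profile from a canonical CSV export
#'
#' The canonical dialect is a UTF-8 CSV with header
#' `distance_mm,force_N,phase`, one file per replicate, with the filename
#' stem `<filament_id>__rep<k>`. Leading compression samples below the
#' trigger force are trimmed and the distance axis re-zeroed at the first
#' at-trigger sample, matching the instrument's trigger semantics. A curve
#' that never reaches the trigger force is returned as a floppy profile with
#' no retained samples.
#'
#' @param path Path to the CSV file.
#' @param config A [protocol_config()].
#' @return A `flexibility_profile`.
#' @export
read_profile <- function(path, config = protocol_config()) {
  if (!file.exists(path)) {
    stop("read_profile: file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  if (nrow(raw) == 0) {
    stop("read_profile: empty input: ", path, call. = FALSE)
  }
  required <- c("distance_mm", "force_N", "phase")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("read_profile: ", path, ": missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  parse_num <- function(col) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(x) & !is.na(raw[[col]]) & nzchar(trimws(raw[[col]])))
    bad <- c(bad, which(is.na(raw[[col]]) | !nzchar(trimws(raw[[col]]))))
    if (length(bad) > 0) {
      stop("read_profile: ", path, ": non-numeric value in column '", col,
           "' at row ", min(bad), call. = FALSE)
    }
    x
  }
  samples <- data.frame(
    distance_mm = parse_num("distance_mm"),
    force_N = parse_num("force_N"),
    phase = tolower(trimws(raw$phase)),
    stringsAsFactors = FALSE
  )
  if (!all(samples$phase %in% c("compression", "release"))) {
    stop("read_profile: ", path,
         ": phase must be 'compression' or 'release'", call. = FALSE)
  }

  stem <- sub("\\.[^.]*$", "", basename(path))
  if (grepl("__rep[0-9]+$", stem)) {
    filament_id <- sub("__rep[0-9]+$", "", stem)
    replicate <- as.integer(sub("^.*__rep", "", stem))
  } else {
    filament_id <- stem
    replicate <- 1L
  }

  comp_idx <- which(samples$phase == "compression")
  trig <- comp_idx[samples$force_N[comp_idx] >= config$trigger_force]
  if (length(trig) == 0) {
    return(flexibility_profile(
      filament_id, samples[0, , drop = FALSE], replicate = replicate,
      floppy = TRUE,
      metadata = list(source = path,
                      max_recorded_force_N = max(samples$force_N)),
      config = config
    ))
  }
  first <- trig[1]
  offset <- samples$distance_mm[first]
  if (first > 1) samples <- samples[-seq_len(first - 1L), , drop = FALSE]
  samples$distance_mm <- samples$distance_mm - offset
  samples <- samples[samples$distance_mm >= 0, , drop = FALSE]
  rownames(samples) <- NULL

  flexibility_profile(filament_id, samples, replicate = replicate,
                      metadata = list(source = path,
                                      trigger_offset_mm = offset),
                      config = config)
}

#' Write a flexibility profile to the canonical CSV dialect
#'
#' Numeric values are written with 17 significant digits so that a
#' read-then-write round trip preserves them bit-for-bit.
#'
#' @param profile A `flexibility_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  s <- profile$samples
  lines <- c(
    "distance_mm,force_N,phase",
    sprintf("%.17g,%.17g,%s", s$distance_mm, s$force_N, s$phase)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read every canonical profile CSV in a directory
#'
#' @param dir Directory containing `*.csv` profile exports.
#' @param config A [protocol_config()].
#' @return A list of `flexibility_profile` objects.
#' @export
read_profile_dir <- function(dir, config = protocol_config()) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0) {
    stop("read_profile_dir: no .csv files in ", dir, call. = FALSE)
  }
  lapply(files, read_profile, config = config)
}

#' @export
print.flexibility_profile <- function(x, ...) {
  n_comp <- sum(x$samples$phase == "compression")
  n_rel <- sum(x$samples$phase == "release")
  cat(sprintf("Flexibility profile '%s' (replicate %d)%s\n", x$filament_id,
              x$replicate, if (x$floppy) " [floppy: not testable]" else ""))
  cat(sprintf("  %d compression + %d release samples", n_comp, n_rel))
  if (nrow(x$samples) > 0) {
    cat(sprintf(", peak force %.3g N", max(x$samples$force_N)))
  }
  cat("\n")
  invisible(x)
}
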