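#' Texture-analyzer screening protocol constants
#'
#' Bundles the constants of the axial compress-and-release flexibility test:
#' a filament piece is held vertically between conical end caps (which allow
#' bending) and compressed by the texture-analyzer probe at the roller speed
#' of a desktop FDM printer, then released, while force is recorded. Recording
#' starts when the reaction force first reaches the trigger force; specimens
#' that never reach it are "floppy" and cannot be tested. The grid sizes
#' control the common distance grid onto which recorded curves are resampled
#' before correlation.
#'
#' @param compression_speed Probe speed in mm/s. The default, 3.15 mm/s,
#'   matches the filament feeding speed of a common desktop FDM printer.
#' @param compression_distance Total probe travel in mm (default 15).
#' @param trigger_force Force in N at which the instrument starts recording
#'   (default 0.05).
#' @param specimen_length Free length of the filament specimen in mm
#'   (default 50).
#' @param specimen_diameter Filament diameter in mm (default 1.75, the
#'   standard FDM feedstock diameter).
#' @param grid_points_compression,grid_points_release Number of resampling
#'   stations for the compression and release phases (default 128 each).
#'
#' @return An object of class `protocol_config`.
#' @examples
#' cfg <- protocol_config()
#' cfg$trigger_force
#' @export
protocol_config <- function(compression_speed = 3.15,
                            compression_distance = 15,
                            trigger_force = 0.05,
                            specimen_length = 50,
                            specimen_diameter = 1.75,
                            grid_points_compression = 128L,
                            grid_points_release = 128L) {
  cfg <- list(
    compression_speed = as.numeric(compression_speed),
    compression_distance = as.numeric(compression_distance),
    trigger_force = as.numeric(trigger_force),
    specimen_length = as.numeric(specimen_length),
    specimen_diameter = as.numeric(specimen_diameter),
    grid_points_compression = as.integer(grid_points_compression),
    grid_points_release = as.integer(grid_points_release)
  )
  for (nm in names(cfg)) {
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop("protocol_config: '", nm, "' must be a single strictly positive value",
           call. = FALSE)
    }
  }
  structure(cfg, class = "protocol_config")
}

#' Read protocol constants from a JSON config file
#'
#' All keys are optional; missing keys fall back to the [protocol_config()]
#' defaults. Unknown keys raise an error so that typos do not silently
#' leave a constant at its default.
#'
#' @param path Path to a flat JSON object of protocol constants.
#' @return A `protocol_config`.
#' @export
read_protocol_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(protocol_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("read_protocol_config: unknown key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(protocol_config, vals)
}

#' @export
print.protocol_config <- function(x, ...) {
  cat("Flexibility-test protocol\n")
  cat(sprintf("  compression: %.2f mm at %.2f mm/s, trigger %.3f N\n",
              x$compression_distance, x$compression_speed, x$trigger_force))
  cat(sprintf("  specimen: %.1f mm x %.2f mm diameter\n",
              x$specimen_length, x$specimen_diameter))
  cat(sprintf("  resampling grid: %d compression + %d release stations\n",
              x$grid_points_compression, x$grid_points_release))
  invisible(x)
}
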