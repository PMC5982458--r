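# fixtures are built in code: tiny protocol configs and hand-made curves

small_config <- function(ngrid = 4L) {
  protocol_config(grid_points_compression = ngrid, grid_points_release = ngrid)
}

# straight-ramp profile force = slope * distance over the full stroke,
# with a mirrored release at recovery * compression force
ramp_profile <- function(slope = 2, config = protocol_config(),
                         recovery = 0.5, id = "ramp", n = 31) {
  d <- seq(0, config$compression_distance, length.out = n)
  samples <- data.frame(
    distance_mm = c(d, rev(d)),
    force_N = c(slope * d, recovery * slope * rev(d)),
    phase = rep(c("compression", "release"), each = n)
  )
  flexibility_profile(id, samples, config = config, validate = FALSE)
}

write_profile_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(c("distance_mm,force_N,phase", lines), path)
  path
}

# normalized vector on the default grid from an arbitrary value sequence
as_profile_vector <- function(values, id = "v", config = protocol_config(),
                              normalized = FALSE) {
  grid <- protocol_grid(config)
  stopifnot(length(values) == nrow(grid))
  v <- feedscreen:::new_profile_vector(id, grid, values, normalized)
  v
}

default_grid_length <- function(config = protocol_config()) {
  config$grid_points_compression + config$grid_points_release
}
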