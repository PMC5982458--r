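#' Published-style feedability screening panel
#'
#' Correlation coefficients of 17 hot-melt-extruded pharmaceutical filaments
#' against three commercial reference filaments (ABS, a dissolvable support
#' filament, and PLA), together with the printer feeding outcome
#' (`fed_successfully`) and the report's average and rounded scores. Two
#' further formulations of the original panel (an over-plasticized
#' HPMCAS-PEO blend and a Soluplus-Tween blend) were too floppy to be tested
#' and therefore carry no coefficients. The table is the worked example for
#' [score_coefficients()]: recomputing the mean-then-round rule from the
#' per-reference coefficients reproduces the reported columns.
#'
#' @return Tibble with columns `filament_id`, `fed_successfully` (Y/N),
#'   `ABS`, `Dissolvable`, `PLA`, `reported_average`, `reported_rounded`.
#' @examples
#' panel <- feedability_panel()
#' scored <- score_coefficients(panel, ref_cols = c("ABS", "Dissolvable", "PLA"))
#' all(scored$display_score == panel$reported_average)
#' @export
feedability_panel <- function() {
  path <- system.file("extdata", "filament_panel_scores.csv",
                      package = "feedscreen", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Consistency matrix of the commercial reference filaments
#'
#' Pairwise correlation coefficients among the three commercial reference
#' filaments of [feedability_panel()]. The dissolvable filament correlates
#' weakly with the other two (0.62 and 0.51 against their mutual 0.92),
#' the pattern that motivates the outlier rule of
#' [build_reference_library()].
#'
#' @return A symmetric 3 x 3 numeric matrix with unit diagonal.
#' @export
reference_consistency <- function() {
  path <- system.file("extdata", "reference_consistency.csv",
                      package = "feedscreen", mustWork = TRUE)
  df <- utils::read.csv(path, row.names = 1)
  as.matrix(df)
}
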