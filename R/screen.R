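#' Screen a panel of filament profiles end to end
#'
#' Runs the complete screening pipeline: reference profiles are resampled,
#' normalized and built into a [build_reference_library()]; each candidate is
#' then prepared the same way and scored. Floppy candidates (never reached
#' the trigger force) bypass scoring and are called `"not-testable"`;
#' everything else receives the Boolean feedability call, reported as
#' `"feedable"` or `"non-feedable"`.
#'
#' @param candidates List of `flexibility_profile`s, or a `labeled_panel`.
#'   Replicates sharing a `filament_id` are averaged.
#' @param references List of `flexibility_profile`s of known-feedable
#'   reference filaments, or a `labeled_panel`.
#' @param config A [protocol_config()].
#' @param outlier_threshold Passed to [build_reference_library()].
#' @param ... Passed to [score_panel()] (`profile_form`,
#'   `compression_phase_only`, `threshold`, `margin`, `method`).
#' @return List with `table` (tibble: score columns plus a `call` column),
#'   and `library` (the `reference_library`).
#' @export
screen_panel <- function(candidates, references, config = protocol_config(),
                         outlier_threshold = 0.55, ...) {
  if (inherits(candidates, "labeled_panel")) candidates <- candidates$profiles
  if (inherits(references, "labeled_panel")) references <- references$profiles

  ref_vecs <- prepare_by_filament(references, config)
  library <- build_reference_library(ref_vecs,
                                     outlier_threshold = outlier_threshold)

  cand_groups <- split_by_filament(candidates)
  floppy_ids <- names(cand_groups)[vapply(cand_groups, function(g) {
    all(vapply(g, `[[`, logical(1), "floppy"))
  }, logical(1))]
  testable <- setdiff(names(cand_groups), floppy_ids)

  cand_vecs <- lapply(cand_groups[testable], prepare_profile, config = config)
  scored <- score_panel(cand_vecs, library, ...)
  scored$call <- ifelse(scored$feedable, "feedable", "non-feedable")

  if (length(floppy_ids) > 0) {
    template <- empty_score_table(names(library$references))
    cols <- c(list(filament_id = floppy_ids),
              stats::setNames(
                replicate(ncol(template) - 6L,
                          rep(NA_real_, length(floppy_ids)),
                          simplify = FALSE),
                grep("^C_", names(template), value = TRUE)),
              list(mean_score = rep(NA_real_, length(floppy_ids)),
                   display_score = rep(NA_real_, length(floppy_ids)),
                   rounded_score = rep(NA_integer_, length(floppy_ids)),
                   feedable = rep(NA, length(floppy_ids)),
                   borderline = rep(NA, length(floppy_ids)),
                   call = rep("not-testable", length(floppy_ids))))
    scored <- rbind(scored, tibble::as_tibble(cols))
  }
  scored <- scored[order(match(scored$filament_id, names(cand_groups))), ]
  list(table = scored, library = library)
}

split_by_filament <- function(profiles) {
  ids <- vapply(profiles, `[[`, character(1), "filament_id")
  split(profiles, factor(ids, levels = unique(ids)))
}

prepare_by_filament <- function(profiles, config) {
  groups <- split_by_filament(profiles)
  lapply(groups, prepare_profile, config = config)
}

#' Fraction of screening calls matching ground truth
#'
#' Compares the `call` column of a [screen_panel()] table with a truth map
#' (as produced by [make_panel()]).
#'
#' @param table The `table` element of a [screen_panel()] result.
#' @param truth Named character vector: filament_id to
#'   `"feedable"` / `"non-feedable"` / `"not-testable"`.
#' @return Proportion of filaments whose call equals the truth label.
#' @export
recovery_rate <- function(table, truth) {
  stopifnot(all(table$filament_id %in% names(truth)))
  mean(table$call == truth[table$filament_id])
}

#' Phenotype-recovery experiment on simulated panels
#'
#' The headline validation of the pipeline on synthetic data: over `n_seeds`
#' independently seeded rounds, simulate a reference library and a candidate
#' panel, screen the panel, and record the fraction of filaments whose call
#' matches the ground truth.
#'
#' @param counts Phenotype counts per panel (default 2 filaments of each
#'   phenotype).
#' @param n_seeds Number of seeded rounds (default 100).
#' @param seed Master seed from which round seeds are derived.
#' @param config A [protocol_config()].
#' @param noise_sd Simulator noise level in N.
#' @param ... Passed to [screen_panel()].
#' @return List with `overall` recovery rate, `per_round` rates, and `n`
#'   (total filament calls compared).
#' @export
phenotype_recovery <- function(counts = c(pliable = 2, sharp_brittle = 2,
                                          strain_bearing_brittle = 2,
                                          floppy = 2),
                               n_seeds = 100, seed = 1,
                               config = protocol_config(), noise_sd = 0.02,
                               ...) {
  round_seeds <- derive_seeds(seed, 2L * n_seeds)
  per_round <- numeric(n_seeds)
  n_total <- 0L
  n_match <- 0L
  for (r in seq_len(n_seeds)) {
    refs <- make_reference_library(config, seed = round_seeds[2L * r - 1L],
                                   noise_sd = noise_sd)
    panel <- make_panel(counts, config, seed = round_seeds[2L * r],
                        noise_sd = noise_sd)
    res <- screen_panel(panel, refs, config, ...)
    ok <- res$table$call == panel$truth[res$table$filament_id]
    per_round[r] <- mean(ok)
    n_total <- n_total + length(ok)
    n_match <- n_match + sum(ok)
  }
  list(overall = n_match / n_total, per_round = per_round, n = n_total)
}
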