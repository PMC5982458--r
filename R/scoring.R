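#' Round half away from zero
#'
#' Display rounding used in feedability reports (2 decimals by default).
#' Spreadsheet-style half-away-from-zero, so e.g. a mean of -1.19/3 prints
#' as -0.40 rather than base R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Correlate two profile vectors
#'
#' Pearson product-moment correlation between two equal-length curve vectors;
#' the similarity measure underlying the feedability score. Because Pearson
#' correlation is invariant under positive affine rescaling, it is unaffected
#' by the data-range normalization and by the absolute force scale of the
#' filament. Spearman rank correlation is available for robustness studies.
#'
#' @param x,y `profile_vector`s or plain numeric vectors of equal length.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
correlate_profiles <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  vx <- if (inherits(x, "profile_vector")) x$values else as.numeric(x)
  vy <- if (inherits(y, "profile_vector")) y$values else as.numeric(y)
  if (length(vx) != length(vy)) {
    stop("correlate_profiles: vectors differ in length (", length(vx),
         " vs ", length(vy), "); resample onto one grid first", call. = FALSE)
  }
  if (stats::sd(vx) == 0 || stats::sd(vy) == 0) {
    stop("correlate_profiles: zero-variance profile has no shape to correlate",
         call. = FALSE)
  }
  stats::cor(vx, vy, method = method)
}

#' Mean correlation score over a reference library
#'
#' The feedability score of a candidate is the arithmetic mean of its
#' correlation coefficients with the reference filaments,
#' `(C_ref1 + ... + C_refk) / k`. References excluded from the consistency
#' analysis still count here unless explicitly listed in `excluded`.
#'
#' @param per_reference Named numeric vector of per-reference correlations.
#' @param excluded Character vector of reference names to drop.
#' @return The mean score at full precision.
#' @export
mean_score <- function(per_reference, excluded = character()) {
  keep <- setdiff(names(per_reference), excluded)
  if (length(keep) == 0) {
    stop("mean_score: no references left after exclusion", call. = FALSE)
  }
  mean(unlist(per_reference[keep]))
}

#' Boolean feedability call from a mean correlation score
#'
#' Mean scores below 0.5 round down to 0 (non-feedable) and scores above 0.5
#' round up to 1 (feedable); feedability is treated as a Boolean, not a
#' graded ranking. A score exactly at the threshold rounds up and is always
#' flagged borderline, as are scores within `margin` of the threshold.
#'
#' @param score Mean correlation score in \[-1, 1\].
#' @param threshold Decision threshold (default 0.5).
#' @param margin Half-width of the borderline band (default 0.05).
#' @return List with `rounded_score` (0/1), `feedable` and `borderline`.
#' @export
classify_feedability <- function(score, threshold = 0.5, margin = 0.05) {
  stopifnot(length(score) == 1, is.finite(score))
  rounded <- if (score < threshold) 0L else 1L
  list(
    rounded_score = rounded,
    feedable = rounded == 1L,
    borderline = abs(score - threshold) < margin || score == threshold
  )
}

#' Build a reference library from known-feedable profiles
#'
#' Computes the pairwise correlation (consistency) matrix among the reference
#' curves. A reference whose mean correlation with the other references falls
#' below `outlier_threshold` is marked excluded-for-PCA: it stays in the mean
#' feedability score (the Boolean call keeps all purchased controls) but is
#' left out of the principal component analysis, where a dissimilar control
#' would smear the cluster structure.
#'
#' @param references Named list of normalized `profile_vector`s, or a list
#'   whose elements carry `filament_id`s used as names.
#' @param outlier_threshold Mean off-diagonal correlation below which a
#'   reference is flagged (default 0.55).
#' @param method Correlation flavor, see [correlate_profiles()].
#' @return An object of class `reference_library` with elements `references`,
#'   `consistency_matrix` and `excluded`.
#' @export
build_reference_library <- function(references, outlier_threshold = 0.55,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.null(names(references)) || any(!nzchar(names(references)))) {
    names(references) <- vapply(references, `[[`, character(1), "filament_id")
  }
  if (anyDuplicated(names(references))) {
    stop("build_reference_library: duplicate reference names", call. = FALSE)
  }
  if (length(references) < 2) {
    stop("build_reference_library: need at least 2 reference profiles",
         call. = FALSE)
  }
  n <- length(references)
  cm <- diag(1, n)
  dimnames(cm) <- list(names(references), names(references))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cm[i, j] <- cm[j, i] <-
        correlate_profiles(references[[i]], references[[j]], method = method)
    }
  }
  mean_off <- (rowSums(cm) - 1) / (n - 1)
  excluded <- names(references)[mean_off < outlier_threshold]
  structure(
    list(references = references, consistency_matrix = cm,
         excluded = excluded, outlier_threshold = outlier_threshold,
         method = method),
    class = "reference_library"
  )
}

#' @export
print.reference_library <- function(x, ...) {
  cat(sprintf("Reference library: %d filaments (%s)\n",
              length(x$references), paste(names(x$references), collapse = ", ")))
  cat("Consistency matrix:\n")
  print(round(x$consistency_matrix, 2))
  if (length(x$excluded) > 0) {
    cat("Excluded from PCA (mean correlation < ", x$outlier_threshold, "): ",
        paste(x$excluded, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Score a panel of candidate profiles against a reference library
#'
#' For each candidate, computes the correlation with every reference (the
#' full library, including PCA-excluded references, enters the mean score),
#' the mean score, its 2-decimal display value and the Boolean feedability
#' call. The output mirrors the columns of a feedability report table:
#' per-reference coefficients, average score, rounded score.
#'
#' @param candidates Named list of normalized `profile_vector`s (names default
#'   to the vectors' `filament_id`s).
#' @param library A `reference_library`.
#' @param profile_form `"curve"` correlates the normalized curves point by
#'   point (default); `"cumulative"` correlates their cumulative-area curves.
#' @param compression_phase_only Use only the compression-phase stations.
#' @param threshold,margin Passed to [classify_feedability()].
#' @param method Correlation flavor.
#' @return A tibble with one row per candidate: `filament_id`, one `C_<ref>`
#'   column per reference, `mean_score`, `display_score`, `rounded_score`,
#'   `feedable`, `borderline`.
#' @export
score_panel <- function(candidates, library,
                        profile_form = c("curve", "cumulative"),
                        compression_phase_only = FALSE,
                        threshold = 0.5, margin = 0.05,
                        method = c("pearson", "spearman")) {
  profile_form <- match.arg(profile_form)
  method <- match.arg(method)
  stopifnot(inherits(library, "reference_library"))
  if (length(candidates) == 0) {
    return(empty_score_table(names(library$references)))
  }
  if (is.null(names(candidates)) || any(!nzchar(names(candidates)))) {
    names(candidates) <- vapply(candidates, `[[`, character(1), "filament_id")
  }
  refs <- library$references
  xform <- function(v) {
    if (compression_phase_only) v <- compression_only(v)
    if (profile_form == "cumulative") v <- cumulative_profile(v)
    v
  }
  refs_t <- lapply(refs, xform)
  ngrid <- length(refs_t[[1]]$values)
  rows <- lapply(names(candidates), function(id) {
    cand <- xform(candidates[[id]])
    if (length(cand$values) != ngrid) {
      stop("score_panel: candidate '", id, "' is not on the library grid",
           call. = FALSE)
    }
    cc <- vapply(refs_t, function(r) {
      correlate_profiles(cand, r, method = method)
    }, numeric(1))
    ms <- mean_score(as.list(cc))
    cls <- classify_feedability(ms, threshold = threshold, margin = margin)
    out <- c(list(filament_id = id),
             stats::setNames(as.list(cc), paste0("C_", names(cc))),
             list(mean_score = ms,
                  display_score = round_half_up(ms, 2),
                  rounded_score = cls$rounded_score,
                  feedable = cls$feedable,
                  borderline = cls$borderline))
    tibble::as_tibble(out)
  })
  do.call(rbind, rows)
}

empty_score_table <- function(ref_names) {
  cols <- c(list(filament_id = character()),
            stats::setNames(replicate(length(ref_names), numeric(),
                                      simplify = FALSE),
                            paste0("C_", ref_names)),
            list(mean_score = numeric(), display_score = numeric(),
                 rounded_score = integer(), feedable = logical(),
                 borderline = logical()))
  tibble::as_tibble(cols)
}

#' Score a panel given per-reference coefficients
#'
#' Applies the mean-then-round feedability rule to a table of already
#' computed per-reference correlation coefficients (for example a published
#' report table, or per-replicate coefficients), without access to the raw
#' curves.
#'
#' @param coefficients Data frame with a `filament_id` column and one numeric
#'   column per reference.
#' @param ref_cols Names of the coefficient columns; defaults to every
#'   numeric column.
#' @param threshold,margin Passed to [classify_feedability()].
#' @return A tibble with `mean_score`, `display_score`, `rounded_score`,
#'   `feedable` and `borderline` appended.
#' @export
score_coefficients <- function(coefficients, ref_cols = NULL,
                               threshold = 0.5, margin = 0.05) {
  df <- as.data.frame(coefficients)
  if (is.null(ref_cols)) {
    ref_cols <- names(df)[vapply(df, is.numeric, logical(1))]
  }
  if (length(ref_cols) == 0) {
    stop("score_coefficients: no coefficient columns found", call. = FALSE)
  }
  ms <- rowMeans(df[, ref_cols, drop = FALSE])
  cls <- lapply(ms, classify_feedability, threshold = threshold,
                margin = margin)
  df$mean_score <- ms
  df$display_score <- round_half_up(ms, 2)
  df$rounded_score <- vapply(cls, `[[`, integer(1), "rounded_score")
  df$feedable <- vapply(cls, `[[`, logical(1), "feedable")
  df$borderline <- vapply(cls, `[[`, logical(1), "borderline")
  tibble::as_tibble(df)
}
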