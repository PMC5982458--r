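#' Assemble the PCA data matrix from a profile panel
#'
#' The filaments are the variables and the grid stations the observations:
#' each column is one filament's normalized curve, standardized to zero mean
#' and unit variance. The component analysis then works on the filaments'
#' correlation matrix, so eigenvalues sum to the number of filaments and the
#' Kaiser rule applies on its usual scale.
#'
#' @param panel Named list of normalized `profile_vector`s on one grid
#'   (3 or more).
#' @return Numeric matrix, stations x filaments, standardized columns.
#' @export
assemble_profile_matrix <- function(panel) {
  if (is.null(names(panel)) || any(!nzchar(names(panel)))) {
    names(panel) <- vapply(panel, `[[`, character(1), "filament_id")
  }
  if (length(panel) < 3) {
    stop("assemble_profile_matrix: need at least 3 filaments", call. = FALSE)
  }
  n <- length(panel[[1]]$values)
  X <- vapply(panel, function(v) {
    if (length(v$values) != n) {
      stop("assemble_profile_matrix: '", v$filament_id,
           "' is not on the common grid", call. = FALSE)
    }
    v$values
  }, numeric(n))
  sds <- apply(X, 2, stats::sd)
  flat <- colnames(X)[sds == 0]
  if (length(flat) > 0) {
    stop("assemble_profile_matrix: zero-variance (flat) profile(s): ",
         paste(flat, collapse = ", "), call. = FALSE)
  }
  scale(X)
}

#' Eigendecomposition of the filament correlation matrix
#'
#' Principal components of the variables' correlation matrix. Loadings are
#' scaled so the squared loadings of each component sum to its eigenvalue
#' (the usual factor-analytic scaling); each component's sign is fixed so its
#' largest-magnitude loading is positive, making results deterministic across
#' platforms.
#'
#' @param x Standardized stations x filaments matrix from
#'   [assemble_profile_matrix()].
#' @return List with `eigenvalues` (descending) and `loadings`
#'   (filaments x components).
#' @export
pca_eigen <- function(x) {
  if (nrow(x) < 2) {
    stop("pca_eigen: need at least 2 observations", call. = FALSE)
  }
  R <- stats::cor(x)
  ee <- eigen(R, symmetric = TRUE)
  ev <- pmax(ee$values, 0)  # clip tiny negative roundoff
  L <- ee$vectors %*% diag(sqrt(ev), nrow = length(ev))
  rownames(L) <- colnames(x)
  colnames(L) <- paste0("PC", seq_along(ev))
  list(eigenvalues = ev, loadings = fix_loading_signs(L))
}

fix_loading_signs <- function(L) {
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  L
}

#' Kaiser rule: number of components to retain
#'
#' Retains the components of a correlation-matrix PCA whose eigenvalue is at
#' least 1, i.e. components that carry more variance than a single
#' standardized variable.
#'
#' @param eigenvalues Numeric vector of eigenvalues in descending order.
#' @return Integer count of retained components; warns when none qualify.
#' @export
kaiser_select <- function(eigenvalues) {
  if (is.unsorted(rev(eigenvalues))) {
    stop("kaiser_select: eigenvalues must be in descending order",
         call. = FALSE)
  }
  n <- sum(eigenvalues >= 1)
  if (n == 0) {
    warning("kaiser_select: no component reaches an eigenvalue of 1",
            call. = FALSE)
  }
  as.integer(n)
}

#' Varimax criterion of a loading matrix
#'
#' The quantity varimax rotation maximizes: the summed variance of the
#' squared loadings within each component, optionally after Kaiser row
#' normalization (each variable's loadings divided by the square root of its
#' communality).
#'
#' @param loadings Variables x components matrix.
#' @param kaiser_normalize Apply Kaiser row normalization first.
#' @return The criterion value.
#' @export
varimax_criterion <- function(loadings, kaiser_normalize = TRUE) {
  L <- as.matrix(loadings)
  if (kaiser_normalize) {
    L <- L / sqrt(rowSums(L^2))
  }
  p <- nrow(L)
  sq <- L^2
  sum(colSums(sq^2) - colSums(sq)^2 / p) / p
}

#' Varimax rotation of a loading matrix
#'
#' Orthogonal rotation maximizing the varimax criterion, with Kaiser row
#' normalization on by default, a convergence tolerance on the criterion's
#' surrogate, and a fixed iteration budget (default 25). Communalities (row
#' sums of squared loadings) are invariant under the rotation, and the result
#' is deterministic for a fixed input: component signs are fixed as in
#' [pca_eigen()].
#'
#' @param loadings Variables x components matrix (k >= 1 columns).
#' @param max_iterations Iteration budget (default 25).
#' @param tolerance Relative convergence tolerance (default 1e-6).
#' @param kaiser_normalize Apply Kaiser row normalization (default `TRUE`).
#' @return List with `loadings` (rotated), `rotation` (k x k orthogonal
#'   matrix), `iterations` and `converged`.
#' @export
varimax_rotate <- function(loadings, max_iterations = 25, tolerance = 1e-6,
                           kaiser_normalize = TRUE) {
  L <- as.matrix(loadings)
  k <- ncol(L)
  if (k == 0) {
    warning("varimax_rotate: no components to rotate", call. = FALSE)
    return(list(loadings = L, rotation = diag(0), iterations = 0L,
                converged = TRUE))
  }
  if (k == 1) {
    return(list(loadings = fix_loading_signs(L), rotation = diag(1),
                iterations = 0L, converged = TRUE))
  }
  p <- nrow(L)
  sc <- if (kaiser_normalize) sqrt(rowSums(L^2)) else rep(1, p)
  x <- L / sc
  rot <- diag(k)
  d <- 0
  converged <- FALSE
  iter <- 0L
  for (i in seq_len(max_iterations)) {
    iter <- i
    z <- x %*% rot
    B <- t(x) %*% (z^3 - z %*% diag(colSums(z^2) / p, nrow = k))
    sv <- svd(B)
    rot <- sv$u %*% t(sv$v)
    d_prev <- d
    d <- sum(sv$d)
    if (d < d_prev * (1 + tolerance)) {
      converged <- TRUE
      break
    }
  }
  z <- (x %*% rot) * sc
  dimnames(z) <- dimnames(L)
  list(loadings = fix_loading_signs(z), rotation = rot, iterations = iter,
       converged = converged)
}

#' Principal component sorting of a filament panel
#'
#' Runs the full component analysis on a panel of normalized flexibility
#' profiles: standardize, eigendecompose the filament correlation matrix,
#' retain components by the Kaiser rule, and varimax-rotate the retained
#' loadings. The rotated loadings place each filament in component space,
#' where feedable, tunable and non-feedable filaments separate into clusters.
#'
#' @param panel Named list of normalized `profile_vector`s.
#' @param exclude Names of filaments to drop before the analysis (e.g. a
#'   reference flagged as an outlier by [build_reference_library()]).
#' @param group_labels Optional named character vector of group labels
#'   (e.g. feedable / tunable / non-feedable) carried through to plots.
#' @param max_iterations,tolerance,kaiser_normalize Passed to
#'   [varimax_rotate()].
#' @return An object of class `pca_solution`.
#' @export
pca_profiles <- function(panel, exclude = character(), group_labels = NULL,
                         max_iterations = 25, tolerance = 1e-6,
                         kaiser_normalize = TRUE) {
  if (is.null(names(panel)) || any(!nzchar(names(panel)))) {
    names(panel) <- vapply(panel, `[[`, character(1), "filament_id")
  }
  panel <- panel[setdiff(names(panel), exclude)]
  X <- assemble_profile_matrix(panel)
  dec <- pca_eigen(X)
  n_ret <- kaiser_select(dec$eigenvalues)
  L <- dec$loadings[, seq_len(n_ret), drop = FALSE]
  if (n_ret >= 2) {
    rot <- varimax_rotate(L, max_iterations = max_iterations,
                          tolerance = tolerance,
                          kaiser_normalize = kaiser_normalize)
  } else {
    rot <- list(loadings = L, rotation = diag(n_ret), iterations = 0L,
                converged = TRUE)
  }
  structure(
    list(variable_names = names(panel),
         eigenvalues = dec$eigenvalues,
         n_retained = n_ret,
         loadings_unrotated = L,
         loadings_rotated = rot$loadings,
         rotation = rot$rotation,
         rotation_iterations = rot$iterations,
         converged = rot$converged,
         excluded = exclude,
         group_labels = group_labels),
    class = "pca_solution"
  )
}

#' @export
print.pca_solution <- function(x, ...) {
  cat(sprintf("PCA of %d filament flexibility profiles\n",
              length(x$variable_names)))
  ev <- x$eigenvalues[seq_len(min(5, length(x$eigenvalues)))]
  cat("  leading eigenvalues:", paste(sprintf("%.2f", ev), collapse = ", "),
      if (length(x$eigenvalues) > 5) "..." else "", "\n")
  cat(sprintf("  Kaiser rule retains %d component(s); varimax %s in %d iteration(s)\n",
              x$n_retained,
              if (x$converged) "converged" else "did not converge",
              x$rotation_iterations))
  if (length(x$excluded) > 0) {
    cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Space-plot coordinates of a rotated solution
#'
#' Emits each filament's rotated loadings as coordinates in component space,
#' with optional group labels for coloring a space plot. Clusters in this
#' space correspond to mechanically similar filaments.
#'
#' @param solution A `pca_solution` with at least 2 retained components.
#' @return Tibble with `filament_id`, one column per rotated component, and
#'   a `group` column when group labels are present.
#' @export
space_plot_coordinates <- function(solution) {
  stopifnot(inherits(solution, "pca_solution"))
  if (solution$n_retained < 2) {
    stop("space_plot_coordinates: fewer than 2 components retained; ",
         "a space plot needs 2 or 3 -- inspect the loadings directly instead",
         call. = FALSE)
  }
  df <- tibble::as_tibble(as.data.frame(solution$loadings_rotated))
  df <- tibble::add_column(df, filament_id = solution$variable_names,
                           .before = 1)
  if (!is.null(solution$group_labels)) {
    df$group <- unname(solution$group_labels[df$filament_id])
  }
  df
}

#' Plot the rotated component space
#'
#' 2-D space plot of the first two rotated components (the first three
#' components are tabulated by [space_plot_coordinates()]; a flat figure is
#' the portable view). Points are labelled by filament and colored by group
#' when group labels are present.
#'
#' @param solution A `pca_solution`.
#' @return A ggplot object.
#' @export
plot_space <- function(solution) {
  df <- space_plot_coordinates(solution)
  aes_args <- if ("group" %in% names(df)) {
    ggplot2::aes(x = .data$PC1, y = .data$PC2, color = .data$group)
  } else {
    ggplot2::aes(x = .data$PC1, y = .data$PC2)
  }
  ggplot2::ggplot(df, aes_args) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$filament_id),
                       vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "Rotated component 1", y = "Rotated component 2",
                  color = NULL,
                  title = "Filament flexibility profiles in rotated component space") +
    ggplot2::theme_minimal()
}

#' Silhouette of a labelling in rotated component space
#'
#' Mean silhouette width of the filaments' rotated coordinates under a given
#' labelling (e.g. mechanical phenotype). Positive values mean filaments sit
#' closer to their own group than to the nearest other group -- the
#' separation one reads off a space plot, as a number.
#'
#' @param coords Matrix or data frame of numeric coordinates (rows =
#'   filaments), e.g. `solution$loadings_rotated`.
#' @param labels Group label per row (2 or more distinct values).
#' @return Mean silhouette width.
#' @export
silhouette_separation <- function(coords, labels) {
  coords <- as.matrix(coords[, vapply(as.data.frame(coords), is.numeric,
                                      logical(1)), drop = FALSE])
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2) {
    stop("silhouette_separation: need at least 2 groups", call. = FALSE)
  }
  sil <- cluster::silhouette(labels, stats::dist(coords))
  mean(sil[, "sil_width"])
}
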