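#' PCA embedding of a feature matrix
#'
#' Eigendecomposition of the feature covariance via [stats::prcomp]
#' (centered, not rescaled -- rescaling is the job of
#' [normalize_features()]).  Retains either a fixed number of
#' components or the smallest number whose cumulative variance reaches
#' `var_target`.
#'
#' @param fm A `feature_matrix` (normalized, for the binning route) or
#'   a plain numeric matrix with rownames.
#' @param n_components Number of components to retain; `NULL` defers to
#'   `var_target`.
#' @param var_target Retain the smallest leading set of components
#'   whose cumulative variance fraction is at least this value.  If
#'   both arguments are `NULL`, all components are kept.
#' @return An object of class `pca_embedding`: `ids`, `coordinates`
#'   (scores, rows x retained components), `eigenvalues` (all, variance
#'   per component, non-increasing), `loadings` (feature x retained
#'   component eigenvectors), `var_explained` (cumulative fraction at
#'   the retained cut), `center`.
#' @export
pca_embed <- function(fm, n_components = NULL, var_target = NULL) {
  x <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  if (nrow(x) < 2L) stop("need at least 2 rows for a PCA")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  total <- sum(ev)
  cum <- if (total > 0) cumsum(ev) / total else rep(1, length(ev))

  q <- length(ev)
  if (!is.null(var_target)) {
    if (var_target <= 0 || var_target > 1) stop("'var_target' must be in (0, 1]")
    q <- which(cum >= var_target - 1e-12)[1L]
  }
  if (!is.null(n_components)) {
    n_components <- as.integer(n_components)
    if (n_components < 1L || n_components > min(nrow(x) - 1L, ncol(x)))
      stop("'n_components' must be between 1 and min(rows - 1, cols)")
    q <- if (is.null(var_target)) n_components else min(q, n_components)
  }
  q <- max(1L, min(q, ncol(pc$x)))

  structure(list(ids = rownames(x),
                 coordinates = pc$x[, seq_len(q), drop = FALSE],
                 eigenvalues = ev,
                 loadings = pc$rotation[, seq_len(q), drop = FALSE],
                 var_explained = cum[q],
                 center = pc$center),
            class = "pca_embedding")
}

#' @export
print.pca_embedding <- function(x, ...) {
  cat(sprintf("pca_embedding: %d rows, %d components retained (%.1f%% variance)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              100 * x$var_explained))
  invisible(x)
}
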