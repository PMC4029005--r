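#' Best-of-N restarted K-means
#'
#' Lloyd's algorithm with Euclidean distances and `runs` random
#' (Forgy) initializations; the run with the smallest within-cluster
#' sum of squared distances is returned.  Clusters that empty out
#' during an iteration are re-seeded at the point currently farthest
#' from its assigned center.  With a fixed `seed` the initializations
#' for `runs = r` are a prefix of those for any larger `runs`, so the
#' best SSE is non-increasing in `runs`.
#'
#' @param x Numeric matrix (rows = observations) or a `pca_embedding`,
#'   whose coordinates are then clustered.
#' @param k Number of clusters (>= 1).
#' @param runs Number of random restarts.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param max_iter Iteration cap per run.
#' @return An object of class `cluster_assignment`: `cluster` (named
#'   integer vector, contiguous indices from 1), `method`
#'   (`"kmeans_pca"`), `k`, `runs`, `score` (best SSE), `sse_runs`
#'   (per-run SSE), `centers`.
#' @export
kmeans_best_of <- function(x, k = 10, runs = 100, seed = NULL,
                           max_iter = 100) {
  if (inherits(x, "pca_embedding")) x <- x$coordinates
  x <- as.matrix(x)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("'k' must be >= 1")
  if (nrow(x) < k) stop("need at least k rows")
  runs <- as.integer(runs)
  if (runs < 1L) stop("'runs' must be >= 1")
  maybe_seed(seed)

  n <- nrow(x)
  xsq <- rowSums(x^2)
  best <- NULL
  sse_runs <- numeric(runs)
  for (r in seq_len(runs)) {
    centers <- x[sample.int(n, k), , drop = FALSE]
    assign_prev <- integer(0)
    for (it in seq_len(max_iter)) {
      d2 <- outer(xsq, rowSums(centers^2), "+") - 2 * x %*% t(centers)
      assign <- max.col(-d2, ties.method = "first")
      mind2 <- d2[cbind(seq_len(n), assign)]
      empty <- setdiff(seq_len(k), unique(assign))
      if (length(empty)) {
        # re-seed each empty cluster at the worst-fit point
        ord <- order(mind2, decreasing = TRUE)
        for (j in seq_along(empty)) {
          centers[empty[j], ] <- x[ord[j], ]
        }
        next
      }
      if (identical(assign, assign_prev)) break
      assign_prev <- assign
      centers <- rowsum(x, assign) / as.vector(table(assign))
    }
    sse <- sum(pmax(mind2, 0))
    sse_runs[r] <- sse
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(assign = assign, centers = centers, sse = sse)
    }
  }

  # relabel to contiguous indices, ordered by first appearance
  lev <- unique(best$assign)
  cluster <- match(best$assign, lev)
  names(cluster) <- rownames(x)
  structure(list(cluster = cluster, method = "kmeans_pca", k = k,
                 runs = runs, score = best$sse, sse_runs = sse_runs,
                 centers = best$centers[lev, , drop = FALSE]),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment (%s): %d items in %d clusters, score %.4g\n",
              x$method, length(x$cluster), length(unique(x$cluster)),
              x$score))
  if (!is.null(x$taxon)) {
    lab <- x$cluster_labels
    cat(sprintf("  labeled: %d of %d clusters carry a taxon\n",
                sum(lab$taxon != "UNLABELED"), nrow(lab)))
  }
  invisible(x)
}
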