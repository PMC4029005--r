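#' Train an emergent self-organizing map
#'
#' Standard online SOM training: per epoch, each (shuffled) input
#' vector is presented, its best-matching unit (BMU) found by Euclidean
#' distance, and neuron weights within a Gaussian neighborhood of
#' decaying radius are pulled toward the input with a decaying learning
#' rate.  Decay of both is linear over all presentation steps.  The
#' emergent regime -- many more neurons than expected clusters -- makes
#' the U-matrix (mean distance of each neuron's weight to its grid
#' neighbors) display clusters as valleys separated by ridges.
#'
#' @param fm A normalized `feature_matrix` (typically the
#'   tetranucleotide block, see [feature_block()] usage in
#'   [consensus_binning()]) or a plain numeric matrix with rownames.
#' @param rows,cols Grid dimensions (>= 2 each).  Defaults give about
#'   two neurons per input row at a 1.64 aspect ratio.
#' @param epochs Training epochs (full passes over the data).
#' @param lr Learning rate start and end values.
#' @param radius Neighborhood radius start and end, in grid units;
#'   default `c(max(rows, cols) / 2, 1)`.
#' @param topology `"toroidal"` (wrap-around neighborhoods, the
#'   emergent-map standard) or `"planar"`.
#' @param seed Integer seed for weight initialization and presentation
#'   order.
#' @param record_qe If `TRUE`, record the quantization error after each
#'   epoch (one extra BMU pass per epoch).
#' @return An object of class `esom_map`: grid dimensions and
#'   `topology`, `weights` (neuron x feature), `pos` (neuron grid
#'   coordinates, row-major), `bmu` (named neuron index per input row),
#'   `qe` (final mean quantization error), `umatrix` (rows x cols),
#'   optionally `qe_epochs`.
#' @export
esom_train <- function(fm, rows = NULL, cols = NULL, epochs = 20,
                       lr = c(0.5, 0.05), radius = NULL,
                       topology = c("toroidal", "planar"), seed = NULL,
                       record_qe = FALSE) {
  topology <- match.arg(topology)
  x <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  n <- nrow(x)
  if (n < 1L) stop("empty input")
  if (is.null(rows)) rows <- max(2L, round(sqrt(2 * n / 1.64)))
  if (is.null(cols)) cols <- max(2L, round(1.64 * rows))
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 2L || cols < 2L) stop("grid must be at least 2x2")
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop("'epochs' must be >= 1")
  if (is.null(radius)) radius <- c(max(rows, cols) / 2, 1)
  maybe_seed(seed)

  m <- rows * cols
  pos <- cbind(rep(seq_len(rows) - 1L, each = cols),
               rep(seq_len(cols) - 1L, times = rows))
  w0 <- x[sample.int(n, m, replace = TRUE), , drop = FALSE] +
    matrix(rnorm(m * ncol(x), sd = 0.05), m, ncol(x))
  order0 <- as.integer(unlist(lapply(seq_len(epochs),
                                     function(e) sample.int(n)))) - 1L

  fit <- som_train_cpp(x, w0, pos, rows, cols, order0, epochs,
                       lr[1], lr[2], radius[1], radius[2],
                       topology == "toroidal", record_qe)
  w <- fit$weights
  b <- bmu_cpp(x, w)
  bmu <- stats::setNames(b$bmu, rownames(x))

  structure(list(rows = rows, cols = cols, topology = topology,
                 weights = w, pos = pos + 1L, bmu = bmu, qe = b$qe,
                 qe_epochs = fit$qe_epochs,
                 umatrix = umatrix_from_weights(w, rows, cols, topology),
                 ids = rownames(x)),
            class = "esom_map")
}

# Neuron index (row-major, 1-based) of the grid cell (r, c), with
# optional toroidal wrapping.
grid_index <- function(r, c, rows, cols, toroidal) {
  if (toroidal) {
    r <- ((r - 1L) %% rows) + 1L
    c <- ((c - 1L) %% cols) + 1L
    (r - 1L) * cols + c
  } else {
    ok <- r >= 1L & r <= rows & c >= 1L & c <= cols
    ifelse(ok, (r - 1L) * cols + c, NA_integer_)
  }
}

# U-matrix: per neuron, mean Euclidean distance of its weight to the
# weights of its (up to) 8 grid neighbors.
umatrix_from_weights <- function(w, rows, cols, topology) {
  toroidal <- topology == "toroidal"
  m <- rows * cols
  r <- rep(seq_len(rows), each = cols)
  c <- rep(seq_len(cols), times = rows)
  acc <- numeric(m)
  cnt <- numeric(m)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- grid_index(r + dr, c + dc, rows, cols, toroidal)
    ok <- !is.na(nb)
    d <- sqrt(rowSums((w[which(ok), , drop = FALSE] -
                         w[nb[ok], , drop = FALSE])^2))
    acc[ok] <- acc[ok] + d
    cnt[ok] <- cnt[ok] + 1
  }
  matrix(acc / cnt, nrow = rows, ncol = cols, byrow = TRUE)
}

#' @export
print.esom_map <- function(x, ...) {
  cat(sprintf("esom_map: %dx%d %s grid, %d inputs, quantization error %.4f\n",
              x$rows, x$cols, x$topology, length(x$bmu), x$qe))
  invisible(x)
}

#' Extract clusters from a trained map's U-matrix
#'
#' Neurons whose U-matrix value lies at or below the `ridge_quantile`
#' quantile form "valley" cells; connected valley components (8-cell
#' adjacency, wrapped for toroidal maps) define the clusters.  Each
#' input inherits the component of its BMU; inputs whose BMU sits on a
#' ridge join the nearest valley component by grid distance (ties
#' resolved toward the lower component index, then the lower neuron
#' index).  Only components that receive at least one input appear in
#' the result; indices are contiguous from 1.
#'
#' @param map A trained `esom_map`.
#' @param ridge_quantile Quantile of U-matrix values separating valleys
#'   (below) from ridges (above); `1` makes every neuron a valley and
#'   hence (on a torus) yields a single cluster.
#' @return A `cluster_assignment` with `method = "esom"`; also carries
#'   `valley` (logical per neuron), `component` (per-neuron component
#'   index, `NA` on ridges) and `threshold`.
#' @export
esom_clusters <- function(map, ridge_quantile = 0.6) {
  if (!inherits(map, "esom_map")) stop("'map' must be an esom_map")
  if (ridge_quantile < 0 || ridge_quantile > 1)
    stop("'ridge_quantile' must be in [0, 1]")
  u <- as.vector(t(map$umatrix))  # row-major, matching neuron indices
  thr <- as.numeric(quantile(u, ridge_quantile))
  valley <- u <= thr
  if (!any(valley)) stop("degenerate threshold: no valley cells")

  rows <- map$rows; cols <- map$cols
  toroidal <- map$topology == "toroidal"
  r <- rep(seq_len(rows), each = cols)
  c <- rep(seq_len(cols), times = rows)
  from <- integer(0); to <- integer(0)
  for (sh in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    nb <- grid_index(r + sh[1], c + sh[2], rows, cols, toroidal)
    ok <- !is.na(nb) & valley & valley[ifelse(is.na(nb), 1L, nb)]
    from <- c(from, which(ok)); to <- c(to, nb[ok])
  }
  vids <- which(valley)
  g <- igraph::graph_from_edgelist(
    cbind(match(from, vids), match(to, vids)), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(vids) - igraph::vcount(g)))
  comp_raw <- igraph::components(g)$membership
  # relabel components by their smallest neuron index (vids is sorted)
  comp <- as.integer(factor(comp_raw, levels = unique(comp_raw)))
  component <- rep(NA_integer_, rows * cols)
  component[vids] <- comp

  bmu <- map$bmu
  cl <- component[bmu]
  ridge_bmus <- which(is.na(cl))
  if (length(ridge_bmus)) {
    vr <- r[vids]; vc <- c[vids]
    for (i in ridge_bmus) {
      dr <- abs(r[bmu[i]] - vr); dc <- abs(c[bmu[i]] - vc)
      if (toroidal) {
        dr <- pmin(dr, rows - dr); dc <- pmin(dc, cols - dc)
      }
      d2 <- dr^2 + dc^2
      pick <- order(d2, comp, vids)[1L]
      cl[i] <- comp[pick]
    }
  }

  lev <- sort(unique(cl))
  cluster <- stats::setNames(match(cl, lev), names(bmu))
  structure(list(cluster = cluster, method = "esom",
                 k = length(lev), score = map$qe,
                 valley = valley, component = component,
                 threshold = thr, ridge_quantile = ridge_quantile,
                 map_dims = c(rows, cols)),
            class = "cluster_assignment")
}
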