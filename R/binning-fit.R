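#' Consensus composition-based binning
#'
#' The full dual-route binning workflow in one call.  Contigs of
#' length >= `min_len` are described by GC content and k-mer
#' frequencies for each `k` in `ks`, z-scored per feature.  Route one
#' clusters a PCA embedding of the full matrix with best-of-`runs`
#' K-means (`k` clusters, Euclidean distances); route two trains an
#' emergent self-organizing map on the z-scored tetranucleotide block
#' and extracts U-matrix valley clusters.  Both clusterings are
#' labeled from the partial annotation table by strict majority vote,
#' and the consensus keeps a contig only when the routes do not
#' contradict each other: contigs assigned different taxa are
#' discarded as ambiguous.
#'
#' @param contigs [Biostrings::DNAStringSet] or named character vector.
#' @param labels Partial annotation table: data frame with columns
#'   `contig_id`, `taxon`, or a named character vector.
#' @param min_len Length cutoff for binning (the clustering is run on
#'   contigs at least this long).
#' @param ks Word sizes for the composition matrix.
#' @param strand_mode K-mer counting mode, see [kmer_frequencies()].
#' @param k,runs K-means cluster count and restarts
#'   ([kmeans_best_of()]).  `k` may exceed the expected number of taxa;
#'   surplus clusters sharing a majority taxon merge at the labeling
#'   step.
#' @param var_target PCA variance fraction retained before K-means.
#' @param esom_rows,esom_cols ESOM grid ([esom_train()] defaults apply
#'   when `NULL`).
#' @param epochs,ridge_quantile ESOM training length and U-matrix
#'   valley threshold ([esom_train()], [esom_clusters()]).
#' @param min_frac Majority-vote support threshold
#'   ([label_clusters()]).
#' @param seed Integer seed; sub-seeds for the stochastic stages are
#'   derived from it deterministically.
#' @return An object of class `consensus_binning` with components
#'   `bins` (the [consensus_bins()] result), `summary` (per-taxon
#'   [bin_summary()]), `agreement` (the [agreement_fraction()] between
#'   routes), `kmeans`, `esom`, `esom_map`, `pca`, `features`
#'   (dimensions and exclusions), and `params`.
#' @examples
#' specs <- lapply(1:3, function(i)
#'   genome_spec(paste0("G", i), 60000, gc = 0.25 + 0.15 * i, skew = 0.4))
#' cs <- community_spec(specs, n_contigs = 240, min_contig_len = 1000,
#'                      label_fraction = 0.3)
#' com <- simulate_community(cs, seed = 7)
#' fit <- consensus_binning(com$contigs, com$labels, runs = 10,
#'                          esom_rows = 12, esom_cols = 20, epochs = 5,
#'                          seed = 7)
#' fit
#' @export
consensus_binning <- function(contigs, labels, min_len = 1000, ks = 2:5,
                              strand_mode = "single", k = 10, runs = 100,
                              var_target = 0.9, esom_rows = NULL,
                              esom_cols = NULL, epochs = 20,
                              ridge_quantile = 0.6, min_frac = 0.5,
                              seed = NULL) {
  if (!4L %in% ks)
    stop("'ks' must include 4: the ESOM route runs on tetranucleotides")
  fm <- composition_matrix(contigs, ks = ks, min_len = min_len,
                           strand_mode = strand_mode)
  fmz <- normalize_features(fm)

  emb <- pca_embed(fmz, var_target = var_target)
  km <- kmeans_best_of(emb, k = k, runs = runs,
                       seed = if (is.null(seed)) NULL else derive_seed(seed, 1L))

  tetra <- feature_block(fmz, "k4")
  map <- esom_train(tetra, rows = esom_rows, cols = esom_cols,
                    epochs = epochs,
                    seed = if (is.null(seed)) NULL else derive_seed(seed, 2L))
  es <- esom_clusters(map, ridge_quantile = ridge_quantile)

  km_lab <- label_clusters(km, labels, min_frac = min_frac)
  es_lab <- label_clusters(es, labels, min_frac = min_frac)

  bins <- consensus_bins(km_lab, es_lab)
  structure(list(bins = bins,
                 summary = bin_summary(bins, contigs),
                 agreement = agreement_fraction(km_lab, es_lab),
                 kmeans = km_lab, esom = es_lab, esom_map = map,
                 pca = emb,
                 features = list(n_contigs = nrow(fmz$values),
                                 n_features = ncol(fmz$values),
                                 excluded = fmz$excluded),
                 params = list(min_len = min_len, ks = ks,
                               strand_mode = strand_mode, k = k,
                               runs = runs, var_target = var_target,
                               epochs = epochs,
                               ridge_quantile = ridge_quantile,
                               min_frac = min_frac, seed = seed)),
            class = "consensus_binning")
}

#' @export
print.consensus_binning <- function(x, ...) {
  asg <- x$bins$assignments
  cat("Consensus composition-based binning\n")
  cat(sprintf("  %d contigs binned (%d excluded below %d bp)\n",
              x$features$n_contigs, length(x$features$excluded),
              x$params$min_len))
  cat(sprintf("  K-means route: %d clusters; ESOM route: %d valley clusters\n",
              length(unique(x$kmeans$cluster)), x$esom$k))
  cat(sprintf("  route agreement on mutually labeled contigs: %.1f%%\n",
              100 * x$agreement))
  cat(sprintf("  consensus: %d assigned, %d discarded, %d unbinned\n",
              sum(!asg$taxon %in% c("DISCARDED", "UNBINNED")),
              sum(asg$taxon == "DISCARDED"),
              sum(asg$taxon == "UNBINNED")))
  invisible(x)
}

#' @export
summary.consensus_binning <- function(object, ...) {
  out <- list(summary = object$summary, agreement = object$agreement,
              kmeans_labels = object$kmeans$cluster_labels,
              esom_labels = object$esom$cluster_labels)
  class(out) <- "summary.consensus_binning"
  out
}

#' @export
print.summary.consensus_binning <- function(x, ...) {
  cat("Per-bin summary:\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("\nRoute agreement: %.1f%%\n", 100 * x$agreement))
  cat("\nK-means cluster labels:\n")
  print(x$kmeans_labels, row.names = FALSE)
  cat("\nESOM cluster labels:\n")
  print(x$esom_labels, row.names = FALSE)
  invisible(x)
}

#' Plot a consensus binning
#'
#' Two panels: the contigs in the first two principal components,
#' colored by consensus taxon (discarded contigs in grey), and the
#' ESOM U-matrix with valleys dark and ridges light.
#'
#' @param x A `consensus_binning` object.
#' @param ... Ignored.
#' @export
plot.consensus_binning <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(par(op))
  asg <- x$bins$assignments
  taxa <- setdiff(sort(unique(asg$taxon)), c("DISCARDED", "UNBINNED"))
  pal <- c(hcl.colors(max(3, length(taxa)), "Dark 3")[seq_along(taxa)])
  colmap <- stats::setNames(pal, taxa)
  colmap[c("DISCARDED", "UNBINNED")] <- c("grey60", "grey85")
  xy <- x$pca$coordinates[, 1:2, drop = FALSE]
  col <- colmap[asg$taxon[match(rownames(xy), asg$contig_id)]]
  plot(xy, col = col, pch = 16, cex = 0.5, xlab = "PC1", ylab = "PC2",
       main = "PCA / K-means route")
  legend("topright", legend = names(colmap), col = colmap, pch = 16,
         cex = 0.6, bty = "n")
  image(t(x$esom_map$umatrix)[, x$esom_map$rows:1],
        col = hcl.colors(64, "Blue-Yellow"), axes = FALSE,
        main = "ESOM U-matrix")
  invisible(x)
}
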