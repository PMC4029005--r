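#' Default eight-genome benchmark community
#'
#' Eight order-2 Markov genomes at GC 0.30 to 0.65 in steps of 0.05,
#' each with its own context-level composition skew (so adjacent-GC
#' genomes still differ in higher-order signature), equal abundances,
#' ~2 kb median contigs with a 1 kb floor and 20% annotation labels.
#' This is the community the package's recovery benchmark and the
#' binning validation run on.
#'
#' @param n_contigs Number of contigs.
#' @param n_genomes Number of genomes (GC values are spread evenly
#'   over `gc_range`).
#' @param gc_range GC of the first and last genome.
#' @param skew Context-split half-width for every genome (see
#'   [genome_spec()]).
#' @param genome_length Length of each genome, bases.
#' @param label_fraction Fraction of contigs annotated.
#' @param min_contig_len Contig length floor.
#' @return A [community_spec()].
#' @export
benchmark_community_spec <- function(n_contigs = 2000, n_genomes = 8,
                                     gc_range = c(0.30, 0.65), skew = 0.35,
                                     genome_length = 400000,
                                     label_fraction = 0.2,
                                     min_contig_len = 1000) {
  gcs <- seq(gc_range[1], gc_range[2], length.out = n_genomes)
  genomes <- lapply(seq_len(n_genomes), function(i)
    genome_spec(sprintf("G%02d", i), genome_length, gc = gcs[i],
                order = 2, skew = skew))
  community_spec(genomes, n_contigs = n_contigs,
                 min_contig_len = min_contig_len,
                 label_fraction = label_fraction)
}

#' Bin-recovery benchmark over seeds
#'
#' Simulates the benchmark community once per seed, runs the full
#' consensus binning ([consensus_binning()]) with the given
#' parameters, and scores each run: the between-route agreement
#' fraction, the number of ESOM valley clusters, the consensus
#' discard rate, and (when \pkg{mclust} is installed) the adjusted
#' Rand index between the consensus bins and the simulation truth on
#' the contigs that received a taxon.
#'
#' @param seeds Integer vector of community seeds (one run each).
#' @param cspec Community specification; default
#'   [benchmark_community_spec()].
#' @param esom_rows,esom_cols ESOM grid for the benchmark; the 50 x 82
#'   toroidal default gives about two neurons per contig at the
#'   benchmark's community size.
#' @param ... Further binning parameters passed on to
#'   [consensus_binning()] (e.g. `k`, `runs`, `epochs`).
#' @return Data frame with one row per seed: `seed`, `n_contigs`,
#'   `agreement`, `esom_k`, `kmeans_k`, `discard_rate`, `ari`.
#' @export
bin_recovery_experiment <- function(seeds = 1:10,
                                    cspec = benchmark_community_spec(),
                                    esom_rows = 50, esom_cols = 82,
                                    ...) {
  has_mclust <- requireNamespace("mclust", quietly = TRUE)
  rows <- lapply(seeds, function(s) {
    com <- simulate_community(cspec, seed = s)
    fit <- consensus_binning(com$contigs, com$labels, seed = s,
                             esom_rows = esom_rows, esom_cols = esom_cols,
                             ...)
    asg <- fit$bins$assignments
    assigned <- !asg$taxon %in% c("DISCARDED", "UNBINNED")
    ari <- NA_real_
    if (has_mclust && any(assigned)) {
      truth <- com$truth$taxon[match(asg$contig_id[assigned],
                                     com$truth$contig_id)]
      ari <- mclust::adjustedRandIndex(asg$taxon[assigned], truth)
    }
    data.frame(seed = s, n_contigs = fit$features$n_contigs,
               agreement = fit$agreement, esom_k = fit$esom$k,
               kmeans_k = length(unique(fit$kmeans$cluster)),
               discard_rate = mean(asg$taxon == "DISCARDED"),
               ari = ari)
  })
  do.call(rbind, rows)
}
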