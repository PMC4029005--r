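# Small, well-separated communities for fast unit tests, plus a cached
# run of the full-scale recovery benchmark shared by the acceptance
# checks (it is expensive, so it is computed once per test session).

small_genome_specs <- function(n = 3, gc = seq(0.30, 0.70, length.out = n),
                               len = 60000, skew = 0.4) {
  lapply(seq_len(n), function(i)
    genome_spec(sprintf("G%d", i), len, gc = gc[i], order = 2, skew = skew))
}

small_community <- function(seed = 7, n_contigs = 240, n_genomes = 3,
                            label_fraction = 0.3) {
  cs <- community_spec(small_genome_specs(n_genomes),
                       n_contigs = n_contigs, min_contig_len = 1000,
                       label_fraction = label_fraction)
  simulate_community(cs, seed = seed)
}

small_fit <- function(com, seed = 7, ...) {
  consensus_binning(com$contigs, com$labels, runs = 10, esom_rows = 12,
                    esom_cols = 20, epochs = 5, seed = seed, ...)
}

.benchmark_cache <- new.env(parent = emptyenv())

benchmark_run <- function() {
  if (is.null(.benchmark_cache$res)) {
    .benchmark_cache$res <- bin_recovery_experiment(seeds = 1:10)
  }
  .benchmark_cache$res
}
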