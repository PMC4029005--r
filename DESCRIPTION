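Package: compbin
Title: Composition-Based Contig Binning and Gut Metagenome Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bins metagenome contigs into organism-level groups from
    nucleotide composition alone, by two independent routes: K-means
    clustering of a PCA embedding of GC content and di- through
    penta-nucleotide frequencies, and an emergent self-organizing map
    (ESOM) trained on tetranucleotide frequencies with U-matrix valley
    extraction.  Cluster labels inferred from partial taxonomic
    annotations are reconciled by a consensus rule that discards contigs
    the two routes assign to different taxa.  Also provides the
    companion community profiling computations (relative abundance,
    cumulative dominance, rarefaction-style subsampled richness,
    functional-category normalization and PCA) and a synthetic
    community generator (Markov-chain genomes with controlled GC and
    higher-order compositional bias) used to validate bin recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    igraph,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vegan,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
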