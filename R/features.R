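#' GC fraction of sequences
#'
#' (#G + #C) / (#A + #C + #G + #T) per sequence.  Bases outside ACGT
#' (ambiguity codes, N) are excluded from both numerator and
#' denominator.
#'
#' @param seq A character vector, [Biostrings::DNAString] or
#'   [Biostrings::DNAStringSet].
#' @return Numeric vector of GC fractions in `[0, 1]`.
#' @export
gc_fraction <- function(seq) {
  x <- as_dss(seq)
  if (length(x) == 0L) stop("empty input")
  counts <- Biostrings::letterFrequency(x, letters = c("A", "C", "G", "T"))
  denom <- rowSums(counts)
  if (any(denom == 0))
    stop("sequence with no ACGT bases: GC fraction undefined")
  unname((counts[, "C"] + counts[, "G"]) / denom)
}

# Coerce character / DNAString input to a DNAStringSet, uppercased.
as_dss <- function(seq) {
  if (inherits(seq, "DNAStringSet")) return(seq)
  if (inherits(seq, "DNAString")) return(Biostrings::DNAStringSet(seq))
  Biostrings::DNAStringSet(toupper(seq))
}

#' K-mer frequency vectors
#'
#' Sliding-window k-mer frequencies per sequence: windows containing
#' any non-ACGT base are skipped; counts are divided by the number of
#' valid windows so each row sums to 1.  In `combined` mode the counts
#' of each k-mer and its reverse complement are pooled before
#' normalizing (strand-independent, canonical counting).
#'
#' @param seq Sequences as in [gc_fraction()].
#' @param k Word size, 2 to 5.
#' @param strand_mode `"single"` (count the given strand only) or
#'   `"combined"` (add reverse-complement counts).
#' @return Numeric matrix, sequences x 4^k k-mers, rows summing to 1.
#' @export
kmer_frequencies <- function(seq, k, strand_mode = c("single", "combined")) {
  strand_mode <- match.arg(strand_mode)
  k <- as.integer(k)
  if (is.na(k) || k < 2L || k > 5L) stop("'k' must be between 2 and 5")
  x <- as_dss(seq)
  if (any(Biostrings::width(x) < k)) stop("sequence shorter than k")
  counts <- Biostrings::oligonucleotideFrequency(x, width = k)
  if (strand_mode == "combined") {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(colnames(counts))))
    counts <- counts + counts[, rc, drop = FALSE]
  }
  tot <- rowSums(counts)
  if (any(tot == 0))
    stop("sequence with no valid ACGT window of length k")
  freq <- counts / tot
  rownames(freq) <- names(x)
  freq
}

#' Composition feature matrix for a contig set
#'
#' One row per contig of length >= `min_len`, columns: GC fraction
#' followed by the k-mer frequency blocks for each `k` in `ks` (fixed
#' lexicographic k-mer order).  This raw matrix is the input to
#' [normalize_features()] and the binning routes.
#'
#' @param contigs Named character vector or [Biostrings::DNAStringSet];
#'   names are the contig ids (must be unique).
#' @param ks Integer vector of word sizes, each in 2..5.
#' @param min_len Minimum contig length retained (must be >= `max(ks)`);
#'   shorter contigs are reported in `$excluded`.
#' @param strand_mode Passed to [kmer_frequencies()].
#' @return An object of class `feature_matrix`: list with `values`
#'   (numeric matrix, rownames = contig ids), `ks`, `strand_mode`,
#'   `k_blocks` (column indices per feature block), `normalized`
#'   (logical), `excluded` (ids below `min_len`).
#' @export
composition_matrix <- function(contigs, ks = 2:5, min_len = 1000,
                               strand_mode = c("single", "combined")) {
  strand_mode <- match.arg(strand_mode)
  ks <- sort(unique(as.integer(ks)))
  if (any(ks < 2L | ks > 5L)) stop("all 'ks' must be between 2 and 5")
  if (min_len < max(ks)) stop("'min_len' must be >= max(ks)")
  x <- as_dss(contigs)
  if (is.null(names(x)) || anyDuplicated(names(x)))
    stop("contigs must have unique names")
  keep <- Biostrings::width(x) >= min_len
  excluded <- names(x)[!keep]
  x <- x[keep]
  if (length(x) == 0L) stop("no contigs of length >= min_len")

  blocks <- c(list(gc = matrix(gc_fraction(x), ncol = 1,
                               dimnames = list(names(x), "gc"))),
              lapply(ks, function(k) kmer_frequencies(x, k, strand_mode)))
  values <- do.call(cbind, blocks)
  idx <- cumsum(c(1L, 4L^ks))
  k_blocks <- c(list(gc = 1L),
                stats::setNames(lapply(seq_along(ks), function(i)
                  seq.int(idx[i] + 1L, idx[i + 1L])), paste0("k", ks)))

  structure(list(values = values, ks = ks, strand_mode = strand_mode,
                 k_blocks = k_blocks, normalized = FALSE,
                 excluded = excluded, constant_cols = character(0)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d contigs x %d features (%s, %s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "z-scored" else "raw frequencies",
              paste0("k=", paste(x$ks, collapse = ","))))
  if (length(x$excluded))
    cat(sprintf("  %d contigs excluded below length cutoff\n",
                length(x$excluded)))
  if (length(x$constant_cols))
    cat(sprintf("  %d constant columns zeroed by normalization\n",
                length(x$constant_cols)))
  invisible(x)
}

#' Z-score feature columns
#'
#' Per-column standardization `(x - mean) / sd`, putting GC (percent
#' scale) and k-mer frequencies (<= 1 scale) on comparable footing for
#' Euclidean clustering.  Constant columns are set to 0 and recorded in
#' `$constant_cols`.  Idempotent up to floating-point error.
#'
#' @param fm A `feature_matrix` (raw or already normalized) from
#'   [composition_matrix()].
#' @return The `feature_matrix` with z-scored `values` and
#'   `normalized = TRUE`.
#' @export
normalize_features <- function(fm) {
  if (!inherits(fm, "feature_matrix")) stop("'fm' must be a feature_matrix")
  if (nrow(fm$values) < 2L) stop("need at least 2 rows to normalize")
  mu <- colMeans(fm$values)
  sdv <- apply(fm$values, 2L, sd)
  const <- sdv < 1e-12
  sdv[const] <- 1
  z <- sweep(sweep(fm$values, 2L, mu, "-"), 2L, sdv, "/")
  z[, const] <- 0
  fm$values <- z
  fm$normalized <- TRUE
  fm$constant_cols <- union(fm$constant_cols, colnames(z)[const])
  fm
}

# Pull a sub-block of features (e.g. the tetranucleotide block) as a
# new feature_matrix.
feature_block <- function(fm, block) {
  if (!block %in% names(fm$k_blocks)) stop("unknown feature block: ", block)
  fm$values <- fm$values[, fm$k_blocks[[block]], drop = FALSE]
  fm$k_blocks <- stats::setNames(list(seq_len(ncol(fm$values))), block)
  fm
}
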