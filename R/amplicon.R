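#' Relative abundance of taxon counts
#'
#' Divides each sample's counts by its total.  Accepts a taxa x
#' samples matrix (each column a sample) or a single named count
#' vector.
#'
#' @param counts Non-negative integer matrix (taxa x samples) or named
#'   vector.
#' @return Fractions with the same shape; each sample sums to 1.
#' @export
relative_abundance <- function(counts) {
  if (is.matrix(counts) || is.data.frame(counts)) {
    counts <- as.matrix(counts)
    if (any(counts < 0)) stop("counts must be non-negative")
    tot <- colSums(counts)
    if (any(tot == 0)) stop("sample with zero total reads: fractions undefined")
    sweep(counts, 2L, tot, "/")
  } else {
    if (any(counts < 0)) stop("counts must be non-negative")
    tot <- sum(counts)
    if (tot == 0) stop("sample with zero total reads: fractions undefined")
    counts / tot
  }
}

#' Cumulative share of named taxa
#'
#' The summed percentage of a set of taxa in one sample, as reported
#' in dominance statements ("the top taxa accounted for X% of the
#' sequences").  The rounded integer percent is returned alongside the
#' exact value.
#'
#' @param fractions Named fraction vector for one sample (e.g. a
#'   column of [relative_abundance()]).
#' @param taxa Taxa to sum; every name must exist in `fractions`.
#' @return List with `percent` (integer, half-up rounding) and
#'   `percent_exact`.
#' @export
cumulative_share <- function(fractions, taxa) {
  missing <- setdiff(taxa, names(fractions))
  if (length(missing))
    stop("unknown taxa: ", paste(missing, collapse = ", "))
  exact <- 100 * sum(fractions[taxa])
  list(percent = as.integer(round_half_up(exact)), percent_exact = exact)
}

#' Expected richness under subsampling
#'
#' Closed-form expectation of the number of taxa observed when `depth`
#' reads are drawn without replacement:
#' `E[S] = sum_t (1 - choose(N - n_t, depth) / choose(N, depth))`.
#'
#' @param counts Named non-negative integer vector for one sample.
#' @param depth Subsampling depth, at most `sum(counts)`.
#' @return Expected observed richness.
#' @export
expected_richness <- function(counts, depth) {
  n <- sum(counts)
  if (depth > n) stop("'depth' exceeds the sample total")
  p_missed <- exp(lchoose(n - counts, depth) - lchoose(n, depth))
  p_missed[counts > n - depth] <- 0
  sum(counts > 0) - sum(p_missed[counts > 0])
}

#' Subsampled (rarefied) richness
#'
#' Monte-Carlo rarefaction: draw `depth` reads without replacement
#' from the sample, count the taxa observed at least once, and repeat.
#' Sampling uses sequential hypergeometric draws, so large samples
#' never need to be expanded read-by-read.
#'
#' @param counts Named non-negative integer vector for one sample.
#' @param depth Subsampling depth (`<= sum(counts)`); a common choice
#'   is the smallest sample total in a study.
#' @param seed Integer seed.
#' @param reps Number of subsampling repetitions.
#' @return List with `mean`, `sd`, `reps`, `depth`, `richness` (the
#'   per-repetition values) and `expected` (the closed-form
#'   expectation, for reference).
#' @export
subsampled_richness <- function(counts, depth, seed = NULL, reps = 100) {
  if (any(counts < 0)) stop("counts must be non-negative")
  counts <- as.integer(counts)
  n <- sum(counts)
  depth <- as.integer(depth)
  if (depth < 1L) stop("'depth' must be >= 1")
  if (depth > n) stop("'depth' exceeds the sample total")
  maybe_seed(seed)
  nt <- length(counts)
  rich <- integer(reps)
  for (r in seq_len(reps)) {
    remaining <- n
    need <- depth
    s <- 0L
    for (t in seq_len(nt)) {
      if (need == 0L) break
      x <- rhyper(1L, counts[t], remaining - counts[t], need)
      if (x > 0L) s <- s + 1L
      need <- need - x
      remaining <- remaining - counts[t]
    }
    rich[r] <- s
  }
  list(mean = mean(rich), sd = sd(rich), reps = reps, depth = depth,
       richness = rich, expected = expected_richness(counts, depth))
}
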