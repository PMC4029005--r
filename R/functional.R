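#' Normalize functional-category hit counts
#'
#' Divides each sample's per-category hits by its total number of
#' hits, the standard normalization before comparing functional
#' profiles across metagenomes.
#'
#' @param counts Categories x samples matrix, or a named vector for a
#'   single sample.
#' @param total Optional explicit total to divide by (useful when the
#'   supplied categories are a subset of all hits); defaults to the
#'   column (or vector) sum.
#' @return Proportions with the same shape as `counts`.
#' @export
normalize_categories <- function(counts, total = NULL) {
  if (is.matrix(counts) || is.data.frame(counts)) {
    counts <- as.matrix(counts)
    if (any(counts < 0)) stop("counts must be non-negative")
    tot <- total %||% colSums(counts)
    if (any(tot <= 0)) stop("sample with zero total hits: proportions undefined")
    sweep(counts, 2L, tot, "/")
  } else {
    if (any(counts < 0)) stop("counts must be non-negative")
    tot <- total %||% sum(counts)
    if (tot <= 0) stop("sample with zero total hits: proportions undefined")
    counts / tot
  }
}

#' Percent view of category proportions
#'
#' Proportions times 100, rounded half-up to one decimal -- the
#' precision used in printed category tables.
#'
#' @param proportions Output of [normalize_categories()].
#' @return Percentages at one decimal.
#' @export
category_percent <- function(proportions) {
  round_half_up(100 * proportions, 1)
}

#' Total hits implied by printed (hits, percent) pairs
#'
#' Published category tables print raw hit counts next to percentages
#' of an unprinted total.  A single pair implies `hits / (percent/100)`
#' directly.  Several pairs over-determine the total because each
#' printed percent is rounded; in that case the midpoint of the
#' interval of totals consistent with every pair (each percent rounded
#' half-up to 1 decimal) is returned.
#'
#' @param hits Integer hit counts.
#' @param percents Printed percentages (1 decimal), same length.
#' @return The implied total (a single pair gives the exact ratio).
#' @export
implied_total <- function(hits, percents) {
  if (length(hits) != length(percents) || length(hits) == 0L)
    stop("'hits' and 'percents' must have equal positive length")
  if (length(hits) == 1L) return(100 * hits / percents)
  lo <- max(100 * hits / (percents + 0.05))
  hi <- min(100 * hits / (percents - 0.05))
  if (lo > hi)
    stop("no single total is consistent with all printed pairs")
  (lo + hi) / 2
}

#' PCA of functional profiles across samples
#'
#' Samples as rows, categories as columns: [pca_embed()] on the
#' normalized proportions (covariance PCA; the per-sample
#' normalization already puts categories on a common scale).
#'
#' @param proportions Categories x samples proportion matrix (as
#'   produced by [normalize_categories()]); it is transposed so that
#'   samples become rows.
#' @param scale. If `TRUE`, additionally z-score categories before the
#'   PCA (off by default).
#' @param ... Passed to [pca_embed()] (`n_components`, `var_target`).
#' @return A `pca_embedding` with per-sample coordinates.
#' @export
profile_pca <- function(proportions, scale. = FALSE, ...) {
  x <- t(as.matrix(proportions))
  if (nrow(x) < 3L) stop("need at least 3 samples for a profile PCA")
  if (scale.) {
    sdv <- apply(x, 2L, sd)
    sdv[sdv < 1e-12] <- 1
    x <- sweep(x, 2L, sdv, "/")
  }
  pca_embed(x, ...)
}

#' Nearest profile to a query sample
#'
#' Euclidean distance from the query to every other sample, in full
#' proportion space (or any coordinate matrix); ties broken by
#' lexicographic sample id.
#'
#' @param proportions Categories x samples proportion matrix, or a
#'   `pca_embedding` (distances then in the embedding).
#' @param query Sample id present in the input.
#' @return List with `nearest`, `distance`, and `ranking` (data frame
#'   of all other samples sorted by distance).
#' @export
nearest_profile <- function(proportions, query) {
  if (inherits(proportions, "pca_embedding")) {
    x <- proportions$coordinates
  } else {
    x <- t(as.matrix(proportions))
  }
  if (nrow(x) < 2L) stop("need at least 2 samples")
  if (!query %in% rownames(x)) stop("unknown sample: ", query)
  others <- setdiff(rownames(x), query)
  d <- sqrt(colSums((t(x[others, , drop = FALSE]) - x[query, ])^2))
  ord <- order(d, others)
  ranking <- data.frame(sample = others[ord], distance = unname(d[ord]),
                        stringsAsFactors = FALSE)
  list(nearest = ranking$sample[1L], distance = ranking$distance[1L],
       ranking = ranking)
}

#' Two-profile category comparison table
#'
#' Rebuilds the classic published comparison: per category, the hit
#' count and percentage of profile A next to the percentage of
#' profile B, with a Spearman rank correlation between the two percent
#' columns as a concordance statistic.
#'
#' @param hits_a Named integer hit counts for profile A.
#' @param percent_b Named percentages for profile B (only categories
#'   shared with A are used).
#' @param total_a Total hits behind profile A; defaults to
#'   `sum(hits_a)` (appropriate only when `hits_a` covers all
#'   categories).
#' @return List with `table` (category, hits_a, percent_a, percent_b)
#'   and `spearman`.
#' @export
compare_category_tables <- function(hits_a, percent_b, total_a = NULL) {
  shared <- intersect(names(hits_a), names(percent_b))
  if (length(shared) == 0L) stop("no shared categories")
  prop <- normalize_categories(hits_a[shared], total = total_a %||% sum(hits_a))
  tab <- data.frame(category = shared,
                    hits_a = as.integer(hits_a[shared]),
                    percent_a = category_percent(prop),
                    percent_b = unname(percent_b[shared]),
                    row.names = NULL, stringsAsFactors = FALSE)
  rho <- if (length(shared) > 1L)
    cor(tab$percent_a, tab$percent_b, method = "spearman") else NA_real_
  list(table = tab, spearman = rho)
}
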