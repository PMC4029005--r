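#' Specify a synthetic genome
#'
#' Describes one bacterial genome for the community simulator: an
#' order-`order` Markov chain over {A,C,G,T} whose conditional
#' distributions are constructed so that every context emits G+C with
#' probability exactly `gc`, while the split of that probability between
#' G and C (and of `1 - gc` between A and T) varies by context within
#' `0.5 +/- skew`.  The context-specific splits are drawn from the
#' generation seed, so genomes generated with different seeds carry
#' distinct higher-order compositional signatures even at equal GC --
#' the property composition-based binning relies on.
#'
#' @param name Taxon label for the genome.
#' @param length Genome length in bases.
#' @param gc Target GC fraction, strictly between 0 and 1.
#' @param order Markov order, an integer from 0 to 3.
#' @param skew Half-width of the context-dependent G-vs-C (and A-vs-T)
#'   split, in `[0, 0.5]`.  `0` reduces the model to independent draws
#'   at the target GC; larger values sharpen the genome's k-mer
#'   signature.
#' @param repeat_element `NULL`, or a list with elements `length`
#'   (bases, default 1000) and `copies` (non-negative integer): a single
#'   sequence pasted intact at `copies` random positions, emulating a
#'   shared insertion element.
#' @return An object of class `genome_spec`.
#' @seealso [generate_genome()], [community_spec()]
#' @export
genome_spec <- function(name, length, gc = 0.5, order = 2, skew = 0.3,
                        repeat_element = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  length <- as.integer(length)
  if (is.na(length) || length <= 0L)
    stop("genome 'length' must be a positive integer")
  if (!is.numeric(gc) || gc <= 0 || gc >= 1)
    stop("'gc' must lie strictly between 0 and 1")
  order <- as.integer(order)
  if (is.na(order) || order < 0L || order > 3L)
    stop("'order' must be an integer between 0 and 3")
  if (!is.numeric(skew) || skew < 0 || skew > 0.5)
    stop("'skew' must lie in [0, 0.5]")
  if (!is.null(repeat_element)) {
    repeat_element$length <- as.integer(repeat_element$length %||% 1000L)
    repeat_element$copies <- as.integer(repeat_element$copies %||% 0L)
    if (repeat_element$length <= 0L) stop("repeat element length must be positive")
    if (repeat_element$copies < 0L) stop("repeat element copy count must be >= 0")
    if (repeat_element$copies * repeat_element$length >= length)
      stop("repeat copies do not fit inside the genome length")
  }
  structure(list(name = name, length = length, gc = gc, order = order,
                 skew = skew, repeat_element = repeat_element),
            class = "genome_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("genome_spec '%s': %d bp, GC %.2f, Markov order %d, skew %.2f\n",
              x$name, x$length, x$gc, x$order, x$skew))
  if (!is.null(x$repeat_element))
    cat(sprintf("  repeat element: %d bp x %d copies\n",
                x$repeat_element$length, x$repeat_element$copies))
  invisible(x)
}

# Build the (4^order x 4) conditional probability matrix for a spec.
# Columns are A, C, G, T.  Every row has P(C)+P(G) = gc exactly, so the
# marginal GC of the chain equals the target irrespective of which
# contexts are visited.
markov_conditionals <- function(spec) {
  ncontext <- 4L^spec$order
  u_c <- runif(ncontext, 0.5 - spec$skew, 0.5 + spec$skew)
  u_a <- runif(ncontext, 0.5 - spec$skew, 0.5 + spec$skew)
  cbind(A = (1 - spec$gc) * u_a,
        C = spec$gc * u_c,
        G = spec$gc * (1 - u_c),
        T = (1 - spec$gc) * (1 - u_a))
}

#' Generate a genome sequence from a spec
#'
#' Samples an order-`order` Markov chain of the requested length, then
#' (if the spec has a repeat element) pastes the identical element
#' sequence at random positions so that the final length still equals
#' `spec$length`.
#'
#' @param spec A [genome_spec()].
#' @param seed Integer seed; the whole construction (context splits,
#'   chain, element and its positions) is a deterministic function of it.
#' @return A single character string of `spec$length` bases over ACGT.
#' @export
generate_genome <- function(spec, seed) {
  if (!inherits(spec, "genome_spec")) stop("'spec' must be a genome_spec")
  maybe_seed(seed)
  bases <- c("A", "C", "G", "T")
  cond <- markov_conditionals(spec)
  init <- c((1 - spec$gc) / 2, spec$gc / 2, spec$gc / 2, (1 - spec$gc) / 2)

  copies <- if (is.null(spec$repeat_element)) 0L else spec$repeat_element$copies
  elen <- if (copies > 0L) spec$repeat_element$length else 0L
  base_len <- spec$length - copies * elen

  codes <- markov_sample_cpp(cond, spec$order, base_len, init, runif(base_len))
  if (copies > 0L) {
    el <- markov_sample_cpp(cond, spec$order, elen, init, runif(elen))
    cuts <- sort(sample.int(base_len + 1L, copies, replace = TRUE) - 1L)
    pieces <- character(2L * copies + 1L)
    prev <- 0L
    for (i in seq_len(copies)) {
      pieces[2L * i - 1L] <- paste(bases[codes[seq_len(cuts[i] - prev) + prev] + 1L],
                                   collapse = "")
      pieces[2L * i] <- paste(bases[el + 1L], collapse = "")
      prev <- cuts[i]
    }
    pieces[2L * copies + 1L] <-
      paste(bases[codes[seq_len(base_len - prev) + prev] + 1L], collapse = "")
    paste(pieces, collapse = "")
  } else {
    paste(bases[codes + 1L], collapse = "")
  }
}

#' Specify a synthetic community
#'
#' @param genomes List of [genome_spec()] objects with unique names.
#' @param abundances Non-negative relative abundances, one per genome,
#'   summing to 1 (tolerance `1e-6`).
#' @param n_contigs Number of contigs to draw.
#' @param median_contig_len Median of the log-normal contig length
#'   distribution, in bases.
#' @param contig_length_sdlog Log-scale standard deviation of contig
#'   lengths; the default gives the heavy right tail typical of
#'   assembly output.
#' @param min_contig_len Minimum contig length; shorter draws are
#'   rejected and redrawn (truncated log-normal).
#' @param label_fraction Fraction of contigs that receive an observed
#'   taxon label (emulating partial annotation).
#' @param label_error Probability that an observed label is replaced by
#'   a different (wrong) taxon.
#' @return An object of class `community_spec`.
#' @export
community_spec <- function(genomes, abundances = NULL, n_contigs = 2000,
                           median_contig_len = 2000,
                           contig_length_sdlog = 0.55,
                           min_contig_len = 500, label_fraction = 0.2,
                           label_error = 0) {
  if (!is.list(genomes) || length(genomes) == 0L ||
      !all(vapply(genomes, inherits, logical(1), "genome_spec")))
    stop("'genomes' must be a non-empty list of genome_spec objects")
  nm <- vapply(genomes, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("genome names must be unique")
  if (is.null(abundances)) abundances <- rep(1 / length(genomes), length(genomes))
  if (length(abundances) != length(genomes) || any(abundances < 0))
    stop("'abundances' must be non-negative, one per genome")
  if (abs(sum(abundances) - 1) > 1e-6)
    stop("'abundances' must sum to 1")
  min_contig_len <- as.integer(min_contig_len)
  if (min_contig_len < 1L) stop("'min_contig_len' must be >= 1")
  if (label_fraction < 0 || label_fraction > 1)
    stop("'label_fraction' must lie in [0, 1]")
  if (label_error < 0 || label_error > 1)
    stop("'label_error' must lie in [0, 1]")
  structure(list(genomes = genomes, abundances = abundances,
                 n_contigs = as.integer(n_contigs),
                 median_contig_len = median_contig_len,
                 contig_length_sdlog = contig_length_sdlog,
                 min_contig_len = min_contig_len,
                 label_fraction = label_fraction,
                 label_error = label_error),
            class = "community_spec")
}

#' @export
print.community_spec <- function(x, ...) {
  cat(sprintf("community_spec: %d genomes, %d contigs, min length %d bp\n",
              length(x$genomes), x$n_contigs, x$min_contig_len))
  cat(sprintf("  label fraction %.2f, label error %.2f\n",
              x$label_fraction, x$label_error))
  invisible(x)
}

#' Simulate an assembled community
#'
#' Generates one genome per spec, then draws contigs as random
#' substrings: the source genome of each contig is sampled with
#' probability proportional to abundance x genome length, the length
#' from a log-normal truncated at `min_contig_len`, the start position
#' uniformly.  A `label_fraction` subset of contigs receives an
#' observed taxon label (true taxon, corrupted with probability
#' `label_error`), standing in for partial homology-based annotation.
#'
#' @param cspec A [community_spec()].
#' @param seed Integer seed; the full dataset is a deterministic
#'   function of it.
#' @return An object of class `community_dataset` with elements
#'   `contigs` (a [Biostrings::DNAStringSet] with metadata columns
#'   `source` and `coverage`), `truth` and `labels` (data frames with
#'   columns `contig_id`, `taxon`), `genomes` (the generated sequences),
#'   and `manifest` (seed and spec echo).
#' @export
simulate_community <- function(cspec, seed) {
  if (!inherits(cspec, "community_spec")) stop("'cspec' must be a community_spec")
  ng <- length(cspec$genomes)
  glens <- vapply(cspec$genomes, `[[`, integer(1), "length")
  gnames <- vapply(cspec$genomes, `[[`, character(1), "name")

  genomes <- lapply(seq_len(ng), function(i)
    generate_genome(cspec$genomes[[i]], derive_seed(seed, i)))

  maybe_seed(derive_seed(seed, 1000L + ng))
  w <- cspec$abundances * glens
  src <- sample.int(ng, cspec$n_contigs, replace = TRUE, prob = w / sum(w))

  meanlog <- log(cspec$median_contig_len)
  lens <- integer(cspec$n_contigs)
  todo <- seq_len(cspec$n_contigs)
  while (length(todo)) {
    draw <- round(rlnorm(length(todo), meanlog, cspec$contig_length_sdlog))
    ok <- draw >= cspec$min_contig_len
    lens[todo[ok]] <- as.integer(draw[ok])
    todo <- todo[!ok]
  }
  lens <- pmin(lens, glens[src])

  starts <- floor(runif(cspec$n_contigs) * (glens[src] - lens + 1)) + 1L
  seqs <- substr(genomes[src], starts, starts + lens - 1L)
  ids <- sprintf("contig_%05d", seq_len(cspec$n_contigs))

  cov <- as.vector(tapply(lens, factor(src, levels = seq_len(ng)), sum)) / glens
  cov[is.na(cov)] <- 0

  contigs <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
  S4Vectors::mcols(contigs) <- S4Vectors::DataFrame(
    source = gnames[src], coverage = cov[src])

  truth <- data.frame(contig_id = ids, taxon = gnames[src],
                      stringsAsFactors = FALSE)
  nlab <- round(cspec$label_fraction * cspec$n_contigs)
  lab_idx <- sort(sample.int(cspec$n_contigs, nlab))
  lab_tax <- gnames[src[lab_idx]]
  if (cspec$label_error > 0 && nlab > 0 && ng > 1) {
    flip <- runif(nlab) < cspec$label_error
    if (any(flip)) {
      lab_tax[flip] <- vapply(lab_tax[flip], function(t)
        sample(setdiff(gnames, t), 1L), character(1))
    }
  }
  labels <- data.frame(contig_id = ids[lab_idx], taxon = lab_tax,
                       stringsAsFactors = FALSE)

  structure(list(contigs = contigs, truth = truth, labels = labels,
                 genomes = stats::setNames(genomes, gnames),
                 manifest = list(seed = seed, n_contigs = cspec$n_contigs,
                                 genome_names = gnames,
                                 genome_lengths = glens,
                                 abundances = cspec$abundances,
                                 min_contig_len = cspec$min_contig_len,
                                 label_fraction = cspec$label_fraction)),
            class = "community_dataset")
}

#' @export
print.community_dataset <- function(x, ...) {
  cat(sprintf("community_dataset: %d contigs from %d genomes (seed %s)\n",
              length(x$contigs), length(x$genomes),
              format(x$manifest$seed)))
  cat(sprintf("  total %.2f MB, %d labeled contigs\n",
              sum(Biostrings::width(x$contigs)) / 1e6, nrow(x$labels)))
  invisible(x)
}

#' Simulate per-sample amplicon counts
#'
#' Draws one multinomial per sample: taxon proportions `profiles[, s]`
#' at total depth `depths[s]`.  Row sums of the result equal the depths
#' exactly.
#'
#' @param profiles Numeric matrix, taxa x samples; each column must be a
#'   probability vector (non-negative, summing to 1).
#' @param depths Positive integer read totals, one per sample.
#' @param seed Integer seed.
#' @return Integer count matrix, taxa x samples.
#' @export
simulate_amplicon_counts <- function(profiles, depths, seed = NULL) {
  profiles <- as.matrix(profiles)
  if (any(profiles < 0)) stop("proportions must be non-negative")
  if (any(abs(colSums(profiles) - 1) > 1e-6))
    stop("each sample's proportions must sum to 1")
  if (length(depths) != ncol(profiles))
    stop("'depths' must have one entry per sample")
  if (any(depths < 1)) stop("depths must be >= 1")
  maybe_seed(seed)
  counts <- vapply(seq_len(ncol(profiles)), function(s)
    rmultinom(1L, as.integer(depths[s]), profiles[, s])[, 1L],
    integer(nrow(profiles)))
  dimnames(counts) <- dimnames(profiles)
  counts
}

#' Simulate functional-category hit counts for one sample
#'
#' One multinomial draw over categories, emulating the per-category hit
#' totals of a database search summarized at category level.
#'
#' @param base Probability vector over categories (non-negative, sums
#'   to 1); names are carried to the result.
#' @param total_hits Positive integer total number of hits.
#' @param seed Integer seed.
#' @return Named integer vector of counts summing to `total_hits`.
#' @export
simulate_category_counts <- function(base, total_hits, seed = NULL) {
  if (any(base < 0)) stop("proportions must be non-negative")
  if (abs(sum(base) - 1) > 1e-6) stop("'base' must sum to 1")
  total_hits <- as.integer(total_hits)
  if (is.na(total_hits) || total_hits < 1) stop("'total_hits' must be >= 1")
  maybe_seed(seed)
  counts <- rmultinom(1L, total_hits, base)[, 1L]
  names(counts) <- names(base)
  counts
}
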