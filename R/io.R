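#' Read contigs from a FASTA file
#'
#' Ids are the header tokens up to the first whitespace; sequences are
#' uppercased.  Duplicate ids are an error.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by contig id.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(nm))
    stop("duplicate contig ids in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(x) <- nm
  Biostrings::DNAStringSet(toupper(x))
}

#' Write contigs to a FASTA file
#'
#' Sequence lines wrapped at 80 columns.
#'
#' @param contigs Named character vector or [Biostrings::DNAStringSet].
#' @param path Output path.
#' @export
write_fasta <- function(contigs, path) {
  Biostrings::writeXStringSet(as_dss(contigs), path, width = 80L)
  invisible(path)
}

#' Assembly summary statistics
#'
#' Contig count, total bases, mean length, N50 and maximum length
#' after a minimum-length filter.  N50 follows the dominant
#' convention: sort lengths descending; N50 is the first length at
#' which the cumulative sum reaches at least half the filtered total.
#'
#' @param contigs [Biostrings::DNAStringSet], named character vector,
#'   or a numeric vector of contig lengths.
#' @param min_len Minimum contig length included.
#' @return List with `count`, `total_bases`, `mean_length`, `n50`,
#'   `max_length`.
#' @export
assembly_stats <- function(contigs, min_len = 0) {
  lens <- if (is.numeric(contigs)) as.numeric(contigs)
          else as.numeric(Biostrings::width(as_dss(contigs)))
  lens <- lens[lens >= min_len]
  if (length(lens) == 0L) stop("no contigs of length >= min_len")
  sorted <- sort(lens, decreasing = TRUE)
  csum <- cumsum(sorted)
  n50 <- sorted[which(csum >= sum(sorted) / 2)[1L]]
  list(count = length(lens), total_bases = sum(lens),
       mean_length = mean(lens), n50 = n50, max_length = max(lens))
}

#' Write a tab-separated table
#'
#' Deterministic row order (sorted on the first column), no quoting,
#' with a header -- the on-disk exchange format for all package
#' tables.
#'
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  df <- df[order(df[[1L]]), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write a run manifest
#'
#' Flat `key: value` lines (YAML-style) recording the seed and the
#' parameters of a run, sufficient to reproduce its outputs.
#'
#' @param config Named list of scalar or vector values.
#' @param path Output path.
#' @export
write_manifest <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("%s: %s", k, paste(format(v, trim = TRUE), collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export a simulated community to plain-text files
#'
#' Writes `contigs.fasta`, `truth.tsv`, `labels.tsv` and
#' `manifest.txt` under `dir`.
#'
#' @param dataset A `community_dataset` from [simulate_community()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_community <- function(dataset, dir) {
  if (!inherits(dataset, "community_dataset"))
    stop("'dataset' must be a community_dataset")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(dataset$contigs, file.path(dir, "contigs.fasta"))
  write_tsv(dataset$truth, file.path(dir, "truth.tsv"))
  write_tsv(dataset$labels, file.path(dir, "labels.tsv"))
  write_manifest(dataset$manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}
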