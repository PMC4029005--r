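#' Label clusters from partial annotations
#'
#' Each cluster adopts the majority taxon among its annotated members,
#' provided that majority is strict: the top taxon's support (fraction
#' of the cluster's annotated members) must exceed `min_frac`, and no
#' other taxon may tie it.  Clusters failing either condition -- or
#' containing no annotated member -- become `"UNLABELED"`.
#'
#' @param ca A `cluster_assignment` from [kmeans_best_of()] or
#'   [esom_clusters()].
#' @param labels Data frame with columns `contig_id` and `taxon`, or a
#'   named character vector (names = contig ids).
#' @param min_frac Support threshold (strict); the default 0.5 demands
#'   an absolute majority, so a two-way tie is never labeled.
#' @return The `cluster_assignment` with added fields `taxon` (named
#'   per-contig taxon or `"UNLABELED"`) and `cluster_labels` (per
#'   cluster: taxon, support, number of annotated members).
#' @export
label_clusters <- function(ca, labels, min_frac = 0.5) {
  if (!inherits(ca, "cluster_assignment"))
    stop("'ca' must be a cluster_assignment")
  if (is.data.frame(labels)) {
    lab <- stats::setNames(as.character(labels$taxon),
                           as.character(labels$contig_id))
  } else {
    lab <- labels
  }
  if (length(lab) == 0L) {
    warning("empty label table: all clusters UNLABELED")
  }
  if (min_frac < 0 || min_frac >= 1) stop("'min_frac' must be in [0, 1)")

  ks <- sort(unique(ca$cluster))
  out <- data.frame(cluster = ks, taxon = "UNLABELED", support = NA_real_,
                    n_labeled = 0L, stringsAsFactors = FALSE)
  for (i in seq_along(ks)) {
    members <- names(ca$cluster)[ca$cluster == ks[i]]
    ml <- lab[intersect(members, names(lab))]
    out$n_labeled[i] <- length(ml)
    if (length(ml) == 0L) next
    tab <- sort(table(ml), decreasing = TRUE)
    support <- as.numeric(tab[1L]) / length(ml)
    out$support[i] <- support
    tied <- sum(tab == tab[1L]) > 1L
    if (!tied && support > min_frac) out$taxon[i] <- names(tab)[1L]
  }
  ca$taxon <- stats::setNames(
    out$taxon[match(ca$cluster, out$cluster)], names(ca$cluster))
  ca$cluster_labels <- out
  ca
}

#' Consensus of two labeled clusterings
#'
#' For each contig in both routes: if both routes assign the same
#' (non-UNLABELED) taxon, that taxon is kept; if they assign different
#' taxa, the contig is `"DISCARDED"` as ambiguous; if exactly one route
#' is UNLABELED, the labeled route's taxon is adopted and the contig is
#' flagged `single_route`; if neither route carries a label the contig
#' is `"UNBINNED"`.
#'
#' @param a,b Labeled `cluster_assignment` objects (see
#'   [label_clusters()]) over the same contig universe; the
#'   intersection is used and the complement reported.
#' @return An object of class `bin_assignment`: data frame
#'   `assignments` (contig_id, taxon, route_a, route_b, single_route),
#'   `provenance` (the two inputs), `not_shared` (ids outside the
#'   intersection).
#' @export
consensus_bins <- function(a, b) {
  for (x in list(a, b)) {
    if (!inherits(x, "cluster_assignment") || is.null(x$taxon))
      stop("inputs must be labeled cluster_assignments")
  }
  ids <- intersect(names(a$taxon), names(b$taxon))
  if (length(ids) == 0L) stop("empty consensus: disjoint contig sets")
  ta <- a$taxon[ids]; tb <- b$taxon[ids]
  ua <- ta == "UNLABELED"; ub <- tb == "UNLABELED"
  taxon <- ifelse(!ua & !ub, ifelse(ta == tb, ta, "DISCARDED"),
                  ifelse(ua & ub, "UNBINNED", ifelse(ua, tb, ta)))
  res <- data.frame(contig_id = ids, taxon = taxon, route_a = ta,
                    route_b = tb, single_route = xor(ua, ub),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(assignments = res,
                 provenance = list(a = a$method, b = b$method),
                 not_shared = setdiff(union(names(a$taxon), names(b$taxon)),
                                      ids)),
            class = "bin_assignment")
}

#' @export
print.bin_assignment <- function(x, ...) {
  tab <- table(x$assignments$taxon)
  cat(sprintf("bin_assignment: %d contigs (%s vs %s)\n",
              nrow(x$assignments), x$provenance$a, x$provenance$b))
  cat(sprintf("  %d binned, %d discarded, %d unbinned, %d single-route\n",
              sum(!x$assignments$taxon %in% c("DISCARDED", "UNBINNED")),
              sum(x$assignments$taxon == "DISCARDED"),
              sum(x$assignments$taxon == "UNBINNED"),
              sum(x$assignments$single_route)))
  invisible(x)
}

#' Agreement between two labeled clusterings
#'
#' The fraction of contigs carrying the identical (non-UNLABELED)
#' taxon in both routes, among contigs labeled in both.
#'
#' @param a,b Labeled `cluster_assignment` objects.
#' @return A fraction in `[0, 1]`.
#' @export
agreement_fraction <- function(a, b) {
  for (x in list(a, b)) {
    if (!inherits(x, "cluster_assignment") || is.null(x$taxon))
      stop("inputs must be labeled cluster_assignments")
  }
  ids <- intersect(names(a$taxon), names(b$taxon))
  ta <- a$taxon[ids]; tb <- b$taxon[ids]
  both <- ta != "UNLABELED" & tb != "UNLABELED"
  if (!any(both)) stop("no contig is labeled by both routes")
  mean(ta[both] == tb[both])
}

#' Summarize bins
#'
#' Per-taxon contig count, total bases (also in MB to 2 decimals) and
#' mean fold-coverage when coverage metadata is present.  DISCARDED and
#' UNBINNED rows are listed last.
#'
#' @param bins A `bin_assignment`.
#' @param contigs The contig set the bins refer to
#'   ([Biostrings::DNAStringSet], optionally with a `coverage` metadata
#'   column, or a named character vector).
#' @return Data frame with columns `taxon`, `n_contigs`, `bases`, `mb`,
#'   and `mean_coverage` (NA without metadata).
#' @export
bin_summary <- function(bins, contigs) {
  if (!inherits(bins, "bin_assignment")) stop("'bins' must be a bin_assignment")
  x <- as_dss(contigs)
  asg <- bins$assignments
  idx <- match(asg$contig_id, names(x))
  if (anyNA(idx)) stop("bins refer to contigs absent from 'contigs'")
  w <- as.numeric(Biostrings::width(x))[idx]
  cov <- rep(NA_real_, length(idx))
  mc <- tryCatch(S4Vectors::mcols(x), error = function(e) NULL)
  if (!is.null(mc) && "coverage" %in% colnames(mc))
    cov <- mc$coverage[idx]

  taxa <- sort(unique(asg$taxon))
  special <- c("DISCARDED", "UNBINNED")
  taxa <- c(setdiff(taxa, special), intersect(special, taxa))
  out <- do.call(rbind, lapply(taxa, function(t) {
    sel <- asg$taxon == t
    data.frame(taxon = t, n_contigs = sum(sel), bases = sum(w[sel]),
               mb = round(sum(w[sel]) / 1e6, 2),
               mean_coverage = if (all(is.na(cov[sel]))) NA_real_
                               else mean(cov[sel], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
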