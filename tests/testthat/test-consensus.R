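mk_ca <- function(cluster, method = "kmeans_pca") {
  structure(list(cluster = cluster, method = method, k = max(cluster),
                 score = 0), class = "cluster_assignment")
}

mk_labeled <- function(taxa) {
  ca <- mk_ca(stats::setNames(seq_along(taxa), names(taxa)))
  ca$taxon <- taxa
  ca
}

test_that("cluster labeling takes a strict majority and reports support", {
  ca <- mk_ca(c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 3))
  labels <- data.frame(contig_id = c("a", "b", "c", "d", "e"),
                       taxon = c("X", "X", "X", "X", "Y"))
  out <- label_clusters(ca, labels)
  expect_identical(unname(out$taxon[c("a", "d", "f")]),
                   c("X", "UNLABELED", "UNLABELED"))
  cl <- out$cluster_labels
  expect_equal(cl$support[cl$cluster == 1], 1.0)
  expect_identical(cl$taxon[cl$cluster == 2], "UNLABELED")  # 0.5 tie
  expect_identical(cl$n_labeled[cl$cluster == 3], 0L)

  # a non-strict minority threshold still refuses exact ties
  out2 <- label_clusters(ca, labels, min_frac = 0.3)
  expect_identical(unname(out2$taxon["d"]), "UNLABELED")

  expect_warning(label_clusters(ca, data.frame(contig_id = character(0),
                                               taxon = character(0))),
                 "empty label table")
})

test_that("consensus keeps agreements, discards conflicts, flags single routes", {
  a <- mk_labeled(c(c1 = "X", c2 = "X", c3 = "X", c4 = "UNLABELED"))
  b <- mk_labeled(c(c1 = "X", c2 = "Y", c3 = "UNLABELED",
                    c4 = "UNLABELED"))
  bins <- consensus_bins(a, b)
  asg <- bins$assignments
  expect_identical(asg$taxon[match(c("c1", "c2", "c3", "c4"), asg$contig_id)],
                   c("X", "DISCARDED", "X", "UNBINNED"))
  expect_identical(asg$single_route[asg$contig_id == "c3"], TRUE)
  expect_identical(asg$single_route[asg$contig_id == "c1"], FALSE)

  # discarded count equals disagreement count; no invented taxa
  expect_identical(sum(asg$taxon == "DISCARDED"),
                   sum(a$taxon != "UNLABELED" & b$taxon != "UNLABELED" &
                         a$taxon != b$taxon))
  expect_true(all(setdiff(asg$taxon, c("DISCARDED", "UNBINNED")) %in%
                    union(a$taxon, b$taxon)))

  expect_error(consensus_bins(mk_labeled(c(z1 = "X")),
                              mk_labeled(c(z2 = "X"))), "disjoint")
})

test_that("consensus taxa never fall outside the two routes' labels", {
  set.seed(13)
  taxa_pool <- c("X", "Y", "Z", "UNLABELED")
  for (i in 1:20) {
    ids <- paste0("c", 1:30)
    a <- mk_labeled(stats::setNames(sample(taxa_pool, 30, TRUE), ids))
    b <- mk_labeled(stats::setNames(sample(taxa_pool, 30, TRUE), ids))
    asg <- consensus_bins(a, b)$assignments
    real <- !asg$taxon %in% c("DISCARDED", "UNBINNED")
    expect_true(all(asg$taxon[real] %in% c(a$taxon, b$taxon)))
    expect_identical(sum(asg$taxon == "DISCARDED"),
                     sum(a$taxon != "UNLABELED" & b$taxon != "UNLABELED" &
                           a$taxon != b$taxon))
  }
})

test_that("agreement fraction counts mutually labeled contigs only", {
  a <- mk_labeled(c(c1 = "X", c2 = "X", c3 = "Y", c4 = "Y"))
  b <- mk_labeled(c(c1 = "X", c2 = "X", c3 = "Y", c4 = "Z"))
  expect_equal(agreement_fraction(a, b), 0.75)
  expect_equal(agreement_fraction(a, a), 1.0)

  b2 <- mk_labeled(c(c1 = "UNLABELED", c2 = "X", c3 = "Y", c4 = "Z"))
  expect_equal(agreement_fraction(a, b2), 2 / 3)

  allun <- mk_labeled(c(c1 = "UNLABELED", c2 = "UNLABELED",
                        c3 = "UNLABELED", c4 = "UNLABELED"))
  expect_error(agreement_fraction(a, allun), "no contig")
})

test_that("bin summary bookkeeping adds up", {
  contigs <- Biostrings::DNAStringSet(c(
    c1 = strrep("A", 1000), c2 = strrep("C", 2000), c3 = strrep("G", 500)))
  a <- mk_labeled(c(c1 = "X", c2 = "X", c3 = "Y"))
  b <- mk_labeled(c(c1 = "X", c2 = "X", c3 = "Z"))
  bins <- consensus_bins(a, b)
  sm <- bin_summary(bins, contigs)
  expect_identical(sm$bases[sm$taxon == "X"], 3000)
  expect_identical(sm$mb[sm$taxon == "X"], 0.00)
  expect_identical(sm$n_contigs[sm$taxon == "DISCARDED"], 1L)
  expect_identical(sum(sm$n_contigs), nrow(bins$assignments))

  # all-discarded edge
  b3 <- mk_labeled(c(c1 = "Q", c2 = "Q", c3 = "Q"))
  sm2 <- bin_summary(consensus_bins(a, b3), contigs)
  expect_identical(sm2$taxon, "DISCARDED")
})
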