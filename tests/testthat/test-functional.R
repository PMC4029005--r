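test_that("category normalization is a per-sample proportion", {
  expect_equal(unname(normalize_categories(c(c1 = 96, c2 = 96))),
               c(0.5, 0.5))
  counts <- cbind(s1 = c(a = 10, b = 30), s2 = c(a = 2, b = 2))
  pr <- normalize_categories(counts)
  expect_equal(unname(pr[, "s1"]), c(0.25, 0.75))
  expect_error(normalize_categories(c(a = 0, b = 0)), "zero total")

  # scale invariance
  v <- c(a = 3, b = 7, c = 11)
  expect_equal(normalize_categories(v * 17), normalize_categories(v))
})

test_that("implied totals reconstruct printed percent columns", {
  # single anchor: plain ratio
  expect_equal(implied_total(96, 5.1), 9600 / 5.1)

  # several printed pairs constrain the total to a feasible interval
  hits <- c(96, 112, 149, 46, 92, 44, 87, 17)
  pct <- c(5.1, 6.0, 7.9, 2.5, 4.9, 2.3, 4.6, 0.9)
  total <- implied_total(hits, pct)
  expect_equal(category_percent(normalize_categories(
    stats::setNames(hits, paste0("c", 1:8)), total = total)),
    stats::setNames(pct, paste0("c", 1:8)))

  expect_error(implied_total(c(10, 10), c(1, 2)), "consistent")
})

test_that("profile PCA separates two simulated community classes", {
  # identical samples coincide
  pr <- cbind(s1 = c(0.2, 0.8), s2 = c(0.2, 0.8), s3 = c(0.7, 0.3))
  rownames(pr) <- c("a", "b")
  emb <- pca_embed(t(pr))
  expect_equal(emb$coordinates["s1", ], emb$coordinates["s2", ])

  # gut-like vs environment-like base profiles, multinomial noise
  set.seed(31)
  ncat <- 20
  gut <- normalize_categories(stats::setNames(rgamma(ncat, 2), paste0("c", 1:ncat)))
  env <- normalize_categories(stats::setNames(rgamma(ncat, 2), paste0("c", 1:ncat)))
  counts <- sapply(1:10, function(i)
    simulate_category_counts(if (i <= 5) gut else env, 5000, seed = 100 + i))
  colnames(counts) <- c(paste0("gut", 1:5), paste0("env", 1:5))
  emb2 <- profile_pca(normalize_categories(counts))
  cls <- rep(c(1, 0), each = 5)
  r <- cor(emb2$coordinates[, 1], cls)
  expect_gt(abs(r), 0.9)

  # coordinates invariant (up to sign) under category reordering
  perm <- sample(ncat)
  emb3 <- profile_pca(normalize_categories(counts[perm, ]))
  agree <- vapply(1:2, function(j)
    max(abs(cor(emb2$coordinates[, j], emb3$coordinates[, j]))), numeric(1))
  expect_true(all(agree > 1 - 1e-6))

  expect_error(profile_pca(pr[, 1:2]), "at least 3 samples")
})

test_that("nearest profile ranks by distance with deterministic ties", {
  pr <- cbind(s1 = c(0.2, 0.8), s2 = c(0.2, 0.8), s3 = c(0.7, 0.3))
  rownames(pr) <- c("a", "b")
  np <- nearest_profile(pr, "s1")
  expect_identical(np$nearest, "s2")
  expect_equal(np$distance, 0)
  expect_false("s1" %in% np$ranking$sample)  # self excluded
  expect_error(nearest_profile(pr, "s9"), "unknown sample")
})

test_that("simulated gut samples stay nearest to gut samples", {
  ncat <- 25
  ok <- vapply(1:10, function(s) {
    set.seed(500 + s)
    gut <- normalize_categories(stats::setNames(rgamma(ncat, 2), paste0("c", 1:ncat)))
    env <- normalize_categories(stats::setNames(rgamma(ncat, 2), paste0("c", 1:ncat)))
    counts <- sapply(1:10, function(i)
      simulate_category_counts(if (i <= 5) gut else env, 4000))
    colnames(counts) <- c(paste0("gut", 1:5), paste0("env", 1:5))
    pr <- normalize_categories(counts)
    all(vapply(paste0("gut", 1:5), function(q)
      startsWith(nearest_profile(pr, q)$nearest, "gut"), logical(1)))
  }, logical(1))
  expect_gte(sum(ok), 9L)
})

test_that("category comparison tables report Spearman concordance", {
  a <- c(x = 10, y = 20, z = 30)
  identical_b <- c(x = 100 / 6, y = 200 / 6, z = 300 / 6)
  cmp <- compare_category_tables(a, identical_b)
  expect_equal(cmp$spearman, 1)

  reversed <- c(x = 30, y = 20, z = 10)
  cmp2 <- compare_category_tables(a, normalize_categories(reversed) * 100)
  expect_equal(cmp2$spearman, -1)

  # printed two-column table: hand-computed rank correlation as oracle
  pa <- c(5.1, 6.0, 7.9, 2.5, 4.9, 2.3, 4.6, 0.9)
  pb <- c(4.8, 9.8, 6.5, 2.2, 3.3, 2.2, 6.2, 0.9)
  names(pa) <- names(pb) <- paste0("c", 1:8)
  hits <- stats::setNames(c(96, 112, 149, 46, 92, 44, 87, 17), names(pa))
  cmp3 <- compare_category_tables(hits, pb,
                                  total_a = implied_total(hits, pa))
  ra <- rank(cmp3$table$percent_a); rb <- rank(cmp3$table$percent_b)
  hand_rho <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  expect_equal(cmp3$spearman, hand_rho, tolerance = 1e-12)

  expect_error(compare_category_tables(c(q = 1), c(w = 1)), "shared")
})
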