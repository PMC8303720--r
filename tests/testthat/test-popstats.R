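test_that("both allele-frequency estimators match hand computation", {
  expect_equal(allele_frequency(9, 9, 41), 27 / 82)
  expect_equal(allele_frequency(9, 9, 41, mode = "printed"), 27 / 82)
  expect_equal(allele_frequency(8, 6, 41, mode = "printed"), 22 / 82)
  expect_equal(allele_frequency(8, 6, 41, mode = "standard"), 20 / 82)
  expect_equal(allele_frequency(14, 6, 41), 26 / 82)
  expect_equal(allele_frequency(0, 0, 41), 0)
  expect_equal(allele_frequency(0, 41, 41), 1)
  expect_error(allele_frequency(30, 30, 41),
               class = "cryscreen_consistency_error")
  expect_error(allele_frequency(1, 1, 0),
               class = "cryscreen_parameter_error")
  # scale invariance
  for (k in c(2, 5, 10))
    expect_equal(allele_frequency(8 * k, 6 * k, 41 * k, "printed"),
                 allele_frequency(8, 6, 41, "printed"))
})

test_that("frequency formatting truncates or rounds at 4 decimals", {
  expect_equal(format_frequency(27 / 82, mode = "truncate"), 0.3292)
  expect_equal(format_frequency(27 / 82, mode = "round"), 0.3293)
  expect_equal(format_frequency(22 / 82, mode = "round"), 0.2683)
  expect_equal(format_frequency(26 / 82, mode = "truncate"), 0.3170)
})

test_that("concordance counts agreements and lists discrepancies", {
  a <- c(s1 = "SS", s2 = "Sr", s3 = "rr")
  cc <- concordance(a, a)
  expect_equal(cc$rate, 1)
  expect_equal(nrow(cc$discrepancies), 0L)
  b <- c(s1 = "Sr", s2 = "rr", s3 = "SS")
  expect_equal(concordance(a, b)$rate, 0)
  # symmetric
  cc_ab <- concordance(a, b); cc_ba <- concordance(b, a)
  expect_equal(cc_ab$n_concordant, cc_ba$n_concordant)
  # alignment by name, error on disjoint ids
  expect_equal(concordance(a, b[c(2, 1, 3)])$rate, 0)
  expect_error(concordance(a, c(x = "SS", y = "SS", z = "SS")),
               class = "cryscreen_alignment_error")
  expect_error(concordance(a, a[1:2]),
               class = "cryscreen_alignment_error")
})

test_that("per-location carrier summaries handle degenerate tables", {
  tab <- data.frame(sample_id = sprintf("s%d", 1:4), location = "only",
                    method = "m", call = "SS")
  cs <- carrier_summary(tab, "m")
  expect_equal(cs$pct_carriers, 0L)
  expect_equal(cs$pct_hom, 0L)
  expect_equal(cs$pct_het, 0L)
  expect_error(carrier_summary(tab, "nope"),
               class = "cryscreen_lookup_error")
  expect_error(carrier_summary(tab[0, ], "m"),
               class = "cryscreen_parameter_error")
})

test_that("genotype PCA separates planted clusters and orders variance", {
  # two clusters of identical rows: PC1 separates, within-cluster 0
  mat <- rbind(matrix(rep(c(0, 0, 2, 2, 0), 5), 5, byrow = TRUE),
               matrix(rep(c(2, 2, 0, 0, 2), 5), 5, byrow = TRUE))
  p <- genotype_pca(mat)
  expect_equal(sd(p$projections[1:5, 1]), 0)
  expect_equal(sd(p$projections[6:10, 1]), 0)
  expect_gt(abs(mean(p$projections[1:5, 1]) -
                  mean(p$projections[6:10, 1])), 1)
  expect_equal(p$explained[1], 1)

  set.seed(21)
  m2 <- matrix(sample(0:2, 20 * 50, replace = TRUE), 20, 50)
  p2 <- genotype_pca(m2)
  expect_true(all(diff(p2$explained) <= 1e-12))
  expect_lte(sum(p2$explained), 1 + 1e-9)
  # row permutation gives the same projections up to order and sign
  perm <- sample(20)
  p3 <- genotype_pca(m2[perm, ])
  for (k in 1:3) {
    a <- p2$projections[perm, k]; b <- p3$projections[, k]
    expect_true(max(abs(a - b)) < 1e-8 || max(abs(a + b)) < 1e-8)
  }
  # adding a constant to a column changes nothing (centring)
  m4 <- m2; m4[, 1] <- m4[, 1] + 7
  p4 <- genotype_pca(m4)
  expect_equal(abs(p4$projections[, 1]), abs(p2$projections[, 1]),
               tolerance = 1e-8)
  # degenerate matrix
  expect_error(genotype_pca(matrix(1, 4, 3)),
               class = "cryscreen_degenerate_error")
})

test_that("PCA mean imputation reproduces explicit imputation", {
  set.seed(31)
  m <- matrix(sample(0:2, 15 * 8, replace = TRUE), 15, 8)
  m_na <- m
  m_na[sample(length(m), 12)] <- NA
  imp <- m_na
  for (j in seq_len(ncol(imp))) {
    miss <- is.na(imp[, j])
    imp[miss, j] <- mean(imp[, j], na.rm = TRUE)
  }
  expect_equal(genotype_pca(m_na)$projections,
               genotype_pca(imp)$projections)
})

test_that("association scan matches the hypergeometric tail oracle", {
  # perfectly separating site, 20 per class
  g <- matrix(c(rep(2, 20), rep(0, 20)), ncol = 1)
  labs <- rep(c("a", "b"), each = 20)
  res <- association_scan(g, labs)
  expect_lt(res$p_value, 1e-5)
  # identical allele counts in both classes -> p = 1
  g2 <- matrix(rep(c(0, 1), 20), ncol = 1)
  expect_equal(association_scan(g2, labs)$p_value, 1)
  # oracle: Fisher p for a 2x2 equals sum of hypergeometric tails
  tab <- matrix(c(30, 10, 12, 28), 2)
  expect_equal(fisher.test(tab)$p.value, {
    # enumerate all tables with the same margins
    m <- sum(tab[, 1]); n <- sum(tab[, 2]); k <- sum(tab[1, ])
    x <- tab[1, 1]
    probs <- dhyper(0:k, m, n, k)
    sum(probs[probs <= dhyper(x, m, n, k) * (1 + 1e-7)])
  })
  expect_error(association_scan(g, rep("a", 40)),
               class = "cryscreen_parameter_error")
})

test_that("association scan holds its type-I error under permutation", {
  set.seed(99)
  n <- 40; labs <- rep(c("a", "b"), each = n / 2)
  g <- matrix(sample(0:2, n, replace = TRUE), ncol = 1)
  n_perm <- 1000
  p <- numeric(n_perm)
  for (i in seq_len(n_perm))
    p[i] <- association_scan(g, sample(labs))$p_value
  # Fisher's exact test is conservative: rejections at 0.05 should not
  # exceed nominal by more than 3 binomial SE
  rej <- mean(p < 0.05)
  expect_lt(rej, 0.05 + 3 * sqrt(0.05 * 0.95 / n_perm))
})

test_that("cohort tables assemble from wide data and fixtures", {
  t1 <- load_fixture("table1")
  tab <- cohort_table(t1)
  expect_equal(nrow(tab), 82L)
  expect_setequal(unique(tab$method), c("taqman", "kmer"))
  cs <- carrier_summary(tab, "taqman")
  expect_equal(cs$n[cs$location == "Lajas"], 15L)
})
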