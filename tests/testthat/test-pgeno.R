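make_site <- function() {
  insertion_site("s", "ACGTACGTAC", "TTGGCCAATT", "GC")
}

test_that("scan_read detects mutant, wild-type and uninformative layouts", {
  site <- make_site()
  mut <- paste0(site$left_flank, "GC", site$right_flank)
  wt <- paste0(site$left_flank, site$right_flank)
  expect_equal(scan_read(mut, site), "MUT")
  expect_equal(scan_read(wt, site), "WT")
  expect_equal(scan_read(paste0("TTTT", mut, "AAAA"), site), "MUT")
  expect_equal(scan_read(revcomp(mut), site), "MUT")
  expect_equal(scan_read(revcomp(mut), site, scan_revcomp = FALSE),
               "UNINFORMATIVE")
  # two mismatches in the left flank still match
  wt2 <- wt
  substr(wt2, 1, 1) <- "T"; substr(wt2, 3, 3) <- "T"
  expect_equal(scan_read(wt2, site), "WT")
  # three mismatches do not
  wt3 <- wt2
  substr(wt3, 5, 5) <- "G"
  expect_equal(scan_read(wt3, site), "UNINFORMATIVE")
  # inserted bases must match exactly
  near_mut <- paste0(site$left_flank, "GT", site$right_flank)
  expect_false(scan_read(near_mut, site) == "MUT")
  # N never matches
  wtn <- wt
  substr(wtn, 1, 3) <- "NNN"
  expect_equal(scan_read(wtn, site), "UNINFORMATIVE")
  expect_error(scan_read("", site), class = "cryscreen_parameter_error")
})

test_that("site definitions are validated and round-trip through TSV", {
  expect_error(insertion_site("s", "ACGT", "TTGGCCAATT", "GC"),
               class = "cryscreen_parameter_error")
  expect_error(insertion_site("s", "ACGTACGTAC", "TTGGCCAATT", ""),
               class = "cryscreen_parameter_error")
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("site_id\tleft_flank\tinserted\tright_flank\tmax_mm",
               "s1\tACGTACGTAC\tGC\tTTGGCCAATT\t2"), tsv)
  sites <- read_insertion_sites(tsv)
  expect_equal(sites$s1$left_flank, "ACGTACGTAC")
  expect_equal(sites$s1$max_mismatch_per_flank, 2L)
})

test_that("scanner agrees with the brute-force Hamming oracle", {
  set.seed(101)
  site <- make_site()
  # random reads plus planted layouts with random corruption
  n <- 2000
  reads <- random_dna(n, sample(20:40, n, replace = TRUE))
  planted <- vapply(seq_len(n), function(i) {
    core <- if (i %% 3 == 0) paste0(site$left_flank, "GC", site$right_flank)
            else paste0(site$left_flank, site$right_flank)
    s <- paste0(substr(reads[i], 1, 5), core)
    k <- sample(0:4, 1)
    if (k > 0) {
      v <- strsplit(s, "")[[1]]
      at <- sample(length(v), k)
      v[at] <- sample(c("A", "C", "G", "T", "N"), k, replace = TRUE)
      s <- paste(v, collapse = "")
    }
    if (i %% 2 == 0) s <- revcomp(s)
    s
  }, character(1))
  all_reads <- c(reads, planted)
  expect_equal(scan_read(all_reads, site), oracle_scan(all_reads, site))
})

test_that("genotype calls follow the coverage and proportion thresholds", {
  site <- make_site()
  mut <- paste0(site$left_flank, "GC", site$right_flank)
  wt <- paste0(site$left_flank, site$right_flank)
  mk <- function(n_mut, n_wt) c(rep(mut, n_mut), rep(wt, n_wt))

  expect_equal(genotype_site(mk(0, 100), site)$call, "SS")
  expect_equal(genotype_site(mk(0, 39), site)$call, "NoCall")
  expect_equal(genotype_site(mk(50, 50), site)$call, "Sr")
  expect_equal(genotype_site(mk(10, 90), site)$call, "SS")
  # boundary semantics: exactly 15% is SS, exactly 85% is rr
  expect_equal(genotype_site(mk(15, 85), site)$call, "SS")
  expect_equal(genotype_site(mk(85, 15), site)$call, "rr")
  expect_equal(genotype_site(mk(16, 84), site)$call, "Sr")
  g <- genotype_site(character(), site)
  expect_equal(g$call, "NoCall")
  expect_equal(g$coverage, 0L)
  expect_error(genotype_site(mk(1, 1), site, carrier_min_proportion = 0.9,
                             hom_min_proportion = 0.8),
               class = "cryscreen_parameter_error")
})

test_that("calls are permutation invariant and conserve informative reads", {
  set.seed(55)
  site <- make_site()
  mut <- paste0(site$left_flank, "GC", site$right_flank)
  wt <- paste0(site$left_flank, site$right_flank)
  reads <- c(rep(mut, 30), rep(wt, 40), random_dna(30, 30))
  g1 <- genotype_site(reads, site)
  g2 <- genotype_site(sample(reads), site)
  expect_equal(g1$call, g2$call)
  expect_equal(g1$n_wt + g1$n_mut, g1$coverage)
  expect_equal(g1$coverage,
               sum(scan_read(reads, site) != "UNINFORMATIVE"))
  # raising min_coverage can only turn calls into NoCall
  for (mc in c(10, 40, 71, 200)) {
    g <- genotype_site(reads, site, min_coverage = mc)
    if (g$call != "NoCall") expect_equal(g$call, g1$call)
  }
  expect_equal(genotype_site(reads, site, min_coverage = 71)$call,
               "NoCall")
})

test_that("cohort genotyping recovers simulated truths and flags failures", {
  m <- example_gene_model()
  sites <- default_sites(m)
  dir <- file.path(tempdir(), "pgeno_cohort")
  fx <- make_cohort_fixture(m, sites, n_samples = 12, mean_depth = 200,
                            error_rate = 0, seed = 77L, dir = dir)
  site <- site_from_model(m, sites$pos[sites$site_id == "mut_ins"], "GC",
                          site_id = "mut_ins")
  calls <- genotype_cohort(fx$files, site)
  expect_equal(nrow(calls), 12)
  expect_equal(calls$call, unname(fx$truth$mut_ins[
    match(calls$sample_id, fx$truth$sample_id)]))
  s <- attr(calls, "summary")
  expect_equal(sum(s[c("n_SS", "n_Sr", "n_rr", "n_NoCall")]), 12)
  # unreadable FASTQ -> per-sample error, excluded from summary
  bad <- fx$files
  bad["broken"] <- file.path(dir, "no_such_file.fastq")
  calls2 <- genotype_cohort(bad, site)
  expect_true(any(!is.na(calls2$error)))
  expect_equal(attr(calls2, "summary")[["n_failed"]], 1L)
  unlink(dir, recursive = TRUE)
})

test_that("a low-coverage sample gets NoCall in a cohort", {
  m <- example_gene_model()
  sites <- default_sites(m)
  site <- site_from_model(m, sites$pos[1], "GC", site_id = "mut_ins")
  spec <- sample_spec("low1", seed = 12L)
  d <- design_tiles(nchar(m$sequence))
  sim <- simulate_sample_reads(m, spec, d, mean_depth = 1,
                               error_rate = 0)
  calls <- genotype_read_sets(list(low1 = sim$reads), site)
  expect_equal(calls$call, "NoCall")
})
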