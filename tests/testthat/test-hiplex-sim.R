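test_that("tile designs cover the region with the required overlap", {
  d <- design_tiles(460, 180, 50)
  expect_equal(d$tiles,
               data.frame(start = c(1L, 131L, 261L, 281L),
                          end = c(180L, 310L, 440L, 460L)))
  expect_equal(design_tiles(150, 180)$tiles,
               data.frame(start = 1L, end = 150L))
  expect_error(design_tiles(500, 180, 180),
               class = "cryscreen_parameter_error")

  # brute-force coverage/overlap check across many geometries
  set.seed(7)
  for (i in 1:25) {
    rl <- sample(100:3000, 1)
    al <- sample(180:200, 1)
    d <- design_tiles(rl, al, 50)
    covered <- logical(rl)
    for (t in seq_len(nrow(d$tiles)))
      covered[d$tiles$start[t]:d$tiles$end[t]] <- TRUE
    expect_true(all(covered))
    if (nrow(d$tiles) > 1) {
      ov <- d$tiles$end[-nrow(d$tiles)] - d$tiles$start[-1] + 1L
      expect_true(all(ov >= 50))
      expect_true(all(d$tiles$end - d$tiles$start + 1L <= al))
    }
  }
})

test_that("error-free reads from a reference sample are gene substrings", {
  m <- example_gene_model()
  spec <- sample_spec("ref1", seed = 3L)
  d <- design_tiles(nchar(m$sequence))
  sim <- simulate_sample_reads(m, spec, d, mean_depth = 20,
                               error_rate = 0)
  expect_gt(nrow(sim$reads), 0)
  expect_true(all(vapply(sim$reads$seq, grepl, logical(1),
                         x = m$sequence, fixed = TRUE)))
  expect_equal(nrow(sim$truth), 0)
})

test_that("heterozygous insertion appears in about half the reads", {
  m <- example_gene_model()
  sites <- default_sites(m)
  ins <- sites[sites$site_id == "mut_ins", ]
  spec <- sample_spec("het1", hap1 = ins[, c("pos", "ref", "alt")],
                      seed = 11L)
  # single tile over the insertion so every read covers the site
  d <- design_tiles(nchar(m$sequence))
  covering <- d$tiles$start <= ins$pos - 10 & d$tiles$end >= ins$pos + 12
  d$tiles <- d$tiles[which(covering)[1], , drop = FALSE]
  sim <- simulate_sample_reads(m, spec, d, mean_depth = 1000,
                               error_rate = 0)
  site <- site_from_model(m, ins$pos, "GC", site_id = "mut_ins")
  status <- scan_read(sim$reads$seq, site)
  n_inf <- sum(status != "UNINFORMATIVE")
  frac <- sum(status == "MUT") / n_inf
  # binomial oracle: 3 SD around 0.5
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n_inf))
  expect_equal(sim$truth$genotype, "Sr")
})

test_that("simulation is reproducible and FASTQ output is byte-stable", {
  m <- example_gene_model()
  spec <- sample_spec("s1", hap1 = default_sites(m)[1, c("pos", "ref", "alt")],
                      seed = 5L)
  d <- design_tiles(nchar(m$sequence))
  s1 <- simulate_sample_reads(m, spec, d, mean_depth = 30)
  s2 <- simulate_sample_reads(m, spec, d, mean_depth = 30)
  expect_identical(s1, s2)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(s1$reads, f1); write_fastq(s2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
  # round trip
  back <- read_fastq(f1)
  expect_equal(back$seq, s1$reads$seq)
})

test_that("read counts per tile track efficiency multipliers", {
  m <- example_gene_model()
  d <- design_tiles(nchar(m$sequence))
  eff <- rep(c(0.5, 1, 2), length.out = nrow(d$tiles))
  spec <- sample_spec("eff1", efficiency = eff, seed = 21L)
  sim <- simulate_sample_reads(m, spec, d, mean_depth = 1000,
                               error_rate = 0)
  # assign reads back to tiles by length+content
  tile_seq <- vapply(seq_len(nrow(d$tiles)), function(t)
    substr(m$sequence, d$tiles$start[t], d$tiles$end[t]), character(1))
  counts <- vapply(tile_seq, function(s) sum(sim$reads$seq == s),
                   numeric(1))
  expected <- 1000 * eff
  chi <- suppressWarnings(
    stats::chisq.test(counts, p = expected / sum(expected)))
  expect_gt(chi$p.value, 1e-4)
})

test_that("substitution error rate is recovered from mismatch counts", {
  m <- example_gene_model()
  d <- design_tiles(nchar(m$sequence))
  spec <- sample_spec("err1", seed = 31L)
  e <- 0.01
  sim <- simulate_sample_reads(m, spec, d, mean_depth = 200,
                               error_rate = e)
  # compare each read to the reference tile of the same length/start
  tile_seq <- vapply(seq_len(nrow(d$tiles)), function(t)
    substr(m$sequence, d$tiles$start[t], d$tiles$end[t]), character(1))
  total_mm <- 0; total_bases <- 0
  for (r in sim$reads$seq) {
    ref <- tile_seq[nchar(tile_seq) == nchar(r)][1]
    # match by best tile (identical length tiles share amp_len; compare all)
    cands <- tile_seq[nchar(tile_seq) == nchar(r)]
    mm <- min(vapply(cands, function(s)
      sum(strsplit(r, "")[[1]] != strsplit(s, "")[[1]]), numeric(1)))
    total_mm <- total_mm + mm
    total_bases <- total_bases + nchar(r)
  }
  obs <- total_mm / total_bases
  expect_lt(abs(obs - e), 3 * sqrt(e * (1 - e) / total_bases))
})

test_that("cohort fixtures recover the input allele frequencies", {
  m <- example_gene_model()
  sites <- default_sites(m)
  sites$freq <- c(0.33, 0.32)
  fx <- make_cohort_fixture(m, sites, n_samples = 200, mean_depth = 1,
                            error_rate = 0, seed = 9L)
  expect_equal(nrow(fx$truth), 200)
  for (s in sites$site_id) {
    g <- fx$truth[[s]]
    f_hat <- (2 * sum(g == "rr") + sum(g == "Sr")) / (2 * length(g))
    f <- sites$freq[sites$site_id == s]
    se <- sqrt(f * (1 - f) / (2 * length(g)))
    expect_lt(abs(f_hat - f), 3 * se)
  }
  # degenerate frequencies
  sites0 <- sites; sites0$freq <- 0
  fx0 <- make_cohort_fixture(m, sites0, n_samples = 10, mean_depth = 1,
                             error_rate = 0, seed = 2L)
  expect_true(all(fx0$truth$mut_ins == "SS"))
  sites1 <- sites; sites1$freq <- 1
  fx1 <- make_cohort_fixture(m, sites1, n_samples = 10, mean_depth = 1,
                             error_rate = 0, seed = 2L)
  expect_true(all(fx1$truth$mut_ins == "rr"))
})
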