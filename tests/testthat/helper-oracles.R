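# Independent oracles and in-code fixture builders shared by the suite.

# Brute-force all-offsets Hamming scan, independent of the package's
# scanner: visits offsets left to right, tests the mutant layout before
# the wild type at each offset, forward orientation before reverse
# complement. Any non-identical pair, or any character outside A/C/G/T,
# is a mismatch.
oracle_scan_one <- function(seq, left, ins, right, max_mm) {
  hamming <- function(a, b) {
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    sum(av != bv | !(av %in% c("A", "C", "G", "T")))
  }
  L <- nchar(left); I <- nchar(ins); R <- nchar(right); n <- nchar(seq)
  if (n < L + R) return("UNINFORMATIVE")
  for (i in seq_len(n - L + 1L)) {
    if (hamming(substr(seq, i, i + L - 1L), left) > max_mm) next
    if (i + L + I + R - 1L <= n &&
        substr(seq, i + L, i + L + I - 1L) == ins &&
        hamming(substr(seq, i + L + I, i + L + I + R - 1L), right) <= max_mm)
      return("MUT")
    if (i + L + R - 1L <= n &&
        hamming(substr(seq, i + L, i + L + R - 1L), right) <= max_mm)
      return("WT")
  }
  "UNINFORMATIVE"
}

oracle_scan <- function(reads, site) {
  vapply(reads, function(r) {
    r <- toupper(r)
    res <- oracle_scan_one(r, site$left_flank, site$inserted,
                           site$right_flank, site$max_mismatch_per_flank)
    if (res == "UNINFORMATIVE")
      res <- oracle_scan_one(revcomp(r), site$left_flank, site$inserted,
                             site$right_flank,
                             site$max_mismatch_per_flank)
    res
  }, character(1), USE.NAMES = FALSE)
}

random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE),
          collapse = ""), character(1))
}

# A tiny two-exon model used across tests: CDS "ATG GTA CAG TAA" split
# around one intron.
tiny_model <- function() {
  # exon1 ATGGT | intron gtaaccgcag | exon2 ACAGTAA
  build_gene_model("tiny", "ATGGTGTAACCGCAGACAGTAA",
                   rbind(c(1, 5), c(16, 22)))
}

# Random toy variant set for filter property trials.
random_variant_set <- function(n_rec = 5L, n_samp = 6L) {
  gts <- c("0/0", "0/1", "1/1", NA)
  alts <- c("T", "G", "TG", "T,G")
  fix <- data.frame(pos = sort(sample.int(1000L, n_rec)),
                    ref = sample(c("A", "C", "AT"), n_rec, replace = TRUE),
                    alt = sample(alts, n_rec, replace = TRUE),
                    qual = runif(n_rec, 20, 80))
  gt <- matrix(sample(gts, n_rec * n_samp, replace = TRUE,
                      prob = c(0.4, 0.25, 0.2, 0.15)),
               n_rec, n_samp)
  ad <- matrix(NA_character_, n_rec, n_samp)
  for (r in seq_len(n_rec)) {
    k <- length(strsplit(fix$alt[r], ",", fixed = TRUE)[[1]]) + 1L
    for (s in seq_len(n_samp)) {
      if (!is.na(gt[r, s]))
        ad[r, s] <- paste(sample(0:15, k, replace = TRUE), collapse = ",")
    }
  }
  colnames(gt) <- colnames(ad) <- sprintf("S%02d", seq_len(n_samp))
  variant_set(fix, gt, ad)
}

# Write a small multi-sample VCF for a set of samples carrying the
# synthetic sites; GT/AD are derived from the truth table with fixed
# depths, so the file is deterministic.
write_truth_vcf <- function(truth, sites, path, depth = 30L) {
  samples <- truth$sample_id
  fix <- data.frame(pos = sites$pos, ref = sites$ref, alt = sites$alt,
                    qual = 60)
  gt <- matrix(NA_character_, nrow(sites), length(samples))
  ad <- matrix(NA_character_, nrow(sites), length(samples))
  for (r in seq_len(nrow(sites))) {
    g <- truth[[sites$site_id[r]]]
    gt[r, ] <- c(SS = "0/0", Sr = "0/1", rr = "1/1")[g]
    ad[r, ] <- c(SS = paste0(depth, ",0"),
                 Sr = paste0(depth %/% 2, ",", depth %/% 2),
                 rr = paste0("0,", depth))[g]
  }
  colnames(gt) <- colnames(ad) <- samples
  write_variant_vcf(variant_set(fix, gt, ad), path, chrom = "gene")
  path
}
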