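#' Filtering thresholds for multi-sample variant calls
#'
#' Defaults follow the screen's published cascade: site quality strictly
#' greater than 40; per-sample support requiring total depth of
#' coverage >= 8 with each called allele's depth >= 2; the variant
#' called in at least 25% of samples; alternate allele frequency across
#' called samples >= 5%; optional restriction to bi-allelic records;
#' and a sample-level mapping-rate cutoff of 80%.
#'
#' @param qual_min site quality threshold (strict `>`).
#' @param depth_min per-sample total depth (inclusive `>=`).
#' @param allele_depth_min per-called-allele depth (inclusive `>=`).
#' @param alt_af_min cohort alternate allele frequency (inclusive).
#' @param call_fraction_min fraction of samples with qualifying support.
#' @param biallelic_only drop multi-allelic records in the cascade.
#' @param mapping_rate_min sample retention cutoff (inclusive).
#' @return object of class `filter_config`.
#' @export
filter_config <- function(qual_min = 40, depth_min = 8L,
                          allele_depth_min = 2L, alt_af_min = 0.05,
                          call_fraction_min = 0.25,
                          biallelic_only = FALSE,
                          mapping_rate_min = 0.80) {
  stopifnot(qual_min >= 0, depth_min >= 0, allele_depth_min >= 0,
            alt_af_min >= 0, alt_af_min <= 1,
            call_fraction_min >= 0, call_fraction_min <= 1,
            mapping_rate_min >= 0, mapping_rate_min <= 1)
  structure(list(qual_min = qual_min, depth_min = as.integer(depth_min),
                 allele_depth_min = as.integer(allele_depth_min),
                 alt_af_min = alt_af_min,
                 call_fraction_min = call_fraction_min,
                 biallelic_only = isTRUE(biallelic_only),
                 mapping_rate_min = mapping_rate_min),
            class = "filter_config")
}

#' Construct a multi-sample variant set
#'
#' The in-memory representation consumed by the filter cascade and the
#' annotator: a record table plus aligned per-sample genotype and
#' allele-depth matrices (VCF `GT` and `AD` conventions).
#'
#' @param fix data.frame with columns `pos`, `ref`, `alt` (alt a
#'   comma-separated string for multi-allelic records) and `qual`.
#' @param gt character matrix (records x samples) of `GT` strings
#'   (`"0/0"`, `"0/1"`, ..., `NA` or `"./."` for missing).
#' @param ad character matrix of `AD` strings (`"12,3"`), `NA` when the
#'   field is absent.
#' @return object of class `variant_set`.
#' @export
variant_set <- function(fix, gt, ad) {
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  stopifnot(all(c("pos", "ref", "alt", "qual") %in% names(fix)))
  gt <- as.matrix(gt); ad <- as.matrix(ad)
  stopifnot(nrow(gt) == nrow(fix), nrow(ad) == nrow(fix),
            ncol(gt) == ncol(ad))
  gt[gt %in% c("./.", ".|.", ".")] <- NA_character_
  structure(list(fix = fix, gt = gt, ad = ad,
                 samples = colnames(gt)), class = "variant_set")
}

#' @exportS3Method base::print
print.variant_set <- function(x, ...) {
  cat(sprintf("<variant_set> %d record(s) x %d sample(s)\n",
              nrow(x$fix), ncol(x$gt)))
  invisible(x)
}

#' @noRd
subset_variant_set <- function(vset, keep) {
  variant_set(vset$fix[keep, , drop = FALSE],
              vset$gt[keep, , drop = FALSE],
              vset$ad[keep, , drop = FALSE])
}

#' Number of alternate alleles per record
#' @noRd
n_alt <- function(vset) {
  ifelse(is.na(vset$fix$alt) | vset$fix$alt == "", 0L,
         lengths(strsplit(vset$fix$alt, ",", fixed = TRUE)))
}

#' Retain samples passing the mapping-rate rule
#'
#' @param mapping_rates named numeric vector of per-sample mapped-read
#'   fractions in `[0, 1]`.
#' @param min_rate retention cutoff, inclusive ("80% or higher").
#' @return character vector of retained sample names, input order
#'   preserved.
#' @examples
#' qc_samples(c(a = 0.95, b = 0.79, c = 0.81))
#' @export
qc_samples <- function(mapping_rates, min_rate = 0.80) {
  if (!length(mapping_rates)) return(character())
  stopifnot(all(mapping_rates >= 0), all(mapping_rates <= 1))
  names(mapping_rates)[mapping_rates >= min_rate]
}

#' Apply the post-calling filter cascade
#'
#' A record survives when (stage 1) its site quality is strictly above
#' `qual_min`; (stage 2) at least `ceil(call_fraction_min * n_samples)`
#' samples carry a called genotype whose total allele depth is at least
#' `depth_min` with every called allele's depth at least
#' `allele_depth_min`; and (stage 3) the alternate allele frequency
#' across called genotypes is at least `alt_af_min` (allele-count
#' based; for multi-allelic records the combined non-reference
#' frequency is used). Records whose called genotypes lack `AD` are
#' flagged and removed at stage 2 with a reason.
#'
#' @param vset a [variant_set()].
#' @param cfg a [filter_config()].
#' @param n_samples cohort size for the call-fraction rule (defaults to
#'   the number of sample columns).
#' @return the surviving `variant_set`; attribute `attrition` is a
#'   data.frame of per-stage input/removed counts, attribute `flagged`
#'   lists records excluded for missing `AD`.
#' @export
filter_variants <- function(vset, cfg = filter_config(),
                            n_samples = length(vset$samples)) {
  stopifnot(inherits(vset, "variant_set"), inherits(cfg, "filter_config"))
  if (n_samples < 1L)
    cry_error("n_samples must be >= 1", "cryscreen_parameter_error")
  stages <- list()
  flagged <- integer()

  n0 <- nrow(vset$fix)
  keep <- !is.na(vset$fix$qual) & vset$fix$qual > cfg$qual_min
  stages[["site_quality"]] <- c(input = n0, removed = sum(!keep))
  vset <- subset_variant_set(vset, keep)

  n1 <- nrow(vset$fix)
  min_called <- ceiling(cfg$call_fraction_min * n_samples)
  support <- logical(n1)
  missing_ad <- logical(n1)
  for (r in seq_len(n1)) {
    called <- which(!is.na(vset$gt[r, ]))
    if (!length(called)) { support[r] <- FALSE; next }
    ads <- strsplit(vset$ad[r, called], ",", fixed = TRUE)
    if (any(is.na(vset$ad[r, called]))) { missing_ad[r] <- TRUE; next }
    ok <- vapply(seq_along(called), function(j) {
      depths <- suppressWarnings(as.integer(ads[[j]]))
      if (anyNA(depths)) return(NA)
      alleles <- unique(as.integer(
        strsplit(vset$gt[r, called[j]], "[/|]")[[1]]))
      sum(depths) >= cfg$depth_min &&
        all(depths[alleles + 1L] >= cfg$allele_depth_min)
    }, logical(1))
    if (anyNA(ok)) { missing_ad[r] <- TRUE; next }
    support[r] <- sum(ok) >= min_called
  }
  stages[["missing_allele_depth"]] <- c(input = n1, removed = sum(missing_ad))
  stages[["genotype_support"]] <- c(input = n1 - sum(missing_ad),
                                    removed = sum(!support & !missing_ad))
  flagged <- vset$fix$pos[missing_ad]
  vset <- subset_variant_set(vset, support & !missing_ad)

  n2 <- nrow(vset$fix)
  af_ok <- logical(n2)
  for (r in seq_len(n2)) {
    alleles <- unlist(strsplit(vset$gt[r, ], "[/|]"))
    alleles <- suppressWarnings(as.integer(alleles[!is.na(alleles)]))
    alleles <- alleles[!is.na(alleles)]
    af_ok[r] <- length(alleles) > 0L &&
      mean(alleles > 0L) >= cfg$alt_af_min
  }
  stages[["alt_allele_frequency"]] <- c(input = n2, removed = sum(!af_ok))
  vset <- subset_variant_set(vset, af_ok)

  if (cfg$biallelic_only) {
    n3 <- nrow(vset$fix)
    bi <- n_alt(vset) == 1L
    stages[["biallelic"]] <- c(input = n3, removed = sum(!bi))
    vset <- subset_variant_set(vset, bi)
  }

  attr(vset, "attrition") <- data.frame(
    stage = names(stages),
    input = vapply(stages, `[[`, integer(1), "input"),
    removed = vapply(stages, `[[`, integer(1), "removed"),
    row.names = NULL)
  attr(vset, "flagged") <- flagged
  vset
}

#' Select bi-allelic records and tally SNPs vs indels
#'
#' Multi-allelic records are dropped, not decomposed. A record with one
#' alternate allele is a SNP when `nchar(ref) == nchar(alt)` and an
#' indel otherwise.
#'
#' @param vset a [variant_set()].
#' @return the bi-allelic `variant_set`; attribute `tally` holds
#'   `n_snp`, `n_indel`.
#' @export
select_biallelic <- function(vset) {
  stopifnot(inherits(vset, "variant_set"))
  keep <- n_alt(vset) == 1L
  out <- subset_variant_set(vset, keep)
  is_snp <- nchar(out$fix$ref) == nchar(out$fix$alt)
  attr(out, "tally") <- c(n_snp = sum(is_snp), n_indel = sum(!is_snp))
  out
}

#' Write a filter attrition report to TSV
#'
#' @param vset filtered `variant_set` carrying an `attrition` attribute.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_attrition_tsv <- function(vset, path) {
  att <- attr(vset, "attrition")
  if (is.null(att))
    cry_error("variant set carries no attrition report",
              "cryscreen_lookup_error")
  write.table(att, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
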