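#' Classify candidate alleles by their predicted protein consequence
#'
#' Nonsense and frameshift alleles truncate the receptor and are
#' `TRUNCATING`; missense alleles are `MISSENSE_CANDIDATE` (their
#' effect on toxin binding needs functional testing, so they never
#' drive a resistance verdict); everything else is `NON_CANDIDATE`.
#'
#' @param annotations an `effect_annotations` data.frame (from
#'   [annotate_variant()]) or any data.frame with `aa_change`,
#'   `effect_class` and optionally `truncating`.
#' @return data.frame `allele` (amino-acid-change key), `category`.
#' @export
classify_alleles <- function(annotations) {
  cls <- annotations$effect_class
  trunc <- if (!is.null(annotations$truncating)) annotations$truncating
           else cls %in% c("NON", "SHIFT")
  category <- ifelse(trunc, "TRUNCATING",
              ifelse(cls == "MISS", "MISSENSE_CANDIDATE",
                     "NON_CANDIDATE"))
  data.frame(allele = aa_key(annotations$aa_change),
             category = category, stringsAsFactors = FALSE)
}

#' Predict the Cry1F-resistance phenotype of one sample
#'
#' Applies the truncation rule: a sample homozygous for any truncating
#' allele is predicted resistant; a sample heterozygous for two or more
#' distinct truncating alleles (none homozygous) is a complementation
#' candidate, since short reads cannot phase the two alleles; a single
#' heterozygous truncating allele makes a carrier; otherwise no
#' truncating allele is present. Missense genotypes never contribute.
#'
#' @param genotypes named character vector, allele key ->
#'   `"SS"|"Sr"|"rr"` (or `"NoCall"`, ignored).
#' @param classes allele classification from [classify_alleles()].
#' @return list of class `phenotype_prediction`: `verdict`,
#'   `supporting` (data.frame allele/genotype of truncating alleles
#'   with a mutant copy).
#' @examples
#' cls <- data.frame(allele = c("D740A", "A15"),
#'                   category = c("TRUNCATING", "TRUNCATING"))
#' predict_phenotype(c(D740A = "rr"), cls)$verdict
#' @export
predict_phenotype <- function(genotypes, classes) {
  if (!length(genotypes))
    cry_error("genotype map must be non-empty", "cryscreen_parameter_error")
  alleles <- names(genotypes)
  unknown <- setdiff(alleles, classes$allele)
  if (length(unknown))
    cry_error(sprintf("unknown allele id(s): %s",
                      paste(unknown, collapse = ", ")),
              "cryscreen_config_error")
  cat_of <- setNames(classes$category, classes$allele)[alleles]
  trunc <- cat_of == "TRUNCATING" & genotypes %in% c("Sr", "rr")
  supporting <- data.frame(allele = alleles[trunc],
                           genotype = unname(genotypes[trunc]),
                           stringsAsFactors = FALSE)
  verdict <- if (any(supporting$genotype == "rr"))
    "PREDICTED_RESISTANT_HOM"
  else if (sum(supporting$genotype == "Sr") >= 2L)
    "CANDIDATE_RESISTANT_COMPLEMENTATION"
  else if (nrow(supporting) == 1L) "CARRIER"
  else "NO_TRUNCATING_ALLELE"
  structure(list(verdict = verdict, supporting = supporting),
            class = "phenotype_prediction")
}

#' Predict phenotypes for a cohort genotype matrix
#'
#' @param genotype_table data.frame with `sample_id` plus one column
#'   per allele key holding `SS`/`Sr`/`rr`/`NoCall`.
#' @param classes allele classification from [classify_alleles()].
#' @return data.frame `sample_id`, `verdict`, `supporting_alleles`
#'   (comma-separated `allele:genotype`).
#' @export
predict_cohort <- function(genotype_table, classes) {
  allele_cols <- setdiff(names(genotype_table), c("sample_id", "location"))
  rows <- lapply(seq_len(nrow(genotype_table)), function(i) {
    g <- unlist(genotype_table[i, allele_cols, drop = FALSE])
    p <- predict_phenotype(setNames(as.character(g), allele_cols), classes)
    data.frame(sample_id = genotype_table$sample_id[i],
               verdict = p$verdict,
               supporting_alleles = paste(
                 sprintf("%s:%s", p$supporting$allele,
                         p$supporting$genotype), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tally candidate resistance alleles
#'
#' Tallies are computed in the published table's class vocabulary
#' (in-frame indels reported as `SHIFT`): counts of missense, nonsense
#' and nonsynonymous (missense + nonsense) changes, and of frameshift
#' changes excluding already-known alleles. When a genotype table is
#' supplied, carrier and homozygote counts over truncating alleles are
#' added.
#'
#' @param annotations data.frame with `effect_class` (table-compat
#'   labels, e.g. [load_fixture()]`("table2")` or
#'   [annotate_variant()] with `table_compat = TRUE`) and `aa_change`.
#' @param known_alleles character vector of already-known allele keys
#'   excluded from the frameshift count (e.g. `"D740A"`).
#' @param genotype_table optional data.frame `sample_id` x allele-key
#'   columns with `SS`/`Sr`/`rr` calls.
#' @return named list of tallies: `n_nonsynonymous`, `n_missense`,
#'   `n_nonsense`, `n_frameshift_excl_known`,
#'   `n_carriers_any_truncating`, `n_hom_truncating`.
#' @export
summarize_candidates <- function(annotations,
                                 known_alleles = character(),
                                 genotype_table = NULL) {
  cls <- annotations$effect_class
  cls[cls == "INFRAME"] <- "SHIFT"  # table-compat tallies
  keys <- aa_key(annotations$aa_change)
  known <- aa_key(known_alleles)
  n_miss <- sum(cls == "MISS")
  n_non <- sum(cls == "NON")
  n_shift <- sum(cls == "SHIFT" & !(keys %in% known))
  out <- list(n_nonsynonymous = n_miss + n_non, n_missense = n_miss,
              n_nonsense = n_non, n_frameshift_excl_known = n_shift,
              n_carriers_any_truncating = NA_integer_,
              n_hom_truncating = NA_integer_)
  if (!is.null(genotype_table)) {
    trunc_alleles <- keys[cls %in% c("NON", "SHIFT")]
    cols <- intersect(trunc_alleles, names(genotype_table))
    g <- as.matrix(genotype_table[, cols, drop = FALSE])
    out$n_carriers_any_truncating <-
      sum(apply(g, 1L, function(x) any(x %in% c("Sr", "rr"))))
    out$n_hom_truncating <-
      sum(apply(g, 1L, function(x) any(x == "rr")))
  }
  out
}

#' Percentage of a cohort carrying a mutation
#'
#' @param n_positive samples positive for the mutation.
#' @param n_total cohort size.
#' @return integer percentage (rounded).
#' @export
carrier_pct <- function(n_positive, n_total) {
  as.integer(round(100 * n_positive / n_total))
}

#' @exportS3Method base::print
print.phenotype_prediction <- function(x, ...) {
  cat(sprintf("<phenotype_prediction> %s", x$verdict))
  if (nrow(x$supporting))
    cat(" [", paste(sprintf("%s:%s", x$supporting$allele,
                            x$supporting$genotype), collapse = ", "),
        "]", sep = "")
  cat("\n")
  invisible(x)
}
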