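#' Location from a sample-name prefix
#'
#' Samples are named by trapping location: `PRL` (Lajas), `PRS`
#' (Salinas), `PRSI` (Santa Isabel). Unknown prefixes map to
#' `"other"`.
#'
#' @param sample_id character vector of sample names.
#' @return character vector of locations.
#' @export
location_from_sample <- function(sample_id) {
  ifelse(grepl("^PRSI", sample_id), "Santa Isabel",
  ifelse(grepl("^PRS", sample_id), "Salinas",
  ifelse(grepl("^PRL", sample_id), "Lajas", "other")))
}

#' Load a packaged cohort fixture
#'
#' Two fixtures transcribe the screen's published cohort results:
#' `"table1"` is the 41-sample TaqMan vs k-mer genotype comparison for
#' the known 2-bp insertion allele (columns `sample_id`, `location` —
#' derived from the sample-name prefix —, `taqman`, `kmer`);
#' `"table2"` is the 24-row table of nonsynonymous and frameshift
#' mutations (columns `position`, `class`, `mutation`  — `ref/alt`
#' codon display —, `aa_change`, `n_samples`; class labels use the
#' published vocabulary, where in-frame deletions appear as `SHIFT`).
#'
#' @param name `"table1"` or `"table2"`.
#' @return data.frame.
#' @examples
#' nrow(load_fixture("table1")) # 41
#' @export
load_fixture <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("table1", "table2"))
    cry_error("unknown fixture; use \"table1\" or \"table2\"",
              "cryscreen_lookup_error")
  file <- switch(name, table1 = "table1_genotypes.tsv",
                 table2 = "table2_mutations.tsv")
  path <- system.file("extdata", file, package = "cryscreen",
                      mustWork = TRUE)
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (name == "table1") {
    d <- data.frame(sample_id = d$sample_id,
                    location = location_from_sample(d$sample_id),
                    taqman = d$taqman, kmer = d$kmer,
                    stringsAsFactors = FALSE)
  }
  d
}

#' Split a published `ref/alt` codon-display string
#'
#' @param mutation character vector like `"aCg/aTg"` or `"gct/"`.
#' @return data.frame `ref_codons`, `alt_codons`.
#' @export
split_mutation <- function(mutation) {
  parts <- strsplit(mutation, "/", fixed = TRUE)
  data.frame(
    ref_codons = vapply(parts, `[`, character(1), 1L),
    alt_codons = vapply(parts, function(p)
      if (length(p) > 1L) trimws(p[2L]) else "", character(1)),
    stringsAsFactors = FALSE)
}
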