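#' Read a multi-sample VCF into a variant set
#'
#' Uses vcfR to parse the file; per-sample `GT` and `AD` fields are
#' required by the filter cascade (`AD` may be absent, in which case
#' records are flagged at filtering time).
#'
#' @param path VCF (4.2) file.
#' @return a [variant_set()].
#' @export
read_variant_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  fixm <- matrix(fixm, ncol = 7L,
                 dimnames = list(NULL, c("CHROM", "POS", "ID", "REF",
                                         "ALT", "QUAL", "FILTER")))
  fix <- data.frame(chrom = fixm[, "CHROM"],
                    pos = as.integer(fixm[, "POS"]),
                    id = fixm[, "ID"],
                    ref = fixm[, "REF"],
                    alt = fixm[, "ALT"],
                    qual = suppressWarnings(as.numeric(fixm[, "QUAL"])),
                    stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"),
                 error = function(e) {
                   matrix(NA_character_, nrow(gt), ncol(gt),
                          dimnames = dimnames(gt))
                 })
  variant_set(fix, gt, ad)
}

#' Write a variant set as a plain-text VCF 4.2 file
#'
#' Emits a minimal, deterministic VCF with `GT:AD` per-sample fields,
#' suitable for round-tripping through [read_variant_vcf()].
#'
#' @param vset a [variant_set()].
#' @param path output file.
#' @param chrom chromosome/contig label used when the set carries none.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(vset, path, chrom = "gene") {
  stopifnot(inherits(vset, "variant_set"))
  fix <- vset$fix
  chroms <- if (!is.null(fix$chrom)) fix$chrom else rep(chrom, nrow(fix))
  ids <- if (!is.null(fix$id)) ifelse(is.na(fix$id), ".", fix$id)
         else rep(".", nrow(fix))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(chroms)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", vset$samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(fix)), function(r) {
    cells <- vapply(seq_along(vset$samples), function(j) {
      g <- vset$gt[r, j]; a <- vset$ad[r, j]
      if (is.na(g)) g <- "./."
      if (is.na(a)) a <- "."
      paste0(g, ":", a)
    }, character(1))
    paste(c(chroms[r], fix$pos[r], ids[r], fix$ref[r], fix$alt[r],
            format(fix$qual[r], trim = TRUE), "PASS", ".", "GT:AD",
            cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
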