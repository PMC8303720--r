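#' Map CDS indices back to gene positions
#'
#' Inverse of the exonic branch of [map_to_cds()].
#'
#' @param model a [build_gene_model()] object.
#' @param cds_index integer vector of 1-based CDS indices.
#' @return integer vector of gene positions.
#' @export
cds_to_gene <- function(model, cds_index) {
  ex <- model$exons
  lens <- ex$end - ex$start + 1L
  cum <- cumsum(lens)
  cds_index <- as.integer(cds_index)
  if (any(cds_index < 1L) || any(cds_index > sum(lens)))
    cry_error("cds_index out of range", "cryscreen_bounds_error")
  vapply(cds_index, function(ci) {
    j <- which(cum >= ci)[1L]
    before <- if (j == 1L) 0L else cum[j - 1L]
    ex$start[j] + (ci - before) - 1L
  }, integer(1))
}

#' A deterministic synthetic gene model for examples and simulation
#'
#' Builds a fixed synthetic ABC-transporter-like gene: a 1200 bp coding
#' sequence (400 codons, ATG start, single terminal stop) split across
#' five exons by four 80 bp introns with canonical GT..AG ends. The
#' model is generated from a fixed internal seed, so every call returns
#' the same sequence. It is a synthetic stand-in used by the simulator
#' and the test-suite; it is not the SfABCC2 reference.
#'
#' @return a `gene_model` of length 1520 bp with 5 exons.
#' @examples
#' example_gene_model()
#' @export
example_gene_model <- function() {
  with_seed(761803L, {
    bases <- c("A", "C", "G", "T")
    codons <- apply(matrix(sample(bases, 399L * 3L, replace = TRUE),
                           ncol = 3L), 1L, paste, collapse = "")
    # resample stop codons and internal ATG-independent stops
    while (any(bad <- codons %in% c("TAA", "TAG", "TGA")))
      codons[bad] <- replicate(sum(bad),
        paste(sample(bases, 3L, replace = TRUE), collapse = ""))
    cds <- paste0("ATG", paste(codons[-1L], collapse = ""), "TAA")
    intron <- function() paste0("GT",
      paste(sample(bases, 76L, replace = TRUE), collapse = ""), "AG")
    exon_cds <- substring(cds, c(1, 241, 481, 721, 961),
                          c(240, 480, 720, 960, 1200))
    seq <- exon_cds[1L]
    exons <- data.frame(start = 1L, end = 240L)
    for (k in 2:5) {
      seq <- paste0(seq, intron())
      s <- nchar(seq) + 1L
      seq <- paste0(seq, exon_cds[k])
      exons <- rbind(exons, data.frame(start = s, end = nchar(seq)))
    }
    build_gene_model("synthetic_abcc2", seq, exons)
  })
}

#' Default variant sites of the synthetic cohort
#'
#' Two resistance-style truncating sites in the synthetic gene: a 2-bp
#' GC insertion after the first base of codon 240 (population frequency
#' 0.33, mirroring the known insertion allele) and a 1-bp frameshift
#' deletion in codon 60 (frequency 0.32, mirroring the most common
#' frameshift allele).
#'
#' @param model gene model the positions refer to (default
#'   [example_gene_model()]).
#' @return data.frame `site_id`, `pos`, `ref`, `alt`, `freq`.
#' @export
default_sites <- function(model = example_gene_model()) {
  p_ins <- cds_to_gene(model, 3L * (240L - 1L) + 1L)
  p_del <- cds_to_gene(model, 3L * (60L - 1L) + 1L)
  data.frame(
    site_id = c("mut_ins", "fs_del"),
    pos = c(p_ins, p_del),
    ref = c(substr(model$sequence, p_ins, p_ins),
            substr(model$sequence, p_del, p_del + 1L)),
    alt = c(paste0(substr(model$sequence, p_ins, p_ins), "GC"),
            substr(model$sequence, p_del, p_del)),
    freq = c(0.33, 0.32),
    stringsAsFactors = FALSE)
}

#' Insertion genotyping site derived from a gene model position
#'
#' Builds an [insertion_site()] whose 10-mer flanks are the reference
#' bases ending at the anchor position and starting immediately after
#' it.
#'
#' @param model gene model.
#' @param pos anchor position (insertion falls after this base).
#' @param inserted inserted bases (e.g. `"GC"`).
#' @param site_id site label.
#' @param max_mismatch_per_flank mismatch budget per flank.
#' @return an `insertion_site`.
#' @export
site_from_model <- function(model, pos, inserted, site_id = "site",
                            max_mismatch_per_flank = 2L) {
  pos <- as.integer(pos)
  if (pos < 10L || pos + 10L > nchar(model$sequence))
    cry_error("anchor too close to the gene ends for 10-mer flanks",
              "cryscreen_bounds_error")
  insertion_site(site_id,
                 left_flank = substr(model$sequence, pos - 9L, pos),
                 right_flank = substr(model$sequence, pos + 1L, pos + 10L),
                 inserted = inserted,
                 max_mismatch_per_flank = max_mismatch_per_flank)
}
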