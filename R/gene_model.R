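#' Build a gene model from a sequence and exon intervals
#'
#' A gene model couples a plus-strand genomic sequence (gene-local,
#' 1-based) with an ordered set of exon intervals. The coding sequence
#' (CDS) is the concatenation of the exon substrings. Complete models
#' (`partial = FALSE`) must encode an open reading frame: length a
#' multiple of three, starting with ATG and with a single, terminal stop
#' codon. Partial models (e.g. a reference with an N-filled
#' inter-scaffold gap) relax the ORF checks so that unsequenced regions
#' do not invalidate the model.
#'
#' @param gene_id character scalar naming the gene.
#' @param sequence DNA string over `A,C,G,T,N` (case-insensitive).
#' @param exons two-column matrix/data.frame of 1-based inclusive
#'   `(start, end)` intervals, or a list of length-2 vectors.
#' @param partial logical; `TRUE` marks models with unsequenced regions.
#' @return an object of class `gene_model` with elements `gene_id`,
#'   `sequence`, `exons` (data.frame `start`,`end`), `partial`, `cds`
#'   and `protein`.
#' @examples
#' m <- build_gene_model("g1", "ATGTAA", cbind(1, 6))
#' m$protein # "M*"
#' @export
build_gene_model <- function(gene_id, sequence, exons, partial = FALSE) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    cry_error("gene sequence contains symbols outside {A,C,G,T,N}",
              "cryscreen_alphabet_error")
  exons <- normalize_exons(exons)
  L <- nchar(sequence)
  if (any(exons$start > exons$end))
    cry_error("exon interval with start > end", "cryscreen_structural_error")
  if (any(exons$start < 1L) || any(exons$end > L))
    cry_error("exon interval outside 1..L", "cryscreen_structural_error")
  if (nrow(exons) > 1L) {
    if (is.unsorted(exons$start, strictly = TRUE))
      cry_error("exons must be sorted ascending", "cryscreen_structural_error")
    if (any(exons$start[-1L] <= exons$end[-nrow(exons)]))
      cry_error("exons overlap", "cryscreen_structural_error")
  }
  cds <- paste(substring(sequence, exons$start, exons$end), collapse = "")
  if (!partial) {
    if (nchar(cds) %% 3L != 0L)
      cry_error("CDS length is not a multiple of 3", "cryscreen_model_error")
    if (substr(cds, 1L, 3L) != "ATG")
      cry_error("CDS does not begin with ATG", "cryscreen_model_error")
  }
  prot <- as.character(translate_dna(cds, quiet = TRUE))
  if (!partial) {
    stops <- which(strsplit(prot, "", fixed = TRUE)[[1]] == "*")
    if (length(stops) != 1L || stops != nchar(prot))
      cry_error("CDS must contain exactly one, terminal stop codon",
                "cryscreen_model_error")
  }
  structure(list(gene_id = gene_id, sequence = sequence, exons = exons,
                 partial = partial, cds = cds, protein = prot),
            class = "gene_model")
}

#' @noRd
normalize_exons <- function(exons) {
  if (is.list(exons) && !is.data.frame(exons))
    exons <- do.call(rbind, lapply(exons, function(e) e[1:2]))
  exons <- as.data.frame(exons)[, 1:2]
  names(exons) <- c("start", "end")
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (nrow(exons) == 0L)
    cry_error("at least one exon is required", "cryscreen_structural_error")
  exons
}

#' @exportS3Method base::print
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s: %d bp, %d exon(s), CDS %d bp%s\n",
              x$gene_id, nchar(x$sequence), nrow(x$exons), nchar(x$cds),
              if (x$partial) " (partial)" else ""))
  invisible(x)
}

#' Map gene positions to coding coordinates
#'
#' For each 1-based gene position, reports whether it is exonic (with
#' its CDS index, codon number and 1-based offset within the codon),
#' intronic (with distance in bases to the nearest splice junction and
#' which side, donor or acceptor, that junction is), or outside the
#' modelled exon/intron span.
#'
#' @param model a [build_gene_model()] object.
#' @param pos integer vector of gene positions (>= 1).
#' @return data.frame with columns `pos`, `region`
#'   (`"exonic"|"intronic"|"outside"`), `cds_index`, `codon_number`,
#'   `offset_in_codon`, `distance_to_splice`, `splice_side`.
#' @examples
#' m <- build_gene_model("g2", "ATGGTACAGTAA", rbind(c(1, 3), c(10, 12)))
#' map_to_cds(m, c(10, 5))
#' @export
map_to_cds <- function(model, pos) {
  stopifnot(inherits(model, "gene_model"))
  pos <- as.integer(pos)
  if (any(!is.finite(pos)) || any(pos < 1L))
    cry_error("positions must be >= 1", "cryscreen_bounds_error")
  ex <- model$exons
  cum <- cumsum(ex$end - ex$start + 1L)
  cds_before <- c(0L, cum[-length(cum)])
  out <- data.frame(pos = pos, region = "outside", cds_index = NA_integer_,
                    codon_number = NA_integer_, offset_in_codon = NA_integer_,
                    distance_to_splice = NA_integer_,
                    splice_side = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(pos)) {
    p <- pos[i]
    j <- which(ex$start <= p & p <= ex$end)
    if (length(j) == 1L) {
      ci <- cds_before[j] + (p - ex$start[j]) + 1L
      out$region[i] <- "exonic"
      out$cds_index[i] <- ci
      out$codon_number[i] <- (ci - 1L) %/% 3L + 1L
      out$offset_in_codon[i] <- (ci - 1L) %% 3L + 1L
    } else {
      up <- which(ex$end < p)     # exon upstream of p
      dn <- which(ex$start > p)   # exon downstream of p
      if (length(up) && length(dn)) {
        d_donor <- p - max(ex$end[up])
        d_acceptor <- min(ex$start[dn]) - p
        out$region[i] <- "intronic"
        if (d_donor <= d_acceptor) {
          out$distance_to_splice[i] <- d_donor
          out$splice_side[i] <- "donor"
        } else {
          out$distance_to_splice[i] <- d_acceptor
          out$splice_side[i] <- "acceptor"
        }
      } # else before first / after last exon: "outside"
    }
  }
  out
}

#' Translate a DNA coding sequence with the standard genetic code
#'
#' Codons containing N translate to `"X"`; stop codons render `"*"`.
#' A trailing incomplete codon is ignored and flagged via the
#' `"incomplete"` attribute (with a warning unless `quiet = TRUE`).
#'
#' @param cds DNA string (length >= 3) over `A,C,G,T,N`.
#' @param quiet suppress the incomplete-codon warning.
#' @return protein string; attribute `incomplete` is `TRUE` when a
#'   trailing partial codon was dropped.
#' @examples
#' translate_dna("ATGGCT") # "MA"
#' translate_dna("GCG")    # "A"
#' @export
translate_dna <- function(cds, quiet = FALSE) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  if (grepl("[^ACGTN]", cds))
    cry_error("sequence contains symbols outside {A,C,G,T,N}",
              "cryscreen_alphabet_error")
  if (nchar(cds) < 3L)
    cry_error("coding sequence shorter than one codon",
              "cryscreen_bounds_error")
  n_codon <- nchar(cds) %/% 3L
  incomplete <- nchar(cds) %% 3L != 0L
  if (incomplete && !quiet)
    warning("trailing incomplete codon ignored", call. = FALSE)
  starts <- 3L * (seq_len(n_codon) - 1L) + 1L
  codons <- substring(cds, starts, starts + 2L)
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"  # any codon containing N
  structure(paste(aa, collapse = ""), incomplete = incomplete)
}

#' Positions of splice-region bases around exon junctions
#'
#' Flags whether gene positions fall in the splice-region window around
#' any internal exon boundary: by default the first/last
#' `intronic_flank` intronic bases (which include the 2-base
#' donor/acceptor core) and the `exonic_flank` exonic bases adjacent to
#' a junction.
#'
#' @param model a [build_gene_model()] object.
#' @param pos integer vector of gene positions.
#' @param exonic_flank exonic bases adjacent to a junction (default 3).
#' @param intronic_flank intronic bases adjacent to a junction
#'   (default 8).
#' @return logical vector.
#' @export
in_splice_region <- function(model, pos, exonic_flank = 3L,
                             intronic_flank = 8L) {
  mp <- map_to_cds(model, pos)
  res <- logical(length(pos))
  res[mp$region == "intronic"] <-
    mp$distance_to_splice[mp$region == "intronic"] <= intronic_flank
  ex <- model$exons
  if (nrow(ex) > 1L) {
    donor_edges <- ex$end[-nrow(ex)]      # last exonic base before intron
    acceptor_edges <- ex$start[-1L]       # first exonic base after intron
    for (i in which(mp$region == "exonic")) {
      p <- pos[i]
      res[i] <- any(p > donor_edges - exonic_flank & p <= donor_edges) ||
        any(p >= acceptor_edges & p < acceptor_edges + exonic_flank)
    }
  }
  res
}

#' Read a gene sequence from a FASTA file
#'
#' @param path FASTA file; the first record is used unless `gene_id`
#'   selects one by name.
#' @param gene_id optional record name to select.
#' @return named character scalar (name = record id).
#' @export
read_gene_fasta <- function(path, gene_id = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (!is.null(gene_id)) {
    hit <- which(sub("\\s.*$", "", names(seqs)) == gene_id)
    if (!length(hit))
      cry_error(sprintf("no FASTA record named '%s'", gene_id),
                "cryscreen_lookup_error")
    seqs <- seqs[hit[1L]]
  }
  setNames(as.character(seqs[1L]), sub("\\s.*$", "", names(seqs)[1L]))
}

#' Write a gene sequence to FASTA
#'
#' @param sequence DNA string.
#' @param gene_id record name.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_fasta <- function(sequence, gene_id, path) {
  x <- Biostrings::DNAStringSet(setNames(sequence, gene_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read exon intervals from a GFF3-like file
#'
#' Consumes the `exon` features of a GFF3 file (1-based inclusive
#' coordinates) whose seqid matches `gene_id`, sorted by start.
#'
#' @param path GFF3 file.
#' @param gene_id required seqid.
#' @return data.frame with columns `start`, `end`.
#' @export
read_exon_gff <- function(path, gene_id) {
  g <- as.data.frame(rtracklayer::readGFF(path))
  g <- g[g$type == "exon" & as.character(g$seqid) == gene_id, , drop = FALSE]
  if (!nrow(g))
    cry_error(sprintf("no exon features with seqid '%s'", gene_id),
              "cryscreen_lookup_error")
  g <- g[order(g$start), , drop = FALSE]
  data.frame(start = as.integer(g$start), end = as.integer(g$end))
}

#' Write exon intervals as a minimal GFF3 file
#'
#' @param exons data.frame with `start`, `end`.
#' @param gene_id seqid to write.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_exon_gff <- function(exons, gene_id, path) {
  exons <- normalize_exons(exons)
  lines <- c("##gff-version 3",
             sprintf("%s\tcryscreen\texon\t%d\t%d\t.\t+\t.\tID=exon%d",
                     gene_id, exons$start, exons$end, seq_len(nrow(exons))))
  writeLines(lines, path)
  invisible(path)
}
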