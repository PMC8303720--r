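# Codon-level effect classification with the published table's display
# conventions: codon context is written lowercase with the changed or
# inserted bases uppercase, and amino-acid changes are written
# refAA + codon number + alt residues, with " *" appended when the
# event shifts the reading frame (or substitutes a stop).

#' @noRd
count_lower <- function(x) nchar(gsub("[^a-z]", "", x))

# Pad an alt codon display with the reference bases it omits. The
# table's typography marks retained reference bases lowercase; when
# fewer lowercase bases appear in the alt string than the reference
# codon context has, the trailing reference bases are appended so the
# downstream frame reads through them.
#' @noRd
pad_alt_codons <- function(ref_codons, alt_codons) {
  n_low <- count_lower(alt_codons)
  n_ref <- nchar(ref_codons)
  if (nzchar(alt_codons) && n_low > 0L && n_low < n_ref)
    paste0(alt_codons, tolower(substr(ref_codons, n_low + 1L, n_ref)))
  else alt_codons
}

#' Classify a codon-level sequence change
#'
#' Equal-length changes are classified by translation: `SYN` when the
#' protein is unchanged, `NON` when the alternate gains a stop codon,
#' `MISS` otherwise. Length-changing events are `SHIFT` when the
#' length difference is not a multiple of three and `INFRAME`
#' otherwise. `table_compat = TRUE` reports `INFRAME` as `SHIFT`,
#' matching the published table's labelling of in-frame deletions.
#'
#' @param ref_codons reference codon context (DNA string, any case).
#' @param alt_codons alternate codon string (`""` for a deletion).
#' @param table_compat map `INFRAME` to `SHIFT`.
#' @return one of `"SYN"`, `"MISS"`, `"NON"`, `"SHIFT"`, `"INFRAME"`.
#' @examples
#' classify_codon_change("aCg", "aTg")      # MISS
#' classify_codon_change("gat", "gCGat")    # SHIFT
#' @export
classify_codon_change <- function(ref_codons, alt_codons,
                                  table_compat = FALSE) {
  diff <- nchar(alt_codons) - nchar(ref_codons)
  if (diff != 0L) {
    cls <- if (abs(diff) %% 3L != 0L) "SHIFT" else "INFRAME"
    if (table_compat && cls == "INFRAME") cls <- "SHIFT"
    return(cls)
  }
  ref_aa <- translate_dna(ref_codons, quiet = TRUE)
  alt_aa <- translate_dna(alt_codons, quiet = TRUE)
  if (ref_aa == alt_aa) "SYN"
  else if (grepl("*", alt_aa, fixed = TRUE)) "NON"
  else "MISS"
}

#' Format an amino-acid change in the table's notation
#'
#' Substitutions render `refAA + position + altAA` (a gained stop
#' renders as `" *"`). Insertions render the reference residue, the
#' position, then the translation of the altered codon string (padded
#' with the omitted reference tail when the display abbreviates it),
#' with `" *"` appended when the insertion shifts the frame. Deletions
#' render the deleted residues followed by the position, with `" *"`
#' when the deletion shifts the frame.
#'
#' @param ref_codons reference codon context.
#' @param alt_codons alternate codon string (`""` for a deletion).
#' @param codon_number 1-based codon number of the first affected
#'   codon.
#' @return notation string, e.g. `"T14M"`, `"D740A *"`, `"CMV753"`.
#' @examples
#' format_aa_change("gat", "gCGat", 740)      # "D740A *"
#' format_aa_change("gtg", "gGTCAACG", 16)    # "V16GQR *"
#' format_aa_change("gga", "", 950)           # "G950"
#' @export
format_aa_change <- function(ref_codons, alt_codons, codon_number) {
  diff <- nchar(alt_codons) - nchar(ref_codons)
  shift <- abs(diff) %% 3L != 0L
  if (diff == 0L) {
    ref_aa <- translate_dna(ref_codons, quiet = TRUE)
    alt_aa <- translate_dna(alt_codons, quiet = TRUE)
    if (grepl("*", alt_aa, fixed = TRUE))
      return(paste0(ref_aa, codon_number, " *"))
    return(paste0(ref_aa, codon_number, alt_aa))
  }
  if (diff < 0L) {  # deletion: affected reference residues + position
    res <- translate_dna(ref_codons, quiet = TRUE)
    return(paste0(res, codon_number, if (shift) " *" else ""))
  }
  # insertion (possibly with retained reference context)
  ref_aa <- substr(translate_dna(ref_codons, quiet = TRUE), 1L, 1L)
  padded <- pad_alt_codons(ref_codons, alt_codons)
  n_codon <- nchar(padded) %/% 3L
  alt_aa <- if (n_codon >= 1L) translate_dna(padded, quiet = TRUE) else ""
  paste0(ref_aa, codon_number, alt_aa, if (shift) " *" else "")
}

#' Annotate variants against a gene model
#'
#' Classifies each left-anchored variant (`pos`, `ref`, `alt` in the
#' VCF convention, gene-local coordinates) into
#' `SYN`/`MISS`/`NON`/`SHIFT`/`INFRAME`/`INTRONIC`/`NONCODING`,
#' rebuilds the codon context (lowercase, changed bases uppercase),
#' formats the amino-acid change and flags splice-region proximity.
#' `NON` and `SHIFT` effects are truncating.
#'
#' @param model a [build_gene_model()] object.
#' @param variants data.frame with `pos`, `ref`, `alt` (single alt per
#'   row; filter multi-allelic records first), or a bi-allelic
#'   [variant_set()].
#' @param table_compat report `INFRAME` as `SHIFT` (published-table
#'   labelling).
#' @param splice_exonic,splice_intronic splice-region window passed to
#'   [in_splice_region()].
#' @return data.frame of class `effect_annotations`: `pos`, `ref`,
#'   `alt`, `effect_class`, `codon_number`, `codon_display`,
#'   `aa_change`, `truncating`, `splice_region`, `novel` (NA until
#'   [filter_novel()]).
#' @export
annotate_variant <- function(model, variants, table_compat = FALSE,
                             splice_exonic = 3L, splice_intronic = 8L) {
  stopifnot(inherits(model, "gene_model"))
  if (inherits(variants, "variant_set")) {
    if (any(n_alt(variants) != 1L))
      cry_error("variant set must be bi-allelic; run select_biallelic()",
                "cryscreen_parameter_error")
    variants <- variants$fix[, c("pos", "ref", "alt")]
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(variants)), function(i)
    annotate_one(model, variants$pos[i], variants$ref[i],
                 variants$alt[i], table_compat,
                 splice_exonic, splice_intronic))
  out <- do.call(rbind, rows)
  out$novel <- NA
  class(out) <- c("effect_annotations", "data.frame")
  out
}

#' @noRd
annotate_one <- function(model, pos, ref, alt, table_compat,
                         splice_exonic, splice_intronic) {
  pos <- as.integer(pos)
  ref <- toupper(ref); alt <- toupper(alt)
  L <- nchar(model$sequence)
  if (pos < 1L || pos + nchar(ref) - 1L > L)
    cry_error("variant outside the gene", "cryscreen_bounds_error")
  if (substr(model$sequence, pos, pos + nchar(ref) - 1L) != ref)
    cry_error(sprintf("ref allele does not match gene sequence at %d", pos),
              "cryscreen_reference_error")
  base <- data.frame(pos = pos, ref = ref, alt = alt,
                     effect_class = NA_character_,
                     codon_number = NA_integer_,
                     codon_display = NA_character_,
                     aa_change = NA_character_, truncating = FALSE,
                     splice_region = FALSE, stringsAsFactors = FALSE)

  is_sub <- nchar(ref) == nchar(alt)
  # the bases the event actually changes (anchor excluded for indels)
  change_span <- if (is_sub) pos:(pos + nchar(ref) - 1L)
                 else (pos + 1L):max(pos + 1L, pos + nchar(ref) - 1L)
  change_span <- pmin(change_span, L)
  regions <- map_to_cds(model, change_span)$region
  base$splice_region <- any(in_splice_region(
    model, pos:min(pos + max(nchar(ref), 1L) - 1L, L),
    splice_exonic, splice_intronic))
  if (!any(regions == "exonic")) {
    base$effect_class <- if (any(regions == "intronic")) "INTRONIC"
                         else "NONCODING"
    return(base)
  }

  if (is_sub) {
    ann <- annotate_substitution(model, pos, ref, alt)
  } else if (nchar(alt) > nchar(ref)) {
    ann <- annotate_insertion(model, pos, ref, alt)
  } else {
    ann <- annotate_deletion(model, pos, ref, alt)
  }
  # codons containing N are excluded from effect classification
  if (grepl("n", ann$ref_codons, ignore.case = TRUE)) {
    base$effect_class <- "NONCODING"
    return(base)
  }
  cls <- classify_codon_change(ann$ref_codons, ann$alt_codons)
  base$truncating <- cls %in% c("NON", "SHIFT")
  if (table_compat && cls == "INFRAME") cls <- "SHIFT"
  base$effect_class <- cls
  base$codon_number <- ann$codon_number
  base$codon_display <- paste0(ann$ref_display, "/", ann$alt_display)
  base$aa_change <- format_aa_change(ann$ref_codons, ann$alt_codons,
                                     ann$codon_number)
  base
}

#' @noRd
ref_codon_at <- function(model, codon_number) {
  substr(model$cds, 3L * (codon_number - 1L) + 1L, 3L * codon_number)
}

#' @noRd
annotate_substitution <- function(model, pos, ref, alt) {
  # classify per-base; handle the common single-base case fully, and
  # longer MNPs by their spanned codons
  mp <- map_to_cds(model, pos)
  cn <- mp$codon_number
  off <- mp$offset_in_codon
  ref_codon <- ref_codon_at(model, cn)
  if (nchar(ref) == 1L) {
    alt_codon <- ref_codon
    substr(alt_codon, off, off) <- alt
    disp_ref <- tolower(ref_codon)
    substr(disp_ref, off, off) <- toupper(substr(ref_codon, off, off))
    disp_alt <- tolower(alt_codon)
    substr(disp_alt, off, off) <- toupper(alt)
    list(codon_number = cn, ref_codons = disp_ref, alt_codons = disp_alt,
         ref_display = disp_ref, alt_display = disp_alt)
  } else {
    idx <- map_to_cds(model, pos:(pos + nchar(ref) - 1L))
    cn1 <- min(idx$codon_number, na.rm = TRUE)
    cn2 <- max(idx$codon_number, na.rm = TRUE)
    ref_span <- paste(vapply(cn1:cn2, ref_codon_at, character(1),
                             model = model), collapse = "")
    alt_span <- ref_span
    substr(alt_span, off, off + nchar(alt) - 1L) <- alt
    list(codon_number = cn1, ref_codons = ref_span, alt_codons = alt_span,
         ref_display = tolower(ref_span), alt_display = tolower(alt_span))
  }
}

#' @noRd
annotate_insertion <- function(model, pos, ref, alt) {
  # left-anchored: inserted bases follow the anchor base at `pos`
  inserted <- substr(alt, nchar(ref) + 1L, nchar(alt))
  mp <- map_to_cds(model, pos)
  cn <- mp$codon_number
  off <- mp$offset_in_codon
  ref_codon <- ref_codon_at(model, cn)
  disp_ref <- tolower(ref_codon)
  alt_codons <- paste0(tolower(substr(ref_codon, 1L, off)),
                       toupper(inserted),
                       tolower(substr(ref_codon, off + 1L, 3L)))
  list(codon_number = cn, ref_codons = tolower(ref_codon),
       alt_codons = alt_codons, ref_display = disp_ref,
       alt_display = alt_codons)
}

#' @noRd
annotate_deletion <- function(model, pos, ref, alt) {
  # left-anchored: bases pos+1 .. pos+nchar(ref)-1 are deleted
  del_start <- pos + nchar(alt)
  del_end <- pos + nchar(ref) - 1L
  idx <- map_to_cds(model, del_start:del_end)
  cns <- idx$codon_number[idx$region == "exonic"]
  cn1 <- min(cns); cn2 <- max(cns)
  ref_span <- paste(vapply(cn1:cn2, ref_codon_at, character(1),
                           model = model), collapse = "")
  n_del <- del_end - del_start + 1L
  o <- idx$offset_in_codon[idx$region == "exonic"][1L]
  # whole-codon deletions display the deleted codons with empty alt
  if (o == 1L && n_del %% 3L == 0L && n_del == nchar(ref_span)) {
    list(codon_number = cn1, ref_codons = tolower(ref_span),
         alt_codons = "", ref_display = tolower(ref_span),
         alt_display = "")
  } else {
    # remaining bases of the spanned codons after the deletion
    keep_left <- substr(ref_span, 1L, o - 1L)
    keep_right <- substr(ref_span, o + n_del, nchar(ref_span))
    alt_codons <- paste0(tolower(keep_left), tolower(keep_right))
    list(codon_number = cn1, ref_codons = tolower(ref_span),
         alt_codons = alt_codons, ref_display = tolower(ref_span),
         alt_display = alt_codons)
  }
}

#' Flag annotations absent from susceptible reference sequences
#'
#' Changes already observed in Cry1F-susceptible reference cDNAs are
#' not novel candidates; nothing is removed, downstream summaries
#' select on the flag. Matching is by amino-acid-change key with any
#' trailing `" *"` stripped.
#'
#' @param annotations an `effect_annotations` data.frame.
#' @param susceptible_changes character vector of amino-acid-change
#'   keys (may be empty).
#' @return the annotations with `novel` set.
#' @export
filter_novel <- function(annotations, susceptible_changes = character()) {
  keys <- aa_key(annotations$aa_change)
  annotations$novel <- !(keys %in% aa_key(susceptible_changes))
  annotations
}

#' Normalize an amino-acid-change string to a comparison key
#'
#' Strips the trailing premature-stop marker, so `"D740A *"` and
#' `"D740A"` compare equal.
#'
#' @param x character vector of amino-acid-change strings.
#' @return character vector of keys.
#' @export
aa_key <- function(x) sub("\\s*\\*$", "", x)

#' Read a susceptible-changes list (one amino-acid change per line)
#'
#' @param path one-column file.
#' @return character vector.
#' @export
read_susceptible_changes <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Write annotations as a table mirroring the published layout
#'
#' Columns: `position`, `class`, `mutation` (`ref/alt` codon display),
#' `aa_change`, plus any carrier counts supplied.
#'
#' @param annotations `effect_annotations`.
#' @param path output TSV.
#' @param n_samples optional integer vector of per-row carrier counts.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(annotations, path, n_samples = NULL) {
  out <- data.frame(position = annotations$pos,
                    class = annotations$effect_class,
                    mutation = annotations$codon_display,
                    aa_change = annotations$aa_change,
                    stringsAsFactors = FALSE)
  if (!is.null(n_samples)) out$n_samples <- n_samples
  if (!all(is.na(annotations$novel))) out$novel <- annotations$novel
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
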