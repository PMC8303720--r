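#' Define a known insertion genotyping site
#'
#' A genotyping site is described by its two 10-mer flanking sequences
#' and the inserted bases between them. Reads are scanned for the
#' flanks with a per-flank mismatch budget; the inserted bases must
#' match exactly.
#'
#' @param site_id site label.
#' @param left_flank,right_flank 10-base DNA strings immediately left /
#'   right of the insertion point.
#' @param inserted non-empty inserted bases (e.g. `"GC"`).
#' @param max_mismatch_per_flank allowed mismatches per flank
#'   (default 2).
#' @return object of class `insertion_site`.
#' @export
insertion_site <- function(site_id, left_flank, right_flank, inserted,
                           max_mismatch_per_flank = 2L) {
  left_flank <- toupper(left_flank)
  right_flank <- toupper(right_flank)
  inserted <- toupper(inserted)
  if (nchar(left_flank) != 10L || nchar(right_flank) != 10L)
    cry_error("flanking sequences must be exactly 10 bases",
              "cryscreen_parameter_error")
  if (!nzchar(inserted))
    cry_error("inserted bases must be non-empty",
              "cryscreen_parameter_error")
  max_mismatch_per_flank <- as.integer(max_mismatch_per_flank)
  if (max_mismatch_per_flank < 0L || max_mismatch_per_flank > 10L)
    cry_error("max_mismatch_per_flank must be in 0..flank length",
              "cryscreen_parameter_error")
  structure(list(site_id = site_id, left_flank = left_flank,
                 right_flank = right_flank, inserted = inserted,
                 max_mismatch_per_flank = max_mismatch_per_flank),
            class = "insertion_site")
}

#' Read genotyping-site definitions from a TSV file
#'
#' Columns: `site_id`, `left_flank`, `inserted`, `right_flank`,
#' `max_mm` (optional, default 2).
#'
#' @param path TSV file.
#' @return list of [insertion_site()] objects, named by `site_id`.
#' @export
read_insertion_sites <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (is.null(d$max_mm)) d$max_mm <- 2L
  sites <- lapply(seq_len(nrow(d)), function(i)
    insertion_site(d$site_id[i], d$left_flank[i], d$right_flank[i],
                   d$inserted[i], d$max_mm[i]))
  setNames(sites, d$site_id)
}

#' Scan reads for a known insertion
#'
#' Classifies each read as `MUT` when the left flank, the inserted
#' bases and the right flank occur contiguously in that order (each
#' flank within its mismatch budget; inserted bases exact), `WT` when
#' the two flanks occur contiguously with no intervening bases, and
#' `UNINFORMATIVE` otherwise. Offsets are scanned left to right and the
#' mutant layout is tested before the wild-type layout at each left
#' flank hit. By default the reverse complement is scanned when the
#' forward orientation is uninformative; the first informative
#' orientation wins. Non-DNA symbols (including N) count as
#' mismatches.
#'
#' @param reads character vector of read sequences.
#' @param site an [insertion_site()].
#' @param scan_revcomp also scan the reverse complement (default
#'   `TRUE`; merged amplicon reads have arbitrary orientation).
#' @return character vector in `c("MUT", "WT", "UNINFORMATIVE")`.
#' @examples
#' site <- insertion_site("s", "ACGTACGTAC", "TTGGCCAATT", "GC")
#' scan_read(c("ACGTACGTACGCTTGGCCAATT", "ACGTACGTACTTGGCCAATT"), site)
#' @export
scan_read <- function(reads, site, scan_revcomp = TRUE) {
  stopifnot(inherits(site, "insertion_site"))
  if (!length(reads)) return(character())
  if (any(!nzchar(reads)))
    cry_error("reads must be non-empty", "cryscreen_parameter_error")
  codes <- .scan_reads_cpp(reads, site$left_flank, site$inserted,
                           site$right_flank, site$max_mismatch_per_flank,
                           scan_revcomp)
  c("UNINFORMATIVE", "WT", "MUT")[codes + 1L]
}

#' Call a genotype at an insertion site from a sample's reads
#'
#' Counts informative reads (`coverage = n_wt + n_mut`; reads in which
#' both flanks were located) and applies the calling thresholds:
#' coverage below `min_coverage` gives `NoCall`; otherwise the mutant
#' read proportion `p = n_mut / coverage` gives `SS` when
#' `p <= carrier_min_proportion` (the carrier rule is strictly "more
#' than"), `rr` when `p >= hom_min_proportion`, and `Sr` in between.
#'
#' @param reads character vector of read sequences (may be empty).
#' @param site an [insertion_site()].
#' @param min_coverage minimum informative reads to call (default 40).
#' @param carrier_min_proportion carrier threshold (default 0.15).
#' @param hom_min_proportion homozygote threshold (default 0.85).
#' @param scan_revcomp passed to [scan_read()].
#' @return one-row data.frame of class `genotype_call`: `site_id`,
#'   `call`, `n_wt`, `n_mut`, `coverage`, `proportion`.
#' @export
genotype_site <- function(reads, site, min_coverage = 40L,
                          carrier_min_proportion = 0.15,
                          hom_min_proportion = 0.85,
                          scan_revcomp = TRUE) {
  if (!(carrier_min_proportion > 0 &&
        carrier_min_proportion < hom_min_proportion &&
        hom_min_proportion <= 1))
    cry_error("thresholds must satisfy 0 < carrier_min < hom_min <= 1",
              "cryscreen_parameter_error")
  status <- scan_read(reads, site, scan_revcomp = scan_revcomp)
  n_wt <- sum(status == "WT")
  n_mut <- sum(status == "MUT")
  coverage <- n_wt + n_mut
  proportion <- if (coverage > 0L) n_mut / coverage else NA_real_
  call <- if (coverage < min_coverage) "NoCall"
    else if (proportion <= carrier_min_proportion) "SS"
    else if (proportion >= hom_min_proportion) "rr"
    else "Sr"
  structure(data.frame(site_id = site$site_id, call = call, n_wt = n_wt,
                       n_mut = n_mut, coverage = coverage,
                       proportion = proportion, stringsAsFactors = FALSE),
            class = c("genotype_call", "data.frame"))
}

#' Genotype a cohort of per-sample FASTQ files at an insertion site
#'
#' @param fastq_files character vector of FASTQ paths; names are used
#'   as sample ids (basenames without extension otherwise). A directory
#'   path may be given instead, in which case all `*.fastq`/`*.fq`
#'   files in it are used.
#' @param site an [insertion_site()].
#' @param ... thresholds passed to [genotype_site()].
#' @return data.frame (`cohort_calls`) with one row per sample:
#'   `sample_id`, `site_id`, `call`, `n_wt`, `n_mut`, `coverage`,
#'   `proportion`, `error` (NA or the per-sample failure message).
#'   Attribute `summary` holds `n_SS`, `n_Sr`, `n_rr`, `n_NoCall`,
#'   `n_failed` (failed samples are excluded from the call summary).
#' @export
genotype_cohort <- function(fastq_files, site, ...) {
  if (length(fastq_files) == 1L && dir.exists(fastq_files)) {
    fastq_files <- list.files(fastq_files, pattern = "\\.(fastq|fq)(\\.gz)?$",
                              full.names = TRUE)
  }
  if (!length(fastq_files))
    cry_error("at least one sample is required", "cryscreen_parameter_error")
  ids <- names(fastq_files)
  if (is.null(ids))
    ids <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(fastq_files))
  rows <- lapply(seq_along(fastq_files), function(i) {
    res <- tryCatch({
      reads <- read_fastq(fastq_files[i])
      gc <- genotype_site(reads$seq, site, ...)
      gc$error <- NA_character_
      gc
    }, error = function(e) {
      data.frame(site_id = site$site_id, call = NA_character_,
                 n_wt = NA_integer_, n_mut = NA_integer_,
                 coverage = NA_integer_, proportion = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    cbind(data.frame(sample_id = ids[i], stringsAsFactors = FALSE), res)
  })
  out <- do.call(rbind, rows)
  ok <- is.na(out$error)
  attr(out, "summary") <- c(n_SS = sum(out$call[ok] == "SS"),
                            n_Sr = sum(out$call[ok] == "Sr"),
                            n_rr = sum(out$call[ok] == "rr"),
                            n_NoCall = sum(out$call[ok] == "NoCall"),
                            n_failed = sum(!ok))
  class(out) <- c("cohort_calls", "data.frame")
  out
}

#' Genotype in-memory read sets at an insertion site
#'
#' Convenience companion of [genotype_cohort()] for simulator output
#' that was not written to disk.
#'
#' @param read_sets named list of read data.frames (or character
#'   vectors of sequences), one element per sample.
#' @param site an [insertion_site()].
#' @param ... thresholds passed to [genotype_site()].
#' @return as [genotype_cohort()].
#' @export
genotype_read_sets <- function(read_sets, site, ...) {
  stopifnot(length(read_sets) >= 1L, !is.null(names(read_sets)))
  rows <- lapply(names(read_sets), function(id) {
    r <- read_sets[[id]]
    if (is.data.frame(r)) r <- r$seq
    gc <- genotype_site(r, site, ...)
    gc$error <- NA_character_
    cbind(data.frame(sample_id = id, stringsAsFactors = FALSE), gc)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- c(n_SS = sum(out$call == "SS"),
                            n_Sr = sum(out$call == "Sr"),
                            n_rr = sum(out$call == "rr"),
                            n_NoCall = sum(out$call == "NoCall"),
                            n_failed = 0L)
  class(out) <- c("cohort_calls", "data.frame")
  out
}

#' Write cohort genotype calls to TSV
#'
#' @param calls a `cohort_calls` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
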