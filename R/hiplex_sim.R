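#' Design a tiled amplicon layout over a target region
#'
#' Tiles advance by `amp_len - overlap` so that consecutive amplicons
#' share at least `overlap` bases; the final tile is right-aligned to
#' the region end so the whole region is covered. Regions shorter than
#' one amplicon yield a single full-region tile.
#'
#' @param region_length region size in bp.
#' @param amp_len amplicon length in bp (the screen used 180--200).
#' @param overlap minimum overlap between consecutive tiles (default 50).
#' @return object of class `amplicon_design`: list with `tiles`
#'   (data.frame `start`,`end`, 1-based inclusive), `amp_len`,
#'   `overlap`.
#' @examples
#' design_tiles(460, 180, 50)$tiles
#' @export
design_tiles <- function(region_length, amp_len = 180L, overlap = 50L) {
  region_length <- as.integer(region_length)
  amp_len <- as.integer(amp_len)
  overlap <- as.integer(overlap)
  if (region_length < 1L)
    cry_error("region_length must be >= 1", "cryscreen_parameter_error")
  if (overlap >= amp_len)
    cry_error("overlap must be smaller than the amplicon length",
              "cryscreen_parameter_error")
  if (region_length <= amp_len) {
    tiles <- data.frame(start = 1L, end = region_length)
  } else {
    step <- amp_len - overlap
    starts <- seq.int(1L, region_length - amp_len, by = step)
    tiles <- data.frame(start = starts, end = starts + amp_len - 1L)
    if (tiles$end[nrow(tiles)] < region_length)
      tiles <- rbind(tiles, data.frame(start = region_length - amp_len + 1L,
                                       end = region_length))
  }
  structure(list(tiles = tiles, amp_len = amp_len, overlap = overlap),
            class = "amplicon_design")
}

#' @exportS3Method base::print
print.amplicon_design <- function(x, ...) {
  cat(sprintf("<amplicon_design> %d tile(s), amp_len %d, overlap %d\n",
              nrow(x$tiles), x$amp_len, x$overlap))
  invisible(x)
}

#' Specify the diploid truth for one synthetic sample
#'
#' Each haplotype is a set of left-anchored edits `(pos, ref, alt)` in
#' gene coordinates, the convention used by VCF: substitutions have
#' `nchar(ref) == nchar(alt)`, insertions have `alt` extending `ref`,
#' deletions have `ref` extending `alt`.
#'
#' @param sample_id sample name.
#' @param location collection-site label.
#' @param hap1,hap2 data.frames with columns `pos`, `ref`, `alt`
#'   (zero-row data.frame or `NULL` for a reference haplotype).
#' @param efficiency positive per-tile amplification multipliers
#'   (recycled to the number of tiles at simulation time).
#' @param seed per-sample RNG seed.
#' @return object of class `sample_spec`.
#' @export
sample_spec <- function(sample_id, location = "other", hap1 = NULL,
                        hap2 = NULL, efficiency = 1, seed = 1L) {
  norm <- function(h) {
    if (is.null(h) || NROW(h) == 0L)
      return(data.frame(pos = integer(), ref = character(),
                        alt = character(), stringsAsFactors = FALSE))
    h <- as.data.frame(h, stringsAsFactors = FALSE)
    stopifnot(all(c("pos", "ref", "alt") %in% names(h)))
    h$pos <- as.integer(h$pos)
    h <- h[order(h$pos), c("pos", "ref", "alt")]
    ends <- h$pos + nchar(h$ref) - 1L
    if (nrow(h) > 1L && any(h$pos[-1L] <= ends[-nrow(h)]))
      cry_error("edits on one haplotype overlap", "cryscreen_parameter_error")
    h
  }
  if (any(efficiency <= 0))
    cry_error("efficiency multipliers must be > 0",
              "cryscreen_parameter_error")
  structure(list(sample_id = sample_id, location = location,
                 haplotypes = list(norm(hap1), norm(hap2)),
                 efficiency = efficiency, seed = as.integer(seed)),
            class = "sample_spec")
}

# Apply edits to the gene sequence. Returns a per-position list of
# strings so that tile extraction in gene coordinates keeps inserted
# bases and drops deleted ones automatically.
#' @noRd
edited_pieces <- function(sequence, edits) {
  pieces <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(pieces)
  for (k in seq_len(NROW(edits))) {
    p <- edits$pos[k]; ref <- edits$ref[k]; alt <- edits$alt[k]
    if (p < 1L || p + nchar(ref) - 1L > L)
      cry_error("edit outside gene bounds", "cryscreen_bounds_error")
    if (toupper(substr(sequence, p, p + nchar(ref) - 1L)) != toupper(ref))
      cry_error("edit ref does not match gene sequence",
                "cryscreen_reference_error")
    pieces[p] <- toupper(alt)
    if (nchar(ref) > 1L) pieces[(p + 1L):(p + nchar(ref) - 1L)] <- ""
  }
  pieces
}

#' Simulate merged amplicon reads for one sample
#'
#' Emulates already merged (single, full-amplicon-length) reads: each
#' tile yields a Poisson number of reads with mean
#' `mean_depth * efficiency[tile]`, each read drawn from one of the two
#' haplotypes with equal probability and subjected to i.i.d.
#' substitution errors. Indel errors are not simulated.
#'
#' @param model a [build_gene_model()] object.
#' @param spec a [sample_spec()].
#' @param design an [design_tiles()] layout.
#' @param mean_depth expected reads per tile (>= 1).
#' @param error_rate per-base substitution error in `[0, 0.1)`.
#' @param seed RNG seed; defaults to the spec's own seed.
#' @return list with `reads` (data.frame `read_id`, `seq`), and `truth`
#'   (data.frame `sample_id`, `site_id`, `pos`, `genotype` with one row
#'   per distinct edit site, SS/Sr/rr).
#' @export
simulate_sample_reads <- function(model, spec, design, mean_depth = 100,
                                  error_rate = 0.001, seed = spec$seed) {
  stopifnot(inherits(model, "gene_model"), inherits(spec, "sample_spec"),
            inherits(design, "amplicon_design"))
  if (mean_depth < 1)
    cry_error("mean_depth must be >= 1", "cryscreen_parameter_error")
  if (error_rate < 0 || error_rate >= 0.1)
    cry_error("error_rate must be in [0, 0.1)", "cryscreen_parameter_error")
  tiles <- design$tiles
  eff <- rep_len(spec$efficiency, nrow(tiles))
  hap_pieces <- lapply(spec$haplotypes, function(h)
    edited_pieces(model$sequence, h))
  reads <- with_seed(seed, {
    out <- vector("list", nrow(tiles))
    for (t in seq_len(nrow(tiles))) {
      n <- rpois(1L, mean_depth * eff[t])
      if (n == 0L) next
      hap <- rbinom(n, 1L, 0.5) + 1L
      idx <- tiles$start[t]:tiles$end[t]
      tile_seq <- vapply(hap_pieces, function(p)
        paste(p[idx], collapse = ""), character(1))
      rs <- tile_seq[hap]
      if (error_rate > 0) rs <- add_substitution_errors(rs, error_rate)
      out[[t]] <- rs
    }
    unlist(out)
  })
  if (is.null(reads)) reads <- character()
  truth <- sample_truth(spec)
  list(reads = data.frame(
         read_id = sprintf("%s_read%06d", spec$sample_id,
                           seq_along(reads)),
         seq = reads, stringsAsFactors = FALSE),
       truth = truth)
}

#' @noRd
add_substitution_errors <- function(reads, error_rate) {
  bases <- c("A", "C", "G", "T")
  lens <- nchar(reads)
  n_err <- rbinom(length(reads), lens, error_rate)
  for (i in which(n_err > 0L)) {
    pos <- sample.int(lens[i], n_err[i])
    s <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    for (p in pos) {
      alt <- setdiff(bases, s[p])
      s[p] <- alt[sample.int(3L, 1L)]
    }
    reads[i] <- paste(s, collapse = "")
  }
  reads
}

#' Per-site diploid genotype implied by a sample spec
#'
#' @param spec a [sample_spec()].
#' @return data.frame `sample_id`, `site_id`, `pos`, `genotype`.
#' @export
sample_truth <- function(spec) {
  all_edits <- unique(do.call(rbind, spec$haplotypes))
  if (NROW(all_edits) == 0L)
    return(data.frame(sample_id = character(), site_id = character(),
                      pos = integer(), genotype = character(),
                      stringsAsFactors = FALSE))
  key <- function(h) paste(h$pos, h$ref, h$alt)
  k1 <- key(spec$haplotypes[[1]]); k2 <- key(spec$haplotypes[[2]])
  ka <- key(all_edits)
  dose <- (ka %in% k1) + (ka %in% k2)
  data.frame(sample_id = spec$sample_id,
             site_id = paste0("site_", all_edits$pos),
             pos = all_edits$pos,
             genotype = c("SS", "Sr", "rr")[dose + 1L],
             stringsAsFactors = FALSE)[order(all_edits$pos), ]
}

#' Write reads to a FASTQ file with constant base quality
#'
#' @param reads data.frame with `read_id`, `seq` (as produced by
#'   [simulate_sample_reads()]).
#' @param path output FASTQ path.
#' @param quality_char Phred+33 quality character applied to every base
#'   (default `"I"`, Q40).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  seqs <- Biostrings::DNAStringSet(setNames(reads$seq, reads$read_id))
  quals <- Biostrings::BStringSet(strrep(quality_char, nchar(reads$seq)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

#' Read a FASTQ file into the simulator's read representation
#'
#' @param path FASTQ file.
#' @return data.frame with `read_id`, `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = names(x), seq = as.character(x),
             stringsAsFactors = FALSE)
}

#' Default location labels and sizes of the screened cohort
#'
#' Forty-one samples named by trapping location: 15 PRL (Lajas), 12 PRS
#' (Salinas) and 14 PRSI (Santa Isabel).
#' @return data.frame `prefix`, `location`, `n`.
#' @export
default_cohort_layout <- function() {
  data.frame(prefix = c("PRL", "PRS", "PRSI"),
             location = c("Lajas", "Salinas", "Santa Isabel"),
             n = c(15L, 12L, 14L), stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort of tiled amplicon samples
#'
#' Draws per-sample diploid genotypes at each configured site under
#' Hardy--Weinberg proportions, assigns heterozygous edits to a random
#' haplotype, simulates per-sample reads and (optionally) writes one
#' FASTQ per sample. Per-tile efficiencies are drawn once per sample
#' from a lognormal distribution (`sdlog = 0.5`), mimicking uneven but
#' reproducible primer efficiencies in a single multiplex.
#'
#' @param model gene model (default [example_gene_model()]).
#' @param sites data.frame `site_id`, `pos`, `ref`, `alt`, `freq`
#'   (default [default_sites()] for `model`: a 2-bp GC insertion at
#'   frequency 0.33 and a 1-bp frameshift deletion at 0.32).
#' @param n_samples number of samples (default 41).
#' @param layout location layout as in [default_cohort_layout()];
#'   sample counts are rescaled when `n_samples` differs from its total.
#' @param design amplicon design (default tiles over the whole gene).
#' @param mean_depth expected reads per tile (default 100).
#' @param error_rate per-base substitution error (default 0.001).
#' @param efficiency_sdlog lognormal sdlog of per-tile efficiencies.
#' @param seed master seed; per-sample seeds are derived from it and
#'   recorded in the truth table.
#' @param dir if non-`NULL`, write one FASTQ per sample here.
#' @return list with `specs` (list of [sample_spec()]), `truth`
#'   (data.frame incl. per-sample seed), `sites`, `design`, and `files`
#'   (named FASTQ paths, when `dir` was given) or `reads` (named list of
#'   read data.frames otherwise).
#' @export
make_cohort_fixture <- function(model = example_gene_model(),
                                sites = default_sites(model),
                                n_samples = 41L,
                                layout = default_cohort_layout(),
                                design = design_tiles(nchar(model$sequence)),
                                mean_depth = 100, error_rate = 0.001,
                                efficiency_sdlog = 0.5,
                                seed = 1L, dir = NULL) {
  if (any(sites$freq < 0) || any(sites$freq > 1))
    cry_error("site frequencies must be in [0, 1]",
              "cryscreen_parameter_error")
  n_samples <- as.integer(n_samples)
  n_loc <- round(layout$n / sum(layout$n) * n_samples)
  n_loc[1L] <- n_samples - sum(n_loc[-1L])
  ids <- unlist(lapply(seq_len(nrow(layout)), function(i)
    sprintf("%s_%d", layout$prefix[i], seq_len(n_loc[i]))))
  locs <- rep(layout$location, n_loc)

  specs <- vector("list", n_samples)
  gts <- with_seed(derive_seed(seed, "cohort_genotypes"), {
    m <- matrix(0L, n_samples, nrow(sites))
    for (s in seq_len(nrow(sites))) {
      f <- sites$freq[s]
      m[, s] <- sample(0:2, n_samples, replace = TRUE,
                       prob = c((1 - f)^2, 2 * f * (1 - f), f^2))
    }
    m
  })
  hap_of_het <- with_seed(derive_seed(seed, "het_phase"),
                          matrix(sample(1:2, n_samples * nrow(sites),
                                        replace = TRUE),
                                 n_samples, nrow(sites)))
  for (i in seq_len(n_samples)) {
    h <- list(NULL, NULL)
    for (s in seq_len(nrow(sites))) {
      edit <- sites[s, c("pos", "ref", "alt")]
      if (gts[i, s] == 2L) {
        h[[1]] <- rbind(h[[1]], edit); h[[2]] <- rbind(h[[2]], edit)
      } else if (gts[i, s] == 1L) {
        w <- hap_of_het[i, s]
        h[[w]] <- rbind(h[[w]], edit)
      }
    }
    eff <- with_seed(derive_seed(seed, paste0("eff_", ids[i])),
                     rlnorm(nrow(design$tiles), 0, efficiency_sdlog))
    specs[[i]] <- sample_spec(ids[i], locs[i], h[[1]], h[[2]],
                              efficiency = eff,
                              seed = derive_seed(seed, paste0("reads_", ids[i])))
  }

  truth_list <- vector("list", n_samples)
  out_reads <- if (is.null(dir)) vector("list", n_samples) else NULL
  files <- if (!is.null(dir)) character(n_samples) else NULL
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_len(n_samples)) {
    sim <- simulate_sample_reads(model, specs[[i]], design,
                                 mean_depth = mean_depth,
                                 error_rate = error_rate)
    tr <- data.frame(sample_id = ids[i], location = locs[i],
                     stringsAsFactors = FALSE)
    tr <- cbind(tr, setNames(as.data.frame(t(gts[i, , drop = TRUE])),
                             sites$site_id))
    tr$seed <- specs[[i]]$seed
    truth_list[[i]] <- tr
    if (is.null(dir)) {
      out_reads[[i]] <- sim$reads
    } else {
      files[i] <- file.path(dir, paste0(ids[i], ".fastq"))
      write_fastq(sim$reads, files[i])
    }
  }
  truth <- do.call(rbind, truth_list)
  truth[sites$site_id] <- lapply(truth[sites$site_id], function(d)
    c("SS", "Sr", "rr")[d + 1L])
  res <- list(specs = specs, truth = truth, sites = sites, design = design)
  if (is.null(dir)) {
    res$reads <- setNames(out_reads, ids)
  } else {
    res$files <- setNames(files, ids)
  }
  res
}

#' Write a cohort truth table to TSV
#'
#' @param truth truth data.frame from [make_cohort_fixture()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an amplicon design as a BED-like TSV (1-based inclusive)
#'
#' @param design an [design_tiles()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_design_tsv <- function(design, path) {
  write.table(design$tiles, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
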