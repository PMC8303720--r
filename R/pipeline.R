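#' Validate an end-to-end pipeline configuration
#'
#' @param gene_fasta gene reference FASTA.
#' @param exon_gff GFF3 exon file for the gene.
#' @param fastq_dir directory of demultiplexed per-sample FASTQs.
#' @param vcf multi-sample VCF of called variants.
#' @param site_tsv genotyping-site definitions
#'   ([read_insertion_sites()] format); the first site is genotyped.
#' @param susceptible optional one-column file of amino-acid changes
#'   present in susceptible reference cDNAs.
#' @param gene_id seqid shared by FASTA and GFF (default: FASTA record
#'   name).
#' @param known_alleles allele keys treated as already known (default
#'   `"D740A"`-style keys come from `susceptible`; may be empty).
#' @param pgeno list of [genotype_site()] threshold overrides.
#' @param filter a [filter_config()].
#' @param rounding frequency display mode for the report
#'   (`"round"`/`"truncate"`).
#' @param freq_mode [allele_frequency()] mode for the report.
#' @param seed pipeline seed (recorded; stages are deterministic).
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(gene_fasta, exon_gff, fastq_dir, vcf,
                            site_tsv, susceptible = NULL, gene_id = NULL,
                            known_alleles = character(),
                            pgeno = list(), filter = filter_config(),
                            rounding = "round", freq_mode = "standard",
                            seed = 1L) {
  paths <- c(gene_fasta = gene_fasta, exon_gff = exon_gff,
             fastq_dir = fastq_dir, vcf = vcf, site_tsv = site_tsv)
  if (!is.null(susceptible)) paths["susceptible"] <- susceptible
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    cry_error(paste("missing input path(s):",
                    paste(sprintf("%s=%s", names(missing), missing),
                          collapse = ", ")),
              "cryscreen_config_error")
  structure(list(gene_fasta = gene_fasta, exon_gff = exon_gff,
                 fastq_dir = fastq_dir, vcf = vcf, site_tsv = site_tsv,
                 susceptible = susceptible, gene_id = gene_id,
                 known_alleles = known_alleles, pgeno = pgeno,
                 filter = filter, rounding = rounding,
                 freq_mode = freq_mode, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the end-to-end screen: genotyping, filtering, annotation,
#' phenotype prediction and cohort statistics
#'
#' Stages: (1) k-mer genotyping of the configured insertion site over
#' the FASTQ directory; (2) VCF filter cascade and bi-allelic
#' selection; (3) effect annotation against the gene model and novelty
#' flagging; (4) allele classification and per-sample phenotype
#' prediction from the k-mer calls; (5) cohort statistics (allele
#' frequency, per-location carrier summary). All stages are
#' deterministic given the inputs, so repeated runs write identical
#' reports.
#'
#' @param config a [pipeline_config()].
#' @param out_dir directory for report files (created if needed);
#'   `NULL` skips writing.
#' @return list of class `screen_report`: `calls`, `variants`
#'   (filtered bi-allelic set), `annotations`, `classes`,
#'   `predictions`, `stats` (list with `n_*` counts, `allele_frequency`
#'   raw + displayed, `carrier_summary`), `files` (paths written).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cry_error(sprintf("[%s] %s", name, conditionMessage(e)),
                "cryscreen_stage_error")
    })
  }
  gene <- stage("gene_model", {
    seq <- read_gene_fasta(config$gene_fasta, config$gene_id)
    gid <- if (is.null(config$gene_id)) names(seq) else config$gene_id
    exons <- read_exon_gff(config$exon_gff, gid)
    build_gene_model(gid, unname(seq), exons, partial = TRUE)
  })
  site <- stage("site", read_insertion_sites(config$site_tsv)[[1L]])
  calls <- stage("pgeno", do.call(genotype_cohort,
    c(list(config$fastq_dir, site), config$pgeno)))
  variants <- stage("variant_filter", {
    v <- read_variant_vcf(config$vcf)
    filtered <- filter_variants(v, config$filter)
    bi <- select_biallelic(filtered)
    attr(bi, "attrition") <- rbind(
      attr(filtered, "attrition"),
      data.frame(stage = "biallelic", input = nrow(filtered$fix),
                 removed = nrow(filtered$fix) - nrow(bi$fix)))
    bi
  })
  annotations <- stage("effect_annotator", {
    a <- annotate_variant(gene, variants, table_compat = TRUE)
    susceptible <- if (is.null(config$susceptible)) character()
                   else read_susceptible_changes(config$susceptible)
    filter_novel(a, susceptible)
  })
  classes <- stage("resistance_caller", classify_alleles(annotations))
  predictions <- stage("resistance_caller", {
    gt <- data.frame(sample_id = calls$sample_id,
                     stringsAsFactors = FALSE)
    gt[[site$site_id]] <- calls$call
    site_class <- data.frame(allele = site$site_id,
                             category = "TRUNCATING",
                             stringsAsFactors = FALSE)
    predict_cohort(gt, rbind(classes, site_class))
  })
  stats <- stage("popstats", {
    ok <- is.na(calls$error) & calls$call != "NoCall"
    n_het <- sum(calls$call[ok] == "Sr")
    n_hom <- sum(calls$call[ok] == "rr")
    n_tot <- sum(ok)
    f <- allele_frequency(n_het, n_hom, max(n_tot, 1L),
                          mode = config$freq_mode)
    tab <- cohort_table(data.frame(
      sample_id = calls$sample_id,
      location = location_from_sample(calls$sample_id),
      kmer = calls$call, stringsAsFactors = FALSE))
    list(n_samples = nrow(calls), n_called = n_tot, n_het = n_het,
         n_hom = n_hom,
         allele_frequency = f,
         allele_frequency_display =
           format_frequency(f, mode = config$rounding),
         carrier_summary = carrier_summary(tab, "kmer"),
         summary_counts = attr(calls, "summary"))
  })
  files <- character()
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    files <- c(
      calls = write_calls_tsv(calls, file.path(out_dir, "calls.tsv")),
      annotations = write_annotation_tsv(
        annotations, file.path(out_dir, "annotations.tsv")),
      predictions = {
        p <- file.path(out_dir, "predictions.tsv")
        write.table(predictions, p, sep = "\t", quote = FALSE,
                    row.names = FALSE); p
      },
      attrition = write_attrition_tsv(
        variants, file.path(out_dir, "attrition.tsv")),
      summary = {
        p <- file.path(out_dir, "summary.txt")
        writeLines(c(
          sprintf("samples\t%d", stats$n_samples),
          sprintf("called\t%d", stats$n_called),
          sprintf("het\t%d", stats$n_het),
          sprintf("hom\t%d", stats$n_hom),
          sprintf("allele_frequency\t%.6f", stats$allele_frequency),
          sprintf("allele_frequency_display\t%.4f",
                  stats$allele_frequency_display),
          sprintf("variants_biallelic\t%d", nrow(variants$fix)),
          sprintf("seed\t%d", config$seed)), p); p
      })
  }
  # attrition carried on the pre-biallelic filter result
  structure(list(gene = gene, site = site, calls = calls,
                 variants = variants, annotations = annotations,
                 classes = classes, predictions = predictions,
                 stats = stats, files = files),
            class = "screen_report")
}

#' @exportS3Method base::print
print.screen_report <- function(x, ...) {
  cat(sprintf(paste0("<screen_report> %d sample(s); %d/%d het/hom at ",
                     "'%s'; F = %.4f; %d bi-allelic variant(s)\n"),
              x$stats$n_samples, x$stats$n_het, x$stats$n_hom,
              x$site$site_id, x$stats$allele_frequency,
              nrow(x$variants$fix)))
  invisible(x)
}
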