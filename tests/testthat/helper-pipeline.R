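# Builds a complete set of pipeline inputs (FASTA, GFF, FASTQ dir,
# VCF, site TSV) for the synthetic gene under one seed.
build_pipeline_inputs <- function(root, seed = 123L, n_samples = 8L,
                                  mean_depth = 200) {
  m <- example_gene_model()
  sites <- default_sites(m)
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  fastq_dir <- file.path(root, "fastq")
  fx <- make_cohort_fixture(m, sites, n_samples = n_samples,
                            mean_depth = mean_depth, error_rate = 0.001,
                            seed = seed, dir = fastq_dir)
  write_gene_fasta(m$sequence, m$gene_id, file.path(root, "gene.fasta"))
  write_exon_gff(m$exons, m$gene_id, file.path(root, "gene.gff3"))
  write_truth_vcf(fx$truth, sites, file.path(root, "cohort.vcf"))
  ins <- sites[sites$site_id == "mut_ins", ]
  site <- site_from_model(m, ins$pos, "GC", site_id = "mut_ins")
  writeLines(c("site_id\tleft_flank\tinserted\tright_flank\tmax_mm",
               sprintf("mut_ins\t%s\tGC\t%s\t2", site$left_flank,
                       site$right_flank)),
             file.path(root, "site.tsv"))
  list(root = root, fx = fx, model = m, sites = sites)
}
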