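test_that("codon-change classification covers all effect classes", {
  expect_equal(classify_codon_change("aCg", "aTg"), "MISS")
  expect_equal(classify_codon_change("Gaa", "Taa"), "NON")
  expect_equal(classify_codon_change("gat", "gCGat"), "SHIFT")
  expect_equal(classify_codon_change("tcc", "tcc"), "SYN")
  expect_equal(classify_codon_change("tca", "tct"), "SYN")
  expect_equal(classify_codon_change("tgcatggtg", ""), "INFRAME")
  expect_equal(classify_codon_change("tgcatggtg", "", table_compat = TRUE),
               "SHIFT")
  expect_equal(classify_codon_change("gga", ""), "INFRAME")
})

test_that("published mutation rows reproduce class and notation", {
  t2 <- load_fixture("table2")
  mm <- split_mutation(t2$mutation)
  codon_no <- as.integer(gsub("[^0-9]", "", t2$aa_change))
  # notation known to be printed without the frameshift stop marker,
  # or (A15) with a marker on an in-frame deletion
  aa_excluded <- t2$position %in% c(38L, 42L, 9122L)
  for (i in seq_len(nrow(t2))) {
    expect_equal(classify_codon_change(mm$ref_codons[i], mm$alt_codons[i],
                                       table_compat = TRUE),
                 t2$class[i], info = paste("position", t2$position[i]))
    if (!aa_excluded[i]) {
      expect_equal(format_aa_change(mm$ref_codons[i], mm$alt_codons[i],
                                    codon_no[i]),
                   t2$aa_change[i], info = paste("position", t2$position[i]))
    }
  }
})

test_that("annotation against a gene model handles each variant kind", {
  m <- tiny_model()  # CDS ATG GTA CAG TAA, intron 6..15
  # synonymous: GTA -> GTG at codon 2 (cds 4..6 => gene 4,5,16)
  syn <- annotate_variant(m, data.frame(pos = 16, ref = "A", alt = "G"))
  expect_equal(syn$effect_class, "SYN")
  expect_false(syn$truncating)
  # missense: GTA -> GAA (cds 5, gene 5)
  mis <- annotate_variant(m, data.frame(pos = 5, ref = "T", alt = "A"))
  expect_equal(mis$effect_class, "MISS")
  expect_equal(mis$aa_change, "V2E")
  expect_equal(mis$codon_display, "gTa/gAa")
  # nonsense: CAG -> TAG (cds 7, gene 17)
  non <- annotate_variant(m, data.frame(pos = 17, ref = "C", alt = "T"))
  expect_equal(non$effect_class, "NON")
  expect_true(non$truncating)
  expect_equal(non$aa_change, "Q3 *")
  # frameshift insertion after gene 4 (codon 2 base 1)
  ins <- annotate_variant(m, data.frame(pos = 4, ref = "G", alt = "GCG"))
  expect_equal(ins$effect_class, "SHIFT")
  expect_true(ins$truncating)
  # in-frame whole-codon deletion (codon 3 = gene 17..19 "CAG",
  # anchored at gene 16)
  del <- annotate_variant(m, data.frame(pos = 16, ref = "ACAG", alt = "A"))
  expect_equal(del$effect_class, "INFRAME")
  expect_false(del$truncating)
  expect_equal(del$aa_change, "Q3")
  expect_equal(annotate_variant(m, data.frame(pos = 16, ref = "ACAG",
                                              alt = "A"),
                                table_compat = TRUE)$effect_class, "SHIFT")
  # intronic and splice-region
  intr <- annotate_variant(m, data.frame(pos = 10, ref = "C", alt = "T"))
  expect_equal(intr$effect_class, "INTRONIC")
  expect_true(intr$splice_region)  # intron length 10, always within 8
  # reference mismatch
  expect_error(annotate_variant(m, data.frame(pos = 5, ref = "G",
                                              alt = "A")),
               class = "cryscreen_reference_error")
})

test_that("synonymy is equivalent to unchanged translation", {
  set.seed(77)
  bases <- c("A", "C", "G", "T")
  for (i in 1:200) {
    ref <- paste(sample(bases, 3, replace = TRUE), collapse = "")
    alt <- ref
    at <- sample(3, 1)
    substr(alt, at, at) <- sample(setdiff(bases, substr(ref, at, at)), 1)
    cls <- classify_codon_change(ref, alt)
    same_aa <- as.character(translate_dna(ref, quiet = TRUE)) ==
      as.character(translate_dna(alt, quiet = TRUE))
    expect_equal(cls == "SYN", same_aa)
  }
})

test_that("frameshift is equivalent to indel length not divisible by 3", {
  set.seed(78)
  bases <- c("A", "C", "G", "T")
  for (i in 1:200) {
    ref <- paste(sample(bases, 3, replace = TRUE), collapse = "")
    k <- sample(1:7, 1)
    alt <- paste0(substr(ref, 1, 1),
                  paste(sample(bases, k, replace = TRUE), collapse = ""),
                  substr(ref, 2, 3))
    cls <- classify_codon_change(ref, alt)
    expect_equal(cls == "SHIFT", k %% 3 != 0)
  }
})

test_that("codons containing N are excluded from effect calls", {
  m <- build_gene_model("gn", "ATGNNNTAA", cbind(1, 9), partial = TRUE)
  out <- annotate_variant(m, data.frame(pos = 4, ref = "N", alt = "A"))
  expect_equal(out$effect_class, "NONCODING")
})

test_that("novelty flags respect the susceptible list without deleting", {
  t2 <- load_fixture("table2")
  ann <- data.frame(aa_change = t2$aa_change, effect_class = t2$class,
                    stringsAsFactors = FALSE)
  out <- filter_novel(ann, character())
  expect_equal(sum(out$novel), 24L)
  out2 <- filter_novel(ann, c("T14M", "D740A"))
  expect_equal(nrow(out2), 24L)
  expect_false(out2$novel[out2$aa_change == "T14M"])
  expect_false(out2$novel[out2$aa_change == "D740A *"])
  expect_equal(sum(out2$novel), 22L)
})
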