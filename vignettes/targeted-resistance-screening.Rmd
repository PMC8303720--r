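---
title: "Methods: targeted amplicon screening for Cry1F resistance alleles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted amplicon screening for Cry1F resistance alleles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryscreen)
```

## Scope and model

`cryscreen` implements the analysis side of a tiled-amplicon
resistance screen of the fall armyworm *SfABCC2* gene. Truncation of
the SfABCC2 ABC transporter removes the midgut receptor of the Cry1F
toxin, so nonsense and frameshift alleles are candidate resistance
alleles and homozygotes for them (or trans-heterozygotes combining two
different truncating alleles) are predicted Cry1F-resistant. The
package covers five cooperating pieces: a gene model with coordinate
arithmetic, a read simulator of the tiled amplicon design, the k-mer
flank genotyper for a known 2-bp insertion, a variant filter cascade
with codon-level effect annotation, and cohort statistics.

## Gene model

A `gene_model` couples a plus-strand, gene-local sequence with ordered
exon intervals (1-based inclusive, matching how positions are reported
in mutation tables). The CDS is the concatenation of exon substrings;
complete models must be an open reading frame (ATG start, length a
multiple of three, one terminal stop), while `partial = TRUE` relaxes
this for references containing unsequenced, N-filled regions — codons
containing N translate to `X` and are excluded from effect
classification rather than failing. Reverse-strand genes and multiple
isoforms are out of scope. Exon intervals are consumed from a GFF3
file rather than recomputed by spliced alignment.

One coordinate contract deserves note: positions that fall before the
first exon or after the last are reported as `outside` rather than
raising, and positions beyond the sequence end are likewise `outside`;
only positions below 1 raise a bounds error. This makes the mapper
total over plausible scan ranges.

## Read simulator

The simulator emulates data as it looks *after* read merging: single
full-amplicon-length reads. `design_tiles()` advances tiles by
`amp_len − overlap` (defaults 180 bp and 50 bp, the screen's design
parameters) and right-aligns a final tile so the region is always
covered. Per sample, each tile yields a Poisson number of reads with
mean `mean_depth × efficiency`, drawn from the two haplotypes with
equal probability, with i.i.d. substitution errors.

Defaults are the study's conditions, chosen once:

* 41 samples split 15/12/14 across the three trapping locations
  (sample names `PRL_*`, `PRS_*`, `PRSI_*`);
* mean per-tile depth 100 (the screen sequenced to more than 100× per
  target);
* per-tile efficiency multipliers drawn from a lognormal with
  `sdlog = 0.5`. Multiplex PCR efficiencies are only described
  qualitatively (reproducible, uneven, up to ~1000× on some targets);
  a lognormal is the usual model for multiplicative amplification
  noise and 0.5 gives roughly a 4-fold central spread, enough that the
  coverage floor of the genotyper is actually exercised;
* substitution error 0.001, a typical post-merge short-read error
  scale; the test suites also run at 0 and 0.01;
* two default sites in the synthetic gene: a 2-bp GC insertion at
  population frequency 0.33 (mirroring the known resistance insertion)
  and a 1-bp frameshift deletion at 0.32 (mirroring the most common
  novel frameshift allele). Genotypes are drawn under Hardy–Weinberg
  proportions.

What the simulator does *not* model: indel sequencing errors (kept out
so the genotyper's substitution-error behaviour is testable in
isolation), primer thermodynamics and primer-dimer artifacts, PCR
chimeras, quality-score profiles (qualities are constant), and in-read
barcodes (demultiplexing is represented by one FASTQ per sample).
Passing tests on simulated cohorts therefore demonstrate the
statistical correctness of the calling and filtering rules under this
error model, not robustness to alignment artifacts or systematic
base-calling error in real data.

The synthetic gene (`example_gene_model()`) is a fixed 1520 bp,
five-exon construct with a 1200 bp ORF, generated from an internal
constant seed; it is a synthetic stand-in, not the real gene sequence.

## k-mer flank genotyper

A genotyping site is two 10-mer flanks around a known insertion. A
read is mutant evidence when `left + inserted + right` occur
contiguously, wild-type evidence when `left + right` are contiguous;
each flank tolerates up to 2 mismatches while the inserted bases must
match exactly (the mismatch budget models unknown flanking variation,
not uncertainty about the insertion itself). Offsets are scanned left
to right, the mutant layout is tried before the wild type at each left
flank hit, and the reverse complement is scanned when the forward
orientation is uninformative — merged reads have arbitrary
orientation. N and any non-DNA symbol count as mismatches.

Calling uses informative reads only ("coverage" means reads in which
both flanks were located, the natural reading of counting matching
reads): below 40 the sample is NoCall; otherwise with mutant
proportion `p`, `p ≤ 0.15` is SS (the carrier rule is strictly "more
than 15%"), `p ≥ 0.85` is rr, and anything between is Sr. The
published rule fixes only the 15% carrier threshold; the homozygote
boundary is set symmetric at 85% and both are configurable — symmetry
is the neutral default and tolerates moderate allele-specific
amplification. At exact boundaries, 0.15 is SS and 0.85 is rr.

Accuracy bookkeeping follows genotyping convention: *call rate* is the
fraction of samples not NoCall, *accuracy* is the fraction of called
samples matching truth. With the site covered by a single tile and
lognormal efficiency skew, a few percent of samples at mean depth 100
fall under the 40× informative-read floor; these are the coverage rule
working as designed, not miscalls, and they are excluded from cohort
allele-frequency estimates exactly as a NoCall sample would be in
practice.

The scanner is a brute-force all-offsets Hamming search written in
C++ for throughput; the test suite pins it against an independent R
implementation on random and planted reads.

## Variant filter cascade

The filter consumes a multi-sample VCF (any caller; calling itself is
out of scope) with per-sample `GT` and `AD` fields and applies, in
order: site quality strictly above 40; qualifying genotype support
(total allele depth ≥ 8 with every called allele's depth ≥ 2) in at
least 25% of samples; cohort alternate allele frequency ≥ 5%,
computed on allele counts across called genotypes. Records lacking
`AD` are flagged and removed with a reason. Comparators follow the
published wording exactly: quality is strict, the depth and frequency
rules are inclusive. Multi-allelic records are dropped whole by
`select_biallelic()`, not decomposed into alleles. Per-stage attrition
counts are attached so the cascade's bookkeeping always sums to its
input. The published accession-scale attrition (2006 → 1861 → 1333
variants) requires the original read data and an external caller, so
the suite characterises the cascade by its properties instead:
idempotence and monotonicity under threshold tightening over
randomized toy VCFs.

A looser alternate-allele-depth setting (≥ 3) is mentioned in parts of
the published analysis; the stricter ≥ 2 is the default here and both
are reachable through `filter_config()`.

## Effect annotation

Variants are classified against the gene model:
substitutions by codon translation into SYN/MISS/NON; coding indels
into SHIFT when the length difference is not a multiple of three and
INFRAME otherwise; intronic positions INTRONIC with a splice-region
flag. NON and SHIFT set `truncating`. The published table labels
in-frame deletions SHIFT, so a `table_compat` mode maps INFRAME to
SHIFT for reproducing its tallies while the annotator retains the
distinction internally (an in-frame deletion is never `truncating`).

Notation follows the table's typography. Codon context is lowercase
with changed or inserted bases uppercase. Amino-acid changes render as
`refAA + codon + altAA` for substitutions (a gained stop as `" *"`),
deleted residues plus position for deletions, and for insertions the
reference residue, position, and the translation of the altered codon
string with `" *"` appended when the frame shifts. Some published alt
codon strings abbreviate away the trailing reference bases; since the
typography marks retained reference bases lowercase, the formatter
pads such strings with the unconsumed reference tail before
translating, which is what makes multi-residue frameshift notations
come out right. Frameshift notation stops at the altered codons — the
actual downstream premature-stop position is not scanned, because the
notation does not encode it.

The splice-region window is ±8 intronic bases (containing the 2-base
donor/acceptor cores) and 3 exonic bases around each internal
junction, configurable; the published analysis flags a splice-region
mutation without stating its window, so a SnpEff-like default is used.

Two printed rows are internally inconsistent (a stop marker on an
in-frame 3-bp deletion; stop markers missing from two frameshift
rows). The packaged fixture preserves the printed strings; the
formatter's own output differs on exactly those rows and the test
suite documents them as exclusions rather than imitating the
inconsistency.

## Resistance phenotype prediction

Alleles classify as TRUNCATING (NON/SHIFT), MISSENSE_CANDIDATE (effect
on toxin binding unknown — never drives a resistance verdict), or
NON_CANDIDATE. Per sample, verdicts are evaluated in priority order:
any homozygous truncating allele predicts resistance; two or more
distinct heterozygous truncating alleles (none homozygous) make a
*candidate* via complementation — candidate, not confirmed, because
short reads cannot phase the two alleles; a single heterozygous
truncating allele is a carrier. Tallies over the mutation table are
computed in table-compat class mode with already-known alleles
excluded from the frameshift count.

## Cohort statistics

Both allele-frequency estimators are first class because published
values mix them: the screening formula as typeset doubles the
heterozygote count, `(2·het + hom)/2N`, while the standard estimator
counts allele copies, `(2·hom + het)/2N`; they coincide when
`het == hom`. The default is `standard`; reproduction scripts pin the
mode per figure. Display likewise mixes 4-decimal truncation and
rounding across figures, so operations return full precision and
`format_frequency()` takes an explicit mode. A documented consequence
of the printed formula is that mutant and wild-type frequencies need
not sum to one.

Concordance counts identical call labels over samples aligned by id.
Carrier summaries report integer percentages per location alongside
raw fractions. Genotype PCA mean-imputes missing doses per site (the
simple standard for genotype matrices; dropping sites is available),
centres columns, and projects from the SVD. The association scan
cross-tabulates allele counts (2 per called sample) against a binary
label and applies Fisher's exact test — substituted deliberately for
an unspecified logistic-regression implementation because an exact
test has defensible behaviour at n = 41; it is property-tested
(null behaviour, separation, permutation type-I error), not
value-matched to any published Manhattan plot.

## Determinism and problem sizes

All randomness descends from explicit seeds; per-sample seeds are
derived from the master seed and recorded in the truth table, and the
pipeline writes byte-identical reports on repeated runs with one
configuration. The test suite sizes are: oracle equivalence on 10,000
random reads; a 200-sample cohort at mean depth 100 and 1% error for
genotyper recovery; 1,000 randomized toy VCFs for the filter
properties; 1,000 label permutations for the association scan's
type-I error. Exact noiseless truth-recovery tests run at mean depth
200, where the informative-coverage floor is essentially never
triggered.

## Known limitations

* Insertion sites only in the k-mer genotyper (as in the original
  screen); arbitrary SNP/deletion flank genotyping and quality-aware
  weighting are out of scope.
* A previously described resistance allele caused by a highly
  repetitive insertion driving aberrant splicing is undetectable by
  this amplicon design, and so also outside this package's reach.
* The filter cascade consumes VCFs; it does not call variants, phase
  haplotypes, or model admixture/population structure beyond PCA.
* Simulated reads are substitution-error only and constant-quality;
  conclusions about indel-error robustness cannot be drawn from the
  simulator.
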