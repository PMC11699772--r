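---
title: "Allele-resolved expression and chromatin analysis with xciseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-resolved expression and chromatin analysis with xciseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xciseq)
library(dplyr)
```

## The problem

In female mammals one of the two X chromosomes is transcriptionally
silenced (X-chromosome inactivation, XCI), initiated when the long
non-coding RNA *Xist* is upregulated on the future inactive X (Xi). In a
hybrid mouse ES cell model (129 x *castaneus*) carrying a *Tsix*
transcriptional stop on the 129 allele, the 129 X is always chosen as the
Xi, so strain-diagnostic SNPs let every sequencing read be attributed to
the Xi or the active X (Xa). `xciseq` implements the complete
allele-resolved analysis for this design — and, because real hybrid data
are large and external, a fully parameterised synthetic hybrid-cross
generator with truth sets so that every stage of the pipeline is testable
on a desk.

The pipeline has two arms:

* **RNA**: strain VCF filtering, pseudo-diploid genome construction,
  MAPQ-filtered read tagging into G1/G2/CF/UA, gene-level total and
  allelic counting, TPM/CPM normalization, allelic ratios, 1.25-fold
  Xi/Xa dysregulation calls, silencing-class summaries, Xist induction
  contrasts, and a differential-expression substitute at FDR 0.1 /
  2-fold.
* **CUT&RUN**: paired-fragment filters (same chromosome, fragment
  < 1 kb), fragment-level allele tagging, RPKM coverage tracks with IgG
  subtraction, threshold peak calling with signal filters, ±5 kb TSS
  windows, gene-level peak overlap and Venn counts, and Xi-specific peak
  gain calling with the wild type as background.

## Model and conventions

**Coordinates.** All internal interval arithmetic is 0-based half-open
(`start`, `end` columns); SNP positions are 1-based as in VCF. Conversions
happen only at I/O boundaries (`read_vcf()`, `write_bedgraph()`, ...).

**Haplotypes.** Haplotype 1 is the 129-analog maternal strain, which is
always the Xi in the skewed design; haplotype 2 is the *cast*-analog Xa
strain. The pseudo-diploid pair substitutes each retained SNP allele into
a copy of the reference, so both genomes share reference coordinates and
differ from each other exactly at diagnostic SNP sites (indels are
filtered out, never lifted over).

**Tagging.** A read's (or pooled fragment pair's) bases at covered SNP
sites are matched against both alleles. Only haplotype-1 matches: `G1`;
only haplotype-2: `G2`; both: `CF` (conflicting); no valid observation:
`UA`. A base matching neither allele is treated as invalid evidence (most
likely a sequencing error) and ignored, so an all-invalid read is `UA`,
not `CF`. CF reads are excluded from allelic counts but retained in the
summaries; a three-category rollup (`uncertain = CF + UA`) is also
reported for RNA libraries. Because simulated alignments are gapless and
carry true coordinates, comparing base evidence at SNP sites is exactly
equivalent to mapping against both pseudo-genomes and comparing the
alignments; the test suite asserts this equivalence against an
independent base-by-base oracle.

**Normalization.** TPM divides each gene's count by its summed exon
length in kb and rescales per library to 1e6; CPM omits the length term.
Coverage tracks use the standard RPKM form
`count / (bin kb x mapped units in millions)`; a published variant of
this formula with a 1e8 denominator constant is typographically garbled
and the standard per-kilobase-per-million form is what the cited
bigWig-generation tools compute, so that is what `rpkm_track()`
implements. IgG subtraction is binwise with a floor at zero — negative
signal has no meaning for threshold peak calling.

**Differential expression.** `differential_expression()` is a documented
substitute for a negative-binomial fit, not a replication: DESeq-style
median-of-ratios size factors, a per-gene two-sided Welch t-test on
`log2(normalized + 0.5)`, Benjamini–Hochberg correction, and the study's
thresholds (FDR ≤ 0.1, |fold| ≥ 2). With two replicates per group the
Welch statistic has roughly two degrees of freedom, which bounds how
small p-values can get: a power calculation (t ≈ log-fold / se with
se ≈ sqrt(1/µ)/ln 2 per library) shows that 80% power for 4-fold shifts
under BH correction over a few hundred genes needs mean counts around
2000 per gene. The calibration tests therefore simulate at that depth;
the null-calibration tests run at ordinary depth, where the substitute is
conservative (far fewer than 10% of null genes flagged).

**Peak calling.** `call_peaks()` substitutes for a sparse-signal peak
caller operating on bedGraph tracks: without a control the threshold is a
quantile (default 0.99) of nonzero bin values; with a control, a bin is
supra-threshold when it exceeds the control's bin. Contiguous
supra-threshold bins merge, and single-bin gaps are bridged. Two
analysis parameters matter and are chosen per experiment:

* the threshold quantile `q` should satisfy `1 - q` > (expected enriched
  fraction of nonzero bins), otherwise the adaptive threshold climbs into
  the enriched domains and fragments them — recovery experiments with
  ~2% of bins enriched use `q = 0.95`;
* called peaks are then filtered on total signal, mirroring the fixed
  post-call signal cutoffs used for comparing samples (10 for
  differentiated H3K27me3, 5 for the lower-coverage KDM6A sample). On
  simulated tracks, whose units are RPKM, the scale-free analogue `10 x
  mean nonzero bin value` separates planted domains (hundreds of bins of
  high signal) from single-bin noise excursions by about two orders of
  magnitude. `run_pipeline()` exposes this as `peak_signal_mult`
  (default 3 x the calling threshold).

**Allelic fold changes.** Gene TPM is apportioned to the Xi and Xa by the
informative-read fraction `g1/(g1+g2)`; condition values average
replicate clones before the ratio; calls use the 1.25-fold threshold
(`increased` at ≥ 1.25, `decreased` at ≤ 0.8). A zero reference mean with
nonzero test mean is reported as an infinite, flagged, increased fold.
The allelic ratio itself is reported both as the bounded fraction
`g1/(g1+g2)` and as the raw odds `g1/g2`. The 1.25-fold call operates on
clone-averaged values by default; a per-clone analysis is available by
passing a restricted library table.

## What the generator emulates

`sim_config()` fixes the genome and sequencing model; `xci_program()`
fixes the biology:

| parameter | default | why |
|---|---|---|
| `snp_density` | 0.008 /bp | 129 x *cast* divergence is roughly one diagnostic SNP per 125–150 bp |
| `read_length` | 75 bp | the study's single-end RNA reads and paired CUT&RUN mates |
| `indel_fraction`, `lowqual_fraction` | 0.10 each | enough planted filter violations to exercise the variant filters |
| `lowmapq_fraction` | 0.05 | MAPQ < 30 alignments to exercise the mapping filter deterministically |
| `fragment_mean/sd` | 250 / 60 bp | nucleosome-scale CUT&RUN fragments |
| `heavy_tail_fraction` | 0.02 | > 1 kb fragments violating the length filter |
| `chimera_fraction` | 0.01 | cross-chromosome mate pairs |
| `xi_fractions` | early 0.02, intermediate 0.05, late 0.10, escape 0.30 | residual Xi output after differentiation in the wild type rises with silencing timing; escape genes stay partially expressed from the Xi |
| `ko_xi_upshift`, `ko_upshift_prob` | 1.5, 0.8 | the knockout program: impaired silencing raises Xi output 1.5-fold for 80% of silenced genes |
| `xist_induction` | wt 6, ko 2.5 | differentiation-induced Xist fold changes (D15/D0) |
| `xist_xi_fraction` | 0.95 | Xist is expressed from the Xi after XCI |

Sequencing depth is deliberately *not* fixed by the program — it is an
experiment-level choice. The statistical experiments in the test suite
state their depths in code and they were chosen by binomial arithmetic:
estimating a planted Xi fraction within ±0.05 needs several hundred
informative (G1+G2) reads per gene (sd at 0.5 with n = 600 is ≈ 0.02),
and calling a 1.5-fold Xi shift against a residual fraction of 0.02–0.10
needs on the order of 100+ Xi-attributed reads per gene per condition, so
those simulations use 30k–400k reads per library over a few dozen genes.

All randomness flows from the config seed through per-stage sub-streams,
so identical configs give byte-identical outputs (asserted down to file
checksums). Every read and fragment appears exactly once in the truth
set, with planted violations flagged.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: no splice structure (reads stay within
exons), no PCR duplicates, no coverage biases (GC, mappability), no
quality strings, flat per-base error rate, gapless alignments with true
coordinates (no aligner ambiguity), regular exon geometry, and
independent reads (no fragment-level overdispersion beyond the planted
mixtures). Results about filter exactness, normalization identities and
estimator calibration transfer to real data; absolute recovery rates do
not.

## Numerical choices and degenerate inputs

* Variant filtering precedence: indel > multiallelic > low-quality >
  non-diagnostic, so removal counts sum to the input size. Duplicate
  records are deduplicated when identical and an error when conflicting.
* "Low quality" means VCF `FILTER != PASS`, optionally tightened with a
  QUAL threshold; sites overlapping filtered indels are *not* excluded.
* Boundary semantics are inclusive where the study states them: MAPQ 30
  is kept, fragment length 1000 is dropped (strict "< 1 kb"), CPM 2.5 and
  peak signal 10/5 are kept at the threshold, fold 1.25 is `increased`.
* An all-zero track yields an empty peak list, not an error; a zero-count
  library yields an all-zero TPM column with a warning; zero-length
  chromosomes and enrichment factors below 1 are configuration errors.
* Ambiguous reads (overlapping several genes' exons) are dropped from all
  genes and counted, so gene totals + ambiguous + intergenic equals the
  passed-filter count exactly.
* Ties in the peak threshold use strict `>` comparison; the threshold
  itself is attached to the peak set for downstream signal filtering.

## Design choices where the design was open

* The RNA taxonomy in the source design has three categories while
  CUT&RUN has four; `xciseq` computes four categories in both modes and
  derives the three-category rollup for RNA summaries, so no information
  is lost either way.
* CF reads' downstream fate is unstated in the source design; they are
  excluded from allelic counts (conservative) but kept in summaries.
* Whether the peak signal cutoffs refer to total or maximum signal is
  unstated; total signal is used (the statistic the upstream caller
  reports), and maximum signal is retained on every peak for inspection.
* The CPM filter's library count is a required argument rather than a
  default, because published descriptions of the same analysis disagree
  ("at least two libraries" vs "4 libraries").
* Escape calling on synthetic data uses a configurable Xi-fraction
  threshold (default 0.1); the original analysis used curated escape
  lists, which the reporting layer accepts as class-assignment input.

## Running the pipeline

```{r, eval = FALSE}
run <- run_pipeline(sim_config(seed = 42), xci_program())
run$rna$induction            # Xist induction per condition
attr(run$rna$folds$xi, "call_fractions")
run$cutrun$gains             # Xi-specific peak gains, KO vs wt background
plot_allelic_ratios(run$rna$ratios, run$genes)
autoplot(run$rna$de)
```

The default toy run (two 150 kb chromosomes, 24 genes, 20k reads per
library, 20k fragments per CUT&RUN library) completes in well under five
minutes on one CPU; the statistical experiments in
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R` state their
own problem sizes (30k–400k reads per library, 5–20 seeds) as noted
above.

## Known limitations

* The DE substitute is conservative at low replication and is not a
  negative-binomial model; dispersion shrinkage across genes is out of
  scope.
* The peak caller does not reproduce any external caller's numeric
  thresholds; at adaptive-quantile settings mismatched to the enriched
  fraction it fragments wide domains (see the quantile rule above), and
  isolated noise bins can occasionally survive the signal filter and
  appear as spurious single-bin gains.
* Allelic TPM splitting assumes informative reads are representative of
  the gene's transcripts; genes with very few SNPs have noisy splits, and
  the reporting layer therefore exposes `min_informative` floors.
* bedGraph is the only track output (no bigWig); isoform-level
  quantification and batch modelling are out of scope.
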