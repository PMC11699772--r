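#' Simulation configuration for a synthetic hybrid cross
#'
#' Bundles every tunable parameter of the synthetic-data generator: the
#' chromosome layout, strain-variant density, gene/exon geometry, read and
#' fragment models, and the planted defects (indels, low-quality variant
#' records, sub-threshold MAPQ alignments, over-long and chimeric fragments)
#' that exercise the pipeline's filters. All downstream `simulate_*()`
#' functions are deterministic given a config: equal configs (including
#' `seed`) produce byte-identical output.
#'
#' @param seed Integer seed; every source of randomness in the generator is
#'   derived from it.
#' @param chromosomes Tibble with columns `chrom`, `length` (bp), `is_x`.
#' @param snp_density Per-bp probability that a position carries a
#'   strain-diagnostic variant record (129xcast-like divergence is roughly
#'   0.008).
#' @param indel_fraction Fraction of variant records emitted as indels
#'   (present only to be filtered out, as in the analysis).
#' @param lowqual_fraction Fraction of SNP records flagged with a non-PASS
#'   FILTER.
#' @param genes_per_chromosome Number of non-overlapping gene models placed
#'   per chromosome.
#' @param exons_per_gene,exon_length,intron_length Exon model geometry (bp).
#'   `exon_length` must be at least `read_length` (reads are drawn within
#'   single exons; no splice-aware structure).
#' @param read_length Read length in bp (75 bp, matching single-end RNA-seq
#'   and paired-end CUT&RUN mates).
#' @param reads_per_library RNA-seq depth per library.
#' @param error_rate Per-base substitution sequencing-error probability.
#' @param lowmapq_fraction Fraction of alignments assigned MAPQ below 30 so
#'   the mapping-quality filter is exercised deterministically.
#' @param fragment_mean,fragment_sd CUT&RUN fragment length model (bp),
#'   truncated to \[50, 999\].
#' @param heavy_tail_fraction Fraction of fragments drawn over-long
#'   (>= 1 kb), violating the fragment-length filter.
#' @param chimera_fraction Fraction of fragment pairs whose mates land on
#'   different chromosomes.
#' @param cutrun_fragments CUT&RUN depth (fragments per library).
#' @param expr_meanlog,expr_sdlog Log-normal gene-expression baseline
#'   (relative transcript abundance across genes).
#' @param bin_size Default coverage-track bin width (bp).
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chromosomes = tibble(
                         chrom = c("chr1", "chrX"),
                         length = c(150000L, 150000L),
                         is_x = c(FALSE, TRUE)),
                       snp_density = 0.008,
                       indel_fraction = 0.10,
                       lowqual_fraction = 0.10,
                       genes_per_chromosome = 12L,
                       exons_per_gene = 4L,
                       exon_length = 400L,
                       intron_length = 200L,
                       read_length = 75L,
                       reads_per_library = 20000L,
                       error_rate = 0.001,
                       lowmapq_fraction = 0.05,
                       fragment_mean = 250,
                       fragment_sd = 60,
                       heavy_tail_fraction = 0.02,
                       chimera_fraction = 0.01,
                       cutrun_fragments = 20000L,
                       expr_meanlog = log(100),
                       expr_sdlog = 0.5,
                       bin_size = 50L) {
  chromosomes <- as_tibble(chromosomes)
  stopifnot(all(c("chrom", "length", "is_x") %in% names(chromosomes)))
  if (any(chromosomes$length <= 0)) {
    abort("chromosome lengths must be > 0")
  }
  for (nm in c("snp_density", "indel_fraction", "lowqual_fraction",
               "error_rate", "lowmapq_fraction", "heavy_tail_fraction",
               "chimera_fraction")) {
    assert_fraction(get(nm), nm)
  }
  assert_positive(read_length, "read_length")
  if (exon_length < read_length) {
    abort("`exon_length` must be >= `read_length` (reads are drawn within exons)")
  }
  structure(
    list(seed = as.integer(seed),
         chromosomes = chromosomes,
         snp_density = snp_density,
         indel_fraction = indel_fraction,
         lowqual_fraction = lowqual_fraction,
         genes_per_chromosome = as.integer(genes_per_chromosome),
         exons_per_gene = as.integer(exons_per_gene),
         exon_length = as.integer(exon_length),
         intron_length = as.integer(intron_length),
         read_length = as.integer(read_length),
         reads_per_library = as.integer(reads_per_library),
         error_rate = error_rate,
         lowmapq_fraction = lowmapq_fraction,
         fragment_mean = fragment_mean,
         fragment_sd = fragment_sd,
         heavy_tail_fraction = heavy_tail_fraction,
         chimera_fraction = chimera_fraction,
         cutrun_fragments = as.integer(cutrun_fragments),
         expr_meanlog = expr_meanlog,
         expr_sdlog = expr_sdlog,
         bin_size = as.integer(bin_size)),
    class = "sim_config")
}

#' X-inactivation program for the synthetic cross
#'
#' Describes the expression truth the generator plants: which fraction of
#' each X-linked gene's transcripts originates from the inactive-X
#' haplotype (haplotype 1, the 129-analog maternal strain, which is always
#' the Xi in the skewed Tsix-stop design), per silencing class, condition
#' and timepoint; the knockout perturbation (a fold increase of Xi output
#' for a random subset of silenced genes); and the Xist-like locus's
#' differentiation-induced upregulation per condition.
#'
#' At the undifferentiated timepoint every gene is biallelic
#' (`xi_fraction = 0.5`); X inactivation has not yet occurred. After
#' differentiation, silenced-class genes drop to their class-specific
#' residual Xi fraction while escape genes retain substantial Xi output.
#' Autosomal genes are fixed at 0.5 throughout.
#'
#' @param xi_fractions Named numeric: residual Xi transcript fraction after
#'   differentiation in the wild type, for classes `early`, `intermediate`,
#'   `late`, `escape`.
#' @param ko_xi_upshift Multiplicative increase of Xi output in the knockout
#'   (differentiated timepoint) for perturbed silenced genes.
#' @param ko_upshift_prob Probability that a silenced X gene is perturbed in
#'   the knockout.
#' @param xist_induction Named numeric, fold change of Xist-like output at
#'   the differentiated vs undifferentiated timepoint per condition.
#' @param xist_base Relative expression of the Xist-like locus before
#'   differentiation (same units as the log-normal gene baseline).
#' @param xist_xi_fraction Xi transcript fraction of the Xist-like locus
#'   after differentiation (Xist is expressed from the Xi).
#' @param class_weights Named numeric, sampling weights of silencing classes
#'   for X-linked genes.
#' @param conditions,timepoints Character vectors of condition and timepoint
#'   labels; the second timepoint is the differentiated one.
#' @param replicates Libraries per condition x timepoint (the study used two
#'   wild-type replicates and two knockout clones).
#'
#' @return A list of class `xci_program`.
#' @export
xci_program <- function(xi_fractions = c(early = 0.02, intermediate = 0.05,
                                         late = 0.10, escape = 0.30),
                        ko_xi_upshift = 1.5,
                        ko_upshift_prob = 0.8,
                        xist_induction = c(wt = 6, ko = 2.5),
                        xist_base = 30,
                        xist_xi_fraction = 0.95,
                        class_weights = c(early = 0.25, intermediate = 0.25,
                                          late = 0.25, escape = 0.25),
                        conditions = c("wt", "ko"),
                        timepoints = c("D0", "D15"),
                        replicates = 2L) {
  stopifnot(setequal(names(xi_fractions),
                     c("early", "intermediate", "late", "escape")))
  assert_fraction(xi_fractions, "xi_fractions")
  assert_fraction(ko_upshift_prob, "ko_upshift_prob")
  assert_fraction(xist_xi_fraction, "xist_xi_fraction")
  if (ko_xi_upshift < 0) abort("`ko_xi_upshift` must be >= 0")
  stopifnot(length(timepoints) == 2L, length(conditions) >= 1L)
  stopifnot(setequal(names(xist_induction), conditions))
  structure(
    list(xi_fractions = xi_fractions,
         ko_xi_upshift = ko_xi_upshift,
         ko_upshift_prob = ko_upshift_prob,
         xist_induction = xist_induction,
         xist_base = xist_base,
         xist_xi_fraction = xist_xi_fraction,
         class_weights = class_weights,
         conditions = conditions,
         timepoints = timepoints,
         replicates = as.integer(replicates)),
    class = "xci_program")
}

#' Library design table for a program
#'
#' One row per sequencing library: condition, timepoint, replicate and a
#' library id such as `wt_D15_r1`.
#'
#' @param program An [xci_program()].
#' @return A tibble with columns `library`, `condition`, `timepoint`,
#'   `replicate`.
#' @export
library_design <- function(program) {
  tidyr::expand_grid(condition = program$conditions,
                     timepoint = program$timepoints,
                     replicate = seq_len(program$replicates)) %>%
    mutate(library = paste0(.data$condition, "_", .data$timepoint,
                            "_r", .data$replicate)) %>%
    select("library", "condition", "timepoint", "replicate")
}
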