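# shared fixtures, built in code

# small, fast configuration for most tests
tiny_config <- function(seed = 1L, ...) {
  defaults <- list(
    seed = seed,
    chromosomes = tibble::tibble(chrom = c("chr1", "chrX"),
                                 length = c(40000L, 40000L),
                                 is_x = c(FALSE, TRUE)),
    genes_per_chromosome = 6L,
    reads_per_library = 4000L,
    cutrun_fragments = 4000L)
  dots <- list(...)
  do.call(sim_config, utils::modifyList(defaults, dots))
}

# single-condition, single-timepoint program (one library) for simulator
# unit tests
flat_program <- function(replicates = 1L, ...) {
  xci_program(conditions = "wt", xist_induction = c(wt = 6),
              replicates = replicates, ...)
}

# simulate reference + pseudogenomes + genes in one call
tiny_world <- function(config = tiny_config(), program = flat_program()) {
  ref <- simulate_hybrid_reference(config)
  snps <- filter_variants(ref$variants)
  genomes <- build_pseudogenomes(ref$reference, snps)
  genes <- simulate_annotation(config, program)
  list(ref = ref, snps = snps, genomes = genomes, genes = genes,
       config = config, program = program)
}

# independent tagging oracle: compare the read sequence base-by-base
# against the two pseudo-genome sequences restricted to SNP sites covered
# by the read; tag by the same G1/G2/CF/UA rule, but from genome strings
# rather than the SNP table's allele columns.
oracle_tags <- function(alignments, genomes, snps) {
  g1 <- as.character(genomes$g1)
  g2 <- as.character(genomes$g2)
  vapply(seq_len(nrow(alignments)), function(i) {
    a <- alignments[i, ]
    s <- snps[snps$chrom == a$chrom & snps$pos > a$start & snps$pos <= a$end, ]
    if (nrow(s) == 0L) return("UA")
    rb <- substring(a$seq, s$pos - a$start, s$pos - a$start)
    b1 <- substring(g1[[a$chrom]], s$pos, s$pos)
    b2 <- substring(g2[[a$chrom]], s$pos, s$pos)
    n1 <- sum(rb == b1 & b1 != b2)
    n2 <- sum(rb == b2 & b1 != b2)
    if (n1 > 0 && n2 == 0) "G1" else if (n2 > 0 && n1 == 0) "G2"
    else if (n1 > 0 && n2 > 0) "CF" else "UA"
  }, character(1))
}

# hand-built expression table (gene x library long form) for report tests
manual_expression <- function(...) {
  df <- tibble::tribble(...)
  stopifnot(all(c("gene_id", "library", "total", "g1", "g2", "tpm") %in%
                  names(df)))
  if (!"cpm" %in% names(df)) df$cpm <- df$tpm
  if (!"exon_length" %in% names(df)) df$exon_length <- 1000L
  df
}

# constant-signal coverage track on one chromosome, for peak fixtures
manual_track <- function(values, chrom = "chrX", bin_size = 100L,
                         normalization = "rpkm") {
  n <- length(values)
  xciseq:::new_coverage_track(
    tibble::tibble(chrom = chrom,
                   start = (seq_len(n) - 1L) * bin_size,
                   end = seq_len(n) * bin_size,
                   value = values),
    bin_size, normalization, sum(values))
}
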