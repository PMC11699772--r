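# I/O boundaries. Internal interval arithmetic is 0-based half-open;
# conversions to the 1-based conventions of FASTA/VCF/GRanges happen here.

#' Write / read reference sequences as FASTA
#' @param seqs A [Biostrings::DNAStringSet].
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write simulated variants as a VCF v4 file
#'
#' Emits one record per variant with the two strain haplotypes as samples
#' `g1` and `g2` (homozygous genotypes referencing REF or ALT), QUAL and
#' FILTER columns included so the variant filters can be exercised from
#' file input.
#'
#' @param variants Variant tibble from [simulate_hybrid_reference()].
#' @param path Output file.
#' @export
write_vcf <- function(variants, path) {
  gt <- function(allele, ref) ifelse(allele == ref, "0/0", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "g1", "g2", sep = "\t"))
  body <- if (nrow(variants) == 0L) character(0) else
    paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
          variants$qual, variants$filter, ".", "GT",
          gt(variants$allele_g1, variants$ref),
          gt(variants$allele_g2, variants$ref), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read strain variants from a VCF file
#'
#' Parses a VCF (via vcfR) carrying two haplotype samples `g1` and `g2`
#' and returns the raw variant tibble consumed by [filter_variants()].
#'
#' @param path VCF file.
#' @return Tibble with `chrom`, `pos`, `ref`, `alt`, `qual`, `filter`,
#'   `allele_g1`, `allele_g2`, `is_indel`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as_tibble(as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE))
  gt <- vcfR::extract.gt(v, element = "GT")
  pick <- function(gt_col, ref, alt) {
    ifelse(substr(gt_col, 1, 1) == "0", ref, alt)
  }
  tibble(chrom = fix$CHROM,
         pos = as.integer(fix$POS),
         ref = fix$REF,
         alt = fix$ALT,
         qual = as.numeric(fix$QUAL),
         filter = fix$FILTER,
         allele_g1 = unname(pick(gt[, "g1"], fix$REF, fix$ALT)),
         allele_g2 = unname(pick(gt[, "g2"], fix$REF, fix$ALT)),
         is_indel = nchar(fix$REF) != 1L |
           (nchar(fix$ALT) != 1L & !grepl(",", fix$ALT, fixed = TRUE)))
}

#' Write / read SAM-like alignment tables
#'
#' The simulator's alignment records are tab-delimited with explicit
#' 0-based half-open coordinates (a SAM-like layout without CIGAR, since
#' simulated alignments are gapless).
#'
#' @param alignments Alignment tibble.
#' @param path Output file.
#' @export
write_alignments <- function(alignments, path) {
  readr::write_tsv(alignments, path)
  invisible(path)
}

#' @rdname write_alignments
#' @export
read_alignments <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write per-tag alignment files
#'
#' Separates G1- and G2-tagged records into two alignment files (the
#' inputs for allele-specific browser tracks).
#'
#' @param tagged Output of [tag_library()].
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Paths of the files written.
#' @export
write_tagged_alignments <- function(tagged, dir, prefix = "tagged") {
  paths <- purrr::map_chr(c("G1", "G2"), function(tg) {
    p <- file.path(dir, paste0(prefix, "_", tg, ".tsv"))
    readr::write_tsv(filter(tagged, .data$tag == tg), p)
    p
  })
  invisible(paths)
}

#' Write / read a coverage track as bedGraph
#'
#' Four-column bedGraph (0-based half-open), via rtracklayer.
#'
#' @param track A `coverage_track`.
#' @param path Output file.
#' @export
write_bedgraph <- function(track, path) {
  gr <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$start + 1L, track$end),
                               score = track$value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_bedgraph
#' @param bin_size,normalization,total_units Track metadata to re-attach.
#' @export
read_bedgraph <- function(path, bin_size = NA_integer_,
                          normalization = "unknown",
                          total_units = NA_integer_) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  new_coverage_track(
    tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
           start = GenomicRanges::start(gr) - 1L,
           end = GenomicRanges::end(gr),
           value = gr$score),
    bin_size, normalization, total_units)
}

#' Write peaks as BED6
#'
#' name = source library, score = total signal (rounded), strand = ".".
#'
#' @param peaks A `peak_set`.
#' @param path Output file.
#' @export
write_peaks_bed <- function(peaks, path) {
  df <- tibble(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
               name = peaks$library, score = round(peaks$total_signal, 3),
               strand = ".")
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}
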