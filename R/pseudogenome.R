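#' Filter raw strain-variant records down to diagnostic SNPs
#'
#' Reproduces the variant pre-filtering used before any allelic step:
#' indels and low-quality records are removed, and only biallelic SNPs
#' whose two strain alleles are single, distinct A/C/G/T bases are kept (a
#' site where the strains agree cannot diagnose a read's allele of origin
#' and is dropped as non-diagnostic; multi-allelic records are dropped
#' because the tagging taxonomy is defined for two alleles). "Low quality"
#' is operationalised as VCF `FILTER != PASS`, optionally tightened with a
#' QUAL threshold.
#'
#' Removal reasons are counted with precedence
#' indel > multiallelic > low-quality > non-diagnostic, so that
#' `nrow(input) == nrow(retained) + sum(removed per reason)`.
#'
#' @param variants Tibble of raw records with columns `chrom`, `pos`
#'   (1-based), `allele_g1`, `allele_g2`, `filter`, and either `is_indel`
#'   or `ref`/`alt` from which indels are inferred. Optional `qual`.
#' @param min_qual Optional numeric; records with `qual < min_qual` are
#'   also counted as low-quality.
#' @return A tibble of retained SNPs (class `snp_table`), position-sorted
#'   and de-duplicated per chromosome, with the removal accounting
#'   available via [filter_summary()].
#' @export
filter_variants <- function(variants, min_qual = NULL) {
  variants <- as_tibble(variants)
  req <- c("chrom", "pos", "allele_g1", "allele_g2", "filter")
  missing_cols <- setdiff(req, names(variants))
  if (length(missing_cols) > 0L) {
    abort(paste0("malformed variant records: missing column(s) ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(variants) > 0 && (any(is.na(variants$pos)) ||
                             any(variants$pos < 1))) {
    bad <- which(is.na(variants$pos) | variants$pos < 1)[[1]]
    abort(paste0("malformed variant record at line ", bad,
                 ": invalid position"))
  }
  single_base <- function(x) x %in% c("A", "C", "G", "T")
  is_indel <- if ("is_indel" %in% names(variants)) {
    variants$is_indel
  } else if (all(c("ref", "alt") %in% names(variants))) {
    nchar(variants$ref) != 1L |
      (nchar(variants$alt) != 1L & !grepl(",", variants$alt, fixed = TRUE))
  } else {
    rep(FALSE, nrow(variants))
  }
  is_indel <- is_indel | nchar(variants$allele_g1) > 1L |
    nchar(variants$allele_g2) > 1L
  multi <- if ("alt" %in% names(variants)) {
    !is_indel & grepl(",", variants$alt, fixed = TRUE)
  } else rep(FALSE, nrow(variants))
  lowq <- !is_indel & !multi &
    (variants$filter != "PASS" |
       (if (!is.null(min_qual) && "qual" %in% names(variants))
         variants$qual < min_qual else FALSE))
  nondiag <- !is_indel & !multi & !lowq &
    (variants$allele_g1 == variants$allele_g2 |
       !single_base(variants$allele_g1) | !single_base(variants$allele_g2))
  keep <- !is_indel & !multi & !lowq & !nondiag

  retained <- variants[keep, c("chrom", "pos", "allele_g1", "allele_g2")] %>%
    arrange(.data$chrom, .data$pos)
  dup <- retained %>%
    distinct() %>%
    count(.data$chrom, .data$pos) %>%
    filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(paste0("duplicate position with conflicting alleles: ",
                 dup$chrom[[1]], ":", dup$pos[[1]]))
  }
  n_dup_identical <- nrow(retained) - nrow(distinct(retained))
  retained <- distinct(retained)

  summary <- tibble(
    reason = c("retained", "indel", "multiallelic", "low_quality",
               "non_diagnostic", "duplicate"),
    n = c(nrow(retained), sum(is_indel), sum(multi), sum(lowq),
          sum(nondiag), n_dup_identical))
  structure(retained, class = c("snp_table", class(retained)),
            filter_summary = summary)
}

#' Removal accounting from [filter_variants()]
#'
#' @param x A `snp_table`.
#' @return Tibble with columns `reason`, `n`; the counts sum to the number
#'   of input records.
#' @export
filter_summary <- function(x) {
  attr(x, "filter_summary") %||%
    abort("no filter summary attached; was this made by filter_variants()?")
}

#' Build the two strain-substituted pseudo-genomes
#'
#' Substitutes each retained SNP's haplotype-1 allele into one copy of the
#' reference and its haplotype-2 allele into the other, yielding two
#' equal-length genomes on shared reference coordinates (SNP-only
#' substitution preserves length) that differ from each other exactly at
#' the retained SNP positions.
#'
#' @param reference A [Biostrings::DNAStringSet] of reference chromosomes.
#' @param snps A `snp_table` from [filter_variants()] (any tibble with
#'   `chrom`, `pos`, `allele_g1`, `allele_g2` works).
#' @return A list of class `pseudogenome_pair` with elements `g1`, `g2`
#'   (each a `DNAStringSet`) and `snps`.
#' @export
build_pseudogenomes <- function(reference, snps) {
  stopifnot(methods::is(reference, "DNAStringSet"))
  snps <- as_tibble(snps)
  missing_chr <- setdiff(unique(snps$chrom), names(reference))
  if (length(missing_chr) > 0L) {
    abort(paste0("SNP chromosome absent from reference: ",
                 paste(missing_chr, collapse = ", ")))
  }
  g1 <- reference
  g2 <- reference
  for (cc in unique(snps$chrom)) {
    s <- snps[snps$chrom == cc, ]
    L <- length(reference[[cc]])
    if (any(s$pos > L)) {
      abort(paste0("SNP position beyond end of ", cc))
    }
    g1[[cc]] <- Biostrings::replaceLetterAt(
      reference[[cc]], s$pos, paste(s$allele_g1, collapse = ""))
    g2[[cc]] <- Biostrings::replaceLetterAt(
      reference[[cc]], s$pos, paste(s$allele_g2, collapse = ""))
  }
  structure(list(g1 = g1, g2 = g2, snps = snps),
            class = "pseudogenome_pair")
}

#' @export
print.pseudogenome_pair <- function(x, ...) {
  cat("<pseudogenome_pair>", length(x$g1), "chromosome(s),",
      nrow(x$snps), "substituted SNP site(s)\n")
  invisible(x)
}
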