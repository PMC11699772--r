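#' Filter single-end alignments on mapping quality
#'
#' Keeps records that are mapped with MAPQ at or above the threshold
#' (default 30, the "mapped uniquely and with a high-quality mapping score"
#' criterion). Dropped records are recorded with a reason, retrievable via
#' [dropped_records()].
#'
#' @param alignments Alignment tibble with columns `read_id`, `mapq`,
#'   `mapped`.
#' @param min_mapq Minimum MAPQ kept (inclusive).
#' @return The kept rows, with a `dropped` attribute.
#' @export
filter_alignments <- function(alignments, min_mapq = 30) {
  alignments <- as_tibble(alignments)
  mapped <- alignments$mapped %||% rep(TRUE, nrow(alignments))
  reason <- dplyr::case_when(!mapped ~ "unmapped",
                             alignments$mapq < min_mapq ~ "low_mapq",
                             TRUE ~ NA_character_)
  keep <- is.na(reason)
  structure(alignments[keep, ],
            dropped = tibble(read_id = alignments$read_id[!keep],
                             reason = reason[!keep]))
}

#' Filter paired alignments on mate chromosome and fragment length
#'
#' CUT&RUN pair filter: a fragment is kept only if both mates are present,
#' both map to the same chromosome, and the fragment length is strictly
#' less than `max_fragment` bp (default 1000; a 1000 bp fragment is
#' dropped). Reasons recorded: `orphan`, `chimeric`, `overlong`.
#'
#' @param alignments Mate-level tibble with `fragment_id`, `chrom`,
#'   `fragment_length` (one row per mate).
#' @param max_fragment Strict upper bound on fragment length (bp).
#' @return Kept mate rows with a `dropped` attribute (one row per dropped
#'   fragment).
#' @export
filter_pairs <- function(alignments, max_fragment = 1000) {
  alignments <- as_tibble(alignments)
  per_frag <- alignments %>%
    group_by(.data$fragment_id) %>%
    summarise(n_mates = n(),
              same_chrom = dplyr::n_distinct(.data$chrom) == 1L,
              frag_len = .data$fragment_length[[1]],
              .groups = "drop") %>%
    mutate(reason = dplyr::case_when(
      .data$n_mates != 2L ~ "orphan",
      !.data$same_chrom ~ "chimeric",
      is.na(.data$frag_len) | .data$frag_len >= max_fragment ~ "overlong",
      TRUE ~ NA_character_))
  keep_ids <- per_frag$fragment_id[is.na(per_frag$reason)]
  structure(alignments[alignments$fragment_id %in% keep_ids, ],
            dropped = per_frag %>%
              filter(!is.na(.data$reason)) %>%
              select(fragment_id = "fragment_id", reason = "reason"))
}

#' Records dropped by an alignment or pair filter
#' @param x Output of [filter_alignments()] or [filter_pairs()].
#' @return Tibble of dropped ids and reasons.
#' @export
dropped_records <- function(x) {
  attr(x, "dropped") %||% tibble(read_id = character(), reason = character())
}

# collect per-unit evidence at diagnostic SNP sites: for every alignment
# base sitting on a SNP position, count matches to allele_g1 / allele_g2;
# bases matching neither are sequencing errors and are ignored (invalid).
snp_evidence <- function(alignments, snps, unit) {
  units <- unique(alignments[[unit]])
  ev <- tibble(unit = character(), n_g1 = integer(), n_g2 = integer(),
               n_other = integer())
  per_chrom <- purrr::map(intersect(unique(alignments$chrom),
                                    unique(snps$chrom)), function(cc) {
    a <- alignments[alignments$chrom == cc, ]
    s <- snps[snps$chrom == cc, ]
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(a$start + 1L, a$end),
      IRanges::IRanges(s$pos, s$pos))
    if (length(hits) == 0L) return(NULL)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    base <- substring(a$seq[qi], s$pos[si] - a$start[qi],
                      s$pos[si] - a$start[qi])
    tibble(unit = a[[unit]][qi],
           g1 = base == s$allele_g1[si],
           g2 = base == s$allele_g2[si]) %>%
      group_by(.data$unit) %>%
      summarise(n_g1 = sum(.data$g1), n_g2 = sum(.data$g2),
                n_other = sum(!.data$g1 & !.data$g2), .groups = "drop")
  }) %>% purrr::list_rbind()
  if (!is.null(per_chrom) && nrow(per_chrom) > 0L) {
    # a fragment's mates may sit on the same chromosome only (pairs passed
    # the same-chromosome filter), so per-chromosome groups are disjoint
    ev <- per_chrom %>%
      group_by(.data$unit) %>%
      summarise(across(c("n_g1", "n_g2", "n_other"), sum), .groups = "drop")
  }
  tibble(unit = units) %>%
    left_join(ev, by = "unit") %>%
    mutate(across(c("n_g1", "n_g2", "n_other"), ~ tidyr::replace_na(.x, 0L)))
}

# evidence counts -> G1/G2/CF/UA tag
evidence_tag <- function(n_g1, n_g2) {
  dplyr::case_when(n_g1 > 0L & n_g2 == 0L ~ "G1",
                   n_g2 > 0L & n_g1 == 0L ~ "G2",
                   n_g1 > 0L & n_g2 > 0L ~ "CF",
                   TRUE ~ "UA")
}

#' Classify reads (or fragments) by allele of origin at SNP sites
#'
#' Collects the sequenced base at every diagnostic SNP position covered by
#' the alignment, matches it against the two strain alleles, and tags the
#' unit `G1` (only haplotype-1 matches), `G2` (only haplotype-2 matches),
#' `CF` (conflicting: at least one of each) or `UA` (no valid SNP
#' observation). A base matching neither allele is treated as invalid (a
#' likely sequencing error) and ignored, so an all-invalid read is `UA`,
#' not `CF`. With `unit = "fragment_id"` the evidence of both mates is
#' pooled before tagging.
#'
#' @param alignments Alignment tibble (`chrom`, `start`, `end`, `seq`, and
#'   the unit id column).
#' @param snps A `snp_table`.
#' @param unit Column defining the tagging unit: `"read_id"` (single-end
#'   RNA) or `"fragment_id"` (paired CUT&RUN).
#' @return One row per unit: unit id, `n_g1`, `n_g2`, `n_other`, `tag`.
#' @export
classify_reads <- function(alignments, snps, unit = "read_id") {
  stopifnot(unit %in% names(alignments))
  snp_evidence(alignments, snps, unit) %>%
    mutate(tag = evidence_tag(.data$n_g1, .data$n_g2)) %>%
    rename(!!unit := "unit")
}

#' Filter and allele-tag a whole library
#'
#' Applies the mode's filters (RNA: MAPQ only on single-end reads; CUT&RUN:
#' pair filter — same chromosome, fragment < `max_fragment` — then MAPQ on
#' both mates), classifies every passed unit into G1/G2/CF/UA, and attaches
#' a per-library allelic mapping summary (retrievable with
#' [allelic_summary()]) mirroring the columns of an allelic mapping metrics
#' table: total, passed, per-tag counts and fractions, plus a
#' three-category rollup where `uncertain = CF + UA` for RNA reporting.
#'
#' @param alignments Alignment tibble; must carry `library`.
#' @param snps A `snp_table`.
#' @param mode `"rna"` or `"cutrun"`.
#' @param min_mapq MAPQ threshold (default 30).
#' @param max_fragment Strict fragment-length bound for cutrun (default
#'   1000 bp).
#' @return Tagged tibble (one row per read in rna mode, per fragment in
#'   cutrun mode, with the fragment's full interval) with attributes
#'   `summary` and `dropped`.
#' @export
tag_library <- function(alignments, snps, mode = c("rna", "cutrun"),
                        min_mapq = 30, max_fragment = 1000) {
  mode <- match.arg(mode)
  alignments <- as_tibble(alignments)
  bad_chr <- setdiff(unique(alignments$chrom), unique(snps$chrom))
  # chromosomes with no SNPs are legitimate (reads there are UA); only a
  # fully disjoint chromosome set indicates mismatched inputs
  if (nrow(alignments) > 0L && nrow(snps) > 0L &&
      length(bad_chr) == length(unique(alignments$chrom))) {
    abort("alignment and SNP-table chromosomes do not overlap")
  }
  total <- if (mode == "rna") nrow(alignments) else
    dplyr::n_distinct(alignments$fragment_id)

  if (mode == "rna") {
    kept <- filter_alignments(alignments, min_mapq = min_mapq)
    dropped <- dropped_records(kept)
    tags <- classify_reads(kept, snps, unit = "read_id")
    tagged <- kept %>% inner_join(tags, by = "read_id")
  } else {
    paired <- filter_pairs(alignments, max_fragment = max_fragment)
    drop1 <- dropped_records(paired)
    # MAPQ: both mates must pass, as each mate's placement must be reliable
    mq <- paired %>%
      group_by(.data$fragment_id) %>%
      summarise(ok = all(.data$mapq >= min_mapq) && all(.data$mapped),
                .groups = "drop")
    kept <- paired[paired$fragment_id %in% mq$fragment_id[mq$ok], ]
    drop2 <- tibble(fragment_id = mq$fragment_id[!mq$ok],
                    reason = "low_mapq")
    tags <- classify_reads(kept, snps, unit = "fragment_id")
    tagged <- kept %>%
      group_by(.data$fragment_id) %>%
      summarise(library = .data$library[[1]], chrom = .data$chrom[[1]],
                start = min(.data$start), end = max(.data$end),
                fragment_length = .data$fragment_length[[1]],
                .groups = "drop") %>%
      inner_join(tags, by = "fragment_id")
    dropped <- bind_rows(drop1, drop2)
  }

  totals <- if (mode == "rna") {
    alignments %>% count(.data$library, name = "total")
  } else {
    alignments %>%
      distinct(.data$library, .data$fragment_id) %>%
      count(.data$library, name = "total")
  }
  summary <- tagged %>%
    mutate(tag = factor(.data$tag, levels = c("G1", "G2", "CF", "UA"))) %>%
    count(.data$library, .data$tag, .drop = FALSE) %>%
    tidyr::pivot_wider(names_from = "tag", values_from = "n") %>%
    rename(g1 = "G1", g2 = "G2", cf = "CF", ua = "UA") %>%
    left_join(totals, by = "library") %>%
    mutate(mode = mode,
           passed = .data$g1 + .data$g2 + .data$cf + .data$ua,
           uncertain = .data$cf + .data$ua,
           frac_g1 = .data$g1 / .data$passed,
           frac_g2 = .data$g2 / .data$passed,
           frac_uncertain = .data$uncertain / .data$passed) %>%
    select("library", "mode", "total", "passed", "g1", "g2", "cf", "ua",
           "uncertain", "frac_g1", "frac_g2", "frac_uncertain")
  structure(tagged, summary = summary, dropped = dropped)
}

#' Allelic mapping summary of a tagged library
#' @param x Output of [tag_library()].
#' @return One-row tibble of per-tag counts and fractions.
#' @export
allelic_summary <- function(x) {
  attr(x, "summary") %||% abort("no summary attached; use tag_library()")
}
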