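#' Threshold peak calling on a coverage track
#'
#' A documented substitute for sparse-chromatin peak calling from bedGraph
#' signal (the "norm"-mode caller the study used is not re-implemented
#' numerically): without a control track the threshold is the
#' `threshold_quantile` quantile of the track's nonzero bin values; with a
#' control, a bin is supra-threshold when its signal exceeds the control's
#' corresponding bin. Contiguous supra-threshold bins are merged into
#' peaks, and single-bin sub-threshold gaps between supra-threshold runs
#' are bridged. Each peak records the sum (`total_signal`) and maximum
#' (`max_signal`) of its bin values.
#'
#' @param track A `coverage_track` (normalized signal).
#' @param control Optional `coverage_track` on identical bins.
#' @param threshold_quantile Quantile of nonzero bin values used as the
#'   data-derived threshold when no control is given (default 0.99).
#' @param library Label stored with the peaks.
#' @return Tibble of class `peak_set`: `chrom`, `start`, `end` (0-based
#'   half-open), `total_signal`, `max_signal`, `library`; disjoint and
#'   sorted within chromosomes. The data-derived threshold is attached as
#'   the `threshold` attribute. An all-zero track yields zero peaks.
#' @export
call_peaks <- function(track, control = NULL, threshold_quantile = 0.99,
                       library = "sample") {
  if (!is.null(control)) assert_same_binning(track, control)
  nz <- track$value[track$value > 0]
  if (length(nz) == 0L) return(empty_peaks(library))
  thr <- NA_real_
  above <- if (is.null(control)) {
    thr <- quantile(nz, threshold_quantile, names = FALSE)
    track$value > thr
  } else {
    track$value > control$value & track$value > 0
  }
  out <- purrr::map(unique(track$chrom), function(cc) {
    idx <- which(track$chrom == cc)
    ab <- above[idx]
    if (!any(ab)) return(NULL)
    # bridge single-bin gaps flanked by supra-threshold bins
    n <- length(ab)
    if (n >= 3L) {
      gap <- which(!ab[2:(n - 1L)] & ab[1:(n - 2L)] & ab[3:n]) + 1L
      ab[gap] <- TRUE
    }
    r <- rle(ab)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    keep <- which(r$values)
    purrr::map(keep, function(k) {
      rows <- idx[starts_i[[k]]:ends_i[[k]]]
      tibble(chrom = cc,
             start = track$start[rows[[1]]],
             end = track$end[rows[[length(rows)]]],
             total_signal = sum(track$value[rows]),
             max_signal = max(track$value[rows]))
    }) %>% purrr::list_rbind()
  }) %>% purrr::list_rbind()
  if (is.null(out) || nrow(out) == 0L) return(empty_peaks(library))
  structure(mutate(out, library = library),
            class = c("peak_set", class(tibble())), threshold = thr)
}

empty_peaks <- function(library = character(0)) {
  structure(tibble(chrom = character(), start = integer(), end = integer(),
                   total_signal = numeric(), max_signal = numeric(),
                   library = character()),
            class = c("peak_set", class(tibble())))
}

#' Filter peaks on total signal
#'
#' Retains peaks whose `total_signal` is at or above `min_total_signal`
#' (the cutoffs applied in the study: 10 for differentiated H3K27me3
#' samples, 5 for the lower-coverage KDM6A sample; a peak exactly at the
#' cutoff is retained). Idempotent and order-preserving.
#'
#' @param peaks A `peak_set`.
#' @param min_total_signal Non-negative signal cutoff.
#' @return The retained peaks.
#' @export
filter_peaks_by_signal <- function(peaks, min_total_signal) {
  if (min_total_signal < 0) abort("`min_total_signal` must be >= 0")
  filter(peaks, .data$total_signal >= min_total_signal)
}

#' TSS windows (+/- flank) per transcript
#'
#' One window per gene model around its strand-aware transcription start
#' site — the leftmost coordinate for plus-strand genes, the rightmost for
#' minus-strand genes — extending `flank` bp both ways (default 5 kb) and
#' clamped to chromosome bounds, so every window contains its TSS and is
#' at most `2 * flank` wide.
#'
#' @param genes Annotation with `gene_id`, `chrom`, `tss`.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param flank Half-width in bp.
#' @return Tibble: `gene_id`, `chrom`, `start`, `end` (0-based half-open),
#'   `tss`.
#' @export
tss_regions <- function(genes, chrom_lengths, flank = 5000L) {
  missing_chr <- setdiff(unique(genes$chrom), names(chrom_lengths))
  if (length(missing_chr) > 0L) {
    abort(paste0("gene on unknown chromosome: ",
                 paste(missing_chr, collapse = ", ")))
  }
  genes %>%
    transmute(gene_id = .data$gene_id, chrom = .data$chrom,
              start = pmax(0L, .data$tss - as.integer(flank)),
              end = pmin(as.integer(chrom_lengths[.data$chrom]),
                         .data$tss + as.integer(flank)),
              tss = .data$tss)
}

#' Genes whose TSS windows contain at least one peak
#'
#' Overlap is >= 1 shared bp on 0-based half-open intervals; a gene with
#' several transcripts (several TSS windows) is counted once.
#'
#' @param peaks A `peak_set`.
#' @param tss Output of [tss_regions()].
#' @return Sorted character vector of gene ids.
#' @export
peaks_at_tss <- function(peaks, tss) {
  if (nrow(peaks) == 0L || nrow(tss) == 0L) return(character(0))
  hits <- purrr::map(intersect(unique(peaks$chrom), unique(tss$chrom)),
                     function(cc) {
    p <- peaks[peaks$chrom == cc, ]
    t <- tss[tss$chrom == cc, ]
    ov <- IRanges::findOverlaps(IRanges::IRanges(p$start + 1L, p$end),
                                IRanges::IRanges(t$start + 1L, t$end))
    t$gene_id[S4Vectors::subjectHits(ov)]
  })
  sort(unique(unlist(hits)))
}

#' Venn partition counts for 2-3 gene sets
#'
#' Counts every region of the 2- or 3-set Venn partition (exclusive
#' regions, pairwise-only intersections, and the triple intersection); the
#' counts sum to the size of the union.
#'
#' @param sets Named list of 2 or 3 character vectors.
#' @return Tibble: `region`, `n`.
#' @export
venn_counts <- function(sets) {
  k <- length(sets)
  if (k < 2L || k > 3L) abort("venn_counts() takes 2 or 3 sets")
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- LETTERS[seq_len(k)]
  }
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  regions <- unlist(lapply(seq_len(k), function(m) {
    utils::combn(names(sets), m, paste, collapse = "&")
  }))
  tibble(region = regions,
         n = vapply(regions, function(r) sum(pattern == r), integer(1),
                    USE.NAMES = FALSE))
}

#' Xi-specific peak gains against a background sample
#'
#' Calls peaks gained in a test sample relative to a background sample on
#' the same allele and chromosome (the wild type serving as background for
#' knockout Xi peaks): a gained peak is a test peak with no overlap
#' against any background peak. Reports the fraction of the target
#' chromosome's bases covered by gained peaks and the count of gains per
#' genomic context (TSS window, gene body, intergenic; a gain touching a
#' TSS window is counted as TSS).
#'
#' @param test_peaks,background_peaks `peak_set`s restricted to the same
#'   allele and chromosome.
#' @param chrom Target chromosome name.
#' @param chrom_length Its length in bp.
#' @param genes Optional annotation for the context counts.
#' @param tss Optional [tss_regions()] output for the context counts.
#' @return A list of class `peak_gain_report`: `gains` (peak tibble),
#'   `covered_fraction`, `context` (tibble `context`, `n`).
#' @export
xi_specific_gains <- function(test_peaks, background_peaks, chrom,
                              chrom_length, genes = NULL, tss = NULL) {
  for (p in list(test_peaks, background_peaks)) {
    if (nrow(p) > 0L && !all(p$chrom == chrom)) {
      abort("peaks must be restricted to the target chromosome")
    }
  }
  gained <- test_peaks
  if (nrow(test_peaks) > 0L && nrow(background_peaks) > 0L) {
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(test_peaks$start + 1L, test_peaks$end),
      IRanges::IRanges(background_peaks$start + 1L, background_peaks$end))
    gained <- test_peaks[setdiff(seq_len(nrow(test_peaks)),
                                 unique(S4Vectors::queryHits(ov))), ]
  }
  covered <- sum(gained$end - gained$start) / chrom_length
  context <- NULL
  if (!is.null(genes) && nrow(gained) > 0L) {
    g <- genes[genes$chrom == chrom, ]
    in_tss <- if (!is.null(tss) && nrow(tss) > 0L) {
      t <- tss[tss$chrom == chrom, ]
      IRanges::overlapsAny(IRanges::IRanges(gained$start + 1L, gained$end),
                           IRanges::IRanges(t$start + 1L, t$end))
    } else rep(FALSE, nrow(gained))
    in_body <- IRanges::overlapsAny(
      IRanges::IRanges(gained$start + 1L, gained$end),
      IRanges::IRanges(g$start + 1L, g$end))
    ctx <- dplyr::case_when(in_tss ~ "tss", in_body ~ "gene_body",
                            TRUE ~ "intergenic")
    context <- count(tibble(context = factor(
      ctx, levels = c("tss", "gene_body", "intergenic"))),
      .data$context, .drop = FALSE)
  }
  structure(list(gains = gained, covered_fraction = covered,
                 context = context),
            class = "peak_gain_report")
}

#' @export
print.peak_gain_report <- function(x, ...) {
  cat("<peak_gain_report>", nrow(x$gains), "gained peak(s);",
      sprintf("%.4g%%", 100 * x$covered_fraction),
      "of target chromosome covered\n")
  invisible(x)
}
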