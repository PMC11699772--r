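# coverage_track: a tibble (chrom, start, end, value) whose bins tile each
# chromosome exactly, with bin_size / normalization / total_units attributes.

new_coverage_track <- function(df, bin_size, normalization, total_units) {
  structure(df, class = c("coverage_track", class(tibble())),
            bin_size = bin_size, normalization = normalization,
            total_units = total_units)
}

track_bins <- function(chrom_lengths, bin_size) {
  purrr::imap(chrom_lengths, function(L, cc) {
    starts <- seq(0L, L - 1L, by = bin_size)
    tibble(chrom = cc, start = as.integer(starts),
           end = as.integer(pmin(starts + bin_size, L)))
  }) %>% purrr::list_rbind()
}

#' RPKM-normalized binned coverage track
#'
#' Tiles each chromosome with fixed-width bins (the last bin may be
#' shorter) and counts the reads — fragments, when the input carries
#' fragment intervals — overlapping each bin. With
#' `normalization = "rpkm"` each bin count is divided by
#' `(bin width in kb) * (total mapped units in millions)`, the standard
#' reads-per-kilobase-per-million form; `"raw"` keeps counts.
#'
#' @param alignments Tibble with `chrom`, `start`, `end` (0-based
#'   half-open); typically filtered alignments or tagged fragments.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param bin_size Bin width in bp (> 0).
#' @param normalization `"rpkm"` or `"raw"`.
#' @param total_units Denominator for the per-million term; defaults to
#'   `nrow(alignments)` (the library's mapped units).
#' @return A `coverage_track` tibble: `chrom`, `start`, `end`, `value`.
#' @export
rpkm_track <- function(alignments, chrom_lengths, bin_size = 50L,
                       normalization = c("rpkm", "raw"),
                       total_units = NULL) {
  normalization <- match.arg(normalization)
  if (bin_size <= 0) abort("`bin_size` must be > 0")
  total_units <- total_units %||% nrow(alignments)
  bins <- track_bins(chrom_lengths, bin_size)
  bins$value <- 0
  for (cc in intersect(unique(alignments$chrom), names(chrom_lengths))) {
    a <- alignments[alignments$chrom == cc, ]
    b_idx <- which(bins$chrom == cc)
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(bins$start[b_idx] + 1L, bins$end[b_idx]),
      IRanges::IRanges(a$start + 1L, a$end))
    cnt <- tabulate(S4Vectors::queryHits(ov), nbins = length(b_idx))
    bins$value[b_idx] <- cnt
  }
  if (normalization == "rpkm") {
    width_kb <- (bins$end - bins$start) / 1000
    if (total_units > 0) {
      bins$value <- bins$value / (width_kb * total_units / 1e6)
    }
  }
  new_coverage_track(bins, bin_size, normalization, total_units)
}

assert_same_binning <- function(a, b) {
  if (nrow(a) != nrow(b) ||
      !all(a$chrom == b$chrom) || !all(a$start == b$start) ||
      !all(a$end == b$end)) {
    abort("tracks have different binning or chromosomes")
  }
}

#' Subtract a control track binwise, flooring at zero
#'
#' The IgG-subtraction step: `treatment - control` per bin, with negative
#' values floored at zero (negative signal has no meaning for threshold
#' peak calling). Both tracks must share binning and chromosomes.
#'
#' @param treatment,control `coverage_track`s on identical bins.
#' @return A `coverage_track` labelled `control-subtracted`.
#' @export
subtract_control <- function(treatment, control) {
  assert_same_binning(treatment, control)
  out <- treatment
  out$value <- pmax(treatment$value - control$value, 0)
  new_coverage_track(as_tibble(out), attr(treatment, "bin_size"),
                     "control-subtracted", attr(treatment, "total_units"))
}

#' Allele-specific coverage tracks from tagged units
#'
#' Builds one RPKM track from the G1-tagged units and one from the
#' G2-tagged units, each normalized by its own tagged-unit total (the
#' allele-specific display convention).
#'
#' @param tagged Output of [tag_library()] (or any tibble with `chrom`,
#'   `start`, `end`, `tag`).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param bin_size Bin width (bp).
#' @param normalization Passed to [rpkm_track()].
#' @return A list with `coverage_track`s `g1` and `g2`.
#' @export
allelic_tracks <- function(tagged, chrom_lengths, bin_size = 50L,
                           normalization = "rpkm") {
  list(
    g1 = rpkm_track(filter(tagged, .data$tag == "G1"), chrom_lengths,
                    bin_size, normalization),
    g2 = rpkm_track(filter(tagged, .data$tag == "G2"), chrom_lengths,
                    bin_size, normalization))
}
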