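#' Per-gene allelic expression ratios
#'
#' For every expressed gene (TPM above `min_tpm`, default 1) with at least
#' one informative read, computes the Xi fraction `g1 / (g1 + g2)` from
#' informative (G1 + G2) reads — haplotype 1 being the Xi strain — and the
#' raw odds `g1 / g2`. Conflicting and unassigned reads are excluded from
#' the ratio. Genes omitted for low expression or lack of informative
#' reads are listed with a reason in the `omitted` attribute.
#'
#' @param expression Output of [quantify_expression()].
#' @param genes Annotation (used for `silencing_class` and chromosome).
#' @param min_tpm Expression floor; genes at or below it are omitted.
#' @param min_informative Minimum informative reads (default 1).
#' @return Tibble: `gene_id`, `library`, `chrom`, `silencing_class`,
#'   `informative`, `xi_fraction`, `xi_odds`, `tpm`.
#' @export
allelic_ratios <- function(expression, genes, min_tpm = 1,
                           min_informative = 1) {
  joined <- expression %>%
    inner_join(select(genes, "gene_id", "chrom", "silencing_class"),
               by = "gene_id") %>%
    mutate(informative = .data$g1 + .data$g2)
  omitted <- joined %>%
    filter(.data$tpm <= min_tpm | .data$informative < min_informative) %>%
    transmute(.data$gene_id, .data$library,
              reason = ifelse(.data$tpm <= min_tpm, "low_expression",
                              "no_informative_reads"))
  out <- joined %>%
    filter(.data$tpm > min_tpm, .data$informative >= min_informative) %>%
    transmute(.data$gene_id, .data$library, .data$chrom,
              .data$silencing_class, .data$informative,
              xi_fraction = .data$g1 / .data$informative,
              xi_odds = .data$g1 / .data$g2,
              .data$tpm)
  structure(out, omitted = omitted)
}

# allelic TPM split: gene TPM apportioned by informative-read fractions
allelic_tpm <- function(expression) {
  expression %>%
    mutate(informative = .data$g1 + .data$g2,
           tpm_xi = ifelse(.data$informative > 0,
                           .data$tpm * .data$g1 / .data$informative, NA_real_),
           tpm_xa = ifelse(.data$informative > 0,
                           .data$tpm * .data$g2 / .data$informative, NA_real_))
}

#' Fold-change calls between conditions at a chosen allele scope
#'
#' Computes, per gene, the ratio of condition-mean TPM (replicate clones
#' averaged before the ratio) between a test and a reference condition, at
#' diploid scope (total TPM), Xi scope (TPM apportioned to haplotype 1 by
#' the informative-read fraction) or Xa scope (haplotype 2), and calls each
#' gene `increased` (fold >= threshold), `decreased` (fold <= 1/threshold)
#' or `unchanged` at the 1.25-fold threshold used for X-linked
#' dysregulation. A zero reference mean with a nonzero test mean yields an
#' infinite fold, called `increased` and flagged.
#'
#' @param expression Output of [quantify_expression()].
#' @param libraries Library design tibble (`library`, `condition`,
#'   `timepoint`).
#' @param scope `"diploid"`, `"xi"` or `"xa"`.
#' @param timepoint Timepoint analysed (default the design's last).
#' @param reference,test Condition labels (defaults: first condition as
#'   reference, second as test).
#' @param threshold Fold-change call threshold (default 1.25).
#' @param min_informative For allelic scopes, minimum condition-summed
#'   informative reads for a gene to be assayed (default 1).
#' @return Tibble: `gene_id`, `scope`, `wt_mean`, `ko_mean`, `fold`,
#'   `log2_fold`, `call`, `flagged`; the fraction of calls per category is
#'   attached as the `call_fractions` attribute.
#' @export
fold_change_calls <- function(expression, libraries,
                              scope = c("diploid", "xi", "xa"),
                              timepoint = NULL, reference = NULL,
                              test = NULL, threshold = 1.25,
                              min_informative = 1) {
  scope <- match.arg(scope)
  conds <- unique(libraries$condition)
  reference <- reference %||% conds[[1]]
  test <- test %||% setdiff(conds, reference)[[1]]
  timepoint <- timepoint %||% tail(unique(libraries$timepoint), 1)

  lib_sel <- libraries %>%
    filter(.data$timepoint == !!timepoint,
           .data$condition %in% c(reference, test))
  dat <- expression %>%
    inner_join(select(lib_sel, "library", "condition"), by = "library") %>%
    allelic_tpm()
  value_col <- switch(scope, diploid = "tpm", xi = "tpm_xi", xa = "tpm_xa")

  per_cond <- dat %>%
    group_by(.data$gene_id, .data$condition) %>%
    summarise(mean_tpm = mean(.data[[value_col]]),
              informative = sum(.data$informative), .groups = "drop")
  if (scope != "diploid") {
    assayable <- per_cond %>%
      group_by(.data$gene_id) %>%
      summarise(ok = all(!is.na(.data$mean_tpm)) &
                  all(.data$informative >= min_informative)) %>%
      filter(.data$ok) %>% pull("gene_id")
    per_cond <- filter(per_cond, .data$gene_id %in% assayable)
  }
  out <- per_cond %>%
    select(-"informative") %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "mean_tpm") %>%
    rename(wt_mean = !!reference, ko_mean = !!test) %>%
    mutate(scope = scope,
           fold = .data$ko_mean / .data$wt_mean,
           flagged = .data$wt_mean == 0 & .data$ko_mean > 0,
           fold = ifelse(.data$flagged, Inf, .data$fold),
           log2_fold = log2(.data$fold),
           call = dplyr::case_when(
             .data$fold >= threshold ~ "increased",
             .data$fold <= 1 / threshold ~ "decreased",
             TRUE ~ "unchanged")) %>%
    select("gene_id", "scope", "wt_mean", "ko_mean", "fold", "log2_fold",
           "call", "flagged")
  fr <- out %>%
    count(.data$call) %>%
    mutate(fraction = .data$n / sum(.data$n))
  structure(out, call_fractions = fr)
}

#' Median allelic expression by silencing class
#'
#' Summarises, per silencing class and condition (at one timepoint), the
#' median Xi- and Xa-apportioned TPM and the number of class members
#' assayed — the histogram-style summary of silencing-timing clusters
#' (early, intermediate, late, escape).
#'
#' @param expression Output of [quantify_expression()].
#' @param genes Annotation carrying `silencing_class`; class labels other
#'   than early/intermediate/late/escape/xist/autosomal are an error.
#' @param libraries Library design tibble.
#' @param timepoint Timepoint to summarise (default the design's last).
#' @param classes Classes to keep (default the four temporal clusters).
#' @return Tibble: `silencing_class`, `condition`, `median_xi`,
#'   `median_xa`, `n`.
#' @export
silencing_class_summary <- function(expression, genes, libraries,
                                    timepoint = NULL,
                                    classes = c("early", "intermediate",
                                                "late", "escape")) {
  known <- c("early", "intermediate", "late", "escape", "xist", "autosomal")
  bad <- setdiff(unique(genes$silencing_class), known)
  if (length(bad) > 0L) {
    abort(paste0("unknown silencing class label: ",
                 paste(bad, collapse = ", ")))
  }
  timepoint <- timepoint %||% tail(unique(libraries$timepoint), 1)
  lib_sel <- filter(libraries, .data$timepoint == !!timepoint)
  expression %>%
    inner_join(select(lib_sel, "library", "condition"), by = "library") %>%
    inner_join(select(genes, "gene_id", "silencing_class"), by = "gene_id") %>%
    filter(.data$silencing_class %in% classes) %>%
    allelic_tpm() %>%
    filter(.data$informative > 0) %>%
    group_by(silencing_class = factor(.data$silencing_class,
                                      levels = classes),
             .data$condition) %>%
    summarise(median_xi = median(.data$tpm_xi),
              median_xa = median(.data$tpm_xa),
              n = dplyr::n_distinct(.data$gene_id), .groups = "drop")
}

#' Call escape from the Xi fraction
#'
#' A gene escapes silencing when its Xi transcript fraction is at or above
#' the threshold (default 0.1). The study itself used curated escape lists;
#' this data-driven classifier serves simulated data, where the truth is
#' known.
#'
#' @param ratios Output of [allelic_ratios()].
#' @param threshold Xi-fraction threshold (default 0.1).
#' @return `ratios` with an added logical `escape` column.
#' @export
escape_call <- function(ratios, threshold = 0.1) {
  mutate(ratios, escape = .data$xi_fraction >= threshold)
}

#' Differentiation-induction contrast for one gene
#'
#' Per condition, the fold change of a named gene's mean TPM at the later
#' timepoint relative to the earlier one — the Xist induction contrast
#' (wild type around 6-fold, knockout around 2.5-fold in the study). A
#' zero baseline gives an infinite, flagged fold.
#'
#' @param expression Output of [quantify_expression()].
#' @param libraries Library design tibble.
#' @param gene_id Gene to contrast (the Xist-like locus in simulations).
#' @param timepoints Length-2 character vector `c(baseline, induced)`;
#'   default the design's first two timepoints.
#' @return Tibble: `condition`, `gene_id`, `baseline_tpm`, `induced_tpm`,
#'   `fold`, `log2_fold`, `flagged`.
#' @export
induction_contrast <- function(expression, libraries, gene_id,
                               timepoints = NULL) {
  timepoints <- timepoints %||% unique(libraries$timepoint)[1:2]
  expression %>%
    filter(.data$gene_id == !!gene_id) %>%
    inner_join(select(libraries, "library", "condition", "timepoint"),
               by = "library") %>%
    filter(.data$timepoint %in% timepoints) %>%
    group_by(.data$condition, .data$timepoint) %>%
    summarise(mean_tpm = mean(.data$tpm), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "timepoint", values_from = "mean_tpm") %>%
    rename(baseline_tpm = !!timepoints[[1]],
           induced_tpm = !!timepoints[[2]]) %>%
    mutate(gene_id = !!gene_id,
           flagged = .data$baseline_tpm == 0,
           fold = ifelse(.data$flagged, Inf,
                         .data$induced_tpm / .data$baseline_tpm),
           log2_fold = log2(.data$fold)) %>%
    select("condition", "gene_id", "baseline_tpm", "induced_tpm",
           "fold", "log2_fold", "flagged")
}
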