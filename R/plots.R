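#' Plot allelic X-linked expression ratios by library
#'
#' Boxplots of per-gene Xi fractions (129:cast-style ratios) per library,
#' restricted to X-linked genes — the view in which wild-type
#' differentiation pulls ratios toward zero while an impaired knockout
#' leaves residual Xi expression.
#'
#' @param ratios Output of [allelic_ratios()].
#' @param genes Annotation (used to keep X-linked, non-Xist genes).
#' @return A ggplot.
#' @export
plot_allelic_ratios <- function(ratios, genes) {
  x_genes <- genes$gene_id[genes$silencing_class != "autosomal" &
                             !genes$is_xist]
  ggplot(filter(as_tibble(ratios), .data$gene_id %in% x_genes),
         aes(x = .data$library, y = .data$xi_fraction)) +
    geom_boxplot(outlier.size = 0.6, fill = "grey85") +
    labs(x = NULL, y = "Xi fraction g1/(g1+g2)",
         title = "Allelic X-linked expression ratios") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Plot fold-change calls along a chromosome
#'
#' Log2 TPM fold change (test/reference) per gene against gene position,
#' coloured by call — the chromosome-wide dysregulation view at a given
#' allele scope.
#'
#' @param folds Output of [fold_change_calls()].
#' @param genes Annotation (positions).
#' @param chrom Chromosome to display (default: all).
#' @return A ggplot.
#' @export
plot_fold_change <- function(folds, genes, chrom = NULL) {
  df <- as_tibble(folds) %>%
    inner_join(select(genes, "gene_id", "chrom", "start"), by = "gene_id") %>%
    filter(is.finite(.data$log2_fold))
  if (!is.null(chrom)) df <- filter(df, .data$chrom == !!chrom)
  ggplot(df, aes(x = .data$start / 1e3, y = .data$log2_fold,
                 colour = .data$call)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    geom_point(size = 1.5) +
    scale_colour_manual(values = c(increased = "#c0392b",
                                   decreased = "#2b6cb0",
                                   unchanged = "grey55")) +
    facet_wrap(~chrom, scales = "free_x") +
    labs(x = "position (kb)", y = "log2 fold change",
         colour = NULL,
         title = paste0("Fold-change calls (", df$scope[1], " scope)")) +
    theme_minimal()
}

#' Plot a coverage track
#' @param object A `coverage_track`.
#' @param ... Unused.
#' @method autoplot coverage_track
#' @export
autoplot.coverage_track <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = (.data$start + .data$end) / 2e3, y = .data$value)) +
    geom_area(fill = "#4a6fa5", alpha = 0.8) +
    facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    labs(x = "position (kb)",
         y = attr(object, "normalization") %||% "signal",
         title = "Coverage track") +
    theme_minimal()
}

#' Volcano plot of a differential-expression fit
#' @param object An `xci_de` object.
#' @param ... Unused.
#' @method autoplot xci_de
#' @export
autoplot.xci_de <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$log2_fold_change, y = -log10(.data$p_value),
                 colour = .data$de)) +
    geom_point(size = 1.2, alpha = 0.8) +
    scale_colour_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "grey60"),
                        labels = c(`TRUE` = "DE", `FALSE` = "not DE")) +
    labs(x = "log2 fold change", y = "-log10 p", colour = NULL,
         title = sprintf("Differential expression (%s vs %s)",
                         object$test, object$reference)) +
    theme_minimal()
}

#' Plot silencing-class medians per condition
#'
#' Side-by-side bars of median Xi and Xa allelic TPM per silencing class
#' and condition — the histogram summary of temporal silencing clusters.
#'
#' @param class_summary Output of [silencing_class_summary()].
#' @return A ggplot.
#' @export
plot_silencing_classes <- function(class_summary) {
  df <- class_summary %>%
    tidyr::pivot_longer(c("median_xi", "median_xa"),
                        names_to = "allele", values_to = "median_tpm") %>%
    mutate(allele = ifelse(.data$allele == "median_xi", "Xi", "Xa"))
  ggplot(df, aes(x = .data$silencing_class, y = .data$median_tpm,
                 fill = .data$condition)) +
    geom_col(position = "dodge") +
    facet_wrap(~allele, scales = "free_y") +
    labs(x = "silencing class", y = "median allelic TPM", fill = NULL,
         title = "Median allelic expression by silencing class") +
    theme_minimal()
}
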