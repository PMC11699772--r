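#' Count total and allelic reads per gene
#'
#' A read (or fragment) increments a gene's total count when its aligned
#' span overlaps any of the gene's exons; its G1/G2 tag increments the
#' corresponding allelic count (CF and UA units count toward the total
#' only). Units overlapping the exons of more than one gene are ambiguous
#' and are discarded from all genes; units overlapping no exon are
#' intergenic. Both are counted in the accounting attached as the
#' `counting` attribute, so that per library
#' `sum(total) + ambiguous + intergenic == passed units`.
#'
#' @param tagged Tagged tibble from [tag_library()] (needs `chrom`,
#'   `start`, `end`, `library`, `tag` and a unit id column).
#' @param genes Annotation from [simulate_annotation()] (uses the exon
#'   list-columns).
#' @return Long tibble: `gene_id`, `library`, `total`, `g1`, `g2` — every
#'   gene x library combination, zero-filled.
#' @export
count_reads <- function(tagged, genes) {
  if (nrow(genes) == 0L) abort("empty annotation")
  tagged <- as_tibble(tagged)
  unit <- if ("fragment_id" %in% names(tagged)) "fragment_id" else "read_id"
  exons <- genes %>%
    select("gene_id", "chrom", "exon_starts", "exon_ends") %>%
    tidyr::unnest(c("exon_starts", "exon_ends")) %>%
    rename(start = "exon_starts", end = "exon_ends")

  hits <- purrr::map(intersect(unique(tagged$chrom), unique(exons$chrom)),
                     function(cc) {
    a <- tagged[tagged$chrom == cc, ]
    e <- exons[exons$chrom == cc, ]
    ov <- IRanges::findOverlaps(IRanges::IRanges(a$start + 1L, a$end),
                                IRanges::IRanges(e$start + 1L, e$end))
    tibble(unit = a[[unit]][S4Vectors::queryHits(ov)],
           library = a$library[S4Vectors::queryHits(ov)],
           tag = a$tag[S4Vectors::queryHits(ov)],
           gene_id = e$gene_id[S4Vectors::subjectHits(ov)]) %>%
      distinct()
  }) %>% purrr::list_rbind()

  libs <- unique(tagged$library)
  empty <- tidyr::expand_grid(gene_id = genes$gene_id, library = libs) %>%
    mutate(total = 0L, g1 = 0L, g2 = 0L)
  if (is.null(hits) || nrow(hits) == 0L) {
    n_units <- tagged %>% distinct(.data$library, unit = .data[[unit]]) %>%
      count(.data$library, name = "intergenic")
    return(structure(empty, counting = mutate(n_units, ambiguous = 0L)))
  }

  genes_per_unit <- hits %>%
    group_by(.data$library, .data$unit) %>%
    summarise(n_genes = dplyr::n_distinct(.data$gene_id), .groups = "drop")
  ambiguous <- genes_per_unit %>% filter(.data$n_genes > 1L)
  unambig <- hits %>%
    anti_join(ambiguous, by = c("library", "unit"))

  counts <- unambig %>%
    group_by(.data$gene_id, .data$library) %>%
    summarise(total = n(),
              g1 = sum(.data$tag == "G1"),
              g2 = sum(.data$tag == "G2"), .groups = "drop")
  out <- empty %>%
    select("gene_id", "library") %>%
    left_join(counts, by = c("gene_id", "library")) %>%
    mutate(across(c("total", "g1", "g2"), ~ tidyr::replace_na(.x, 0L)))

  accounting <- tagged %>%
    distinct(.data$library, unit = .data[[unit]]) %>%
    count(.data$library, name = "passed_units") %>%
    left_join(count(ambiguous, .data$library, name = "ambiguous"),
              by = "library") %>%
    mutate(ambiguous = tidyr::replace_na(.data$ambiguous, 0L)) %>%
    left_join(out %>% group_by(.data$library) %>%
                summarise(assigned = sum(.data$total)), by = "library") %>%
    mutate(intergenic = .data$passed_units - .data$ambiguous - .data$assigned)
  structure(out, counting = accounting)
}

#' Counting accounting from [count_reads()]
#' @param x Output of [count_reads()].
#' @return Tibble with per-library `passed_units`, `ambiguous`, `assigned`,
#'   `intergenic`.
#' @export
counting_summary <- function(x) {
  attr(x, "counting") %||% abort("no counting attribute; use count_reads()")
}

#' Normalize counts to TPM and CPM
#'
#' TPM (transcripts per kilobase of exon length per million mapped reads):
#' per gene, a length-normalized rate `count / (exon length in kb)`; rates
#' are rescaled per library to sum to 1e6. CPM is computed analogously
#' without the length normalization. TPM and CPM columns each sum to 1e6
#' per library (up to floating-point tolerance); a library with zero total
#' counts yields an all-zero column with a warning.
#'
#' @param counts Long count tibble from [count_reads()].
#' @param genes Annotation with `gene_id` and `exon_length` (bp), or a
#'   tibble with those two columns.
#' @return `counts` with added `exon_length`, `cpm`, `tpm` columns.
#' @export
quantify_expression <- function(counts, genes) {
  lengths <- genes %>% select("gene_id", "exon_length")
  if (any(lengths$exon_length <= 0)) abort("gene lengths must be > 0")
  out <- counts %>%
    inner_join(lengths, by = "gene_id") %>%
    group_by(.data$library) %>%
    mutate(rate = .data$total / (.data$exon_length / 1000),
           rate_sum = sum(.data$rate),
           lib_total = sum(.data$total),
           tpm = ifelse(.data$rate_sum > 0,
                        .data$rate / .data$rate_sum * 1e6, 0),
           cpm = ifelse(.data$lib_total > 0,
                        .data$total / .data$lib_total * 1e6, 0)) %>%
    ungroup() %>%
    select(-"rate", -"rate_sum", -"lib_total")
  zero_libs <- out %>% group_by(.data$library) %>%
    summarise(z = all(.data$total == 0)) %>% filter(.data$z)
  if (nrow(zero_libs) > 0L) {
    warn(paste0("library with zero total counts: ",
                paste(zero_libs$library, collapse = ", ")))
  }
  out
}

#' Keep genes passing a minimum-CPM expression filter
#'
#' Retains genes with CPM at or above `min_cpm` in at least `min_libraries`
#' libraries (the inclusion rule used before differential expression:
#' 2.5 CPM in at least two libraries). `min_libraries` is deliberately a
#' required argument: published legends vary between "two" and "four"
#' libraries, so the caller must choose.
#'
#' @param expression Output of [quantify_expression()].
#' @param min_cpm Minimum CPM (inclusive); default 2.5.
#' @param min_libraries Number of libraries that must reach `min_cpm`.
#' @return `expression` restricted to retained genes; removed gene ids in
#'   the `removed_genes` attribute.
#' @export
expression_filter <- function(expression, min_cpm = 2.5, min_libraries) {
  n_lib <- dplyr::n_distinct(expression$library)
  if (min_libraries > n_lib) {
    abort(paste0("min_libraries (", min_libraries,
                 ") exceeds the number of libraries (", n_lib, ")"))
  }
  keep <- expression %>%
    group_by(.data$gene_id) %>%
    summarise(n_ok = sum(.data$cpm >= min_cpm)) %>%
    filter(.data$n_ok >= min_libraries) %>%
    pull("gene_id")
  structure(filter(expression, .data$gene_id %in% keep),
            removed_genes = setdiff(unique(expression$gene_id), keep))
}

# DESeq-style median-of-ratios size factors on a genes x libraries matrix
median_of_ratios <- function(mat) {
  loggeo <- rowMeans(log(mat))
  use <- is.finite(loggeo)
  if (!any(use)) return(setNames(rep(1, ncol(mat)), colnames(mat)))
  apply(mat[use, , drop = FALSE], 2,
        function(col) exp(median(log(col) - loggeo[use])))
}

#' Differential expression at the FDR 0.1 / 2-fold thresholds
#'
#' A documented substitute for a negative-binomial DE fit, not a
#' replication of one: counts are normalized with DESeq-style
#' median-of-ratios size factors, each gene is tested with a two-sided
#' Welch t-test on `log2(normalized count + 0.5)` between the two groups,
#' p-values are Benjamini-Hochberg adjusted, and a gene is flagged DE when
#' `FDR <= alpha` and `|fold change| >= fold_cutoff` (defaults 0.1 and 2).
#' The log2 fold change is the log-ratio of group means of normalized
#' counts (test group over reference).
#'
#' @param counts Long tibble with `gene_id`, `library`, `total`.
#' @param groups Tibble with columns `library`, `group`, or a named vector
#'   mapping library to group. Exactly two groups, each with >= 2
#'   libraries.
#' @param reference Group label used as the fold-change denominator;
#'   defaults to the first group level.
#' @param alpha FDR threshold for the DE flag.
#' @param fold_cutoff Fold-change cutoff for the DE flag.
#' @return An object of class `xci_de`; use [tidy()] for the per-gene
#'   table and [glance()] for the fit summary.
#' @export
differential_expression <- function(counts, groups, reference = NULL,
                                    alpha = 0.1, fold_cutoff = 2) {
  if (!is.data.frame(groups)) {
    groups <- tibble(library = names(groups), group = unname(groups))
  }
  lv <- unique(groups$group)
  if (length(lv) != 2L) abort("exactly two groups are required")
  reference <- reference %||% lv[[1]]
  test_grp <- setdiff(lv, reference)
  sizes <- count(groups, .data$group)
  if (any(sizes$n < 2L)) abort("each group needs at least two libraries")

  mat <- counts %>%
    select("gene_id", "library", "total") %>%
    tidyr::pivot_wider(names_from = "library", values_from = "total") %>%
    tibble::column_to_rownames("gene_id") %>%
    as.matrix()
  mat <- mat[, groups$library, drop = FALSE]
  sf <- median_of_ratios(mat)
  norm <- sweep(mat, 2, sf, "/")
  lognorm <- log2(norm + 0.5)
  ref_cols <- groups$library[groups$group == reference]
  test_cols <- groups$library[groups$group == test_grp]

  lfc <- log2((rowMeans(norm[, test_cols, drop = FALSE]) + 0.5) /
                (rowMeans(norm[, ref_cols, drop = FALSE]) + 0.5))
  pval <- vapply(seq_len(nrow(lognorm)), function(i) {
    x <- lognorm[i, test_cols]
    y <- lognorm[i, ref_cols]
    if (stats::sd(c(x, y)) == 0) return(1)
    tryCatch(t.test(x, y)$p.value, error = function(e) 1)
  }, numeric(1))
  fdr <- p.adjust(pval, method = "BH")
  tab <- tibble(gene_id = rownames(mat),
                log2_fold_change = lfc,
                p_value = pval,
                fdr = fdr,
                de = fdr <= alpha & abs(lfc) >= log2(fold_cutoff))
  structure(list(table = tab, size_factors = sf,
                 reference = reference, test = test_grp,
                 alpha = alpha, fold_cutoff = fold_cutoff),
            class = "xci_de")
}

#' @export
print.xci_de <- function(x, ...) {
  cat("<xci_de> ", x$test, " vs ", x$reference, ": ",
      sum(x$table$de), "/", nrow(x$table),
      " genes DE at FDR <= ", x$alpha, ", |fold| >= ", x$fold_cutoff,
      "\n", sep = "")
  invisible(x)
}

#' Per-gene differential-expression table
#' @param x An `xci_de` object.
#' @param ... Unused.
#' @return Tibble with `gene_id`, `log2_fold_change`, `p_value`, `fdr`,
#'   `de`.
#' @method tidy xci_de
#' @export
tidy.xci_de <- function(x, ...) x$table

#' One-row summary of a differential-expression fit
#' @param x An `xci_de` object.
#' @param ... Unused.
#' @method glance xci_de
#' @export
glance.xci_de <- function(x, ...) {
  tibble(n_genes = nrow(x$table), n_de = sum(x$table$de),
         n_up = sum(x$table$de & x$table$log2_fold_change > 0),
         n_down = sum(x$table$de & x$table$log2_fold_change < 0),
         alpha = x$alpha, fold_cutoff = x$fold_cutoff,
         reference = x$reference, test = x$test)
}
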