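#' Default planted CUT&RUN domain set for a pipeline run
#'
#' A background H3K27me3-like domain shared by both conditions plus, in the
#' knockout only, an Xi-specific (haplotype-1-biased) domain over the
#' Xist-like locus — the configuration in which the knockout gains
#' Xi peaks absent from the wild type.
#'
#' @param genes Annotation from [simulate_annotation()].
#' @param enrichment Enrichment factor of the planted domains.
#' @param conditions Condition labels (first = wild type).
#' @return Domain tibble for [simulate_cutrun()] with a `library` column
#'   (`<condition>_h3k27me3`).
#' @export
default_cutrun_domains <- function(genes, enrichment = 8,
                                   conditions = c("wt", "ko")) {
  xist <- genes[genes$is_xist, ]
  if (nrow(xist) == 0L) abort("annotation has no Xist-like locus")
  auto <- genes %>% filter(.data$silencing_class == "autosomal") %>% head(1)
  shared <- purrr::map(conditions, function(cd) {
    tibble(chrom = auto$chrom, start = auto$start, end = auto$end,
           enrichment = enrichment, hap1_prob = 0.5,
           library = paste0(cd, "_h3k27me3"))
  }) %>% purrr::list_rbind()
  ko_only <- tibble(chrom = xist$chrom,
                    start = pmax(0L, xist$start - 2000L),
                    end = xist$end + 2000L,
                    enrichment = enrichment, hap1_prob = 0.95,
                    library = paste0(conditions[[2]], "_h3k27me3"))
  bind_rows(shared, ko_only)
}

#' Run the full allelic expression + chromatin pipeline on simulated data
#'
#' Executes simulate -> pseudo-genome -> tag -> quantify -> report for the
#' RNA arm and simulate -> tag -> tracks -> peaks -> Xi-gain calling for
#' the CUT&RUN arm, entirely from one configuration and program, and
#' returns all tables plus the truth sets. With `outdir` set, every table
#' is written (FASTA, VCF, tab-delimited tables, bedGraph, BED) along with
#' a JSON run manifest listing each file with its MD5 checksum and the
#' parameters and seed used. Reruns with the same config are
#' byte-identical.
#'
#' @param config A [sim_config()].
#' @param program An [xci_program()].
#' @param outdir Optional output directory (created if needed).
#' @param min_mapq,max_fragment,min_cpm,min_libraries,fold_threshold
#'   Analysis parameters (defaults: 30, 1000 bp, 2.5 CPM in 2 libraries,
#'   1.25-fold).
#' @param cutrun Logical; run the CUT&RUN arm (default TRUE).
#' @param threshold_quantile Peak-calling threshold quantile.
#' @param peak_signal_mult Post-call signal filter: peaks must have total
#'   signal at least this multiple of the calling threshold (the
#'   scale-free analogue of the fixed signal cutoffs applied to called
#'   peaks before comparisons).
#' @return A list of class `xci_run` with elements `snps`, `genes`,
#'   `truth_expr`, `rna` (tagged summary, counts, expression, ratios,
#'   fold calls per scope, class summary, induction, DE fit) and `cutrun`
#'   (summaries, peaks, gain report), plus `manifest` when written.
#' @export
run_pipeline <- function(config = sim_config(), program = xci_program(),
                         outdir = NULL, min_mapq = 30, max_fragment = 1000,
                         min_cpm = 2.5, min_libraries = 2,
                         fold_threshold = 1.25, cutrun = TRUE,
                         threshold_quantile = 0.99, peak_signal_mult = 3) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage `", name, "` failed: ",
                   conditionMessage(e)))
    })
  }
  ref <- stage("simulate_reference", simulate_hybrid_reference(config))
  snps <- stage("filter_variants", filter_variants(ref$variants))
  genomes <- stage("build_pseudogenomes",
                   build_pseudogenomes(ref$reference, snps))
  genes <- stage("simulate_annotation", simulate_annotation(config, program))
  truth_expr <- stage("expression_program",
                      expression_program(genes, program, config))
  libs <- library_design(program)
  chrom_len <- setNames(Biostrings::width(ref$reference),
                        names(ref$reference))

  rna_sim <- stage("simulate_rnaseq",
                   simulate_rnaseq(genomes, genes, truth_expr, config, libs))
  tagged <- stage("tag_rna",
                  tag_library(rna_sim$alignments, snps, mode = "rna",
                              min_mapq = min_mapq))
  counts <- stage("count_reads", count_reads(tagged, genes))
  expr <- stage("quantify", quantify_expression(counts, genes))
  ratios <- stage("ratios", allelic_ratios(expr, genes))
  folds <- purrr::map(
    setNames(c("diploid", "xi", "xa"), c("diploid", "xi", "xa")),
    ~ stage(paste0("folds_", .x),
            fold_change_calls(expr, libs, scope = .x,
                              threshold = fold_threshold)))
  class_summary <- stage("class_summary",
                         silencing_class_summary(expr, genes, libs))
  xist_id <- genes$gene_id[genes$is_xist][1]
  induction <- stage("induction",
                     induction_contrast(expr, libs, xist_id))
  de <- stage("differential_expression", {
    tp <- tail(program$timepoints, 1)
    de_libs <- filter(libs, .data$timepoint == tp)
    de_counts <- expr %>%
      dplyr::semi_join(de_libs, by = "library") %>%
      expression_filter(min_cpm = min_cpm, min_libraries = min_libraries)
    differential_expression(
      de_counts, setNames(de_libs$condition, de_libs$library),
      reference = program$conditions[[1]])
  })
  rna <- list(summary = allelic_summary(tagged), counts = counts,
              expression = expr, ratios = ratios, folds = folds,
              class_summary = class_summary, induction = induction,
              de = de, truth = rna_sim$truth)

  cr <- NULL
  if (cutrun) {
    cr <- stage("cutrun", {
      conds <- program$conditions[1:2]
      cr_libs <- tibble(
        library = c(paste0(conds, "_h3k27me3"), "igg"),
        is_control = c(FALSE, FALSE, TRUE))
      domains <- default_cutrun_domains(genes, conditions = conds)
      sim <- simulate_cutrun(genomes, domains, config, cr_libs)
      tg <- tag_library(sim$alignments, snps, mode = "cutrun",
                        min_mapq = min_mapq, max_fragment = max_fragment)
      per_lib <- split(as_tibble(tg), tg$library)
      igg_track <- rpkm_track(per_lib$igg, chrom_len, config$bin_size)
      xchr <- names(chrom_len)[config$chromosomes$is_x][1]
      tracks <- purrr::map(conds, function(cd) {
        lib <- per_lib[[paste0(cd, "_h3k27me3")]]
        al <- allelic_tracks(lib, chrom_len, config$bin_size)
        list(total = subtract_control(
          rpkm_track(lib, chrom_len, config$bin_size), igg_track),
          g1 = al$g1, g2 = al$g2)
      }) %>% setNames(conds)
      xi_peaks <- purrr::map(conds, function(cd) {
        tr <- tracks[[cd]]$g1
        tr_x <- new_coverage_track(filter(as_tibble(tr), .data$chrom == xchr),
                                   attr(tr, "bin_size"),
                                   attr(tr, "normalization"),
                                   attr(tr, "total_units"))
        pk <- call_peaks(tr_x, threshold_quantile = threshold_quantile,
                         library = paste0(cd, "_Xi"))
        # signal filter mirroring the post-call signal cutoffs: drop
        # marginal (noise) peaks whose summed signal barely exceeds the
        # calling threshold
        filter_peaks_by_signal(pk, peak_signal_mult *
                                 (attr(pk, "threshold") %||% 0))
      }) %>% setNames(conds)
      tssr <- tss_regions(genes, chrom_len)
      gains <- xi_specific_gains(xi_peaks[[conds[[2]]]],
                                 xi_peaks[[conds[[1]]]],
                                 chrom = xchr,
                                 chrom_length = chrom_len[[xchr]],
                                 genes = genes, tss = tssr)
      list(summary = allelic_summary(tg), domains = domains,
           tracks = tracks, xi_peaks = xi_peaks, gains = gains,
           truth = sim$truth)
    })
  }

  result <- structure(
    list(config = config, program = program, snps = snps, genes = genes,
         truth_expr = truth_expr, libraries = libs, rna = rna, cutrun = cr),
    class = "xci_run")

  if (!is.null(outdir)) {
    result$manifest <- write_run(result, ref, outdir)
  }
  result
}

# write an xci_run's tables and a checksum manifest
write_run <- function(result, ref, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  write_fasta(ref$reference, p("reference.fa"))
  write_vcf(ref$variants, p("variants.vcf"))
  readr::write_tsv(as_tibble(result$snps), p("retained_snps.tsv"))
  readr::write_tsv(filter_summary(result$snps), p("variant_filter_summary.tsv"))
  readr::write_tsv(result$genes %>%
                     select(-"exon_starts", -"exon_ends"), p("genes.tsv"))
  readr::write_tsv(result$rna$summary, p("allelic_mapping_summary.tsv"))
  readr::write_tsv(as_tibble(result$rna$counts), p("counts.tsv"))
  readr::write_tsv(result$rna$expression, p("expression.tsv"))
  readr::write_tsv(as_tibble(result$rna$ratios), p("allelic_ratios.tsv"))
  purrr::iwalk(result$rna$folds, function(f, nm) {
    readr::write_tsv(as_tibble(f), p(paste0("fold_calls_", nm, ".tsv")))
  })
  readr::write_tsv(result$rna$class_summary, p("silencing_class_summary.tsv"))
  readr::write_tsv(result$rna$induction, p("xist_induction.tsv"))
  readr::write_tsv(tidy(result$rna$de), p("differential_expression.tsv"))
  if (!is.null(result$cutrun)) {
    purrr::iwalk(result$cutrun$tracks, function(tr, cd) {
      write_bedgraph(tr$total, p(paste0(cd, "_h3k27me3.bedgraph")))
      write_bedgraph(tr$g1, p(paste0(cd, "_h3k27me3_g1.bedgraph")))
      write_bedgraph(tr$g2, p(paste0(cd, "_h3k27me3_g2.bedgraph")))
    })
    purrr::iwalk(result$cutrun$xi_peaks, function(pk, cd) {
      write_peaks_bed(pk, p(paste0(cd, "_xi_peaks.bed")))
    })
    write_peaks_bed(result$cutrun$gains$gains, p("xi_gained_peaks.bed"))
  }
  files <- sort(list.files(outdir, full.names = TRUE))
  manifest <- list(
    seed = result$config$seed,
    parameters = result$config[setdiff(names(result$config), "chromosomes")],
    files = tibble(file = basename(files),
                   md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  manifest
}

#' @export
print.xci_run <- function(x, ...) {
  cat("<xci_run> seed", x$config$seed, "-",
      nrow(x$genes), "genes,", nrow(x$snps), "SNPs,",
      nrow(x$libraries), "RNA libraries",
      if (!is.null(x$cutrun)) "+ CUT&RUN arm" else "", "\n")
  invisible(x)
}
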