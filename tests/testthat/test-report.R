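simple_genes <- function() {
  tibble::tibble(gene_id = c("gx", "ga"), chrom = c("chrX", "chr1"),
                 silencing_class = c("early", "autosomal"),
                 is_xist = FALSE, start = 0L, end = 1000L, tss = 0L,
                 strand = "+")
}

test_that("allelic ratios follow the informative-read definition", {
  expr <- manual_expression(
    ~gene_id, ~library, ~total, ~g1, ~g2, ~tpm,
    "gx", "l1", 100L, 0L, 50L, 20,
    "ga", "l1", 100L, 30L, 30L, 20,
    "gx", "l2", 100L, 10L, 30L, 0.5,   # below the TPM floor
    "ga", "l2", 100L, 0L, 0L, 20)      # no informative reads
  r <- allelic_ratios(expr, simple_genes())
  expect_equal(nrow(r), 2L)
  expect_equal(r$xi_fraction[r$gene_id == "gx"], 0)     # fully silenced
  expect_equal(r$xi_fraction[r$gene_id == "ga"], 0.5)   # biallelic
  expect_equal(r$xi_odds[r$gene_id == "ga"], 1)
  om <- attr(r, "omitted")
  expect_equal(om$reason[om$gene_id == "gx" & om$library == "l2"],
               "low_expression")
  expect_equal(om$reason[om$gene_id == "ga" & om$library == "l2"],
               "no_informative_reads")
  # escape calling at the default threshold
  ec <- escape_call(r)
  expect_false(ec$escape[ec$gene_id == "gx"])
  expect_true(ec$escape[ec$gene_id == "ga"])
  expect_false(escape_call(r, threshold = 0.6)$escape[ec$gene_id == "ga"])
})

fold_fixture <- function(ko_tpm) {
  libs <- tidyr::expand_grid(condition = c("wt", "ko"),
                             replicate = 1:2) %>%
    dplyr::mutate(library = paste0(condition, "_r", replicate),
                  timepoint = "D15")
  expr <- tidyr::expand_grid(gene_id = names(ko_tpm),
                             library = libs$library) %>%
    dplyr::mutate(condition = sub("_r.", "", .data$library),
                  tpm = ifelse(.data$condition == "ko",
                               ko_tpm[.data$gene_id], 100),
                  total = 200L, g1 = 50L, g2 = 50L,
                  cpm = .data$tpm, exon_length = 1000L) %>%
    dplyr::select(-"condition")
  list(expr = expr, libs = libs)
}

test_that("fold-change calls use the 1.25 threshold on clone-averaged TPM", {
  fx <- fold_fixture(c(up = 130, flat = 100, down = 50, zero = 0))
  calls <- fold_change_calls(fx$expr, fx$libs, scope = "diploid")
  get <- function(g) calls$call[calls$gene_id == g]
  expect_equal(get("up"), "increased")     # fold 1.30
  expect_equal(get("flat"), "unchanged")   # fold 1.00
  expect_equal(get("down"), "decreased")   # fold 0.50
  expect_equal(get("zero"), "decreased")
  # boundary: exactly 1.25 is increased, exactly 1/1.25 decreased
  fb <- fold_fixture(c(edge_up = 125, edge_dn = 80))
  cb <- fold_change_calls(fb$expr, fb$libs, scope = "diploid")
  expect_equal(cb$call[cb$gene_id == "edge_up"], "increased")
  expect_equal(cb$call[cb$gene_id == "edge_dn"], "decreased")
  # identical conditions -> everything unchanged
  f0 <- fold_fixture(c(a = 100, b = 100))
  c0 <- fold_change_calls(f0$expr, f0$libs, scope = "diploid")
  expect_true(all(c0$call == "unchanged"))
  # scale invariance: multiplying all TPM by a constant changes nothing
  fx2 <- fx
  fx2$expr$tpm <- fx2$expr$tpm * 7.3
  c2 <- fold_change_calls(fx2$expr, fx2$libs, scope = "diploid")
  expect_equal(c2$call, calls$call)
  expect_equal(c2$fold, calls$fold, tolerance = 1e-12)
  # zero reference with nonzero test -> infinite, flagged, increased
  frev <- fold_fixture(c(g = 100))
  frev$expr$tpm[grepl("wt", frev$expr$library)] <- 0
  crev <- fold_change_calls(frev$expr, frev$libs, scope = "diploid")
  expect_true(crev$flagged)
  expect_equal(crev$call, "increased")
  expect_equal(crev$fold, Inf)
})

test_that("allelic scopes split TPM by informative-read fractions", {
  libs <- tibble::tibble(library = c("wt_r1", "wt_r2", "ko_r1", "ko_r2"),
                         condition = rep(c("wt", "ko"), each = 2),
                         timepoint = "D15", replicate = c(1, 2, 1, 2))
  # Xi share rises from 10% to 20% while total TPM is constant:
  # Xi-scope fold = 2, Xa-scope fold = 8/9 (neither crosses 1.25 down)
  expr <- tidyr::expand_grid(gene_id = "g", library = libs$library) %>%
    dplyr::mutate(tpm = 100, total = 100L,
                  g1 = ifelse(grepl("wt", .data$library), 10L, 20L),
                  g2 = ifelse(grepl("wt", .data$library), 90L, 80L),
                  cpm = 100, exon_length = 1000L)
  xi <- fold_change_calls(expr, libs, scope = "xi")
  xa <- fold_change_calls(expr, libs, scope = "xa")
  expect_equal(xi$fold, 2)
  expect_equal(xi$call, "increased")
  expect_equal(xa$fold, 8 / 9, tolerance = 1e-12)
  expect_equal(xa$call, "unchanged")
})

test_that("class summaries compute medians per class and reject bad labels", {
  genes <- tibble::tibble(
    gene_id = c("e1", "e2", "esc"), chrom = "chrX",
    silencing_class = c("early", "early", "escape"),
    is_xist = FALSE, start = 0L, end = 100L, tss = 0L, strand = "+")
  libs <- tibble::tibble(library = c("wt_r1", "ko_r1"),
                         condition = c("wt", "ko"), timepoint = "D15",
                         replicate = 1)
  expr <- tidyr::expand_grid(gene_id = genes$gene_id,
                             library = libs$library) %>%
    dplyr::mutate(tpm = c(10, 12, 30, 40, 100, 110),
                  total = 100L, g1 = c(0L, 2L, 4L, 10L, 30L, 40L),
                  g2 = c(100L, 98L, 96L, 90L, 70L, 60L),
                  cpm = .data$tpm, exon_length = 1000L)
  cs <- silencing_class_summary(expr, genes, libs)
  # single-gene class: medians equal that gene's allelic values
  esc_wt <- cs[cs$silencing_class == "escape" & cs$condition == "wt", ]
  expr_esc <- expr[expr$gene_id == "esc" & expr$library == "wt_r1", ]
  expect_equal(esc_wt$median_xi,
               expr_esc$tpm * expr_esc$g1 / (expr_esc$g1 + expr_esc$g2))
  expect_equal(esc_wt$n, 1L)
  # brute-force median oracle for the two-gene class
  early_wt <- cs[cs$silencing_class == "early" & cs$condition == "wt", ]
  vals <- expr %>%
    dplyr::filter(.data$gene_id %in% c("e1", "e2"),
                  .data$library == "wt_r1") %>%
    dplyr::mutate(xi = .data$tpm * .data$g1 / (.data$g1 + .data$g2))
  expect_equal(early_wt$median_xi, sort(vals$xi)[1:2] %>% mean())
  # permutation invariance in gene order
  cs2 <- silencing_class_summary(expr[sample(nrow(expr)), ], genes, libs)
  expect_equal(as.data.frame(cs), as.data.frame(cs2))
  expect_error(
    silencing_class_summary(expr,
                            dplyr::mutate(genes, silencing_class = "odd"),
                            libs),
    "unknown")
})

test_that("induction contrast recovers planted fold changes", {
  libs <- tidyr::expand_grid(condition = c("wt", "ko"),
                             timepoint = c("D0", "D15")) %>%
    dplyr::mutate(library = paste0(condition, "_", timepoint),
                  replicate = 1)
  expr <- tidyr::expand_grid(gene_id = "xist", library = libs$library) %>%
    dplyr::mutate(tpm = c(10, 60, 10, 25),
                  total = 100L, g1 = 50L, g2 = 50L, cpm = .data$tpm,
                  exon_length = 1000L)
  ic <- induction_contrast(expr, libs, "xist")
  expect_equal(ic$fold[ic$condition == "wt"], 6)
  expect_equal(ic$fold[ic$condition == "ko"], 2.5)
  expect_equal(ic$log2_fold[ic$condition == "wt"], log2(6))
  # equal timepoints -> fold 1, log2 0
  expr1 <- dplyr::mutate(expr, tpm = 10)
  ic1 <- induction_contrast(expr1, libs, "xist")
  expect_true(all(ic1$fold == 1))
  expect_true(all(ic1$log2_fold == 0))
  # zero baseline flagged infinite
  expr0 <- dplyr::mutate(expr, tpm = ifelse(grepl("D0", library), 0, tpm))
  ic0 <- induction_contrast(expr0, libs, "xist")
  expect_true(all(ic0$flagged))
  expect_true(all(is.infinite(ic0$fold)))
})

test_that("the end-to-end pipeline is deterministic and writes a manifest", {
  cfg <- tiny_config(seed = 77L, reads_per_library = 2000L,
                     cutrun_fragments = 2000L)
  prog <- xci_program(replicates = 2L)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  r1 <- run_pipeline(cfg, prog, outdir = out1)
  r2 <- run_pipeline(cfg, prog, outdir = out2)
  # identical report tables on rerun with the same seed
  expect_equal(as.data.frame(r1$rna$expression),
               as.data.frame(r2$rna$expression))
  expect_equal(tidy(r1$rna$de), tidy(r2$rna$de))
  f1 <- list.files(out1); f2 <- list.files(out2)
  expect_identical(f1, f2)
  md1 <- tools::md5sum(file.path(out1, f1))
  md2 <- tools::md5sum(file.path(out2, f2))
  expect_identical(unname(md1), unname(md2))
  # the manifest lists the written files with checksums
  man <- jsonlite::read_json(file.path(out1, "manifest.json"),
                             simplifyVector = TRUE)
  expect_true(all(man$files$file %in% f1))
  recomputed <- unname(tools::md5sum(file.path(out1, man$files$file)))
  expect_identical(man$files$md5, recomputed)
  expect_equal(man$seed, 77L)
})
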