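# minimal hand-built annotation: one exon per gene
manual_genes <- function(...) {
  g <- tibble::tribble(...)
  g %>%
    dplyr::mutate(exon_starts = purrr::map(.data$start, identity),
                  exon_ends = purrr::map(.data$end, identity),
                  exon_length = .data$end - .data$start,
                  tss = .data$start, strand = "+",
                  silencing_class = "autosomal", is_xist = FALSE)
}

tagged_row <- function(id, chrom, start, end, tag, library = "lib") {
  tibble::tibble(read_id = id, library = library, chrom = chrom,
                 start = start, end = end, tag = tag)
}

test_that("gene counting separates totals, alleles, ambiguous, intergenic", {
  genes <- manual_genes(
    ~gene_id, ~chrom, ~start, ~end,
    "gA", "chr1", 100L, 600L,
    "gB", "chr1", 500L, 1100L,   # overlaps gA in [500, 600)
    "gC", "chr1", 2000L, 2500L)
  reads <- dplyr::bind_rows(
    purrr::map(1:10, ~ tagged_row(paste0("g1_", .x), "chr1", 150L, 200L, "G1")),
    purrr::map(1:5, ~ tagged_row(paste0("g2_", .x), "chr1", 150L, 200L, "G2")),
    purrr::map(1:3, ~ tagged_row(paste0("ua_", .x), "chr1", 150L, 200L, "UA")),
    tagged_row("amb", "chr1", 550L, 590L, "G1"),     # spans gA and gB
    tagged_row("inter", "chr1", 1500L, 1550L, "G1")) # no gene
  cnt <- count_reads(reads, genes)
  gA <- cnt[cnt$gene_id == "gA", ]
  expect_equal(gA$total, 18L)
  expect_equal(gA$g1, 10L)
  expect_equal(gA$g2, 5L)
  expect_equal(cnt$total[cnt$gene_id == "gB"], 0L)
  acc <- counting_summary(cnt)
  expect_equal(acc$ambiguous, 1L)
  expect_equal(acc$intergenic, 1L)
  # conservation: totals + ambiguous + intergenic = passed units
  expect_equal(sum(cnt$total) + acc$ambiguous + acc$intergenic,
               acc$passed_units)
  # brute-force interval scan oracle
  brute <- purrr::map_int(genes$gene_id, function(g) {
    gr <- genes[genes$gene_id == g, ]
    sum(purrr::map_lgl(seq_len(nrow(reads)), function(i) {
      r <- reads[i, ]
      own <- r$start < gr$end & r$end > gr$start & r$chrom == gr$chrom
      others <- sum(r$start < genes$end & r$end > genes$start &
                      r$chrom == genes$chrom) > 1
      own && !others
    }))
  })
  expect_equal(cnt$total[match(genes$gene_id, cnt$gene_id)], brute)
  # no reads -> zero matrix
  z <- count_reads(reads[0, ], genes)
  expect_true(all(z$total == 0))
  expect_error(count_reads(reads, genes[0, ]), "empty annotation")
})

test_that("TPM normalization matches hand computation and sums to 1e6", {
  genes <- manual_genes(
    ~gene_id, ~chrom, ~start, ~end,
    "a", "chr1", 0L, 1000L,
    "b", "chr1", 2000L, 4000L,
    "c", "chr1", 5000L, 8000L)
  counts <- tibble::tibble(gene_id = c("a", "b", "c"), library = "l1",
                           total = c(10L, 20L, 30L), g1 = 0L, g2 = 0L)
  expr <- quantify_expression(counts, genes)
  # rates (10, 10, 10) -> equal TPM thirds
  expect_equal(expr$tpm, rep(1e6 / 3, 3), tolerance = 1e-12)
  expect_equal(sum(expr$tpm), 1e6, tolerance = 1e-9)
  expect_equal(sum(expr$cpm), 1e6, tolerance = 1e-9)
  # one-gene library -> TPM = 1e6; two equal genes -> 5e5 each
  one <- quantify_expression(counts[1, ], genes)
  expect_equal(one$tpm, 1e6)
  two <- quantify_expression(
    tibble::tibble(gene_id = c("a", "b"), library = "l1",
                   total = c(7L, 14L), g1 = 0L, g2 = 0L),
    manual_genes(~gene_id, ~chrom, ~start, ~end,
                 "a", "chr1", 0L, 1000L, "b", "chr1", 2000L, 3000L) %>%
      dplyr::mutate(exon_length = 1000L)) %>%
    dplyr::filter(.data$total == 7L | .data$total == 14L)
  # equal lengths, counts 7 and 14 -> TPM 1/3 and 2/3 of a million
  expect_equal(sort(two$tpm), c(1e6 / 3, 2e6 / 3), tolerance = 1e-12)
  # zero-count library warns and yields zeros
  expect_warning(
    z <- quantify_expression(dplyr::mutate(counts, total = 0L), genes),
    "zero")
  expect_true(all(z$tpm == 0))
})

test_that("CPM expression filter retains genes by the stated rule", {
  cpm_fix <- tidyr::expand_grid(gene_id = c("g1", "g2", "g3"),
                                library = paste0("l", 1:4)) %>%
    dplyr::mutate(total = 100L, g1 = 0L, g2 = 0L, exon_length = 1000L,
                  tpm = 0,
                  cpm = dplyr::case_when(
                    gene_id == "g1" & library %in% c("l1", "l2") ~ 2.5,
                    gene_id == "g1" ~ 1.0,
                    gene_id == "g2" ~ 0,
                    gene_id == "g3" ~ 10))
  kept <- expression_filter(cpm_fix, min_cpm = 2.5, min_libraries = 2)
  # exactly 2.5 CPM in exactly 2 of 4 libraries is retained
  expect_setequal(unique(kept$gene_id), c("g1", "g3"))
  expect_true("g2" %in% attr(kept, "removed_genes"))
  # independent per-gene scan
  scan <- cpm_fix %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(keep = sum(.data$cpm >= 2.5) >= 2)
  expect_setequal(unique(kept$gene_id), scan$gene_id[scan$keep])
  expect_error(expression_filter(cpm_fix, min_libraries = 5),
               "exceeds")
})

test_that("identical groups produce zero fold changes and no DE calls", {
  counts <- tidyr::expand_grid(gene_id = paste0("g", 1:20),
                               library = paste0("l", 1:4)) %>%
    dplyr::mutate(total = rep(rpois(20, 100), each = 4))
  de <- differential_expression(
    counts, setNames(c("a", "a", "b", "b"), paste0("l", 1:4)))
  tab <- tidy(de)
  expect_true(all(abs(tab$log2_fold_change) < 1e-12))
  expect_false(any(tab$de))
  expect_equal(glance(de)$n_de, 0L)
})

test_that("the DE substitute controls false positives and finds 4-fold shifts", {
  n_genes <- 200
  null_frac <- vapply(1:20, function(s) {
    set.seed(s)
    mu <- exp(rnorm(n_genes, log(200), 0.8))
    counts <- tidyr::expand_grid(gene_id = sprintf("g%03d", 1:n_genes),
                                 library = paste0("l", 1:4)) %>%
      dplyr::mutate(total = rpois(dplyr::n(), rep(mu, each = 4)))
    de <- differential_expression(
      counts, setNames(c("a", "a", "b", "b"), paste0("l", 1:4)))
    mean(tidy(de)$fdr <= 0.1)
  }, numeric(1))
  # on average at most the nominal fraction of genes is flagged under the null
  expect_lte(mean(null_frac), 0.1)

  power <- vapply(1:5, function(s) {
    set.seed(100 + s)
    mu <- exp(rnorm(n_genes, log(2000), 0.5))
    planted <- seq_len(n_genes) <= n_genes / 10
    shift <- ifelse(planted, 4, 1)
    counts <- tidyr::expand_grid(gene_id = sprintf("g%03d", 1:n_genes),
                                 library = paste0("l", 1:4)) %>%
      dplyr::mutate(grp = rep(c("a", "a", "b", "b"), n_genes),
                    total = rpois(dplyr::n(),
                                  rep(mu, each = 4) *
                                    ifelse(.data$grp == "b",
                                           rep(shift, each = 4), 1))) %>%
      dplyr::select(-"grp")
    de <- differential_expression(
      counts, setNames(c("a", "a", "b", "b"), paste0("l", 1:4)))
    tab <- tidy(de)
    c(power = mean(tab$de[planted]), fp = mean(tab$de[!planted]))
  }, numeric(2))
  expect_gte(mean(power["power", ]), 0.8)
  expect_lte(mean(power["fp", ]), 0.1)
})

test_that("RPKM tracks normalize, tile, and respect Poisson uniformity", {
  # single-bin cancellation: all N reads inside one 1 kb bin -> 1e6
  reads <- tibble::tibble(chrom = "chr1",
                          start = rep(100L, 50), end = rep(200L, 50))
  tr <- rpkm_track(reads, c(chr1 = 1000L), bin_size = 1000L)
  expect_equal(tr$value, 1e6)
  # empty library -> all zero
  tr0 <- rpkm_track(reads[0, ], c(chr1 = 1000L), bin_size = 100L)
  expect_true(all(tr0$value == 0))
  # bins tile the chromosome exactly, last bin short
  tr2 <- rpkm_track(reads, c(chr1 = 950L), bin_size = 100L)
  expect_equal(tr2$start[1], 0L)
  expect_equal(tr2$end[nrow(tr2)], 950L)
  expect_true(all(tr2$start[-1] == tr2$end[-nrow(tr2)]))
  expect_error(rpkm_track(reads, c(chr1 = 1000L), bin_size = 0), "bin_size")
  # uniform placement: interior bins within 3 Poisson sd of the mean
  set.seed(4)
  n <- 20000
  u_start <- sample.int(99000L, n, replace = TRUE) - 1L
  u <- tibble::tibble(chrom = "chr1", start = u_start, end = u_start + 100L)
  tru <- rpkm_track(u, c(chr1 = 100000L), bin_size = 1000L,
                    normalization = "raw")
  interior <- tru$value[2:(nrow(tru) - 1L)]
  lambda <- mean(interior)
  within3 <- abs(interior - lambda) <= 3 * sqrt(lambda) + 1
  # essentially all bins inside the 3-sd band, none wildly outside
  expect_gte(mean(within3), 0.99)
  expect_true(all(abs(interior - lambda) <= 5 * sqrt(lambda) + 1))
})

test_that("control subtraction floors at zero and checks binning", {
  a <- manual_track(c(5, 5, 2, 0))
  b <- manual_track(c(2, 7, 2, 1))
  d <- subtract_control(a, b)
  expect_equal(d$value, c(3, 0, 0, 0))
  expect_identical(attr(d, "normalization"), "control-subtracted")
  # identical tracks -> identically zero
  expect_true(all(subtract_control(a, a)$value == 0))
  expect_error(subtract_control(a, manual_track(c(1, 2))), "binning")
})

test_that("allelic tracks are built from each tag's own reads", {
  tagged <- dplyr::bind_rows(
    tagged_row(paste0("a", 1:8), "chr1", 100L, 200L, "G1"),
    tagged_row(paste0("b", 1:2), "chr1", 500L, 600L, "UA"))
  al <- allelic_tracks(tagged, c(chr1 = 1000L), bin_size = 100L)
  expect_true(all(al$g2$value == 0))
  expect_gt(sum(al$g1$value), 0)
  # raw g1 + g2 counts never exceed the total track's counts
  tot <- rpkm_track(tagged, c(chr1 = 1000L), bin_size = 100L,
                    normalization = "raw")
  alr <- allelic_tracks(tagged, c(chr1 = 1000L), bin_size = 100L,
                        normalization = "raw")
  expect_true(all(alr$g1$value + alr$g2$value <= tot$value))
})
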