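#' Simulate a hybrid-cross reference genome and strain variants
#'
#' Draws a random reference sequence per chromosome and places biallelic
#' strain-diagnostic variant records at rate `snp_density` per bp (each
#' position independently, i.e. a binomial placement model). Each SNP record
#' carries one haplotype-1 (129-analog) and one haplotype-2 (cast-analog)
#' allele, one of which equals the reference base. A configurable fraction
#' of records are emitted as indels and a fraction of SNPs carry a non-PASS
#' FILTER flag; both exist only to exercise the variant filters downstream.
#'
#' @param config A [sim_config()].
#' @return A list with elements `reference` (a [Biostrings::DNAStringSet])
#'   and `variants` (a tibble with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `qual`, `filter`, `allele_g1`, `allele_g2`, `is_indel`).
#' @export
simulate_hybrid_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(config$chromosomes$length <= 0)) abort("chromosome lengths must be > 0")
  set.seed(substream_seed(config$seed, "reference"))
  bases <- c("A", "C", "G", "T")

  seqs <- purrr::map_chr(config$chromosomes$length, function(L) {
    paste(sample(bases, L, replace = TRUE), collapse = "")
  })
  reference <- Biostrings::DNAStringSet(setNames(seqs, config$chromosomes$chrom))

  variants <- purrr::pmap(
    list(chrom = config$chromosomes$chrom, L = config$chromosomes$length),
    function(chrom, L) {
    pos <- which(runif(L) < config$snp_density)
    n <- length(pos)
    if (n == 0L) return(NULL)
    ref <- strsplit(seqs[[match(chrom, config$chromosomes$chrom)]],
                    "")[[1]][pos]
    # one alternate base per site, distinct from the reference base
    alt <- purrr::map_chr(ref, function(b) sample(setdiff(bases, b), 1L))
    is_indel <- runif(n) < config$indel_fraction
    # indels: short insertion relative to the reference base
    ins <- purrr::map_chr(seq_len(sum(is_indel)), function(i) {
      paste(sample(bases, sample(1:3, 1L), replace = TRUE), collapse = "")
    })
    alt[is_indel] <- paste0(ref[is_indel], ins)
    g1_is_ref <- runif(n) < 0.5
    allele_g1 <- ifelse(g1_is_ref, ref, alt)
    allele_g2 <- ifelse(g1_is_ref, alt, ref)
    filt <- rep("PASS", n)
    low <- !is_indel & runif(n) < config$lowqual_fraction
    filt[low] <- "LowQual"
    tibble(chrom = chrom, pos = pos, ref = ref, alt = alt,
           qual = round(runif(n, 20, 60), 1), filter = filt,
           allele_g1 = allele_g1, allele_g2 = allele_g2,
           is_indel = is_indel)
  }) %>% purrr::list_rbind()
  if (nrow(variants) == 0L) {
    variants <- tibble(chrom = character(), pos = integer(), ref = character(),
                       alt = character(), qual = numeric(), filter = character(),
                       allele_g1 = character(), allele_g2 = character(),
                       is_indel = logical())
  }
  list(reference = reference, variants = variants)
}

#' Simulate non-overlapping gene models with exons and silencing classes
#'
#' Places `genes_per_chromosome` gene models per chromosome, each with a
#' fixed exon/intron geometry, a random strand, and a strand-aware TSS (the
#' leftmost coordinate on plus-strand genes, the rightmost on minus-strand
#' genes). X-linked genes are assigned a silencing class (`early`,
#' `intermediate`, `late`, `escape`) by the program's class weights, and one
#' randomly chosen X-linked gene is designated the Xist-like locus (class
#' `xist`). Autosomal genes have class `autosomal`.
#'
#' @param config A [sim_config()].
#' @param program An [xci_program()].
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open), `tss` (0-based position),
#'   `silencing_class`, `is_xist`, `exon_length` (summed exon bp) and
#'   list-columns `exon_starts`, `exon_ends`.
#' @export
simulate_annotation <- function(config, program) {
  stopifnot(inherits(config, "sim_config"), inherits(program, "xci_program"))
  set.seed(substream_seed(config$seed, "annotation"))
  E <- config$exons_per_gene
  span <- E * config$exon_length + (E - 1L) * config$intron_length

  genes <- purrr::pmap(
    list(chrom = config$chromosomes$chrom, L = config$chromosomes$length,
         is_x = config$chromosomes$is_x),
    function(chrom, L, is_x) {
    n <- config$genes_per_chromosome
    if (n == 0L) return(NULL)
    if (n * span > L) {
      abort(paste0("cannot place ", n, " genes of span ", span,
                   " bp on ", chrom, " (", L, " bp)"))
    }
    slack <- L - n * span
    starts <- floor(sort(runif(n, 0, slack))) + (seq_len(n) - 1L) * span
    strand <- sample(c("+", "-"), n, replace = TRUE)
    cls <- if (is_x) {
      sample(names(program$class_weights), n, replace = TRUE,
             prob = program$class_weights)
    } else rep("autosomal", n)
    tibble(gene_id = sprintf("%s_g%02d", chrom, seq_len(n)),
           chrom = chrom, strand = strand,
           start = as.integer(starts), end = as.integer(starts + span),
           silencing_class = cls, is_x = is_x)
  }) %>% purrr::list_rbind()

  if (is.null(genes) || nrow(genes) == 0L) {
    return(tibble(gene_id = character(), chrom = character(),
                  strand = character(), start = integer(), end = integer(),
                  tss = integer(), silencing_class = character(),
                  is_xist = logical(), exon_length = integer(),
                  exon_starts = list(), exon_ends = list()))
  }

  genes$is_xist <- FALSE
  x_idx <- which(genes$is_x)
  if (length(x_idx) > 0L) {
    xist <- if (length(x_idx) == 1L) x_idx else sample(x_idx, 1L)
    genes$is_xist[xist] <- TRUE
    genes$silencing_class[xist] <- "xist"
  }

  rel_starts <- (seq_len(E) - 1L) * (config$exon_length + config$intron_length)
  genes %>%
    mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L),
           tss = as.integer(.data$tss),
           exon_starts = purrr::map(.data$start, ~ .x + rel_starts),
           exon_ends = purrr::map(.data$exon_starts, ~ .x + config$exon_length),
           exon_length = E * config$exon_length) %>%
    select("gene_id", "chrom", "strand", "start", "end", "tss",
           "silencing_class", "is_xist", "exon_length",
           "exon_starts", "exon_ends")
}

#' Expand the XCI program into a per-gene, per-library expression truth
#'
#' Assigns every gene a baseline relative expression (log-normal across
#' genes) and, for every condition x timepoint, the expected Xi transcript
#' fraction and total output implied by the program:
#' * undifferentiated timepoint: all genes biallelic (`xi_fraction` 0.5);
#' * differentiated wild type: silenced classes drop to their residual Xi
#'   fraction, escape genes to the escape fraction;
#' * differentiated knockout: a random subset (`ko_upshift_prob`) of
#'   silenced X genes has its Xi output multiplied by `ko_xi_upshift`
#'   (raising both its Xi fraction and its total output);
#' * the Xist-like locus is induced `xist_induction[condition]`-fold at the
#'   differentiated timepoint and is then expressed mostly from the Xi.
#'
#' The first element of `program$conditions` is treated as the wild type;
#' all other conditions receive the knockout perturbation.
#'
#' @param genes Annotation from [simulate_annotation()].
#' @param program An [xci_program()].
#' @param config A [sim_config()] (seed source).
#' @return A tibble: `gene_id`, `condition`, `timepoint`, `rel_expr`,
#'   `xi_fraction`, `perturbed`.
#' @export
expression_program <- function(genes, program, config) {
  stopifnot(inherits(program, "xci_program"), inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "program"))
  wt <- program$conditions[[1]]
  tp_diff <- program$timepoints[[2]]

  base <- genes %>%
    select("gene_id", "silencing_class", "is_xist") %>%
    mutate(base_expr = rlnorm_det(n(), config$expr_meanlog, config$expr_sdlog),
           base_expr = ifelse(.data$is_xist, program$xist_base, .data$base_expr),
           silenced = .data$silencing_class %in%
             c("early", "intermediate", "late"),
           perturbed = .data$silenced &
             runif(n()) < program$ko_upshift_prob)

  tidyr::expand_grid(base,
                     condition = program$conditions,
                     timepoint = program$timepoints) %>%
    mutate(
      is_ko = .data$condition != wt,
      f_wt = dplyr::case_when(
        .data$timepoint != tp_diff ~ 0.5,
        .data$silencing_class == "autosomal" ~ 0.5,
        .data$silencing_class == "xist" ~ program$xist_xi_fraction,
        TRUE ~ unname(program$xi_fractions[.data$silencing_class])),
      upshift = ifelse(.data$is_ko & .data$perturbed &
                         .data$timepoint == tp_diff,
                       program$ko_xi_upshift, 1),
      xi_out = .data$f_wt * .data$upshift,
      xa_out = 1 - .data$f_wt,
      xi_fraction = .data$xi_out / (.data$xi_out + .data$xa_out),
      induction = ifelse(.data$is_xist & .data$timepoint == tp_diff,
                         unname(program$xist_induction[.data$condition]), 1),
      rel_expr = .data$base_expr * (.data$xi_out + .data$xa_out) *
        .data$induction,
      perturbed = .data$perturbed & .data$is_ko) %>%
    select("gene_id", "condition", "timepoint", "rel_expr",
           "xi_fraction", "perturbed")
}

# deterministic log-normal draw (wrapper kept separate so the program
# sub-stream is easy to audit)
rlnorm_det <- function(n, meanlog, sdlog) exp(rnorm(n, meanlog, sdlog))

#' Simulate allele-resolved RNA-seq alignments
#'
#' Draws single-end reads gene by gene: read counts per gene are multinomial
#' with weights `rel_expr * exon_length` (so TPM recovers `rel_expr`
#' proportions), each read originates from haplotype 1 (the Xi strain) with
#' probability the gene's `xi_fraction` and from haplotype 2 otherwise, and
#' its sequence is taken from the corresponding pseudo-genome within a
#' single exon (gapless; no splice-aware structure). Per-base substitution
#' errors are applied at `error_rate`, and a configurable fraction of
#' alignments receives MAPQ below 30 so the mapping-quality filter is
#' exercised. Alignment records carry the true placement coordinates.
#'
#' @param genomes A `pseudogenome_pair` from [build_pseudogenomes()].
#' @param genes Annotation from [simulate_annotation()].
#' @param truth_expr Per-gene/library truth from [expression_program()].
#' @param config A [sim_config()].
#' @param libraries Tibble from [library_design()], or any tibble with
#'   columns `library`, `condition`, `timepoint`.
#' @return A list with `alignments` (tibble: `read_id`, `library`, `chrom`,
#'   `start`, `end` (0-based half-open), `seq`, `mapq`, `mapped`) and
#'   `truth` (tibble: `read_id`, `library`, `gene_id`, `true_hap`,
#'   `lowmapq`), every read appearing exactly once in the truth.
#' @export
simulate_rnaseq <- function(genomes, genes, truth_expr, config, libraries) {
  stopifnot(inherits(genomes, "pseudogenome_pair"),
            inherits(config, "sim_config"))
  if (nrow(genes) == 0L) abort("no genes to simulate from")
  missing_chr <- setdiff(genes$chrom, names(genomes$g1))
  if (length(missing_chr) > 0L) {
    abort(paste0("gene chromosome absent from genomes: ",
                 paste(missing_chr, collapse = ", ")))
  }
  set.seed(substream_seed(config$seed, "rnaseq"))
  rl <- config$read_length
  g1_chr <- as.character(genomes$g1)
  g2_chr <- as.character(genomes$g2)

  out <- purrr::pmap(libraries, function(library, condition, timepoint, ...) {
    tr <- truth_expr %>%
      filter(.data$condition == !!condition, .data$timepoint == !!timepoint) %>%
      inner_join(genes, by = "gene_id")
    if (nrow(tr) == 0L) abort("expression program missing this library's cells")
    w <- tr$rel_expr * tr$exon_length / 1000
    counts <- as.integer(rmultinom(1L, config$reads_per_library, w))
    idx <- rep.int(seq_len(nrow(tr)), counts)
    n <- length(idx)
    hap <- ifelse(runif(n) < tr$xi_fraction[idx], 1L, 2L)
    # uniform exon choice (equal exon lengths), uniform start within exon
    exon_i <- sample.int(config$exons_per_gene, n, replace = TRUE)
    # regular exon geometry: exon k starts at gene start + (k-1)(exon+intron)
    exon_start <- tr$start[idx] +
      (exon_i - 1L) * (config$exon_length + config$intron_length)
    offset <- sample.int(config$exon_length - rl + 1L, n, replace = TRUE) - 1L
    start <- exon_start + offset
    chrom <- tr$chrom[idx]
    seq <- character(n)
    for (cc in unique(chrom)) {
      for (h in 1:2) {
        sel <- which(chrom == cc & hap == h)
        if (length(sel) == 0L) next
        src <- if (h == 1L) g1_chr[[cc]] else g2_chr[[cc]]
        seq[sel] <- substring(src, start[sel] + 1L, start[sel] + rl)
      }
    }
    seq <- apply_seq_errors(seq, config$error_rate)
    low <- runif(n) < config$lowmapq_fraction
    mapq <- integer(n)
    mapq[low] <- sample(0:29, sum(low), replace = TRUE)
    mapq[!low] <- sample(30:42, sum(!low), replace = TRUE)
    read_id <- sprintf("%s_%06d", library, seq_len(n))
    list(
      alignments = tibble(read_id = read_id, library = library, chrom = chrom,
                          start = start, end = start + rl, seq = seq,
                          mapq = mapq, mapped = TRUE),
      truth = tibble(read_id = read_id, library = library,
                     gene_id = tr$gene_id[idx],
                     true_hap = ifelse(hap == 1L, "g1", "g2"),
                     lowmapq = low))
  })
  list(alignments = purrr::list_rbind(purrr::map(out, "alignments")),
       truth = purrr::list_rbind(purrr::map(out, "truth")))
}

# apply independent per-base substitution errors to a character vector of
# equal-length reads
apply_seq_errors <- function(seq, error_rate) {
  if (error_rate <= 0 || length(seq) == 0L) return(seq)
  bases <- c("A", "C", "G", "T")
  rl <- nchar(seq[[1]])
  n_err <- rbinom(length(seq), rl, error_rate)
  for (i in which(n_err > 0L)) {
    s <- strsplit(seq[[i]], "")[[1]]
    pos <- sample.int(rl, n_err[[i]])
    s[pos] <- vapply(s[pos], function(b) sample(setdiff(bases, b), 1L), "")
    seq[[i]] <- paste(s, collapse = "")
  }
  seq
}

#' Simulate paired CUT&RUN fragments with planted enriched domains
#'
#' Fragment midpoints are drawn from a mixture of a uniform genome-wide
#' background and the planted domains, each domain weighted by
#' `width * (enrichment - 1)` of extra mass so that a domain with
#' enrichment factor f covering fraction w of the genome captures an
#' expected fragment share of `w f / (w f + 1 - w)`. Fragment lengths follow
#' a truncated normal with a configurable heavy-tail fraction exceeding
#' 1 kb; a configurable fraction of pairs is chimeric (mates on different
#' chromosomes). Control (IgG) libraries are background-only. Each fragment
#' carries a haplotype (domain-specific `hap1_prob`, 0.5 in background) and
#' two mate alignments whose sequences come from that haplotype's
#' pseudo-genome. All planted violations are flagged in the truth set.
#'
#' @param genomes A `pseudogenome_pair`.
#' @param domains Tibble of planted domains: `chrom`, `start`, `end`
#'   (0-based half-open), `enrichment` (>= 1), optional `hap1_prob`
#'   (defaults to 0.5). An optional `library` column restricts a domain to
#'   one treatment library. `NULL` for background-only libraries.
#' @param config A [sim_config()].
#' @param libraries Tibble with columns `library` and `is_control`
#'   (controls ignore the planted domains).
#' @return A list with `alignments` (one row per mate: `read_id`,
#'   `fragment_id`, `library`, `chrom`, `start`, `end`, `seq`, `mapq`,
#'   `mapped`, `mate_chrom`, `fragment_length`) and `truth` (one row per
#'   fragment: `fragment_id`, `library`, `true_hap`, `in_domain`,
#'   `overlong`, `chimeric`, `lowmapq`).
#' @export
simulate_cutrun <- function(genomes, domains, config,
                            libraries = tibble(
                              library = c("treatment", "igg"),
                              is_control = c(FALSE, TRUE))) {
  stopifnot(inherits(genomes, "pseudogenome_pair"),
            inherits(config, "sim_config"))
  chrom_len <- setNames(Biostrings::width(genomes$g1), names(genomes$g1))
  if (!is.null(domains)) {
    domains <- as_tibble(domains)
    if (!"hap1_prob" %in% names(domains)) domains$hap1_prob <- 0.5
    if (any(domains$enrichment < 1)) {
      abort("domain enrichment factors must be >= 1")
    }
    bad <- domains$start < 0 | domains$end > chrom_len[domains$chrom]
    if (any(is.na(bad)) || any(bad)) {
      abort("planted domains must lie within their chromosomes")
    }
  }
  set.seed(substream_seed(config$seed, "cutrun"))
  rl <- config$read_length
  g1_chr <- as.character(genomes$g1)
  g2_chr <- as.character(genomes$g2)
  chroms <- names(chrom_len)
  total_len <- sum(chrom_len)

  out <- purrr::pmap(libraries, function(library, is_control, ...) {
    n <- config$cutrun_fragments
    dom <- if (is_control || is.null(domains)) NULL else domains
    # a `library` column on the domain table restricts domains per library
    if (!is.null(dom) && "library" %in% names(dom)) {
      dom <- dom[dom$library == library, ]
      if (nrow(dom) == 0L) dom <- NULL
    }
    # fragment lengths: truncated normal, with a heavy tail past 1 kb
    heavy <- runif(n) < config$heavy_tail_fraction
    len <- as.integer(pmin(999, pmax(
      rl, round(rnorm(n, config$fragment_mean, config$fragment_sd)))))
    len[heavy] <- as.integer(1000 + round(rexp(sum(heavy), 1 / 300)))
    # midpoint mixture: background mass = genome length, domain i extra
    # mass = width_i * (enrichment_i - 1)
    extra <- if (is.null(dom)) numeric(0) else
      (dom$end - dom$start) * (dom$enrichment - 1)
    comp <- sample.int(1L + length(extra), n, replace = TRUE,
                       prob = c(total_len, extra)) - 1L
    bg <- comp == 0L
    chrom <- character(n)
    mid <- integer(n)
    chrom[bg] <- sample(chroms, sum(bg), replace = TRUE,
                        prob = chrom_len / total_len)
    mid[bg] <- floor(runif(sum(bg)) * chrom_len[chrom[bg]])
    if (any(!bg)) {
      di <- comp[!bg]
      chrom[!bg] <- dom$chrom[di]
      mid[!bg] <- dom$start[di] +
        floor(runif(sum(!bg)) * (dom$end[di] - dom$start[di]))
    }
    start <- pmax(0L, pmin(mid - len %/% 2L,
                           as.integer(chrom_len[chrom]) - len))
    start <- pmax(0L, start)  # chromosomes shorter than an overlong fragment
    end <- pmin(start + len, as.integer(chrom_len[chrom]))
    p1 <- rep(0.5, n)
    if (any(!bg)) p1[!bg] <- dom$hap1_prob[comp[!bg]]
    hap <- ifelse(runif(n) < p1, 1L, 2L)
    chim <- if (length(chroms) > 1L) runif(n) < config$chimera_fraction
      else rep(FALSE, n)
    mate2_chrom <- chrom
    mate2_start <- pmax(0L, end - rl)
    if (any(chim)) {
      mate2_chrom[chim] <- vapply(chrom[chim], function(cc)
        sample(setdiff(chroms, cc), 1L), "")
      mate2_start[chim] <- floor(runif(sum(chim)) *
                                   (chrom_len[mate2_chrom[chim]] - rl))
    }
    frag_len <- ifelse(chim, NA_integer_, end - start)
    extract <- function(cc, h, s) {
      src <- if (h == 1L) g1_chr[[cc]] else g2_chr[[cc]]
      substring(src, s + 1L, s + rl)
    }
    seq1 <- character(n); seq2 <- character(n)
    for (cc in chroms) for (h in 1:2) {
      s1 <- which(chrom == cc & hap == h)
      if (length(s1)) seq1[s1] <- extract(cc, h, start[s1])
      s2 <- which(mate2_chrom == cc & hap == h)
      if (length(s2)) seq2[s2] <- extract(cc, h, mate2_start[s2])
    }
    seq1 <- apply_seq_errors(seq1, config$error_rate)
    seq2 <- apply_seq_errors(seq2, config$error_rate)
    low <- runif(2L * n) < config$lowmapq_fraction
    mapq <- integer(2L * n)
    mapq[low] <- sample(0:29, sum(low), replace = TRUE)
    mapq[!low] <- sample(30:42, sum(!low), replace = TRUE)
    frag_id <- sprintf("%s_f%06d", library, seq_len(n))
    in_domain <- rep(FALSE, n)
    if (!is.null(dom)) {
      for (i in seq_len(nrow(dom))) {
        in_domain <- in_domain | (chrom == dom$chrom[[i]] &
                                    mid >= dom$start[[i]] & mid < dom$end[[i]])
      }
    }
    mate1_end <- pmin(start + rl, end)
    col_chrom <- c(chrom, mate2_chrom)
    col_start <- c(start, mate2_start)
    col_end <- c(mate1_end, mate2_start + rl)
    col_mate_chrom <- c(mate2_chrom, chrom)
    aln <- tibble(
      read_id = c(paste0(frag_id, "/1"), paste0(frag_id, "/2")),
      fragment_id = c(frag_id, frag_id),
      library = library,
      chrom = col_chrom,
      start = col_start,
      end = col_end,
      seq = c(seq1, seq2),
      mapq = mapq,
      mapped = TRUE,
      mate_chrom = col_mate_chrom,
      fragment_length = c(frag_len, frag_len)) %>%
      arrange(.data$fragment_id, .data$read_id)
    truth <- tibble(fragment_id = frag_id, library = library,
                    true_hap = ifelse(hap == 1L, "g1", "g2"),
                    in_domain = in_domain,
                    overlong = len >= 1000L,
                    chimeric = chim,
                    lowmapq = low[seq_len(n)] | low[n + seq_len(n)])
    list(alignments = aln, truth = truth)
  })
  list(alignments = purrr::list_rbind(purrr::map(out, "alignments")),
       truth = purrr::list_rbind(purrr::map(out, "truth")))
}
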