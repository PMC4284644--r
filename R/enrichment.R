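# Enrichment of DMRs in gene annotations, GWAS loci and candidate gene
# sets: strand-aware promoter/gene-body annotation, a TSS-proximity
# permutation test, one-sided Fisher (hypergeometric) overlap tests at the
# bin and gene level, and a rank-resampling test of gene p-value ranking.

enrichment_row <- function(method, observed, null_mean, null_sd, p, n_perm,
                           note = NA_character_) {
  fold <- if (is.finite(null_mean) && null_mean > 0) observed / null_mean
          else NA_real_
  out <- tibble(method = method, observed = observed,
                null_mean = null_mean, null_sd = null_sd,
                fold = fold, p = p, n_perm = n_perm, note = note)
  class(out) <- c("twindmr_enrichment", class(out))
  out
}

#' Strand-aware gene models with extended promoters
#'
#' Derives, for each gene, the transcription start site (TSS) and an
#' extended promoter interval reaching `promoter_bp` upstream of the gene
#' (20 kb by default, capturing distal promoter and nearby regulatory
#' elements), clipped to chromosome bounds when sizes are supplied.  On the
#' plus strand the TSS is the gene start and the promoter lies before it;
#' on the minus strand the TSS is `end - 1` and the promoter follows the
#' gene.  All coordinates are 0-based half-open.
#'
#' @param genes Data frame with `gene_id`, `chrom`, `strand` (`"+"`/`"-"`),
#'   `start`, `end`.
#' @param promoter_bp Upstream extent of the promoter in bp.
#' @param chrom_sizes Optional chromosome sizes for clipping.
#' @return The gene tibble with `tss`, `promoter_start`, `promoter_end`.
#' @export
gene_models <- function(genes, promoter_bp = 20000, chrom_sizes = NULL) {
  genes <- as_tibble(genes)
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("gene strand must be '+' or '-'.", class = "twindmr_annotation_error")
  }
  plus <- genes$strand == "+"
  genes$tss <- ifelse(plus, genes$start, genes$end - 1)
  genes$promoter_start <- ifelse(plus, genes$start - promoter_bp, genes$end)
  genes$promoter_end <- ifelse(plus, genes$start, genes$end + promoter_bp)
  genes$promoter_start <- pmax(genes$promoter_start, 0)
  if (!is.null(chrom_sizes)) {
    chrom_sizes <- as_chrom_sizes(chrom_sizes)
    genes$promoter_end <- pmin(genes$promoter_end,
                               chrom_sizes[genes$chrom])
  }
  genes
}

#' GWAS locus windows
#'
#' Builds the interval `[pos - flank_bp, pos + flank_bp)` around each locus
#' SNP (50 kb either side by default), clipped at zero and at the
#' chromosome end when sizes are given.
#'
#' @param loci Data frame with `locus_id`, `chrom`, `pos`.
#' @param flank_bp Flank on each side of the SNP.
#' @param chrom_sizes Optional chromosome sizes for clipping.
#' @return A tibble with `locus_id`, `chrom`, `start`, `end`.
#' @export
locus_windows <- function(loci, flank_bp = 50000, chrom_sizes = NULL) {
  loci <- as_tibble(loci)
  out <- tibble(locus_id = loci$locus_id, chrom = loci$chrom,
                start = pmax(loci$pos - flank_bp, 0),
                end = loci$pos + flank_bp)
  if (!is.null(chrom_sizes)) {
    chrom_sizes <- as_chrom_sizes(chrom_sizes)
    out$end <- pmin(out$end, chrom_sizes[out$chrom])
  }
  out
}

# Overlap join between two 0-based half-open interval tables (>= 1 bp),
# chromosome by chromosome.  Returns index pairs.
interval_overlaps <- function(a, b) {
  hits_a <- integer()
  hits_b <- integer()
  for (chrom in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == chrom)
    ib <- which(b$chrom == chrom)
    ra <- IRanges::IRanges(start = a$start[ia] + 1L, end = a$end[ia])
    rb <- IRanges::IRanges(start = b$start[ib] + 1L, end = b$end[ib])
    h <- IRanges::findOverlaps(ra, rb, minoverlap = 1L)
    hits_a <- c(hits_a, ia[S4Vectors::queryHits(h)])
    hits_b <- c(hits_b, ib[S4Vectors::subjectHits(h)])
  }
  list(a = hits_a, b = hits_b)
}

#' Annotate DMRs to genes
#'
#' Assigns every DMR to each gene whose body or extended promoter it
#' overlaps by at least 1 bp.  When a DMR overlaps both the body and the
#' promoter of the same gene the class label is `gene_body`.  DMRs touching
#' no gene are reported once with class `intergenic`.
#'
#' @param dmrs Data frame of DMR intervals (`bin_id`, `chrom`, `start`,
#'   `end`), e.g. a tier of [dmr_scan()] records.
#' @param genes Gene table; passed through [gene_models()] if the promoter
#'   columns are absent.
#' @param promoter_bp Upstream promoter extent (bp).
#' @param chrom_sizes Optional chromosome sizes for promoter clipping.
#' @return A tibble `(bin_id, gene_id, class)`; the `gene_list` attribute
#'   holds the unique genes with at least one assigned DMR.
#' @export
annotate_dmrs_to_genes <- function(dmrs, genes, promoter_bp = 20000,
                                   chrom_sizes = NULL) {
  dmrs <- as_tibble(dmrs)
  if (!nrow(genes)) {
    out <- tibble(bin_id = dmrs$bin_id, gene_id = NA_character_,
                  class = "intergenic")
    attr(out, "gene_list") <- character()
    return(out)
  }
  genes <- if (!all(c("tss", "promoter_start", "promoter_end") %in%
                    names(genes))) {
    gene_models(genes, promoter_bp, chrom_sizes)
  } else {
    as_tibble(genes)
  }
  body_hits <- interval_overlaps(dmrs, genes)
  prom <- tibble(chrom = genes$chrom, start = genes$promoter_start,
                 end = genes$promoter_end)
  prom_hits <- interval_overlaps(dmrs, prom)
  assign <- bind_rows(
    tibble(bin_id = dmrs$bin_id[body_hits$a],
           gene_id = genes$gene_id[body_hits$b], class = "gene_body"),
    tibble(bin_id = dmrs$bin_id[prom_hits$a],
           gene_id = genes$gene_id[prom_hits$b], class = "promoter")
  )
  # gene_body takes precedence over promoter for the same (DMR, gene).
  assign <- assign |>
    dplyr::mutate(rank = ifelse(.data$class == "gene_body", 1L, 2L)) |>
    dplyr::arrange(.data$bin_id, .data$gene_id, .data$rank) |>
    dplyr::distinct(.data$bin_id, .data$gene_id, .keep_all = TRUE) |>
    dplyr::select(-"rank")
  orphan <- setdiff(dmrs$bin_id, assign$bin_id)
  out <- bind_rows(assign,
                   tibble(bin_id = orphan, gene_id = NA_character_,
                          class = "intergenic"))
  out <- out[order(match(out$bin_id, dmrs$bin_id)), ]
  attr(out, "gene_list") <- sort(unique(assign$gene_id))
  out
}

#' TSS-proximity permutation test
#'
#' Observed statistic: the fraction of DMRs whose midpoint lies within
#' `window_bp` of any transcription start site.  The null relocates every
#' TSS uniformly at random within its own chromosome (per-chromosome TSS
#' counts preserved) `n_perm` times; the empirical p-value uses the add-one
#' correction `(1 + #[null >= observed]) / (n_perm + 1)`, so the smallest
#' attainable p is `1 / (n_perm + 1)`.  The historical default of 20
#' permutations bounds p below at 1/21; at least 999 permutations are
#' recommended and a warning is issued below that.
#'
#' @param dmrs DMR intervals (`chrom`, `start`, `end`).
#' @param genes Gene table with `tss` (or passed through [gene_models()]).
#' @param chrom_sizes Chromosome sizes (needed to relocate TSSs).
#' @param window_bp Proximity window around the TSS in bp.
#' @param n_perm Number of TSS permutations.
#' @param seed Seed for the permutation stream.
#' @return A one-row enrichment tibble (`observed`, `null_mean`, `fold`,
#'   `p`, ...); `excess_pct` in the note column reports `100 * (fold - 1)`.
#' @export
tss_proximity_test <- function(dmrs, genes, chrom_sizes, window_bp = 100,
                               n_perm = 20, seed = 1) {
  if (n_perm < 1) config_error("`n_perm` must be >= 1.", field = "n_perm")
  if (n_perm < 999) {
    warn(sprintf("n_perm = %d is low; empirical p is bounded below by 1/%d. Consider n_perm >= 999.",
                 n_perm, n_perm + 1))
  }
  dmrs <- as_tibble(dmrs)
  if (!nrow(dmrs) || !nrow(genes)) {
    input_error("need at least one DMR and one gene.")
  }
  if (!"tss" %in% names(genes)) genes <- gene_models(genes)
  chrom_sizes <- as_chrom_sizes(chrom_sizes)
  mid <- floor((dmrs$start + dmrs$end) / 2)
  near_frac <- function(tss_by_chrom) {
    hit <- logical(nrow(dmrs))
    for (chrom in names(tss_by_chrom)) {
      sel <- dmrs$chrom == chrom
      if (!any(sel)) next
      tss <- sort(tss_by_chrom[[chrom]])
      if (!length(tss)) next
      idx <- findInterval(mid[sel], tss)
      lo <- pmax(idx, 1)
      hi <- pmin(idx + 1, length(tss))
      d <- pmin(abs(mid[sel] - tss[lo]), abs(mid[sel] - tss[hi]))
      hit[sel] <- d <= window_bp
    }
    mean(hit)
  }
  tss_obs <- split(genes$tss, genes$chrom)
  observed <- near_frac(tss_obs)
  counts <- lengths(tss_obs)
  null_stat <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      perm <- lapply(names(tss_obs), function(chrom) {
        floor(runif(counts[[chrom]], 0, chrom_sizes[[chrom]]))
      })
      names(perm) <- names(tss_obs)
      near_frac(perm)
    }, numeric(1))
  })
  p <- (1 + sum(null_stat >= observed)) / (n_perm + 1)
  res <- enrichment_row("tss_proximity", observed, mean(null_stat),
                        sd(null_stat), p, n_perm)
  res$note <- sprintf("excess_pct=%.1f",
                      100 * (res$fold - 1))
  attr(res, "null_stats") <- null_stat
  res
}

# One-sided (enrichment) hypergeometric tail P(X >= x) for a 2x2 table over
# a universe of N units with K marked, n selected and x marked-and-selected.
hyper_tail <- function(x, K, n, N) {
  phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Region-overlap Fisher test
#'
#' One-sided Fisher exact (hypergeometric tail) test of whether DMR bins
#' overlap a set of genomic windows (e.g. GWAS-locus windows of 50 kb
#' either side of the lead SNP) more often than expected among the
#' coverage-universe bins.  The testing unit is the bin; a bin is "in a
#' window" when it overlaps any window by at least 1 bp.
#'
#' @param dmr_bins Bin intervals of the DMR set (subset of the universe).
#' @param windows Window intervals (`chrom`, `start`, `end`).
#' @param universe_bins All bins with MeDIP-seq coverage (`bin_id`,
#'   `chrom`, `start`, `end`).
#' @return A one-row enrichment tibble with the overlap count, fold over
#'   the independence expectation, odds ratio (in `note`) and p-value.
#' @export
region_overlap_fisher <- function(dmr_bins, windows, universe_bins) {
  universe_bins <- as_tibble(universe_bins)
  dmr_bins <- as_tibble(dmr_bins)
  if (!nrow(universe_bins)) input_error("empty bin universe.")
  if (!all(dmr_bins$bin_id %in% universe_bins$bin_id)) {
    input_error("`dmr_bins` must be a subset of `universe_bins`.")
  }
  hits <- interval_overlaps(universe_bins, as_tibble(windows))
  in_window <- universe_bins$bin_id %in% universe_bins$bin_id[unique(hits$a)]
  is_dmr <- universe_bins$bin_id %in% dmr_bins$bin_id
  N <- nrow(universe_bins)
  K <- sum(is_dmr)
  n <- sum(in_window)
  x <- sum(is_dmr & in_window)
  if (n == 0 || n == N) {
    return(enrichment_row("region_overlap_fisher", x, NA_real_, NA_real_,
                          NA_real_, NA_integer_,
                          note = "untestable: degenerate window margin"))
  }
  expected <- K * n / N
  p <- hyper_tail(x, K, n, N)
  or <- (x * (N - K - n + x)) / ((K - x) * (n - x))
  res <- enrichment_row("region_overlap_fisher", x, expected,
                        NA_real_, p, NA_integer_)
  res$note <- sprintf("odds_ratio=%.3g;N=%d;K=%d;n=%d", or, N, K, n)
  res
}

#' Gene-set Fisher test
#'
#' One-sided Fisher exact test of overlap between the DMR gene list and a
#' target gene set (e.g. the genes nearest published GWAS loci, or
#' imprinted genes) over a gene universe.  `fold` is the observed overlap
#' divided by the independence expectation
#' `|target| * |dmr_genes| / |universe|`.
#'
#' @param dmr_genes Character vector of genes containing at least one DMR.
#' @param target_genes Character vector, the candidate set.
#' @param universe_genes Character vector, all annotatable genes.
#' @param allow_drop Drop target/DMR IDs outside the universe with a
#'   warning instead of erroring.
#' @return A one-row enrichment tibble.
#' @export
gene_set_fisher <- function(dmr_genes, target_genes, universe_genes,
                            allow_drop = FALSE) {
  universe_genes <- unique(universe_genes)
  dmr_genes <- unique(dmr_genes)
  target_genes <- unique(target_genes)
  out_t <- setdiff(target_genes, universe_genes)
  out_d <- setdiff(dmr_genes, universe_genes)
  if (length(out_t) || length(out_d)) {
    if (!allow_drop) {
      input_error(sprintf("gene IDs outside the universe: %s",
                          paste(head(c(out_t, out_d), 10), collapse = ", ")))
    }
    warn(sprintf("dropping %d gene ID(s) outside the universe.",
                 length(out_t) + length(out_d)))
    target_genes <- intersect(target_genes, universe_genes)
    dmr_genes <- intersect(dmr_genes, universe_genes)
  }
  N <- length(universe_genes)
  K <- length(dmr_genes)
  n <- length(target_genes)
  x <- length(intersect(dmr_genes, target_genes))
  expected <- K * n / N
  p <- hyper_tail(x, K, n, N)
  res <- enrichment_row("gene_set_fisher", x, expected, NA_real_, p,
                        NA_integer_)
  res$note <- sprintf("N=%d;K=%d;n=%d", N, K, n)
  res
}

#' Gene-level summary p-values
#'
#' Summarises per-bin scan p-values to one p-value per gene using the
#' DMR-to-gene assignment: by default the minimum p across a gene's
#' assigned bins (monotone and simple); `method = "mean"` averages instead.
#'
#' @param annotation Result of [annotate_dmrs_to_genes()] on all tested
#'   bins (the coverage universe).
#' @param records Scan records with `bin_id` and `p`.
#' @param method `"min"` (default) or `"mean"`.
#' @return A tibble `(gene_id, p)` over covered genes.
#' @export
gene_level_p <- function(annotation, records, method = c("min", "mean")) {
  method <- match.arg(method)
  joined <- annotation |>
    dplyr::filter(!is.na(.data$gene_id)) |>
    dplyr::left_join(records[, c("bin_id", "p")], by = "bin_id") |>
    dplyr::filter(is.finite(.data$p))
  joined |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(p = if (method == "min") min(.data$p)
                     else mean(.data$p), .groups = "drop")
}

#' Rank-resampling enrichment test of gene p-value ranking
#'
#' Tests whether a target gene set carries systematically better (smaller)
#' scan p-values than the remaining covered genes.  The observed statistic
#' is the Wilcoxon rank sum of the target genes' p-value ranks (average
#' ranks for ties); the null resamples `n_draws` gene sets of the same size
#' uniformly from the covered genes.  Enrichment means a SMALL rank sum, so
#' the empirical p counts draws with a statistic at least as small:
#' `p = (1 + #[draw <= observed]) / (n_draws + 1)`.
#'
#' @param gene_p Tibble `(gene_id, p)` from [gene_level_p()].
#' @param target_genes Character vector of target genes (subset of
#'   `gene_p$gene_id`).
#' @param n_draws Number of resampled gene sets.
#' @param seed Seed for the resampling stream.
#' @return A one-row enrichment tibble; `observed` is the target rank sum.
#' @export
rank_resampling_test <- function(gene_p, target_genes, n_draws = 10000,
                                 seed = 1) {
  gene_p <- as_tibble(gene_p)
  target_genes <- unique(target_genes)
  if (length(target_genes) > nrow(gene_p)) {
    input_error("target set larger than the covered-gene universe.")
  }
  if (!all(target_genes %in% gene_p$gene_id)) {
    input_error("target genes must all be covered (present in `gene_p`).")
  }
  ranks <- rank(gene_p$p, ties.method = "average")
  k <- length(target_genes)
  observed <- sum(ranks[gene_p$gene_id %in% target_genes])
  null_stat <- with_seed(seed, {
    vapply(seq_len(n_draws), function(i) {
      sum(ranks[sample.int(length(ranks), k)])
    }, numeric(1))
  })
  p <- (1 + sum(null_stat <= observed)) / (n_draws + 1)
  res <- enrichment_row("rank_resampling", observed, mean(null_stat),
                        sd(null_stat), p, n_draws)
  attr(res, "null_stats") <- null_stat
  res
}
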