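make_gene_fixture <- function() {
  tibble::tibble(
    gene_id = c("gPlus", "gMinus"),
    chrom = "chr1",
    strand = c("+", "-"),
    start = c(100000, 300000),
    end = c(120000, 320000)
  )
}

test_that("gene models are strand aware with clipped 20 kb promoters", {
  g <- gene_models(make_gene_fixture(), chrom_sizes = c(chr1 = 330000))
  expect_equal(g$tss, c(100000, 319999))
  expect_equal(g$promoter_start, c(80000, 320000))
  expect_equal(g$promoter_end, c(100000, 330000))  # clipped at chrom end
  near0 <- gene_models(tibble::tibble(gene_id = "g", chrom = "c",
                                      strand = "+", start = 5000,
                                      end = 6000))
  expect_equal(near0$promoter_start, 0)
  expect_error(gene_models(dplyr::mutate(make_gene_fixture(),
                                         strand = "*")),
               class = "twindmr_annotation_error")
})

test_that("DMRs are classed promoter / gene body / intergenic by strand", {
  genes <- make_gene_fixture()
  dmrs <- tibble::tibble(
    bin_id = c("up15kb_plus", "in_body", "down15kb_minus", "nowhere"),
    chrom = "chr1",
    start = c(85000, 110000, 285000, 200000),
    end = c(85500, 110500, 285500, 200500)
  )
  ann <- annotate_dmrs_to_genes(dmrs, genes)
  get <- function(id) ann[ann$bin_id == id, ]
  expect_equal(get("up15kb_plus")$class, "promoter")
  expect_equal(get("up15kb_plus")$gene_id, "gPlus")
  expect_equal(get("in_body")$class, "gene_body")
  # 15 kb downstream of a minus-strand gene is NOT its promoter side
  expect_equal(get("down15kb_minus")$class, "intergenic")
  expect_equal(get("nowhere")$class, "intergenic")
  # and 15 kb upstream of the minus-strand gene (i.e. past its end) is
  expect_equal(annotate_dmrs_to_genes(
    tibble::tibble(bin_id = "b", chrom = "chr1", start = 335000 - 10000,
                   end = 335000 - 9500), genes)$class, "promoter")
})

test_that("annotation matches a brute-force all-pairs interval check", {
  withr::with_seed(21, {
    genes <- tibble::tibble(
      gene_id = sprintf("g%02d", 1:40),
      chrom = sample(c("c1", "c2"), 40, replace = TRUE),
      strand = sample(c("+", "-"), 40, replace = TRUE),
      start = sample(0:800000, 40)
    )
    genes$end <- genes$start + sample(5000:40000, 40)
    gm <- gene_models(genes)
    dmrs <- tibble::tibble(bin_id = sprintf("b%03d", 1:150),
                           chrom = sample(c("c1", "c2"), 150,
                                          replace = TRUE),
                           start = sample(0:850000, 150))
    dmrs$end <- dmrs$start + 500
    ann <- annotate_dmrs_to_genes(dmrs, gm)
    hit <- ann[!is.na(ann$gene_id), ]
    for (k in seq_len(nrow(hit))) {
      d <- dmrs[dmrs$bin_id == hit$bin_id[k], ]
      g <- gm[gm$gene_id == hit$gene_id[k], ]
      body_ov <- d$chrom == g$chrom && d$start < g$end && d$end > g$start
      prom_ov <- d$chrom == g$chrom && d$start < g$promoter_end &&
        d$end > g$promoter_start
      expect_true(body_ov || prom_ov)
      expect_equal(hit$class[k], if (body_ov) "gene_body" else "promoter")
    }
    # completeness: every overlapping pair is reported
    n_pairs <- sum(vapply(seq_len(nrow(dmrs)), function(i) {
      d <- dmrs[i, ]
      sum(d$chrom == gm$chrom &
            ((d$start < gm$end & d$end > gm$start) |
               (d$start < gm$promoter_end & d$end > gm$promoter_start)))
    }, numeric(1)))
    expect_equal(nrow(hit), n_pairs)
  })
  empty <- annotate_dmrs_to_genes(
    tibble::tibble(bin_id = "b", chrom = "c", start = 0, end = 500),
    tibble::tibble(gene_id = character(), chrom = character(),
                   strand = character(), start = numeric(),
                   end = numeric()))
  expect_equal(empty$class, "intergenic")
  expect_length(attr(empty, "gene_list"), 0)
})

test_that("TSS permutation test attains the add-one minimum on extremal input", {
  genes <- tibble::tibble(gene_id = sprintf("g%d", 1:5), chrom = "c1",
                          strand = "+",
                          start = c(1, 3, 5, 7, 9) * 1e6)
  genes$end <- genes$start + 10000
  gm <- gene_models(genes)
  dmrs <- tibble::tibble(bin_id = sprintf("b%d", 1:5), chrom = "c1",
                         start = gm$tss - 250, end = gm$tss + 250)
  expect_warning(
    res <- tss_proximity_test(dmrs, gm, c(c1 = 1e8), window_bp = 100,
                              n_perm = 20, seed = 2),
    regexp = "n_perm"
  )
  expect_equal(res$observed, 1)
  expect_equal(res$p, 1 / 21)
  # reproducible under the same seed
  res2 <- suppressWarnings(
    tss_proximity_test(dmrs, gm, c(c1 = 1e8), 100, 20, seed = 2))
  expect_identical(res$null_mean, res2$null_mean)
  expect_error(suppressWarnings(
    tss_proximity_test(dmrs, gm, c(c1 = 1e8), 100, n_perm = 0)),
    class = "twindmr_config_error")
})

test_that("Fisher overlap tests match direct hypergeometric summation", {
  withr::with_seed(33, {
    for (i in 1:50) {
      N <- sample(20:500, 1)
      K <- sample(1:(N - 1), 1)
      n <- sample(1:(N - 1), 1)
      universe <- sprintf("g%04d", 1:N)
      dmr <- sample(universe, K)
      target <- sample(universe, n)
      res <- gene_set_fisher(dmr, target, universe)
      x <- length(intersect(dmr, target))
      expect_equal(res$observed, x)
      expect_equal(res$p, oracle_hyper_tail(x, K, n, N),
                   tolerance = 1e-10)
      expect_equal(res$fold, x / (K * n / N))
    }
  })
  # worked example: expected overlap 1, observed 5 -> fold 5
  withr::with_seed(34, {
    universe <- sprintf("u%04d", 1:1000)
    dmr <- universe[1:100]
    target <- c(universe[1:5], universe[996:1000])
    res <- gene_set_fisher(dmr, target, universe)
    expect_equal(res$fold, 5)
  })
  expect_error(gene_set_fisher(c("a", "zzz"), "a", c("a", "b")),
               class = "twindmr_input_error")
  expect_warning(gene_set_fisher(c("a", "zzz"), "a", c("a", "b"),
                                 allow_drop = TRUE))
})

test_that("region overlap Fisher works on bins and degenerate margins", {
  bins <- tile_genome(c(cA = 50000), 500, 500)  # 100 bins
  universe <- bins
  dmr <- bins[1:20, ]
  windows <- tibble::tibble(chrom = "cA", start = 0, end = 5000)  # 10 bins
  res <- region_overlap_fisher(dmr, windows, universe)
  expect_equal(res$observed, 10)
  expect_equal(res$p, oracle_hyper_tail(10, 20, 10, 100),
               tolerance = 1e-10)
  none <- region_overlap_fisher(bins[60:70, ], windows, universe)
  expect_equal(none$observed, 0)
  expect_equal(none$p, 1)
  whole <- region_overlap_fisher(dmr, tibble::tibble(
    chrom = "cA", start = 0, end = 50000), universe)
  expect_match(whole$note, "untestable")
  expect_error(region_overlap_fisher(
    tibble::tibble(bin_id = "zz:0-1", chrom = "zz", start = 0, end = 1),
    windows, universe), class = "twindmr_input_error")
})

test_that("rank resampling is extremal on top-ranked targets and seeded", {
  withr::with_seed(8, {
    gene_p <- tibble::tibble(gene_id = sprintf("g%03d", 1:60),
                             p = runif(60))
    top <- gene_p$gene_id[order(gene_p$p)][1:5]
    res <- rank_resampling_test(gene_p, top, n_draws = 999, seed = 4)
    expect_equal(res$p, 1 / 1000)
    expect_equal(res$observed, sum(1:5))
    # invariant to input record order
    res2 <- rank_resampling_test(gene_p[sample(60), ], top,
                                 n_draws = 999, seed = 4)
    expect_equal(res2$p, res$p)
    expect_equal(res2$observed, res$observed)
    expect_error(rank_resampling_test(gene_p, c(top, "nope"), 99, 1),
                 class = "twindmr_input_error")
    expect_error(rank_resampling_test(gene_p[1:3, ], gene_p$gene_id, 99, 1),
                 class = "twindmr_input_error")
  })
})

test_that("gene-level p is the minimum (or mean) over assigned bins", {
  ann <- tibble::tibble(bin_id = c("b1", "b2", "b3", "b4"),
                        gene_id = c("g1", "g1", "g2", NA),
                        class = c("promoter", "gene_body", "gene_body",
                                  "intergenic"))
  rec <- tibble::tibble(bin_id = c("b1", "b2", "b3", "b4"),
                        p = c(0.2, 0.05, 0.5, 0.001))
  gp <- gene_level_p(ann, rec)
  expect_equal(gp$p[gp$gene_id == "g1"], 0.05)
  expect_equal(gp$p[gp$gene_id == "g2"], 0.5)
  gp2 <- gene_level_p(ann, rec, method = "mean")
  expect_equal(gp2$p[gp2$gene_id == "g1"], 0.125)
})
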