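make_mqtl_fixture <- function(n = 80, cis_effect = 1, seed = 14) {
  withr::with_seed(seed, {
    samples <- tibble::tibble(
      sample_id = sprintf("s%03d", 1:n),
      family_id = sprintf("f%03d", 1:n),
      is_case = rbinom(n, 1, 0.3),
      age = runif(n, 40, 80), sex = rbinom(n, 1, 0.5),
      bmi = rnorm(n, 27, 4)
    )
    bins <- tibble::tibble(bin_id = c("c1:100000-100500",
                                      "c1:400000-400500",
                                      "c2:100000-100500"),
                           chrom = c("c1", "c1", "c2"),
                           start = c(1e5, 4e5, 1e5),
                           end = c(1e5, 4e5, 1e5) + 500)
    snps <- tibble::tibble(snp_id = c("rsA", "rsB", "rsC"),
                           chrom = c("c1", "c1", "c2"),
                           pos = c(110000, 390000, 500000))
    G <- matrix(rbinom(3 * n, 2, 0.3), 3, n,
                dimnames = list(snps$snp_id, samples$sample_id))
    v <- matrix(rnorm(3 * n), 3, n,
                dimnames = list(bins$bin_id, samples$sample_id))
    v[1, ] <- v[1, ] + cis_effect * G[1, ]  # rsA drives bin 1 in cis
    m <- binned_methylome(bins, v, samples$sample_id, "AMS")
    list(samples = samples, methylome = m,
         genotypes = genotype_matrix(snps, G))
  })
}

test_that("cis window membership is positional and half-open", {
  bins <- tibble::tibble(bin_id = "c1:100000-100500", chrom = "c1",
                         start = 1e5, end = 1e5 + 500)
  snps <- tibble::tibble(
    snp_id = c("left_in", "left_edge", "right_in", "right_edge"),
    chrom = "c1",
    pos = c(1e5 - 50000, 1e5 - 50001, 1e5 + 500 + 49999, 1e5 + 500 + 50000))
  pairs <- twindmr:::cis_pairs(bins, snps, 50000)
  expect_equal(sort(pairs$snp_idx), c(1, 3))
})

test_that("cis scan finds the planted mQTL and adjusts for multiplicity", {
  fx <- make_mqtl_fixture()
  res <- cis_mqtl_scan(fx$methylome, fx$genotypes, fx$samples)
  expect_equal(sort(unique(res$snp_id)), c("rsA", "rsB"))
  best <- res[which.min(res$p), ]
  expect_equal(best$snp_id, "rsA")
  expect_equal(best$bin_id, "c1:100000-100500")
  expect_true(all(res$p_bonferroni >= res$p))
  expect_true(all(res$q >= res$p))
  expect_equal(attr(res, "best_snp")$snp_id[
    attr(res, "best_snp")$bin_id == "c1:100000-100500"], "rsA")
})

test_that("cis and trans scans partition the pairs exactly", {
  fx <- make_mqtl_fixture()
  cis <- cis_mqtl_scan(fx$methylome, fx$genotypes, fx$samples)
  trans <- trans_mqtl_scan(fx$methylome, fx$genotypes, fx$samples)
  key <- function(d) paste(d$bin_id, d$snp_id)
  expect_length(intersect(key(cis), key(trans)), 0)
  expect_equal(sort(c(key(cis), key(trans))),
               sort(as.vector(outer(fx$methylome$bins$bin_id,
                                    fx$genotypes$snps$snp_id, paste))))
})

test_that("slope test matches the closed-form simple regression oracle", {
  withr::with_seed(2, {
    n <- 50
    g <- rbinom(n, 2, 0.4)
    y <- 0.4 * g + rnorm(n)
    st <- twindmr:::slope_test(y, g, matrix(1, n, 1))
    b <- cov(y, g) / var(g)
    r <- y - mean(y) - b * (g - mean(g))
    se <- sqrt(sum(r^2) / (n - 2) / sum((g - mean(g))^2))
    expect_equal(st[["beta"]], b, tolerance = 1e-8)
    expect_equal(st[["se"]], se, tolerance = 1e-8)
    expect_equal(st[["p"]], 2 * pt(-abs(b / se), n - 2), tolerance = 1e-8)
  })
})

test_that("monomorphic SNPs are skipped with a count", {
  fx <- make_mqtl_fixture()
  fx$genotypes$dosage["rsB", ] <- 0
  fx$genotypes$snps$maf[2] <- 0
  res <- cis_mqtl_scan(fx$methylome, fx$genotypes, fx$samples)
  expect_false("rsB" %in% res$snp_id)
  expect_equal(attr(res, "n_skipped_monomorphic"), 1L)
})

test_that("permuted genotypes give nominal cis false-positive rates", {
  withr::with_seed(19, {
    n <- 60
    ps <- replicate(300, {
      g <- rbinom(n, 2, 0.3)
      y <- rnorm(n)
      twindmr:::slope_test(y, g, matrix(1, n, 1))[["p"]]
    })
    rate <- mean(ps <= 0.05)
    expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 300))
  })
})

test_that("causal inference test has valid structure and seeding", {
  tri <- simulate_mediation_triple(n = 120, scenario = "causal", seed = 5)
  res <- causal_inference_test(tri$L, tri$M, tri$trait, B = 200, seed = 9)
  expect_equal(res$p_omnibus, max(res$p1, res$p2, res$p3, res$p4))
  expect_gte(res$p4, 1 / 201)
  res2 <- causal_inference_test(tri$L, tri$M, tri$trait, B = 200, seed = 9)
  expect_identical(res$p4, res2$p4)
  expect_error(causal_inference_test(rep(1, 120), tri$M, tri$trait),
               class = "twindmr_input_error")
  expect_error(causal_inference_test(tri$L[1:10], tri$M[1:10],
                                     tri$trait[1:10]),
               class = "twindmr_input_error")
  const <- causal_inference_test(tri$L, rep(2, 120), tri$trait, B = 200)
  expect_true(const$untestable)
})

test_that("null locus gives uniform p1 over replicates", {
  withr::with_seed(23, {
    p1s <- vapply(1:150, function(i) {
      tri <- simulate_mediation_triple(n = 80, scenario = "null",
                                      seed = 3000 + i)
      causal_inference_test(tri$L, tri$M, tri$trait, B = 100,
                            seed = i)$p1
    }, numeric(1))
    expect_gt(stats::ks.test(p1s, "punif")$p.value, 0.01)
  })
})
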