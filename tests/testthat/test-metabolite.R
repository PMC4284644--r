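make_metab_fixture <- function(n_met = 6, samples, coupling = 0,
                               meth = NULL, seed = 3, n_days = 3) {
  withr::with_seed(seed, {
    n <- nrow(samples)
    v <- matrix(rnorm(n_met * n), n_met, n)
    if (coupling != 0) v[1, ] <- coupling * meth + rnorm(n, 0, 0.3)
    run_day <- sprintf("d%d", rep_len(seq_len(n_days), n))
    metabolite_matrix((v + 10), run_day,
                      sprintf("m%02d", seq_len(n_met)),
                      samples$sample_id)
  })
}

test_that("run-day median normalization removes day scale and standardizes", {
  one_day <- metabolite_matrix(matrix(c(2, 4, 6), 1), rep("d1", 3),
                               "m1", c("a", "b", "c"))
  norm <- runday_median_normalize(one_day)
  # after dividing by the day median (4): 0.5, 1, 1.5; then standardized
  expect_equal(unname(norm$values[1, ]),
               unname(scale(c(0.5, 1, 1.5))[, 1]))
  expect_equal(mean(norm$values), 0, tolerance = 1e-12)
  expect_equal(sd(norm$values[1, ]), 1, tolerance = 1e-12)

  samples <- make_twin_samples(n_disc = 8)
  raw <- make_metab_fixture(samples = samples)
  scaled <- raw
  for (d in unique(raw$run_day)) {
    scaled$values[, raw$run_day == d] <-
      scaled$values[, raw$run_day == d] * which(unique(raw$run_day) == d)
  }
  expect_equal(runday_median_normalize(scaled)$values,
               runday_median_normalize(raw)$values, tolerance = 1e-12)
  # idempotent up to the final standardization
  twice <- runday_median_normalize(runday_median_normalize(raw))
  expect_equal(apply(twice$values, 1, sd), rep(1, 6),
               ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("all-missing (metabolite, day) groups are flagged, not crashed", {
  v <- matrix(rnorm(6), 2, 3)
  v[1, 1] <- NA  # d1 has only sample 1 -> all-missing group for m1
  mm <- metabolite_matrix(v + 10, c("d1", "d2", "d2"), c("m1", "m2"),
                          c("a", "b", "c"))
  norm <- runday_median_normalize(mm)
  expect_true(is.na(norm$values[1, 1]))
  expect_equal(attr(norm, "all_missing_groups")$d1, "m1")
})

test_that("signed-rank test matches exact enumeration on small n", {
  samples <- make_twin_samples(n_disc = 3, n_cc = 0, n_co = 0)
  # plant differences (1, 2, 3) for metabolite 1 across the three pairs
  v <- matrix(0, 2, 6)
  aff <- which(samples$is_case == 1)
  v[1, aff] <- c(1, 2, 3)
  v[2, aff] <- c(1, -1, 0.5)
  mm <- metabolite_matrix(v, rep("d1", 6), c("mA", "mB"),
                          samples$sample_id, normalized = TRUE)
  res <- pairwise_wilcoxon(mm, samples, min_pairs = 2)
  expect_equal(res$statistic[1], 6)          # maximal positive-rank sum
  expect_equal(res$p[1], 2 * (1 / 8))        # 2^3 sign patterns
  expect_equal(res$direction[1], "hyper")
  # enumeration oracle for arbitrary small difference vectors
  withr::with_seed(31, {
    d <- round(rnorm(6), 2)
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 6)))
    V <- function(x) sum(rank(abs(x))[x > 0])
    v_obs <- V(d)
    null_v <- apply(signs, 1, function(s) V(abs(d) * s))
    p_exact <- mean(abs(null_v - sum(rank(abs(d))) / 2) >=
                      abs(v_obs - sum(rank(abs(d))) / 2))
    wt <- suppressWarnings(stats::wilcox.test(d, exact = TRUE))
    expect_equal(wt$p.value, p_exact, tolerance = 1e-12)
  })
  few <- pairwise_wilcoxon(mm, samples, min_pairs = 5)
  expect_true(all(few$untestable))
})

test_that("staged replication carries forward only nominal discoveries", {
  withr::with_seed(41, {
    n <- 80
    unrel <- tibble::tibble(sample_id = sprintf("u%02d", 1:n),
                            family_id = sprintf("uf%02d", 1:n),
                            is_case = rbinom(n, 1, 0.3),
                            age = runif(n, 40, 80),
                            sex = rbinom(n, 1, 0.5),
                            bmi = rnorm(n, 27, 4))
    meth <- setNames(rnorm(n), unrel$sample_id)
    mm <- make_metab_fixture(samples = unrel, coupling = 1.2, meth = meth)
    mm$normalized <- TRUE
    discovery <- tibble::tibble(metabolite = mm$metabolites,
                                p = c(0.01, 0.3, 0.02, 0.9, 0.04, 0.5),
                                direction = "hyper",
                                n_pairs = 17, untestable = FALSE)
    out <- replication_regression(mm, meth, unrel, discovery = discovery)
    expect_equal(out$metabolite, c("m01", "m03", "m05"))
    expect_lt(out$p[out$metabolite == "m01"], 0.05)  # planted coupling
    none <- replication_regression(mm, meth, unrel,
                                   discovery = dplyr::mutate(discovery,
                                                             p = 0.9))
    expect_equal(nrow(none), 0)
  })
})

test_that("signed Stouffer meta-analysis matches closed forms", {
  tbl <- function(p, dir, n = 36) {
    tibble::tibble(metabolite = "m", p = p, direction = dir, n = n)
  }
  same05 <- meta_analyze(tbl(0.05, "hyper"), tbl(0.05, "hyper"))
  expect_equal(same05$meta_p, 2 * pnorm(-sqrt(2) * qnorm(0.975)),
               tolerance = 1e-12)
  expect_equal(same05$meta_p, 0.00557, tolerance = 1e-3)

  p5 <- meta_analyze(tbl(0.5, "hyper"), tbl(0.5, "hyper"))
  expect_equal(p5$meta_p, 2 * pnorm(-sqrt(2) * qnorm(0.75)),
               tolerance = 1e-12)
  expect_equal(p5$meta_p, 0.3402, tolerance = 1e-3)

  opp <- meta_analyze(tbl(0.05, "hyper"), tbl(0.05, "hypo"))
  expect_equal(opp$meta_z, 0)
  expect_equal(opp$meta_p, 1)

  # symmetric in the two stages at equal n
  a <- meta_analyze(tbl(0.01, "hyper"), tbl(0.2, "hypo"))
  b <- meta_analyze(tbl(0.2, "hypo"), tbl(0.01, "hyper"))
  expect_equal(a$meta_p, b$meta_p)

  excl <- suppressMessages(
    meta_analyze(tbl(0.05, NA_character_), tbl(0.05, "hyper")))
  expect_equal(nrow(excl), 0)
})

test_that("within-pair metabolite-methylation coupling is detected", {
  withr::with_seed(55, {
    samples <- make_twin_samples(n_disc = 17, n_cc = 0, n_co = 0)
    meth <- setNames(rnorm(nrow(samples), 0, 1.5), samples$sample_id)
    mm <- make_metab_fixture(n_met = 10, samples = samples,
                             coupling = 1.5, meth = meth)
    mm$normalized <- TRUE
    res <- pair_diff_association(mm, samples, meth)
    expect_equal(which.min(res$p), 1)
    expect_lt(res$p[1], 0.01)
  })
})
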