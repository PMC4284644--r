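test_that("tile_genome follows the stated tiling rule", {
  cases <- list(
    list(L = 1000, bin = 500, step = 250,
         starts = c(0, 250, 500, 750), ends = c(500, 750, 1000, 1000)),
    list(L = 900, bin = 500, step = 250,
         starts = c(0, 250, 500), ends = c(500, 750, 900)),
    list(L = 500, bin = 500, step = 500, starts = 0, ends = 500)
  )
  for (cs in cases) {
    bins <- tile_genome(c(chrA = cs$L), cs$bin, cs$step)
    expect_equal(bins$start, cs$starts)
    expect_equal(bins$end, cs$ends)
  }
  expect_error(tile_genome(c(chrA = 1000), 500, 0),
               class = "twindmr_config_error")
  expect_error(tile_genome(c(chrA = 1000), 250, 500),
               class = "twindmr_config_error")
})

test_that("tiling is deterministic and covers every position", {
  sizes <- c(chr1 = 3721, chr2 = 9999)
  bins <- tile_genome(sizes, 500, 250)
  expect_identical(bins, tile_genome(sizes, 500, 250))
  for (chrom in names(sizes)) {
    b <- bins[bins$chrom == chrom, ]
    covered <- rep(FALSE, sizes[[chrom]])
    for (i in seq_len(nrow(b))) {
      covered[(b$start[i] + 1):b$end[i]] <- TRUE
    }
    expect_true(all(covered))
  }
})

test_that("compute_rpm counts >= 1 bp overlaps and scales per million", {
  bins <- tile_genome(c(chrA = 1000), 500, 250)
  frags <- tibble::tibble(chrom = "chrA", start = rep(100, 10),
                          end = rep(200, 10), sample_id = "s1")
  rpm <- compute_rpm(frags, bins, totals = c(s1 = 2e6),
                     chrom_sizes = c(chrA = 1000))
  expect_equal(unname(rpm$values["chrA:0-500", "s1"]), 5.0)
  expect_equal(rpm$signal_type, "RPM")

  # A 500 bp fragment spanning 250-750 overlaps three of the four bins.
  one <- compute_rpm(tibble::tibble(chrom = "chrA", start = 250, end = 750,
                                    sample_id = "s1"),
                     bins, totals = c(s1 = 1e6))
  expect_equal(unname(one$values[, "s1"] > 0),
               c(TRUE, TRUE, TRUE, FALSE))
})

test_that("compute_rpm matches the brute-force overlap oracle", {
  withr::with_seed(42, {
    bins <- tile_genome(c(c1 = 5000, c2 = 3000), 500, 250)
    frags <- tibble::tibble(
      chrom = sample(c("c1", "c2"), 400, replace = TRUE),
      start = sample(0:2500, 400, replace = TRUE),
      sample_id = sample(c("a", "b"), 400, replace = TRUE)
    )
    frags$end <- frags$start + sample(50:300, 400, replace = TRUE)
    rpm <- compute_rpm(frags, bins,
                       totals = c(a = 1e6, b = 1e6))
    for (s in c("a", "b")) {
      expect_equal(unname(rpm$values[, s]),
                   oracle_overlap_counts(frags[frags$sample_id == s, ],
                                         bins))
    }
  })
})

test_that("RPM scales linearly in counts and rejects bad input", {
  bins <- tile_genome(c(chrA = 1000), 500, 250)
  f1 <- tibble::tibble(chrom = "chrA", start = c(10, 60), end = c(110, 160),
                       sample_id = "s1")
  f2 <- dplyr::bind_rows(f1, f1)
  r1 <- compute_rpm(f1, bins, totals = c(s1 = 1e6))
  r2 <- compute_rpm(f2, bins, totals = c(s1 = 1e6))
  expect_equal(r2$values, 2 * r1$values)
  expect_error(compute_rpm(f1, bins, totals = c(s1 = 0)),
               class = "twindmr_input_error")
  bad <- tibble::tibble(chrom = "chrA", start = 900, end = 1100,
                        sample_id = "s1")
  expect_error(compute_rpm(bad, bins, chrom_sizes = c(chrA = 1000)),
               regexp = "chrA:900-1100")
})

test_that("zscore normalization standardizes every retained bin", {
  samples <- make_twin_samples()
  m <- make_methylome(samples, n_bins = 30)
  m$values[5, ] <- 7  # constant bin
  norm <- suppressMessages(normalize_bins(m))
  expect_equal(norm$signal_type, "normalized")
  expect_equal(attr(norm, "excluded_bins"), m$bins$bin_id[5])
  expect_false(m$bins$bin_id[5] %in% norm$bins$bin_id)
  expect_lt(max(abs(rowMeans(norm$values))), 1e-8)
  expect_lt(max(abs(apply(norm$values, 1, var) - 1)), 1e-8)
  expect_equal(unname(normalize_bins(binned_methylome(
    m$bins[1, ], matrix(c(1, 2, 3), 1), c("a", "b", "c"), "AMS"
  ))$values[1, ]), c(-1, 0, 1))
})

test_that("inverse normal transform is rank invariant", {
  samples <- make_twin_samples()
  m <- make_methylome(samples, n_bins = 20)
  a <- normalize_bins(m, "inverse_normal")
  m2 <- m
  m2$values <- exp(m$values / 2)  # strictly monotone transform
  b <- normalize_bins(m2, "inverse_normal")
  expect_equal(a$values, b$values)
  expect_error(normalize_bins(binned_methylome(
    m$bins[1, ], matrix(1:2, 1), c("a", "b"), "AMS")),
    class = "twindmr_input_error")
})

test_that("filter_bins applies the coverage threshold and records it", {
  bins <- tile_genome(c(chrA = 1500), 500, 500)
  v <- matrix(1, 3, 4, dimnames = list(NULL, letters[1:4]))
  v[2, 1] <- 0
  m <- binned_methylome(bins, v, letters[1:4], "RPM")
  expect_equal(nrow(filter_bins(m, 0)$bins), 3)
  kept <- filter_bins(m, 1)
  expect_equal(nrow(kept$bins), 2)
  expect_false(bins$bin_id[2] %in% attr(kept, "coverage_universe"))
  expect_equal(length(attr(kept, "coverage_universe")), 2)
})
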