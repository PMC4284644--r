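# Independent oracles and small fixtures shared across the test files.
# Every oracle here is deliberately naive (brute force / direct summation /
# closed form) and independent of the implementation paths it checks.

# Brute-force >= 1 bp overlap count between fragment and bin interval sets
# (0-based half-open).
oracle_overlap_counts <- function(frags, bins) {
  vapply(seq_len(nrow(bins)), function(b) {
    sum(frags$chrom == bins$chrom[b] &
          frags$start < bins$end[b] &
          frags$end > bins$start[b])
  }, numeric(1))
}

# Direct step-up BH computation: q_i = min_{j >= i} p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Hypergeometric upper tail P(X >= x) by direct summation of dhyper terms.
oracle_hyper_tail <- function(x, K, n, N) {
  xs <- x:min(K, n)
  if (!length(xs) || x > min(K, n)) return(0)
  sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}

# Exact two-sided p of the df = 2 one-sample t statistic:
# P(T > t) = 1/2 - t / (2 * sqrt(2 + t^2)).
oracle_t_df2_p <- function(t) 2 * (0.5 - t / (2 * sqrt(2 + t^2)))

# A tiny twin sample table: n_disc discordant + n_cc concordant-case +
# n_co concordant-control pairs, with covariates.
make_twin_samples <- function(n_disc = 6, n_cc = 2, n_co = 2, seed = 1) {
  withr::with_seed(seed, {
    n_pairs <- n_disc + n_cc + n_co
    type <- rep(c("discordant", "concordant_case", "concordant_control"),
                c(n_disc, n_cc, n_co))
    fam <- sprintf("F%02d", seq_len(n_pairs))
    pt2 <- rep(type, each = 2)
    tibble::tibble(
      sample_id = paste0(rep(fam, each = 2), c("_a", "_b")),
      family_id = rep(fam, each = 2),
      pair_type = pt2,
      is_case = as.integer(pt2 == "concordant_case" |
                             (pt2 == "discordant" &
                                rep(c(TRUE, FALSE), n_pairs))),
      age = rep(runif(n_pairs, 40, 80), each = 2),
      sex = rep(rbinom(n_pairs, 1, 0.5), each = 2),
      bmi = rnorm(2 * n_pairs, 27, 4)
    )
  })
}

# A methylome with iid N(0,1)-ish raw values for the given samples.
make_methylome <- function(samples, n_bins = 50, seed = 1,
                           signal_type = "AMS") {
  withr::with_seed(seed, {
    bins <- tile_genome(c(chrT = n_bins * 500), bin_size = 500, step = 500)
    binned_methylome(bins,
                     matrix(rnorm(n_bins * nrow(samples), 8, 1), n_bins,
                            nrow(samples)),
                     samples$sample_id, signal_type = signal_type)
  })
}

# Simulate one bin's data from the family mixed model, returning y plus the
# design used by the scan.
simulate_lmm_bin <- function(samples, beta_disease = 0, sigma_b = 1,
                             sigma_e = 1) {
  fam <- unique(samples$family_id)
  u <- stats::rnorm(length(fam), 0, sigma_b)
  y <- beta_disease * samples$is_case +
    u[match(samples$family_id, fam)] +
    stats::rnorm(nrow(samples), 0, sigma_e)
  X <- cbind(`(Intercept)` = 1, disease = samples$is_case)
  list(y = y, X = X)
}
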