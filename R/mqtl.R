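#' Genotype dosage container
#'
#' Additively coded SNP dosages (0-2, possibly fractional for imputed
#' genotypes) for a set of samples, with SNP positions and minor-allele
#' frequencies.  Common-variant filtering (e.g. MAF > 5%) is assumed to
#' have been applied upstream; [genotype_matrix()] checks that the stored
#' MAF matches the matrix.
#'
#' @param snps Tibble with `snp_id`, `chrom`, `pos` and optionally `maf`.
#' @param dosage Numeric matrix, SNPs by samples, values in `[0, 2]`.
#' @param samples Sample IDs (default: column names of `dosage`).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(snps, dosage, samples = colnames(dosage)) {
  snps <- as_tibble(snps)
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != nrow(snps)) {
    input_error("`dosage` must have one row per SNP.")
  }
  if (any(dosage < 0 | dosage > 2, na.rm = TRUE)) {
    input_error("dosages must lie in [0, 2].")
  }
  emp_maf <- rowMeans(dosage) / 2
  emp_maf <- pmin(emp_maf, 1 - emp_maf)
  if (!"maf" %in% names(snps)) {
    snps$maf <- emp_maf
  } else if (max(abs(snps$maf - emp_maf)) > 1e-8) {
    input_error("stored MAF disagrees with the dosage matrix.")
  }
  rownames(dosage) <- snps$snp_id
  colnames(dosage) <- samples
  structure(list(snps = snps, samples = as.character(samples),
                 dosage = dosage),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d SNPs x %d samples\n",
              nrow(x$snps), length(x$samples)))
  invisible(x)
}

# Cis window membership: SNP position in [bin_start - window, bin_end +
# window), half-open on the right.
cis_pairs <- function(bins, snps, window) {
  out <- lapply(seq_len(nrow(bins)), function(b) {
    sel <- which(snps$chrom == bins$chrom[b] &
                   snps$pos >= bins$start[b] - window &
                   snps$pos < bins$end[b] + window)
    if (length(sel)) tibble(bin_idx = b, snp_idx = sel) else NULL
  })
  bind_rows(out)
}

# Slope test of each (y, g) pair after adjusting both for covariates C
# (Frisch-Waugh); returns beta, se, t, p with df = n - ncol(C) - 1.
slope_test <- function(y, g, C) {
  qc <- qr(C)
  ry <- qr.resid(qc, y)
  rg <- qr.resid(qc, g)
  sxx <- sum(rg^2)
  beta <- sum(rg * ry) / sxx
  df <- length(y) - ncol(C) - 1
  rss <- sum((ry - beta * rg)^2)
  se <- sqrt(rss / df / sxx)
  tstat <- beta / se
  c(beta = beta, se = se, statistic = tstat, p = 2 * pt(-abs(tstat), df))
}

mqtl_scan_engine <- function(methylome, genotypes, samples, pairs,
                             covariates) {
  m <- subset_methylome(methylome, samples = samples$sample_id)
  G <- genotypes$dosage[, match(samples$sample_id, genotypes$samples),
                        drop = FALSE]
  C <- matrix(1, nrow(samples), 1)
  for (col in covariates) C <- cbind(C, as.numeric(samples[[col]]))
  colnames(C) <- c("(Intercept)", covariates)
  skipped <- 0L
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    b <- pairs$bin_idx[i]
    s <- pairs$snp_idx[i]
    g <- G[s, ]
    if (var(g) == 0) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    st <- slope_test(m$values[b, ], g, C)
    tibble(bin_id = m$bins$bin_id[b], snp_id = genotypes$snps$snp_id[s],
           beta = st[["beta"]], se = st[["se"]],
           statistic = st[["statistic"]], p = st[["p"]])
  })
  out <- bind_rows(rows)
  attr(out, "n_skipped_monomorphic") <- skipped
  out
}

#' Cis methylation-QTL scan
#'
#' Tests, for every DMR, the SNPs whose position falls within `window` bp
#' of the region (`[start - window, end + window)`, half-open) by ordinary
#' least squares of methylation on dosage adjusted for covariates (age and
#' sex by default).  Monomorphic SNPs in the tested samples are skipped and
#' counted.  Both a Bonferroni-adjusted p (over all tested pairs) and a BH
#' q-value are reported.
#'
#' @param methylome [binned_methylome()] restricted to the DMRs of
#'   interest (per-DMR normalized signal).
#' @param genotypes A [genotype_matrix()].
#' @param samples Sample table (must include the covariate columns).
#' @param window Cis window in bp (default 50 kb).
#' @param covariates Covariate column names.
#' @return A tibble of per-(DMR, SNP) records with `p`, `p_bonferroni`,
#'   `q`; the `best_snp` attribute holds the top SNP per DMR.
#' @export
cis_mqtl_scan <- function(methylome, genotypes, samples, window = 50000,
                          covariates = c("age", "sex")) {
  samples <- as_tibble(samples)
  pairs <- cis_pairs(methylome$bins, genotypes$snps, window)
  if (!nrow(pairs)) {
    out <- tibble(bin_id = character(), snp_id = character(),
                  beta = numeric(), se = numeric(), statistic = numeric(),
                  p = numeric(), p_bonferroni = numeric(), q = numeric())
    attr(out, "best_snp") <- out
    return(out)
  }
  out <- mqtl_scan_engine(methylome, genotypes, samples, pairs, covariates)
  out$p_bonferroni <- pmin(out$p * nrow(out), 1)
  out$q <- bh_fdr(out$p)
  best <- out |>
    dplyr::group_by(.data$bin_id) |>
    dplyr::slice_min(.data$p, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  attr(out, "best_snp") <- best
  out
}

#' Trans methylation-QTL scan
#'
#' Genome-wide (DMR, SNP) regressions excluding the cis window, with BH
#' FDR; pairs with `q <= fdr` are flagged as trans mQTL.  The cis/trans
#' partition is exact: every tested pair appears in exactly one scan.
#'
#' @inheritParams cis_mqtl_scan
#' @param cis_window Window excluded around each DMR (must match the cis
#'   scan to keep the partition exhaustive).
#' @param fdr FDR threshold flagging trans mQTL.
#' @return A tibble of per-(DMR, SNP) records with `q` and `is_trans_mqtl`.
#' @export
trans_mqtl_scan <- function(methylome, genotypes, samples,
                            cis_window = 50000,
                            covariates = c("age", "sex"), fdr = 0.05) {
  samples <- as_tibble(samples)
  cis <- cis_pairs(methylome$bins, genotypes$snps, cis_window)
  all_pairs <- tidyr::expand_grid(bin_idx = seq_len(nrow(methylome$bins)),
                                  snp_idx = seq_len(nrow(genotypes$snps)))
  key <- paste(all_pairs$bin_idx, all_pairs$snp_idx)
  cis_key <- paste(cis$bin_idx, cis$snp_idx)
  pairs <- all_pairs[!key %in% cis_key, ]
  if (!nrow(pairs)) {
    return(tibble(bin_id = character(), snp_id = character(),
                  beta = numeric(), se = numeric(), statistic = numeric(),
                  p = numeric(), q = numeric(), is_trans_mqtl = logical()))
  }
  out <- mqtl_scan_engine(methylome, genotypes, samples, pairs, covariates)
  out$q <- bh_fdr(out$p)
  out$is_trans_mqtl <- out$q <= fdr
  out
}
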