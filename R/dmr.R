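#' Benjamini-Hochberg q-values
#'
#' Step-up adjusted q-values `q_i = min_{j >= i} (p_(j) * m / j)`, capped at
#' one and mapped back to input order (via [stats::p.adjust()]).  Input
#' p-values must lie in `(0, 1]`.
#'
#' @param p Numeric vector of p-values.
#' @return Numeric vector of q-values in input order.
#' @export
#' @examples
#' bh_fdr(c(0.001, 0.01, 0.02, 0.8))
bh_fdr <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    input_error("p-values must be numeric in (0, 1].")
  }
  p.adjust(p, method = "BH")
}

# Build the fixed-effect design matrix for the disease scan from a sample
# table; disease status is always the first non-intercept column.
build_design <- function(samples, covariates) {
  samples <- as_tibble(samples)
  needed <- c("is_case", covariates)
  missing_cols <- setdiff(needed, names(samples))
  if (length(missing_cols)) {
    input_error(sprintf("sample table lacks column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  for (col in needed) {
    if (anyNA(samples[[col]])) {
      bad <- samples$sample_id[is.na(samples[[col]])]
      input_error(sprintf("missing `%s` for sample(s): %s", col,
                          paste(head(bad, 5), collapse = ", ")))
    }
  }
  X <- cbind(`(Intercept)` = 1, disease = as.numeric(samples$is_case))
  for (col in covariates) {
    X <- cbind(X, as.numeric(samples[[col]]))
    colnames(X)[ncol(X)] <- col
  }
  X
}

#' Genome-wide DMR scan with a family mixed model
#'
#' Regresses normalized per-bin methylation on disease status plus
#' covariates with a family random intercept (see
#' [fit_family_mixed_model()]), one fit per retained bin, and adjusts the
#' disease-effect p-values by Benjamini-Hochberg across all tested bins.
#' Bins whose fit does not converge are excluded and counted in the
#' `n_nonconverged` attribute.  The direction label follows the sign of the
#' disease coefficient: `"hyper"` means hypermethylated in cases.
#'
#' @param methylome A normalized [binned_methylome()].
#' @param samples Sample table with `sample_id`, `family_id`, `is_case` and
#'   the covariate columns.
#' @param covariates Character vector of covariate column names (default
#'   age, sex, BMI).
#' @param fdr_tiers Reporting thresholds attached to the result summary.
#'
#' @return A tibble of class `twindmr_scan` with one row per tested bin:
#'   `bin_id`, coordinates, `beta`, `se`, `statistic`, `p`, `q`,
#'   `direction`, variance components and `converged`.
#' @export
dmr_scan <- function(methylome, samples,
                     covariates = c("age", "sex", "bmi"),
                     fdr_tiers = c(0.05, 0.10, 0.25)) {
  stopifnot(inherits(methylome, "binned_methylome"))
  if (methylome$signal_type != "normalized") {
    input_error("`methylome` must be normalized (see normalize_bins()).")
  }
  samples <- as_tibble(samples)
  if (!all(samples$sample_id %in% methylome$samples)) {
    input_error("every sample in `samples` must be present in the methylome.")
  }
  m <- subset_methylome(methylome, samples = samples$sample_id)
  X <- build_design(samples, covariates)
  tr <- family_transform(samples$family_id)
  Xt <- rotate_rows(X, tr)
  Yt <- rotate_rows(t(m$values), tr)  # samples x bins, rotated
  n <- nrow(X)
  p <- ncol(X)
  if (!nrow(m$bins)) {
    res <- empty_scan_records()
    inform("dmr_scan: no testable bins (all constant or filtered).")
    return(res)
  }
  fits <- lapply(seq_len(nrow(m$bins)), function(b) {
    fit_family_lmm_rotated(Xt, Yt[, b], tr$lam_type, n, p,
                           terms = colnames(X))
  })
  conv <- vapply(fits, `[[`, logical(1), "converged")
  rec <- tibble(
    bin_id = m$bins$bin_id,
    chrom = m$bins$chrom,
    start = m$bins$start,
    end = m$bins$end,
    beta = vapply(fits, function(f) f$coefficients[["disease"]], numeric(1)),
    se = vapply(fits, function(f) f$se[["disease"]], numeric(1)),
    statistic = vapply(fits, function(f) f$z[["disease"]], numeric(1)),
    p = vapply(fits, function(f) f$p.value[["disease"]], numeric(1)),
    sigma_family_sq = vapply(fits, `[[`, numeric(1), "sigma_family_sq"),
    sigma_resid_sq = vapply(fits, `[[`, numeric(1), "sigma_resid_sq"),
    converged = conv
  )
  rec <- rec[rec$converged & is.finite(rec$p), ]
  rec$q <- bh_fdr(rec$p)
  rec$direction <- direction_label(rec$beta)
  rec <- rec[, c("bin_id", "chrom", "start", "end", "beta", "se",
                 "statistic", "p", "q", "direction",
                 "sigma_family_sq", "sigma_resid_sq", "converged")]
  class(rec) <- c("twindmr_scan", class(rec))
  attr(rec, "scan") <- "dmr"
  attr(rec, "n_nonconverged") <- sum(!conv)
  attr(rec, "fdr_tiers") <- fdr_tiers
  rec
}

empty_scan_records <- function() {
  rec <- tibble(bin_id = character(), chrom = character(),
                start = numeric(), end = numeric(),
                beta = numeric(), se = numeric(), statistic = numeric(),
                p = numeric(), q = numeric(), direction = character(),
                sigma_family_sq = numeric(), sigma_resid_sq = numeric(),
                converged = logical())
  class(rec) <- c("twindmr_scan", class(rec))
  rec
}

#' Count discoveries per FDR tier
#'
#' @param records A scan result from [dmr_scan()] or [gidmr_scan()].
#' @param tiers FDR thresholds.
#' @return A tibble with one row per tier (`q_threshold`, `n_dmrs`,
#'   `n_hyper`, `n_hypo`).
#' @export
dmr_tiers <- function(records, tiers = attr(records, "fdr_tiers") %||%
                        c(0.05, 0.10, 0.25)) {
  purrr::map_dfr(tiers, function(thr) {
    sel <- records[records$q <= thr, ]
    tibble(q_threshold = thr,
           n_dmrs = nrow(sel),
           n_hyper = sum(sel$direction == "hyper", na.rm = TRUE),
           n_hypo = sum(sel$direction == "hypo", na.rm = TRUE))
  })
}

# Vectorized OLS of every column of Y on a common design X; returns the
# slope, SE and two-sided t p-value of the column named `term`.
ols_scan_fixed_design <- function(Y, X, term) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    abort("design matrix is rank deficient.", class = "twindmr_model_error")
  }
  coef <- qr.coef(qrX, Y)
  resid <- Y - X %*% coef
  df <- nrow(X) - ncol(X)
  s2 <- colSums(resid^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  d <- XtXinv[match(term, colnames(X)), match(term, colnames(X))]
  beta <- coef[match(term, colnames(X)), ]
  se <- sqrt(s2 * d)
  tstat <- beta / se
  list(beta = beta, se = se, statistic = tstat,
       p = 2 * pt(-abs(tstat), df), df = df)
}

#' Replicate discovery DMRs in unrelated samples
#'
#' Per discovery DMR, ordinary least squares of (normalized) methylation on
#' disease status plus covariates in an independent set of unrelated
#' samples.  A DMR is `same_direction` when the replication slope agrees in
#' sign with the discovery effect and `replicated` when it additionally
#' reaches `p < alpha`.  DMRs with a zero discovery effect cannot be
#' oriented and are flagged `ambiguous`; DMRs absent from the replication
#' matrix are flagged `missing` and excluded from the summary denominators.
#'
#' @param discovery A scan result from [dmr_scan()] (or any tibble with
#'   `bin_id` and `beta`), usually restricted to the suggestive tier.
#' @param methylome Replication [binned_methylome()] (normalized).
#' @param samples Replication sample table; all families must be singletons.
#' @param covariates Covariate column names for the replication regression.
#' @param alpha Nominal significance threshold for replication.
#'
#' @return A tibble with per-DMR replication effect, p-value and flags; the
#'   `summary` attribute holds the same-direction and replicated fractions.
#' @export
replicate_dmrs <- function(discovery, methylome, samples,
                           covariates = c("age", "sex", "bmi"),
                           alpha = 0.05) {
  stopifnot(inherits(methylome, "binned_methylome"))
  samples <- as_tibble(samples)
  if (any(table(samples$family_id) > 1)) {
    input_error("replication samples must be unrelated (singleton families).")
  }
  m <- subset_methylome(methylome, samples = samples$sample_id)
  X <- build_design(samples, covariates)
  present <- discovery$bin_id %in% m$bins$bin_id
  out <- tibble(bin_id = discovery$bin_id,
                discovery_beta = discovery$beta,
                missing = !present)
  Y <- t(m$values[match(discovery$bin_id[present], m$bins$bin_id), ,
                  drop = FALSE])
  if (ncol(Y)) {
    fit <- ols_scan_fixed_design(Y, X, "disease")
    out$beta <- out$se <- out$p <- NA_real_
    out$beta[present] <- fit$beta
    out$se[present] <- fit$se
    out$p[present] <- fit$p
  } else {
    out$beta <- out$se <- out$p <- NA_real_
  }
  out$ambiguous <- !out$missing & out$discovery_beta == 0
  out$same_direction <- !out$missing & !out$ambiguous &
    sign(out$beta) == sign(out$discovery_beta)
  out$replicated <- out$same_direction & out$p < alpha
  denom <- sum(!out$missing & !out$ambiguous)
  attr(out, "summary") <- tibble(
    n_tested = denom,
    n_missing = sum(out$missing),
    n_same_direction = sum(out$same_direction),
    frac_same_direction = if (denom) sum(out$same_direction) / denom else NA_real_,
    n_replicated = sum(out$replicated),
    frac_replicated = if (denom) sum(out$replicated) / denom else NA_real_
  )
  out
}

#' Confounder check for suggestive DMRs
#'
#' Refits the family mixed model at each DMR adding one extra covariate
#' (for example diabetes-medication use, or one white-blood-cell subtype
#' count) and reports the covariate's own p-value together with the
#' disease p-value after adjustment.  The `summary` attribute counts DMRs
#' whose covariate effect passes BH FDR < 0.05 -- the criterion for calling
#' the covariate a material confounder.
#'
#' @param records Scan records (e.g. the q <= 0.25 tier of [dmr_scan()]).
#' @param methylome The normalized discovery [binned_methylome()].
#' @param samples Sample table containing the extra covariate column.
#' @param extra_covariate Name of the covariate column to add.
#' @param covariates Base covariates of the scan model.
#'
#' @return A tibble with `bin_id`, `covariate_beta`, `covariate_p`,
#'   `disease_p_adjusted` and an `untestable` flag (constant or collinear
#'   covariate).
#' @export
confounder_check <- function(records, methylome, samples, extra_covariate,
                             covariates = c("age", "sex", "bmi")) {
  stopifnot(inherits(methylome, "binned_methylome"))
  samples <- as_tibble(samples)
  if (!extra_covariate %in% names(samples)) {
    input_error(sprintf("sample table lacks column `%s`.", extra_covariate))
  }
  m <- subset_methylome(methylome, samples = samples$sample_id,
                        bins = intersect(records$bin_id,
                                         methylome$bins$bin_id))
  X <- build_design(samples, c(covariates, extra_covariate))
  if (var(as.numeric(samples[[extra_covariate]])) == 0) {
    return(tibble(bin_id = m$bins$bin_id, covariate_beta = NA_real_,
                  covariate_p = NA_real_, disease_p_adjusted = NA_real_,
                  untestable = TRUE))
  }
  rank_ok <- qr(X)$rank == ncol(X)
  if (!rank_ok) {
    warn(sprintf("`%s` is collinear with the base design; DMRs flagged untestable.",
                 extra_covariate))
    return(tibble(bin_id = m$bins$bin_id, covariate_beta = NA_real_,
                  covariate_p = NA_real_, disease_p_adjusted = NA_real_,
                  untestable = TRUE))
  }
  tr <- family_transform(samples$family_id)
  Xt <- rotate_rows(X, tr)
  Yt <- rotate_rows(t(m$values), tr)
  n <- nrow(X)
  p <- ncol(X)
  rows <- lapply(seq_len(nrow(m$bins)), function(b) {
    f <- fit_family_lmm_rotated(Xt, Yt[, b], tr$lam_type, n, p,
                                terms = colnames(X))
    tibble(bin_id = m$bins$bin_id[b],
           covariate_beta = f$coefficients[[extra_covariate]],
           covariate_p = f$p.value[[extra_covariate]],
           disease_p_adjusted = f$p.value[["disease"]],
           untestable = !f$converged)
  })
  out <- bind_rows(rows)
  tested <- !out$untestable & is.finite(out$covariate_p)
  qv <- rep(NA_real_, nrow(out))
  if (any(tested)) qv[tested] <- bh_fdr(out$covariate_p[tested])
  out$covariate_q <- qv
  attr(out, "summary") <- tibble(
    covariate = extra_covariate,
    n_tested = sum(tested),
    n_confounded_fdr05 = sum(qv <= 0.05, na.rm = TRUE)
  )
  out
}
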