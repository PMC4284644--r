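#' Metabolite matrix container
#'
#' Metabolite levels (metabolites by samples) with the mass-spectrometry
#' run-day label of every sample, as needed for run-day median
#' normalization.
#'
#' @param values Numeric matrix, metabolites by samples; `NA` marks missing
#'   measurements.
#' @param run_day Run-day label per sample.
#' @param metabolites Metabolite IDs (default: row names).
#' @param samples Sample IDs (default: column names).
#' @param normalized Whether values are already normalized.
#' @return An object of class `metabolite_matrix`.
#' @export
metabolite_matrix <- function(values, run_day,
                              metabolites = rownames(values),
                              samples = colnames(values),
                              normalized = FALSE) {
  values <- as.matrix(values)
  if (length(run_day) != ncol(values)) {
    input_error("`run_day` must have one label per sample.")
  }
  rownames(values) <- metabolites
  colnames(values) <- samples
  structure(list(values = values, run_day = as.character(run_day),
                 metabolites = as.character(metabolites),
                 samples = as.character(samples), normalized = normalized),
            class = "metabolite_matrix")
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  cat(sprintf("<metabolite_matrix> %d metabolites x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' Run-day median normalization of metabolite data
#'
#' Corrects the between-day machine tuning effect by dividing each value by
#' its (metabolite, run-day) median, then standardizes every metabolite
#' across samples (mean 0, sd 1).  The transformation is invariant to any
#' per-day multiplicative scale by construction.  Groups whose values are
#' all missing are flagged and left missing.
#'
#' @param metabolites A raw [metabolite_matrix()].
#' @return A normalized [metabolite_matrix()]; flagged (metabolite, day)
#'   groups are listed in the `all_missing_groups` attribute.
#' @export
runday_median_normalize <- function(metabolites) {
  stopifnot(inherits(metabolites, "metabolite_matrix"))
  v <- metabolites$values
  day <- metabolites$run_day
  flagged <- list()
  for (d in unique(day)) {
    sel <- day == d
    med <- apply(v[, sel, drop = FALSE], 1, median, na.rm = TRUE)
    miss <- !is.finite(med) | med == 0
    if (any(miss)) {
      flagged[[d]] <- metabolites$metabolites[miss]
      med[miss] <- NA_real_
    }
    v[, sel] <- v[, sel, drop = FALSE] / med
  }
  mu <- rowMeans(v, na.rm = TRUE)
  s <- apply(v, 1, sd, na.rm = TRUE)
  s[!is.finite(s) | s == 0] <- NA_real_
  v <- (v - mu) / s
  out <- metabolite_matrix(v, day, metabolites$metabolites,
                           metabolites$samples, normalized = TRUE)
  attr(out, "all_missing_groups") <- flagged
  out
}

#' Within-pair Wilcoxon signed-rank test per metabolite
#'
#' For each metabolite, computes the affected-minus-unaffected difference
#' within every disease-discordant twin pair and tests whether the
#' differences are centred at zero with the Wilcoxon signed-rank test
#' (exact null distribution up to 25 pairs, normal approximation with
#' continuity correction above; zero differences dropped by the standard
#' signed-rank convention).  Metabolites with fewer than `min_pairs`
#' usable pairs are flagged untestable.
#'
#' @param metabolites A (normalized) [metabolite_matrix()].
#' @param samples Sample table with `sample_id`, `family_id`, `is_case`.
#' @param min_pairs Minimum usable pairs per metabolite.
#' @return A tibble with one row per metabolite: `n_pairs`, `statistic`
#'   (V, the positive-rank sum), `p`, `direction` (sign of the mean
#'   difference) and `untestable`.
#' @export
pairwise_wilcoxon <- function(metabolites, samples, min_pairs = 5) {
  stopifnot(inherits(metabolites, "metabolite_matrix"))
  samples <- as_tibble(samples)
  samples <- samples[samples$sample_id %in% metabolites$samples, ]
  fam <- split(seq_len(nrow(samples)), samples$family_id)
  fam <- fam[lengths(fam) == 2]
  disc <- Filter(function(idx) sum(samples$is_case[idx]) == 1, fam)
  aff <- vapply(disc, function(i) i[samples$is_case[i] == 1], integer(1))
  unaff <- vapply(disc, function(i) i[samples$is_case[i] == 0], integer(1))
  col_a <- match(samples$sample_id[aff], metabolites$samples)
  col_u <- match(samples$sample_id[unaff], metabolites$samples)
  rows <- lapply(seq_len(nrow(metabolites$values)), function(m) {
    d <- metabolites$values[m, col_a] - metabolites$values[m, col_u]
    d <- d[is.finite(d)]
    nz <- d[d != 0]
    if (length(nz) < min_pairs) {
      return(tibble(metabolite = metabolites$metabolites[m],
                    n_pairs = length(nz), statistic = NA_real_,
                    p = NA_real_, direction = NA_character_,
                    untestable = TRUE))
    }
    wt <- suppressWarnings(
      wilcox.test(nz, mu = 0, exact = length(nz) <= 25, correct = TRUE)
    )
    tibble(metabolite = metabolites$metabolites[m],
           n_pairs = length(nz),
           statistic = unname(wt$statistic),
           p = wt$p.value,
           direction = direction_label(mean(d)),
           untestable = FALSE)
  })
  bind_rows(rows)
}

#' Association of within-pair metabolite and methylation differences
#'
#' A companion to [pairwise_wilcoxon()] that conditions on methylation:
#' per metabolite, the within-pair (affected - unaffected) metabolite
#' difference is regressed on the within-pair methylation difference at a
#' chosen DMR across discordant pairs.
#'
#' @inheritParams pairwise_wilcoxon
#' @param methylation Named numeric vector of per-sample methylation at the
#'   DMR of interest (names = sample IDs).
#' @return A tibble with per-metabolite slope, p and direction.
#' @export
pair_diff_association <- function(metabolites, samples, methylation,
                                  min_pairs = 5) {
  stopifnot(inherits(metabolites, "metabolite_matrix"))
  samples <- as_tibble(samples)
  samples <- samples[samples$sample_id %in% metabolites$samples, ]
  fam <- split(seq_len(nrow(samples)), samples$family_id)
  fam <- fam[lengths(fam) == 2]
  disc <- Filter(function(idx) sum(samples$is_case[idx]) == 1, fam)
  aff <- vapply(disc, function(i) i[samples$is_case[i] == 1], integer(1))
  unaff <- vapply(disc, function(i) i[samples$is_case[i] == 0], integer(1))
  dm <- methylation[samples$sample_id[aff]] -
    methylation[samples$sample_id[unaff]]
  col_a <- match(samples$sample_id[aff], metabolites$samples)
  col_u <- match(samples$sample_id[unaff], metabolites$samples)
  rows <- lapply(seq_len(nrow(metabolites$values)), function(m) {
    d <- metabolites$values[m, col_a] - metabolites$values[m, col_u]
    ok <- is.finite(d) & is.finite(dm)
    if (sum(ok) < min_pairs || var(dm[ok]) == 0) {
      return(tibble(metabolite = metabolites$metabolites[m],
                    n_pairs = sum(ok), beta = NA_real_, p = NA_real_,
                    direction = NA_character_, untestable = TRUE))
    }
    st <- slope_test(d[ok], dm[ok], matrix(1, sum(ok), 1))
    tibble(metabolite = metabolites$metabolites[m], n_pairs = sum(ok),
           beta = st[["beta"]], p = st[["p"]],
           direction = direction_label(st[["beta"]]), untestable = FALSE)
  })
  bind_rows(rows)
}

#' Replication regression of metabolites on methylation
#'
#' Stage-two test in unrelated samples: ordinary least squares of each
#' metabolite on methylation plus covariates.  When a discovery table is
#' supplied, only metabolites that passed the discovery stage at
#' `alpha` are carried forward (the staged design); the rest are omitted.
#'
#' @param metabolites A (normalized) [metabolite_matrix()].
#' @param methylation Named numeric vector of per-sample methylation.
#' @param samples Unrelated-sample table with the covariate columns.
#' @param discovery Optional discovery results from [pairwise_wilcoxon()]
#'   used to select metabolites (`p < alpha`).
#' @param alpha Discovery carry-forward threshold.
#' @param covariates Covariate columns.
#' @return A tibble with per-metabolite `beta`, `p`, `direction`, `n`.
#' @export
replication_regression <- function(metabolites, methylation, samples,
                                   discovery = NULL, alpha = 0.05,
                                   covariates = c("age", "sex", "bmi")) {
  stopifnot(inherits(metabolites, "metabolite_matrix"))
  samples <- as_tibble(samples)
  if (any(table(samples$family_id) > 1)) {
    input_error("replication samples must be unrelated.")
  }
  keep <- metabolites$metabolites
  if (!is.null(discovery)) {
    keep <- discovery$metabolite[!discovery$untestable &
                                   discovery$p < alpha]
  }
  if (!length(keep)) {
    return(tibble(metabolite = character(), n = integer(),
                  beta = numeric(), p = numeric(), direction = character()))
  }
  has_meth <- samples$sample_id %in% names(methylation)[
    is.finite(methylation)]
  if (any(!has_meth)) {
    inform(sprintf("replication_regression: dropped %d sample(s) without methylation.",
                   sum(!has_meth)))
  }
  samples <- samples[has_meth, ]
  C <- matrix(1, nrow(samples), 1)
  for (col in covariates) C <- cbind(C, as.numeric(samples[[col]]))
  meth <- methylation[samples$sample_id]
  cols <- match(samples$sample_id, metabolites$samples)
  rows <- lapply(keep, function(met) {
    y <- metabolites$values[match(met, metabolites$metabolites), cols]
    ok <- is.finite(y)
    st <- slope_test(meth[ok], y[ok], C[ok, , drop = FALSE])
    tibble(metabolite = met, n = sum(ok), beta = st[["beta"]],
           p = st[["p"]], direction = direction_label(st[["beta"]]))
  })
  bind_rows(rows)
}

#' Meta-analysis of discovery and replication metabolite associations
#'
#' Combines the two stages per metabolite by signed Stouffer weighting:
#' each two-sided p and direction is converted to a signed z,
#' `z_i = sign_i * qnorm(1 - p_i / 2)`, and combined as
#' `z_meta = (w1 z1 + w2 z2) / sqrt(w1^2 + w2^2)` with weights
#' `w = sqrt(n)`; the meta p is two-sided normal.  Bonferroni correction
#' is applied over the meta-analysed metabolites.  Metabolites missing a
#' direction in either stage are excluded and counted.
#'
#' @param discovery Tibble with `metabolite`, `p`, `direction`, `n` (or
#'   `n_pairs`).
#' @param replication Tibble with the same columns.
#' @return A tibble with `meta_z`, `meta_p`, `p_bonferroni` and a
#'   `significant` flag at Bonferroni 0.05.
#' @export
#' @examples
#' meta_analyze(
#'   tibble::tibble(metabolite = "taurocholate", p = 0.05,
#'                  direction = "hyper", n = 36),
#'   tibble::tibble(metabolite = "taurocholate", p = 0.05,
#'                  direction = "hyper", n = 36)
#' )
meta_analyze <- function(discovery, replication) {
  norm_tbl <- function(x, stage) {
    x <- as_tibble(x)
    if (!"n" %in% names(x) && "n_pairs" %in% names(x)) x$n <- x$n_pairs
    x <- x[, c("metabolite", "p", "direction", "n")]
    names(x)[2:4] <- paste0(c("p_", "direction_", "n_"), stage)
    x
  }
  both <- dplyr::inner_join(norm_tbl(discovery, "discovery"),
                            norm_tbl(replication, "replication"),
                            by = "metabolite")
  usable <- !is.na(both$direction_discovery) &
    !is.na(both$direction_replication) &
    is.finite(both$p_discovery) & is.finite(both$p_replication)
  if (any(!usable)) {
    inform(sprintf("meta_analyze: excluded %d metabolite(s) without direction.",
                   sum(!usable)))
  }
  both <- both[usable, ]
  sgn <- function(d) ifelse(d == "hyper", 1, -1)
  # Guard against p-values that underflowed to zero.
  clamp <- function(p) pmax(p, .Machine$double.xmin)
  z1 <- sgn(both$direction_discovery) *
    qnorm(clamp(both$p_discovery) / 2, lower.tail = FALSE)
  z2 <- sgn(both$direction_replication) *
    qnorm(clamp(both$p_replication) / 2, lower.tail = FALSE)
  w1 <- sqrt(both$n_discovery)
  w2 <- sqrt(both$n_replication)
  zm <- (w1 * z1 + w2 * z2) / sqrt(w1^2 + w2^2)
  out <- tibble(metabolite = both$metabolite,
                meta_z = zm,
                meta_p = 2 * pnorm(-abs(zm)),
                direction = direction_label(zm))
  m <- nrow(out)
  out$p_bonferroni <- pmin(out$meta_p * m, 1)
  out$significant <- out$p_bonferroni < 0.05
  out
}
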