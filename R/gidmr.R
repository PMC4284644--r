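# Genetically independent DMRs: within-pair analysis of disease-discordant
# monozygotic twins.  Because co-twins are genetically identical and share
# the family environment, the affected-minus-unaffected methylation
# difference cancels genetic and pair-shared effects by construction; what
# remains reflects discordance-specific (environmental, stochastic or
# disease-consequent) methylation variation.

#' Within-pair methylation differences for discordant twin pairs
#'
#' Computes, per bin, the affected-minus-unaffected co-twin difference for
#' every disease-discordant pair.  Concordant pairs and unrelated samples
#' are excluded.  Positive differences mean hypermethylation in the
#' affected twin, matching the direction convention of [dmr_scan()].
#'
#' @param methylome A [binned_methylome()].
#' @param samples Sample table with `sample_id`, `family_id`, `is_case`.
#' @return An object of class `pair_differences`: a pairs-by-bins matrix
#'   of differences plus the pair table.  `as_tibble()` gives a long view.
#' @export
pair_differences <- function(methylome, samples) {
  stopifnot(inherits(methylome, "binned_methylome"))
  samples <- as_tibble(samples)
  if (!is.null(samples$pair_type)) {
    claimed <- samples |>
      dplyr::filter(.data$pair_type == "discordant") |>
      dplyr::group_by(.data$family_id) |>
      dplyr::summarise(n_case = sum(.data$is_case), n = dplyr::n())
    bad <- claimed$family_id[claimed$n == 2 & claimed$n_case != 1]
    if (length(bad)) {
      input_error(sprintf(
        "pair(s) labelled discordant but not status-discordant: %s",
        paste(bad, collapse = ", ")))
    }
  }
  fam <- split(seq_len(nrow(samples)), samples$family_id)
  fam <- fam[lengths(fam) == 2]
  disc <- Filter(function(idx) sum(samples$is_case[idx]) == 1, fam)
  if (length(disc) < 2) {
    input_error("need at least 2 discordant pairs.")
  }
  aff <- vapply(disc, function(idx) idx[samples$is_case[idx] == 1],
                integer(1))
  unaff <- vapply(disc, function(idx) idx[samples$is_case[idx] == 0],
                  integer(1))
  m <- subset_methylome(methylome, samples = samples$sample_id)
  D <- t(m$values[, aff, drop = FALSE] - m$values[, unaff, drop = FALSE])
  rownames(D) <- names(disc)
  structure(
    list(diffs = D,
         pairs = tibble(pair_id = names(disc),
                        affected = samples$sample_id[aff],
                        unaffected = samples$sample_id[unaff]),
         bins = m$bins),
    class = "pair_differences"
  )
}

#' @export
print.pair_differences <- function(x, ...) {
  cat(sprintf("<pair_differences> %d discordant pairs x %d bins\n",
              nrow(x$diffs), ncol(x$diffs)))
  invisible(x)
}

#' @method as_tibble pair_differences
#' @export
as_tibble.pair_differences <- function(x, ...) {
  out <- tidyr::expand_grid(pair_id = x$pairs$pair_id,
                            bin_id = x$bins$bin_id)
  out$difference <- as.vector(t(x$diffs))
  out
}

#' One-sample t-test on within-pair differences
#'
#' Tests whether the mean of the supplied differences departs from zero:
#' `t = mean / (sd / sqrt(n))`, two-sided p-value from the t reference with
#' `n - 1` degrees of freedom.  Zero sample variance makes the parametric
#' test undefined; such input is flagged untestable rather than assigned
#' a p-value.
#'
#' @param x Numeric vector of differences (`n >= 2`).
#' @return A one-row tibble with `estimate` (mean difference), `statistic`,
#'   `df`, `p` and `untestable`.
#' @export
#' @examples
#' one_sample_t(c(1, 2, 3))
one_sample_t <- function(x) {
  if (length(x) < 2) input_error("need at least 2 differences.")
  s <- sd(x)
  n <- length(x)
  if (!is.finite(s) || s == 0) {
    return(tibble(estimate = mean(x), statistic = NA_real_,
                  df = n - 1, p = NA_real_, untestable = TRUE))
  }
  tstat <- mean(x) / (s / sqrt(n))
  tibble(estimate = mean(x), statistic = tstat, df = n - 1,
         p = 2 * pt(-abs(tstat), n - 1), untestable = FALSE)
}

#' Genetically independent DMR scan
#'
#' Runs the one-sample t-test of [one_sample_t()] on the within-pair
#' differences of every bin across the disease-discordant pairs and adjusts
#' p-values by Benjamini-Hochberg.  Bins with zero difference variance are
#' excluded and counted in the `n_untestable` attribute.
#'
#' @inheritParams pair_differences
#' @param fdr_tiers Reporting thresholds attached to the result summary.
#' @return A tibble of class `twindmr_scan`; `beta` is the mean within-pair
#'   difference.
#' @export
gidmr_scan <- function(methylome, samples, fdr_tiers = c(0.05, 0.10, 0.25)) {
  pd <- pair_differences(methylome, samples)
  D <- pd$diffs
  n <- nrow(D)
  mn <- colMeans(D)
  sds <- apply(D, 2, sd)
  testable <- is.finite(sds) & sds > 0
  tstat <- mn[testable] / (sds[testable] / sqrt(n))
  rec <- tibble(
    bin_id = pd$bins$bin_id[testable],
    chrom = pd$bins$chrom[testable],
    start = pd$bins$start[testable],
    end = pd$bins$end[testable],
    beta = mn[testable],
    se = sds[testable] / sqrt(n),
    statistic = tstat,
    p = 2 * pt(-abs(tstat), n - 1)
  )
  rec$q <- if (nrow(rec)) bh_fdr(rec$p) else numeric()
  rec$direction <- direction_label(rec$beta)
  class(rec) <- c("twindmr_scan", class(rec))
  attr(rec, "scan") <- "gidmr"
  attr(rec, "n_pairs") <- n
  attr(rec, "n_untestable") <- sum(!testable)
  attr(rec, "fdr_tiers") <- fdr_tiers
  if (any(!testable)) {
    inform(sprintf("gidmr_scan: %d bin(s) with zero difference variance excluded.",
                   sum(!testable)))
  }
  rec
}

#' Overlap between the giDMR and primary DMR scans
#'
#' @param gidmr_records Result of [gidmr_scan()].
#' @param dmr_records Result of [dmr_scan()].
#' @param q_threshold FDR tier defining each scan's discovery set.
#' @return A tibble with one row per bin discovered in either scan and an
#'   `in_both_scans` flag; the `summary` attribute counts shared bins.
#' @export
gidmr_overlap <- function(gidmr_records, dmr_records, q_threshold = 0.25) {
  g <- gidmr_records$bin_id[gidmr_records$q <= q_threshold]
  d <- dmr_records$bin_id[dmr_records$q <= q_threshold]
  all_bins <- union(g, d)
  out <- tibble(bin_id = all_bins,
                in_gidmr = all_bins %in% g,
                in_dmr = all_bins %in% d)
  out$in_both_scans <- out$in_gidmr & out$in_dmr
  attr(out, "summary") <- tibble(q_threshold = q_threshold,
                                 n_gidmr = length(g), n_dmr = length(d),
                                 n_shared = sum(out$in_both_scans))
  out
}
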