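#' Tile a genome into overlapping bins
#'
#' Tiles each chromosome with windows of `bin_size` bp advancing by `step`
#' bp, the binning scheme used throughout for MeDIP-seq quantification
#' (defaults: 500 bp windows sliding by 250 bp).  Coordinates are 0-based
#' and half-open.  The final window on a chromosome is truncated at the
#' chromosome end and dropped entirely when shorter than `step`, so no
#' unstable slivers enter the analysis.
#'
#' @param chrom_sizes Named numeric vector (chromosome -> length in bp) or a
#'   two-column data frame `(chrom, size)`.
#' @param bin_size Window width in bp.
#' @param step Slide in bp; must satisfy `0 < step <= bin_size`.
#'
#' @return A tibble of bins with columns `bin_id`, `chrom`, `start`, `end`,
#'   ordered by (chromosome, start).
#' @export
#' @examples
#' tile_genome(c(chrA = 1000), bin_size = 500, step = 250)
tile_genome <- function(chrom_sizes, bin_size = 500, step = 250) {
  chrom_sizes <- as_chrom_sizes(chrom_sizes)
  if (step <= 0 || bin_size < step) {
    config_error("need 0 < step <= bin_size.", field = "step")
  }
  if (any(chrom_sizes <= 0)) {
    config_error("all chromosome lengths must be positive.",
                 field = "chrom_sizes")
  }
  pieces <- lapply(names(chrom_sizes), function(chrom) {
    L <- chrom_sizes[[chrom]]
    starts <- seq(0, L - 1, by = step)
    ends <- pmin(starts + bin_size, L)
    keep <- (ends - starts) >= step
    tibble(chrom = chrom, start = starts[keep], end = ends[keep])
  })
  out <- bind_rows(pieces)
  out$bin_id <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  out[, c("bin_id", "chrom", "start", "end")]
}

as_chrom_sizes <- function(chrom_sizes) {
  if (is.data.frame(chrom_sizes)) {
    chrom_sizes <- setNames(as.numeric(chrom_sizes[[2]]),
                            as.character(chrom_sizes[[1]]))
  }
  if (is.null(names(chrom_sizes)) || any(names(chrom_sizes) == "")) {
    input_error("chromosome sizes must be named by chromosome.")
  }
  chrom_sizes
}

#' Per-bin RPM from fragment intervals
#'
#' Counts, for every sample, the fragments overlapping each bin by at least
#' 1 bp (a fragment spanning two bins counts once in each) and scales counts
#' to fragments per million mapped (the relative methylation score, RPM):
#' `RPM = count / (total / 1e6)`.
#'
#' @param fragments Data frame of fragment intervals with columns `chrom`,
#'   `start`, `end`, `sample_id` (0-based half-open, as in BED).
#' @param bins Bin tibble as produced by [tile_genome()].
#' @param totals Named numeric vector of total mapped fragments per sample;
#'   defaults to the per-sample fragment counts in `fragments`.
#' @param chrom_sizes Chromosome sizes used to validate fragment coordinates.
#'
#' @return A [binned_methylome()] with `signal_type = "RPM"`.
#' @export
compute_rpm <- function(fragments, bins, totals = NULL, chrom_sizes = NULL) {
  fragments <- as_tibble(fragments)
  needed <- c("chrom", "start", "end", "sample_id")
  if (!all(needed %in% names(fragments))) {
    input_error(sprintf("`fragments` must have columns %s.",
                        paste(needed, collapse = ", ")))
  }
  if (!is.null(chrom_sizes)) {
    chrom_sizes <- as_chrom_sizes(chrom_sizes)
    lim <- chrom_sizes[fragments$chrom]
    bad <- which(is.na(lim) | fragments$end > lim | fragments$start < 0)
    if (length(bad)) {
      b <- fragments[bad[1], ]
      input_error(sprintf(
        "fragment outside chromosome bounds: %s:%d-%d (sample %s; %d offending records).",
        b$chrom, b$start, b$end, b$sample_id, length(bad)))
    }
  }
  samples <- unique(fragments$sample_id)
  if (is.null(totals)) {
    totals <- table(factor(fragments$sample_id, levels = samples))
    totals <- setNames(as.numeric(totals), samples)
  }
  if (is.null(names(totals)) || !all(samples %in% names(totals))) {
    input_error("`totals` must be named and cover every sample present.")
  }
  if (any(totals[samples] <= 0)) {
    input_error("total mapped fragments must be positive for every sample.")
  }
  counts <- matrix(0, nrow = nrow(bins), ncol = length(samples),
                   dimnames = list(bins$bin_id, samples))
  for (chrom in unique(bins$chrom)) {
    bsel <- which(bins$chrom == chrom)
    fsel <- fragments[fragments$chrom == chrom, ]
    if (!nrow(fsel)) next
    # IRanges is 1-based closed; a 0-based half-open [s, e) maps to [s+1, e].
    bin_ir <- IRanges::IRanges(start = bins$start[bsel] + 1L,
                               end = bins$end[bsel])
    for (s in unique(fsel$sample_id)) {
      fs <- fsel[fsel$sample_id == s, ]
      frag_ir <- IRanges::IRanges(start = fs$start + 1L, end = fs$end)
      counts[bsel, s] <- counts[bsel, s] +
        IRanges::countOverlaps(bin_ir, frag_ir, minoverlap = 1L)
    }
  }
  rpm <- sweep(counts, 2, totals[samples] / 1e6, "/")
  binned_methylome(bins = bins, values = rpm, samples = samples,
                   signal_type = "RPM")
}

#' Normalize per-bin methylation values across samples
#'
#' Per-bin transformation to an approximately standard normal scale before
#' association testing.  `"zscore"` subtracts the per-bin mean and divides
#' by the per-bin sample standard deviation (denominator n - 1).
#' `"inverse_normal"` maps average ranks (ties averaged) through the
#' standard normal quantile function with the Blom offset,
#' `qnorm((r - 3/8) / (n + 1/4))`, which is invariant to any strictly
#' monotone transform of the raw values.  Bins with zero variance cannot be
#' standardized; they are removed and recorded in the `excluded_bins`
#' attribute so downstream scans never see them.
#'
#' @param methylome A [binned_methylome()].
#' @param method `"zscore"` (default) or `"inverse_normal"`.
#' @return A [binned_methylome()] with `signal_type = "normalized"`.
#' @export
normalize_bins <- function(methylome, method = c("zscore", "inverse_normal")) {
  method <- match.arg(method)
  stopifnot(inherits(methylome, "binned_methylome"))
  n <- length(methylome$samples)
  if (n < 3) input_error("normalization requires at least 3 samples.")
  v <- methylome$values
  sds <- apply(v, 1, sd)
  constant <- !is.finite(sds) | sds == 0
  v <- v[!constant, , drop = FALSE]
  if (method == "zscore") {
    mu <- rowMeans(v)
    out <- (v - mu) / sds[!constant]
  } else {
    out <- t(apply(v, 1, function(row) {
      r <- rank(row, ties.method = "average")
      qnorm((r - 0.375) / (length(row) + 0.25))
    }))
    colnames(out) <- colnames(v)
  }
  res <- binned_methylome(
    bins = methylome$bins[!constant, ],
    values = out,
    samples = methylome$samples,
    signal_type = "normalized"
  )
  attr(res, "excluded_bins") <- methylome$bins$bin_id[constant]
  if (any(constant)) {
    inform(sprintf("normalize_bins: excluded %d constant bin(s).",
                   sum(constant)))
  }
  res
}

#' Filter bins by coverage
#'
#' Retains bins whose fraction of samples with signal greater than zero is
#' at least `min_nonzero_fraction`.  The retained bin list defines the
#' coverage universe used by the enrichment module and is recorded in the
#' `coverage_universe` attribute.
#'
#' @param methylome A [binned_methylome()].
#' @param min_nonzero_fraction Threshold in `[0, 1]`.
#' @return A filtered [binned_methylome()].
#' @export
filter_bins <- function(methylome, min_nonzero_fraction = 0) {
  stopifnot(inherits(methylome, "binned_methylome"))
  check_number(min_nonzero_fraction, "min_nonzero_fraction", 0, 1)
  frac <- rowMeans(methylome$values > 0)
  keep <- frac >= min_nonzero_fraction
  res <- binned_methylome(
    bins = methylome$bins[keep, ],
    values = methylome$values[keep, , drop = FALSE],
    samples = methylome$samples,
    signal_type = methylome$signal_type
  )
  attr(res, "coverage_universe") <- methylome$bins$bin_id[keep]
  res
}
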