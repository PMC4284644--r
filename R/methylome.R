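#' Binned methylome container
#'
#' A light container for a bins-by-samples methylation matrix together with
#' the bin coordinates and a label for the signal type.  This is the unit of
#' data passed between the quantification, DMR-scan and downstream modules:
#' MeDIP-seq enrichment is summarised per genomic bin (by default 500 bp
#' windows sliding by 250 bp), and every sample contributes one column.
#'
#' @param bins A data frame with columns `bin_id`, `chrom`, `start`, `end`
#'   (0-based, half-open coordinates).
#' @param values Numeric matrix, one row per bin and one column per sample.
#' @param samples Character vector of sample identifiers (defaults to the
#'   column names of `values`).
#' @param signal_type One of `"RPM"` (relative methylation score, fragments
#'   per bin scaled to per-million mapped fragments), `"AMS"` (externally
#'   supplied absolute methylation signal) or `"normalized"` (per-bin
#'   mean 0 / variance 1 values ready for association testing).
#'
#' @return An object of class `binned_methylome`.
#' @export
binned_methylome <- function(bins, values, samples = colnames(values),
                             signal_type = c("RPM", "AMS", "normalized")) {
  signal_type <- match.arg(signal_type)
  bins <- as_tibble(bins)
  needed <- c("bin_id", "chrom", "start", "end")
  if (!all(needed %in% names(bins))) {
    input_error(sprintf("`bins` must have columns %s.",
                        paste(needed, collapse = ", ")))
  }
  values <- as.matrix(values)
  if (nrow(values) != nrow(bins)) {
    input_error("`values` must have one row per bin.")
  }
  if (is.null(samples)) {
    input_error("sample identifiers are required (set colnames on `values`).")
  }
  if (ncol(values) != length(samples)) {
    input_error("`values` must have one column per sample.")
  }
  if (anyDuplicated(samples)) input_error("duplicated sample identifiers.")
  if (anyDuplicated(bins$bin_id)) input_error("duplicated bin identifiers.")
  if (signal_type == "RPM" && any(values < 0, na.rm = TRUE)) {
    input_error("RPM values must be nonnegative.")
  }
  rownames(values) <- bins$bin_id
  colnames(values) <- samples
  structure(
    list(bins = bins, samples = as.character(samples), values = values,
         signal_type = signal_type),
    class = "binned_methylome"
  )
}

#' @export
print.binned_methylome <- function(x, ...) {
  cat(sprintf("<binned_methylome> %d bins x %d samples [%s]\n",
              nrow(x$bins), length(x$samples), x$signal_type))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$bins$chrom), collapse = ", ")))
  invisible(x)
}

#' @export
dim.binned_methylome <- function(x) dim(x$values)

#' Long-format view of a binned methylome
#'
#' @param x A [binned_methylome()].
#' @param ... Unused.
#' @return A tibble with one row per (bin, sample) pair.
#' @method as_tibble binned_methylome
#' @export
as_tibble.binned_methylome <- function(x, ...) {
  out <- as_tibble(x$bins)
  out <- tidyr::expand_grid(out, sample_id = x$samples)
  out$value <- as.vector(t(x$values))
  out$signal_type <- x$signal_type
  out
}

#' Subset a methylome to a set of samples and/or bins
#'
#' @param methylome A [binned_methylome()].
#' @param samples Character vector of sample IDs to keep (order preserved).
#' @param bins Character vector of bin IDs to keep.
#' @return A [binned_methylome()] restricted to the requested entries.
#' @export
subset_methylome <- function(methylome, samples = NULL, bins = NULL) {
  stopifnot(inherits(methylome, "binned_methylome"))
  keep_s <- methylome$samples
  if (!is.null(samples)) {
    missing <- setdiff(samples, methylome$samples)
    if (length(missing)) {
      input_error(sprintf("samples not in methylome: %s",
                          paste(head(missing, 5), collapse = ", ")))
    }
    keep_s <- samples
  }
  keep_b <- methylome$bins$bin_id
  if (!is.null(bins)) {
    missing <- setdiff(bins, keep_b)
    if (length(missing)) {
      input_error(sprintf("bins not in methylome: %s",
                          paste(head(missing, 5), collapse = ", ")))
    }
    keep_b <- bins
  }
  binned_methylome(
    bins = methylome$bins[match(keep_b, methylome$bins$bin_id), ],
    values = methylome$values[match(keep_b, methylome$bins$bin_id),
                              match(keep_s, methylome$samples), drop = FALSE],
    samples = keep_s,
    signal_type = methylome$signal_type
  )
}
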