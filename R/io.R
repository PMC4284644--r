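# Readers and writers for the plain-text interchange formats: methylation
# matrix TSV (rows "chrom:start-end"), sample table TSV, BED3 fragment
# files, chromosome-sizes TSV, dosage TSV, gene/locus tables and the
# planted-truth key-value file.  All genomic coordinates are 0-based
# half-open, matching BED natively.

parse_bin_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  bad <- vapply(m, length, integer(1)) != 4
  if (any(bad)) {
    input_error(sprintf("malformed bin ID(s): %s",
                        paste(head(ids[bad], 3), collapse = ", ")))
  }
  tibble(bin_id = ids,
         chrom = vapply(m, `[`, character(1), 2),
         start = as.numeric(vapply(m, `[`, character(1), 3)),
         end = as.numeric(vapply(m, `[`, character(1), 4)))
}

#' Write / read a binned methylome as TSV
#'
#' Rows are bins identified as `chrom:start-end`; columns are samples.
#'
#' @param methylome A [binned_methylome()].
#' @param path File path.
#' @param signal_type Signal label to attach on read.
#' @return `read_methylome_tsv()` returns a [binned_methylome()].
#' @export
write_methylome_tsv <- function(methylome, path) {
  df <- as.data.frame(methylome$values)
  df <- cbind(bin = methylome$bins$bin_id, df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_methylome_tsv
#' @export
read_methylome_tsv <- function(path, signal_type = "RPM") {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  bins <- parse_bin_ids(df$bin)
  values <- as.matrix(df[, -1])
  binned_methylome(bins, values, colnames(values), signal_type)
}

#' Write intervals as BED
#'
#' Writes `chrom`, `start`, `end` (and optionally `name`, `score`,
#' `strand`) columns, tab-separated without header, 0-based half-open.
#'
#' @param intervals Data frame with at least `chrom`, `start`, `end`.
#' @param path File path.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(intervals))
  df <- as.data.frame(intervals)[, cols, drop = FALSE]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read a BED3(+) file of fragment intervals
#'
#' @param path BED file path.
#' @param sample_id Sample label attached to every record.
#' @return A tibble `chrom`, `start`, `end`, `sample_id`.
#' @export
read_fragments_bed <- function(path, sample_id) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  tibble(chrom = as.character(df[[1]]), start = as.numeric(df[[2]]),
         end = as.numeric(df[[3]]), sample_id = sample_id)
}

#' Read a two-column chromosome-sizes file
#'
#' @param path TSV with columns chromosome, length.
#' @return Named numeric vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Write / read a genotype dosage matrix as TSV
#'
#' Rows are SNPs with `snp_id`, `chrom`, `pos`, `maf` columns followed by
#' one column per sample.
#'
#' @param genotypes A [genotype_matrix()].
#' @param path File path.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  df <- cbind(as.data.frame(genotypes$snps),
              as.data.frame(genotypes$dosage))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  meta <- c("snp_id", "chrom", "pos", "maf")
  genotype_matrix(df[, intersect(meta, names(df))],
                  as.matrix(df[, setdiff(names(df), meta)]))
}

#' Write the planted truth as a key-value text file
#'
#' @param truth A `planted_truth` object.
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  lines <- c(
    paste0("seed\t", truth$seed),
    paste0("scenario\t", truth$scenario),
    paste0("dmr_effect_raw\t", format(truth$dmr_effect_raw, digits = 15)),
    paste0("dmr_bin_ids\t", paste(truth$dmr_bin_ids, collapse = ",")),
    paste0("mqtl_assignments\t",
           paste(sprintf("%s:%s:%s", truth$mqtl_assignments$snp_id,
                         truth$mqtl_assignments$bin_id,
                         format(truth$mqtl_assignments$effect,
                                digits = 15)), collapse = ",")),
    paste0("mediation_scenario\t",
           truth$mediation$scenario %||% "none"),
    paste0("coupled_metabolites\t",
           paste(truth$coupled_metabolites, collapse = ","))
  )
  writeLines(lines, path)
  invisible(path)
}
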