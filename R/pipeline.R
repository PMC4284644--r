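#' Analysis configuration
#'
#' All tuning constants of the pipeline in one validated object, defaulting
#' to the analysis' canonical values: 500/250 bp binning, FDR tiers
#' 0.05/0.10/0.25 (0.25 defines the suggestive set), a 100 bp TSS window,
#' 20 kb extended promoters, 50 kb GWAS-locus flanks and cis windows, 20
#' TSS permutations (warned as low), 10,000 rank-resampling draws, 1,000
#' causal-inference permutations and a 0.05 replication alpha.
#'
#' @param bin_size,step Binning scheme in bp.
#' @param fdr_tiers Strictly increasing FDR thresholds in (0, 1).
#' @param tss_window_bp TSS proximity window.
#' @param promoter_bp Extended promoter upstream extent.
#' @param gwas_flank_bp GWAS locus window flank.
#' @param cis_window_bp Cis mQTL window.
#' @param n_perm TSS permutations.
#' @param n_draws Rank-resampling draws.
#' @param cit_B Causal-inference permutations.
#' @param replication_alpha Nominal replication threshold.
#' @param normalization `"zscore"` or `"inverse_normal"`.
#' @param min_nonzero_fraction Coverage filter threshold.
#' @param seed Root seed for all pipeline randomness.
#' @return A validated list of class `analysis_config`.
#' @export
analysis_config <- function(bin_size = 500, step = 250,
                            fdr_tiers = c(0.05, 0.10, 0.25),
                            tss_window_bp = 100, promoter_bp = 20000,
                            gwas_flank_bp = 50000, cis_window_bp = 50000,
                            n_perm = 20, n_draws = 10000, cit_B = 1000,
                            replication_alpha = 0.05,
                            normalization = c("zscore", "inverse_normal"),
                            min_nonzero_fraction = 0,
                            seed = 1) {
  normalization <- match.arg(normalization)
  for (f in c("bin_size", "step", "tss_window_bp", "promoter_bp",
              "gwas_flank_bp", "cis_window_bp", "n_perm", "n_draws",
              "cit_B")) {
    check_count(get(f), f, min = 1)
  }
  if (step > bin_size) config_error("need step <= bin_size.", field = "step")
  if (any(diff(fdr_tiers) <= 0) || any(fdr_tiers <= 0 | fdr_tiers >= 1)) {
    config_error("`fdr_tiers` must be strictly increasing in (0, 1).",
                 field = "fdr_tiers")
  }
  check_number(replication_alpha, "replication_alpha", 0, 1)
  check_number(min_nonzero_fraction, "min_nonzero_fraction", 0, 1)
  check_count(seed, "seed")
  structure(mget(names(formals())), class = "analysis_config")
}

#' Load an analysis configuration from a YAML file
#'
#' Unknown keys are rejected (naming the key), missing keys take their
#' defaults, and type mismatches raise an error naming the key.  An empty
#' file yields the full default configuration.
#'
#' @param path YAML file path.
#' @return An [analysis_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    config_error(sprintf("config file not found: %s", path))
  }
  vals <- yaml::yaml.load_file(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    config_error(sprintf("unknown config key(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  for (key in names(vals)) {
    if (!is.numeric(vals[[key]]) && !is.character(vals[[key]])) {
      config_error(sprintf("config key `%s` has unsupported type %s.",
                           key, class(vals[[key]])[1]), field = key)
    }
  }
  do.call(analysis_config, vals)
}

#' Export scan records as a BED file
#'
#' BED5 with name = bin ID, score = `min(1000, round(-10 * log10 p))` and
#' strand `"."`.
#'
#' @param records Scan records with `bin_id`, coordinates and `p`.
#' @param path Output path.
#' @param q_max Optional FDR tier filter applied before export.
#' @export
export_bed <- function(records, path, q_max = NULL) {
  if (!is.null(q_max)) records <- records[records$q <= q_max, ]
  out <- tibble(chrom = records$chrom, start = records$start,
                end = records$end, name = records$bin_id,
                score = pmin(1000, round(-10 * log10(records$p))),
                strand = ".")
  write_bed(out, path)
  invisible(path)
}

pipeline_log <- function(log_lines, msg) {
  c(log_lines, sprintf("[%s] %s", "twindmr", msg))
}

#' Run the full pipeline on simulated data
#'
#' Executes quantification, the mixed-model DMR scan, the within-pair
#' giDMR scan, replication, enrichment against genes / GWAS loci /
#' imprinted genes, the cis and trans mQTL scans with the causal inference
#' test, and the metabolite stage, on data produced by the synthetic
#' generator.  Writes per-stage TSV/BED outputs, a run log, the effective
#' configuration and a summary report into `outdir`.  With a fixed seed
#' the outputs are byte-identical across runs (the wall-clock timestamp
#' lives only in `run_log.txt`).
#'
#' @param config An [analysis_config()].
#' @param sim_cfg A [sim_config()]; its seed is overridden by
#'   `config$seed` so one seed controls the whole run.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config = analysis_config(),
                         sim_cfg = sim_config(), outdir) {
  stopifnot(inherits(config, "analysis_config"),
            inherits(sim_cfg, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  sim_cfg$seed <- config$seed
  log_lines <- pipeline_log(log_lines, sprintf("seed = %d", config$seed))

  # --- simulate -----------------------------------------------------------
  sim <- simulate_twin_methylome(sim_cfg)
  geno <- simulate_genotypes(sim_cfg, sim)
  sim[c("methylome", "samples", "truth")] <-
    geno[c("methylome", "samples", "truth")]
  sim$genotypes <- geno$genotypes
  ann <- simulate_annotations(sim_cfg, sim)
  met <- simulate_metabolites(sim_cfg, sim)
  truth <- met$truth
  log_lines <- pipeline_log(log_lines, sprintf(
    "simulated %d bins x %d samples; %d planted DMRs",
    nrow(sim$methylome$bins), length(sim$methylome$samples),
    length(truth$dmr_bin_indices)))
  write_methylome_tsv(sim$methylome, file.path(outdir, "methylome.tsv"))
  readr::write_tsv(sim$samples, file.path(outdir, "samples.tsv"))
  write_genotypes_tsv(sim$genotypes, file.path(outdir, "genotypes.tsv"))
  readr::write_tsv(ann$genes, file.path(outdir, "genes.tsv"))
  readr::write_tsv(ann$gwas_loci, file.path(outdir, "gwas_loci.tsv"))
  writeLines(ann$imprinted, file.path(outdir, "imprinted_genes.txt"))
  write_truth(truth, file.path(outdir, "truth.txt"))

  # --- quantify (RPM path exercised on the same bins) ---------------------
  frag <- simulate_fragments(sim$methylome$bins, rates = 20,
                             n_samples = 3, sim_cfg$toy_genome,
                             seed = child_seed(config$seed, "fragments"))
  write_bed(frag$fragments[, c("chrom", "start", "end")],
            file.path(outdir, "fragments_demo.bed"))
  rpm_demo <- compute_rpm(frag$fragments, sim$methylome$bins,
                          chrom_sizes = frag$chrom_sizes)
  log_lines <- pipeline_log(log_lines, sprintf(
    "RPM demo: %d fragments quantified over %d bins",
    nrow(frag$fragments), nrow(rpm_demo$bins)))

  # --- DMR scan (discovery twins) ----------------------------------------
  disc <- sim$samples[sim$samples$cohort == "discovery", ]
  rep_s <- sim$samples[sim$samples$cohort == "replication", ]
  m_disc <- normalize_bins(subset_methylome(sim$methylome,
                                            samples = disc$sample_id),
                           method = config$normalization)
  m_rep <- normalize_bins(subset_methylome(sim$methylome,
                                           samples = rep_s$sample_id),
                          method = config$normalization)
  dmr <- dmr_scan(m_disc, disc, fdr_tiers = config$fdr_tiers)
  tiers <- dmr_tiers(dmr)
  readr::write_tsv(dmr, file.path(outdir, "dmr_scan.tsv"))
  export_bed(dmr, file.path(outdir, "dmr_suggestive.bed"),
             q_max = max(config$fdr_tiers))
  log_lines <- pipeline_log(log_lines, sprintf(
    "dmr_scan: %s DMRs at tiers %s",
    paste(tiers$n_dmrs, collapse = "/"),
    paste(tiers$q_threshold, collapse = "/")))

  # --- giDMR scan ---------------------------------------------------------
  gidmr <- gidmr_scan(m_disc, disc, fdr_tiers = config$fdr_tiers)
  readr::write_tsv(gidmr, file.path(outdir, "gidmr_scan.tsv"))
  overlap <- gidmr_overlap(gidmr, dmr, q_threshold = max(config$fdr_tiers))
  readr::write_tsv(overlap, file.path(outdir, "gidmr_overlap.tsv"))

  # --- replication --------------------------------------------------------
  sugg <- dmr[dmr$q <= max(config$fdr_tiers), ]
  repl <- replicate_dmrs(sugg, m_rep, rep_s,
                         alpha = config$replication_alpha)
  readr::write_tsv(repl, file.path(outdir, "replication.tsv"))
  repl_sum <- attr(repl, "summary")
  log_lines <- pipeline_log(log_lines, sprintf(
    "replication: %.0f%% same direction, %.0f%% replicated",
    100 * (repl_sum$frac_same_direction %||% NA),
    100 * (repl_sum$frac_replicated %||% NA)))

  # --- confounder checks --------------------------------------------------
  conf <- purrr::map(c("medication", "monocytes"), function(cv) {
    confounder_check(sugg, m_disc, disc, cv)
  })
  readr::write_tsv(bind_rows(purrr::map(conf, attr, "summary")),
                   file.path(outdir, "confounder_summary.tsv"))

  # --- enrichment ---------------------------------------------------------
  genes <- gene_models(ann$genes, config$promoter_bp, sim_cfg$toy_genome)
  annot_all <- annotate_dmrs_to_genes(dmr, genes)
  annot_sugg <- annotate_dmrs_to_genes(sugg, genes)
  dmr_genes <- attr(annot_sugg, "gene_list")
  windows <- locus_windows(ann$gwas_loci, config$gwas_flank_bp,
                           sim_cfg$toy_genome)
  gene_p <- gene_level_p(annot_all, dmr)
  locus_ann <- annotate_dmrs_to_genes(
    tibble(bin_id = ann$gwas_loci$locus_id, chrom = ann$gwas_loci$chrom,
           start = ann$gwas_loci$pos, end = ann$gwas_loci$pos + 1), genes)
  locus_genes <- attr(locus_ann, "gene_list")
  enrich <- withCallingHandlers(
    bind_rows(
      tss_proximity_test(sugg, genes, sim_cfg$toy_genome,
                         config$tss_window_bp, config$n_perm,
                         seed = child_seed(config$seed, "tss")),
      region_overlap_fisher(sugg, windows, dmr),
      gene_set_fisher(dmr_genes, intersect(locus_genes, genes$gene_id),
                      genes$gene_id),
      gene_set_fisher(dmr_genes, ann$imprinted, genes$gene_id),
      rank_resampling_test(gene_p,
                           intersect(locus_genes, gene_p$gene_id),
                           config$n_draws,
                           seed = child_seed(config$seed, "rank"))
    ),
    warning = function(w) {
      log_lines <<- pipeline_log(log_lines, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  enrich$test <- c("tss_proximity", "gwas_region_overlap",
                   "gwas_gene_overlap", "imprinted_gene_overlap",
                   "gwas_rank_resampling")
  readr::write_tsv(enrich, file.path(outdir, "enrichment.tsv"))

  # --- mQTL + causal inference -------------------------------------------
  dmr_bins_m <- subset_methylome(m_rep, bins = intersect(
    sugg$bin_id, m_rep$bins$bin_id))
  cis <- cis_mqtl_scan(dmr_bins_m, sim$genotypes, rep_s,
                       window = config$cis_window_bp)
  readr::write_tsv(cis, file.path(outdir, "cis_mqtl.tsv"))
  trans <- trans_mqtl_scan(dmr_bins_m, sim$genotypes, rep_s,
                           cis_window = config$cis_window_bp)
  readr::write_tsv(trans, file.path(outdir, "trans_mqtl.tsv"))
  cit <- NULL
  med <- truth$mediation
  if (!is.null(med) && !is.na(med$snp_id) &&
      med$bin_id %in% m_rep$bins$bin_id) {
    L <- sim$genotypes$dosage[med$snp_id,
                              match(rep_s$sample_id,
                                    sim$genotypes$samples)]
    M <- m_rep$values[med$bin_id, rep_s$sample_id]
    cit <- causal_inference_test(L, M, rep_s$is_case,
                                 covariates = rep_s[, c("age", "sex")],
                                 B = config$cit_B,
                                 seed = child_seed(config$seed, "cit"))
    cit <- mutate(cit, snp_id = med$snp_id, bin_id = med$bin_id,
                  scenario_truth = med$scenario)
    readr::write_tsv(cit, file.path(outdir, "cit.tsv"))
  } else {
    log_lines <- pipeline_log(log_lines,
                              "cit: skipped (no mediation triple)")
  }

  # --- metabolites --------------------------------------------------------
  metab <- runday_median_normalize(met$metabolites)
  target_bin <- if (length(truth$dmr_bin_indices)) {
    truth$dmr_bin_ids[1]
  } else {
    sim$methylome$bins$bin_id[1]
  }
  disc_w <- pairwise_wilcoxon(
    subset_metabolites(metab, disc$sample_id), disc)
  meth_rep <- m_rep$values[target_bin, ]
  repl_m <- replication_regression(
    subset_metabolites(metab, rep_s$sample_id), meth_rep, rep_s,
    discovery = disc_w, alpha = config$replication_alpha)
  meta <- meta_analyze(disc_w[!disc_w$untestable, ], repl_m)
  readr::write_tsv(disc_w, file.path(outdir, "metabolite_discovery.tsv"))
  readr::write_tsv(repl_m, file.path(outdir, "metabolite_replication.tsv"))
  readr::write_tsv(meta, file.path(outdir, "metabolite_meta.tsv"))
  log_lines <- pipeline_log(log_lines, sprintf(
    "metabolites: %d carried forward, %d Bonferroni-significant in meta",
    nrow(repl_m), sum(meta$significant)))

  # --- summary ------------------------------------------------------------
  planted <- truth$dmr_bin_ids
  sugg_ids <- sugg$bin_id
  recovery <- tibble(
    n_planted = length(planted),
    n_suggestive = length(sugg_ids),
    n_recovered = length(intersect(planted, sugg_ids)),
    false_discovery_proportion =
      if (length(sugg_ids)) {
        length(setdiff(sugg_ids, planted)) / length(sugg_ids)
      } else {
        NA_real_
      },
    frac_hyper = mean(sugg$direction == "hyper")
  )
  readr::write_tsv(bind_rows(tiers), file.path(outdir, "summary_tiers.tsv"))
  readr::write_tsv(recovery, file.path(outdir, "summary_recovery.tsv"))
  cfg_out <- unclass(config)
  cfg_out$fdr_tiers <- paste(cfg_out$fdr_tiers, collapse = ",")
  yaml::write_yaml(cfg_out, file.path(outdir, "config_effective.yaml"))
  writeLines(c(log_lines, sprintf("[twindmr] finished at %s",
                                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"))),
             file.path(outdir, "run_log.txt"))
  invisible(list(sim = sim, truth = truth, dmr = dmr, gidmr = gidmr,
                 replication = repl, enrichment = enrich, cis = cis,
                 trans = trans, cit = cit, metabolites = meta,
                 tiers = tiers, recovery = recovery))
}

#' Subset a metabolite matrix to samples
#'
#' @param metabolites A [metabolite_matrix()].
#' @param samples Sample IDs to keep.
#' @return A [metabolite_matrix()].
#' @export
subset_metabolites <- function(metabolites, samples) {
  stopifnot(inherits(metabolites, "metabolite_matrix"))
  idx <- match(samples, metabolites$samples)
  if (anyNA(idx)) input_error("samples not present in metabolite matrix.")
  metabolite_matrix(metabolites$values[, idx, drop = FALSE],
                    metabolites$run_day[idx], metabolites$metabolites,
                    samples, normalized = metabolites$normalized)
}
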