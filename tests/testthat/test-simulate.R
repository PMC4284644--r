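small_cfg <- function(...) {
  defaults <- list(n_bins = 120, n_planted_dmrs = 10, n_mqtls = 4,
                   n_unrelated_cases = 12, n_unrelated_controls = 30,
                   n_snps = 30, n_metabolites = 12,
                   n_coupled_metabolites = 2, n_genes = 30,
                   n_gwas_loci = 10, n_imprinted = 5)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("configuration is validated field by field", {
  expect_error(sim_config(n_bins = -1), class = "twindmr_config_error")
  expect_error(sim_config(n_planted_dmrs = 50, n_bins = 10),
               regexp = "n_planted_dmrs")
  expect_error(sim_config(maf_range = c(0, 0.5)), regexp = "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), regexp = "maf_range")
  expect_error(sim_config(sigma_family_sq = -1),
               regexp = "sigma_family_sq")
  expect_error(sim_config(seed = 1.5), regexp = "seed")
})

test_that("identical seed and config give identical outputs", {
  cfg <- small_cfg(seed = 42)
  a <- simulate_twin_methylome(cfg)
  b <- simulate_twin_methylome(cfg)
  expect_identical(a$methylome$values, b$methylome$values)
  expect_identical(a$samples, b$samples)
  ga <- simulate_genotypes(cfg, a)
  gb <- simulate_genotypes(cfg, b)
  expect_identical(ga$genotypes$dosage, gb$genotypes$dosage)
  c2 <- simulate_twin_methylome(small_cfg(seed = 43))
  expect_false(identical(a$methylome$values, c2$methylome$values))
})

test_that("the generator realizes the assumed variance components", {
  cfg <- sim_config(n_bins = 600, scenario = "null", sigma_family_sq = 3,
                    sigma_resid_sq = 1, n_unrelated_cases = 0,
                    covariate_effects = c(age = 0, sex = 0, bmi = 0),
                    n_unrelated_controls = 0, n_planted_dmrs = 0,
                    n_mqtls = 0, seed = 6)
  sim <- simulate_twin_methylome(cfg)
  fam <- split(seq_len(nrow(sim$samples)), sim$samples$family_id)
  i1 <- vapply(fam, `[`, integer(1), 1)
  i2 <- vapply(fam, `[`, integer(1), 2)
  v <- sim$methylome$values
  icc <- mean(vapply(seq_len(nrow(v)),
                     function(b) cor(v[b, i1], v[b, i2]), numeric(1)))
  expect_lt(abs(icc - 0.75), 0.05)  # sigma_b^2 / (sigma_b^2 + sigma_e^2)
  # null scenario with sigma_b = 0: no within-pair correlation
  cfg0 <- sim_config(n_bins = 400, scenario = "null", sigma_family_sq = 0,
                     covariate_effects = c(age = 0, sex = 0, bmi = 0),
                     n_unrelated_cases = 0, n_unrelated_controls = 0,
                     n_mqtls = 0, seed = 7)
  sim0 <- simulate_twin_methylome(cfg0)
  v0 <- sim0$methylome$values
  icc0 <- mean(vapply(seq_len(nrow(v0)),
                      function(b) cor(v0[b, i1], v0[b, i2]), numeric(1)))
  expect_lt(abs(icc0), 0.05)
})

test_that("planted truth is complete and indexes valid entries", {
  cfg <- small_cfg(seed = 9)
  sim <- simulate_twin_methylome(cfg)
  g <- simulate_genotypes(cfg, sim)
  met <- simulate_metabolites(cfg, g)
  truth <- met$truth
  expect_length(truth$dmr_bin_indices, 10)
  expect_true(all(truth$dmr_bin_indices %in%
                    seq_len(nrow(sim$methylome$bins))))
  expect_equal(truth$dmr_bin_ids,
               sim$methylome$bins$bin_id[truth$dmr_bin_indices])
  expect_equal(nrow(truth$mqtl_assignments), 4)
  expect_true(all(truth$mqtl_assignments$snp_id %in%
                    g$genotypes$snps$snp_id))
  expect_true(all(truth$mqtl_assignments$bin_id %in% truth$dmr_bin_ids))
  expect_length(truth$coupled_metabolites, 2)
  # only planted bins differ in case-control mean structure
  null_cfg <- small_cfg(seed = 9, scenario = "null")
  expect_length(simulate_twin_methylome(null_cfg)$truth$dmr_bin_indices, 0)
})

test_that("monozygotic co-twins share dosages at every SNP", {
  cfg <- small_cfg(seed = 10)
  sim <- simulate_twin_methylome(cfg)
  g <- simulate_genotypes(cfg, sim)
  twins <- g$samples[g$samples$cohort == "discovery", ]
  for (fam in unique(twins$family_id)) {
    ids <- twins$sample_id[twins$family_id == fam]
    expect_identical(g$genotypes$dosage[, ids[1]],
                     g$genotypes$dosage[, ids[2]])
  }
  # cis effect shifts the assigned bin by effect-per-allele
  cfg2 <- small_cfg(seed = 10, cis_effect = 5)
  sim2 <- simulate_twin_methylome(cfg2)
  g2 <- simulate_genotypes(cfg2, sim2)
  asn <- g2$truth$mqtl_assignments[1, ]
  dos <- g2$genotypes$dosage[asn$snp_id, ]
  delta <- g2$methylome$values[asn$bin_id, ] -
    sim2$methylome$values[asn$bin_id, ]
  expect_equal(unname(delta), unname(5 * dos))
})

test_that("fragment simulation respects rates, bounds and empty input", {
  bins <- tile_genome(c(cX = 10000), 500, 500)
  empty <- simulate_fragments(bins, rates = 0, n_samples = 3,
                              chrom_sizes = c(cX = 10000), seed = 1)
  expect_equal(nrow(empty$fragments), 0)
  fr <- simulate_fragments(bins[1, ], rates = 100, n_samples = 10,
                           chrom_sizes = c(cX = 10000), seed = 2)
  per_sample <- table(fr$fragments$sample_id)
  expect_lt(abs(mean(per_sample) - 100), 3 * sqrt(100 / 10))
  expect_true(all(fr$fragments$end <= 10000))
  expect_true(all(fr$fragments$start >= 0))
  expect_error(simulate_fragments(bins, rates = -1, n_samples = 1,
                                  chrom_sizes = c(cX = 10000)),
               class = "twindmr_config_error")
})

test_that("annotation generator plants locus-DMR overlap as configured", {
  cfg <- small_cfg(seed = 12)
  sim <- simulate_twin_methylome(cfg)
  ann1 <- simulate_annotations(cfg, sim, enrichment_fraction = 1)
  windows <- locus_windows(ann1$gwas_loci, 50000)
  planted <- sim$methylome$bins[sim$truth$dmr_bin_indices, ]
  hits <- twindmr:::interval_overlaps(planted, windows)
  # every locus was centred on a planted bin
  expect_length(unique(hits$b), nrow(ann1$gwas_loci))
  ann0 <- simulate_annotations(cfg, sim, enrichment_fraction = 0)
  expect_equal(nrow(ann0$gwas_loci), 10)
  expect_length(ann0$imprinted, 5)
  # zero genes: annotation ops degrade gracefully
  cfg0 <- small_cfg(seed = 12, n_genes = 0, n_imprinted = 0)
  annz <- simulate_annotations(cfg0, sim)
  expect_equal(nrow(annz$genes), 0)
  out <- annotate_dmrs_to_genes(planted, annz$genes)
  expect_true(all(out$class == "intergenic"))
})

test_that("metabolite generator couples, labels days and validates", {
  cfg <- small_cfg(seed = 13, metabolite_coupling = 2)
  sim <- simulate_twin_methylome(cfg)
  met <- simulate_metabolites(cfg, sim)
  mm <- met$metabolites
  expect_equal(dim(mm$values), c(12, nrow(sim$samples)))
  expect_equal(length(unique(mm$run_day)), 8)
  norm <- runday_median_normalize(mm)
  target <- sim$methylome$values[sim$truth$dmr_bin_indices[1], ]
  cors <- apply(norm$values, 1, cor, y = target)
  expect_true(all(rank(-abs(cors))[1:2] <= 3))  # coupled metabolites lead
  cfg_bad <- small_cfg(scenario = "null", n_planted_dmrs = 0, n_mqtls = 0)
  sim_bad <- simulate_twin_methylome(cfg_bad)
  expect_error(simulate_metabolites(cfg_bad, sim_bad),
               class = "twindmr_config_error")
  cfg_none <- small_cfg(seed = 14, n_metabolites = 0,
                        n_coupled_metabolites = 0)
  sim_none <- simulate_twin_methylome(cfg_none)
  expect_equal(nrow(simulate_metabolites(cfg_none,
                                         sim_none)$metabolites$values), 0)
})

test_that("mediation wiring matches the declared architecture", {
  for (scen in c("causal", "independent", "null")) {
    cfg <- small_cfg(seed = 15, mediation_scenario = scen)
    sim <- simulate_twin_methylome(cfg)
    g <- simulate_genotypes(cfg, sim)
    expect_equal(g$truth$mediation$scenario, scen)
    unrel <- g$samples[g$samples$cohort == "replication", ]
    expect_equal(sum(unrel$is_case), 12)  # case count preserved
  }
  cfg <- small_cfg(seed = 16, mediation_scenario = "reactive")
  sim <- simulate_twin_methylome(cfg)
  g <- simulate_genotypes(cfg, sim)
  unrel <- g$samples[g$samples$cohort == "replication", ]
  m_id <- g$truth$mediation$bin_id
  diff <- g$methylome$values[m_id, unrel$sample_id] -
    sim$methylome$values[m_id, unrel$sample_id]
  # reactive: the trait feeds back on the mediator bin
  expect_gt(cor(diff, unrel$is_case), 0.5)
})
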