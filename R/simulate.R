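# Synthetic-data generator for the whole pipeline.  It emulates the
# statistical structure of a twin-design MeDIP-seq methylation study:
# monozygotic pairs sharing a family random intercept (and genotype),
# case-control mean shifts at planted DMR bins, covariate effects, additive
# cis-SNP effects on methylation, three mediation architectures, and
# metabolite-methylation coupling -- with a machine-readable record of the
# planted truth so every downstream stage is testable without external
# data.

#' Simulation configuration
#'
#' Defaults follow the design of the motivating twin study: 17
#' disease-discordant, 3 concordant-case and 7 concordant-control
#' monozygotic pairs (54 twins), with 42 unrelated cases and 221 matched
#' controls for replication; a MAF > 5% common-variant filter; 503
#' metabolites.  Desk-scale choices (toy genome of 2 chromosomes of 10 Mb,
#' 2,000 bins, 5% of bins planted as DMRs) keep every stage testable in
#' seconds while preserving the interval and variance-component structure
#' the analysis assumes.
#'
#' @param n_discordant_pairs,n_concordant_case_pairs,n_concordant_control_pairs
#'   Twin-pair counts for the discovery cohort.
#' @param n_unrelated_cases,n_unrelated_controls Unrelated replication
#'   cohort sizes.
#' @param n_bins Number of (non-overlapping, evenly spaced, 500 bp) bins
#'   the generator places on the toy genome.
#' @param toy_genome Named vector of chromosome lengths in bp.
#' @param n_planted_dmrs Number of bins given a case-control shift.
#' @param dmr_effect Standardized case-minus-control mean shift at planted
#'   bins, in units of the total per-bin standard deviation
#'   `sqrt(sigma_family_sq + sigma_resid_sq)`.
#' @param sigma_family_sq Family random-intercept variance.
#' @param sigma_resid_sq Residual variance.
#' @param covariate_effects Named coefficients (age, sex, bmi) on the raw
#'   methylation scale.
#' @param shared_env_effect Standardized pair-shared environmental shift
#'   applied to BOTH co-twins in proportion to the pair's mean case
#'   status, at the planted bins, when `scenario = "shared_env"`.  Such a
#'   shift is visible to the between-family contrast of the mixed-model
#'   scan but cancels exactly in the within-pair giDMR test.
#' @param scenario `"planted"` (default), `"null"` (no effects) or
#'   `"shared_env"` (pair-shared shift instead of an individual one).
#' @param n_snps,maf_range,cis_effect,n_mqtls Genotype block: SNP count,
#'   minor-allele-frequency bounds (within (0, 0.5]), per-allele
#'   methylation shift at mQTL bins, and number of planted cis mQTLs.
#' @param mediation_scenario One of `"causal"`, `"reactive"`,
#'   `"independent"`, `"null"`: the architecture wiring the first planted
#'   (SNP, bin) pair to the trait in the unrelated cohort.
#' @param n_metabolites,n_coupled_metabolites,metabolite_coupling,n_run_days
#'   Metabolite block: matrix size, number of metabolites coupled to the
#'   first planted DMR, coupling coefficient (on the standardized
#'   methylation scale), and number of mass-spec run days.
#' @param n_genes,n_gwas_loci,n_imprinted,enrichment_fraction Annotation
#'   block: gene / GWAS locus / imprinted-list sizes and the fraction of
#'   GWAS loci (and imprinted genes) placed to overlap planted DMRs.
#' @param seed Root seed; every stage derives its own child seed from it,
#'   so identical (seed, config) gives bit-identical outputs.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_discordant_pairs = 17,
                       n_concordant_case_pairs = 3,
                       n_concordant_control_pairs = 7,
                       n_unrelated_cases = 42,
                       n_unrelated_controls = 221,
                       n_bins = 2000,
                       toy_genome = c(chr1 = 1e7, chr2 = 1e7),
                       n_planted_dmrs = 100,
                       dmr_effect = 0.8,
                       sigma_family_sq = 1,
                       sigma_resid_sq = 1,
                       covariate_effects = c(age = 0.02, sex = 0.5,
                                             bmi = 0.05),
                       shared_env_effect = 2.5,
                       scenario = c("planted", "null", "shared_env"),
                       n_snps = 200,
                       maf_range = c(0.05, 0.5),
                       cis_effect = 0.5,
                       n_mqtls = 20,
                       mediation_scenario = c("causal", "reactive",
                                              "independent", "null"),
                       n_metabolites = 503,
                       n_coupled_metabolites = 7,
                       metabolite_coupling = 1,
                       n_run_days = 8,
                       n_genes = 200,
                       n_gwas_loci = 65,
                       n_imprinted = 30,
                       enrichment_fraction = 0.5,
                       seed = 1) {
  scenario <- match.arg(scenario)
  mediation_scenario <- match.arg(mediation_scenario)
  for (f in c("n_discordant_pairs", "n_concordant_case_pairs",
              "n_concordant_control_pairs", "n_unrelated_cases",
              "n_unrelated_controls", "n_bins", "n_planted_dmrs",
              "n_snps", "n_mqtls", "n_metabolites",
              "n_coupled_metabolites", "n_run_days", "n_genes",
              "n_gwas_loci", "n_imprinted")) {
    check_count(get(f), f)
  }
  check_number(dmr_effect, "dmr_effect")
  check_number(sigma_family_sq, "sigma_family_sq", min = 0)
  check_number(sigma_resid_sq, "sigma_resid_sq", min = 0)
  check_number(cis_effect, "cis_effect")
  check_number(metabolite_coupling, "metabolite_coupling")
  check_number(enrichment_fraction, "enrichment_fraction", 0, 1)
  check_count(seed, "seed")
  if (n_planted_dmrs > n_bins) {
    config_error("`n_planted_dmrs` cannot exceed `n_bins`.",
                 field = "n_planted_dmrs")
  }
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    config_error("`maf_range` bounds must lie within (0, 0.5].",
                 field = "maf_range")
  }
  if (n_mqtls > n_planted_dmrs) {
    config_error("`n_mqtls` cannot exceed `n_planted_dmrs`.",
                 field = "n_mqtls")
  }
  toy_genome <- as_chrom_sizes(toy_genome)
  if (any(toy_genome <= 0)) {
    config_error("toy genome chromosome lengths must be positive.",
                 field = "toy_genome")
  }
  structure(mget(names(formals())), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  utils::str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

# Evenly spaced non-overlapping 500 bp bins across the toy genome,
# allocated to chromosomes proportionally to length.
place_sim_bins <- function(toy_genome, n_bins, width = 500) {
  total <- sum(toy_genome)
  alloc <- floor(n_bins * toy_genome / total)
  rem <- n_bins - sum(alloc)
  if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1
  pieces <- lapply(names(toy_genome), function(chrom) {
    k <- alloc[[chrom]]
    if (!k) return(NULL)
    L <- toy_genome[[chrom]]
    starts <- unique(floor(seq(0, L - width, length.out = k)))
    tibble(chrom = chrom, start = starts, end = starts + width)
  })
  out <- bind_rows(pieces)
  out$bin_id <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  out[, c("bin_id", "chrom", "start", "end")]
}

# Sample table for the full design (twins + unrelated replication cohort).
build_sample_table <- function(config) {
  nd <- config$n_discordant_pairs
  ncc <- config$n_concordant_case_pairs
  nco <- config$n_concordant_control_pairs
  n_pairs <- nd + ncc + nco
  pair_type <- rep(c("discordant", "concordant_case", "concordant_control"),
                   c(nd, ncc, nco))
  fam <- sprintf("F%03d", seq_len(n_pairs))
  pt2 <- rep(pair_type, each = 2)
  twin <- tibble(
    sample_id = paste0(rep(fam, each = 2), c("_a", "_b")),
    family_id = rep(fam, each = 2),
    pair_type = pt2,
    cohort = "discovery",
    is_case = as.integer(pt2 == "concordant_case" |
                           (pt2 == "discordant" &
                              rep(c(TRUE, FALSE), n_pairs)))
  )
  nuc <- config$n_unrelated_cases
  nuo <- config$n_unrelated_controls
  unrel <- tibble(
    sample_id = sprintf("U%03d", seq_len(nuc + nuo)),
    family_id = sprintf("UF%03d", seq_len(nuc + nuo)),
    pair_type = "unrelated",
    cohort = "replication",
    is_case = rep(c(1L, 0L), c(nuc, nuo))
  )
  samples <- bind_rows(twin, unrel)
  n_fam <- length(unique(samples$family_id))
  fam_idx <- match(samples$family_id, unique(samples$family_id))
  # Age and sex are shared within a pair; BMI is correlated 0.5 between
  # co-twins via a shared component.
  age_f <- runif(n_fam, 40, 80)
  sex_f <- rbinom(n_fam, 1, 0.5)
  bmi_shared <- rnorm(n_fam, 0, 4 * sqrt(0.5))
  samples$age <- age_f[fam_idx]
  samples$sex <- sex_f[fam_idx]
  samples$bmi <- 27 + bmi_shared[fam_idx] +
    rnorm(nrow(samples), 0, 4 * sqrt(0.5))
  samples$smoking <- rbinom(nrow(samples), 1, 0.2)
  samples$medication <- ifelse(samples$is_case == 1,
                               rbinom(nrow(samples), 1, 0.5), 0L)
  # White-blood-cell subtype counts (10^3 cells/ul scale), independent of
  # methylation by construction so confounder checks are null-calibrated.
  samples$neutrophils <- exp(rnorm(nrow(samples), log(4), 0.25))
  samples$eosinophils <- exp(rnorm(nrow(samples), log(0.2), 0.4))
  samples$monocytes <- exp(rnorm(nrow(samples), log(0.5), 0.3))
  samples$lymphocytes <- exp(rnorm(nrow(samples), log(2), 0.25))
  samples$total_wbc <- samples$neutrophils + samples$eosinophils +
    samples$monocytes + samples$lymphocytes
  samples
}

#' Simulate a twin-design binned methylome
#'
#' Generates per-bin methylation values under the model the analysis
#' assumes: for bin `b`, sample `j` in family `i`,
#' `y = mu_b + beta_b * case_j + sum_c gamma_c * covariate_cj + u_i + e_ij`
#' with `u_i ~ N(0, sigma_family_sq)` shared by co-twins and
#' `e ~ N(0, sigma_resid_sq)`.  `beta_b` equals
#' `dmr_effect * sqrt(sigma_family_sq + sigma_resid_sq)` at planted bins
#' and zero elsewhere; under `scenario = "shared_env"` the planted shift is
#' instead `shared_env_effect * (pair mean case status)` applied to both
#' co-twins, and under `"null"` nothing is planted.  Monozygotic co-twins
#' share the family intercept, age, sex and family ID.  Discordance is
#' assigned by design, not emergent.
#'
#' @param config A [sim_config()].
#' @return A list with `methylome` (a [binned_methylome()], signal type
#'   AMS covering twins and the unrelated cohort), `samples` (tibble) and
#'   `truth` (class `planted_truth`, recording every planted effect).
#' @export
simulate_twin_methylome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, "methylome"), {
    samples <- build_sample_table(config)
    bins <- place_sim_bins(config$toy_genome, config$n_bins)
    nb <- nrow(bins)
    ns <- nrow(samples)
    fam_idx <- match(samples$family_id, unique(samples$family_id))
    n_fam <- max(fam_idx)
    planted <- if (config$scenario == "null" ||
                   config$n_planted_dmrs == 0) {
      integer()
    } else {
      sort(sample.int(nb, config$n_planted_dmrs))
    }
    sd_tot <- sqrt(config$sigma_family_sq + config$sigma_resid_sq)
    beta <- numeric(nb)
    mu_b <- rnorm(nb, 8, 1)
    g <- config$covariate_effects
    cov_shift <- g[["age"]] * (samples$age - 60) +
      g[["sex"]] * samples$sex + g[["bmi"]] * (samples$bmi - 27)
    u <- matrix(rnorm(nb * n_fam, 0, sqrt(config$sigma_family_sq)),
                nb, n_fam)
    e <- matrix(rnorm(nb * ns, 0, sqrt(config$sigma_resid_sq)), nb, ns)
    y <- mu_b + u[, fam_idx] + e
    y <- sweep(y, 2, cov_shift, "+")
    if (config$scenario == "planted" && length(planted)) {
      beta[planted] <- config$dmr_effect * sd_tot
      y[planted, ] <- y[planted, ] +
        outer(beta[planted], as.numeric(samples$is_case))
    }
    if (config$scenario == "shared_env" && length(planted)) {
      pair_mean <- stats::ave(samples$is_case, samples$family_id)
      shift <- config$shared_env_effect * sd_tot
      y[planted, ] <- y[planted, ] + outer(rep(shift, length(planted)),
                                           pair_mean)
    }
    methylome <- binned_methylome(bins, y, samples$sample_id,
                                  signal_type = "AMS")
    truth <- structure(
      list(dmr_bin_indices = planted,
           dmr_bin_ids = bins$bin_id[planted],
           dmr_effect_raw = if (config$scenario == "planted")
             config$dmr_effect * sd_tot else 0,
           scenario = config$scenario,
           mqtl_assignments = tibble(snp_id = character(),
                                     bin_id = character(),
                                     effect = numeric()),
           mediation = NULL,
           coupled_metabolites = character(),
           seed = config$seed),
      class = "planted_truth"
    )
    list(methylome = methylome, samples = samples, truth = truth)
  })
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf("<planted_truth> %d planted DMR bins; %d mQTLs; mediation: %s; %d coupled metabolites\n",
              length(x$dmr_bin_indices), nrow(x$mqtl_assignments),
              if (is.null(x$mediation)) "none" else x$mediation$scenario,
              length(x$coupled_metabolites)))
  invisible(x)
}

#' Simulate genotypes with planted cis mQTLs and a mediation architecture
#'
#' Draws SNP dosages `Binomial(2, MAF)` independently per family -- with
#' monozygotic co-twins sharing dosages, since MZ twins are genetically
#' identical -- places `n_mqtls` SNPs in cis (within 50 kb) of distinct
#' planted DMR bins and adds `cis_effect` per alternate allele to those
#' bins' methylation values.  The configured mediation scenario then wires
#' the first planted (SNP, bin) pair to the trait in the UNRELATED cohort
#' (twin statuses are fixed by design): `causal` makes the trait depend on
#' the methylation bin (so L -> M -> T), `reactive` makes the trait depend
#' on the locus and the bin depend on the trait (L -> T -> M),
#' `independent` gives the locus separate paths to both (L -> M, L -> T),
#' and `null` leaves the locus disconnected from the trait.  Case labels
#' in the unrelated cohort are reassigned by thresholding the simulated
#' liability so cohort case counts are preserved.
#'
#' @param config A [sim_config()].
#' @param sim Result of [simulate_twin_methylome()].
#' @return A list with `genotypes` (a [genotype_matrix()]), updated
#'   `methylome`, `samples` and `truth`.
#' @export
simulate_genotypes <- function(config, sim) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, "genotypes"), {
    methylome <- sim$methylome
    samples <- sim$samples
    truth <- sim$truth
    bins <- methylome$bins
    toy <- config$toy_genome
    ns <- nrow(samples)
    n_snps <- config$n_snps
    n_mqtl <- min(config$n_mqtls, length(truth$dmr_bin_indices), n_snps)
    mqtl_bins <- if (n_mqtl) {
      sample(truth$dmr_bin_indices, n_mqtl)
    } else {
      integer()
    }
    chrom <- character(n_snps)
    pos <- numeric(n_snps)
    if (n_mqtl) {
      chrom[seq_len(n_mqtl)] <- bins$chrom[mqtl_bins]
      offset <- floor(runif(n_mqtl, -30000, 30000))
      pos[seq_len(n_mqtl)] <- pmax(bins$start[mqtl_bins] + offset, 0)
    }
    if (n_snps > n_mqtl) {
      idx <- (n_mqtl + 1):n_snps
      chrom[idx] <- sample(names(toy), length(idx), replace = TRUE,
                           prob = toy / sum(toy))
      pos[idx] <- floor(runif(length(idx), 0, toy[chrom[idx]]))
    }
    maf <- runif(n_snps, config$maf_range[1], config$maf_range[2])
    fam_ids <- unique(samples$family_id)
    fam_idx <- match(samples$family_id, fam_ids)
    G_fam <- matrix(rbinom(n_snps * length(fam_ids), 2, rep(maf,
                    times = length(fam_ids))), nrow = n_snps)
    G <- G_fam[, fam_idx, drop = FALSE]
    snps <- tibble(snp_id = sprintf("rs%05d", seq_len(n_snps)),
                   chrom = chrom, pos = pos)
    # Additive cis effects on the assigned bins.
    if (n_mqtl && config$cis_effect != 0) {
      methylome$values[mqtl_bins, ] <- methylome$values[mqtl_bins, ] +
        config$cis_effect * G[seq_len(n_mqtl), , drop = FALSE]
    }
    truth$mqtl_assignments <- tibble(
      snp_id = snps$snp_id[seq_len(n_mqtl)],
      bin_id = bins$bin_id[mqtl_bins],
      effect = rep(config$cis_effect, n_mqtl)
    )
    # Mediation wiring in the unrelated cohort.
    scen <- config$mediation_scenario
    if (scen != "null" && n_mqtl >= 1) {
      unrel <- which(samples$cohort == "replication")
      n_cases <- sum(samples$is_case[unrel])
      L <- G[1, unrel]
      b <- 1  # liability coefficient on the standardized mediator / locus
      # The assigned case status enters the liability too, so the planted
      # DMR-disease associations survive the relabelling and the mediation
      # edge is added on top (it confounds M and T but leaves the
      # conditional-independence structure of each scenario intact).
      base_liab <- 1.2 * samples$is_case[unrel]
      m_idx <- mqtl_bins[1]
      if (scen == "causal") {
        Mv <- methylome$values[m_idx, unrel]
        liab <- base_liab + b * (Mv - mean(Mv)) / sd(Mv) +
          rnorm(length(unrel))
      } else if (scen == "independent") {
        liab <- base_liab + 0.5 * L + rnorm(length(unrel))
      } else { # reactive: trait from locus, then methylation from trait
        liab <- base_liab + 0.5 * L + rnorm(length(unrel))
      }
      thr <- sort(liab, decreasing = TRUE)[n_cases]
      new_case <- as.integer(liab >= thr)
      samples$is_case[unrel] <- new_case
      if (scen == "reactive") {
        methylome$values[m_idx, unrel] <-
          methylome$values[m_idx, unrel] + b * new_case
      }
      truth$mediation <- list(scenario = scen,
                              snp_id = snps$snp_id[1],
                              bin_id = bins$bin_id[m_idx])
    } else {
      truth$mediation <- list(scenario = "null",
                              snp_id = NA_character_,
                              bin_id = NA_character_)
    }
    genotypes <- genotype_matrix(snps, G, samples$sample_id)
    list(genotypes = genotypes, methylome = methylome,
         samples = samples, truth = truth)
  })
}

#' Simulate gene, GWAS-locus and imprinted-gene annotations
#'
#' Places genes (random strand, lengths 5-50 kb) on the toy genome and
#' constructs a GWAS locus table and an imprinted-gene list.  A fraction
#' `enrichment_fraction` of GWAS loci are centred on planted DMR bins (so
#' their 50 kb windows overlap them -- planting enrichment) and the rest
#' placed uniformly; the imprinted list draws the same fraction from genes
#' overlapping planted DMRs.
#'
#' @param config A [sim_config()].
#' @param sim Result of [simulate_twin_methylome()] (for bin coordinates
#'   and truth).
#' @param enrichment_fraction Overrides the configured fraction.
#' @return A list with `genes`, `gwas_loci` and `imprinted`.
#' @export
simulate_annotations <- function(config, sim,
                                 enrichment_fraction =
                                   config$enrichment_fraction) {
  stopifnot(inherits(config, "sim_config"))
  check_number(enrichment_fraction, "enrichment_fraction", 0, 1)
  with_seed(child_seed(config$seed, "annotations"), {
    toy <- config$toy_genome
    bins <- sim$methylome$bins
    truth <- sim$truth
    ng <- config$n_genes
    if (ng == 0) {
      genes <- tibble(gene_id = character(), chrom = character(),
                      strand = character(), start = numeric(),
                      end = numeric())
    } else {
      chrom <- sample(names(toy), ng, replace = TRUE,
                      prob = toy / sum(toy))
      len <- floor(runif(ng, 5000, 50000))
      start <- floor(runif(ng, 0, toy[chrom] - len))
      if (any(start + len > toy[chrom])) {
        abort("generated gene exceeds chromosome bounds.",
              class = "twindmr_generation_error")
      }
      genes <- tibble(gene_id = sprintf("G%04d", seq_len(ng)),
                      chrom = chrom, strand = sample(c("+", "-"), ng,
                                                     replace = TRUE),
                      start = start, end = start + len)
    }
    nl <- config$n_gwas_loci
    planted_bins <- bins[truth$dmr_bin_indices, , drop = FALSE]
    n_enriched <- if (nrow(planted_bins)) {
      round(enrichment_fraction * nl)
    } else {
      0
    }
    pos <- numeric(nl)
    chrom_l <- character(nl)
    if (n_enriched > 0) {
      pick <- sample.int(nrow(planted_bins), n_enriched,
                         replace = n_enriched > nrow(planted_bins))
      chrom_l[seq_len(n_enriched)] <- planted_bins$chrom[pick]
      pos[seq_len(n_enriched)] <- floor((planted_bins$start[pick] +
                                           planted_bins$end[pick]) / 2)
    }
    if (nl > n_enriched) {
      idx <- (n_enriched + 1):nl
      chrom_l[idx] <- sample(names(toy), length(idx), replace = TRUE,
                             prob = toy / sum(toy))
      pos[idx] <- floor(runif(length(idx), 0, toy[chrom_l[idx]]))
    }
    gwas_loci <- if (nl) {
      tibble(locus_id = sprintf("L%03d", seq_len(nl)),
             chrom = chrom_l, pos = pos)
    } else {
      tibble(locus_id = character(), chrom = character(), pos = numeric())
    }
    imprinted <- character()
    if (config$n_imprinted > 0 && nrow(genes)) {
      overlapping <- unique(genes$gene_id[
        interval_overlaps(genes, planted_bins)$a])
      n_from_planted <- min(round(enrichment_fraction *
                                    config$n_imprinted),
                            length(overlapping))
      imprinted <- sample(overlapping, n_from_planted)
      rest <- setdiff(genes$gene_id, imprinted)
      extra <- min(config$n_imprinted - n_from_planted, length(rest))
      imprinted <- sort(c(imprinted, sample(rest, extra)))
    }
    list(genes = genes, gwas_loci = gwas_loci, imprinted = imprinted)
  })
}

#' Simulate MeDIP fragment intervals
#'
#' Draws, per sample and bin, a Poisson number of fragments with the given
#' expected count and places each fragment uniformly within the bin
#' (clipped at the chromosome end), emulating the post-alignment fragment
#' files from which per-bin RPM is quantified.
#'
#' @param bins Bin tibble (`bin_id`, `chrom`, `start`, `end`).
#' @param rates Expected fragment count per bin (recycled to `nrow(bins)`).
#' @param n_samples Number of samples to simulate.
#' @param chrom_sizes Chromosome sizes for clipping.
#' @param fragment_length Fragment length in bp.
#' @param seed Seed.
#' @return A list with `fragments` (tibble `chrom`, `start`, `end`,
#'   `sample_id`) and `chrom_sizes`.
#' @export
simulate_fragments <- function(bins, rates, n_samples,
                               chrom_sizes, fragment_length = 200,
                               seed = 1) {
  if (any(rates < 0)) {
    config_error("fragment rates must be nonnegative.", field = "rates")
  }
  chrom_sizes <- as_chrom_sizes(chrom_sizes)
  rates <- rep_len(rates, nrow(bins))
  with_seed(seed, {
    pieces <- lapply(seq_len(n_samples), function(s) {
      counts <- rpois(nrow(bins), rates)
      tot <- sum(counts)
      if (!tot) return(NULL)
      idx <- rep.int(seq_len(nrow(bins)), counts)
      start <- floor(runif(tot, bins$start[idx], bins$end[idx]))
      end <- pmin(start + fragment_length, chrom_sizes[bins$chrom[idx]])
      tibble(chrom = bins$chrom[idx], start = start, end = unname(end),
             sample_id = sprintf("S%03d", s))
    })
    frags <- bind_rows(pieces)
    if (!nrow(frags)) {
      frags <- tibble(chrom = character(), start = numeric(),
                      end = numeric(), sample_id = character())
    }
    list(fragments = frags, chrom_sizes = chrom_sizes)
  })
}

#' Simulate metabolite profiles coupled to methylation
#'
#' Generates a metabolites-by-samples matrix in which
#' `n_coupled_metabolites` metabolites equal
#' `metabolite_coupling * (standardized methylation at the first planted
#' DMR bin) + noise` and the rest are pure noise; run-day labels are
#' assigned round-robin and a multiplicative per-day scale is applied so
#' that run-day median normalization is exercised.
#'
#' @param config A [sim_config()].
#' @param sim Result of [simulate_twin_methylome()] (possibly updated by
#'   [simulate_genotypes()]).
#' @return A list with `metabolites` (raw [metabolite_matrix()]) and
#'   updated `truth`.
#' @export
simulate_metabolites <- function(config, sim) {
  stopifnot(inherits(config, "sim_config"))
  truth <- sim$truth
  n_met <- config$n_metabolites
  n_cpl <- min(config$n_coupled_metabolites, n_met)
  if (n_cpl > 0 && config$metabolite_coupling != 0 &&
      !length(truth$dmr_bin_indices)) {
    config_error("metabolite coupling requested but no DMRs are planted.",
                 field = "n_coupled_metabolites")
  }
  with_seed(child_seed(config$seed, "metabolites"), {
    samples <- sim$samples$sample_id
    ns <- length(samples)
    ids <- sprintf("M%04d", seq_len(n_met))
    values <- matrix(rnorm(n_met * ns), n_met, ns,
                     dimnames = list(ids, samples))
    coupled <- character()
    if (n_cpl > 0 && length(truth$dmr_bin_indices)) {
      mv <- sim$methylome$values[truth$dmr_bin_indices[1], ]
      mv <- (mv - mean(mv)) / sd(mv)
      values[seq_len(n_cpl), ] <- config$metabolite_coupling *
        matrix(mv, n_cpl, ns, byrow = TRUE) +
        matrix(rnorm(n_cpl * ns), n_cpl, ns)
      coupled <- ids[seq_len(n_cpl)]
    }
    run_day <- sprintf("day%02d",
                       rep_len(seq_len(max(config$n_run_days, 1)), ns))
    day_scale <- exp(rnorm(max(config$n_run_days, 1), 0, 0.4))
    raw <- (values + 10) * day_scale[match(run_day,
                                           sprintf("day%02d",
                                                   seq_len(max(config$n_run_days, 1))))][col(values)]
    truth$coupled_metabolites <- coupled
    list(metabolites = metabolite_matrix(raw, run_day, ids, samples,
                                         normalized = FALSE),
         truth = truth)
  })
}

#' Simulate one mediation triple
#'
#' A small stand-alone generator for (locus, mediator, trait) triples in
#' unrelated samples under the four architectures of the causal inference
#' test, used for calibration and power studies of
#' [causal_inference_test()].
#'
#' @param n Number of unrelated samples.
#' @param scenario `"causal"` (L -> M -> T), `"reactive"` (L -> T -> M),
#'   `"independent"` (L -> M and L -> T via separate paths) or `"null"`.
#' @param maf Minor-allele frequency of the locus.
#' @param a Effect of the locus on its direct target(s).
#' @param b Effect along the second edge (M -> T or T -> M).
#' @param seed Seed.
#' @return A list with numeric vectors `L`, `M`, `trait` (binary).
#' @export
simulate_mediation_triple <- function(n = 200,
                                      scenario = c("causal", "reactive",
                                                   "independent", "null"),
                                      maf = 0.3, a = 0.8, b = 1.5,
                                      seed = 1) {
  scenario <- match.arg(scenario)
  with_seed(seed, {
    L <- rbinom(n, 2, maf)
    if (scenario == "causal") {
      M <- a * L + rnorm(n)
      liab <- b * M + rnorm(n)
      trait <- as.integer(liab > quantile(liab, 0.6))
    } else if (scenario == "reactive") {
      liab <- a * L + rnorm(n)
      trait <- as.integer(liab > quantile(liab, 0.6))
      M <- b * trait + rnorm(n)
    } else if (scenario == "independent") {
      M <- a * L + rnorm(n)
      liab <- a * L + rnorm(n)
      trait <- as.integer(liab > quantile(liab, 0.6))
    } else {
      M <- rnorm(n)
      trait <- as.integer(rnorm(n) > 0.25)
    }
    list(L = L, M = M, trait = trait)
  })
}
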