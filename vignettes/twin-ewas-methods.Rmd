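---
title: "Methods: twin-design EWAS for binned MeDIP-seq methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin-design EWAS for binned MeDIP-seq methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twindmr)
```

## The problem and the design

MeDIP-seq measures genome-wide DNA methylation as an enrichment signal:
after immunoprecipitation of methylated fragments, the data are fragment
counts, summarised per genomic bin (here 500 bp windows sliding by 250 bp)
either as RPM (fragments per bin per million mapped) or as an externally
computed CpG-density-adjusted signal (AMS).  `twindmr` implements a
case-control epigenome-wide association analysis of such binned profiles
built around a monozygotic (MZ) twin design:

* a **DMR scan** over all twin pairs (discordant and concordant) with a
  linear mixed model carrying a family random intercept;
* a **giDMR scan** restricted to disease-discordant MZ pairs, testing
  within-pair differences — since co-twins are genetically identical and
  share family environment, whatever survives the differencing is
  genetically independent by construction;
* **replication** of discovered regions in unrelated cases and controls by
  ordinary least squares;
* **enrichment** of DMRs against gene annotations, GWAS risk loci and
  candidate gene sets (imprinted genes);
* **mQTL scans** (cis within 50 kb, trans elsewhere) and a **causal
  inference test** asking whether methylation mediates a genetic effect on
  disease;
* **metabolite integration** with run-day median normalization, within-pair
  signed-rank tests, staged replication and a signed Stouffer
  meta-analysis.

Everything runs end to end on synthetic data from the package's seeded
generator, which records the planted truth so that error rates, power and
recovery can be measured exactly.

## The mixed model and how it is fitted

For each bin, the model for sample $j$ in family $i$ is

$$ y_{ij} = \mathbf{x}_{ij}^\top \beta + u_i + e_{ij}, \qquad
   u_i \sim N(0, \sigma_b^2), \quad e_{ij} \sim N(0, \sigma_e^2), $$

with fixed effects for disease status, age, sex and BMI, and co-twins
sharing $u_i$.  Writing $\tau^2 = \sigma_b^2 + \sigma_e^2$ and
$\rho = \sigma_b^2 / \tau^2$ (the within-pair intraclass correlation), the
marginal covariance of a pair is exchangeable, and the orthogonal rotation
of each pair to (sum, difference)$/\sqrt 2$ diagonalises it with
eigenvalues $\tau^2(1 \pm \rho)$.  `fit_family_mixed_model()` exploits
this: for a fixed $\rho$ the generalized least squares fit is a weighted
regression in the rotated basis and $\tau^2$ profiles out in closed form,
leaving a one-dimensional restricted likelihood in $\rho \in [0, 1)$ that
is maximized by bounded scalar search (tolerance $10^{-8}$, with an
explicit comparison against the $\rho = 0$ boundary, which is the common
null case).  REML rather than ML is used because variance components in
small samples are otherwise biased downward.

**Test reference.**  Fixed effects are tested by Wald statistics referred
to a $t$ distribution with *between-within* denominator degrees of freedom
(the rule used by `nlme` and SAS `DDFM=BW`): covariates that vary within
families are tested against $n - G - p_w$ df ($G$ families, $p_w$
within-varying terms) and family-level covariates against the
between-family df.  The asymptotic normal reference is anti-conservative
here — with 27 families it rejects a true null at roughly 0.065–0.07
instead of 0.05 in our calibration simulations (8,000 null bins), while
the between-within $t$ reference stays within Monte-Carlo error of the
nominal rate.  That calibration, not convention, decided the default.

P-values are adjusted by Benjamini–Hochberg across all tested bins;
reporting tiers default to FDR 5% / 10% / 25%, the last defining the
"suggestive" set carried into replication and enrichment.

## The giDMR construction

`gidmr_scan()` forms the affected-minus-unaffected difference per
discordant pair and applies a one-sample $t$ test per bin
($t = \bar d / (s_d/\sqrt n)$, $n - 1$ df).  Differencing cancels *any*
pair-shared additive term exactly — genetic background, shared
environment, age, sex — which is the defining property of the design, and
is asserted in the test suite to $10^{-12}$.  The complementary property
is planted in simulation: a pair-shared environmental shift proportional
to the pair's mean case status is detectable by the mixed-model scan
(through between-family contrasts) but invisible to the giDMR scan.
Because a pair-level effect is identified only by between-family
information, this positive control uses a concordant-rich design (10
discordant + 20 concordant-case + 20 concordant-control pairs) and a
3-SD shift; a design-stage power calculation (effective information
$\approx \Sigma_b/(\Sigma_b + \Sigma_w)$ under the rotated-basis weights)
puts the mixed-model power above 0.9 there, whereas the default 17/3/7
cohort would have power below 0.2 for the same shift.

## Normalization choices

The scan operates on per-bin values normalized across samples.  The
default is the z-score (literal "normalized to N(0,1)"); a rank-based
inverse-normal transform with the Blom offset,
$\Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)$, is provided for heavy-tailed
signals and is invariant to monotone transforms of the raw data.
Zero-variance bins cannot be standardized; they are excluded and counted,
never silently dropped.  Coordinates are 0-based half-open everywhere
internally (BED-native); fragment-to-bin assignment uses the simplest
auditable rule, overlap of at least 1 bp, with trailing bins shorter than
the step dropped at tiling time.

## Enrichment constructions

Three constructions are provided, all order-invariant and seeded:

* **TSS proximity** — fraction of DMR midpoints within 100 bp of any TSS,
  against a null that relocates each chromosome's TSSs uniformly
  (per-chromosome counts preserved).  Empirical p-values use the add-one
  rule $p = (1 + \#\{\text{null} \ge \text{obs}\})/(n_\mathrm{perm} + 1)$,
  so with the historical default of 20 permutations the smallest
  attainable p is $1/21 \approx 0.048$; the function warns below 999
  permutations.
* **Fisher overlap tests** — one-sided hypergeometric tails, at the bin
  level (is a coverage-universe bin a DMR × does it overlap a 50 kb GWAS
  locus window) and at the gene level (DMR genes × candidate set over the
  annotated universe).  The unit for the region test is the bin because
  bins are the testing unit everywhere else.  The tail is computed by
  `phyper` and verified against direct `dhyper` summation to $10^{-10}$
  in the tests.  One-sided toward enrichment matches the direction of the
  scientific claims; fold is observed over the independence expectation.
* **Rank resampling** — the Wilcoxon rank sum of a target gene set's
  p-value ranks against draws of random same-size sets from the covered
  genes (10,000 draws by default).  The per-gene summary p is the minimum
  over the gene's assigned bins — simple and monotone; a mean alternative
  is exposed by argument.

Gene annotation is strand-aware: the extended promoter reaches 20 kb
upstream of the TSS (gene start on "+", gene end on "−"), clipped to
chromosome bounds, and gene-body overlap takes precedence over promoter
for the class label.

## mQTL scans and the causal inference test

Cis SNPs are those positioned within 50 kb of a region
(`[start − 50 kb, end + 50 kb)`); methylation is regressed on dosage plus
age and sex by OLS, with both Bonferroni-adjusted p-values and BH
q-values reported (the two conventions coexist in the literature for this
analysis).  The trans scan covers all remaining (region, SNP) pairs, so
the partition is exact and exhaustive.

The causal inference test for a triple (locus $L$, methylation $M$, trait
$T$) combines four conditions as an intersection-union test (omnibus p =
max of the four): $L$–$T$ association; $L$–$M$ given $T$; $M$–$T$ given
$L$; and an equivalence-style condition that the residual $L$–$T$
association given $M$ is *small*.  The fourth is assessed by permutation:
the trait is permuted within strata of $L$ (genotype classes), which
preserves the marginal $L$–$T$ association while severing $M$–$T$, and
the $F$ statistic for $L$ in $T \sim M + L$ is recomputed per
permutation; $p_4 = (1 + \#\{F^\ast \le F_\mathrm{obs}\})/(B + 1)$.
Under full mediation ($L \to M \to T$) conditioning on $M$ collapses
$F_\mathrm{obs}$ while the permuted statistics retain the marginal
signal, so $p_4$ is small; under a direct $L \to T$ edge the observed
statistic sits inside the permutation distribution and $p_4$ is large.
This stratified-trait permutation was chosen over permuting $L$ within
strata of $M$ after working through the null distributions: the latter
leaves both observed and permuted $F$ central under full mediation, so
it cannot certify mediation at all.  Scenario-separation simulations
(200 replicates each) confirm the realization: causal chains are called
at ≈0.95+ power while reactive ($L \to T \to M$) and independent
pleiotropy architectures are called at well under 10% — the reactive case
is additionally blocked by condition 2 and pleiotropy by condition 3.
A binary trait is handled by linear probability regressions throughout,
keeping the permutation statistic $F$-based and fast.

## Metabolite integration

Raw metabolite levels are divided by their (metabolite, run-day) median —
removing any multiplicative day effect exactly — and then standardized
per metabolite.  Discovery uses the Wilcoxon signed-rank test on
within-pair differences in discordant twins (exact null up to 25 pairs,
normal approximation with continuity correction beyond; zero differences
dropped by the standard convention, with a 5-pair minimum).  Metabolites
passing discovery at p < 0.05 are carried into an OLS replication in
unrelated samples, and the stages are combined by signed Stouffer
weighting, $z = (w_1 z_1 + w_2 z_2)/\sqrt{w_1^2 + w_2^2}$ with
$w = \sqrt n$, Bonferroni-corrected over the meta-analysed metabolites.
Stouffer was chosen over Fisher's combination because it respects
direction; equal-$n$ symmetry and the closed-form worked values
(two same-direction p = 0.05 → meta p ≈ 0.00557) are asserted in tests.
Whether the discovery stage should condition on methylation is left to
the analyst: `pairwise_wilcoxon()` tests metabolite discordance per se,
and `pair_diff_association()` regresses within-pair metabolite
differences on within-pair methylation differences.

## What the generator emulates — and what it does not

`sim_config()` defaults encode the study conditions: 17 discordant + 3
concordant-case + 7 concordant-control MZ pairs (54 twins), 42 unrelated
cases and 221 matched controls, a MAF > 5% variant filter, 65 GWAS loci
and 503 metabolites with 7 coupled to the top DMR.  Age (Uniform 40–80)
and sex are shared within pairs; BMI is N(27, 4²) with a 0.5 co-twin
correlation; discordance is assigned, not emergent, because the design
conditions on it.  The per-bin model is exactly the analysis model
(family intercept + covariates + planted case shift, with
`dmr_effect = 0.8` in total-SD units at 5% of bins), so parameter
recovery and error-rate checks are interpretable.  Desk-scale choices —
a toy genome of 2 × 10 Mb, 2,000 bins, 200 SNPs — keep the full pipeline
under a minute; the test suite and the acceptance script state their own
(sometimes smaller) problem sizes.

The generator does **not** emulate CpG-density structure, read-level
noise, correlated neighbouring bins, batch effects beyond run-day scales,
or linkage disequilibrium between SNPs.  Passing tests therefore certify
the statistical machinery under the stated model, not robustness to
those real-data features.  The simulated methylome is labelled AMS (a
Gaussian per-bin signal); the nonnegative RPM path is exercised
separately through the Poisson fragment generator and `compute_rpm()`.

## Numerical choices and degenerate inputs

* REML profile optimization: golden-section/Brent with tolerance
  $10^{-8}$ plus an explicit boundary check at $\rho = 0$; the abscissa
  precision of scalar search is floored near $\sqrt{\varepsilon}$, so
  results are reproducible to about $10^{-8}$, not machine precision.
* Rank-deficient designs raise an error; non-converged bins are excluded
  and counted; collinear or constant extra covariates in the confounder
  check are flagged untestable rather than fitted.
* All permutation and resampling p-values use the add-one correction and
  are therefore never zero; with a fixed seed they are bit-reproducible.
* Underflowed stage p-values are clamped at the smallest positive double
  before the Stouffer z conversion.
* Hierarchical seeding: every stage derives a child seed from the root
  seed and a stage tag, so stages are individually and jointly
  reproducible, and `run_pipeline()` output directories are
  byte-identical across reruns apart from the timestamp line in the run
  log.

## Known limitations

The between-within df rule is an approximation (exact small-sample df
would require Kenward–Roger-style adjustment); the linear probability
model for binary traits in the causal inference test trades link-function
fidelity for permutation speed (a logistic variant would change component
p-values slightly but not the intersection-union logic); and BH control
is guaranteed under independence or positive dependence of bins — the
generator draws bins independently, matching that assumption, while real
neighbouring bins overlap and are positively correlated.
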