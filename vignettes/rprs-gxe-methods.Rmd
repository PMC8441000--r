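---
title: "Refined polygenic scores and gene-environment interaction: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refined polygenic scores and gene-environment interaction: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem this package addresses

A polygenic risk score (PRS) summarizes an individual's genetic load
for a trait as a weighted count of risk alleles, with weights taken
from an external GWAS and SNPs restricted to those below a GWAS
p-value threshold. When the discovery GWAS comes from a different
population than the study sample -- here, an adult fasting-insulin
GWAS applied to children -- the conventional single-threshold PRS may
carry many SNPs that are irrelevant in the target age group. The
*refined* PRS (rPRS) implemented here addresses this with a two-stage
training procedure on a cohort that has both genotypes and the
anchoring phenotype (peripheral insulin in children):

1. **Threshold scan.** PRSs are computed at 100 GWAS p-value cutoffs
   (0.01, 0.02, ..., 1.00) after LD clumping, and each is entered into
   `phenotype ~ covariates + PRS`. The cutoff whose PRS coefficient is
   most significant is selected (`p_t-initial`). For a single added
   regressor, minimum p and maximum incremental R-squared coincide;
   ties are broken toward larger incremental R-squared, then the
   smaller cutoff, so selection is deterministic.
2. **Per-SNP refinement.** Every SNP inside the selected threshold is
   tested individually (`phenotype ~ covariates + dosage`); SNPs with
   p below `alpha_refine` (default 0.05, no multiple-testing
   correction -- a deliberate, faithful-reproduction choice) are kept
   with their *original GWAS weights*.

The refined set is then transferred to an independent test cohort,
standardized (mean 0, SD 1), and used as the moderator M in the
pre-registered interaction models with cumulative early-life adversity
X and a delay-of-gratification outcome Y:

* model 1: `Y ~ sex + PC1 + PC2 + PC3 + X`
* model 2: `Y ~ sex + PC1 + PC2 + PC3 + M`
* model 3: `Y ~ sex + PC1 + PC2 + PC3 + X + M + X:M`

The interaction is characterized by simple slopes at M = mean +/- 1 SD,
Johnson-Neyman regions of significance, and the interaction-form
indices PoI and PA; uncertainty by a case-resampling bootstrap; missing
adversity components by hot-deck multiple imputation with Rubin
pooling.

## Genotype handling

Dosages are expected counts of a *counted allele* in [0, 2]. Before any
scoring, genotypes are aligned so the counted allele equals the GWAS
effect allele (flipping `d -> 2 - d` where the file counted the other
allele). Strand-ambiguous SNPs (A/T, C/G) are dropped during alignment:
without strand information their orientation cannot be verified, and
dropping them is the conservative community norm.

QC follows the published per-cohort filters as presets: call rate >=
95%, MAF >= 5%, HWE p >= 1e-30 ("mavan", the default), or MAF >= 1%
with HWE p >= 5e-7 ("alspac"). HWE uses hard calls (rounded dosages)
and a 1-df chi-square goodness-of-fit test rather than the exact test;
only a p cutoff is specified upstream, and the chi-square is the
standard array-QC choice at these sample sizes.

Missing-data policy, chosen once and used everywhere: PRS and PCA
mean-impute missing dosages per SNP (deterministic, preserves sample
size); LD and HWE computations use pairwise-complete samples. The
per-SNP refinement regressions also use mean-imputed dosages, keeping
every stage of the score-construction path on one policy.

Pruning and clumping both use squared Pearson correlation of dosages.
Pruning is a sliding window (default 50 kb, step 5 SNPs, r2 > 0.2
removes the later SNP); clumping is greedy by ascending GWAS p with a
250 kb window -- the window size is not specified upstream, and 250 kb
is a common tool default; it is configurable. All position ties and
equal p-values break by lexicographic snp_id: determinism is preferred
over any claimed optimality.

## Adversity score and outcome

Each adversity component is either binary or a continuous instrument
summary dichotomized at an extreme percentile: above the 85th
(high-risk tail) or below the 15th (low tail). Percentiles use linear
interpolation (`quantile()` type 7), and the inequality is strict --
values tied exactly with the cutoff score 0. Points are summed; the
primary analysis is complete-case, with hot-deck imputation (each
missing cell replaced by a uniform draw from the component's observed
values; default 30 sets) as the sub-analysis.

The Snack Delay task yields, per trial, a behavior code (1-7) plus a
latency code (1-2), giving totals in 2-9 over four trials with delays
of 10, 20, 15 and 30 s. Children with a global cooperation score other
than 3 are excluded. The published description never states how the
four trial totals become one outcome; the default here is the mean
(the sum is available via `aggregate = "sum"`), recorded in the report.
Higher scores mean better delay ability, so a negative interaction
coefficient reads as "adversity increases impulsivity at high rPRS".

## Interaction probing

With model 3 written as `Y = b0 + ... + bX X + bM M + bXM XM`, the
simple slope of X at moderator value m is `bX + bXM m` with variance
`Var(bX) + m^2 Var(bXM) + 2m Cov(bX, bXM)`. Johnson-Neyman boundaries
solve the quadratic `(bM + bXM x)^2 = t_crit^2 Var(bM + bXM x)`; the
roots are verified in the test suite against a 10,000-point grid scan.

PoI and PA are reported with an explicit convention, since the source
literature cites but does not define the formulas: the two outcome
lines at M = +/- 1 SD intersect at the crossover `x0 = -bM / bXM`; PoI
is the proportion of the total area between the lines (over the
evaluation range) lying on the side of the crossover where the
high-moderator group fares *worse*; PA is the fraction of observed
adversity values on that same side. PoI near 0.5 indicates differential
susceptibility, near 0 or 1 a diathesis-stress / vantage-sensitivity
form. The evaluation range defaults to the observed min-max of the
adversity score (a +/- 2 SD alternative can be passed explicitly);
PA counts cases, not area -- the area-weighted alternative is noted but
not implemented, as the two cannot be disambiguated from published
values. With `bXM = 0` the indices are degenerate and flagged rather
than computed.

The bootstrap is case-resampling (the standard reading of
"non-parametric bootstrap"), defaults to 1,000 replicates with a
percentile CI, and skips (and counts) rank-deficient replicates, with
more than 10% skipped treated as an error. Classical (non-robust) OLS
standard errors are used throughout, matching a default linear-model
fit. Rubin pooling uses the small-sample degrees of freedom
`(m-1)(1 + W/((1+1/m)B))^2`, with `B = 0` treated as infinite df.

## What the synthetic generator emulates -- and what it does not

The real cohorts are access-restricted, so the package ships a
generator that reproduces the *statistical structure* the analysis
assumes: two cohorts drawn from shared allele frequencies (uniform on
[0.05, 0.5]); block LD from thresholded latent Gaussians
(exchangeable within-block correlation 0.4, block size 10), which
keeps each SNP exactly in HWE; a training phenotype with configurable
heritability (default 0.3) driven by 20 causal SNPs out of 500; GWAS
summary statistics with estimation noise at the standard error implied
by a 100,000-sample reference GWAS, so null p-values are uniform;
seven adversity components with published-like missingness (0-32% per
instrument); and an outcome with a planted standardized interaction of
-0.33, no main effects, and residual SD 1 -- the effect size and sign
reported for the real analysis. Causal effect draws are
`Normal(0, 0.25^2)` pushed to at least 0.15 in magnitude so every
causal SNP is detectable in principle at desk scale; this reconciles
the "normal effects" and "effects >= 0.15" statements in the design
brief.

Not emulated: realistic human LD maps, ancestry admixture and
stratification (the simulated population is homogeneous, so the PC
covariates are exercise rather than correction), genotype-imputation
uncertainty, and instrument-level structure of the adversity
components. A green end-to-end test therefore establishes that the
pipeline recovers a planted interaction under its own model
assumptions -- not that the published cohort estimates are reproduced;
those depend on restricted data.

Default sizes (discovery 2,000; test 600; 500 SNPs) keep every
generator call under a few seconds; the statistical property suites
(400-seed type-I error, 25-seed end-to-end recovery) run in well under
a minute in total.

## Numerical choices and degenerate inputs

* Thresholds are inclusive (`p <= t`); the grid is 0.01-1.00 in steps
  of 0.01 ("100 thresholds between 0 and 1", not further specified
  upstream).
* Constant SNPs: excluded from PCA, skipped in refinement, and treated
  as uncorrelated (r2 effectively 0) during pruning/clumping, where an
  undefined correlation must not trigger removal. `ld_r2()` itself
  signals a distinct `rprsgxe_constant_error`.
* A score that is constant across samples cannot be standardized and
  errors out rather than returning NaN.
* Rank-deficient designs error, naming the collinear columns.
* All generators and resampling routines restore the caller's RNG
  state; every stage is a pure function of (inputs, seed).

## Known limitations

* The per-SNP refinement keeps GWAS weights, not re-estimated ones; at
  `alpha_refine = 0.05` roughly 5% of null SNPs are retained by
  construction (verified as a property test).
* The scan's covariate set ("first 10 PCs" by default, `"none"` as a
  config switch) affects threshold choice; which covariates the
  original training regression used is not documented upstream, so the
  report records which mode ran.
* PoI/PA conventions differ across the literature; comparisons across
  tools should check the orientation stated above.
* The CLI exposes `run` and `simulate` (plus the full R API); the
  stage-level subcommands fold into the all-in-one `run`, whose JSON
  report contains every intermediate summary.
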