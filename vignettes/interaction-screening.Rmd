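---
title: "Two-step survival screening for gene-environment interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step survival screening for gene-environment interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survgxe)
```

## The problem

Genetic variants that *modify* the effect of an environmental exposure on
a time-to-event outcome are hard to find. A variant whose effect is
protective in one exposure stratum and harmful in the other can have a
marginal association near zero, so a conventional genome-wide scan of the
whole cohort will miss it. `survgxe` implements a two-step screen for
such loci in biobank-scale survival data:

1. **Discovery.** Time-to-event GWAS of the outcome in the full cohort
   *and separately within each exposure stratum*, using a Cox score test
   with saddlepoint-approximated tail probabilities. Variants reaching a
   lenient suggestive threshold (`p < 1e-5`, MAF > 0.01 by default) in
   any of the three scans become candidates.
2. **Formal testing.** Candidates are collapsed into independent loci by
   LD clumping (`r^2 < 0.1` within 250 kb), span merging (clusters
   within 250 kb coalesce) and ±250-kb extension. Each candidate SNP is
   then tested for a SNP-by-exposure product term in a Cox model, with
   significance judged against a locus-level Bonferroni threshold
   `0.05 / n_loci`. Hits are profiled by subgroup hazard ratios
   (exposure HR within hard-called genotype groups, per-allele HR within
   exposure strata), with any subgroup holding five or fewer events
   flagged and not estimated.

Every stage is driven by a synthetic cohort generator with *planted*
main and interaction effects, so the whole pipeline is testable without
access-restricted data.

## The Cox engine

`fit_cox()` maximizes the Efron-tie-corrected log partial likelihood by
Newton-Raphson with step-halving; the information matrix receives a
`1e-8` ridge only if it is numerically singular. Convergence is declared
when the relative log-likelihood change falls below `1e-9` (at most 50
iterations). Time-on-study is the analysis time scale and age enters as
a covariate, mirroring the covariate-adjustment convention of large
cohort analyses; delayed entry is not modelled. Efron tie handling is
the default because real biobank follow-up times tie heavily. A
monotone partial likelihood (separation) is reported as an error
suggesting penalization rather than returning a divergent estimate.

The baseline cumulative hazard uses the Breslow estimator, so martingale
residuals are `r_i = delta_i - Lambda0(t_i) exp(x_i' beta)`; with this
pairing the residuals sum to zero identically at any coefficient value,
which the score test below relies on. Wald inference is reported on the
log hazard-ratio scale with normal 95% intervals; a likelihood-ratio
test is available as a diagnostic alternative.

## Score test and saddlepoint tail

For each variant the dosage vector `g` (missing entries mean-imputed) is
residualized on the null-model covariates plus intercept, giving the
score `S = sum_i g_i r~_i`, where `r~` is the covariate-projected
martingale residual vector. The reference distribution treats the
residuals as fixed and the genotypes as exchangeable:

* **Variance.** `V = sum_i (g_i - g_bar)^2 * sum_i r~_i^2 / (n - 1)` is
  the exact variance of `S` under genotype permutation, which makes
  `z^2 = S^2 / V` chi-squared calibrated under the null without any
  per-dataset tuning.
* **Tail.** The normal approximation to `z` is accurate near the centre
  but anti-conservative in the far tail when events are rare or the
  variant is uncommon, because the residual distribution is then heavily
  skewed. When `|z| > 2` (the usual hybrid switch in the saddlepoint
  GWAS literature) the tail probability is recomputed from the cumulant
  generating function of `S` with genotypes modelled iid
  Hardy-Weinberg at the observed allele frequency:
  `K(t) = sum_i log[(1-p)^2 + 2p(1-p) e^{t r~_i} + p^2 e^{2 t r~_i}] - 2pt sum_i r~_i`.
  The saddlepoint `K'(zeta) = s` is solved by safeguarded Newton with
  bracket expansion, and each tail uses the Lugannani-Rice formula
  `w = sign(zeta) sqrt(2(zeta s - K(zeta)))`, `v = zeta sqrt(K''(zeta))`,
  `P = 1 - Phi(w) + phi(w)(1/v - 1/w)`; the two-sided p-value sums the
  upper tail at `|s|` and the lower tail (the upper tail of `-S`). If
  the root-finding fails or `|s|` exceeds the support of `S`, the normal
  p-value is kept and the result flagged `spa_failed_fallback`.

Correctness is anchored to a genotype-permutation oracle (the test suite
compares the saddlepoint tail with a 200,000-permutation empirical tail
at `p ~ 1e-3` on a sparse-event fixture), not to any external
implementation. Two practical notes: with only ~20 events the score
distribution is visibly discrete, so the median-based inflation factor
`lambda_GC` can sit a few percent above 1 in a sparse arm even though
rejection rates are calibrated — pooling a sparse and a moderate arm
gives the cleaner diagnostic; and the hybrid p-value is used everywhere
downstream (`p` column), with `p_normal` and `p_spa` retained for
comparison.

## Loci

Clumping is greedy in ascending p order (ties by position, then id): a
variant joins the best-p existing index within 250 kb *and* `r^2 >= 0.1`
(in-sample dosage correlation), otherwise it founds a new clump — so a
variant inside the window but in linkage equilibrium with the index
starts its own locus. The window is measured index-to-variant during
clumping but span-to-span during merging, where clumps whose member
spans lie within 250 kb coalesce transitively. Extension pads loci by
250 kb each side (floored at position 1) and merges any overlap of at
least 1 bp before counting independent loci. Coordinates are 1-based
inclusive internally; BED input is converted from 0-based half-open on
read. Nearest-gene annotation considers protein-coding entries only,
with distance 0 inside a span and deterministic tie-breaks (smaller
start, then alphabetical symbol).

`run_screen()` pools the extended merged intervals across outcomes and
discovery sources into one Bonferroni denominator (a single
family-wise budget for the whole screen), and also reports per-outcome
counts so a per-outcome correction can be recomputed instead.

## Cohort preparation

Exposure coders are total on their declared vocabularies and raise on
anything else: the supplement questionnaire maps the fish-oil option to
1 and any other response set to 0 (no response is missing), and
oily-fish intake dichotomizes "never"/"less than once a week" versus
all higher frequencies. The epsilon-4 dosage resolves the two-SNP
diplotype (rs429358, rs7412) through the haplotype table e2 = (T,T),
e3 = (T,C), e4 = (C,C), e1 = (C,T); the double heterozygote is
ambiguous between e1/e3 and e2/e4 and is excluded, as is any sample
missing either genotype. The dosage is the count of e4 haplotypes and
feeds the positive-control interaction test.

Missing covariates are completed by single chained-equations imputation:
predictive mean matching (k = 5 donors, type-0 matching on the
linear-model prediction) for continuous variables, logistic draws for
binary, multinomial-logistic draws for unordered categoricals; 10
sweeps in ascending-missingness visit order. A single completed table
(rather than multiple imputations with pooling) keeps the downstream
per-SNP Cox fits simple; because covariate missingness only affects
adjustment covariates here, the efficiency loss is minor, and the
function is deterministic given its seed so screens remain
reproducible. Observed values are never altered; a covariate more than
half missing triggers a warning and a fully missing one an error.

## The synthetic cohort generator

The generator's defaults are the study conditions the screen is
validated under: entry ages truncated-normal 40-69 years (mean 56.81,
SD 8.01), binary exposure prevalence 0.317, administrative censoring at
13.8 years (so median follow-up is ~13.8 years at the low default event
rate), sex Bernoulli(0.5), ten standard-normal principal components,
and an exponential (constant) baseline hazard multiplied by
`exp(covariate effects + exposure effect + sum(beta_main * dosage) +
sum(beta_gxe * dosage * exposure))`. Genotypes are drawn per variant at
a uniform allele frequency in (0.01, 0.5) — anchored at the screen's
common-variant MAF floor, and keeping minor-allele counts resolvable at
the desk-scale sample sizes used in testing — thresholded from latent
block-autoregressive Gaussians so Hardy-Weinberg proportions hold
exactly per variant while `r^2` decays geometrically within a block
(Gaussian-copula LD; no haplotype panel is emulated). All-cause events
are probabilistically classified into Alzheimer's (0.55) and vascular
(0.25) subtypes, giving cause-specific indicators that share one
follow-up time; the subtype proportions are package defaults chosen to
give plausible cause-specific case counts, not anchored constants.
Lifestyle, diet and medical-history covariates for the richer
adjustment models are drawn from fixed plausible marginals (e.g. BMI
~ N(27.4, 4.8), smoking 55/35/10%); they are independent of the hazard
by default, so models 2-4 add pure adjustment noise unless effects are
planted explicitly. One integer seed drives everything; the cohort
stream is derived from it deterministically, so a spec reproduces its
data byte-for-byte.

What passing tests on this generator do *not* show: robustness to
haplotype-panel LD, population stratification, informative censoring,
competing mortality, exposure misclassification, or covariate
missingness that is not at random. The generator is a calibration and
power instrument, not a cohort emulator.

## Numerical choices and degenerate inputs

* Dosages are hard-called by `round()` (ties-to-even at .5) for HWE
  testing and genotype subgrouping; QC order is fixed
  (info → biallelic → MAF → missingness → HWE) so removal attribution
  is deterministic.
* Zero-variance dosages are flagged non-testable rather than tested;
  a degenerate null with all-zero residuals returns p = 1.
* Relatedness pruning removes samples with more than 10 above-cutoff
  (kinship > 0.0442) pairs first, then resolves remaining pairs in
  sorted order with a seeded uniform choice.
* `run_screen()` writes no timestamps into its outputs, so a rerun with
  the same configuration and seed is byte-identical.
* Test problem sizes: the null-calibration suite uses two arms of
  25,000 variant-tests at n = 2,000 (about 1% and 10% event rates);
  interaction-recovery bias uses 200 replicates at n = 20,000; the
  null-uniformity check uses 2,000 replicate fits at n = 1,000 (sized
  for a Kolmogorov-Smirnov distance of ~0.03); the two-step premise
  uses 100 replicates at n = 20,000. The HWE-uniformity property uses
  20,000 samples per variant because the exact test is discrete and
  conservative at small minor-allele counts and approaches uniformity
  only in that regime.

## Known limitations

In-sample LD only (no reference panel); autosomes only; no
time-varying coefficients, frailty terms or proportionality
diagnostics; single imputation rather than multiple imputation with
pooling; the saddlepoint reference treats the null-model residuals as
fixed, which ignores the (second-order) variability from estimating the
null coefficients; consequence annotation beyond nearest protein-coding
gene is out of scope.
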