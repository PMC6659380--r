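---
title: "Partitioning maternal and offspring genetic effects, and using them in Mendelian randomization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning maternal and offspring genetic effects, and using them in Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maternalmr)
library(dplyr)
```

## The problem

A SNP carried by a mother can be associated with her offspring's
phenotype through two routes: directly, because the offspring inherits
the allele with probability one half and it acts in the offspring
(the *offspring* or *fetal* genetic effect, $\beta_o$), and indirectly,
because the allele shapes the intrauterine or postnatal environment the
mother provides (the *maternal* genetic effect, $\beta_m$). Unconditional
regressions mix the two: the population slope of a person's own
phenotype on their own genotype is $b_{own} = \beta_o + \beta_m/2$, and
the slope of an offspring phenotype on the maternal genotype is
$b_{off} = \beta_m + \beta_o/2$. Separating $\beta_m$ from $\beta_o$
matters in its own right, and is a precondition for two-sample Mendelian
randomization (MR) of maternal exposures on offspring outcomes, where
the transmitted offspring genotype otherwise violates the exclusion
restriction.

`maternalmr` implements three estimation routes and their downstream
use:

1. **Conditional regression** (`conditional_regression()`): in genotyped
   mother–offspring pairs, regress the offspring phenotype jointly on
   offspring and maternal dosage. Exact, but such pairs are scarce.
2. **The latent-genotype SEM** (`fit_sem()`): for cohorts of genotyped
   women reporting their own phenotype at birth and/or their first
   offspring's phenotype. The genotypes of the woman's mother and of her
   offspring are *latent*, tied to her observed dosage by the meiotic
   transmission path of $1/2$, with all genotypic variances equal to
   $\Phi$. Integrating the latents out gives closed-form implied moments
   (`implied_moments()`); full-information maximum likelihood lets every
   missingness pattern contribute, so "singletons" with only one
   phenotype still inform the fit.
3. **The summary-statistics route** (`fit_sem_summary()`): two deposited
   unconditional GWAS (own phenotype on own genotype; offspring
   phenotype on maternal genotype) identify $(\beta_m, \beta_o)$ exactly
   through the linear inverse
   $\beta_m = (4 b_{off} - 2 b_{own})/3$,
   $\beta_o = (4 b_{own} - 2 b_{off})/3$.

## Model and implied moments

For one woman, the observed vector is (own phenotype, offspring
phenotype, dosage). With maternal effect $\beta_m$, offspring effect
$\beta_o$, genotypic variance $\Phi$, residual variances
$\sigma^2_\varepsilon, \sigma^2_{\varepsilon_O}$ and residual covariance
$\rho$, covariance algebra over the transmission paths gives

$$
\mathrm{var}(BW) = \Phi(\beta_o^2+\beta_m^2+\beta_o\beta_m)+\sigma^2_\varepsilon,\qquad
\mathrm{cov}(BW, SNP) = \beta_o\Phi + \tfrac{1}{2}\beta_m\Phi,
$$
$$
\mathrm{cov}(BW, BW_O) = \Phi\left(\tfrac{5}{4}\beta_o\beta_m +
\tfrac{\beta_o^2+\beta_m^2}{2}\right)+\rho,\qquad
\mathrm{cov}(BW_O, SNP) = \beta_m\Phi + \tfrac{1}{2}\beta_o\Phi,
$$

and symmetrically for $\mathrm{var}(BW_O)$. Each missingness pattern
contributes the marginal normal density of its observed subvector;
dosage-only records inform only $\Phi$ and the dosage mean.

Numerical choices, all visible in the code and chosen once:

* **Parameterization.** Variances are searched on the log scale and
  $\rho$ through the Fisher transform of its residual correlation, so
  BFGS runs unconstrained and the implied matrix stays positive
  definite. Convergence is declared when the per-record average score
  norm at the optimum falls below `1e-6` (the raw score scales with the
  sample size, so the per-record average is the scale-free criterion)
  and the optimizer reports success; the flag is honest, not assumed.
* **Starting values** come from the two unconditional regressions pushed
  through the closed-form inverse, with sample variances for the
  residuals and zero residual covariance — near-consistent starts that
  make per-SNP scans fast (`fit_sem_loci()`).
* **Standard errors** are the inverse of the observed information,
  evaluated by central finite differences with steps
  $10^{-5}\max(1,|\theta|)$. When a parameter direction carries no
  information — for instance $\rho$ in a cohort with no dual-phenotype
  records — the identified block is inverted and the rest reported `NA`,
  with a warning rather than silence.
* **Covariate adjustment** is by pre-residualizing phenotypes before the
  fit, keeping the three-variable moment structure intact.
* **Means** are free per-locus parameters; no Hardy–Weinberg constraint
  is placed on $\Phi$.

## Summary-statistics fits and sample overlap

When the two GWAS share participants, their effect estimates at each SNP
are correlated; ignoring that misstates the standard errors of the
partitioned effects (the point estimates are unaffected). The sampling
correlation equals the cross-trait LD score regression intercept
$\rho_p N_s/\sqrt{N_1 N_2}$, with $\rho_p$ the phenotypic correlation in
the $N_s$ overlapping samples. `ldsc_overlap()` estimates it by
regressing per-SNP z-score products on LD scores: the LD-dependent slope
absorbs shared polygenic signal and the intercept is the overlap term.
Implementation choices follow common LDSC practice where the method's
description leaves them open: two-pass $1/\ell_j$ weighting with the
first-pass intercept in the second-pass weights, z-score products
winsorized at $|z_1 z_2| \le 100$, and a 200-block delete-one jackknife
for the intercept (and slope) standard errors. The intercept is clamped
to $[-1, 1]$ and the implied overlap count to $[0, \min(N_1, N_2)]$.

`fit_sem_summary()` then propagates errors by generalized least squares:
with $S$ the per-SNP $2\times2$ sampling covariance (off-diagonal
$\text{intercept}\times se_1 se_2$) and $A$ the inverse-map matrix, the
covariance of $(\hat\beta_m,\hat\beta_o)$ is $ASA^\top$. For this
just-identified two-equation system the linear inversion coincides with
an iterated moment-matrix SEM, so the closed form was preferred for
determinism and testability. A consequence worth noting: the assumed
$\rho_p$ enters only the *implied overlap count*, not the estimates or
their standard errors (which use the intercept itself), so
misspecifying $\rho_p$ within a plausible range (0.1–0.3) changes
nothing downstream — the test suite asserts this exactly.

## Two-sample MR on partitioned effects

`harmonize_instruments()` aligns outcome to exposure effect alleles,
drops strand-ambiguous palindromic SNPs (A/T, C/G with MAF > 0.42),
SNPs below a MAF floor (default $10^{-3}$, mirroring the instability of
the SEM at near-monomorphic loci) and non-converged fits, logging each
exclusion. Per-SNP Wald ratios use the first-order delta standard error
(`se_out/|beta_exp|`), matching the usual two-sample computation; a
second-order option exists behind a flag. `mr_ivw()` uses multiplicative
random-effects with the scale floored at one, so heterogeneity can widen
but never shrink the interval; `mr_egger()` orients exposure effects
non-negative, scales SEs by $\max(1,\sqrt{Q/(k-2)})$ and uses
$t_{k-2}$ p-values; `mr_weighted_median()` uses the interpolated
weighted median with a parametric bootstrap (5000 draws, seeded).
P-values for IVW are normal. These conventions fill gaps the method
descriptions leave open; each identity (fixed-effect closed forms,
IVW–Egger relations, allele-flip equivariance) is pinned by a test.

`mr_pipeline()` emits the full grid
{maternal, offspring} × {sem, unadjusted} × {ivw, egger, wmedian}. The
unadjusted arm replaces the partitioned effects by the unconditional
slopes, reproducing the biased analysis: with opposing maternal and
offspring effects the unadjusted estimates converge to
$\theta_m + \theta_o/2$ and $\theta_o + \theta_m/2$ and are attenuated —
the contrast the partitioning exists to remove.

## Power calculator

`power_maternal()` computes noncentral $\chi^2_1$ power with the
asymptotic variance of $\hat\beta_m$ from the expected Fisher
information of the Gaussian covariance block, summed over patterns as
$\sum_p n_p I_p$ and inverted. Because observed-variable means are free,
the mean block decouples and is omitted. Effects are standardized to
unit phenotype variance: $q_m$ is interpreted as the marginal variance
explained by the maternal path, $\beta_m = \sqrt{q_m/\Phi}$ with
$\Phi = 2\,\mathrm{maf}(1-\mathrm{maf})$; the residual correlation
argument is scaled onto the residual variances. For the pairs design the
numeric information reproduces the conditional-regression closed form
$\sigma^2/(n\Phi(1-0.25))$ to $10^{-6}$ relative error (a test), and the
duo SEM approaches the pairs design as the residual correlation
approaches one half.

## The simulator, and what passing tests do and do not show

`simulate_families()` draws founder genotypes from Hardy–Weinberg
equilibrium and transmits *alleles* (a parent with dosage $g$ transmits
with probability $g/2$ — exact Mendelian segregation at a biallelic
locus), so the 0.5 path and the $\Phi/4$ grandmother–grandchild
covariance emerge from the sampling scheme rather than being imposed;
this keeps the covariance-algebra oracles non-circular.
`simulate_mr_study()` builds multi-SNP studies with exposure effects
$\mathcal{N}(0.08, 0.02^2)$, MAF uniform on $(0.05, 0.5)$, optional
directional pleiotropy, and either an individual-level duo cohort (all
loci additive, unit phenotype variance, residual correlation 0.2 by
default) or summary statistics with a configurable overlap fraction.
`simulate_gwas_zscores()` is a separate stylized generator for the LDSC
intercept, with LD scores drawn from a shifted gamma distribution.

Deliberate simplifications: no linkage disequilibrium between
instruments (IVW and Egger assume independence anyway), no assortative
mating, no paternal genetic effects, no parent-of-origin or dominance
effects, continuous liability-scale exposures rather than case–control
log-odds, and Gaussian residuals. Passing tests therefore demonstrate
correctness of the estimators *under the model's own assumptions* — not
robustness to the violations (population stratification, paternal
effects, measurement error in self-reported phenotypes) that real
cohorts bring.

Problem sizes in the test suite were chosen to make Monte-Carlo noise
small relative to the asserted tolerances while keeping the default run
desk-sized: the moment oracle uses $10^6$ records, parameter-recovery
$5\times10^4$ duos, bias and calibration suites 200–500 replicates at
$5\times10^3$ duos, and the end-to-end MR recovery 402 instruments on
$2\times10^4$ duos with acceptance at three simulation standard errors.

## Known limitations

* The SEM surface models one locus at a time; genome-wide scans loop
  over loci (`fit_sem_loci()`), and multi-locus fits are out of scope.
* Offspring genotype, when actually observed, is used only through the
  conditional regression; an SEM variant with observed offspring
  genotype (and hence a three-way combined design at the individual
  level) is not implemented, so SEM-versus-pairs comparisons are
  asymptotic, not record-level.
* LD scores are inputs; computing them from reference panels is not in
  scope.
* Multivariable MR and modal estimators are not provided.

## A worked example

```{r example}
sim <- simulate_mr_study(n_snps = 60, n_both = 8000, theta_m = 0.3,
                         theta_o = -0.2, mode = "summary",
                         n1 = 3e5, n2 = 3e5, seed = 7)
outcome <- fit_sem_summary(sim$own_gwas, sim$off_gwas, intercept = 0)
grid <- mr_pipeline(sim$exposure, outcome, seed = 7)
grid |>
  filter(method == "ivw") |>
  select(arm, adjustment, estimate, se, p, q_statistic, n_snps)
```

The partitioned (sem) rows recover the generating causal effects
$(0.3, -0.2)$; the unadjusted rows sit near the mixtures
$\theta_m + \theta_o/2 = 0.2$ and $\theta_o + \theta_m/2 = -0.05$ —
attenuated, as unpartitioned analyses are whenever the two effects
oppose each other.
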