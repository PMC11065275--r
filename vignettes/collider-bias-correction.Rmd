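---
title: "Correcting collider bias in covariate-adjusted GWAS with robust multivariable MR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting collider bias in covariate-adjusted GWAS with robust multivariable MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colliderMR)
```

## The problem

A conditional GWAS regresses a trait $Y$ on each SNP $G_i$ together with a
set of covariates, either to estimate direct SNP effects or to gain power by
absorbing non-genetic variation. When a covariate $H_k$ is heritable and is
also influenced by an unmeasured confounder $U$ that affects $Y$, the
covariate is a collider: conditioning on it opens a spurious path
$G_i \to U \to Y$. With $p_2$ such covariates
$H = (H_1, \dots, H_{p_2})^\top$, the conditional effect decomposes as

$$\beta_{G_iY}^{C} \;=\; \beta_{G_iY} \;+\; b^\top \beta_{G_iH},$$

a direct effect plus a bias that is linear in the SNP's covariate effects
with a slope vector $b$ shared by all SNPs. Under the linear structural
model (covariates possibly adjusted for their own extra covariates $V$, the
outcome regression additionally containing non-heritable covariates $J$),

$$b = -\beta_{UY}\,\mathrm{Var}(U)\, M\,\beta_{UH}, \qquad
M^{-1} = \beta_{UH}\beta_{UH}^\top \mathrm{Var}(U) + \mathrm{Cov}(E_H)
 + B_{VH}\mathrm{Cov}(V)B_{VH}^\top
 - B_{VH}\mathrm{Cov}(J,V)^\top\mathrm{Cov}(J)^{-1}\mathrm{Cov}(J,V)B_{VH}^\top,$$

implemented in `trueSlope()` and verified against the empirical
conditional-GWAS regression in the test suite. Estimating $b$ from summary
statistics is a multivariable Mendelian randomization (MVMR) problem: the
instrument-outcome association (conditional scale) is regressed on the
instrument-covariate associations, with the twist that here the "pleiotropy"
to be excluded is exactly the direct SNP effect one ultimately wants to keep
for non-instrument SNPs.

## Slope estimation by constrained maximum likelihood

For $l$ approximately independent instruments $Z_j$ with effect vectors
$\hat\beta_j = (\hat\beta_{Z_jY^C}, \hat\beta_{Z_jH_1}, \dots)^\top$ and
per-instrument covariances $\Sigma_j$, the Gaussian summary-data likelihood
has mean $(b^\top\beta_{Z_jH} + r_j,\ \beta_{Z_jH}^\top)^\top$, where $r_j$
is a free outcome intercept that is nonzero only for invalid instruments.
`fitFixedK()` maximises the likelihood under the constraint that exactly
$K$ intercepts are nonzero, with a coordinate scheme whose three steps are
each exact partial maximisations:

1. given $b$, each instrument's likelihood gain from being declared invalid
   is the profiled quadratic
   $q_j(b) = (\hat\beta_{Z_jY^C} - b^\top\hat\beta_{Z_jH})^2 / (v^\top \Sigma_j v)$
   with $v = (1, -b^\top)^\top$; the invalid set is reset to the $K$ largest
   $q_j$ (ties by index);
2. given $b$ and the invalid set, each $\beta_{Z_jH}$ solves its generalised
   least-squares subproblem (invalid instruments are fitted exactly, their
   contribution vanishing);
3. given the $\beta_{Z_jH}$, $b$ solves a weighted least squares over the
   valid instruments.

Each step cannot decrease the log-likelihood, so the iteration converges
monotonically; we stop when the log-likelihood changes by less than
`tol` ($10^{-8}$ by default, `max_iter` 500). The surface is multimodal, so
the best of `n_starts` initialisations is kept: the multivariable IVW
estimate, elemental starts (exactly-identified fits on random $p_2$-subsets
of instruments, which diversify the implied valid/invalid split, in the
spirit of elemental-subset searches in robust regression), and random
perturbations of the IVW start at alternating local (sd $0.5$) and global
(sd $2$) scales. The exhaustive oracle
`cmlOracle()` — enumeration of all invalid subsets with generic numerical
optimisation of the profile likelihood — defines correctness; the
acceptance suite requires agreement on at least 95% of random
model-generated panels.

$K$ is selected by `mvmrCML()` over $0, \dots, l - p_2 - 1$ with
$\mathrm{BIC}(K) = -2\mathcal{L}(K) + K\log N$, $N$ the minimum GWAS sample
size, ties resolved to the smaller $K$ (parsimony). The covariance of
$\hat b$ is the inverse observed Fisher information over the selected valid
instruments (`fisherCov()`, checked against a finite-difference Hessian).
A data-perturbation covariance (`perturbCov()`) is provided as an option
for any estimator; it is the default for the comparator estimators, whose
sampling distributions lack a likelihood-based covariance.

Comparators follow their standard constructions: multivariable IVW
(weights $1/\hat\sigma^2_{Z_jY^C}$, multiplicative random-effects scale
floored at 1), MVMR-Egger with default coding (rows reoriented to positive
effects on the first covariate; the intercept reported as a
directional-pleiotropy diagnostic), MVMR-Lasso (per-instrument intercepts
with an $L_1$ penalty chosen by the heterogeneity stopping rule: the
largest penalty whose zero-intercept set passes a 95% chi-squared
heterogeneity test; post-lasso IVW refit), MVMR-median (weighted $L_1$
regression through the origin by iteratively reweighted least squares),
and, for a single covariate, the Dudbridge-style estimator with the
Hedges–Olkin reliability ratio correcting regression dilution.

## Correction and inference

`correctPanel()` subtracts $\hat b^\top \hat\beta_{G_iH}$ from every
conditional estimate and propagates uncertainty with the independence-form
variance

$$\hat\sigma^2_{G_iY} = \hat\beta_{G_iH}^\top \hat\Sigma_{\hat b}\hat\beta_{G_iH}
 + \textstyle\sum_k \hat b_k^2 \hat\sigma^2_{G_iH_k}
 + \sum_k \hat\sigma^2_{\hat b_k} \hat\sigma^2_{G_iH_k}
 + \hat\sigma^2_{G_iY^C},$$

used for all estimators. Every term is nonnegative for a PSD
$\hat\Sigma_{\hat b}$, so the corrected standard error can never fall below
the raw one — correcting for more heritable covariates costs power. The
full constrained-ML variance that additionally accounts for correlations
between $\hat b$ and the per-SNP summary statistics (and for LD between the
tested SNP and the instruments) is not implemented here; a plug-in
covariance hook would slot into `correctSnp()` where the first term is
formed. Wald tests are two-sided normal; locus counting maps significant
SNPs to half-open LD-block intervals, with SNPs outside every block counted
as singleton loci (a reporting choice; such SNPs are logged).

Instrument hygiene follows GWAS practice: greedy positional LD pruning
(keep-first within a trailing window, defaults window 50 SNPs and
$r^2 < 0.001$), relevance selection by the minimum covariate p-value
(default $5\times10^{-10}$), sample-overlap correlations estimated as the
Pearson correlation of null z-scores (SNPs with $p > 0.1$ for both traits
of a pair, pairwise-complete and repaired to the nearest PSD correlation —
pairwise estimates need not be jointly PSD), per-instrument covariances
$\Sigma_j[s,t] = \mathrm{corr}[s,t]\,\mathrm{se}_{js}\,\mathrm{se}_{jt}$,
and Sanderson-style conditional F statistics
($Q_k/(l - p_2 + 1)$ with a delta-method residual variance; for one
exposure this is the mean squared instrument z-score), flagging exposures
below the conventional threshold of 10. Allele harmonisation aligns every
covariate panel to the outcome panel's effect-allele orientation, flipping
signs for swapped alleles and dropping strand-ambiguous (A/T, C/G)
variants by default — a conservative choice made without allele-frequency
information.

## The synthetic cohort

`simConfig()`/`drawEffects()`/`runExperiment()` implement the type-I error
and power study. A cohort of `n_individuals` carries 1000 focal SNPs and
3000 extra null SNPs on a separate chromosome; among the focal SNPs, 50
affect the covariates only, 50 the outcome only, 50 both (for these,
effects on $Y$ and on $H_1$ are bivariate normal with correlation `rho`),
and the rest are null. Thirty SNPs serve as instruments: the valid ones
drawn from the covariate-only class, the invalid ones (30% or 50%) from the
pleiotropic class. Effects are drawn once per configuration and held fixed;
genotypes, confounder and noises are redrawn each replicate. The GWAS of
$Y$ adjusts for all covariates; each covariate's GWAS is marginal. The
overlap correlation is re-estimated each replicate from the extra null
SNPs' z-scores, mimicking the one-sample design.

Two readings of the variance budget are arithmetically consistent with
"the confounder accounts for 40% of the unknown variance and each error
term for 10% of the total": 40% of the *non-genetic* variance, or 40% *of
the total*. They differ sharply in the implied collider-bias strength: the
non-genetic reading forces a genetic share of 5/6 and a bias too weak to
inflate type-I error noticeably at cohort sizes in the tens of thousands,
whereas the of-total reading (genetics 50%, confounder 40%, noise 10%)
yields pre-correction type-I error around 0.7 for covariate-affecting SNPs
at $n = 20{,}000$ — the regime the study design describes. The package
therefore uses the of-total reading, solved self-consistently per trait
(for the outcome, whose total includes the mediated covariate contribution
and a confounder cross-covariance, the budget is a quadratic in
$\sqrt{\mathrm{Var}(Y)}$ solved in closed form). Effect sizes stay exactly
as drawn (standard normal); nothing else is rescaled.

Because the phenotypes sum over all SNPs, the structural "noise" seen by
any single tested SNP includes the polygenic background of the others. The
population bias slope the estimators target is therefore the generalised

$$b = -\mathrm{Cov}(Z)^{-1}\left[\beta_{UH}\beta_{UY}\mathrm{Var}(U)
 + \mathrm{Cov}(Z_g, W_g)\right],$$

with $Z$ the per-SNP structural residual of $H$ (polygenic background
$Z_g$ + confounder + noise) and $W_g$ the polygenic background of the
direct outcome effects. This reduces to the confounder-only expression
when the backgrounds vanish, and the cross-covariance term —
a fixed, realised quantity even with uncorrelated pleiotropy — is the same
order as the confounder term under the study design. `SimTruth@true_b`
stores this value (estimated against a 20,000-individual reference
genotype draw inside the config-seeded stream); `trueSlope()` remains the
pure structural formula.

Genotypes are Binomial(2, MAF) dosages, MAF uniform on (0.05, 0.5),
centred per column. Two modes are provided. The default, independent SNPs,
matches the layout the calibration targets specify. The block-correlated
mode places the focal SNPs in 20 blocks with an exchangeable latent
correlation (0.1 by default) dichotomised at Hardy–Weinberg quantiles,
non-null SNPs confined to the first half of the blocks and null SNPs to
the second, so nulls never share a block with causal SNPs. This mode is an
*upper envelope* for residual post-pruning LD: it correlates every
within-block pair at the full parameter value, whereas random draws from
pruned biobank blocks are mostly uncorrelated. The consequence is
quantifiable and uncorrectable by design — the corrected estimate of a
covariate-only SNP retains the leaked direct effects
$\sum_k r_{ik}\beta_{G_kY}$ of its neighbours — and with 14 correlated
neighbours per SNP this leakage dominates the corrected z-scores.
Simulation studies of the correction itself therefore run on independent
genotypes; the block mode is exercised by the unit tests and available for
sensitivity analyses of LD leakage.

What the generator does not emulate: real LD patterns (decaying,
signed, heterogeneous), allele-frequency/effect-size coupling, binary
traits (the model is linear throughout), population structure or
relatedness, and genotyping error. Calibration on these synthetic cohorts
therefore shows that the estimator and variance propagation are correct
under the stated model, not that real-data corrections are unbiased.

## Problem sizes and numerical choices

The acceptance-level simulations use $n = 20{,}000$ individuals and 200
replicates per scenario ($p_2 = 1, 2, 4$; 30% invalid instruments;
$\rho = 0$), with 3 coordinate-descent starts per fit inside the
experiment harness (warm-started across the $K$ scan; standalone fits
default to 10 starts). Parameter-recovery and variance-calibration runs
use the same design at $n = 20{,}000$ (all-valid instruments) and
$n = 10{,}000$ / 100 replicates respectively. Dosage generation uses an
internal xoshiro256++ stream seeded from R's RNG, so `set.seed()` fully
determines every replicate. Other numerical choices: BIC ties go to the
smaller $K$; the degenerate $K = l - p_2 - 1$ stays in the candidate set;
near-singular $\Sigma_j$ are ridge-repaired by $10^{-10}\,\overline{\mathrm{diag}}$;
the nearest-PSD repair of the overlap correlation clips negative
eigenvalues and renormalises the diagonal; instrument-selection requires
$l \ge p_2 + 2$ while the panel container itself only requires the
estimable minimum $l \ge p_2 + 1$ (IVW's requirement).

## Known limitations

The comparator estimators treat the instrument-covariate effects as known
(the NOME assumption): with noisily estimated covariate effects their
slopes attenuate toward zero by the classical regression-dilution factor —
about half a percent of the slope under the simulation conditions, visible
in mean-recovery studies once the Monte-Carlo error is small enough. cML
models the covariate-side measurement error explicitly and does not share
this bias; DHO corrects it with the Hedges–Olkin reliability ratio.
The full model-selection uncertainty of the BIC step is not propagated by
default (the data-perturbation option exists but multiplies runtime by the
number of perturbations); with 50% invalid instruments the selected-model
Fisher covariance is expected to be optimistic. The Egger orientation is
anchored to the first covariate and errors out when all its instrument
effects are zero rather than guessing an orientation. Binary outcomes are
out of scope: the decomposition is derived for linear models, and logistic
conditional GWAS with strong covariates is not well approximated by it.
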