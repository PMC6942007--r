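---
title: "Methods: simulating population stratification and probing its correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating population stratification and probing its correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratsim)
```

## The generative model

`stratsim` simulates a single admixed cohort formed from two source
populations whose allele frequencies have diverged, and a phenotype that
can be linked to ancestry through two distinct pathways — a genuinely
genetic one and an environmental one. Every analysis in the package is a
question about what happens to standard methods (PCA correction, ridge
BLUP prediction, two-sample Mendelian randomization) when one or both of
those pathways are active.

For individual $i$ and SNP $l$:

* **Admixture.** $a_i \sim \mathrm{TruncNorm}(a_0, \sigma_a^2)$ with
  $\sigma_a^2 = a_0(1-a_0)/L_{\mathrm{eff}}$, the variance expected if
  ancestry were a binomial average over $L_{\mathrm{eff}}$ independent
  "loci"; small $L_{\mathrm{eff}}$ means recent admixture. Truncation is
  implemented by *clamping* to $[0,1]$, not rejection, deliberately: mass
  may sit exactly at 0 and 1, so pure-ancestry individuals exist.
* **Frequencies.** Ancestral $p_l \sim U(0.05, 0.5)$; population
  frequencies $p_{l1} \sim \mathrm{TruncNorm}(p_l(1 + c_l s),\,
  p_l(1-p_l)\sigma_p^2)$ and $p_{l2} \sim \mathrm{TruncNorm}(p_l,\,
  p_l(1-p_l)\sigma_p^2)$, clamped to $[0,1]$ so drift can fix or lose
  alleles. The shift $s$ acts on causal SNPs ($c_l = 1$) in Population 1
  only — a stylized "selection or extreme drift" that makes the trait's
  genetics genuinely ancestry-associated.
* **Architecture.** A random fraction (`causal_fraction`) of SNPs is
  causal with $\beta_l \sim U(0,\, \beta_0\, p_l(1-p_l))$, zero otherwise.
* **Genotypes.** $X_{il} \sim \mathrm{Bernoulli}(a_i p_{l1} +
  (1-a_i) p_{l2})$: 0/1 dosages, SNPs independent given ancestry (no LD).
  A `diploid = TRUE` option draws two alleles per cell but is off by
  default; the model as stated is haploid.
* **Phenotype.** $Y^G_i = \sum_l X_{il}\beta_l$ standardized to sample
  mean 0 and variance 1 (denominator $N-1$ throughout the package);
  environmental exposure $E_i = (a_i - a_0)/\sigma_a$, which has expected
  variance 1; and
  $Y_i = h\,Y^G_i + (1-h)\,e\,E_i + (1-h)(1-e)\,\varepsilon_i$ with
  $\varepsilon_i \sim N(0,1)$.

Defaults are the model's reference configuration: $N = 2000$, $L = 4000$,
$L_{\mathrm{eff}} = 20$, $a_0 = 0.4$, $\beta_0 = 1$, $s = 0.2$,
$h = e = 0.5$. Two constants are package choices, exposed as parameters:
`sigma_p2 = 0.01` (drift scale) and `causal_fraction = 0.1` (400 causal
SNPs at the default $L$).

Reproducibility: one master seed per parameter set; every stage
(admixture, frequencies, architecture, genotypes, noise, …) draws from a
deterministic substream of it, so any stage can be re-run in isolation
and test cohorts (`make_cohort(..., rep = 1)`) are independent of their
training cohort while sharing its frequency model and architecture.

## What the generator emulates — and what it does not

The simulator reproduces the *confounding geometry* of an admixed GWAS
cohort: a single continuous ancestry axis that tilts both allele
frequencies and environment. It has no coalescent history, no
recombination map, no LD within populations, and no selection dynamics —
the drift and selection terms are single-generation Gaussian
perturbations. A green test therefore establishes that a method behaves
as claimed *under this confounding geometry*; it says nothing about LD
leakage, relatedness structure, or multi-axis ancestry, all of which are
absent by construction. The haplotype-sharing matrices
(`synth_sharing_matrix()`) likewise emulate only the compositional
geometry of chromosome-painting output — Dirichlet rows around group
profiles with a fixed row total — not the painting model itself.

## Detecting structure

`compute_pcs()` standardizes each SNP to unit variance (plain PCA
convention, not the $\sqrt{p(1-p)}$ scaling), drops monomorphic SNPs,
and fixes every axis sign by "largest-magnitude loading is positive" so
results are deterministic. `detectability()` implements the
phase-transition rule $D = F_{ST}\sqrt{NL} > 1$: below it the leading
eigenvector is asymptotically uninformative about ancestry.
`n_detectable_pcs()` is the finite-sample counterpart — the count of
eigenvalues of the standardized kernel (scaled by $1/L$) above the
Marchenko–Pastur bulk edge $(1+\sqrt{n/L})^2$. The
`empirical_fst()` estimator is Hudson's ratio of averages with
finite-sample correction, clamped at zero — a documented package choice,
since no single FST estimator is canonical for this use.

A consequence worth stating plainly, because it shaped a default: at the
package default `sigma_p2 = 0.01`, the effective differentiation along
the admixture gradient is roughly $2\sigma_p^2 \mathrm{var}(a) \approx
2.4\times10^{-4}$, giving $D \approx 0.7$ at $N = 2000$, $L = 4000$ —
*below* the detection threshold. Structure is present but invisible to
PCA, and PC "correction" removes nothing. This is itself one of the
phenomena the package demonstrates. But the prediction scenarios exist
to contrast corrected against uncorrected arms, so `run_scenario()`
raises the drift scale to `sigma_p2 = 0.1` in both cases (overridable
via `case_overrides`), which puts one ancestry axis cleanly above the
threshold.

## Prediction scenarios

`fit_marker_blup()` fits $y = Wb + Xu + \varepsilon$,
$u \sim N(0, \sigma_u^2 I)$, by REML: the genotype kernel
$K = X_cX_c^\top$ is eigendecomposed once, the rotation diagonalizes the
covariance, and the restricted likelihood becomes a one-dimensional
function of $\delta = \sigma_e^2/\sigma_u^2$, optimized over
$\log\delta \in [-25, 25]$ with relative tolerance $10^{-8}$. Given
$\hat\delta$, the marker effects equal the closed-form ridge solution
$(X_c^\top X_c + \hat\delta I)^{-1}X_c^\top(y - W\hat b)$ — the test
suite verifies this equivalence to $10^{-6}$. A residual marker variance
below $10^{-12}$ (e.g., constant $y$) falls back to the
fixed-effects-only fit rather than erroring at the search boundary.

Out-of-sample prediction is the genetic score only (raw genotypes times
marker effects plus intercept): the point of the exercise is what the
*genetic* predictor carries, and covariate contributions can be added
explicitly with `include_covariates = TRUE`. Headline accuracy is the
Pearson correlation, with MSE and $R^2$ always reported alongside,
since "prediction accuracy" names no metric.

The two cases are: Case 1 `{s = 0.2, e = 0, sigma_p2 = 0.1}` — trait
genetics truly ancestry-associated; PC correction discards real signal
and lowers test accuracy. Case 2 `{s = 0, e = 0.5, sigma_p2 = 0.1}` —
ancestry predicts environment only; the uncorrected predictor fits the
environmental component through ancestry-informative SNPs, which flatters
it on a test cohort in the same environment and penalizes it (in MSE)
once `decouple_environment()` permutes the exposure across individuals.
Replicate counts are a runtime choice, not a model statement; the
acceptance suite uses 20 and evaluates the contrasts as paired one-sided
sign tests, since the source figures are plots without printed numbers.

## Two-sample Mendelian randomization

`two_sample_experiment()` instantiates the violated-assumption scenario
concretely: exposure $T$ is the simulated phenotype, outcome
$O = \gamma T + \delta A + N(0,1)$ where $A$ is standardized ancestry —
$\delta \neq 0$ is a direct ancestry-to-outcome path. Causal SNPs are
instruments; each sample runs its own per-SNP GWAS (`snp_summaries()`,
covariates = that sample's own PCs) and the ratios are pooled by
fixed-effect IVW with a weak-instrument guard $|z| \ge 3$ on the
exposure side. The Wald-ratio standard error uses the full first-order
delta method (both error terms), bootstrap-checked in the tests.

Three arms make the differential-correction story testable:
`uncorrected`, `equal_full` (the same individuals re-split into equal
halves, both fully corrected — the benign design), and `differential`
(unequal split, each sample keeping only the PCs its own eigenvalues
support under the Marchenko–Pastur rule, so the small sample
under-corrects). The magnitudes of $\gamma$ and $\delta$ are user
parameters; nothing numeric is claimed about them beyond direction and
monotonicity, which is what the tests assert.

One honest caveat, visible in the tests: with $\gamma \neq 0$ the IVW
estimate carries a small attenuation toward zero from weak-instrument
selection (instruments are chosen by their $z$-score in the same
exposure sample that estimates their effect). This is a property of the
estimator, proportional to $\gamma$ and absent at $\gamma = 0$, which is
where exact unbiasedness is asserted; the $\gamma = 0.5$ recovery check
passes within its stated 3-standard-error tolerance with the attenuation
included.

## Reference-panel projection

`fit_reference_basis()` centers and standardizes the columns of a
reference individuals-by-populations sharing matrix and takes its SVD;
`project_cohort()` maps cohort rows through the *reference* center and
scale into the right singular vectors, so a cohort row equal to a
reference row reproduces that reference individual's coordinates
exactly. `variance_explained()` is plain OLS $R^2$ (joint, plus
per-component marginals) of a phenotype on score columns.
`kernel_smooth_2d()` smooths a phenotype over two score axes with a
Gaussian kernel of user bandwidth and masks any grid node farther than
`max_dist` (default 0.03, honored exactly) from every observation; the
source analysis used a GAM smoother, of which only the masking radius is
specified, so the kernel itself is a package choice. The axis pair is a
free argument — the source material names its own smoothing axes
inconsistently, and the package does not attempt to resolve that.

## Numerical conventions and degenerate inputs

* Sample variance uses denominator $N-1$ everywhere, including the
  standardization of $Y^G$.
* All truncated normals are clamped, never rejected; boundary values are
  legal outputs and legal inputs downstream.
* PC and SVD axis signs: largest-magnitude loading positive.
* Monomorphic SNPs: dropped with a warning in PCA and per-SNP
  regressions (silently inside replicate engines, where they are
  routine); an all-monomorphic matrix errors.
* Zero genetic variance (no causal SNP segregating) and $\sigma_a = 0$
  with $e > 0$ are hard errors with diagnostic messages, not NaNs.
* `floor`/`round` conventions: the causal count is
  `round(causal_fraction * L)` and must be at least 1.

## Known limitations

No LD, no relatedness, a single ancestry axis, haploid dosages by
default, fixed-effect IVW only (no Egger/median/mode), no Tracy–Widom
eigenvalue test (the Marchenko–Pastur edge count stands in), and the
sharing-matrix generator is synthetic plumbing, not a painting model.
Real-cohort magnitudes (variance explained in an actual cohort, absolute
MR bias sizes) are outside what this stated world can reproduce and are
deliberately not asserted anywhere in the tests.
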