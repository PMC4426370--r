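---
title: "Pathway factor phenotypes in twin expression cohorts: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway factor phenotypes in twin expression cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinfact)
```

## The analysis in one paragraph

Bulk expression matrices carry broad, mostly technical, correlated
variation on top of the biology of interest. `twinfact` implements a
two-stage factor-analysis pipeline for twin cohorts: first a small number
of *global factors* (plus observed technical covariates: batch, RNA
quality, RNA concentration) is fitted to the whole matrix and regressed
out; then, for each annotated pathway, the residual expression of the
pathway's genes is summarized as K *pathway factor phenotypes* — weighted
sums of member-gene expression. Each phenotype is treated as a derived
trait: it is tested for a linear age effect with a twin linear mixed model
and a likelihood-ratio test, and its variance is decomposed into
additive-genetic (h²), shared-environment (c²), unique-environment (e²)
and fixed-age components using the monozygotic/dizygotic covariance
contrast. A single-gene scan with Fisher-exact gene-set enrichment
provides the classical alternative for method comparison.

## The factor model

Both stages use the same engine, `fit_factor_model()`. The model is

$$Y \approx C B + X W^\top + \varepsilon,\qquad
\varepsilon_{ig}\sim N(0, \psi_g),$$

with $Y$ an $n\times G$ samples-by-genes matrix, $C$ observed covariates
(unpenalized fixed effects), $X$ latent factor scores and $W$ gene
weights. Estimation is expectation–maximization with the scores as latent
variables. Each factor's weight column carries an automatic relevance
determination (ARD) precision $\alpha_k$ with a Gamma(10⁻³, 10⁻³)
hyperprior, so factors the data do not support are shrunk toward zero; the
maximized objective (observed-data log-likelihood plus weight and
precision log-priors) is non-decreasing across iterations, which the test
suite asserts on the stored trace.

Numerical choices:

* **Initialization** is deterministic — scores start at the top-K left
  singular vectors of the covariate-adjusted matrix — so repeated fits are
  bit-identical without any seed.
* **Convergence**: relative objective change below `tol = 1e-6`, at most
  `max_iter = 1000` iterations; non-convergence sets a flag and warns but
  does not error.
* **Identifiability**: after fitting, each score vector is standardized to
  unit variance (weights absorb the scale) and signs are chosen so the
  gene with the largest absolute weight loads positively. Factor signs are
  otherwise arbitrary — genes may contribute positively or negatively to
  the weighted sum — and this convention makes downstream age-effect signs
  reproducible.
* **Variance accounting** is by sequential orthogonal projection (QR) of
  the covariate-adjusted data onto the score columns: per-factor fractions
  are incremental $R^2$ values that are guaranteed to lie in [0, 1] and to
  sum exactly to the total. A shrunk-weight reconstruction would not give
  either guarantee.
* **`K = 0`** collapses to ordinary covariate regression, the natural null
  configuration.

`residualize()` removes the fitted signal by ordinary least squares on the
combined design `[C, X]`, so residual gene vectors are orthogonal to every
covariate and factor score to numerical precision (< 1e-8 in the tests).
The EM weights are kept only for interpretation and the variance ledger.

With a flat prior (`ard = FALSE`) and isotropic noise the model is
probabilistic PCA and the fitted score space coincides with the top-K
singular subspace — used as an independent spectral oracle in the tests.

## Pathway phenotypes

`filter_pathways()` retains gene sets with *strictly more than*
`min_genes = 10` members present in the matrix — a set with exactly ten
present genes is excluded — and trims membership to present genes. With
186 retained pathways and the default `K = 5`, the pipeline yields
186 × 5 = 930 phenotypes, and the genome-wide Bonferroni threshold at
α = 0.05 is 0.05/930 ≈ 5.38×10⁻⁵.

Per-pathway fits use no covariates: global confounders were removed once,
globally, and re-adjusting per pathway would double-count. Genes belonging
to several pathways participate in each of them, so phenotypes of
overlapping pathways can be correlated; this mirrors how curated pathway
collections overlap and is deliberate. Within a pathway, factors are
ordered by variance explained (descending; ties by original index).

Small pathways can hold less structure than K factors, and ARD may shrink
a factor to numerically zero scores. Because every pathway contributes
exactly K tested phenotypes, collapsed factors are completed
deterministically with the leading principal directions of the pathway
submatrix after removing the surviving factors — the directions that
would explain the next-most variance — standardized to unit variance.

## The twin mixed model

For phenotype $y$ with mean $\beta_0 + \beta_{\text{age}}\,\mathrm{age}$,
the covariance is built from three components in the nested
random-effects convention: a pair-shared intercept with variance
$\sigma^2_{\text{pair}}$, an extra effect with variance
$\sigma^2_{\text{mz}}$ whose level is shared by MZ co-twins but unique to
every DZ twin and singleton, and unique-environment noise
$\sigma^2_{\text{res}}$. Hence every individual has marginal variance
$\sigma^2_{\text{pair}} + \sigma^2_{\text{mz}} + \sigma^2_{\text{res}}$,
while

$$\mathrm{cov}(\text{DZ pair}) = \sigma^2_{\text{pair}},\qquad
\mathrm{cov}(\text{MZ pair}) = \sigma^2_{\text{pair}} + \sigma^2_{\text{mz}}.$$

Equal marginal variances across zygosity classes are essential: they make
covariance contrasts equal correlation contrasts, so the additive-genetic
variance is read off one parameter as $2\sigma^2_{\text{mz}}$ — twice the
additional MZ-over-DZ co-twin resemblance. This is also exactly the model
fitted by a nested `(1 | family) + (1 | mz_unit)` random-effects formula,
and the test suite verifies log-likelihood and component agreement with
`lme4` on mixed cohorts. An alternative convention that adds
$\sigma^2_{\text{mz}}$ to the MZ diagonal only was considered and
rejected: it implies unequal MZ/DZ variances, breaks the
correlation-contrast reading of heritability, and is measurably biased on
classical ACE-generated data.

Fitting is maximum likelihood, not REML, because the age test compares
models differing in a fixed effect. The likelihood is evaluated family
block by family block in closed form (co-twins share age, so each pair
factorizes into sum and difference components), the fixed effects are
profiled out by generalized least squares, and L-BFGS-B maximizes over the
three variance components (bounded at zero, boundary permitted) from
three deterministic starts: method-of-moments from co-twin
cross-products, an equal split, and residual-only. The best optimum is
kept; everything is deterministic. `twin_loglik()` is checked against a
dense multivariate-normal oracle over a thousand random parameter draws.

`lrt_age()` computes $2(\ell_{\text{full}} - \ell_{\text{null}})$ floored
at zero against $\chi^2_1$. Under the null this test is calibrated: over
2000 simulated null phenotypes the 5% rejection rate lands inside the
binomial [0.040, 0.061] band in the acceptance suite.

## Variance decomposition

With the full fit, the total model-implied variance is

$$V = \mathrm{var}(\beta_{\text{age}}\,\mathrm{age}) +
\sigma^2_{\text{pair}} + \sigma^2_{\text{mz}} + \sigma^2_{\text{res}},$$

using the population variance of the fitted age term over the analyzed
cohort. Components: genetic $= 2\sigma^2_{\text{mz}}$, shared environment
$= \sigma^2_{\text{pair}} - \sigma^2_{\text{mz}}$, unique environment
$= \sigma^2_{\text{res}}$, age as above. Each is divided by $V$; negative
implied shares (possible when $\sigma^2_{\text{mz}} > \sigma^2_{\text{pair}}$)
are clipped at zero and the four shares renormalized to sum to one, so all
outputs lie in [0, 1]. The shares are scale-free, so no explicit phenotype
standardization is needed. `age_share_env` is the age share of the
non-genetic variance, `age_share_total / (1 - h2)`.

A boundary effect is worth knowing about: for a phenotype with true
h² = 0, the sampling noise of the MZ−DZ contrast (sd ≈ 0.17 at 250 + 250
pairs) is folded upward by the [0, 1] constraint, so the *mean* estimate
at the boundary is positive (≈ 0.07 at that design) even though the
median stays at zero. This is a property of any constrained estimator at
a boundary, not of the optimizer; away from the boundary (h² = 0.3, 0.6)
the estimator is unbiased well within ±0.05 at the same design.

## Permutations, multiple testing, enrichment

`permute_cohort()` builds empirical nulls by reassigning family-level
identity and age among family units *within* each stratum — MZ pairs with
MZ pairs, DZ pairs with DZ pairs, singletons with singletons — keeping
twin pairs together and phenotype values attached to individuals. The age
multiset, zygosity labels and pair structure are exactly preserved; on a
2 MZ + 2 DZ cohort the reachable assignments are exactly the 2 × 2
within-stratum permutation group, verified by enumeration. Ten permuted
analyses pooled (the default) give the customary Q-Q null band.

Multiple testing: genome-wide Bonferroni at α/n for the 930 phenotypes
and for single-gene scans; Benjamini–Hochberg q-values for the gene list
(the standard step-up choice where only "FDR" is specified); and a
*within-pathway* Bonferroni (α divided by the pathway's gene count) for
the follow-up that traces which member genes drive a significant pathway.
Enrichment uses the one-sided (greater) Fisher exact test per pathway
against a configurable universe — defaulting to all genes in the analyzed
matrix, since the alternative (pathway-annotated genes only) is a
documented option rather than a clear standard. Method concordance is
summarized by Spearman rank correlation (midrank ties, asymptotic p)
between each pathway's minimum factor p-value (Šidák-adjusted min
available) and its enrichment p-value.

## The synthetic-data generator

`generate_cohort()` + `simulate_truth()` + `generate_expression()` emulate
a female twin registry expression study with known ground truth:

* **Cohort**: configurable MZ/DZ pair and singleton counts (default
  168 MZ + 260 DZ pairs, i.e. 336 + 520 individuals); ages drawn from a
  normal distribution truncated to [39, 85] whose location is tuned by
  root-finding so the truncated mean hits 59; co-twins share family id
  and age. The true age distribution of such registries is reported only
  by range and mean, so the truncated normal (sd 12 years) is a stand-in.
* **Global confounders**: `k_global = 5` unit-variance factors with
  Gaussian weights (sd √0.06), giving an expected ≈ 30% of variance —
  broad, technical-like variation for the global stage to remove.
* **Pathway modules**: one latent module score per pathway loading
  (√0.3) on a default 30% of member genes, so pathway factor analysis has
  a plantable, recoverable target. The module latent itself carries an
  A/C/E split (default 0.6/0.1/0.3), making planted modules heritable
  phenotypes — this is what gives the pipeline's central contrast
  (phenotypes more heritable, less noise-driven than genes) something
  real to detect.
* **Gene-level ACE**: additive-genetic effects shared exactly between MZ
  co-twins and correlated 0.5 between DZ co-twins (the standard additive
  assumption the 2×(rMZ − rDZ) estimator presupposes), shared environment
  within any pair, independent noise; defaults v_a = 0.15, v_c = 0.05,
  v_e = 0.5 per gene, leaving the rest of the unit budget to signal.
* **Age effects**: a fixed slope (default 0.02 expression units/year) on
  the module genes of the first `n_age_pathways` pathways.
* **Determinism**: one master seed feeds named streams (cohort ages,
  covariates, truth, expression, permutation), so each stage is
  independently reproducible; random draws are keyed to sorted gene and
  pathway identifiers, so permuting gene order in the truth permutes
  matrix columns identically.

What the generator does *not* emulate: probe-level bead data and raw
intensity artifacts, probe-to-gene mapping ambiguity, non-linear age
trajectories, sex effects (the emulated registry is all-female),
variance heterogeneity with age, and realistic overlapping pathway
memberships (synthetic pathways are disjoint). Passing tests therefore
demonstrate correctness of the machinery under the stated generative
assumptions, not performance on any particular real dataset.

## Problem sizes used by the test and acceptance suites

Chosen to exercise every stage at meaningful scale:

* Pipeline-shape run: 200 gene sets of which 186 hold 20–40 genes
  (the rest at or below the strict >10 filter), a 75 + 75-pair cohort,
  K = 5 — exactly 930 phenotypes tested.
* Twin-likelihood oracle: 1000 random parameter draws on cohorts of up to
  12 individuals against a dense multivariate-normal density.
* Heritability recovery: 200 replicates per true h² at 250 + 250 pairs;
  LRT calibration: 2000 null phenotypes at 100 + 100 pairs.
* Heritability/noise ordering: 50 replicates of 4 pathways × 30 genes at
  the registry-scale cohort (168 + 260 pairs), comparing mean h² and mean
  e² of the 20 phenotypes against their 120 constituent genes.

## Known limitations

* The per-pathway phenotype count K is fixed (default five), not chosen
  by a variance-explained criterion; automatic selection of K is out of
  scope.
* Dominance (ADE) models, covariate random slopes, REML and kinship
  structures beyond MZ/DZ/singleton are not supported.
* On small pathways the projection-based variance-explained figures are
  dominated by K/G and are not comparable across pathway sizes, nor to
  variational-Bayes variance ledgers from other software.
* Significant-pathway counts at desk-scale synthetic cohorts are
  deliberately moderate; per-pathway detection power depends on cohort
  size and planted effect size, and the defaults favour calibration
  checks over saturation.
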