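---
title: "Latent biological traits and their genomic networks: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent biological traits and their genomic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ubtnet` chains five statistical stages — filtering, exploratory factor
analysis (EFA), Bayesian confirmatory factor analysis (CFA), GBLUP, and
Bayesian-network structure learning — into one reproducible pipeline for
deriving *underlying biological traits* (UBT) from panels of correlated
phenotypes and asking how those latent traits influence one another at the
genetic level. This vignette is the package's account of the science: the
models and their assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and the numerical and design choices a maintainer should know about.

## 1. The measurement model

All factor-analytic stages work with the common-factor model on z-scored
traits:

$$ y_i = \Lambda \eta_i + \varepsilon_i, \qquad
   \eta_i \sim N(0, \Phi), \qquad
   \varepsilon_i \sim N(0, \mathrm{diag}(\psi)), $$

with unit factor variances for identification. Two consequences used
throughout:

* for an indicator with a single loading (the CFA's congeneric structure),
  the standardized loading is $\lambda^* = \lambda/\sqrt{\lambda^2+\psi}$ and
  the variance explained is exactly $R^2 = (\lambda^*)^2$ — the package
  reports $R^2$ as the square of the posterior-mean standardized loading so
  the identity survives into the output tables;
* communality + uniqueness = 1 per standardized trait, which `fit_efa()`
  enforces by recomputing uniquenesses as $1-\mathrm{diag}(\Lambda \Phi
  \Lambda')$ after rotation.

## 2. Preprocessing cascade

Order: explicit exclusions → Tukey outliers → complete case → r² pruning →
MSA screening. Choices that were genuinely open:

* **Quantile convention.** Tukey fences use type-7 quantiles (linear
  interpolation of order statistics), the default of mainstream statistics
  environments; the convention is recorded in the filter report.
* **Idempotence.** Setting outliers to missing and dropping incomplete
  animals moves the quartiles, which can expose new outliers; the filter
  therefore iterates flag-then-drop to a fixed point, making the whole
  cascade idempotent (re-running it on its own output changes nothing). The
  extra animal loss beyond a single pass is typically nil to a few animals.
* **r² vs |r|.** The pruning threshold 0.85 applies to the *squared* Pearson
  correlation (|r| ≈ 0.922), reading the published rule literally. When a
  pair trips the threshold the calculated trait loses to the direct measure,
  then the worse configured priority rank, then the later column — so the
  pipeline prefers what a producer can actually measure on the animal.
* **MSA screening is iterative.** Per-variable MSA values change after each
  removal; a single pass can strand variables below threshold. The screen
  removes the worst variable, recomputes, and stops when all survive (or
  fewer than 3 remain, which halts the run). Near-singular correlation
  matrices get a 1e-8 ridge, with a warning, before inversion.

## 3. EFA: extraction, rotation, retention

* **Extraction** is minimum-residual by default (optimizing uniquenesses so
  the top-k eigenpairs of the reduced correlation matrix reproduce the
  off-diagonal correlations in least squares), with maximum likelihood via
  `stats::factanal()` as an option. Heywood cases are bounded at
  uniqueness ≥ 1e-3, with a warning.
* **Rotation** defaults to oblique oblimin (quartimin criterion, implemented
  as a gradient-projection iteration) because biological blocks like body
  size and ovary size are expected to correlate; varimax is available when
  orthogonal factors are wanted. Each factor is reflected so its
  largest-magnitude loading is positive, removing the sign indeterminacy
  that otherwise breaks test reproducibility.
* **Retention** uses parallel analysis: observed correlation-matrix
  eigenvalues versus eigenvalues of `n_sims` simulated uncorrelated
  datasets of the same dimension. The reference is the **95th percentile**
  by default, not the simulated mean. This is a deliberate deviation from
  the classical mean rule: a pure-noise panel's eigenvalues are a draw from
  the very distribution being averaged, so "observed > mean" is close to a
  coin flip and the mean rule retained ≥ 1 spurious factor in roughly a
  third of pure-noise replicates in our calibration runs; the percentile
  reference keeps the false-retention rate at the nominal few percent while
  leaving real factors (loadings ≥ 0.6, a handful of indicators) untouched.
  `quantile = "mean"` restores the classical behaviour.
* **Assignment.** Cross-loading traits go to the factor with the largest
  absolute loading, provided it reaches the salience cutoff (default 0.3, a
  conventional threshold — the source procedure never states one); traits
  below cutoff everywhere are left unassigned and recommended for
  univariate modelling.

## 4. Bayesian CFA

The Gibbs sampler updates, in turn: factor scores (multivariate normal),
loadings (normal, prior `N(0, 10)`), residual precisions (gamma, prior
`G(1, 0.5)`), and the factor correlation matrix. The correlation update uses
parameter expansion: an inverse-Wishart draw (working prior df `k + 2`,
scale `I`) conditioned on the current factor scores is rescaled to a
correlation matrix, with loadings and scores rescaled compensatingly so the
likelihood is untouched. Sign identification re-anchors each factor every
sweep on its first indicator. Indicators are z-scored first, so the
standardized solution is the native scale of the output.

Defaults mirror the reference procedure: 10,000 iterations, 5,000 burn-in,
2 chains from dispersed starts. Convergence is gated on the
potential scale reduction factor computed as
$\widehat{R} = \sqrt{1 + B/(nW)}$ — a variant of Gelman–Rubin chosen because
it is exactly 1 for identical chains and ≥ 1 by construction; for converged
chains of length 5,000 it sits below 1.01. Any parameter above 1.1 flags the
fit non-converged (the result is still returned, prominently flagged).
Factor scores are posterior means of $\eta_i$ accumulated inside the
sampler, averaged over chains; they become the UBT phenotypes.

Indicators whose standardized loading's 95% credible interval dips below
the salience threshold are reported "unexplained" — the package's analogue
of discovering that intramuscular fat and body density belong outside the
latent factors; they join the univariate-modelling recommendation list,
together with traits already removed at the MSA or assignment stages.

A note on the published tables this package uses as worked examples: one
table prints $R^2$ values (0.125, 0.122) for two ovary-diameter rows that
are inconsistent with $R^2 = \lambda^2$ satisfied by every other row; we
treat those two entries as typographical and exclude them from acceptance
targets.

## 5. GBLUP and decorrelation

SNP QC applies, in order, autosome restriction, call rate > 0.95,
MAF ≥ 0.05, and the exact Hardy–Weinberg test at p < 1e-4 (enumeration over
heterozygote counts at fixed allele counts; the test is conservative, so
the filter removes at most ~α of HWE-consistent markers). The GRM is
VanRaden method-1 with observed allele frequencies and per-marker mean
imputation of missing calls; a diagonal ridge (1e-6, escalating to at most
1e-3) guarantees a Cholesky factor `L`.

The mixed model is fitted after rotating by the eigenvectors of G, which
renders records independent with covariance $d_i \Sigma_u + \Sigma_e$.
Variance components come from EM-REML (the E-step includes the
fixed-effect-uncertainty term). Two numerical choices matter:

* **Termination.** With a few hundred nominally unrelated animals the
  likelihood ridge separating $\Sigma_u$ from $\Sigma_e$ is nearly flat —
  identification comes only from the spread of GRM eigenvalues — and plain
  EM crawls. The loop applies Aitken extrapolation along the EM path every
  5 iterations (accepted only if the extrapolated matrices stay PSD) and
  accepts either a small parameter step or a stationary restricted
  log-likelihood (rel. change < 1e-8) as convergence; hitting the
  500-iteration cap returns the estimates flagged non-converged with a
  warning rather than an error, reserving errors for genuine numerical
  failure. The gEBV are insensitive to the tail of that crawl.
* **Univariate default.** The pipeline fits each latent trait separately by
  default. In the joint multivariate fit the genetic *covariances* are the
  most weakly identified components, and spuriously estimated genetic
  correlations propagate into cross-trait gEBV coupling that fabricates
  network edges between genetically independent factors — we observed
  correlations near 0.24 between the gEBV of independent latents, enough
  for a bootstrap-consensus edge. `gblup_mode = "multivariate"` remains
  available and is the right choice when genetic covariance is itself of
  interest.

Adjusted gEBV are $L^{-1}\hat u$ per trait: whitening by the GRM Cholesky
factor removes relatedness-induced dependence between individuals so the
structure-learning stage's i.i.d. assumption holds.

## 6. Network learning

Both learners maximize the decomposable Gaussian BIC
(per node: regression log-likelihood minus $\tfrac{\log n}{2}$ × (parents +
2)). Tabu search takes the best non-tabu add/delete/reverse move, even when
worsening, with a visited-structure tabu list (length 10) and a 15-move
stall limit; on 2- and 3-node problems it provably attains the
exhaustive-enumeration optimum (tested against all 25 three-node DAGs).
MMHC first learns a skeleton by MMPC — Fisher-z partial-correlation tests
at α = 0.05, max–min candidate admission, backward removal, symmetry
correction, conditioning sets up to size 3 — then hill-climbs restricted to
that skeleton.

Bootstrap averaging (default 500 resamples) tallies, per undirected pair,
the fraction of learned networks containing the edge (strength) and, among
those, each orientation's share (direction). The consensus keeps edges with
strength ≥ 0.5 and orients by direction ≥ 0.5; an exact 0.5 direction tie
keeps the edge with lexicographic orientation and logs it, and a cyclic
consensus is repaired by dropping the weakest-direction edge. All of this
is seed-reproducible.

## 7. What the synthetic world is — and is not

The generator's defaults state the world the acceptance tests live in:
300 animals, 2,000 unlinked SNPs on 10 autosomes with MAF ~ U(0.05, 0.5),
three latent factors at heritability 0.5, a single genetic path
body size → ovary size with coefficient 0.6 (a moderate-strong path chosen
a priori; nothing in the source states a value), 16 traits with standardized
loadings 0.6–0.9 in three blocks plus two pure-noise traits, fixed-effect
shifts of ±0.05–0.15 SD on the observed scale, 2% missing cells and 1%
injected outliers (calibrated so complete-case filtering retains roughly
half the animals, mirroring the attrition of the motivating dataset).
Latent genetic values are built from marker effects and scaled so the
in-sample genetic variance ratio equals the configured heritability exactly;
residual parts are orthogonalized against them.

Deliberately *not* emulated: linkage disequilibrium (unlinked markers keep
the GBLUP/network behaviour unchanged at desk scale and the oracles simple),
pedigree/family structure, breed admixture, selection, and repeated
measures. A green end-to-end test therefore establishes that the pipeline
recovers planted factor structure, breeding values and genetic edges under
clean model-consistent data of realistic size — not that it is robust to LD,
stratification, or non-Gaussian traits.

Because the carcass factor has only three indicators, some seeds lose it
entirely at the MSA screen — the same behaviour the motivating study hit
when its single-latent carcass panel could not form a network. The pipeline
treats that as data, not as an error.

## 8. Known limitations

* The ±0.05 sup-norm recovery bound for CFA loadings is unattainable at the
  default fixture's post-filter size (~160 animals): the sampling SE of a
  standardized loading of 0.6–0.75 is 0.05–0.08 there (the published tables'
  own posterior SDs reach 0.10 at comparable n). The corresponding
  acceptance test is left red by design; the same bound passes at n = 2,000
  in the unit suite.
* EM-REML reports `converged = FALSE` when the 500-iteration cap is hit on
  a flat ridge; estimates remain usable for BLUP, but the variance
  components themselves carry large uncertainty at n ≈ 300 with unrelated
  animals. Heritability estimates at that size routinely land 0.1–0.25 away
  from the simulated 0.5.
* The PLINK/VCF codecs cover the 0/1/2 biallelic GT use of this pipeline
  only (SNP-major bed, uncompressed VCF 4.2); they are not general-purpose
  readers.
* Bootstrap consensus edges whose strength hovers at the 0.5 threshold are
  seed-sensitive by nature; report strengths, not just the thresholded
  graph, when publishing.
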