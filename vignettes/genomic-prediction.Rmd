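---
title: "Genomic evaluation with gskit: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic evaluation with gskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gskit)
```

`gskit` implements a complete genomic-evaluation workflow for additive
quantitative traits: pedigree BLUP, GBLUP, single-step GBLUP, five
Bayesian marker-effect models, and the cross-validation machinery to
compare them. This vignette is the package's own account of the science:
the models and their assumptions, what the synthetic-data generator does
and does not emulate, the tunable parameters that matter, and the
numerical choices behind the implementation.

## 1. The animal model and its three covariance structures

Every BLUP variant fits the same single-trait animal model

$$ y = X\beta + Za + e, \qquad a \sim N(0, K\sigma_a^2), \qquad
   e \sim N(0, I\sigma_e^2), $$

with fixed effects limited to categorical factors (sex and feed room by
default, dummy-coded against a first-level reference, additive — no
interaction, which is the conventional parameterization when no design
information argues otherwise). The three structures for $K$:

* **A** (pedigree): tabular method. The diagonal is $1 + F_i$; the
  contract is the matrix value, so $A^{-1}$ is obtained by direct dense
  inversion rather than Henderson's sparse rules — adequate at the desk
  scales this package targets (pedigrees of a few thousand).
* **G** (genomic): VanRaden method 1, $G = ZZ'/(2\sum_i p_i(1-p_i))$ with
  $Z = M - 2p$ and $p$ the *observed* frequency in the genotyped set.
  Monomorphic markers contribute nothing to the numerator and are excluded
  from the denominator. Missing calls are mean-imputed ($2p$) at matrix
  construction only, never persisted — the standard G-matrix convention.
* **H** (single-step): $H^{-1} = A^{-1} + \begin{pmatrix} 0 & 0 \\ 0 &
  G^{-1} - A_{22}^{-1}\end{pmatrix}$ on the genotyped block. No
  G-to-$A_{22}$ rescaling step is applied by default (none is part of the
  basic blend); the regularization weight described next is the only
  modification of raw G.

**G regularization.** With more animals than markers, duplicated animals,
or a closed population, raw G is singular. Before inversion the package
blends $G^* = wG + (1-w)I$ with $w = 0.99$ by default (`g_reg`
argument; `g_reg = 1` inverts raw G, which the equivalence tests use).
The weight is recorded in the returned matrix object.

**Assumptions.** Additive gene action only (no dominance/epistasis),
homogeneous residual variance, non-inbred base population for A's
founders, and a genotyped set representative enough for observed allele
frequencies to centre G. Multi-trait models, genetic correlations, and
maternal effects are out of scope.

## 2. REML: average information on the eigenrotated scale

With two variance components, $V = \sigma_a^2 K + \sigma_e^2 I$. One
eigendecomposition $K = UDU'$ turns $V$ into a diagonal matrix in the
rotated basis, so each AI-REML iteration is $O(n)$ after an $O(n^3)$
setup. Updates are average-information steps with two safeguards:

* an EM-flavoured multiplicative update replaces an AI step that is
  non-finite or would leave the parameter space while the score still
  points inward;
* a parameter whose AI step crosses the lower bound while its score
  points outward jumps to the bound, and once at the bound with an
  outward score it is treated as converged. This is what makes
  null-heritability data converge cleanly to $\hat h^2 \approx 0$
  instead of creeping geometrically toward the boundary.

Convergence is declared at relative parameter change below $10^{-8}$
(maximum 200 iterations; non-convergence is an error carrying the
iteration trace). The SE of $h^2$ comes from the delta method applied to
the inverse AI matrix — the tests check it is calibrated against the
replicate scatter of $\hat h^2$. The lower variance bound is
$10^{-8}\,\mathrm{var}(y)$.

`reml_profile_loglik()` exposes the restricted likelihood profiled over
total variance at fixed $h^2$, which the test suite uses to verify that
no point of a 50-point grid beats the optimizer.

**Cross-validation re-estimates variance components on every training
fold.** Using full-data components would leak validation information into
training; the cost is five REML fits per curve point, which the
eigenrotation keeps cheap.

## 3. Bayesian marker-effect models

All five families share the structure $y = X\beta + \sum_j Z_j\alpha_j +
e$ with centred (not standardized) genotype covariates — consistent with
the $Z = M - 2p$ convention of the GBLUP branch — a flat prior on fixed
effects, and scaled-inverse-$\chi^2$ conditionals for the variance
components. $\pi$ is always the probability of a **non-zero** effect
(uniform prior when estimated). Family-specific priors:

| family | prior on $\alpha_j$ |
|---|---|
| B | spike at 0 w.p. $1-\pi$; scaled $t_\nu$ otherwise ($\nu = 4$ by default, configurable — no canonical value exists) |
| Cπ | spike; $N(0, \sigma^2)$ otherwise |
| N | window indicator gates Cπ-style marker indicators inside non-overlapping windows |
| S | spike; $N(0, (2p_j(1-p_j))^S\sigma^2)$, $S$ sampled |
| R | 4-component normal mixture, variances $\gamma_k\sigma^2$, $\gamma = (0, 0.01, 0.1, 1)$, Dirichlet(1,1,1,1) weights |

Implementation notes, in the order they matter:

* **Single-site Gibbs with residual updating** (compiled via Rcpp). The
  marker indicator is sampled with the effect integrated out, then the
  effect from its normal conditional — the standard conjugate scheme.
* **BayesB** uses per-marker variance augmentation: each marker carries
  $\sigma_j^2$, updated from its inverse-$\chi^2$ conditional when the
  marker is in the model and refreshed from the prior otherwise; the
  common $t$ scale gets a conjugate gamma update. This reproduces the
  scaled-$t$ marginal without Metropolis steps in the effect update.
* **Hierarchical variance scale.** The inverse-$\chi^2$ scale of the
  common effect variance itself carries a gamma hyperprior (centred on a
  variance-explained heuristic at initialization). This matters for
  honest shrinkage: with a *fixed* scale the chain equilibrates at the
  spike/slab indifference point on pure-noise phenotypes and the model
  keeps absorbing a few percent of noise variance; with the hierarchical
  scale both collapse and effects genuinely vanish when the data carry no
  signal.
* **BayesN nesting**: one inclusion indicator per window (tiled from each
  chromosome's first marker position, 0.2 Mb default, non-overlapping)
  gating Cπ-style per-marker indicators inside. The window update
  integrates nothing away: it flips the whole window's current
  contribution against the residual, and a closed window's inner state is
  refreshed from its prior so the next flip proposes fresh effects. This
  two-level mixture follows the standard description of the nested
  model; the reference implementation's exact within-window scheme is not
  public, so this is a faithful-to-text reconstruction, not a clone.
* **BayesS** updates $S$ by random-walk Metropolis within Gibbs (proposal
  SD 0.3, prior $N(0,1)$ — the prior SD is not canonical either and is
  configurable). With no markers in the model the likelihood is flat in
  $S$ and the chain reproduces its prior, which the tests exploit.
* **BayesR** memberships are sampled from categorical conditionals
  renormalized in log space, so probability underflow cannot produce NaN.
* **Chain protocol** defaults to 21,000 iterations / 1,000 burn-in /
  thin 10 → exactly 2,000 retained samples. One chain per fit; a
  split-chain diagnostic on the genetic-variance samples logs a warning
  (never a hard failure) when the two halves disagree by more than one
  SD.
* GEBVs are $Z\hat\alpha$ with **training-set** centring frequencies, so
  validation animals are scored in the training frame.

## 4. What the synthetic-data generator emulates

`sim_study()` produces an F2 cross of two divergent founder lines —
the design of the crossbred duck population that motivates the package's
defaults — with every piece needed downstream: pedigree, genotypes,
marker map, phenotypes with sex and feed-room effects, and the true
marker effects for validation.

* **Founder lines.** Per-line allele frequencies are drawn uniformly in
  `[maf_low, maf_high]` (defaults 0.1–0.5), and each secondary line flips
  to the complementary allele at a random half of markers
  (`line_divergence = 0.5`) so the lines are genuinely divergent.
* **LD model**: a first-order autoregressive latent Gaussian along each
  chromosome, thresholded to match the marginal frequency exactly;
  correlation decays as $\exp(-\lambda\,\mathrm{bp})$ with
  $\lambda = 2\times10^{-6}$ per bp by default. One parameter controls
  the whole LD profile — chosen because density-saturation behaviour
  depends on LD strength but no richer LD structure is specified by the
  study design this emulates. $\lambda \to \infty$ gives linkage
  equilibrium; $\lambda = 0$ perfect correlation.
* **Gene dropping** with a Poisson crossover process (1 cM/Mb default)
  produces F1 and F2 genotypes; Mendelian consistency is exact by
  construction and checked exhaustively in the tests.
* **Trait architectures** mirror the five Bayesian priors (polygenic,
  sparse scaled-t, normal mixture, MAF-coupled, four-component), so each
  sampler can be exercised on data matching its own assumptions.
* **Heritability targeting**: residual variance is scaled to the
  *realized* genetic variance, $\sigma_e^2 =
  \mathrm{var}(g)(1-h^2)/h^2$, not its expectation — this makes
  parameter-recovery tests sharp at moderate sample sizes.
* **Fixed effects** are additive shifts on sex (+100 units by default)
  and feed room (3 rooms, 0/20/40), mirroring a two-factor husbandry
  design.

**What it does not emulate** — and hence what passing tests do not show
about real data: sequencing error and imputation artefacts, selection and
assortative mating, genotype-by-environment interaction, dominance and
epistasis, population-specific LD beyond the one-parameter decay, and
heterogeneous residual variances. Conclusions about model *orderings*
(e.g. single-step above GBLUP when ungenotyped phenotypes exist) transfer
as directions, not magnitudes.

## 5. Quality control and formats

QC applies four per-marker filters in a fixed order — non-autosome, call
rate < 0.90, MAF < 0.05, exact Hardy–Weinberg p < $10^{-6}$ — attributing
each removal to the first failing filter so reports are deterministic.
The HWE test is the two-sided exact test by full enumeration of
heterozygote counts conditional on allele counts (summing configurations
no more probable than the observed one), matching common GWAS-QC
practice; a chi-square approximation would misbehave exactly where the
filter bites (rare alleles). MAF is computed on non-missing calls; a
fully missing marker fails call rate first. Call-rate filtering is
per-marker (per-individual QC is out of scope).

Genotypes read and write as PLINK bed/bim/fam (SNP-major v1.00) and VCF
4.2 (GT only; multi-allelic records are skipped with a count). The
counted allele is recorded in the object so relationship matrices are
invariant to re-reading. Round-trips are bit-exact, including
missingness.

## 6. Evaluation design

* **Folds**: seeded uniform partition, sizes differing by at most one
  (941 ids → 189/188/188/188/188, i.e. the 753/188 train/validation
  split used for a 941-animal genotyped cohort).
* **Adjusted phenotypes** are $y - X\hat\beta$ with $\hat\beta$ from a
  GLS fit on the full data under the fitted polygenic covariance. The
  definition of "adjusted" is a reconstruction — fixed effects only,
  estimated once jointly with a polygenic term to avoid bias from genetic
  structure — and is deliberately shared across all models being
  compared.
* **Masking, not removal**: validation phenotypes are set missing inside
  the fit, so genotyped validation animals still receive predictions
  through G/H (BLUP family) or marker effects (Bayesian family). The
  no-leakage property (training output invariant to permuting masked
  values) is tested bit-exactly.
* **Density experiment**: fold assignment and marker subsampling use two
  independent seed streams, so all densities and repeats share folds and
  differ only in markers. The density grid defaults to the standard
  0.5–500 K ladder capped at the available panel. Whether repeats should
  re-randomize folds is a free design choice; shared
  folds were chosen because they remove fold noise from the density
  contrast.
* **Paired comparison** across traits/replicates uses a two-sided paired
  t-test; identical tables give $t = 0, p = 1$, and a degenerate
  zero-variance difference with non-zero mean is reported as $p \to 0$
  with a logged note.

## 7. Problem sizes used in the shipped checks

The package's own acceptance checks run at sizes chosen to make each
property sharply testable on one CPU in minutes: REML recovery on 20
replicate populations of n = 1000 / m = 2000 (the band ±0.05 around
h² = 0.5 and an SE-to-scatter ratio within 2×); model-ordering runs on
10 replicate crossbred fixtures of 250 F2 with 30% of phenotyped animals
ungenotyped; BayesB-versus-GBLUP architecture contrasts at n = 300 /
m = 1000 with the shortened 2,100-iteration chain; density saturation at
m = 5000 with 10 repeats per density. The noise-shrinkage check uses
n = 500 > m = 400 deliberately: below that ratio a correctly implemented
sampler still absorbs a few percent of noise variance through chance
marker–noise correlations, and the check would measure sample size, not
shrinkage.

## 8. Known limitations

Dense linear algebra throughout (no sparse A⁻¹, no APY); single-trait
models only; no genetic-correlation estimation; no metafounders or
unknown-parent groups; the Bayesian samplers run one chain (the
split-chain warning is the only convergence gate); and the BayesB/BayesS
hyperparameters ($\nu$, prior SD of $S$) follow field convention, as no
canonical values exist, so sensitivity to them should be checked before
scientific use at scale.
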