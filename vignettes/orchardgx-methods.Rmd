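---
title: "Models and methods behind orchardgx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind orchardgx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

orchardgx implements the complete quantitative-genetics workflow of a
multi-environment, clonally replicated crop trial: trees of each genotype
are grafted replicates planted at several locations over several years, and
the analysis walks from raw tree-level measurements to spatially adjusted
values, clonal values, heritabilities, marker-trait associations, genomic
predictions with and without genotype-by-environment interaction (G×E), and
a variance decomposition that classifies traits by their architecture. This
vignette explains each model, the choices we made where several designs were
defensible, and what the synthetic-trial generator can and cannot tell you
about real orchard data.

## The mixed-model core

Every phenotypic stage is a special case of the linear mixed model

$$y = X\beta + \sum_j Z_j u_j + \varepsilon,\qquad
  u_j \sim N(0,\ \sigma_j^2 K_j),\quad \varepsilon \sim N(0,\ \sigma_\varepsilon^2 I),$$

fitted by REML in `fit_lmm()`. Rather than an EM iteration, the engine
maximizes the profiled restricted log-likelihood directly over the log
variance ratios $\gamma_j = \sigma_j^2/\sigma_\varepsilon^2$ with L-BFGS-B;
each evaluation is one sparse Cholesky factorization of the mixed-model
coefficient matrix, so a fit with thousands of random-effect levels takes a
fraction of a second. We chose the direct search because it needs two orders
of magnitude fewer factorizations than EM at these problem sizes and behaves
predictably when a component sits on the zero boundary: ratios driven to the
lower optimizer bound are reported as exactly 0. Kernel-structured random
effects (a genomic relationship or spline penalty matrix over the levels)
are absorbed by an eigendecomposition of the covariance, dropping
eigenvalues below 1e-8 of the maximum; BLUPs are rotated back to the level
scale afterwards. On balanced designs the estimates reproduce the ANOVA
method-of-moments closed forms to 1e-6, and on unbalanced data they match
lme4 to four decimals (both are pinned by tests).

## Spatial adjustment and clonal values

Orchard phenotypes carry smooth field trends (soil, irrigation, border
effects). `adjust_spatial()` models one environment (a location-year) at a
time as

value ~ te(row, col) + genotype (random),

where the tensor-product surface is a low-rank P-spline (B-spline bases with
a second-order difference penalty, basis dimension 8 per margin by default)
whose smoothness is chosen by REML, with additional shrinkage selection so a
genuinely flat field collapses to no adjustment. The genotype term is in the
model only to keep genetic signal out of the surface; the adjusted value is
the observation minus the estimated surface, so the adjustment preserves
record count, scale, and the genetic and residual structure. The contract we
test is recovery: on planted smooth fields the estimated surface correlates
above 0.9 with the truth, and on flat fields the adjustment is numerically
negligible. We do not claim bit-compatibility with any particular published
spline package.

Clonal values are genotype BLUPs from the adjusted tree-level data:
across-location fits use location, year and their interaction as fixed
effects; location-specific fits (for traits measured at a single location)
use year only. Because the two scopes condition on different fixed effects,
the combined "global" table records each trait's scope and should be read
with that caveat. Heavily right-skewed traits are fitted on the natural log;
values at or below zero raise an error rather than silently shifting the
data, because a hidden +1 changes the meaning of the transform.

Clonal-mean heritability uses the standard variance-component ratios: within
one environment $H^2 = \sigma_g^2 / (\sigma_g^2 +
\sigma_\varepsilon^2/\bar n_r)$ with $\bar n_r$ the mean number of replicate
trees, and across environments
$\sigma_p^2 = \sigma_g^2 + \sigma_{ge}^2/n_e +
\sigma_\varepsilon^2/(n_e \bar n_r)$. Environment-trait combinations with
$H^2$ below 0.1 are discarded before any downstream analysis; the boundary
value 0.1 itself is kept.

## Multi-locus association scan

`blink_scan()` is an iterative multi-locus GWAS in the style of
two-fixed-effect-model scanners: (1) every marker is tested in a fixed-effect
regression with two principal components of the standardized marker matrix
as covariates plus the current pseudo-QTNs, excluding any pseudo-QTN in LD
(r² ≥ 0.7) with the tested marker — a marker is trivially in perfect LD with
itself, so pseudo-QTNs are automatically tested without their own signal
absorbed; (2) candidate pseudo-QTNs are the p-ranked markers greedily
filtered to pairwise LD r² < 0.7; (3) the number retained is chosen by
information criterion over the nested candidate sets; the loop repeats until
the set stabilizes (at most 10 iterations). Markers with minor allele
frequency below 0.05 are never tested, and significance is declared at the
Bonferroni level α/m over the m tested markers (the threshold, α and m are
all recorded on the result).

One choice deserves emphasis: the selection criterion is the **extended**
BIC (Chen & Chen 2008) with γ = 1, i.e. each parameter costs
$\log n + 2\log m$ rather than $\log n$. Ordinary BIC is not selection-aware:
the best of m null markers carries a chi-square around $2\log m$, so with
thousands of markers plain BIC admits dozens of noise pseudo-QTNs, and their
conditional p-values can then breach the Bonferroni line on a trait with no
genetic signal at all. With the marker-pool term the scan shows the intended
behaviour on simulations: planted QTL of ~8% variance each are recovered,
null traits yield no significant calls, and reported pseudo-QTN sets always
respect the pairwise LD cutoff. γ is a function argument; 0 recovers plain
BIC.

Downstream cataloguing works on (trait group, chromosome, segment)
combinations, where segments are thirds of the chromosome's marker-spanned
length with left-closed boundaries (a position exactly at L/3 is "top").
Co-localization clusters associations on a chromosome by single linkage with
gaps strictly below 100 kb. Allele-frequency dynamics report, for each major
association, the frequency of the phenotype-increasing allele per recorded
ancestor generation and in the progeny group, with 10 resamples of 30
progeny genotypes for a stability check; LD context comes from squared
Pearson correlations in a window of 3000 markers around the focal
association, truncated at chromosome ends.

## Genomic prediction

All Bayesian models share the intercept-plus-random-effects form
$y = 1\mu + u + \varepsilon$ and a Gibbs sampler; the package default chain
is 12 000 iterations, thinning 5, burn-in 2000.

* **G-BLUP** (`fit_gblup()`): $u \sim N(0, G\sigma_u^2)$ with
  $G = MM'/m$ from the column-standardized dosage matrix. The sampler works
  in the eigenbasis of G, where all genotype effects update elementwise.
* **BayesCπ** (`fit_bayescpi()`): spike-and-slab prior on marker effects
  with a common slab variance and π (the prior probability of a zero
  effect) given a uniform prior and updated from its Beta full conditional;
  the per-marker loop is compiled code. Genomic heritability is computed per
  retained iteration as $V_g/(V_g+V_e)$, with $V_g$ the variance of the
  marker-explained genetic values across genotypes, and averaged.
* **Multi-kernel RKHS** (`fit_rkhs_multikernel()`): Gaussian kernels
  $K_l = \exp(-h_l D)$ of the average squared-Euclidean distance D, with the
  standard bandwidths h = {0.1, 0.5, 2.5} fitted jointly, one variance per
  kernel.
* **Random forest** (`fit_rf()`): 500 trees, mtry = ⌊m/3⌋, delegated to the
  ranger implementation; the contribution here is configuration, not
  algorithm.
* **Bivariate model** (`fit_mtm_un()`): $u \sim N(0, U \otimes G)$ with
  unstructured 2×2 genetic and residual covariances (inverse-Wishart, df
  t+2, identity scale); trait pairs are pre-selected by a genomic
  breeding-value correlation above 0.3 from single-trait G-BLUP fits.

Missing responses — the mechanism behind all cross-validation — are handled
inside every sampler by data augmentation, so a masked genotype's prediction
flows through its genomic relationship to the training set.

Hyperpriors follow one rule: scaled-inverse-chi-square with 5 degrees of
freedom on every variance, scale chosen so the prior mode corresponds to an
even split of the observed response variance between the term and the
residual. One consequence is worth knowing: this prior family has
essentially no mass near zero, so on a trait with no genetic signal the
*component* ratio $\sigma_u^2/(\sigma_u^2+\sigma_\varepsilon^2)$ does not
collapse below roughly 0.2 even though the realized genetic values do
(their posterior-mean variance stays under 15% of the response variance).
We verified this against a two-dimensional quadrature of the exact marginal
posterior — the genotype effects integrate out analytically in the
eigenbasis — and the sampler agrees with that oracle to three decimals;
tests therefore pin both the oracle agreement and the collapse of the
realized values. BayesCπ, whose spike can set effects exactly to zero, shows
near-zero genomic heritability on null traits as expected.

Identifiability of $\sigma_u^2$ against $\sigma_\varepsilon^2$ comes
entirely from spread in the eigenvalues of G: a population of unrelated
individuals gives a nearly flat spectrum and the two variances are then
close to unidentified. The test suite and the acceptance script therefore
simulate panels containing biparental progeny families, which is also what
the targeted study population looks like.

## Multi-environment models and cross-validation

With environments as the combined location-year factor, the stacked response
of length n·r is modelled three ways:

* **G-BLUP.E** (`fit_gblup_e()`): one genetic effect shared by all
  environments, $u \sim N(0, (J \otimes G)\,\sigma_{u0}^2)$ with J the r×r
  all-ones matrix, plus per-environment intercepts.
* **G-BLUP.E.G×E** (`fit_gblup_e_gxe()`): adds environment-specific
  deviations with block-diagonal covariance
  $\mathrm{diag}(\sigma_{u1}^2 G, \dots, \sigma_{ur}^2 G)$, i.e. marker
  effects may change across environments while staying positively
  correlated.
* **MTM.FA** (`fit_mtm_fa()`): environments as traits,
  $u \sim N(0, C \otimes G)$ with factor-analytic $C = BB' + \Psi$,
  Gaussian prior variance 100 on the loadings, unstructured residual
  covariance across environments, and at least three environments required.
  We default to one common factor — the number of factors is genuinely open
  and a function argument — and fix the sign of each factor's first loading
  positive for identifiability.

No sampler ever materializes an nr × nr Kronecker matrix: the shared
eigendecomposition of G and, inside the multivariate sampler, a generalized
eigendecomposition that simultaneously whitens the genetic and residual
trait covariances reduce every update to elementwise operations.

`make_cv_plan()` builds five-fold partitions (fold sizes differ by at most
one) with independent reshuffles per repeat, seeded from one master seed.
The `main` scenario masks global clonal values; `CV1` masks a genotype in
every environment (fully untested material); `CV2` masks it everywhere
except designated reference environments (material phenotyped at the
breeding site only). Predictive ability is the Pearson correlation between
observed and predicted values of masked genotypes, per environment for the
multi-environment models; groups with fewer than three pairs or constant
predictions are reported missing and excluded from averages.

## Variance decomposition and trait clustering

`decompose_variance()` fits adjusted tree-level values with environment as a
fixed effect and, as random effects, one 3-level dosage-class factor per
significantly associated SNP, the residual genotype effect, and G×E. The
environment share is the variance of the fixed-effect fitted values with all
random effects zeroed; genotype and G×E shares are their REML components;
the residual is the remainder, so the shares always total 1. For the SNP
terms we report the realized variance of the fitted class effects across
records rather than the raw component: a 3-level factor's REML component is
a superpopulation variance that over-weights rare dosage classes, and with
roughly two degrees of freedom it is noisy in any case (terms estimated at
zero are flagged). The genotypic variance is the SNP shares plus the
genotype share, which stays stable whether or not the SNP terms are in the
model. Trait clustering standardizes the trait-by-component table, applies
Ward clustering (ward.D2 on Euclidean distances), and cuts the dendrogram at
the largest gap between successive merge heights; it refuses fewer than
three traits because that cut rule is then undefined.

## The synthetic-trial generator

`simulate_trial()` emulates the study design end to end: a diverse accession
group, biparental progeny families bred through a recorded five-generation
ancestor chain, LD-structured biallelic genotypes, and multi-environment
phenotypes with known ground truth. Defaults mirror the trial the pipeline
targets — 269 accessions, 27 crosses of about 10 progeny, six locations by
three years, at least two replicate trees per genotype per environment — at
a desk-scale marker count of 5000 over 17 chromosomes.

Design choices, each picked once for a single tunable knob:

* **LD**: a latent Gaussian AR(1) per chromosome, thresholded at each
  marker's allele-frequency quantile (`ld_rho`, default 0.9, gives the
  strong local LD of array data). This is a stand-in with one decay
  parameter, not a fitted LD map.
* **Recombination**: crossovers as a Poisson process along the physical map
  at `recomb_rate_per_bp` (default 1e-8 M/bp = 1 cM/Mb, the usual plant
  genome average); no interference.
* **Spatial field**: 2–4 random Gaussian bumps plus linear row/column
  gradients, rescaled to `spatial_field_sd` (default 0.3 trait SD) — smooth
  enough that the adjustment stage can recover it, which is exactly the
  property we test.
* **G×E**: per-genotype, per-environment normal deviations; setting
  `gxe_env_cor` draws them with compound-symmetry correlation so scenarios
  with genetically correlated environments (where CV2 should beat CV1) are
  testable.
* **Variance bookkeeping**: every component vector is rescaled so its
  realized variance equals its `trait_spec()` fraction exactly (the
  polygenic tail is first orthogonalized against the QTL component), which
  keeps recovery tests sharp instead of Monte-Carlo fuzzy.

What passing tests do and do not show: the generator has additive genetics
only (no dominance or epistasis), Gaussian residuals, balanced replication,
no missing data mechanism, no selection, and an idealized smooth field.
Success on these simulations demonstrates that the estimators recover what
they target under their own assumptions — it does not certify performance
on real orchard data with outliers, non-additive architecture, or structured
missingness.

## Problem sizes and chain lengths

The package default Gibbs configuration (12 000 / 5 / 2000) suits full-size
analyses. The test suite and `scripts/acceptance.R` monitor posterior means
of genetic values and variance ratios, which stabilize far earlier at the
simulated sizes (n = 250–500, m = 300–5000), so they run chains of 500–3000
iterations and problem sizes of n = 400–500 for recovery checks (genomic
heritability, variance decomposition, planted-QTL GWAS at m = 5000) and
n = 250–300 for model-comparison checks; those sizes are stated here as the
package's own choices. Seed handling is explicit everywhere: simulators take
a seed in their configuration, samplers in `gibbs_config()`, and the
acceptance script derives every sub-seed from its `--seed` argument.

## Known limitations

* The REML engine targets the dense-kernel / sparse-factor sizes of this
  workflow (up to a few thousand random-effect levels), not
  million-record animal-model problems.
* The scan's family-wise error control rests on the extended-BIC selection
  step; with plain BIC (γ = 0) the conditional tests can be anticonservative.
* Permanent non-genetic tree effects across years are deliberately not
  modelled at any stage, so clonal-mean heritabilities can be optimistic for
  perennial traits.
* The multi-environment interaction model assumes positive correlation
  between environments; negatively correlated environments call for the
  factor-analytic model or a different covariance.
* Inverse-chi-square hyperpriors keep variance components away from exact
  zero (see above); rely on realized genetic values or BayesCπ when testing
  for absence of signal.
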