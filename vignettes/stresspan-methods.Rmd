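---
title: "Models and design choices in stresspan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in stresspan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`stresspan` quantifies how environmental stress structures a bacterial
pangenome sampled in a nested landscape design: sites, soil samples within
sites, and sequenced strain isolates within soil samples. This vignette
explains the statistical models stage by stage, the tunable parameters that
matter, what the synthetic-data generator does and does not emulate, and
the numerical choices behind the implementation. It states no empirical
result beyond what the package's tests and `scripts/acceptance.R` compute.

## 1. Stress gradients

Raw environmental measurements (temperature, rainfall, pH, salinity; one
value per soil sample) are converted into four dimensionless gradients with
a common orientation — higher = more stressful:

* salinity is transformed with `log(x + 0.01)` before standardisation,
  because field salinity contains exact zeroes;
* every variable is centred and scaled to mean 0, SD 1 across soil samples
  (sample SD, denominator n − 1 — any consistent choice satisfies the
  mean/SD invariants, and the choice is documented here);
* pH and rainfall are negated *after* standardisation, yielding acidity and
  aridity. Negation commutes with centring and scaling, so reversing before
  or after is equivalent (a property test asserts this).

Standardisation happens at the soil-sample level (the 60 rows of the
default design) because stress is a property of the sample, not of the
strain.

## 2. Gene richness and pangenome diversity

Gene richness (distinct genes per strain, after dropping singletons and
genes present in every strain — both carry no between-strain information)
is count data, modelled with a negative-binomial (NB2) mixed model with all
four stress gradients as simultaneous fixed effects — so each slope is
adjusted for environmental collinearity — and random intercepts for site
and soil sample:

\[
\log E[\mathrm{richness}] = \beta_0 + \textstyle\sum_e \beta_e x_e +
u_{\mathrm{site}} + u_{\mathrm{sample}} .
\]

Pangenome diversity (distinct genes pooled over a soil sample's strains, a
set union, not a sum) uses the same model at the sample level with the site
intercept only, since soil sample is then the observational unit.

Fitting uses the Laplace approximation via `glmmTMB`, with REML for the
variance components: with only 60 soil samples, ML variance estimates are
biased towards zero and normal-reference Wald tests become mildly
anti-conservative. For the same reason, p-values for the stress slopes use
a t reference with between-within degrees of freedom — the gradients vary
at the soil-sample level, so df = (number of soil samples) − (number of
fixed effects) — which simulation shows restores near-nominal type-I
error. Degenerate grouping
(fewer than two levels) falls back to a fixed-effects `MASS::glm.nb` fit,
flagged `no_random_effects_fallback` rather than silently reported. The
core-gene *label* (presence ≥ 99% of strains) and the richness *filter*
(presence = 100%) are deliberately separate thresholds, both exposed as
arguments.

## 3. Per-gene occurrence models and z-scores

Each retained gene gets a binomial GLMM of presence/absence across strains
on the four gradients, with the same random-intercept structure. The
stress response is summarised as \(z_e = \hat\beta_e / \mathrm{SE}_e\):
negative z means the gene tends to be absent where stress e is high.

Fitting thousands of structurally identical GLMMs dominates the pipeline's
runtime, so the implementation builds one `glmmTMB` objective and, per
gene, swaps the response in place, rebuilds the AD tape, re-optimises with
`nlminb`, and takes standard errors from the inverse observed information.
This reproduces `glmmTMB`'s estimates and SEs exactly (verified in tests)
at a fraction of the per-fit overhead.

Per-gene failures use a three-tier policy: full GLMM → fixed-effects
logistic fit (`no_random_effects_fallback`) → `separation` with undefined z
for genes perfectly separated along a gradient. Separation is detected from
the fitted-probability warning together with implausible magnitudes
(|coef| > 8 or SE > 25 on the logit scale). An optional winsorisation of z
at a configurable bound is available but off by default; z values are
otherwise passed through untransformed.

## 4. Functional traits and the meta-regression

Three per-gene traits proxy functional redundancy and multi-functionality:

* **betweenness centrality** (unweighted, unnormalised Brandes; scale is
  immaterial because traits are standardised before regression);
* **mean cosine similarity**: \( \mathrm{cos}(u,v) = |N(u)\cap N(v)| /
  \sqrt{d_u d_v} \) on binary adjacency rows, averaged over *all* other
  network vertices, zeros and other components included (the literal
  network-wide average; per-component averaging would inflate values for
  small components). Computed with sparse matrix–vector products, so memory
  scales with edges, never |V|²;
* **duplication level**: mean copy count among carrying strains (so
  single-copy genes score 1; an "extra copies" variant is exposed because
  the convention is ambiguous).

The meta-regression is OLS of the long-format z table on stress type (four
levels, no global intercept, so per-stress mean z is read off directly)
plus stress × trait interactions, with heteroskedasticity-robust (HC1)
standard errors — per-gene z variances are heterogeneous and no variance
weighting is attempted.

## 5. Loss weights and the stress tetrahedron

For genes with a strong loss propensity (min z < −2, configurable), the
loss signal is distributed over environments as rectified negative z:
\( w_e = \max(-z_e, 0) / \sum_f \max(-z_f, 0) \). This is invariant to
positive rescaling of z and maps each gene into a regular tetrahedron with
one vertex per stress; a gene is "exclusively" lost to an environment when
its maximum weight reaches the dominance threshold (default 0.75). The
chi-square uniformity test on the exclusive counts is the package's
environment-specificity summary. The weighting formula is the package's
own realisation of a relative z weighting; alternatives (e.g. softmax)
would change the embedding but not the dominance ordering.

## 6. Selection summaries

The package consumes per-gene codon summaries from an upstream dN/dS
analysis (n_codons, proportion of codons credibly under purifying
selection, any-positive flag); estimating dN/dS itself is out of scope.

* Gene-level: genes are stratified by z into decrease (min z < −2),
  increase (max z > +2, not already decrease) and none (all |z| < 0.5)
  pools, subsampled to a target size (all taken with a warning when a pool
  is smaller — at desk scale the neutral pool is naturally the smallest,
  because a four-way |z| bound is stringent). The purifying proportion is
  modelled with a **beta regression** (logit mean link, common precision
  φ), written in-package as no beta-regression implementation is among the
  package's dependencies: MLE via BFGS with an analytic gradient, SEs from
  the inverse observed information, and boundary proportions squeezed with
  `(y(n−1) + 0.5)/n`. A grid-search oracle bounds the log-likelihood in
  tests. The rare any-positive flags use a binomial GLM; an all-0/all-1
  category separates the likelihood and is flagged, with exact
  Clopper–Pearson bounds replacing the Wald interval for that category.
* Population-level: the mean purifying proportion per soil sample is
  beta-regressed on the sample's four stress gradients (refused below 10
  samples; a constant response is flagged degenerate rather than fitted).

## 7. Stress-stratified Fst

Soil samples are binned in 4-D stress space (Ward clustering on Euclidean
distance, cut to k = 5, then greedily rebalanced to sizes differing by at
most one) so that Fst pairs compare environmentally similar populations;
the within/between mean-distance ratio is reported and must be below 1.

Pairwise Fst between samples in the same bin uses a Hudson-style
ratio-of-averages estimator adapted to haploid strains:
\( F = 1 - \overline{H_w} / \overline{H_b} \) with unbiased within-sample
heterozygosity \( 2\hat p(1-\hat p)\,n/(n-1) \) and between-sample
heterozygosity \( \hat p_a(1-\hat p_b) + \hat p_b(1-\hat p_a) \); loci
monomorphic for the same allele in both samples are excluded, and negative
pair estimates are retained by default (truncation would bias the
regression). The estimator recovers the Balding–Nichols differentiation
parameter in expectation, which is the package's validation route.

The Fst ~ mean-stress regression violates independence (pairs share
samples), so inference is by permutation: whole stress profiles are
permuted across soil samples — preserving both the stress collinearity and
the pair-dependence structure — and the slope t-statistics recomputed, with
the add-one estimator \( p = (1 + \#\{|t^*| \ge |t|\})/(B+1) \), which is
super-uniform under the null by construction.

## 8. Circular-genome smoothing

Per-gene statistics are smoothed along the circular chromosome with a
Gaussian process whose covariance is Matérn-3/2 on the shortest-arc
distance, plus a white-noise nugget. Numerical choices:

* hyperparameters by profile marginal-likelihood maximisation (the
  marginal variance has a closed-form profile, leaving a 2-D search over
  range and noise ratio), range bounded in [L/500, L/2]; a failed search
  falls back to a fixed range of L/20 and is flagged;
* Cholesky with escalating jitter guards the factorisation (Matérn-3/2 on
  arc distance is not guaranteed positive definite on the circle, though
  at the fitted ranges the spectrum is comfortably positive);
* the returned band is the GP predictive interval of the latent smooth; a
  fully Bayesian posterior band would differ quantitatively but serves the
  same role;
* tracks are periodic by construction (predictions at 0 and L coincide),
  and fits are subsampled to `max_points` genes (default 800 in the
  pipeline, seeded) to keep the dense linear algebra tractable.

Retention hotspots are maximal grid runs where the smoothed |mean| shrinks
below half the magnitude of the track-wide median ("the predominant
z-score") *and* the credible band excludes that median; runs may wrap the
origin. Co-location with the core genome is measured as the Jaccard
overlap between hotspot cells and the top-decile region of a
wrapped-Gaussian kernel density of core-gene positions, compared against a
null that redraws core positions uniformly on the circle.

## 9. The synthetic-data generator

The generator produces all seven inputs under the default study design —
20 sites × 3 soil samples × 6 strains (fixed at 6 for determinism), 5,000
genes, 2,000 SNP loci — with planted truth:

* raw environment from a latent multivariate normal (exchangeable 0.25
  correlation by default, giving realistic collinearity), mapped to
  plausible field scales; salinity gets a 0.3 point mass at zero via a
  threshold on its latent coordinate;
* a duplication–divergence interaction network plus occasional bridge
  vertices, which spreads both cosine similarity and betweenness
  (coefficient of variation above 0.2 from ~200 genes);
* gene occurrence from the same logistic GLMM the analysis fits. Slopes
  combine a common loss trend (−0.3 per SD on all gradients), trait
  effects (similarity −0.4, duplication −0.4, betweenness +0.3 per trait
  SD), and gene noise (SD 1). A 40% fraction of accessory genes is
  essentially stress-neutral (slopes ~ N(0, 0.1)), emulating the
  environmentally unstructured bulk of real accessory genomes and
  populating the "none" stratification pool. Site and sample intercepts
  (SD 0.3 each) are drawn *per gene*: a single shared draw would act as an
  unmodelled environmental gradient whose chance correlation with a stress
  column biases every gene's coefficient in the same direction, which is
  exactly what the per-gene random effects are meant to absorb;
* SNPs from a Balding–Nichols model whose differentiation rises with the
  mean of heat and salinity on the logit scale (base 0.05, slope 0.5),
  planting the differentiation-increases-with-stress pattern;
* selection summaries from beta distributions with category means 0.80
  (loss), 0.60 (neutral), 0.75 (gain) at precision 20, and any-positive
  rates elevated only for the loss category (0.15 vs 0.05);
* genome positions uniform on an 8 Mb circle except core genes and
  stress-neutral accessory genes, enriched 5× inside the planted
  [0, 850 kb) hotspot.

One detection-limit consequence worth knowing: the planted hotspot shifts
the per-environment mean z by only a few tenths of a z-unit (a composition
effect — stress-neutral genes are enriched, strong responders are not
removed), while individual gene z-scores have an SD of several units. At
the default subsample of 800 mapped genes per track the GP smoother
therefore typically does *not* call the hotspot from pipeline output; the
smoother's recovery properties are instead established on tracks with the
band-width-to-signal ratio of the published retention pattern (a 2-z-unit
plateau), which it localises reliably. The acceptance script reports the
planted composition contrast (mean |z| outside minus inside the interval)
directly.

What it does **not** emulate: the empirical gene-frequency spectrum of real
pangenomes, linkage between SNP loci, genome rearrangements, sequence-level
processes, or spatial autocorrelation among sites. Passing tests therefore
demonstrate parameter recovery and internal consistency under the stated
generative model, not performance on any real dataset.

## 10. Problem sizes and scope choices

The test suite runs recovery simulations at the scale that makes each
property informative: 374 strains for richness-model recovery (50
replicates, plus 200 for type-I calibration), 1,000 genes for z-score
validity, 5,000 genes × 50 replicates for the (direct-simulation) trait
meta-regression, 2,000 loci for Fst recovery with 200 null datasets for
permutation calibration, and 1,000 mapped genes for hotspot recovery. The
end-to-end pipeline default (5,000 genes) completes in roughly ten minutes
on a single CPU, dominated by the per-gene GLMMs.

Known limitations: per-gene fits assume the same nested random-intercept
structure for every gene; the beta regression uses a common precision; the
permutation and binning schemes are the package's own documented stand-ins
for supplementary-only procedures of the upstream literature; partial R²
for the richness model is not implemented (its definition lives outside
the sources available to this package); and the GP band is predictive, not
fully Bayesian.
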