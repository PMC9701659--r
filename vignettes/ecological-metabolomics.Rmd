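---
title: "Ecological analysis of untargeted metabolomics data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ecological analysis of untargeted metabolomics data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecometab)
```

## The community analogy

An untargeted LC-MS run reduces a biological sample to a list of detected
ions, each defined by a mass-to-charge ratio and a retention time (an
m/z_rt pair) and quantified by its peak area in counts. `ecometab` treats
that list as a census: each m/z_rt pair is a "species", each biological
replicate a "sampling unit", and the abundance matrix a community matrix
with samples in rows and features in columns. The payoff is that the
well-understood machinery of community ecology — accumulation curves,
richness estimators, diversity and evenness indices, rank-abundance
models — applies directly, and answers questions chemometrics alone does
not: how complete is the sampling, how many features remain undetected,
how is abundance structured across the feature population, and how do
those properties shift under an experimental stressor.

The analogy has limits worth keeping in mind. Features are not independent
entities (adducts, isotopes and in-source fragments of one compound count
as several "species"), detection is censored by ionization efficiency, and
abundances are instrument counts, not organism counts. The workflow
therefore uses presence/absence for everything richness-related, keeps raw
(untransformed) abundances for diversity indices and fold changes, and
reserves normalization for the chemometric step, where it belongs.

## Step (i): chemodiversity

**Accumulation and rarefaction.** The species accumulation curve (SAC) is
estimated by the "random" method: cumulative richness is averaged over
random orderings of the sampling units (default `n_perm = 100`, seeded),
with a 95% band at mean ± 1.96 SD. The analytic counterpart (Mao's tau)
computes the exact expectation for k units,
S − Σ_j C(n − n_j, k)/C(n, k), and the test suite verifies that the
permutation curve converges to it, and that both match exhaustive subset
enumeration for n ≤ 8.

**Richness estimators.** Because the SAC pipeline is presence/absence, the
Chao estimator is computed in its incidence form (driven by Q1, the count
of features seen in exactly one unit, and Q2, seen in exactly two), with
the bias-corrected variant when Q2 = 0; first- and second-order jackknives
complete the set. A caveat the formulas impose: the second-order jackknife
can fall below the observed richness when duplicates dominate uniques
(Q1(2n−3)(n−1) < Q2(n−2)²); the tests assert the lower bound exactly where
the formula guarantees it. An abundance-based Chao variant is deliberately
not the default, since pooled presence/absence is what the accumulation
analysis consumes.

**Indices.** Shannon H′ uses natural logarithms (so a uniform community of
S species scores ln S — with feature counts in the hundreds to thousands,
H′ values up to ~6 are the expected scale in nats). The Simpson index is
reported in its inverse form DSi = 1/Σp², the effective number of equally
common species, which is the form consistent with values in the 3–4 range
for communities of hundreds of features. Pielou J′ = H′/ln S requires at
least two detected species and is left undefined (with an error) below
that. Confidence intervals are percentile bootstrap over sampling units,
default B = 100 resamples with a hard floor of 50.

**Rank-abundance models.** Five classical models are fitted to the
descending abundance vector by Poisson maximum likelihood: broken stick
(the null — no free parameters), geometric/niche preemption (α),
lognormal (μ, σ via the quantile parameterization
a_r = exp(μ + σΦ⁻¹((S − r + 0.5)/S))), Zipf (p1, γ < 0) and
Zipf–Mandelbrot (c, β, γ). The Poisson family matches the counts nature
of ion abundances and the standard `radfit` approach; AIC
(−2 logLik + 2k, gamma terms included so models are comparable) ranks the
fits, ties broken toward fewer parameters. The Zipf–Mandelbrot likelihood
is multimodal, so the optimizer runs Nelder–Mead from five deterministic
jittered restarts. A model-selection criterion based on residual standard
deviation is sometimes quoted alongside AIC in this literature without a
definition; here AIC is the sole selector and the residual SD is reported
for information only. Failed fits stay in the table flagged rather than
raising errors, so a degenerate input still returns a full five-row
ranking.

## Step (ii): chemometrics

Normalization is an explicit, recorded two-stage choice: an elementwise
transform (none or cube root) followed by per-feature scaling — autoscale
(x−mean)/sd, range (x−mean)/(max−min), or Pareto (x−mean)/√sd. The
positive-ionization convention pairs no transform with autoscaling; the
negative mode pairs cube root with range scaling; both are arguments, not
policy. Zero-variance features cannot be scaled and are dropped with a
warning. PCA is a centered SVD on whatever the normalization produced —
it never rescales on its own, so the scaling decision stays visible in
the provenance. The retained component count is either fixed (five is the
conventional choice here) or chosen by an elbow rule: the largest
component whose eigenvalue drop to the next exceeds the mean drop. The
exact elbow criterion is a documented package choice, since "elbow" is
not a single formula; `n_components` overrides it. Loading signs follow a
determinism convention (largest-magnitude entry positive) so runs are
platform-stable. Heatmap inputs default to correlation distance with
average linkage, pairing naturally with the Pearson analyses, and a
reusable threshold filter keeps features whose normalized abundance
reaches 2 anywhere.

## Step (iii): differential screening

Fold changes are ratios of raw group means with the control in the
denominator — scaling would destroy ratio meaning, so it is never applied
here. Zero control means are replaced by a pseudo-count, by default half
the smallest positive abundance in the table; the policy is explicit and
logged because instruments code absence as zero, not as "small". P-values
come from a Welch t-test on log-transformed abundances when each group
has at least two replicates; otherwise the screen degrades, with a
message, to fold-change-only. The threshold pair (FC ≥ 2, p ≤ 0.05) is
the field's volcano convention; the p cutoff is a documented default
since paired FC screening traditions vary, and no multiple-testing
correction is applied by default (a BH option exists) to match common
practice in this workflow style. Features flagged in two or more
comparisons form the consolidated marker list; because bookkeeping
conventions genuinely differ (filter-by-frequency vs deduplicate-all),
both modes are computed and reported.

## Step (iv): annotation and enrichment

Formulas over C, H, N, O, S, P, Na, Cl are parsed to element counts and
summed against embedded monoisotopic masses (six-plus decimals).
Adduct m/z values are the neutral mass plus fixed electron-corrected
shifts (+1.007276 for [M+H]⁺, +22.989218 for [M+Na]⁺, −1.007276 for
[M−H]⁻, +34.969402 for [M+Cl]⁻, +44.998201 for formate, ±18.010565 for
water loss), all singly charged. Matching is mass-only at ±5 ppm
(identification level 3); retention time is carried through but unused,
with an optional window left off by default because level-3 identification
makes no rt claim. The bundled compound and pathway references are local
flat files (TSV + GMT) transcribed from printed annotation tables, so
pathway sizes are the transcribed memberships, not a live KEGG snapshot —
reproducibility is traded for coverage, deliberately.

Enrichment reports two p-values per pathway: the exact hypergeometric
upper tail P(X ≥ k), and a permutation p that rebuilds the null the way an
m/z-based workflow must — random feature lists of the marker-list size are
drawn from all detected features, re-annotated through the same ±5 ppm
matcher, and scored, so the null inherits the annotatability structure of
the data. When every feature is equally annotatable the permutation null
collapses to the hypergeometric one, and a test verifies that convergence
within Monte-Carlo error.

## The synthetic-data generator

`sim_design()` encodes the study conditions the analysis assumes: 3
nitrate concentrations × 5 sampling times × 3 replicates (45 samples), a
baseline pool of 195 features under the control condition, per-arm
richness declines of 28.2% (intermediate stress) and 37.3% (severe
stress) phased in over the time course (none at the first sampling point,
half at the second, full from the third on — nutrient stress takes time to
bite), lognormal(meanlog 3, sdlog 1.2) abundances giving the skewed,
dominance-heavy structure real feature tables show, five stress-only rare
features per stressed arm at late times drawn from the low-abundance
tail, multiplicative replicate noise (lognormal, sdlog 0.2), Bernoulli
detection dropout at 0.10 per replicate-feature, and twenty spiked marker
features at fold change 4 in the stress arms. Where a value had no stated
condition (abundance scale, replicate noise, dropout, marker count) it was
chosen once at what a practitioner would call realistic for QTOF count
data and not revisited.

What the generator does *not* emulate: correlated features (adduct/
fragment families), retention-time drift, batch effects, heteroscedastic
instrument noise, or missingness that depends on abundance. Passing tests
therefore demonstrate that the statistical machinery recovers known
structure under the stated model — not that any particular real dataset
will behave as cleanly.

## Numerical choices and degenerate inputs

All randomized procedures (SAC permutations, bootstrap, Monte-Carlo
Lilliefors null, enrichment permutations, simulation) take explicit seeds,
and the pipeline derives per-step seeds from one global seed, so reruns
are bit-identical. Rarefaction uses log-binomial coefficients for
stability at large n. Presence is strict (> threshold), zero means "not
detected". Single-species vectors error in Pielou, constant samples error
in the normality test, single-unit matrices error in the estimators —
degenerate inputs fail loudly rather than returning NaN. The Lilliefors
p-value defaults to a seeded Monte-Carlo null (10⁴ replicates) because
printed tables are approximation-dependent; the Dallal–Wilkinson analytic
approximation is available for speed and is what the long-loop calibration
test uses.

## Problem sizes used in the tests

The test suite runs simulations at desk scale, chosen as the smallest
sizes at which the checked properties are statistically visible: 20-seed
loops for model-selection recovery, marker recall/false-positive rates and
spiked-pathway ranking; 200 seeds for bootstrap coverage; 1000 analytic
replicates for the normality-test type-I rate; communities of 40–100
features for the screening studies; and exhaustive enumeration up to n = 8
units for rarefaction. The acceptance script runs one full 45-sample
experiment end to end plus a null-background design for error rates.

## Known limitations

Identification stops at level 3 (mass-only): annotations are tentative by
construction. The incidence-based estimators assume exchangeable sampling
units; pooling replicates by condition before estimation changes the
estimand (condition-level richness), which is intended but easy to
overlook. The permutation enrichment inherits the resolution of the
compound reference — a small reference makes the null coarse. And the
broken-stick "null model wins" conclusion the rank-abundance analysis can
support is sensitive to truncating zero-count ranks, which the fitter does
silently on request of the Poisson likelihood.
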