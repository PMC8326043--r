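---
title: "Methods: diet-quality scoring and microbiome association analysis"
author: "dietbiome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diet-quality scoring and microbiome association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietbiome)
```

# What the pipeline does

`dietbiome` implements an end-to-end analysis linking habitual diet,
summarised as a *healthy food choices* (HFC) score built from
food-propensity-questionnaire (FPQ) responses, to the structure of the gut
microbiome: Shannon alpha diversity, Bray-Curtis beta diversity with
permutational inference (PERMANOVA, ANOSIM, dbRDA, PCoA), per-genus
association scans with FDR control, and KEGG-orthology (KO) functional
scans. Because the population cohort that motivates this design is
access-restricted, the package ships a calibrated synthetic cohort
generator with planted effects, so that every stage is testable and every
statistical property of the pipeline can be demonstrated on data with a
known ground truth.

# The HFC score

The FPQ records, for each food item, one of six consumption-frequency
categories. Categories 1–5 convert to fixed times-per-month values
(0.5, 1.5, 4.3, 8.6, 21.5 — a month is taken as 30 days and 4.3 weeks);
category 6 ("once a day or more often") converts to an item-specific tier
of 30, 45 or 60 depending on how often the food is plausibly eaten per day.
The default configuration (`default_food_items()`, shipped as a versioned
TSV so the item map can be extended to a full 42-item FPQ) contains 18
items in 11 components: fiber-rich breads, vegetables, fruits, berries,
juices, fish, poultry, low-fat cheeses, dressings and oils, nuts and seeds,
and red/processed meat.

The four meat items are *inverse scored*: the category is mapped through
the order-reversing bijection `c -> 7 - c` before conversion, so low meat
consumption contributes a high score. We use strict category reversal
because it is the only order-reversing bijection consistent with the
published component range of 2–150 for four meat items with tiers
30/30/45/45; a looser reading (mapping every frequent-consumption response
straight to 0.5) could not reproduce that range. With this convention, per
component, brute-force enumeration over all category assignments reproduces
the published score ranges exactly, and the minimum achievable HFC score is
9. (Summing the component maxima gives 855; the published global range ends
at 745, which no assignment of the published per-item values reproduces, so
the global maximum is deliberately not asserted anywhere.)

The HFC score is the exact sum of the 11 component scores; the *combined
fiber sources* score is the plain (never inverted) sum over the eight
fiber-source items: breads, the three vegetable items, fruits, berries and
juices. Participants missing any scored item are flagged and excluded
listwise — no imputation.

# Diversity and distance inference

Alpha diversity is the Shannon entropy `H = -sum p_i log p_i` of the
relative abundances, in **nats** by default (`0 log 0 := 0`); the log base
is an argument. The natural log is used because a cohort-mean of about 3.4
at ~90-genus resolution is only consistent with nats, and nats is the
prevailing default in ecology. Beta diversity is the Bray-Curtis
dissimilarity `sum|x - y| / sum(x + y)`, computed on relative abundances
(no rarefaction; the upstream protocol is shallow shotgun sequencing
summarised compositionally).

All distance-matrix inference is built on the Gower-centered matrix
`G = -1/2 J D^2 J`:

* **PCoA** eigendecomposes `G`; negative eigenvalues (Bray-Curtis is a
  semimetric) are reported, and Lingoes or Cailliez corrections are
  available.
* **PERMANOVA** partitions `trace(G)` by sequential (Type-I) projections of
  the design, covariates entered before the diet term. Sequential
  partitioning is a documented choice: the motivating analysis reports a
  single R² per diet variable "controlling for" covariates without naming
  an SS type; marginal SS is available via `by = "margin"`. Negative
  eigenvalues stay in the SS totals (McArdle–Anderson convention).
* **ANOSIM** uses Clarke's statistic: mean between-group minus mean
  within-group rank of the `M = n(n-1)/2` distances, divided by `M/2`
  (average ranks on ties), which bounds `R` in `[-1, 1]`.
* **dbRDA** projects `G` on the constraint space; the constrained
  proportion is `trace(HGH)/trace(G)`, constrained axes come from the
  eigendecomposition of the fitted part (negative axes dropped from
  coordinates, retained in totals), and biplot scores are correlations of
  predictors with the constrained sample scores.

Permutation p-values use free permutation of sample labels and the add-one
estimator `(1 + #{F* >= F}) / (1 + n_perm)`; with the default 999
permutations the smallest attainable p is exactly 1e-3. Free label
permutation (rather than residual permutation) is the simplest defensible
default and is flagged as such. Every permutation operation derives its
RNG substream from a master seed *and a hash of the operation name*, so
adding one analysis to a run never shifts another's permutations, and all
results are bit-reproducible given `(n_perm, seed)`. For `n <= 8` an
`exhaustive = TRUE` mode enumerates all `n!` label permutations and returns
the exact p-value; the test suite checks the sampled estimator against this
enumeration.

# Association scans

Per-taxon scans follow the MaAsLin recipe: genera are first reduced to a
*core microbiota* — kept if their relative abundance reaches the detection
threshold (default 0.1%) in at least the prevalence fraction of samples
(default 1%), both comparisons `>=`. "Minimum abundance" is read as a
per-sample detection threshold, the convention of standard core-microbiota
tooling. Core abundances are arcsine-square-root transformed and each taxon
is regressed on the diet variable plus age, sex, BMI, smoking and
medication use. Effects are reported **per 1 SD of the predictor**
(`beta * sd(x)`; the outcome stays on its native scale) — this
predictor-only standardisation matches how the motivating study tabulates
"β/SD", and is applied to binary covariates identically for consistency.
P-values are Benjamini-Hochberg adjusted *within each scan* (not across
scans), with significance at `q < 0.05`.

KO scans regress `log10(abundance + pseudocount)` on the HFC score with the
same covariates. The default pseudocount is half the smallest non-zero
value of each KO across samples (the source analysis is silent; this is the
least-informative conventional choice, overridable). Selection uses raw
`p < 0.05` by default — mirroring how the corresponding functional figures
are filtered — with a q-value mode available; significant KOs are split by
effect sign, and an externally supplied KO-to-node map can aggregate them
to functional-hierarchy nodes by the mean significant estimate.
Diet-by-sex and diet-by-age interactions are available in principle by
pre-building columns, but are excluded from all default models. Species
panels (e.g. short-chain-fatty-acid producers) reuse `per_taxon_scan()` on
a species matrix; there is no species-specific code path.

# The synthetic cohort generator

`simulate_cohort()` draws a latent "health-consciousness" factor
`h ~ N(0, 1)` per participant, shifted by +0.717 for women, and generates
each item's ordinal category from a cut-point model on a logistic latent
scale: `u = a_i + lambda w_i h + logistic noise`, with cut-points
(-3, -1.5, 0, 1.5, 3), loading `lambda = 0.880`, `w_i = 1` for healthy
items and `w_i = -0.6` for meat-consumption items (health-conscious
participants eat less meat). The per-item offsets `a_i` were calibrated
once, semi-analytically, against the study-sample component means, then
jointly scaled so the simulated HFC distribution matches the published
cohort description: mean 250, SD 103.2 times/month, with women scoring
about 58 points higher and the component-level sex differences pointing the
published way. Setting `loading = 0` makes the items mutually independent
(the sex effect flows only through the factor), which the tests exploit.
Covariates follow the published margins: age 48 ± 12.8 y, BMI 26.9 ± 4.6,
53.1% women, smoking 28.5%/19.5% and medication use 29.4%/43.9% by sex.

`simulate_abundances()` draws log-normal taxon intensities around a
heavy-tailed rank power-law panel (exponent 0.95 over 91 core genera —
chosen so the default panel's Shannon index averages ~3.4 nats with SD
~0.39 — plus 100 rare genera at shares of 1e-4.5–1e-5.5 that the core
filter removes). Two design choices make recovery tests exact rather than
approximate:

1. **Planting on the analysis scale.** Per-taxon effects are added directly
   on the arcsine-sqrt scale (`asin(sqrt(p)) + beta * z_HFC`, inverse
   transformed), and only the *non-planted* taxa are rescaled to the
   remaining row mass, so the planted column carries exactly `beta` per SD.
   The two default planted genera (`g003` +0.10, `g005` -0.07) have reduced
   dispersion (sigma 0.4 vs 1.0) so the transform never clips at zero.
2. **A compensated evenness channel.** Shifting a dominant taxon drags the
   Shannon index with it; the generator measures that implicit diversity
   drift on the generated data and lets the evenness channel (per-sample
   compression of the non-planted log shares) carry only the *net*
   configured alpha effect. The Shannon response to compression is probed
   numerically on the data itself rather than taken from a constant, so the
   configured effect (default 0.044 nats per SD of HFC, with covariate
   effects 0.054/-0.039/-0.082/-0.049/-0.039 for age/sex/BMI/smoking/
   medication) is delivered under any panel.

`simulate_ko_table()` is analogous on the log10 scale: planted KOs have
their share multiplied by `10^(beta * z_HFC)` exactly, the rest rescaled.
All generators are pure functions of `(spec, seed)` and attach their ground
truth as an attribute; `simulate_inputs()` writes the four input tables
plus a JSON truth manifest.

What the generator does *not* emulate: phylogenetic correlation between
taxa, sequencing-depth/read-count noise, batch structure, and longitudinal
sampling. Passing tests therefore demonstrate the correctness and
calibration of the *statistical machinery* on data with this structure, not
that real cohorts satisfy the generator's assumptions.

# Numerical choices and degenerate inputs

* Frequencies use the printed one-decimal constants, never re-derived
  floating-point ratios, so score sums are exact.
* `0 * log 0 := 0` in the Shannon index; all-zero samples are an error
  naming the sample, as are negative abundances and non-symmetric distance
  inputs.
* Abundances in `(1, 1 + 1e-12]` are clipped to 1 by the arcsine transform;
  anything further out is an error.
* Permutation F-comparisons use a `1e-8` slack so exhaustive enumeration is
  tie-stable; t-test p-values are floored at the smallest normal double so
  perfect fits stay inside `(0, 1]`.
* Rank-deficient designs fail before any permutation, naming the collinear
  terms; constant predictors, single-member ANOSIM groups, and extreme
  deciles with fewer than two members are all explicit errors.
* Heavy ties at a decile boundary make the extreme-decile groups unequal;
  this is reported, not silently rebalanced.

# Problem sizes

The default synthetic preset uses 500 participants, 191 taxa (91 core), 200
KO groups and 999 permutations; at this size the full `run_all()` graph
(13 diet variables × alpha + PERMANOVA, one dbRDA, one extreme-decile
ANOSIM, 13 per-taxon scans, one KO scan) completes in well under a minute
and is byte-reproducible under a fixed seed. The study-scale cohort
(n = 4930) is available by setting `cohort_spec(n_participants = 4930)`.
Recovery and calibration checks in the test suite use n = 2000 (planted
effect recovery, 100-replicate alpha sign recovery) and 200 replicates of
n = 300 (global-null false-positive calibration).

# Known limitations

* The published global HFC maximum (745) is not reproducible from the
  published per-item values and is not asserted.
* Free label permutation is used throughout; residual permutation schemes
  are out of scope.
* Bray-Curtis dissimilarities are computed on relative abundances without
  rarefaction; phylogeny-aware metrics (UniFrac) and dispersion tests
  (PERMDISP) are out of scope.
* The KO node aggregation consumes an external KO-to-node map; no
  functional hierarchy is bundled.
* The alpha-diversity evenness channel delivers the configured effect up to
  the linearisation of the Shannon-vs-compression response; its sign and
  approximate magnitude are exact in expectation, the magnitude is not
  guaranteed to the third decimal.
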