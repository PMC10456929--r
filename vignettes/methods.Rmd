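---
title: "Models and design choices in metadimorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in metadimorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metadimorph)
```

`metadimorph` asks, for every plasma metabolite in a knockout-mouse
cohort, whether a gene knockout shifts its level and whether that shift
depends on sex. This vignette explains the statistical models, the
tunable parameters, what the synthetic-data generator does and does not
emulate, and the design decisions taken where the methodology was
genuinely open.

## Study design and data model

The design the package targets is a shared-control KO screen: a pool of
wildtype mice (default 20 per sex) and many KO lines with very few animals
each (default 3 per sex), measured on five MS platforms (GC primary
metabolites, HILIC biogenic amines, CSH lipidomics, targeted bile
acids/steroids, targeted oxylipins). Abundances are arbitrary intensity
units, non-negative, with `NA` marking values below detection. All
statistics operate on the natural scale, and fold-changes are ratios of
arithmetic group means — chosen so that reported effect sizes match what a
bench scientist reads off a bar plot, at the cost of some robustness that
log-scale analysis would buy.

## Quality control and preprocessing

Three feature filters run before any statistics, each read strictly at its
boundary:

* **RSD filter.** The relative standard deviation over pooled QC
  injections (sample sd / mean × 100) must not exceed `rsd_max` (default
  50 %); a feature at exactly 50 % is retained because the rule is "greater
  than". Features with fewer than two QC values cannot be evaluated and
  pass.
* **Missingness filter.** A feature missing in at least `missing_max`
  (default 70 %) of study samples is removed; exactly 70 % is removed.
* **Prevalence filter.** A feature must be detected in strictly more than
  `prevalence_min` (default 30 %) of study samples; exactly 30 % is
  removed. With the defaults the missingness and prevalence rules agree at
  the boundary, which is why applying the three rules in any order yields
  the same retained set (a property the tests check).

Internal standards are removed via an annotation flag rather than by
chemical identity, since the package has no chemistry engine.

**Half-minimum imputation** replaces each missing study cell with half the
minimum observed value of that feature within the sample's genotype group.
This is well-posed only under the below-detection interpretation of
missingness, which is exactly what the generator's MNAR mechanism
produces. A group with no observed value falls back to the feature's
global minimum; a feature observed nowhere is an error (the filter should
have removed it). A config switch (`gc_noise_floor`) instead draws
Uniform(0.3, 0.7) × group minimum for GC features, emulating local-noise
replacement policies of electron-impact pipelines; the default is uniform
half-minimum for all platforms. Phenotypes use the *full* group minimum
(not half) — phenotype readings have less variance than intensities and a
missing reading is assumed to be a minimal value, not half of one.

**Median batch normalization** divides each value by its batch's
per-feature median and rescales by the feature's grand median, so batch
medians agree and units are preserved. "Median per batch" is ambiguous
between per-feature and batch-global medians; per-feature correction is
the standard intent of median scaling and is the default, with a
batch-global fallback when a feature has fewer than three observed values
in a batch. Only the HILIC platform is normalized by default; surrogate-
variable or regression-based drift correction for the GC platform is out
of scope, and GC data flow through unchanged (or through the same median
scaling via config).

## Wildtype sex effects

Each metabolite is tested with `Y ~ Sex`, or `Y ~ Sex + Weight` when body
weight (grams) is included as a covariate. Two variance modes exist:

* `pooled` — ordinary least squares; the Wald test of the sex coefficient
  is exactly the pooled-variance two-sample t-test.
* `per-sex` (default) — two-step feasible generalized least squares:
  residual variances are estimated per sex from the OLS fit and the model
  is refit with inverse-variance weights. For a two-group sex model this
  is the natural heteroskedasticity structure; correlation structures are
  not modelled because the design has no repeated measures. When the
  per-sex variances are equal the two modes coincide (tested to 1e-6).

Benjamini–Hochberg adjustment is computed by the package's own step-up
implementation, property-tested against `stats::p.adjust` on random
p-vectors. Directions (`higher-in-M` / `higher-in-F`) always follow the
sign of the arithmetic mean difference M − F.

## KO genotype and interaction effects

For one KO line (its 6 mice plus the full WT pool — shared controls are
deliberate, a per-line subset is available in config), two nested-model F
tests are computed by explicit least squares,
F = ((RSS₀ − RSS₁)/Δdf)/(RSS₁/df₁):

* genotype: `Y ~ Genotype + Sex + Genotype:Sex` vs `Y ~ Sex` (Δdf = 2),
* interaction: the full model vs `Y ~ Genotype + Sex` (Δdf = 1).

Per-sex KO-vs-WT comparisons use two-group OLS (pooled t-test; Welch via
config). No FDR is applied across metabolites here by design — the screen
generates hypotheses rather than biomarkers — and a config flag can turn
it on.

The dimorphism decision tree at level α (default 0.05):

1. genotype and interaction both ≥ α → `ns`;
2. genotype < α, interaction ≥ α → `genotype-no-sex-difference`;
3. interaction < α → `female-only` / `male-only` when exactly one per-sex
   test is significant, `opposite-direction` / `different-effect-size`
   when both are (by sign agreement), and `interaction-only` when neither
   is.

Two open points were decided as follows. First, sub-classification gates
on the interaction test only; requiring the genotype test as well is
available as `gate_genotype` but not default, because the interaction
contrast is the dimorphism claim itself and the genotype p is reported
alongside. Second, the `interaction-only` category is introduced for the
case that a four-way wording does not cover (significant interaction,
neither per-sex contrast resolvable at n = 3); it is always reported
separately and never merged into a neighbouring category.

Standardized fold-changes divide the KO arithmetic mean by the sex-matched
WT arithmetic mean. Their `spread` is the first-order delta-method sd of
the ratio of means, fc·√(sd²_KO/(n_KO·m²_KO) + sd²_WT/(n_WT·m²_WT)),
which matches the bootstrap sd of the same statistic within a few percent
(tested within 20 %).

## Cluster enrichment

Chemical clusters are a supplied input (non-overlapping labels in the
feature annotation; deriving them from ontologies or structural similarity
is out of scope). Each cluster of at least `min_size` (default 3; the
authors of comparable tools do not publish their minimum) is tested with a
one-sided one-sample Kolmogorov–Smirnov statistic, D⁺ = max(i/n − p₍ᵢ₎),
against Uniform(0, 1) — one-sided toward an excess of small p-values,
since depletion of significance is not an interesting alternative here —
followed by BH adjustment across clusters.

## Metabolite–phenotype association

Spearman correlations run per sex in WT mice only; with three KO mice per
sex per line, line-level correlations would be noise. Rho is the Pearson
correlation of average ranks on pairwise-complete observations; the
two-sided p uses the t approximation on n − 2 df. The "more than 14 data
points" rule is read strictly as n ≥ 15 per sex, so the t approximation is
always in its comfortable range; an exact permutation p for n < 10 exists
for safety but is unreachable under the filter. Correlation pairs are
categorized analogously to the KO tree (`female-only`, `male-only`,
`both-same-direction`, `both-opposite-direction`), and the summary counts
each (metabolite, phenotype) pair once, with "significant" meaning
significant in at least one sex — the union reading is what makes the
four category counts sum to the significant total. The cluster ×
phenotype matrix signs −log10 of the KS p by the median rho of the
cluster's significant members, giving the red/blue heatmap coordinates.

## The synthetic cohort generator

`sim_config()` defaults encode the target study shape: 40 WT (20/sex), 30
KO lines × 6 mice (3/sex), 800 features split across the five platforms at
the proportions of a broad plasma panel (13 % GC, 22 % HILIC, 54.5 %
lipidomics, 4 % bile/steroids, 6.5 % oxylipins), 22 QC and 22 blank
injections, and 208 continuous phenotypes.

Key modelling choices, none of which are claims about any real dataset:

* **Lognormal abundances.** Plasma intensities are right-skewed and
  effects are naturally multiplicative; log-additive planted effects make
  fold-changes exact. Per-feature natural-log means are drawn
  U(log 10⁴, log 10⁷) and residual sds U(0.2, 0.6) (biological CV roughly
  20–65 %), a range under which the natural-scale F and t tests hold their
  nominal size in the package's null-calibration tests and the planted
  2-log2 one-sex contrast is detected with power above 0.8 at 3-vs-20.
* **Sex effects** on 55 % of features, log2 magnitudes U(0.25, 2) (up to
  4-fold), 75 % of them higher in males.
* **KO archetypes.** Per line, 30 % of features are affected; one third of
  those are dimorphic, split equally among `female-only`, `male-only`,
  `opposite-direction` and `different-effect-size`, the rest
  `both-sexes-equal`. Planted log2 magnitudes are U(1, 2.5);
  `different-effect-size` plants two same-sign effects at least 1.5 log2
  apart so both per-sex contrasts are detectable yet distinguishable.
  The truth table records every non-null (feature, line) pair for
  recovery testing.
* **MNAR missingness.** Cells below each feature's 30 % abundance quantile
  are censored with 4-fold higher odds, calibrated so the expected overall
  missing fraction equals the target rate (default 10 %); an extra 3 % of
  features sit near the detection limit (~80 % missing) to exercise the
  prevalence filter. This realizes the below-detection assumption that
  justifies half-minimum imputation.
* **QC replicates** with median technical RSD 10 % and a 5 % contingent of
  poor features (RSD 55–120 %) to exercise the RSD filter; a
  multiplicative batch effect (e^0.4) on HILIC features in the second
  batch exercises the normalizer.
* **Phenotypes** are a standardized log-abundance driver feature times
  sex-specific coefficients plus unit Gaussian noise; driver patterns are
  30 % female-only, 30 % male-only, 15 % shared, 5 % opposite, 20 % null,
  planting the correlation dimorphism the association stage must recover.

What the generator does **not** emulate: chromatographic drift curves,
realistic inter-metabolite correlation networks (features are independent
given their planted effects), platform-specific noise shapes, litter and
cage effects, and compound identity. Passing recovery tests therefore
demonstrate that the statistics detect what they claim to detect under
the package's assumptions — not that any particular real cohort satisfies
those assumptions.

## Numerical choices and degenerate inputs

* Constant responses give p = 1 with a warning rather than an error.
* Rank-deficient designs (a sex missing in a KO line) skip the line with a
  warning; p-values are never silently fabricated.
* The F statistic is clamped at 0 against floating-point negativity of
  RSS differences.
* Ties in ranks use average ranks throughout.
* Result TSVs are written at full `as.character()` precision (≥ 15
  significant digits) with deterministic row order, so byte-identical
  reruns and 12-digit p-value round trips are guaranteed.
* All randomness flows from a single integer seed; the pipeline derives
  stage seeds deterministically from it.

## Problem sizes used in the test suite

The suite runs the full study-shaped design where it matters and smaller
cohorts elsewhere: null calibration uses one KO line with 2000 features;
oracle-equivalence checks use 1000 random small instances per statistic;
archetype recovery uses one line with 400 features at three planted effect
sizes (1, 1.75 and 2.5 log2 units); pipeline smoke tests use 3 lines × 80
features with 16 WT per sex. These sizes keep every Monte-Carlo estimate
inside comfortable binomial error bands while the whole suite completes in
a few minutes on one core.

## Known limitations

* Natural-scale ANOVA on lognormal data is slightly liberal at high CV;
  the generator's CV range was chosen where the size distortion is
  negligible, but very noisy real features would benefit from a log
  transform the package deliberately does not apply.
* With n = 3 per sex, the per-sex contrasts that drive sub-classification
  have limited power; `interaction-only` calls and misclassification
  between `different-effect-size` and one-sex categories are expected at
  small effects, as the recovery tests quantify.
* The half-minimum rule biases variances downward when missingness is not
  truly below-detection.
* Cluster enrichment inherits whatever dependence exists among member
  p-values; the KS null assumes independent uniforms, so q-values across
  correlated clusters are approximate.
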