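---
title: "Methods: models, parameters and design choices in polyqscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in polyqscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyqscreen)
```

`polyqscreen` implements the statistical cascade of an image-based
viability screen for suppressors of polyglutamine (Htt-Q94) toxicity:
plate normalization and 3SD hit calling, dose-response validation,
transcriptional-signature connectivity matching, and the downstream
phenotype statistics. This vignette is the package's account of the
models behind each stage, the parameters that matter, and the choices
made where the design was genuinely open.

## The screen model

A well's nuclei count after the growth period is modeled as

```
count ~ NegBin(mean = B * delta^[dox] * e_c * f_plate * f_edge, size = r)
```

with `B` the no-dox baseline (default 2000 nuclei per well, the scale a
few-thousand-cell well reaches after a week from a 100-cell seed),
`delta` the multiplicative viability cost of inducing the toxic protein
(default 0.5), `e_c` the compound's multiplicative effect (1 for inert
compounds, > 1 for rescuers, < 1 for toxic compounds), `f_plate` a
log-normal per-plate factor (SD 0.1 on the log scale) and `f_edge` an
optional border-well factor. Controls of both roles — no-dox, and
dox-only without compound — are scattered over seed-determined interior
positions, 16 of each per plate (scattered, not edge-column, placement
is part of the design being emulated: interior controls are immune to
the edge artifact they are meant to diagnose).

Counts are negative-binomial because well populations grown for a week
are overdispersed relative to Poisson; the default size `r = 111.1`
together with a dox-only mean of 1000 gives a control coefficient of
variation of 10% (`CV^2 = 1/1000 + 1/111.1 = 0.01`), a realistic noise
level for a cell-growth readout. `dispersion = Inf` recovers Poisson. A
second noise model, `noise_model = "gaussian"`, draws rounded
`N(mean, cv * mean)` counts; its role is explained under *Null
calibration* below.

### Normalization and the 3SD rule

Each well is divided by the mean of its own plate's dox-only control
wells. This removes any multiplicative plate factor exactly — a property
the test suite checks as exact hit-set invariance under planted
log-normal factors — and puts all plates on a common percent-of-control
scale in which the dox-only mean is 1 by construction. The dox-only
controls are the screen's vehicle condition (dox + DMSO, no compound),
so they serve as both the normalization denominator and the reference
population for hit calling; no-dox controls are reserved for QC (the
assay window in Z').

A compound's single measurement is the unweighted arithmetic mean of its
per-replicate normalized values. It is a primary hit when that mean
*strictly* exceeds `mu + k * sigma` of the normalized dox-only controls,
with `k = 3` by default — one-sided, increases only, and the boundary
itself is not a hit. Wells with zero nuclei normalize to 0, are kept and
flagged, and can never be hits.

`control_stats()` exposes the two decisions the rule leaves open:

* **scope** — `"pooled"` (default) estimates one `mu`/`sigma` across all
  plates of the screen; `"per_plate"` averages per-plate locations and
  pools within-plate spreads. The robust option (`estimator = "mad"`)
  replaces mean/SD with median/MAD.
* **aggregate** — `"well"` (default) treats each control well as one
  observation, so `sigma` is a *single-well* SD while the compound
  statistic is a *triplicate mean*; this is the conservative, and
  presumably conventional, reading of the rule. `"replicate_mean"` first
  averages each control position across its replicate plates, giving a
  control spread on exactly the scale of the compound statistic.
* **loo** — with `TRUE`, a control well is normalized by the mean of the
  *other* dox-only wells on its plate. Without this, a control well sits
  inside its own denominator and its normalized spread is shrunk by a
  factor `sqrt(1 - 1/n_ctrl)` while compound wells are widened by
  `sqrt(1 + 1/n_ctrl)`; leave-one-out removes the asymmetry.

### Null calibration

The combination `aggregate = "replicate_mean", loo = TRUE` is the
*matched-variance design*: control and compound statistics are means of
the same number of identically distributed well values, so under
Gaussian well noise the null probability that an inert compound exceeds
`mu + 3 sigma` is the one-sided tail `Phi(-3) ~ 1.35e-3`. The
acceptance suite verifies this on a simulated screen of 1e5 inert
compounds in the 384-well triplicate geometry, at control CV 10%, within
three Monte-Carlo standard errors.

Two deliberate conditions make that oracle exact rather than
approximate. First, the calibration uses the Gaussian noise model: a
negative binomial at CV 10% carries skewness of about `2 * CV = 0.2`,
which inflates the 3SD right tail to roughly `1.9e-3` — a real property
of overdispersed counts, not an implementation artifact; the Gaussian
model isolates the rule's calibration from that skew. Second, with the
default `aggregate = "well"` the compound statistic has `1/sqrt(3)` of
the control SD and the implied tail is `Phi(-3 * sqrt(3)) ~ 1e-7`,
unmeasurable at any desk scale; the matched design is the one in which
the rule's nominal tail is testable.

### Planted-effect recovery

The default generator plants 4 rescuers at `e_c = 1.5`. On the 10.5%-CV
background this is about 4.8 control SDs, comfortably above the
threshold's `3 sigma + 3 SE` band, and the acceptance suite requires the
full call-then-validate funnel to recover all four with zero
toxic-compound false positives in at least 90% of 100 seeds. The default
design has `f_edge = 1`: the 3SD pipeline applies no spatial correction
(B-score-style polishing is out of scope), so a border artifact would
mechanically convert border-placed rescuers into threshold coin-flips;
the artifact is instead available as an opt-in stressor
(`edge_effect < 1`) whose detection by the QC edge diagnostic is tested
separately.

### Dose-response validation

Validation re-tests candidates at 0.5, 1, 3 and 10 uM (the doses are a
configurable list) in triplicate. For each compound, normalized well
values at every dose are compared with the validation plates' dox-only
controls: a one-way ANOVA across `{control, doses}` followed by
per-dose contrasts against control. The primary post-hoc is single-step
Dunnett (`multcomp::glht`), the canonical many-to-one procedure;
Holm-adjusted Welch t-tests are the fallback (`method = "holm"`), more
conservative at triplicate scale because each contrast then relies on
two small-sample variances rather than the pooled ANOVA variance. A
dose counts only when its adjusted p is below alpha *and* its mean
exceeds the control mean; validation requires two or more such doses.
Dunnett p-values involve randomized multivariate-t integration, so the
implementation pins an internal RNG substream around each call — the
p-values are reproducible to the digit across runs, which the
end-to-end determinism test relies on.

In the generator, a planted compound's effect is the same at every dose.
A saturating dose-response curve would be more realistic, but the
validation rule is a threshold on the number of significant doses, not a
curve fit (EC50 estimation is deliberately out of scope), and the flat
profile is the simplest shape that exercises it.

## Imaging

Nuclei counting is a deterministic classical stack over EBImage
primitives: Gaussian smoothing (`smoothing_sigma`, default 1 px), global
threshold (Otsu on the smoothed image by default, or a fixed cutoff),
hole filling, watershed on the distance transform for declumping
(`min_split_distance`, default 4 px, is the local-maxima suppression
radius; `watershed_tolerance`, default 0.5 px, the minimum basin depth),
then an area gate (10–2000 px) and optional border exclusion. Border
exclusion is off for whole-well counting — the four tiles of a well
jointly cover it, so border objects belong to a neighbouring tile's
interior — and recommended on for per-cell intensity work, where partial
objects bias means. The original pipeline's operator settings are not
public; every step here is an explicit parameter, and the defaults are
tuned only against this package's own synthetic fixtures (Gaussian-
profile nuclei of radius ~5 px), on which counts are exact in at least
99% of images with disjoint nuclei.

Per-cell intensity is the mean of a signal channel over each retained
region; with `dilate_radius > 0` the nuclear mask is expanded by a disc
and labels are propagated into the new territory, a cytoplasm proxy that
keeps touching cells separate. The statistic is verified against an
explicit per-pixel loop, exactly.

## Signatures and connectivity

The query signature is the top-150 up- and down-regulated genes among
those with Benjamini-Hochberg adjusted p below 0.05, ranked by log2
fold-change (a `rank_by = "pvalue"` switch exists because "ranked by"
could also be read as significance order). LFC ties break by smaller raw
p, then gene id, making extraction deterministic and stable under row
permutation. BH adjustment is the standard step-up procedure
(`stats::p.adjust`); the test suite holds it equal to a brute-force
double-loop oracle.

Connectivity against a reference drug's full gene ranking is the classic
two-sided *unweighted* Kolmogorov-Smirnov enrichment: hit/miss walks for
the up and the down set separately, each scored by its maximal signed
deviation, combined as `tau = (ES_up - ES_down)/2` when the signs
disagree and 0 otherwise. This is intentionally the transparent desk
version of production connectivity scoring — no cell-line
summarization, no normalization of `tau` against a reference null
distribution — because the qualitative contract (extremes at ±1,
antisymmetry under up/down swap, permutation null centred on 0, a
self-derived reference drug ranking first) is what the pipeline needs
and what can be tested exactly. Signature genes absent from the
reference universe are an error by default; `ignore_missing = TRUE`
drops them and records the count. Class enrichment among the top `k`
drugs (default 5% of the reference) is a one-sided hypergeometric tail.

The reference-matrix generator gives drugs of one class a shared latent
gene-score vector, mixing proportion `class_concordance` of the score
variance; an anchor option ties one class's latent scores to a given
signature, planting an agonist class that genuinely resembles the query
— the structure that drives the pipeline's enrichment demonstration.

## Phenotype statistics

**Competition fitness.** With a constant per-day growth-rate difference
`s`, the expressing fraction follows
`p_t = p0 e^(-s t) / (p0 e^(-s t) + 1 - p0)`, linear in logit space.
The fit is weighted least squares of `logit(p_t)` on day, weights
`n_t p_t (1 - p_t)` (inverse large-sample variance of an empirical
logit), with the standard error taken from the weight matrix at
dispersion 1 rather than the residual mean square — with two or three
timepoints a residual-based SE has essentially no degrees of freedom,
while the binomial sampling variance at 4e4 cells per timepoint is
known. Noiseless logistic data are recovered exactly (the fit is a line
through collinear points), and at binomial noise the estimate falls
within 2 SEs of truth in at least 95% of seeds in the acceptance suite.
Proportions of exactly 0 or 1 receive a Haldane half-cell correction
and are flagged. Condition contrasts are Wald tests on the fitted `s`;
a rescue is a negative `delta_s` against vehicle.

**Survival.** The default test is a replicate-level Welch t-test on
per-well survival fractions — three wells per arm is the design scale,
and pooling eggs would ignore well clustering; a pooled two-proportion
test is available when only one replicate exists. Arm summaries report
both SD and SEM, since conventions differ on which error bar is meant.

**Motility.** Welch t-test on per-worm bends per 30 s (Mann-Whitney as
the nonparametric option), with the mean difference as effect size.
Welch's variant is used wherever a t-test is named, as the variance-
equality assumption buys nothing here.

**Conversion metrics.** Purity is marker-positive over nuclei counts,
efficiency marker-positive over plated cells — exact ratios with
validation, scale-consistent by construction.

**Intensity comparisons.** Two groups use a Welch t-test; three or more
take one-way ANOVA with Tukey HSD post-hoc.

## What the generators do and do not emulate

The generators reproduce the *statistical structure* the pipeline must
survive: overdispersed counts with plate and optional edge structure,
scattered controls, planted multiplicative effects, Gaussian-spot nuclei
with additive noise, uniform-null DE p-values with planted extremes,
class-correlated reference rankings, binomial competition/survival
sampling and Poisson bend counts. They do not emulate microscope optics
beyond Gaussian spots, segmentation-error-induced count bias,
cross-contamination or spatial drift within plates, raw sequencing
reads, or flow-cytometry event data. Passing recovery tests therefore
shows the *statistics* behave as designed under their assumed noise
models; it does not certify performance on real images or real DE
output, where miscalibration enters upstream of these models.

## Numerical and degenerate-input conventions

* Every generator draws from a named substream derived from one master
  seed (`substream_seed`), so adding a generator never shifts another's
  stream; identical config and seed give byte-identical outputs, which
  the determinism tests check by file hash.
* Hit margins sort descending with ties broken by compound id;
  connectivity ties by drug id; signature ties by raw p then gene id;
  equal-magnitude KS deviations resolve positive.
* `sigma = 0` control sets are legal (threshold collapses to `mu`,
  flagged); plates without dox-only controls, or with zero control mean,
  are errors naming the plate; constant or saturated images return zero
  objects with a QC flag rather than an error; non-identifiable fitness
  series (all-boundary proportions) are errors naming the condition.
* Problem sizes in the test suite are chosen to give each statistical
  check real resolution at desk scale: 1e5 simulated compounds for tail
  calibration, 100 screen seeds for funnel recovery, 200 images for
  count accuracy, 500 seeds for fitness coverage, 200 seeds for the
  power checks.

## Known limitations

* The 3SD rule's calibration statement is exact only for the matched-
  variance Gaussian design; under the default negative-binomial noise
  the realized null tail is higher (skewness), and under the default
  well-level control spread it is far lower (variance mismatch). The
  package exposes all three regimes rather than pretending one number
  covers them.
* No spatial correction beyond the edge diagnostic; a real screen with
  strong gradients needs polishing before this pipeline's hit rule.
* Connectivity scores are raw ES combinations; they order drugs within
  one reference matrix but are not comparable across matrices the way
  production normalized scores are.
* The fitness model assumes a constant growth-rate difference; real
  competition assays with density effects or drug decay would show
  curvature in logit space, which the residuals expose but the model
  does not capture.
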