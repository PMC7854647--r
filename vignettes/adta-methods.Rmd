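---
title: "Automated digital TIL analysis: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated digital TIL analysis: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adta)
```

## The measurement and the score

Automated digital tumor-infiltrating lymphocyte analysis (ADTA) quantifies
the immune infiltrate of a primary melanoma from H&E whole-slide images.
The package begins where the upstream lymphocyte detector ends: each image
arrives as a table of 100×100-pixel patches, each patch carrying the
coordinates of its upper-left vertex and a probability that lymphocytes are
present. A pathologist supplies a loop drawn around the tumor region; the
package rasterizes that annotation to a binary mask and scores only patches
inside it.

A patch is *TIL-positive* when its probability is at least the positivity
threshold τ (default 0.775, the detector's empirically determined operating
point). The image score is

$$ s = \frac{\#\{\text{positive in-tumor patches}\}}{\#\{\text{in-tumor patches}\}}, $$

and a patient's ADTA score is the **median** of their image scores (primary
melanomas are commonly sectioned so that one tumor yields several slides).
Patients with score at or above a cutoff *c* are **low risk** — a high
lymphocytic infiltrate is protective — and below it **high risk**.

The cutoff is not fixed a priori: on a training cohort the package builds
the ROC of patient scores against the died-of-melanoma label (orientation:
a *low* score predicts death) and selects the threshold maximizing Youden's
J = sensitivity + specificity − 1. The binary risk class is then validated
on an independent cohort with Kaplan–Meier curves, the log-rank
(Mantel–Cox) test, and Cox proportional-hazards models for
disease-specific survival (DSS), alone and alongside Breslow depth,
ulceration, T stage, and derived overall stage. Deaths from other causes
are censored at death.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `positivity_threshold` | 0.775 | probability | detector operating point; `boundary_rule` controls whether exactly-τ counts positive (default: it does, "at least") |
| `risk_cutoff` | 0.065 | score | published operating value; normally re-derived by `select_cutoff()` on a training cohort |
| `patch_size` | 100 | pixels | the upstream detector's tiling; configurable because 20× and 40× scans cover different physical area per patch |
| cutoff criterion | Youden's J | — | pluggable (`accuracy`, `closest_topleft`) so sensitivity of the chosen cutoff to the criterion can be reported |
| Cox `ties` | Efron | — | follow-up in months produces ties; Efron is less biased than Breslow, which remains available for comparison with other software |

## Geometry conventions

Pixel coordinates are 0-based with the origin at the top-left, x rightward,
y downward; a patch anchored at $(x, y)$ covers the half-open box
$[x, x+\text{patch\_size}) \times [y, y+\text{patch\_size})$, so adjacent
patches never share pixels. Rasterization sets a pixel iff its **center**
lies inside the polygon set under the **even-odd rule**; hole rings
therefore subtract, and ring orientation and starting vertex are
irrelevant. A patch belongs to the tumor iff its center pixel is set
(`patch_in_tumor()`); a minimum-overlap alternative exists but is off by
default. The center rule is deterministic, unbiased to first order in the
boundary length, and makes mask-based and polygon-based scoring exactly
equivalent (`patch_in_annotation()` tests the same point against the
polygons directly). Whether the original workflow counted
boundary-straddling patches is not documented anywhere we know of; the
center rule is this package's declared choice, not a reconstruction.

Candidate ROC thresholds are **midpoints** between consecutive sorted
unique scores (plus ∓∞ sentinels), so a selected cutoff never coincides
with a patient's score and boundary classification on the training set is
unambiguous. Exactly tied criterion values resolve toward the smaller
threshold, which calls more patients low risk. Internally the Youden
objective is rescaled by $n_{\text{pos}} n_{\text{neg}}$ into an integer
count so that mathematically tied thresholds compare as exactly tied
rather than by floating-point noise.

## Stage derivation and covariate coding

Overall stage for the Cox models follows the rule: any patient with a known
positive lymph node or documented satellite metastasis is stage III;
otherwise stage I for T1a–T2a and stage II for T2b–T4b. When the recorded T
stage is missing it is derived from Breslow depth and ulceration using the
AJCC thickness bands (≤1, ≤2, ≤4, >4 mm; suffix b when ulcerated). Missing
covariates are represented explicitly and model fits are complete-case,
mirroring how "Unknown" rows appear in clinical tables. Ordinal covariates
(T stage 1–8, TIL grade 0–2, stage 1–3) enter the Cox models as numeric
scores; the high-risk indicator is coded 1 = high risk, so its hazard ratio
is expected above 1.

## The synthetic cohort generator

No patient data ship with the package; `gen_cohort()` generates cohorts on
which every stage is testable. Per patient it draws a latent infiltration
level λ from a two-component mixture — a minority high-infiltrate
component (weight 0.19, echoing the observed size of the good-prognosis
group) and a majority low-infiltrate component — then generates 1–4 images.
Each image gets a random star-shaped tumor polygon covering 30–90% of the
patch grid; `Binomial(n_tumor, λ)` in-tumor patches are marked TIL-high and
placed by kernel-weighted sampling around Poisson-placed cluster centres,
so infiltration is spatially clustered while the *count* of high patches
stays exactly binomial. High patches draw probabilities from Beta(10, 3)
and everything else from Beta(2, 12), giving the closed form

$$ E[s \mid \lambda] = \lambda\, q_{\text{high}} + (1-\lambda)\, q_{\text{low}},
   \qquad q = P(\text{Beta} \ge \tau), $$

which the calibration tests exploit (`expected_positive_fraction()`).

Survival follows a proportional-hazards exponential model,
$h = h_0 \exp(\beta_z z + \beta_d\,\text{depth} + \beta_u\,\text{ulc})$,
with $z = 1$ when the *true* expected score falls below the risk cutoff,
censored by an independent Uniform(0, 180 months) administrative time.
Defaults were fixed once from published cohort tables: depth log-normal
with median ≈ 2.4 mm, ulceration rate 0.44, β_z = log 4 (the validated
effect size), modest depth and ulceration effects (log 1.15/mm, log 1.5),
and h₀ = 0.0015/month giving ≈ 45–55% observed events — the closed form
$P(\text{event}) = 1 - (1 - e^{-rW})/(rW)$ makes this checkable
analytically. The low component is Beta(2, 60) and the grade thresholds
(0.01, 0.30) on λ, chosen analytically so that the true low-risk fraction
(≈ 19%) and the TIL-grade marginals (absent/non-brisk/brisk ≈ 10/72/18%)
match the published cohorts; pathologist misgrading is emulated by a 20%
chance of shifting the grade one level.

**What the generator does and does not emulate.** It reproduces marginal
distributions (depth, ulceration, grades, event rates, class imbalance) and
the input *structure* (patch tables, polygon annotations, clinical tables),
not joint distributions never reported for the real cohorts, nor melanin
artifacts, torn tissue, scanner differences, or inter-pathologist
annotation variability. Passing tests on synthetic cohorts therefore
demonstrate algorithmic correctness and statistical calibration of the
pipeline, not clinical performance on real slides.

**A deliberate idealization and its consequences.** The hazard depends on
the *binary* risk class, not continuously on λ. Within a mixture component
the died/alive score distributions are then identical, so the empirical
Youden curve across a component is a small-drift random walk and the
selected training cutoff (n = 80) is noisy whenever a component's score
continuum straddles the operating region. With the marginal-faithful
defaults the recovered cutoff transfers imperfectly to validation in a
sizeable minority of seeds — which is worth knowing about the method
itself: a single ROC-derived cutoff from 80 patients is a high-variance
estimator unless the score distribution has a real gap. The end-to-end
recovery tests therefore use a strongly separated mixture (low component
with essentially absent infiltration), the regime in which cutoff recovery
is well-posed.

A second structural fact: at study-like sizes (145 validation patients,
~19% low risk, ~40–55% events) the low-risk arm carries only ≈ 6 expected
events, capping log-rank Fisher information near 5.5 and hence power at
α = 0.01 around 0.83 *even with perfect risk classification*. Single
published significance results at these sizes should be read with that in
mind; replication of p < 0.01 in ≥ 90% of repeated draws would require
event rates far above the observed range.

## Numerical and degenerate-input choices

* Probabilities are validated to [0, 1]; duplicate patch coordinates,
  non-positive follow-up, and out-of-domain ordinal codes are errors that
  name the offending row — readers never silently drop rows.
* An image with zero in-tumor patches is excluded with a recorded reason;
  a patient left with no scored images likewise. Risk-class counts plus
  exclusions always sum to the cohort size.
* An all-censored group yields S(t) ≡ 1; the log-rank test refuses to run
  with zero events; a Kruskal–Wallis comparison of all-tied scores returns
  H = 0, p = 1 rather than 0/0.
* Complete separation in a Cox fit (a covariate level with no events) is
  flagged and reported with its unbounded confidence interval instead of
  being hidden.
* Patch tables are written with `%.17g` so a write/read round trip
  reproduces every double bit-exactly.

## Pipeline and configuration format

The file-based stages (`adta_simulate`, `adta_score`, `adta_cutoff`,
`adta_validate`, and the `inst/scripts/adta` subcommand wrapper) write
outputs plus a JSON run manifest (command, parameters, input digests,
package version, seed) into a staging directory promoted atomically on
success, so a failed stage leaves no partial output directory. Stage
configuration lives in a YAML file with one map per stage;
`--set stage.key=value` overrides win over file values. YAML was chosen for
the same reasons one would want TOML — comments and unambiguous scalar
typing — while using a parser from the installed stack.

## Problem sizes used by the test suite

The suite exercises: 1000 randomized grids (≤ 20×20 patches) against an
exhaustive per-patch scoring oracle; 100 random polygons (≤ 300×300 px)
against a per-pixel ray-casting oracle; 1000 random score sets against
all-pairs concordance and exhaustive Youden maximization; hand-computed
product-limit, hypergeometric log-rank, and grid-searched partial-likelihood
oracles; 1000 null two-arm cohorts (n = 200) for log-rank type-I error;
200 replicates (n = 300) for Wald CI coverage of a true hazard ratio of 4;
and 50 end-to-end seeds at the study's cohort sizes (80 training, 145
validation). These sizes keep the full suite in the low minutes on a single
CPU while leaving Monte-Carlo error well inside the asserted bands.

## Known limitations

* Tumor-region annotation is assumed given; no automated segmentation.
* No time-varying covariates, frailty, or competing-risks modelling.
* The upstream detector's file dialect is assumed to be the canonical
  `x,y,prob` CSV; other dialects attach via the `converter` hook of
  `read_patch_table()`.
* Whole-slide image formats (.scn/.svs) are out of scope; masks are the
  only raster format read.
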