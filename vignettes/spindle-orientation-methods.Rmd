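---
title: "Quantifying oriented cell division in adult epidermis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying oriented cell division in adult epidermis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epispindle)
```

## The biological question

Basal keratinocytes of the adult epidermis divide mostly in the plane of the
basement membrane. Regulators of the mitotic spindle — in particular the
cortical adaptor LGN of the NuMA–LGN–Gαi complex — anchor the spindle poles
and maintain this planar bias; losing them can randomize the division axis,
send daughters into the suprabasal compartment, and interact with oncogenic
lesions such as PTEN loss. This package implements the full quantification
chain used to study that question: spindle-angle measurement against the
basement membrane, orientation binning, a Monte-Carlo test of whether an
angle distribution is statistically indistinguishable from uniform, tissue
morphometry, live-imaging division-track classification, rare-event outlier
testing, and tumor-cohort summaries. A synthetic-data generator emulates
every input with known ground truth, so the whole pipeline is testable
without access to the original microscopy annotations.

## Angle measurement and binning

Annotations arrive as calibrated 2-D coordinates in micrometres (y
increasing apically) — the pipeline starts after image segmentation, from
spindle-pole pairs and basement-membrane polylines. The division axis is
the line through the two spindle poles; its angle is measured against a
basal reference direction and folded to the acute value in `[0, 90]`
degrees, so the result is invariant to swapping the poles, flipping the
reference, and rigid motions of the section.

The basement membrane curves, so by default the reference is the direction
of the membrane segment nearest the pole-axis midpoint (`local_tangent()`);
an explicit per-division reference overrides this when an annotation
supplies one. Both conventions are supported because annotation workflows
differ in whether angles were traced against the local membrane or a global
horizontal; the local tangent is the default since it is the stricter
reading of "the basal layer as reference".

Angles are binned as parallel (≤ 30°), oblique (30–60°) and perpendicular
(≥ 60°), with both boundaries belonging to the outer bins. Percentages are
kept unrounded in all machine outputs and only rounded at report rendering.
Quartiles use the linear-interpolation convention (R's default type 7);
median-unbiased alternatives differ by well under a degree at the sample
sizes involved (n ≈ 44–49), and the convention is fixed and documented here
rather than configurable. One consequence worth knowing: bin percentages
and the median are exactly invariant under duplicating a sample, but
linear-interpolation quartiles of a duplicated sample can shift slightly —
this is a property of the convention, not of the data.

```{r}
s <- simulate_angles(n = 45, p_planar = 0.8, p_uniform = 0.2,
                     planar_sd = 10, seed = 1, condition = "example")
distribution_summary(s)
```

## The randomization score

The central statistic asks: is an observed angle distribution statistically
equivalent to a random (uniform) one? The score compares the experimental
sample with `n_reps = 100,000` independent null samples drawn uniformly on
`[0, 90]`, each of the same size as the sample, using the two-sample
Kolmogorov–Smirnov test. The score at threshold α is the percentage of the
null-comparison p-values *strictly* larger than α, reported at α = 0.05
(statistical significance) and α = 0.01 (high significance). A planar-biased
sample is rejected against almost every null draw and scores near 0; a
genuinely uniform sample scores near `100 × (1 − α)`. Because
`{p > 0.05} ⊆ {p > 0.01}`, the score at α = 0.01 is always at least the
score at α = 0.05.

Three numerical choices are configurable and recorded in every result
because the procedure leaves them open:

* **Null support.** "Random numbers between 0 and 90" is read as continuous
  uniform draws — the measured quantity is continuous, and integer nulls
  create ties that perturb KS p-values. An `integer_null` flag provides the
  discrete reading; it forces asymptotic p-values since the exact
  two-sample null assumes continuity.
* **Null sample size.** Defaults to the experimental sample's own n
  (44–49 across conditions), with an override to pin a fixed size such
  as 45.
* **Exact vs asymptotic KS p-values.** Exact is the default (the natural
  choice at n ≈ 45, and what standard software picks automatically at these
  sizes); the asymptotic Kolmogorov series is available and scores under
  the two modes can differ by a few percentage points, so tests pin the
  mode explicitly.

Ties at exactly α count as "not larger", following the strict inequality.
Randomness is managed by hashing a per-repetition substream seed from one
root seed (`substream_seed()`), so a fixed seed reproduces the score
bitwise and raising `n_reps` extends rather than reshuffles the draws. The
statistic is computed by a single sort per repetition and p-values are
memoised over the discrete grid of attainable D values, which keeps a full
100,000-repetition run around half a minute per condition on one CPU.

## The Gaussian-simulation outlier test

Rare proliferative spinous cells (Ki67+ KRT10+ KRT5−) occur at frequencies
of order 10⁻³–10⁻⁴ events per µm of basement membrane. To ask whether a
tested group plausibly contains outlier animals, a Gaussian is fitted to
the reference group's per-animal frequencies, `k` values (the tested group
size, 6 by default) are drawn `n_sim = 10,000` times, and the reported
probability is the fraction of simulated groups in which at least one value
exceeds a threshold. The closed form `1 − Φ((t − μ)/σ)^k` is reported
alongside and the Monte-Carlo estimate is validated against it to within
four binomial standard errors. The threshold is a mandatory explicit
argument: the source material states it inconsistently (0.007 in one place,
0.0007 in another — a tenfold discrepancy), so no default is hard-coded as
correct and the value used is always recorded in the result.

## Morphometry

All tissue metrics reduce to counts over lengths: cell density is cells per
µm of basement-membrane arc length, tissue folding is arc length over the
straight-line span (1 = flat), marker fractions are percentages of layer
totals, and rare-event frequencies are events per µm. Two conventions
matter and are enforced rather than configurable:

* **Pooling** sums counts and lengths before dividing — the pooled
  frequency of sections (3, 1000 µm) and (4, 2500 µm) is 7/3500, never the
  mean of the two ratios.
* **The unit of replication is the animal**: sections are pooled within a
  mouse, and condition-level values are means of per-animal values
  (matching three-to-four mice per condition). Whether published bars are
  animal means or pooled-cell proportions is not stated in general; the
  animal-mean reading is adopted and recorded in the output metadata.

## Live-imaging track classification

Explants are imaged every 5 minutes for 13–15 h. Divisions are planar at or
below 20° — the live-imaging criterion, deliberately distinct from the 30°
fixed-tissue bin, because live measurements concentrate well below 20°. A
non-planar division is *resolved* if its angle has come down to the planar
range 60 minutes after anaphase onset, *persistent* if not, and *censored*
without a t60 measurement. No numeric criterion for "resolution" is stated
in the source; the 20° planar bin is this package's reading, and the
threshold is an argument everywhere it is used. A suprabasally positioned
daughter *reintegrates* if its layer label turns basal within a 6 h window
and stays basal to the end of its track; tracks ending earlier without a
transition are censored, and a transient dip to basal that does not persist
does not count.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated; its defaults are fixed at the magnitudes the study reports, not
tuned afterwards.

* **Angles** come from a mixture of a half-normal planar component
  `|N(0, sd)|`, a uniform component, and an optional perpendicular
  component folded at 90°. Half-normals (rather than von Mises or other
  circular families) are used because the domain is a folded quarter-circle
  and the half-normal CDF gives closed-form bin masses to test recovery
  against — e.g. a planar component with sd 10° puts `2Φ(3) − 1 ≈ 99.7%`
  of its mass below 30°. Fixed-bin scenario samples reproduce the four
  observed conditions exactly: 80/13/7% of 45 (wild type), 53/20/27% of 45
  (LGN loss), 65/20/14% of 49 (PTEN loss), 34/38/27% of 44 (combined loss).
* **Tissue** sections use a sinusoidal basement membrane whose amplitude is
  solved numerically so arc length / span hits the folding target; the
  default span is 2000 µm per section with three sections and three mice
  per condition, which yields well over the 300 cells per animal needed
  for 5% relative recovery of densities and fractions. Counts are Poisson
  at density × arc length, marker labels Bernoulli at the stated fractions
  (e.g. 46% KRT10+ basal, 25% Ki67+, 2% pHH3+), rare events Poisson at
  rate × arc length. The folding default of 1.3 is a realistic snout-tissue
  value chosen once; only its recovery, not its specific value, is ever
  asserted.
* **Tumor cohorts** are zero-inflated: a mouse is affected with the
  incidence probability (0.12 and 0.35 for the two genotypes at the study's
  cohort sizes of 17 and 20), affected mice get a zero-truncated Poisson
  tumor count and iid log-normal volumes. The closed-form mean burden
  `p × λ/(1 − e^{−λ}) × e^{μ+σ²/2}` is the recovery oracle. Tumor-free mice
  contribute burden 0 to cohort means — the zero-inclusive reading is the
  only one consistent with a sub-mm³ mean burden in a group with 12%
  incidence — and the affected-only mean is reported alongside.
* **Tracks** draw anaphase-onset angles from the mixture, resolve
  non-planar divisions with a set probability, and let suprabasal daughters
  descend after a set delay with the reintegration probability.

What the generator does *not* emulate: spatial correlation between
neighbouring cells, per-section segmentation error, drift or z-loss in live
imaging, and any mechanistic coupling between orientation and tumor
formation. Passing recovery tests therefore demonstrates that the
estimators are correct under the stated sampling models, not that the
biological conclusions transfer to real annotations.

## Statistical wrappers

Auxiliary comparisons follow a normality gate: Shapiro–Wilk on each group
at 0.05, then an unpaired two-tailed Student's t test if all groups pass,
otherwise the two-tailed Mann–Whitney test (two groups) or Kruskal–Wallis
in place of one-way ANOVA (three or more). Groups too small or too constant
for the gate default to the rank tests; fully tied comparisons report
p = 1. These are thin wrappers over the standard routines — the package's
own mathematics is confined to the geometry, the randomization score, and
the outlier test.

## Problem sizes and determinism

The test suite validates the randomization score at 10,000 repetitions
over 50 seeded samples per distributional shape, parameter recovery on 10⁴
simulated tracks and nine tissue sections per condition, and the
four-condition scenario at 10,000 repetitions; the analysis drivers and
acceptance script run the four study conditions at the full 100,000
repetitions. Every stochastic routine takes a root seed and derives hashed
substreams per repetition or unit, so all results in this document and in
`results/` are bit-reproducible from the recorded seeds.

## Known limitations

* Angles are measured in 2-D sections with no correction for section
  obliquity; this mirrors the annotation convention the pipeline consumes.
* The exact two-sample KS null is unavailable under ties; tied samples
  silently use the asymptotic series (recorded in the result).
* Tumor volumes are inputs; no image-based volume estimation is attempted.
* Cohort comparisons assume independent animals; littermate or cage
  effects are not modelled.
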