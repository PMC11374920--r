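---
title: "Methods: staining indices, vesicle size cutoffs and fiber–receptor concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staining indices, vesicle size cutoffs and fiber–receptor concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxtrace)
```

`oxtrace` turns the semi-quantitative readouts of an oxytocin-system mapping
study — ordinal section scores, hand-traced vesicle areas, per-profile
vesicle presence, per-cell puncta counts — into reproducible statistics.
This vignette records the models, the assumptions behind them, and the
numerical and design choices the package makes where the underlying
procedures leave room.

## The Staining Density Index

Regions differ enormously in anteroposterior extent, and sparsely labeled
regions show nothing on many of their sections. Raw ordinal scores per
section are therefore normalized to the number of sections NT a region
spans, empty sections included:

$$\mathrm{SDI} = \frac{3N_3 + 2N_2 + N_1}{3\,N_T} \in [0, 1].$$

`compute_sdi()` evaluates this exactly (it equals the mean per-section score
divided by 3, which is how the test suite's brute-force oracle checks it
over all $4^6$ score vectors up to NT = 6). Properties that follow, and
that the suite asserts: invariance to section order, monotone growth when
any section's score rises, and strict dilution when an empty section is
appended.

**Score bins.** The published cell bins overlap at their edges ("1–6" → 1
but "6–12" → 2, "6–12" → 2 but "12 or more" → 3). `score_from_cell_count()`
resolves the overlap in favor of the explicitly phrased endpoints: 0 → 0,
1–6 → 1, 7–11 → 2, ≥ 12 → 3. Fiber codes (`0`, `+`, `++`, `+++`) encode an
observer judgment ("one axon in a small region or 2–4 in a large
cross-section…"); the package ingests the ordinal code rather than
pretending to automate that judgment.

**Pooling.** The pooling rule across animals is not prescribed beyond
"pooled"; the package uses the arithmetic mean of per-animal SDIs (a median
option exists). A region absent from an animal's table is treated as
missing — it contributes 0 only when the region was examined and actually
scored 0 everywhere (NT > 0 recorded).

**Tertiles.** `classify_tertiles()` splits pooled SDIs at the empirical
33.3/66.7 percentiles (linear-interpolation quantiles, type 7), ties going
to the denser class so that a region sitting exactly on a boundary is never
demoted. If all values coincide the partition is degenerate; the function
warns and returns a single class rather than inventing a split.

**Sex screen.** Per region, male and female per-animal SDIs are compared
with Welch's unequal-variance t-test (Welch–Satterthwaite df, two-sided p).
Regions with fewer than `min_obs = 2` values in either sex cannot yield a
within-group variance and are excluded — but they are listed in the output
with the reason, never dropped silently. The zero-variance/equal-means case
has no defined t and is reported as such. The Welch statistic is computed
in closed form (so these edge cases are representable) and cross-checked
against `stats::t.test()` in the tests. No multiple-testing correction is
applied by default, matching the exploratory character of a 100-region
screen with n = 3 per sex; `adjust = TRUE` appends Benjamini–Hochberg
q-values.

## The DCV size cutoff

Dense-cored vesicles package neuropeptides; oxytocin-positive somata carry
large DCVs while surrounding unlabeled neuropil carries small ones. A
size criterion classifies vesicles where immunolabel is absent or
ambiguous. The estimator is the intersection of the two kernel density
estimates:

- Gaussian kernel, Silverman's rule-of-thumb bandwidth (`bw.nrd0`) per
  sample. Neither kernel nor bandwidth is prescribed by the source
  procedure; Silverman is the field-standard default, is recorded in the
  output, and is overridable.
- Shared evaluation grid of 512 points on $[0,\ 1.2\cdot\max(\text{areas})]$;
  each curve integrates to 1 ± 0.01 there.
- The cutoff is the sign change of $\hat f_+ - \hat f_-$ **between the two
  sample modes** — the point where the locally dominant population
  switches. Crossings in the far tails are not eligible. With small
  samples the difference can wiggle; if several crossings occur between
  the modes, the one nearest the midpoint of the modes is chosen and a
  warning lists all of them.
- Roots are refined by linear interpolation between grid points.

The "< 5% of labeled vesicles at or below the cutoff" statement is treated
as an *achieved property to verify*, not an optimization target: the
intersection is the estimator, and `estimate_dcv_cutoff()` raises a
validation flag when the empirical sub-cutoff fraction reaches 5%
(`flag_at = 0.05`, ≥ flags). Under the reported population parameters
(0.016 ± 0.005 vs 0.004 ± 0.002 µm², normal model) the analytic sub-cutoff
mass at the 0.008 µm² cutoff is $\Phi(-1.6) \approx 0.055$ — essentially on
the boundary, which is why the flag exists rather than a hard error.

A vesicle exactly at the cutoff is classified OXT−, following the "at or
below" convention. Equivalent diameters are $d = 2\sqrt{A/\pi}$; rounding
to the nearest 10 nm ("~140 nm") happens only at the report layer.

The distributional family of the vesicle areas is *not* stated in the
source material (only mean ± SD); normality is this package's working
assumption, used for the analytic cross-check
(`gaussian_intersection()`, a closed-form quadratic) and the truncated
sampling in the generator. The assumption is recorded here and in the
generator's documentation, not asserted as established fact.

**Incidence.** Per-profile DCV incidence (a profile counts as positive
when it contains ≥ 1 supra-cutoff DCV — the counting rule is implied, not
stated, and ≥ 1 is adopted) is a binomial fraction with a Wilson score
interval (`prop.test(correct = FALSE)`), chosen over Wald for its behavior
at the small n (30–160 profiles) and extreme fractions (6%) that occur
here. Percentages are additionally reported rounded to integers, the
precision used in prose.

## Fiber–receptor concordance

The receptor side is an external, ordinal 1–4 transcript-score atlas.
`harmonize_regions()` aligns the two nomenclatures through an explicit,
user-supplied mapping: when the receptor atlas subdivides a region, the
subregion scores are averaged; regions without a counterpart on either
side are carried through with `included = FALSE` and a reason, and an
audit (matched/unmatched counts per side) is attached, so the row balance
`matched + excluded = input` is checkable — and checked.

The model is ordinary least squares with a full interaction,
`SDI ~ score × category`. The direction of the regression is genuinely
ambiguous in the source (the prose suggests receptor explained by fibers,
the figure axes the transpose); the package defaults to SDI as the
response with `response = "receptor"` as a switch, and the trend
invariance properties are tested under both orientations. Receptor score
is treated as continuous — the trend analysis implies a slope per score
unit. No weighting by sections or animals per region is applied (none is
described). The hindbrain category is carried through harmonization but
excluded from the default fit, mirroring the five parent categories of the
trend analysis; `include_hindbrain = TRUE` restores it.

The interaction test reports the F statistic of the interaction row of the
sequential ANOVA with the degrees of freedom implied by the fitted design —
numerator df = categories − 1. A published interaction statistic with 1
numerator df cannot arise from a 5-level categorical interaction, and its
exact model specification cannot be inferred; the package reports its own
df honestly and does not force a match. Two numerical notes from testing:
with zero simulated noise a *shared* slope gives an interaction sum of
squares of exactly 0 but an F ratio of 0/0 (the tests assert the sum of
squares); with zero noise and *differing* slopes the F ratio is finite
only through floating-point residuals and the tests assert `p < 1e-6`
rather than a specific F.

Per-category trends are linear contrasts of the coefficient vector
(reference slope plus the category's interaction coefficient) with
delta-method standard errors from `vcov()`, t-tested on the residual df.
This is exactly what an emmeans/emtrends analysis produces, and the test
suite cross-checks estimates, SEs and confidence limits against
`emmeans::emtrends()` to 1e-10 while keeping the implementation
independent. Trends are invariant to the reference level, equal the
per-category simple-regression slopes, and their 95% intervals attain
94–96% coverage over 1000 simulated tables in the acceptance suite.

## RNAScope puncta

"Expressing" is operationalized as ≥ 1 punctum (configurable; no threshold
is stated). Percent expressing is computed per section and summarized
mean ± SD across sections, matching the "15.4% ± 6.9 of cells" convention.
Whether published puncta densities average over all cells or expressing
cells only is not stated; `puncta_density()` computes either and records
the choice, and the pipeline reports both. Control probes: the negative
control passes at median 0 puncta per cell (a quantitative stand-in for
"no specific labeling"), the positive control at mean > 15.

## The synthetic-data generators

The generators exist so that every downstream stage has realistic,
parameter-controlled input; their defaults *are* the study conditions:

| Generator | Structure | Defaults |
|---|---|---|
| `simulate_vesicle_areas()` | two truncated normals | 0.016 ± 0.005 µm² (n = 61), 0.004 ± 0.002 µm² (n = 60) |
| `simulate_profiles()` | Bernoulli per profile | study region rates, e.g. LH 0.06 (n = 48), SON dendrites 0.40 (n = 30) |
| `simulate_section_scores()` | Poisson counts → score bins | 3 animals per sex; per-region λ chosen to span the score range |
| `simulate_concordance()` | per-category linear model + clip to [0, 1] | published per-category slopes (0.13, −0.04, −0.010, −0.003, 0.03), noise SD 0.05, scores on [1, 4] |
| `simulate_cell_puncta()` | Bernoulli(p) × shifted Poisson | p = 0.154, λ = 3.6 puncta/cell |
| `simulate_em_image()` | dark disks on noisy 8-bit background | flagged/optional; dart-throwing placement, ≤ 10⁴ attempts |

Numerical choices: truncation at zero is implemented by rejection — the
rejected mass is 3.2σ below the mean for the labeled and 2σ for the
unlabeled population, inducing a small positive bias on the unlabeled mean
(≈ +1% of σ) that is accepted and documented rather than corrected. A
standard deviation of exactly 0 is allowed and yields the degenerate
point-mass distribution (useful in tests); negative SDs error. Receptor
scores are continuous on [1, 4] by default with an `ordinal` flag, since
the external comparison dataset is ordinal but the trend model treats the
score as continuous. Every generator takes one seed, derived seeds are
split per table inside `run_pipeline()`, and seeding is local — the
caller's RNG stream is saved and restored.

What the generators deliberately do **not** emulate: microscope optics and
point-spread, section-to-section registration error, observer variability
in ordinal scoring, spatial correlation between neighboring regions,
non-normal vesicle-area shapes, and 3-D structure. Passing tests therefore
demonstrate that the *arithmetic and inference* recover known structure
under the stated noise model — not that the laboratory procedure itself is
unbiased.

## Problem sizes

The test and acceptance computations use: exhaustive SDI enumeration to
NT = 6 (4096 + smaller cases); 200 replicates at n = 61/60 for the KDE
cutoff recovery; n = 10⁴ per group for the convergence check against the
closed form (tolerance 5·10⁻⁴ µm²); 200-replicate recovery checks for
incidence, expression probability and trends; and 1000 simulated tables
for trend CI coverage (tolerance ± 2%). These sizes make the stochastic
checks tight enough to catch sign and scale errors while keeping the whole
suite runnable in minutes on one core.

## Known limitations

- Harmonization is by user-supplied label mapping only; no atlas geometry
  or spatial registration.
- No stereological correction for single-section vesicle measurement, and
  no correction for section-plane truncation of vesicles.
- The cutoff assumes two unimodal, reasonably separated populations; it
  errors (rather than guessing) when the densities do not cross between
  the modes.
- Printed full-dataset statistics that depend on undeposited tables (the
  region-level Welch t values, the full interaction F) are format
  anchors, not reproduction targets; reproducing them from rounded
  summaries is numerically impossible and is not attempted.
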