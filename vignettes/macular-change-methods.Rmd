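---
title: "Methods: macular thickness change detection and interval estimation in hypertensive pregnancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: macular thickness change detection and interval estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maculahdp)
```

## The scientific setting

The neurosensory retina has a finite thickness set by microvascular
filtration and outward pumping across the retinal pigment epithelium. In
early pregnancy, rising cardiac output and blood volume provoke
autoregulatory vasoconstriction of the central retinal artery, and the
macula thins by a few micrometres — a change far below clinical visibility
but well within the resolution of spectral-domain OCT. Losing this
thinning response in mid/late gestation (the macula re-expanding toward or
past its non-pregnant thickness) marks capillary leak from breach of the
upper autoregulatory threshold, and frequently precedes the systemic
blood-pressure rise that defines hypertensive disorders of pregnancy
(HDP). The package operationalises this chain: detect per-eye interval
change, classify longitudinal trajectories, estimate interval means
hierarchically, and link retinal events to mean arterial pressure (MAP).

## The decision rule and its null calibration

A scan is a nine-sector ETDRS thickness map (µm). Sector values are
stored to 0.01 µm and all threshold comparisons happen after rounding to
that precision, so ties at the threshold are exact and unambiguous; the
threshold is inclusive (a 4.00 µm difference qualifies).

For an interval between two scans of the same eye the rule fires, in a
direction, when the largest connected component of sectors whose signed
difference exceeds ±τ has at least k members. Defaults are τ = 4 µm —
twice the instrument's test–retest coefficient of repeatability
(CoR = 2 µm) — and k = 3. Both directions are evaluated independently;
thinning and thickening can co-occur in one eye.

Contiguity is not self-defining on an annular grid, so the package fixes a
convention and exposes it as data (`etdrs_adjacency()`): the central disc
touches the four inner quadrants, each ring is a 4-cycle, and matching
inner/outer quadrants are radially adjacent — exactly the sector pairs
sharing a boundary arc on the printed grid. Sixteen edges; every sector
has degree ≥ 2. Any alternative convention (e.g. centre excluded) can be
passed as an edge table to every rule function.

Because consumer decisions hinge on this rule, its false-positive rate is
estimated empirically rather than assumed: the two replicate scans taken
at the same encounter differ only by measurement noise, so all
same-encounter pairs form a null difference distribution.
`calibrate_null()` reports the either-direction firing frequency of the
chosen rule and of every weaker rule on the grid
τ′ ∈ {1, 2, 3, 4} µm × k′ ∈ {1, …, 9} — the full set of rules dominated by
the default. The firing event is monotone in both parameters, so the
frequency surface is non-increasing in τ′ and k′; the tests assert this
and check the frequencies against an independent brute-force enumeration
oracle. The calibration is reported for whatever null pairs are supplied;
under the generator's Gaussian replicate noise the default rule's null
frequency is essentially zero, whereas real instrument nulls (with
segmentation and fixation artifacts) are heavier-tailed — the package
deliberately does not hard-code any published null p-value.

## Trajectory classification

Per eye, with scans in gestational order:

* **Early thinning**: the rule fires in the thinning direction for
  (non-pregnant baseline → pregnancy scan). Scans are checked in order and
  the first firing sets the timing, which may fall after 20 weeks for late
  responders. This right-censors true onset at the visit schedule.
* **Loss of thinning (LOT)**: the rule fires in the thickening direction
  on a *sequential within-pregnancy* pair. The baseline plays no role
  here — the event is detectable on sequential imaging alone, which is the
  clinically important property. Partial effacement below (τ, k) is *not*
  LOT: the calibrated rule is the sole decision instrument.
* **Sudden thinning events**: sequential pairs firing in the thinning
  direction after thinning or LOT is already established; these are
  hypoperfusion candidates.
* **Overt thickening**: a pregnancy scan thicker than the non-pregnant
  baseline by the rule.

`detect_hypoperfusion()` flags an eye when a sudden thinning event
coincides with a MAP fall of at least 15 mmHg relative to the previous
encounter. The source literature calls the drop "significant" without
quantifying it; 15 mmHg is the package default and is configurable. Events
without resolvable blood pressure are skipped with a warning.

Participant aggregation treats the two eyes as independent observations
but requires both to be normal before declaring no microvascular injury.
The primary label (loss_of_thinning ≻ no_early_thinning ≻
maintained_thinning) is exhaustive and mutually exclusive, and invariant
to eye order.

## The hierarchical interval model

`build_long_table()` produces one row per (participant, eye, sector,
pregnancy encounter) with the change from that participant/eye/sector's
non-pregnant value; modelling change directly (rather than absolute
thickness with a baseline level) matches the change scale on which every
estimate is reported. One encounter per epoch enters the table — the first
in gestational time — so supplementary peripartum event scans inform
classification but not interval estimation.

`fit_interval_model()` fits, by REML through `nlme::lme()`:

* fixed effects: one mean per (group × interval) cell;
* random intercepts: participant, eye within participant, sector within
  eye (nested — sector position varies within eye, and nesting keeps the
  likelihood tractable);
* residual serial correlation: continuous-time AR(1)
  (`corCAR1`, exponential decay in week separation) within each sector
  series. The correlation family is not identified by three time points;
  exponential decay is the default and `correlation = "none"` is
  available.

Confidence intervals are Wald intervals on the fixed effects; epoch
contrasts within group use the fixed-effect covariance. Variance
components are reported (`glance()`) but deliberately not part of the
acceptance surface: they are sensitive to the serial-correlation family in
a way the interval means are not. Degenerate inputs with zero variance
(noise-free simulations) fall back to an OLS cell-means fit at the
variance boundary, with a warning; convergence failures first retry with a
different optimiser.

With `by_group = FALSE` the three HDP groups are pooled against controls;
`by_group = TRUE` estimates all four groups. At least two participants per
estimated group and all three intervals are required.

## Hemodynamics

MAP uses the standard one-third pulse pressure formula
dbp + (sbp − dbp)/3, reported to 0.1 mmHg with integer rounding only at
presentation (112/70 → 84.0; 150/100 → 116.7, presented as 117). Anchor
summaries use Student-t 95% CIs on per-participant values; a
single-participant anchor yields a flagged degenerate interval. The MAP
rise between anchors is the mean of *within-participant* differences —
the paired quantity is authoritative and equals the difference of anchor
means only on complete data. Participants whose LOT is first seen at the
delivery encounter are excluded from the LOT anchor: their true MAP at
loss of thinning is not estimable. When several early visits exist,
enrollment is the first encounter.

## The synthetic cohort generator

No patient-level data accompany the study this package emulates, so the
generator (`generate_cohort()`, `cohort_config()`) is a first-class
module: it defines the conditions under which everything else is tested.
Defaults encode the study's composition and effect structure:

* 11 controls and 27 HDP participants (12 de novo, 8 chronic hypertensive
  with LOT — 3 of them first at delivery — and 7 without), 7 single-eye
  LOT, 5 hypoperfusion events (4 with antecedent LOT), and exactly one
  late early-thinner whose thinning first fires between 20 and 32 weeks.
* Visits at 12, 30 and 38 weeks (delivery) plus a postpartum baseline,
  jittered ±2 weeks except in the fixed fixture; two replicate scans per
  eye per encounter with per-sector noise SD
  CoR/(1.96·√2) = 0.72 µm, so replicate differences have SD 1.02 µm and
  the 2 µm coefficient of repeatability is reproduced.
* Group×interval mean thinning effects (µm): control 3.92/3.08/5.16,
  de novo 4.35/2.99/3.45, cHTN-no-LOT 3.91/3.80/4.46, cHTN-LOT
  3.39/2.85/1.06. These are the *realized* group means: planted LOT
  effacement mass is compensated in the base trajectory, so with all noise
  off the sample group×interval means equal the configured values to
  machine precision, in every draw.
* Detectability floor: every designated early thinner receives a
  persistent, mean-zero spatial profile deepening the inner ring so its
  early thinning is at least 6 µm there (thinning is genuinely greatest in
  the inner circle). The profile is constant from the first thinning epoch
  on, so sequential difference maps remain spatially uniform and the floor
  cannot masquerade as loss of thinning.
* LOT is planted as patchy, progressive, contiguous effacement: a 3–4
  sector connected set (inner-ring sets for single-eye LOT) rebounds by
  10 µm at onset, growing to 12 µm at delivery.
* Hypoperfusion events are supplementary peripartum encounters: confluent
  12 µm thinning with a 21 mmHg MAP drop. Delivery-level summaries use the
  first delivery encounter, reflecting that the haemorrhagic drop follows
  the delivery measurement; the classifier still evaluates every scan.
* Dispersion: participant- and eye-level persistent change offsets
  (SD 0.7 and 0.35 µm, truncated at 2 SD), per-sector offsets (0.3 µm),
  serially correlated visit noise (SD 0.45 µm, 10-week correlation range),
  and multiplicative response-intensity factors (±20% participant, ±10%
  eye). Truncation keeps every planted rule firing noise-robust. The
  printed CIs of the emulated study imply a larger between-participant SD
  (≈1.9 µm), but that dispersion includes severe-comorbidity heterogeneity
  (lupus, chronic kidney disease, sickle-cell disease, …) that the
  generator intentionally does not model; the narrower default describes a
  homogeneous idealized cohort whose planted truths remain recoverable
  from a single realization.
* MAP trajectories hit group anchors (de novo: enrollment 84 mmHg, LOT
  anchor, then a within-participant rise of mean 19 mmHg to a delivery
  mean of 101 mmHg; treated cHTN-LOT 87/98/102; cHTN-no-LOT up to
  117 mmHg at delivery) with participant shifts of SD 8 mmHg (truncated
  at 2 SD, so planted normotension at enrollment stays true) and visit
  noise of SD 2.5 mmHg. Published group summaries of the emulated study
  are not mutually consistent here — MAP at LOT (87) plus the mean rise
  (19) exceeds the delivery mean (101) — so the generator anchors the
  delivery mean and the rise, implying a LOT-anchor mean near 82 mmHg.
* Office pressures are emitted as integer sbp/dbp with pulse pressure
  widening with MAP (42 mmHg at MAP 84, 50 at MAP 117), matching both
  printed conversions.

What passing tests show — and what they do not: the generator's noise is
Gaussian, its visit schedule nearly regular, its effacement geometry
fixed, and its participants exchangeable within group. Real OCT data add
segmentation failures, fixation losses, heavy-tailed replicate error and
informative missingness; results here validate the *machinery*, not the
clinical error rates on instrument data.

## Numerical choices and problem sizes

Sector values are compared after rounding to 0.01 µm; scan selection
breaks signal-strength ties toward replicate 1; the component search is
exact (validated against 2⁹ subset enumeration); the calibration uses a
512-entry component-size lookup so large null sets stay fast. The test
suite exercises the full-size default cohort (2052 model rows), a
200-replicate half-size calibration study of CI coverage, a 10,000-pair
null-calibration oracle comparison, and a 25-cohort MAP recovery study —
sizes chosen to give stable Monte-Carlo estimates on a single CPU within
minutes.

## Known limitations

Variance-component estimates ride on a likelihood ridge (persistent
sector-level structure can be absorbed by either the sector intercept or
a near-unit serial correlation); interval means and their CIs are
insensitive to this, which is why only they are acceptance-gated. LOT
onset timing is right-censored at the visit schedule. The generator's
group MAP anchors reproduce printed means, not full trajectories. The
within-participant between-visit biological variance of real maculae is
unknown; the defaults above are declared, not inferred.
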