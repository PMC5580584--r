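---
title: "Methods: the gingival melanosis record and its companion statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the gingival melanosis record and its companion statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmrscore)
```

## The measurement model

The gingival melanosis record (GMR) quantifies the extent of melanin
pigmentation on the anterior maxillary attached gingiva as the percentage of
pigmented sites on a landmark-driven sampling lattice. The lattice is fully
determined by a per-photograph annotation (tooth cervical polylines, the
crown length of the maxillary right lateral incisor, and the
attached-gingiva polygon):

1. **Baseline.** `baseline_y` is the cervical line of tooth 12, evaluated at
   that tooth's central vertical-line position, minus its crown length.
   Using one tooth's crown length as the offset makes the band height scale
   with the photograph, so the procedure needs no metric calibration.
2. **Vertical lines.** Each present tooth between the canines contributes a
   line at its mesial, central and distal x-position, running from the
   baseline down to the cervical line (linearly interpolated along the
   cervical polyline at the line's x; extrapolation beyond the polyline is
   refused rather than guessed). Adjacent teeth share interproximal
   positions; candidates whose x differ by at most `merge_tol` (default
   3 px) are merged — the merged line takes the mean x, the union of its
   source positions, and the mean of its members' cervical intercepts. Six
   fully annotated teeth therefore yield 13 lines from 18 candidates.
3. **Sites.** Nine points per line at `y_top + k/8 · (y_bottom − y_top)`,
   `k = 0..8`: "nine points separating eight equal parts" forces inclusive
   endpoints. Sites are retained iff they lie in the attached-gingiva
   polygon; polygon-boundary points count as inside (a deterministic
   tie-break, applied uniformly).
4. **Calls and score.** Each retained site gets a binary pigment call;
   `GMR = 100 · pigmented / retained`, kept at full precision internally and
   rounded half-up to one decimal only for presentation.

Assumptions worth making explicit: the annotation is trusted (the package
does no landmark detection); the gingiva is approximately frontal-planar in
the photograph, so equal pixel spacing approximates equal anatomical
spacing; and pigment presence is a per-site binary property, not an
intensity.

The canines' own gingiva carries measurement sites by default — the region
"between the canines" is read as inclusive; `exclude_canines = TRUE`
restricts their teeth to region bounds only, for sensitivity analyses.

## Pigment calling

Melanin darkens tissue, so the automatic caller uses CIELAB lightness only:
the RGB pixels of a `(2r+1)²` window around the site (default `r = 2`,
clamped at image edges) are aggregated per channel — median by default, for
robustness to anti-aliased edges — converted to CIELAB, and the site is
pigmented iff `L* ≤ 50`. The threshold sits midway between healthy gingiva
(`L* ≈ 70` for the default palette) and melanotic tissue (`L* ≈ 30`); for
photographs with unknown palettes an Otsu threshold on the image's own L*
histogram is available (`lightness_threshold = "otsu"`). Hue is ignored: the
simplest separable criterion, and the one a human estimator's
presence/absence judgement most resembles. Manual call tables (CSV) bypass
colour calling entirely, mirroring a human-estimator workflow.

## The Hedin grade as an operationalization

Hedin's 0–4 classification is descriptive (no pigmentation; solitary units;
many units; short ribbons; a continuous ribbon) and was never defined on a
sampling lattice. `classify_hedin()` therefore **operationalizes** it:
pigmented sites form connected components under 8-neighbour adjacency on the
(line, point) lattice; a component is a *ribbon* iff it spans ≥ 3 distinct
lines; grade 0 = no pigmented site, 1 = ≤ 2 components with no ribbon,
2 = > 2 components with no ribbon, 3 = ≥ 1 ribbon but none spanning every
line, 4 = a component spanning every line. This is the package's mapping of
the classical descriptors onto the lattice, not a published rubric, and is
validated against an independent flood-fill oracle over every call pattern
of a small lattice. One edge case is resolved by the literal rule: on a
degenerate grid with fewer than three lines, a component spanning all lines
scores 4 even though a ribbon is impossible.

## Statistics

All test statistics are computed from closed-form formulas (the test suite
checks them against base R's fitters to 1e-10): one-way fixed-effects ANOVA
(`F = MS_b/MS_w`, df `(g−1, N−g)`); the paired *t* on follow-up minus
baseline; Spearman's rho as the Pearson correlation of mid-ranks with the
two-sided t-approximation `t = ρ√((n−2)/(1−ρ²))` (an exact permutation
p-value is provided for n ≤ 8 as an oracle); and the Shrout–Fleiss
single-rater intraclass correlations,

- ICC(1,1) = (BMS − WMS)/(BMS + (k−1)·WMS) — one-way decomposition,
  repeatability of one examiner;
- ICC(2,1) = (BMS − EMS)/(BMS + (k−1)·EMS + k·(JMS − EMS)/n) — two-way
  decomposition, stability between examiners.

p-values are two-sided throughout and uncorrected for multiplicity,
matching how such cohort analyses are conventionally reported; the
significance level defaults to 5%. Degenerate inputs are flagged rather
than hidden: zero within-group variance yields an infinite F with a
`degenerate` flag, a constant ratings matrix is an error, and a
zero-variance nonzero paired difference is flagged.

Age groups are fixed at 19–29, 30–39, 40–49, 50–59, ≥60 (the reference
study's bins — note the first bin starts at 19, not 20); ages below 19 are
out of range by design. Smoking status follows the >100 lifetime
cigarettes / previous-30-days definitions.

## The synthetic photograph generator

`render_photograph()` draws a deliberately stylized scene: six anterior
teeth in equal slots with a mild cervical scallop, a gingival band up to the
mucogingival junction, alveolar mucosa above, and a circular melanin patch
(radius 3 px) stamped at every ground-truth-pigmented lattice site. The
palette is chosen so pigment sits ≥ 20 L* units below healthy gingiva
(validated at construction), and patch radius 3 fully covers the default
5×5 calling window while site spacings (≥ 7.5 px along a line, ≈ 50 px
between lines) keep patches out of neighbouring windows — together these
margins make colour calling on a noiseless render reproduce the ground
truth *exactly*, which the test suite exercises across 50 seeds. What the
generator does **not** emulate: illumination gradients, specular highlights,
camera noise beyond optional flat Gaussian noise, lip/cheek occlusion,
irregular mucogingival borders, or continuous pigment intensity. Passing
tests on renders therefore validate the geometry and the decision rule, not
robustness to real photographic variation — on real images the operator
should expect to review calls or use manual call tables.

## The cohort simulator

`simulate_cohort()` targets the reference cohort's cell structure: 133
former and 126 current smokers across five age bins (13/32/29/32/27 and
17/26/32/36/15), with the printed per-cell male counts. Per subject:

- **Age** uniform on the bin (the open bin uses 60–79).
- **Smoking duration** = age − onset, truncated to [0, age − 10], with
  onset ~ Normal(18, 10.9). The onset spread is a *calibrated* constant:
  it is set so the population Spearman correlation between age and
  smoking duration is ≈ 0.85, the value reported for the reference cohort.
  Calibration was done by large-sample simulation over replicate cohorts
  (1000 replicates of n = 259) before freezing the default; the duration
  truncation at age − 10 tightens the age–duration relation considerably,
  which is why the calibrated spread is larger than the onset-age sd one
  might quote from survey data.
- **Baseline GMR** is drawn from a truncated normal on [0, 100] with
  sd 19.8 whose *location* is solved (by root-finding on the truncated-mean
  identity) so that the realized mean equals `gmr_mean` = 26.7. Naively
  truncating a Normal(26.7, 19.8) would inflate the mean to ≈ 30.2 and the
  generator's parameters would no longer be its moments; moment-matching
  keeps "parameter recovery" exactly meaningful. The realized sd is
  slightly below the nominal 19.8 (a documented consequence of
  truncation).
- **Follow-up GMR**: former smokers fade multiplicatively,
  `baseline · (1 − fade_rate)^cessation_years`, with per-year fade rates
  0.02/0.07/0.09/0.11/0.13 across the five age bins — documented package
  constants, increasing with age so that the youngest bin changes least,
  the qualitative age pattern the method was designed to detect. Current
  smokers drift by −1%/year (`current_smoker_drift`), a slight decline.
  Follow-up periods are truncated normals with the printed group means
  (4.50/3.79 years) and sds (2.15/1.17); cessation durations use the
  printed per-bin means (2.62–3.67 years, sd 1.95), truncated to
  [0, follow-up].
- Follow-up GMR has no separate measurement-noise term: the fade model is
  deterministic given the draws above, which makes paired tests on default
  simulations anti-conservative relative to real repeated photography.
  Null analyses in the tests add explicit noise for that reason.

Subject-level Hedin grades in simulated cohorts come from a monotone
GMR→grade mapping (0; (0,10]; (10,25]; (25,50]; >50) — a plausibility
device for cohort tables only; photograph-level grading always uses the
lattice classifier.

A single seed drives each generator call, and every draw flows from that
one stream, so any output is replayable from (parameters, seed).

## Printed reference tables and their internal inconsistencies

`inst/extdata/reference_cohort_*.csv` transcribe the reference cohort's
printed group and subgroup summary cells; `pooled_mean()` reproduces the
printed totals from them (e.g. 26.0/27.5% → 26.7% GMR; 4.50/3.79 → 4.15
follow-up years). Three printed values do **not** pool consistently and are
deliberately not targeted: the former-smoker smoking duration (cells pool
to 27.2 vs printed 27.3), the total age (pools to ≈ 45.7 vs printed 45.9)
and the cessation total (pools to ≈ 3.20 vs printed 3.14) — ordinary
rounding/aggregation artefacts of summary tables, documented here so no one
chases them as bugs.

## Pipeline and reproducibility stage

`run_end_to_end()` chains synthesis → grid → scoring → cohort analysis with
fixed filenames in a run directory and a manifest (config hash, versions,
file list; the run directory itself is not part of the hashed
configuration). Because deterministic automatic calling makes repeated
sessions identical, the reproducibility stage emulates human-estimator
variability: each session/rater flips every site call independently with
probability `rater_flip_prob` (default 0.05), and the photographs span a
range of pigmentation burden around the configured `p_site` so the ICC's
between-target variance is genuine. The reported ICC(1,1)/ICC(2,1) are
therefore properties of that synthetic-rater model, not of human raters.

The run configuration file is YAML (single file, thresholds and seeds);
`read_run_config()` fills unspecified fields from defaults.

## Numerical choices and problem sizes

- Coordinates are 0-based pixels, origin top-left, y downward; apical =
  decreasing y on the maxillary arch. Conversion to R's 1-based array
  indices happens only at pixel access.
- Point-in-polygon uses ray casting with an explicit on-boundary test; a
  winding-number implementation is kept as a genuinely separate code path
  and the two are cross-checked (plus `pracma::inpolygon`) in the tests.
- Rounding for presentation is half-up at the printed precision (1 dp for
  GMR and durations, 2 dp for follow-up years); all internal arithmetic is
  full precision.
- Test/acceptance problem sizes, chosen to keep the suite quick while
  leaving Monte-Carlo error well inside the asserted bands: 200 replicate
  cohorts of n = 259 for the Spearman calibration and GMR mean recovery;
  2000 replicates of n = 30 for the paired-t type-I check; all 4096 call
  patterns of a 4×3 lattice for the Hedin oracle; 50 render seeds for the
  exact-calling property.

## Known limitations

- No landmark detection: annotation quality bounds measurement quality.
- The Hedin mapping is an operationalization; agreement with clinicians'
  Hedin grades on real photographs is untested here.
- The lightness-only decision will miss non-melanin discolourations and may
  misclassify under strong colour casts; Otsu helps only when the image is
  bimodal in L*.
- Synthetic validation shows correctness of the procedure, not field
  performance; the generator's simplifications are listed above.
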