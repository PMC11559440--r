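---
title: "posturekit: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{posturekit: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

posturekit processes 15-second wearable posture telemetry from hospital
stays: per-recording code strings keyed by patient identifier (MRN), source
file and device serial, plus an admissions table with the admit/discharge
window. This vignette documents the model behind each stage, the tunable
parameters with their defaults and units, the numerical and boundary
decisions, what the synthetic generator does and does not emulate, and
known limitations. Everything quantitative claimed here is computed by the
test suite or the examples, not asserted from memory.

## 1. The data model

A recording stream is a sequence of rows `(mrn, file_id, device_serial,
timestamp, posture)` with timestamps on a strict 15-second grid (seconds
0/15/30/45). The posture field is one code or a space-separated permutation
of codes emitted when posture changed within a slot; it may be blank.
Timestamps are *naive local clock times* (stored as POSIXct in UTC): the
daytime/nighttime windows are defined on the ward's clock, and a true local
timezone would introduce DST discontinuities into the grid. A patient's
data may span several files, each usually containing several devices,
because devices are charged daily and swapped.

The code alphabet the pipeline distinguishes is
`LSP, LPR, LRS, LLS` (lying supine/prone/right/left), `U45` (reclined),
`U90` (upright), `WLK` (walking), `UNK`, `FALL`, and `S-`-prefixed
self-reported variants. The full proprietary list is longer, and
permutations multiply the observed outcomes further; unknown tokens are
accepted by the tokenizer and fall to the Unknown group, so the alphabet is
a convenience, not a gate.

## 2. Cleaning

Two error types are flagged and excluded, in a fixed two-stage order:

* **Inconsistency** (stage 1): `timestamp < admit` or
  `timestamp > discharge`. Boundary timestamps are **kept**: recorded
  admit/discharge times are not exact, so the benign reading is inclusive.
  Patients with no admission row cannot be checked and are excluded
  entirely, counted separately.
* **Overlap** (stage 2): after collapsing exact duplicate rows (all five
  fields equal — a re-exported file carries no ambiguity), any
  `(mrn, timestamp)` holding ≥ 2 recordings has **all** of them excluded.
  There is no objective basis for adjudicating which stream is genuine, so
  none is kept. Flagging is per colliding timestamp, not per device stream:
  that is the minimal faithful reading of "flag overlapping records"; a
  stream-level exclusion would be a sensitivity analysis, not the default.

The `cleaning_report` carries per-stage patient/recording counts; at every
stage `recordings_in = recordings_out + excluded (+ deduplicated)`, and the
suite asserts cleaning is invariant to input row order.

## 3. Consolidation and smoothing

Each recording maps to one of five posture groups by precedence over its
tokens: any `S-` prefix → UserDefined; any `UNK` or a blank recording →
Unknown; all tokens lying codes → Lying; any `U90`/`WLK` → Upright; any
`U45` → Reclined; anything else → Unknown with a warning counter (the rule
is total). Walking folds into Upright because the device may label walking
`U90`; self-reports stay separate because their intent is unverifiable.

Smoothing removes *isolated single-timestamp flips*: for each interior
timestamp whose neighbours are both exactly 15 s away, the modal group of
the 3-window wins; a 3-way tie leaves the value unchanged. Numerical
decisions:

* **Simultaneous, single pass.** The vote always reads the input series —
  the categorical analogue of one pass of a 3-point moving average. No
  iteration to a fixed point; consequently the output can contain new
  isolated singletons (e.g. `L R L R L → L L R L L`). The exact
  characterization — positions changed are precisely interior `i` with
  `x[i-1] = x[i+1] ≠ x[i]`, set to `x[i-1]` — is asserted against a
  brute-force re-check on 10^4 random series.
* **Gaps are boundaries.** A timestamp adjacent to a missing grid point is
  never changed; voting across a gap would mix non-adjacent moments.

## 4. Per-patient statistics

* **Day** = local calendar date (midnight boundary). **Total days** counts
  every date with ≥ 1 recording. **Hours of data** is count-based
  (n × 15 s), so the analysis-day rule "≥ 22 hours" is identically
  "≥ 5280 recordings" (the two coincide only on gap-free data; count-based
  is the robust choice). All duration/FPT statistics use analysis days
  only; patients without one are excluded and counted.
* **Windows.** DT is the half-open `[07:00:00, 19:00:00)` — 18:59:45 is the
  last DT slot on the grid — and NT is the complement. Durations:
  per analysis day, the proportion of the window's recordings in each
  group, averaged over days, times 24 (WD) or 12 (DT/NT) hours. Days with
  zero recordings in a window are omitted from that window's average.
* **Transitions.** A transition is a change between grid-adjacent
  recordings restricted to Lying/Reclined/Upright (6 ordered types);
  pairs with Unknown/UserDefined and pairs across gaps are not counted.
  Pairs spanning midnight or a window boundary are attributed to **no**
  day/window — symmetric, at most one pair per boundary, and unbiased.
  FPT = per-day transitions ÷ actual in-window hours, averaged over
  analysis days; windows with zero hours on a day are omitted.
* Conservation is exact and tested: on complete days the five WD durations
  sum to 24 h and `WD = DT + NT` per group; `Rest = Lying + Reclined`.

## 5. Subtyping

Features per window: the four physical/Unknown durations plus FPT
(UserDefined is excluded — essentially zero for everyone, no contrast);
the combined set concatenates DT and NT (10 features, one row per patient —
the row-stacking alternative would not yield a unique assignment per
patient). Columns are z-scored with the sample SD (n−1); a zero-variance
column is an error naming the column; centroids are de-standardized for
reporting.

k-means uses Lloyd iterations (cap 100) from k-means++-style seeds, 50
restarts by default keeping the lowest within-cluster sum of squares. The
number of clusters is chosen over k ∈ 2..10 by maximum average silhouette
width, computed with Euclidean distance in the standardized space (the
space the clustering used); ties go to the smaller k (parsimony);
candidates with k ≥ n are skipped with a warning. Cluster labels are
arbitrary up to permutation, so every report canonicalizes by descending
cluster size (ties by first patient index). The silhouette implementation
is cross-checked in the suite against a brute-force O(n²) computation and
against `cluster::silhouette`. Restart count, seeding and the silhouette
metric are package choices made for stability and reproducibility; exact
reproduction of any particular historical clustering is not attempted.

## 6. The synthetic cohort generator

The generator is a stated world, not a tuning dial: its defaults encode the
conditions the pipeline is designed for, and tests are written against
them.

* **Bout model.** First-order semi-Markov with geometric bout lengths:
  within each DT/NT window segment, bouts are drawn i.i.d. — group from
  the window's weight vector over (Lying, Reclined, Upright, Unknown),
  length `1 + Geometric(1/mean_bout_len)`. Adjacent same-group bouts merge,
  which leaves the stationary time share of each group exactly equal to its
  weight. A new bout starts at each 07:00/19:00 switch. This is the
  simplest model producing the duration/transition structure the
  statistics measure.
* **Archetypes.** Four defaults emulate the subtypes the clustering should
  find — `lying_rester` (night Lying weight 0.88, bout 96),
  `reclined_rester` (day Reclined 0.62, bout 90), `active` (day Upright
  0.48, bout 40, hence the highest transition rate) and
  `unknown_dominant` (Unknown ≈ 0.7, mixed at 42/32/23/3% of the cohort).
  Weight vectors were set from the whole-day time shares such subtypes
  display (two resting styles, one active, one Unknown-dominated) before
  any test was run.
* **Realism knobs and defaults.** `days_per_patient = 2..6` (median stays
  of a few days), `frac_overlap_patients = 0.1` (roughly one patient in
  ten shows overlap in routine exports), `frac_inconsistent_patients =
  0.1` with extensions up to 48 h ("up to days"), `frac_incomplete_days =
  0.3` (a contiguous 3–20 h block deleted, pushing the day below the 22-h
  threshold). Admissions are placed at **midnight** so that day
  completeness is governed solely by `frac_incomplete_days`; mid-day
  admissions can be produced directly with `generate_patient_series()`.
  2-code permutation strings are emitted at within-window bout boundaries
  (probability 0.3); longer permutations (rate 0.002) are constructed to
  classify to the slot's own group, so they exercise the tokenizer without
  perturbing durations; short 2-slot self-reported episodes (per-bout rate
  0.01) keep UserDefined near but not at zero.
* **Noise flips.** Isolated flips are injected per interior timestamp with
  probability `noise_rate` (default 0.01), but only at slots whose two
  neighbours share the slot's group, and never within 2 slots of another
  flip — so the majority vote provably reverts every injected flip
  (recall 1 by construction, asserted with the ground-truth flags). A
  known consequence, accounted for a priori in the recovery test: the
  realized alteration rate is biased low by about
  `2 · noise_rate / mean_bout_len` because bout-edge slots are ineligible.
* **Error injection.** Overlap copies a contiguous segment of a *real*
  other patient (donor device serial and file ID retained, timestamps
  re-aligned to slots the victim already occupies) — mirroring the
  reassigned-device mechanism rather than random noise. Inconsistency
  appends grid-aligned rows strictly outside `[admit, discharge]`. Every
  injected row is flagged in the ground truth, and the acceptance suite
  asserts cleaning removes exactly the injected set (precision = recall
  = 1).
* **What it does not emulate** — and hence what a green test does not
  establish: no accelerometer signals (codes are consumed, never derived),
  no vital-sign channels, no fall events beyond the `FALL` token, no
  correlation between posture habits and demographics, no device clock
  drift, and the code alphabet is the main-text subset of the proprietary
  list. Real exports may have richer failure modes (battery gaps, sensor
  misplacement) that only width of the Unknown group represents here.

## 7. Degenerate inputs, tolerances, reproducibility

Blank posture strings are Unknown; `FALL`/unrecognized tokens are Unknown
with a warning count; empty series yield zero days; a cohort left with no
analysis-day patients raises a clear error at the clustering step rather
than producing a degenerate fit; zero-variance features abort
standardization by name. All stochastic behaviour flows from single integer
seeds (`cohort_config(seed=)`, `fit_kmeans_select(seed=)`); reruns with the
same seed are bitwise-identical, which the suite asserts. Exact identities
(conservation, weighted-mean reconstruction) are tested at 1e-9–1e-12;
statistical recoveries use pre-registered bands (±0.03 for stationary
proportions at 20 days with bout length 20; ±0.5 h for a 12 w daytime
duration; ±3 SE plus the documented eligibility bias for the alteration
rate).

## 8. Known limitations

* The overlap rule excludes all colliding readings; if one stream was in
  fact genuine, its data are lost (conservative by design).
* Count-based "hours of data" slightly overstates coverage when recordings
  cluster; span-based measurement would do the opposite. They agree on
  gap-free data.
* Single-pass smoothing can leave (or create) alternating patterns; a
  fixed-point variant was deliberately rejected to match the one-pass
  moving-window analogy.
* Silhouette-based selection is evaluated per dataset; on weakly separated
  cohorts the chosen k can sit on a plateau where neighbouring k are
  nearly as good — the full `silhouette_by_k` curve is reported for
  inspection.
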