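# posturekit

Quality control and analysis of continuously recorded inpatient posture
telemetry.

Wearable monitors used on hospital wards (ViSi-style systems) emit one
posture recording every 15 seconds — a code such as `LSP` (lying supine),
`U45` (reclined), `U90` (upright) or `WLK` (walking), or a space-separated
permutation like `"U45 U90"` when the posture changed within the slot.
Routinely collected streams of this kind are valuable for quantifying
patient mobilization, but they contain characteristic errors: **overlap**
(two devices reporting different readings under one patient ID at the same
timestamp, the signature of a recharged device reassigned without updating
the record number) and **inconsistency** (recordings stamped before
admission or after discharge). posturekit implements the full pipeline from
raw streams to patient subtypes:

1. **Ingestion** (`read_recordings()`, `read_admissions()`) of the
   canonical CSV dialects, with strict 15-second-grid validation.
2. **Cleaning** (`apply_exclusions()`): flag and exclude inconsistent and
   overlapping recordings in two stages, with a flow report accounting for
   every row.
3. **Consolidation** (`consolidate_recordings()`): every recording maps to
   one of five posture groups — Lying, Reclined, Upright, Unknown,
   User-defined — by a fixed precedence rule over its code tokens.
4. **Smoothing** (`smooth_majority_vote()`): a single-pass 3-point majority
   vote removes isolated single-timestamp posture flips.
5. **Summary statistics** (`patient_summaries()`): per patient, over
   *analysis days* (days with ≥ 22 h ⇔ ≥ 5280 recordings), the average
   hours/day in each group for the whole day (WD), daytime
   (DT, 07:00–18:59) and nighttime (NT) windows — duration(g, window) =
   scale × mean over days of the within-window proportion of recordings in
   g, with scale 24 (WD) or 12 (DT/NT) — plus the frequency of posture
   transitions (FPT, transitions/hour among Lying/Reclined/Upright only).
6. **Subtyping** (`fit_kmeans_select()`): z-scored features, Lloyd's
   k-means with k-means++ seeding and restarts, k ∈ 2..10 chosen by maximum
   average silhouette width; cluster tables in original units.

A first-class synthetic cohort generator (`simulate_cohort()`,
`generate_patient_series()`, `inject_overlap()`, `inject_inconsistency()`)
produces realistic multi-patient streams with ground-truth error flags, so
the entire pipeline is testable without access to hospital data.

## Worked example

```r
library(posturekit)

cfg    <- cohort_config(n_patients = 30, days_per_patient = c(2, 5), seed = 42)
cohort <- simulate_cohort(cfg)                       # ~590k recordings
res    <- apply_exclusions(cohort$recordings, cohort$admissions)
print(res$report)
#> Data cleaning flow
#>   input:                30 patients, 588464 recordings
#>   after inconsistency:  30 patients, 565145 recordings (23319 excluded)
#>   after overlap:        30 patients, 559061 recordings (6084 excluded, 0 deduplicated)
#>   overall excluded:     0.0% of patients, 5.0% of recordings

series <- smooth_majority_vote(consolidate_recordings(res$recordings))
sums   <- patient_summaries(series)
sums[1:3, .(mrn, total_days, analysis_days, `Lying-WD`, `Reclined-WD`,
            `Upright-WD`, `FPT-WD`)]
#>    mrn total_days analysis_days Lying-WD Reclined-WD Upright-WD FPT-WD
#>  P0001          5             3     6.05        9.60       7.06   3.24
#>  P0002          3             3     6.63        9.06       7.46   3.26
#>  P0003          5             3    16.98        3.76       1.41   0.75
```

`Lying-WD = 16.98` means patient P0003 spent on average about 17 of every
24 hours lying flat across their 3 analysis days; `FPT-WD = 3.24` means
P0001 changed physical posture about 3.2 times per hour of data.

```r
fm <- feature_matrix(sums, "wd")      # Lying/Reclined/Upright/Unknown/FPT, WD
cl <- fit_kmeans_select(fm, restarts = 25, seed = 7)
print(cl)
#> k-means subtyping: k = 4 (avg silhouette 0.795)
#>           size  pct silhouette
#> cluster 1   12 40.0      0.776
#> cluster 2    9 30.0      0.799
#> cluster 3    7 23.3      0.777
#> cluster 4    2  6.7      0.960

round(cluster_table(cl, fm), 1)
#>         Lying-WD Reclined-WD Upright-WD Unknown-WD FPT-WD  n   pct
#> C1           5.7        14.1        2.8        1.4    1.2 12  40.0
#> C2           6.0         9.2        7.8        1.1    3.4  9  30.0
#> C3          17.1         3.6        2.1        1.2    0.9  7  23.3
#> C4           4.0         2.5        1.8       15.7    0.2  2   6.7
#> Average      8.3         9.4        4.1        2.2    1.7 30 100.0
```

The four recovered subtypes are the structure the generator planted: a
Reclined-resting group (C1), an active group with high Upright time and
transition rate (C2), a Lying-resting group (C3), and a small group
dominated by Unknown readings (C4).

Labor-savings arithmetic for replacing half-hourly nurse observation
(2 nurse-hours per patient-day):

```r
labor_savings(4847, 2, 41.38)
#> $hours_saved  9694
#> $cost_saved   401138
```

## Command line

```sh
inst/cli/posturekit simulate --out cohort/ --patients 50 --seed 1
inst/cli/posturekit clean --recordings cohort/recordings.csv \
    --admissions cohort/admissions.csv --out clean.csv --report flow.json
inst/cli/posturekit run --recordings cohort/recordings.csv \
    --admissions cohort/admissions.csv --out results/ --seed 1
```

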