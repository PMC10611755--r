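# nodeval

Nodule-level validation of lesion-detection CAD against multi-reader
reference standards.

## What this package is for

When a computer-aided detection (CAD) system for pulmonary nodules is
validated on clinical CT, the ground truth itself must first be
constructed: a panel of radiologists annotates every scan independently, a
majority vote (≥3 of 5 readers) defines the reference nodules, and findings
that fail the 3–30 mm size gate or the vote become *indeterminate* — an
exclusion list whose matches count neither as true nor false positives.
Detections are then scored with a center-within-radius hit criterion and
summarised by FROC analysis: sensitivity against false positives per scan
(FP/s), read off at the seven predefined rates 0.125, 0.25, 0.5, 1, 2, 4
and 8 FP/s, whose mean is the Competition Performance Metric,

CPM = (1/7) Σᵢ sens(fpᵢ),   fpᵢ ∈ {0.125, 0.25, 0.5, 1, 2, 4, 8}.

`nodeval` implements this methodology for anyone running a nodule-CAD
reader study or re-analysing one:

* **consensus** — annotation clustering, majority-vote reference with
  exclusion list, malignancy-registry linkage (panel-missed cancers are
  promoted or appended as targets), subset views, leave-one-out references;
* **matching** — hit-criterion labelling (TP / FP / ignored / duplicate)
  for scored predictions and for unscored reader marks;
* **froc_stats** — FROC curves, sensitivity at predefined rates, CPM,
  operating-point calibration to a target FP/s, scan-level bootstrap
  confidence intervals, paired permutation tests;
* **reader_compare** — per-reader leave-one-out evaluation with AI
  recalibration per comparison and nodule-level significance tests;
* **synthetic_cohort** — a generator for ground-truth cohorts (four
  balanced scan categories), heterogeneous five-reader panels and scored
  CAD output, so the entire pipeline is testable without clinical data;
* **cli_report** — `run_evaluation()` / `run_comparison()` plus a thin
  command-line wrapper (`inst/cli/nodeval.R`) producing the sensitivity
  and comparison tables and FROC point files.

All tables are plain CSV in a LUNA16-style dialect (scan id + world-mm
coordinates); see `?annotations_io`.

## Worked example

```r
library(nodeval)

co    <- generate_cohort(cohort_config(seed = 7))   # 100 scans, 25/category
ann   <- simulate_readers(co)                       # five-reader panel
preds <- simulate_cad(co)                           # scored CAD output

ref <- link_malignancy(build_reference_standard(ann, co$scans),
                       truth_registry(co))
ref
#> Multi-reader reference standard
#>   scans: 100 | readers: 5 | majority: >=3
#>   included nodules: 244 (of 574 clusters)
#>   excluded: 333 (too_small 66, too_large 0, minority 267)
#>   panel-missed cancers: 37

view <- select_subset(ref, min_diameter = 3, class_filter = "all")
m    <- match_predictions(preds, view)
sensitivity_report(froc_curve(m))
#> Sensitivity at predefined FP/s rates (%):
#> 0.125 0.250 0.500 1.000 2.000 4.000 8.000
#>  79.5  80.3  84.0  89.3  92.2  96.3  97.5
#> CPM: 88.5

cal <- calibrate_threshold(froc_curve(m), 1.0)
#> threshold 0.343 -> 1.00 FP/s, sensitivity 89.3%
```

Reading the output: of 574 clustered panel findings, 244 met the size gate
and the majority vote; 37 registry cancers were missed by the panel
majority and entered the reference anyway. At the threshold giving at most
1 false positive per scan the simulated CAD detects 89.3% of reference
nodules; averaging sensitivity over the seven rates gives a CPM of 88.5%.
The five-reader panel and the CAD profile are simulation defaults chosen to
bracket realistic clinical reader heterogeneity and a strong detection
system (see the methods vignette, `vignettes/nodule-cad-validation.Rmd`).

For a reader study, `comparison_table()` (or `run_comparison()`) produces
one row per reader × nodule category with the AI recalibrated to 1 FP/s on
that reader's leave-one-out reference and a paired permutation p-value.

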