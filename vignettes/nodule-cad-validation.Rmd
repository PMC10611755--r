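---
title: "Validating nodule-detection CAD against a multi-reader reference standard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating nodule-detection CAD against a multi-reader reference standard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodeval)
```

## The evaluation problem

A computer-aided detection (CAD) system for pulmonary nodules emits, per CT
scan, a set of candidate locations with nodule-likelihood scores. Evaluating
such a system on clinical data poses two coupled problems:

1. **There is no single ground truth.** Radiologists disagree about what
   constitutes a nodule, so the reference standard is built by consensus: a
   panel of readers annotates every scan independently, marks from different
   readers referring to the same lesion are clustered, and a finding enters
   the reference only when a majority (at least 3 of 5 readers here) marked
   it. Findings outside the 3--30 mm equivalent-diameter window, or marked
   only by a minority, are *indeterminate*: they go to an exclusion list,
   and detections matching them count neither as true nor as false
   positives. This mirrors the LUNA16 evaluation convention.
2. **Detection is free-response.** Performance is summarised by the FROC
   curve -- lesion-level sensitivity against mean false positives per scan
   (FP/s) -- swept over the score threshold, with sensitivity read off at
   seven predefined rates (0.125, 0.25, 0.5, 1, 2, 4, 8 FP/s) and averaged
   into the Competition Performance Metric (CPM).

`nodeval` implements this validation methodology end to end, together with a
synthetic cohort generator so every stage can be exercised -- and its
statistical behaviour verified -- without any clinical data.

## The consensus reference standard

Marks are clustered per scan by greedy agglomerative merging: the closest
pair of clusters merges when the distance between their (running mean)
centers is at most the larger of their mean radii, and no reader contributes
twice to a cluster. The paper trail for a clustered finding is its averaged
position, volume and equivalent diameter (the diameter of the
volume-equivalent sphere, \(d = (6V/\pi)^{1/3}\)); the nodule type is the
plurality vote among contributors, with ties broken by the fixed priority
solid > part-solid > non-solid > perifissural > calcified. The size gate is
applied to the *averaged* diameter. These choices -- merge rule, tie-breaks,
gate placement -- are underdetermined by the methodology being reproduced;
we chose the variants that are deterministic, symmetric under input
reordering, and geometrically consistent with the hit criterion used at
evaluation time. `cluster_annotations()` is property-tested against a
connected-components oracle on well-separated scenes.

A malignancy registry (retrospectively localized, histologically or
clinically confirmed cancers) is then linked: each record attaches to the
nearest included nodule whose radius contains it. A record the majority
missed either *promotes* a minority-excluded finding into the reference
(keeping the panel's measurements, with `detected_by_panel = FALSE`) or, if
no panel finding matches, is appended at the registry coordinates. Malignant
findings are therefore reference targets regardless of panel agreement --
which is what lets CAD sensitivity for metastases exceed the panel's own.
Benign status is an input label (stability over follow-up), never inferred.

An *actionable* benign nodule is benign, at least 5 mm, and neither
calcified nor perifissural -- the subset follow-up guidelines care about.

## Matching and FROC analysis

The hit criterion is center-within-radius, boundary inclusive: a prediction
hits a reference nodule when its center lies within the nodule's
(consensus) radius of the nodule's center. A prediction inside several
targets goes to the nearest center (ties: smaller nodule id); per nodule
only the highest-scoring hit is a true positive, further hits are
*duplicates* (neither TP nor FP); predictions matching only ignore regions
are dropped from both counts; everything else is a false positive.
Subset analyses (diameter thresholds of 3/4/5 mm; benign/malignant classes)
treat out-of-subset included nodules as ignore regions, so the FP/s axis is
identical across subset rows.

The FROC curve enumerates one operating point per distinct score;
`sensitivity_at()` interpolates linearly in FP/s, carries the final
sensitivity forward beyond the largest achieved FP/s (a conservative system
is not penalised at the 8 FP/s query), and interpolates from a zero anchor
below the smallest. Operating-point calibration (`calibrate_threshold()`)
returns the deepest operating point whose FP/s does not exceed the budget;
tables additionally report the interpolated sensitivity at the budget, so
both conventions are visible.

Confidence intervals are percentile bootstrap (2.5th/97.5th) over
scan-level resampling with replacement: a scan drawn $k$ times contributes
its targets and predictions $k$ times, and the whole curve is recomputed
per replicate. Replicates with zero targets are redrawn and counted. The
percentile method is used because the methodology names only the bootstrap
scheme, not an interval construction.

## Reader comparison

Each reader is scored against the consensus rebuilt from the other four
readers (majority still 3, now of 4 -- preserving "majority" with the
panel reduced), so no reader confirms their own marks; registry-linked
malignant findings are retained regardless of remaining agreement. The AI
is matched against the *same* leave-one-out subset view and recalibrated to
1 FP/s per comparison, because the benign reference and exclusion list vary
per reader. Significance uses a two-sided paired permutation test on the
per-nodule detection indicators (registry-added, panel-missed nodules
included): the statistic is the difference in detection fractions, the null
is generated by independent per-pair sign flips, and the p-value carries
the add-one correction \(p = (1 + \#\{|T^\ast| \ge |T|\})/(1 + B)\), so
\(p > 0\) always. Concordant pairs contribute nothing; sampled p-values are
tested against full \(2^n\) enumeration.

## The synthetic cohort generator

The generator emulates the *structure* of the validation cohort, not its
images:

* **Design**: four balanced categories (default 25 scans each): stage I
  lung cancer (exactly one primary cancer, 6--30 mm, plus benign
  background), pulmonary metastases (1 to 15 per scan -- the eligibility
  cap), actionable benign (at least one benign nodule >= 5 mm, neither
  calcified nor perifissural), and normal (only sub-5 mm incidental
  nodules, or none).
* **Nodule population**: per-scan counts with median 2 and IQR 1--4;
  lognormal diameters with median 6.6 mm and IQR 4.7--11.9 mm; type mixture
  81.5/6.3/3.3/5.6/3.3% over solid/part-solid/non-solid/perifissural/
  calcified. The lognormal is parameterised by its median and quartile
  *ratio* (\(\sigma = \log(q_{75}/q_{25})/(2 \cdot 0.6745)\)); a lognormal
  cannot reproduce asymmetric quartiles around the median exactly, and the
  generator recovers the median to within sampling error.
* **Geometry**: centers uniform in a 300 x 250 x 250 mm box,
  rejection-sampled so every pair is separated by more than 1.5 times the
  sum of radii. This guarantees unambiguous clustering and matching --
  deliberately unlike real anatomy (no juxtapleural or juxtavascular
  attachment, no fissure geometry), which is exactly why passing tests here
  certify the *evaluation machinery*, not detection difficulty on real CT.
* **Readers**: detection probability `plogis(a + b log d)` scaled per type,
  Gaussian localisation jitter (sd 0.25 radius), 10% size noise, Poisson
  false-positive marks. The default five profiles bracket the reported
  panel heterogeneity (FP/s 0.1--0.8; metastasis-size sensitivities from
  roughly 30% to 90%). These are configuration, not estimates: no
  reader-level generative model is identifiable from published aggregates.
* **CAD**: per-nodule candidate emission `plogis(1.1 + 1.4 log d)`, scores
  `plogis(-1.85 + 1.5 log d + type effect + N(0, 1.1))`, plus Poisson(10)
  false candidates per scan with Beta(1.2, 6) scores. The score defaults
  were calibrated, once, on large cohorts so the simulated system's design
  operating point is ~90% sensitivity at 1 FP/s with a CPM in the high 80s
  -- the regime of the system whose validation methodology this package
  reproduces. Closed-loop tests then require the full pipeline to report
  that design value within 3 points on 200-scan cohorts.

A single pipeline seed is expanded into per-stage streams by fixed offsets
(+1000 readers, +2000 CAD), so stages can be regenerated independently; all
simulators are pure functions of (inputs, seed).

## Numerical conventions and degenerate inputs

* Distances and coordinates are world millimetres; no voxel handling.
* Hit and merge comparisons are boundary-inclusive with a 1e-9 mm guard
  against float knife-edges; permutation and threshold comparisons use a
  1e-12 guard.
* Percentages are rounded half away from zero to one decimal; p-values
  print with three decimals and a "<0.001" floor.
* A subset with zero targets is an error directing the user to an FP-only
  summary rather than a silent NaN; empty prediction files are valid and
  yield empty sets; readers who mark nothing score zero sensitivity.
* Reference building is invariant under permutation of input rows and
  readers (annotations are canonically sorted before clustering), and the
  cluster count always satisfies `clusters = included + excluded`.

## Problem sizes used in the test-suite simulations

Oracle suites use scenes of up to 10 predictions and 6 nodules (50--60
scenes), permutation exactness uses full enumeration up to \(2^{10}\),
bootstrap coverage uses 100 repeats of a 200-scan scene at 200 replicates,
and closed-loop recovery uses 200-scan cohorts with three replicate seeds
for the operating point and 50 seeded repeats for the significance-power
check. These sizes give Monte-Carlo error comfortably inside the asserted
tolerances while keeping the default suite quick to run.

## Known limitations

* Clustering is greedy; pathological overlapping-lesion configurations
  could in principle be grouped differently by an exhaustive optimiser, but
  such configurations are excluded by construction in the generator and
  rare in practice under the separation the hit criterion implies.
* The generator does not model scanner effects, slice thickness, contrast
  phase, reader type-confusion, or spatially correlated false positives.
* Point-in-sphere matching only; no segmentation-overlap (IoU) criteria.
* Case-level ROC/AUC and JAFROC figures of merit are out of scope.
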