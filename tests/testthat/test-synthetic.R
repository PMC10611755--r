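test_that("cohort generation is deterministic and respects the design", {
  cfg <- cohort_config(seed = 7)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$scans), 100)
  expect_true(all(table(co$scans$category) == 25))
  expect_identical(generate_cohort(cfg), co)

  nod <- co$nodules
  by_cat <- merge(nod, co$scans, by = "scan_id")
  # category rules
  mets <- by_cat[by_cat$category == "metastases", ]
  expect_true(all(table(mets$scan_id) <= 15))
  expect_true(all(mets$malignancy == "metastasis"))
  stage1 <- by_cat[by_cat$category == "stage1_cancer", ]
  pc <- stage1[stage1$malignancy == "primary_cancer", ]
  expect_true(all(table(factor(pc$scan_id,
    co$scans$scan_id[co$scans$category == "stage1_cancer"])) == 1))
  expect_true(all(pc$diameter_mm <= 30))
  normal <- by_cat[by_cat$category == "normal", ]
  expect_true(all(normal$diameter_mm < 5))
  expect_true(all(normal$malignancy == "benign"))
  act <- by_cat[by_cat$category == "actionable_benign", ]
  ok <- act$malignancy == "benign" & act$diameter_mm >= 5 &
    !act$nodule_type %in% c("calcified", "perifissural")
  expect_true(all(tapply(ok, act$scan_id, any)))

  # pairwise separation within each scan
  sep <- cfg$min_separation_factor
  for (sid in unique(nod$scan_id)) {
    s <- nod[nod$scan_id == sid, ]
    if (nrow(s) < 2) next
    d <- as.matrix(dist(s[, c("coord_x_mm", "coord_y_mm", "coord_z_mm")]))
    rsum <- outer(s$diameter_mm / 2, s$diameter_mm / 2, "+")
    expect_true(all(d[upper.tri(d)] > (sep * rsum)[upper.tri(rsum)]))
  }
})

test_that("the lognormal size sampler recovers its configured median", {
  withr::local_seed(22)
  x <- rlnorm_median_iqr(1e4, 6.6, c(4.7, 11.9))
  expect_lt(abs(median(x) - 6.6), 0.2)
  # the lognormal matches the quartile ratio (log-spread), not the
  # individual asymmetric quartiles
  want_ratio <- 11.9 / 4.7
  expect_lt(abs(quantile(x, .75) / quantile(x, .25) - want_ratio),
            0.15 * want_ratio)
})

test_that("reader simulation recovers configured detection and FP rates", {
  co <- generate_cohort(cohort_config(scans_per_category = rep(60, 4),
                                      seed = 31))
  n_nod <- nrow(co$nodules)
  expect_gt(n_nod, 1000 / 2)  # enough nodules for rate recovery
  flat <- reader_profile("rx", a = log(0.8 / 0.2), b = 0,
                         type_mult = setNames(rep(1, 5),
                           c("solid", "part_solid", "non_solid",
                             "perifissural", "calcified")),
                         jitter_frac = 0, size_noise_sd = 0, fp_rate = 0.5)
  ann <- simulate_readers(co, list(flat), seed = 99)
  expect_identical(simulate_readers(co, list(flat), seed = 99), ann)

  # detected marks sit exactly on true nodules (zero jitter); count them
  n_det <- sum(ann$coord_x_mm %in% co$nodules$coord_x_mm)
  p_hat <- n_det / n_nod
  expect_lt(abs(p_hat - 0.8), 3 * sqrt(0.8 * 0.2 / n_nod))

  n_fp <- nrow(ann) - n_det
  n_scans <- nrow(co$scans)
  expect_lt(abs(n_fp / n_scans - 0.5), 3 * sqrt(0.5 / n_scans))
})

test_that("CAD simulation is deterministic and monotone in nodule size", {
  co <- generate_cohort(cohort_config(seed = 12))
  pr <- cad_profile(emission_a = 50, emission_b = 0, score_sd = 0,
                    score_type = setNames(rep(0, 5),
                      c("solid", "part_solid", "non_solid", "perifissural",
                        "calcified")),
                    jitter_frac = 0, fp_rate = 0)
  preds <- simulate_cad(co, pr)
  expect_identical(simulate_cad(co, pr), preds)
  expect_equal(nrow(preds), nrow(co$nodules))  # emission probability 1
  # beta > 0, no noise: larger nodules never score lower
  key <- merge(preds, co$nodules, by = c("scan_id", "coord_x_mm",
                                         "coord_y_mm", "coord_z_mm"))
  o <- order(key$diameter_mm)
  expect_true(all(diff(key$score[o]) >= -1e-12))
  # no FP process: FROC stays at 0 FP/s; sensitivity at 1 FP/s is maximal
  ann <- simulate_readers(co, perfect_reader_profiles())
  ref <- build_reference_standard(ann, co$scans)
  cv <- froc_curve(match_predictions(preds, select_subset(ref)))
  expect_true(all(cv$points$fp_per_scan == 0))
  expect_equal(sensitivity_at(cv, 1.0), max(cv$points$sensitivity))
})

test_that("perfect readers and CAD reproduce the truth end to end", {
  co <- generate_cohort(cohort_config(scans_per_category = rep(10, 4),
                                      seed = 5))
  ann <- simulate_readers(co, perfect_reader_profiles())
  ref <- link_malignancy(build_reference_standard(ann, co$scans),
                         truth_registry(co))
  # consensus equals ground truth: same count, coordinates, sizes, labels
  expect_equal(nrow(ref$nodules), nrow(co$nodules))
  truth <- co$nodules[order(co$nodules$scan_id, co$nodules$coord_x_mm), ]
  got <- ref$nodules[order(ref$nodules$scan_id, ref$nodules$coord_x_mm), ]
  expect_equal(got$coord_x_mm, truth$coord_x_mm)
  expect_equal(got$diameter_mm, truth$diameter_mm)
  expect_identical(got$malignancy, truth$malignancy)
  expect_equal(nrow(ref$exclusions), 0)
  expect_equal(nrow(ref$missed_cancers), 0)
  expect_true(all(got$agreement == 5))

  preds <- simulate_cad(co, perfect_cad_profile())
  cv <- froc_curve(match_predictions(preds, select_subset(ref)))
  expect_equal(max(cv$points$sensitivity), 1.0)
  expect_true(all(cv$points$fp_per_scan == 0))
})

test_that("written synthetic studies re-read into identical tables", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(cohort_config(scans_per_category = rep(3, 4),
                                      seed = 77))
  ann <- simulate_readers(co)
  preds <- simulate_cad(co)
  write_cohort(co, dir, annotations = ann, predictions = preds)
  manifest <- read_scan_manifest(file.path(dir, "scans.csv"))
  expect_identical(manifest, co$scans)
  ann2 <- read_annotations(file.path(dir, "annotations.csv"), manifest)
  expect_equal(nrow(ann2), nrow(ann))
  expect_equal(ann2$coord_x_mm, ann$coord_x_mm, tolerance = 1e-6)
  reg <- read_registry(file.path(dir, "registry.csv"), manifest)
  expect_equal(nrow(reg), sum(co$nodules$malignancy != "benign"))
})
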