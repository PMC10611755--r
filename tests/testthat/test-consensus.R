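readers <- sprintf("r%d", 1:5)

# five readers marking the same sites with optional jitter
panel_marks <- function(sites_x, readers_per_site, d = 6, jitter = 0,
                        scan = "s001") {
  rows <- list()
  for (k in seq_along(sites_x)) {
    for (r in readers_per_site[[k]]) {
      rows[[length(rows) + 1]] <- make_ann(
        scan, r, x = sites_x[k] + rnorm(1, 0, jitter),
        y = rnorm(1, 0, jitter), z = rnorm(1, 0, jitter), d = d)
    }
  }
  do.call(rbind, rows)
}

test_that("coincident and well-separated marks cluster as expected", {
  ann <- panel_marks(0, list(readers))
  cl <- cluster_annotations(ann)
  expect_length(cl, 1)
  expect_equal(nrow(cl[[1]]), 5)

  ann <- panel_marks(c(0, 40), list(c("r1", "r2"), "r3"))
  cl <- cluster_annotations(ann)
  expect_length(cl, 2)
  expect_setequal(cl[[1]]$reader_id, c("r1", "r2"))
  expect_identical(cl[[2]]$reader_id, "r3")

  expect_length(cluster_annotations(make_ann("s", "r", 1)[0, ]), 0)
})

test_that("clustering matches the component oracle on separated scenes", {
  withr::local_seed(101)
  for (rep in 1:20) {
    n_sites <- sample(1:6, 1)
    sites <- seq(0, by = 60, length.out = n_sites) + runif(n_sites, -5, 5)
    who <- lapply(seq_len(n_sites), function(i) {
      sample(readers, sample(1:5, 1))
    })
    ann <- panel_marks(sites, who, d = 8, jitter = 1.0)
    if (nrow(ann) > 12) ann <- ann[1:12, ]
    got <- cluster_annotations(ann)
    want <- oracle_cluster_components(nodeval:::canonical_order(ann))
    expect_equal(length(got), length(want))
    # identical membership, compared as sets of (reader, x) signatures
    sig <- function(df) paste(sort(paste(df$reader_id, df$coord_x_mm)), collapse = "|")
    ord <- nodeval:::canonical_order(ann)
    expect_setequal(vapply(got, sig, ""),
                    vapply(want, function(ix) sig(ord[ix, ]), ""))
  }
})

test_that("size gate and majority vote populate reference and exclusions", {
  manifest <- make_manifest(1)
  # minority cluster: 2 of 5 readers, size-valid
  ann <- panel_marks(0, list(c("r1", "r2")), d = 6)
  ref <- build_reference_standard(ann, manifest, n_readers = 5)
  expect_equal(nrow(ref$nodules), 0)
  expect_identical(ref$exclusions$reason, "minority")

  # full agreement, consensus diameter is the mean
  rows <- Map(function(r, d) make_ann("s001", r, 0, d = d),
              readers, c(4, 5, 6, 5, 5))
  ref <- build_reference_standard(do.call(rbind, rows), manifest)
  expect_equal(nrow(ref$nodules), 1)
  expect_equal(ref$nodules$diameter_mm, 5.0)
  expect_equal(ref$nodules$agreement, 5L)

  # averaged diameter below 3 mm -> too_small even with 4 readers
  rows <- Map(function(r) make_ann("s001", r, 0, d = 2.8), readers[1:4])
  ref <- build_reference_standard(do.call(rbind, rows), manifest, n_readers = 5)
  expect_identical(ref$exclusions$reason, "too_small")

  expect_error(build_reference_standard(ann, manifest, min_agreement = 6,
                                        n_readers = 5),
               "min_agreement")
})

test_that("conservation and min_agreement monotonicity hold on random panels", {
  withr::local_seed(202)
  manifest <- make_manifest(5)
  for (rep in 1:5) {
    ann <- do.call(rbind, lapply(1:5, function(s) {
      n_sites <- sample(2:5, 1)
      sites <- seq(0, by = 50, length.out = n_sites)
      who <- lapply(seq_len(n_sites), function(i) sample(readers, sample(1:5, 1)))
      panel_marks(sites, who, d = runif(1, 2, 8), jitter = 0.5,
                  scan = sprintf("s%03d", s))
    }))
    sizes <- sapply(1:5, function(ma) {
      ref <- build_reference_standard(ann, manifest, min_agreement = ma)
      expect_equal(ref$n_clusters, nrow(ref$nodules) + nrow(ref$exclusions))
      nrow(ref$nodules)
    })
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("identical reader panels reproduce a single reader's set exactly", {
  manifest <- make_manifest(2)
  one <- rbind(make_ann("s001", "r1", c(0, 50, 100), d = c(6, 2, 8)),
               make_ann("s002", "r1", 10, d = 35))
  ann <- do.call(rbind, lapply(readers, function(r) {
    x <- one; x$reader_id <- r; x
  }))
  ref <- build_reference_standard(ann, manifest)
  expect_equal(nrow(ref$nodules), 2)        # size-valid marks only
  expect_setequal(ref$nodules$diameter_mm, c(6, 8))
  expect_false(any(ref$exclusions$reason == "minority"))
  expect_setequal(ref$exclusions$reason, c("too_small", "too_large"))
})

test_that("the reference is invariant under row permutation", {
  withr::local_seed(303)
  manifest <- make_manifest(3)
  ann <- do.call(rbind, lapply(1:3, function(s) {
    panel_marks(c(0, 45, 90), list(readers, readers[1:3], readers[c(2, 4)]),
                d = 7, jitter = 0.8, scan = sprintf("s%03d", s))
  }))
  ref1 <- build_reference_standard(ann, manifest)
  ref2 <- build_reference_standard(ann[sample(nrow(ann)), ], manifest)
  expect_equal(ref1$nodules, ref2$nodules)
  expect_equal(ref1$exclusions, ref2$exclusions)
})

test_that("malignancy linkage relabels, promotes or appends and recomputes flags", {
  manifest <- make_manifest(1)
  ann <- panel_marks(c(0, 60), list(readers, readers), d = 8)
  ref <- build_reference_standard(ann, manifest)
  expect_true(all(ref$nodules$actionable))

  # record at a nodule center: relabel, actionable off
  reg <- data.frame(scan_id = "s001", coord_x_mm = 0, coord_y_mm = 0,
                    coord_z_mm = 0, diameter_mm = 8,
                    status = "primary_cancer", stringsAsFactors = FALSE)
  linked <- link_malignancy(ref, reg)
  i <- which(linked$nodules$malignancy == "primary_cancer")
  expect_length(i, 1)
  expect_false(linked$nodules$actionable[i])
  expect_equal(nrow(linked$missed_cancers), 0)

  # empty registry: everything stays benign
  linked0 <- link_malignancy(ref, reg[0, ])
  expect_true(all(linked0$nodules$malignancy == "benign"))

  # far-away record: reported as panel-missed and appended as a target
  reg$coord_x_mm <- 500
  far <- link_malignancy(ref, reg)
  expect_equal(nrow(far$missed_cancers), 1)
  expect_identical(far$missed_cancers$resolution, "added_from_registry")
  expect_equal(nrow(far$nodules), 3)
  expect_false(far$nodules$detected_by_panel[3])

  # record on a minority cluster: promoted with its panel measurements
  ann2 <- rbind(ann, panel_marks(120, list(c("r1", "r2")), d = 8))
  ref2 <- build_reference_standard(ann2, manifest)
  reg2 <- reg; reg2$coord_x_mm <- 120; reg2$status <- "metastasis"
  prom <- link_malignancy(ref2, reg2)
  expect_identical(prom$missed_cancers$resolution, "promoted_minority")
  expect_equal(sum(prom$exclusions$reason == "minority"), 0)
  j <- which(prom$nodules$malignancy == "metastasis")
  expect_equal(prom$nodules$agreement[j], 2L)
})

test_that("subset selection splits targets from ignore regions", {
  manifest <- make_manifest(1)
  rows <- list(
    panel_marks(0, list(readers), d = 4.2),
    panel_marks(50, list(readers), d = 5.0),
    panel_marks(100, list(readers), d = 7.1),
    panel_marks(150, list(c("r1", "r2")), d = 6))   # minority -> exclusion
  ref <- build_reference_standard(do.call(rbind, rows), manifest)
  expect_equal(nrow(ref$nodules), 3)

  v3 <- select_subset(ref, 3, "all")
  expect_equal(nrow(v3$targets), 3)
  expect_equal(nrow(v3$ignore), 1)       # the exclusion list only

  v5 <- select_subset(ref, 5, "all")
  expect_equal(nrow(v5$targets), 2)      # boundary 5.0 is inclusive
  expect_equal(nrow(v5$ignore), 2)

  # a 6-mm perifissural benign nodule is not an actionable target
  ann <- rbind(panel_marks(0, list(readers), d = 6),
               do.call(rbind, lapply(readers, function(r)
                 make_ann("s001", r, 60, d = 6, type = "perifissural"))))
  refp <- build_reference_standard(ann, manifest)
  va <- select_subset(refp, 3, "actionable_benign")
  expect_equal(nrow(va$targets), 1)
  expect_false("perifissural" %in% va$targets$nodule_type)
  # actionable flag definition holds exactly
  n <- refp$nodules
  expect_equal(sum(n$actionable),
               sum(n$malignancy == "benign" & n$diameter_mm >= 5 &
                     !n$nodule_type %in% c("calcified", "perifissural")))
})

test_that("leave-one-out reference drops only the excluded reader's support", {
  manifest <- make_manifest(1)
  ann <- rbind(
    panel_marks(0, list(readers), d = 6),             # 5/5 benign
    panel_marks(60, list(c("r1", "r2", "r3")), d = 6), # 3/5 benign
    panel_marks(120, list(c("r2", "r4")), d = 6))      # minority, malignant
  reg <- data.frame(scan_id = "s001", coord_x_mm = 120, coord_y_mm = 0,
                    coord_z_mm = 0, diameter_mm = 6, status = "metastasis",
                    stringsAsFactors = FALSE)

  loo <- leave_one_out_reference(ann, manifest, reg, "r1")
  # 5/5 nodule survives (4 >= 3); the 3/5 benign nodule loses r1 -> excluded
  expect_equal(sum(loo$nodules$malignancy == "benign"), 1)
  expect_true(any(loo$exclusions$reason == "minority"))
  # registry-linked metastasis remains a target even at agreement 2
  expect_equal(sum(loo$nodules$malignancy == "metastasis"), 1)

  loo2 <- leave_one_out_reference(ann, manifest, reg, "r2")
  # metastasis still retained with one remaining contributor
  expect_equal(sum(loo2$nodules$malignancy == "metastasis"), 1)

  expect_error(leave_one_out_reference(ann[ann$reader_id %in% readers[1:3], ],
                                       manifest, NULL, "r1"),
               "remaining readers")
  expect_error(leave_one_out_reference(ann, manifest, NULL, "nobody"),
               "unknown reader")
})
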