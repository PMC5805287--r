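# Dataset container, generators, splitting and I/O.

test_that("dataset container validates its invariants", {
  expect_error(wnn_dataset(matrix(0, 3, 2), c(0L, 1L)), "rows")
  expect_error(wnn_dataset(matrix(c(0, Inf), 1, 2), 0L), "finite")
  expect_error(wnn_dataset(matrix(0, 2, 2), c(0L, 2L)), "labels")
  d <- wnn_dataset(matrix(rnorm(6), 3, 2), c(0L, 1L, 0L),
                   patient_ids = c("a", "a", "b"))
  expect_s3_class(d, "wnn_dataset")
  sub <- dataset_subset(d, c(1, 3))
  expect_equal(sub$patient_ids, c("a", "b"))
})

test_that("the two-spiral task has the classic geometry", {
  sp <- two_spiral()
  expect_equal(nrow(sp$features), 194)
  expect_equal(sum(sp$labels == 0), 97)
  expect_equal(sum(sp$labels == 1), 97)
  # first class-0 point: phi = 0, r = 6.5
  expect_equal(unname(sp$features[1, ]), c(0, 6.5))
  # class-1 spiral is the exact negation of class-0 at zero noise
  expect_identical(sp$features[98:194, ], -sp$features[1:97, ],
                   ignore_attr = TRUE)
  # deterministic and seed-independent at zero noise
  expect_identical(two_spiral(), two_spiral(seed = 123))
  # jitter is reproducible under a seed and breaks antisymmetry
  n1 <- two_spiral(noise_sd = 0.1, seed = 5)
  n2 <- two_spiral(noise_sd = 0.1, seed = 5)
  expect_identical(n1, n2)
  expect_false(isTRUE(all.equal(n1$features[98, ], -n1$features[1, ])))
})

test_that("synthetic clinical data has the declared patient structure", {
  d <- synth_clinical(n_patients = 40, records_per_patient = 26,
                      n_features = 26, class_balance = 0.5,
                      effect_size = 1, seed = 2)
  expect_equal(nrow(d$features), 1040)
  expect_equal(sum(d$labels == 0), 520)
  expect_equal(sum(d$labels == 1), 520)
  expect_equal(length(unique(d$patient_ids)), 40)
  # all records of an individual share one label
  expect_true(all(tapply(d$labels, d$patient_ids,
                         function(l) length(unique(l))) == 1))
})

test_that("null effect size gives exchangeable class distributions", {
  d <- synth_clinical(n_patients = 200, records_per_patient = 4,
                      n_features = 2, effect_size = 0, seed = 3)
  ks <- stats::ks.test(d$features[d$labels == 0, 1],
                       d$features[d$labels == 1, 1])
  expect_gt(ks$p.value, 0.001)
})

test_that("a large effect size makes a single-feature threshold accurate", {
  d <- synth_clinical(n_patients = 300, records_per_patient = 2,
                      n_features = 3, effect_size = 5, seed = 4)
  acc <- mean((d$features[, 1] > 2.5) == (d$labels == 1))
  # analytic oracle: classes are N(0,1) vs N(5,1), the midpoint rule errs
  # with probability pnorm(-2.5) ~ 0.0062
  expect_gt(acc, 1 - 2 * stats::pnorm(-2.5) - 0.02)
})

test_that("within-patient correlation matches the requested value", {
  rho <- 0.6
  d <- synth_clinical(n_patients = 250, records_per_patient = 4,
                      n_features = 2, effect_size = 0,
                      within_patient_corr = rho, seed = 6)
  x <- d$features[, 1]
  ids <- d$patient_ids
  pairs1 <- c(); pairs2 <- c()
  for (id in unique(ids)) {
    xi <- x[ids == id]
    cmb <- utils::combn(length(xi), 2)
    pairs1 <- c(pairs1, xi[cmb[1, ]], xi[cmb[2, ]])
    pairs2 <- c(pairs2, xi[cmb[2, ]], xi[cmb[1, ]])
  }
  expect_lt(abs(stats::cor(pairs1, pairs2) - rho), 0.05)
})

test_that("holdout split is stratified, grouped and reproducible", {
  # 200 ungrouped records, balanced classes -> 20-record test set
  d <- wnn_dataset(matrix(rnorm(400), 200, 2), rep(c(0L, 1L), each = 100))
  sp <- holdout_split(d, test_fraction = 0.10, seed = 1)
  expect_equal(length(sp$test$labels), 20)
  expect_equal(sum(sp$test$labels == 0), 10)
  sp2 <- holdout_split(d, test_fraction = 0.10, seed = 1)
  expect_identical(sp, sp2)
  # grouped: no individual spans the split
  dg <- synth_clinical(30, 6, 3, effect_size = 1, seed = 7)
  spg <- holdout_split(dg, test_fraction = 0.2, seed = 2)
  expect_length(intersect(unique(spg$train$patient_ids),
                          unique(spg$test$patient_ids)), 0)
})

test_that("fold assignment is grouped and covers every fold", {
  dg <- synth_clinical(30, 6, 3, effect_size = 1, seed = 8)
  set.seed(9)
  folds <- ewnne:::make_folds(dg, 5)
  expect_setequal(unique(folds), 1:5)
  for (f in 1:5) {
    expect_length(intersect(unique(dg$patient_ids[folds == f]),
                            unique(dg$patient_ids[folds != f])), 0)
  }
  expect_error({set.seed(1); ewnne:::make_folds(dataset_subset(dg, 1:18), 5)},
               "fewer groups than folds")
})

test_that("the feature scaler centres and scales on the training view only", {
  d <- wnn_dataset(matrix(rnorm(60, mean = 5, sd = 3), 30, 2),
                   rep(c(0L, 1L), 15))
  sc <- fit_scaler(d)
  z <- apply_scaler(sc, d)
  expect_equal(unname(colMeans(z$features)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z$features, 2, sd)), c(1, 1), tolerance = 1e-12)
  # applying a train-fitted scaler elsewhere uses the train statistics
  d2 <- wnn_dataset(matrix(0, 2, 2), c(0L, 1L))
  z2 <- apply_scaler(sc, d2)
  expect_equal(z2$features[1, ], -sc$mean / sc$sd, ignore_attr = TRUE)
})

test_that("dataset files round-trip exactly and reject malformed input", {
  d <- synth_clinical(6, 3, 4, effect_size = 1, seed = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, path)
  back <- read_dataset(path, label_column = "label",
                       patient_column = "patient_id")
  expect_equal(back$features, d$features, ignore_attr = TRUE)
  expect_identical(back$labels, d$labels)
  expect_identical(back$patient_ids, d$patient_ids)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("f1,f2,label", "0.1,0.2,0", "0.3,0.4,2"), bad)
  expect_error(read_dataset(bad), "label value '2' at row 2")
  writeLines(c("f1,f2,label", "0.1,oops,0"), bad)
  expect_error(read_dataset(bad), "non-numeric feature cell in column 'f2'")
  writeLines(c("f1,f2,label", "0.1,0.2,0"), bad)
  expect_error(read_dataset(bad, label_column = "outcome"),
               "label column 'outcome' not found")
})

test_that("a clinical-shaped file loads with the expected dimensions", {
  # 195 records, 22 voice features, 31 subjects: the UCI voice-measurement
  # file layout
  set.seed(11)
  n <- 195
  df_feats <- matrix(rnorm(n * 22), n, 22)
  ids <- rep(sprintf("S%02d", 1:31), c(rep(6, 29), 10, 11))
  labs <- as.integer(ids %in% sprintf("S%02d", 1:23))
  d <- wnn_dataset(df_feats, labs, patient_ids = ids)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, path)
  back <- read_dataset(path, label_column = "label",
                       patient_column = "patient_id")
  expect_equal(dim(back$features), c(195, 22))
  expect_equal(length(unique(back$patient_ids)), 31)
})
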