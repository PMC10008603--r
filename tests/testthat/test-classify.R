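test_that("stratified folds partition the cohort proportionally", {
  labels <- rep(c(1L, 0L), c(80, 20))
  folds <- make_stratified_folds(labels, n_folds = 10, seed = 3)
  expect_setequal(unique(folds), 1:10)
  # partition: every sample in exactly one fold
  expect_length(folds, 100)
  for (f in 1:10) {
    expect_equal(sum(labels[folds == f] == 1), 8)
    expect_equal(sum(labels[folds == f] == 0), 2)
  }
  # within-1 proportionality for a non-divisible case
  labels2 <- rep(c(1L, 0L), c(77, 23))
  folds2 <- make_stratified_folds(labels2, n_folds = 10, seed = 3)
  tab <- table(folds2, labels2)
  expect_lte(diff(range(tab[, "1"])), 1)
  expect_lte(diff(range(tab[, "0"])), 1)

  expect_identical(folds, make_stratified_folds(labels, 10, seed = 3))
  expect_false(identical(folds, make_stratified_folds(labels, 10, seed = 4)))

  expect_error(make_stratified_folds(rep(c(1L, 0L), c(95, 5)), n_folds = 10),
               class = "survfuse_validation_error")
  expect_error(make_stratified_folds(rep(1L, 50), n_folds = 5),
               class = "survfuse_validation_error")
})

test_that("minority upsampling balances classes with duplicated originals", {
  withr::with_seed(5, {
    x <- matrix(rnorm(100 * 4), 100, 4)
  })
  y <- rep(c(1L, 0L), c(70, 30))
  bal <- upsample_minority(x, y, seed = 2)
  expect_equal(sum(bal$labels == 1), 70)
  expect_equal(sum(bal$labels == 0), 70)
  # appended rows are duplicates of original minority rows
  extra <- bal$features[101:140, , drop = FALSE]
  orig_min <- x[y == 0, , drop = FALSE]
  for (i in seq_len(nrow(extra))) {
    expect_true(any(apply(orig_min, 1, identical, extra[i, ])))
  }
  # already balanced: identity
  yb <- rep(c(1L, 0L), 50)
  balb <- upsample_minority(x, yb, seed = 2)
  expect_identical(balb$features, x)
  expect_identical(balb$labels, yb)

  expect_error(upsample_minority(x, rep(1L, 100)),
               class = "survfuse_validation_error")
})

test_that("classifier construction resolves gamma and is seeded", {
  spec <- classifier_spec("rbf_svm")
  clf <- build_classifier(spec, n_features = 500)
  expect_equal(clf$gamma, 0.002)

  expect_error(classifier_spec("neural_net"), class = "survfuse_config_error")
  expect_error(classifier_spec("rbf_svm", C = 0),
               class = "survfuse_config_error")

  # linear kernel ignores gamma/degree: predictions invariant to them
  withr::with_seed(6, {
    x <- matrix(rnorm(60 * 3), 60, 3)
    y <- as.integer(x[, 1] + 0.3 * rnorm(60) > 0)
  })
  lin1 <- build_classifier(classifier_spec("linear_svm", degree = 2), 3)
  lin2 <- build_classifier(classifier_spec("linear_svm", degree = 5), 3)
  expect_identical(lin1$predict(lin1$fit(x, y), x),
                   lin2$predict(lin2$fit(x, y), x))

  # forests with the same seed and data agree exactly
  rf <- build_classifier(classifier_spec("random_forest", seed = 9), 3)
  expect_identical(rf$predict(rf$fit(x, y), x), rf$predict(rf$fit(x, y), x))
})

test_that("confusion counts follow the short-term-positive convention", {
  cc <- confusion_counts(c(1, 1, 1, 0, 0, 1), c(1, 1, 1, 1, 0, 1))
  expect_equal(unlist(cc), c(tp = 4, tn = 1, fp = 1, fn = 0))

  perfect <- confusion_counts(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$fp + perfect$fn, 0)

  all_pos <- confusion_counts(c(1, 0, 0, 1), c(1, 1, 1, 1))
  expect_equal(all_pos$tn, 0)
  expect_equal(all_pos$fp, 2)

  expect_error(confusion_counts(c(1, 2), c(1, 0)),
               class = "survfuse_validation_error")
  expect_error(confusion_counts(c(1, 0), c(1)),
               class = "survfuse_validation_error")
})

test_that("metrics match hand evaluation and a brute-force recount", {
  m <- compute_metrics(tibble::tibble(tp = 3, fp = 1, fn = 0, tn = 2))
  expect_equal(m$pre, 0.75)
  expect_equal(m$sn, 1.0)
  expect_equal(m$acc, 5 / 6)
  expect_equal(m$f1, 6 / 7)

  # degenerate: no predicted or actual positives
  w <- capture_warnings(
    m0 <- compute_metrics(tibble::tibble(tp = 0, fp = 0, fn = 0, tn = 10))
  )
  expect_length(w, 3)
  expect_match(w, "0/0", all = TRUE)
  expect_equal(unlist(m0), c(acc = 1, pre = 0, sn = 0, f1 = 0))

  # brute-force oracle: independent recount of the four cells on random pairs
  withr::with_seed(7, {
    for (rep in 1:25) {
      y <- rbinom(1000, 1, runif(1, 0.2, 0.8))
      p <- rbinom(1000, 1, runif(1, 0.2, 0.8))
      cc <- confusion_counts(y, p)
      cells <- table(factor(y, c(0, 1)), factor(p, c(0, 1)))
      expect_identical(cc$tp, unname(cells["1", "1"]))
      expect_identical(cc$tn, unname(cells["0", "0"]))
      expect_identical(cc$fp, unname(cells["0", "1"]))
      expect_identical(cc$fn, unname(cells["1", "0"]))
      mm <- suppressWarnings(compute_metrics(cc))
      expect_equal(mm$acc, mean(y == p))
      if (sum(p) > 0) expect_equal(mm$pre, sum(y & p) / sum(p))
      if (sum(y) > 0) expect_equal(mm$sn, sum(y & p) / sum(y))
    }
  })

  # algebraic identity: predicting all positive gives sn = 1, pre = prevalence
  y <- rbinom(500, 1, 0.77)
  mm <- compute_metrics(confusion_counts(y, rep(1, 500)))
  expect_equal(mm$sn, 1)
  expect_equal(mm$pre, mean(y))
})

test_that("cross-validation is honest: chance on null data, strong on signal", {
  # null: labels independent of features, balanced
  withr::with_seed(8, {
    x_null <- matrix(rnorm(200 * 10), 200, 10)
    y_null <- rep(c(0L, 1L), 100)
  })
  res_null <- suppressWarnings(
    cross_validate(x_null, y_null, classifier_spec("random_forest", seed = 1),
                   n_folds = 10, seed = 2)
  )
  acc_null <- res_null$summary$mean[res_null$summary$metric == "acc"]
  expect_gte(acc_null, 0.4)
  expect_lte(acc_null, 0.6)

  # separable planted data
  withr::with_seed(9, {
    y_sig <- rep(c(0L, 1L), c(60, 140))
    x_sig <- matrix(rnorm(200 * 5), 200, 5) + 3 * y_sig
  })
  res_sig <- cross_validate(x_sig, y_sig, classifier_spec("rbf_svm"),
                            n_folds = 10, seed = 3)
  expect_gte(res_sig$summary$mean[res_sig$summary$metric == "f1"], 0.95)

  # glance/tidy round-trip: summaries recomputable from folds
  g <- glance(res_sig)
  td <- tidy(res_sig)
  expect_equal(g$f1, mean(td$f1))
  expect_equal(g$acc_sd, sd(td$acc))
  expect_equal(sum(td$tp + td$tn + td$fp + td$fn), 200)
})
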