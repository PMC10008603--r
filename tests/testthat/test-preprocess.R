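test_that("the missingness filter is strict at the threshold", {
  x <- matrix(rnorm(100 * 3), 100, 3,
              dimnames = list(NULL, c("keep10", "drop11", "clean")))
  x[1:10, "keep10"] <- NA   # exactly 10% missing -> kept
  x[1:11, "drop11"] <- NA   # 11% missing -> dropped
  d <- toy_table(x)
  out <- drop_high_missing_features(d, threshold = 0.10)
  expect_identical(setdiff(names(out), "patient_id"), c("keep10", "clean"))
  expect_identical(attr(out, "dropped_features"), "drop11")

  clean <- toy_table(matrix(rnorm(20), 10, 2))
  expect_identical(drop_high_missing_features(clean), clean,
                   ignore_attr = TRUE)
  all_na <- toy_table(matrix(NA_real_, 10, 2))
  expect_error(drop_high_missing_features(all_na),
               class = "survfuse_empty_matrix_error")
})

test_that("weighted kNN imputation matches hand-computed cases", {
  # no missing values: identity
  clean <- toy_table(matrix(rnorm(30), 10, 3))
  expect_identical(impute_weighted_knn(clean), clean)

  # two equidistant neighbours with values 2 and 4 -> imputed 3
  x <- rbind(
    c(0, 0, NA),
    c(1, 0, 2),
    c(-1, 0, 4),
    c(9, 9, 9)
  )
  d <- toy_table(x)
  out <- impute_weighted_knn(d, k = 2)
  expect_equal(out$f3[1], 3, tolerance = 1e-9)

  # k = 1: exact copy of the nearest neighbour's value
  out1 <- impute_weighted_knn(d, k = 1)
  expect_true(out1$f3[1] %in% c(2, 4))

  # observed cells are untouched bit-exactly
  expect_identical(as.matrix(out[-1, -1]), as.matrix(d[-1, -1]))

  # a patient with all features missing is an error naming the patient
  bad <- toy_table(rbind(c(NA, NA), c(1, 2), c(3, 4)),
                   ids = c("PX", "PA", "PB"))
  expect_error(impute_weighted_knn(bad), "PX",
               class = "survfuse_validation_error")
})

test_that("min-max normalisation maps to [0, 1] with exact endpoints", {
  expect_equal(minmax_normalize(c(30, 50, 70)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(0, 1)), c(0, 1))
  x <- rnorm(50)
  y <- minmax_normalize(x)
  expect_equal(min(y), 0)
  expect_equal(max(y), 1)
  expect_error(minmax_normalize(rep(2, 5)),
               class = "survfuse_validation_error")
})

test_that("expression discretisation thresholds per-gene z-scores", {
  x <- cbind(const = rep(5, 20), outlier = c(rep(0, 19), 10))
  d <- toy_table(x)
  expect_warning(out <- discretize_expression(d), "zero-variance")
  expect_true(all(out$const == 0))
  expect_equal(out$outlier[20], 1)
  expect_true(all(out$outlier[1:19] %in% c(-1, 0)))

  r <- toy_table(matrix(rnorm(200), 20, 10))
  disc <- discretize_expression(r)
  expect_true(all(unlist(disc[, -1]) %in% c(-1, 0, 1)))
})

test_that("constant features are dropped and informative ones kept", {
  x <- cbind(zeros = rep(0, 10), ok = rnorm(10))
  out <- drop_constant_features(toy_table(x))
  expect_identical(setdiff(names(out), "patient_id"), "ok")
  expect_identical(attr(out, "dropped_features"), "zeros")

  ok <- toy_table(matrix(rnorm(30), 10, 3))
  expect_identical(drop_constant_features(ok), ok, ignore_attr = TRUE)

  expect_error(drop_constant_features(toy_table(matrix(1, 5, 1))),
               class = "survfuse_empty_matrix_error")
})

test_that("top-variance selection ranks, reports and is order-invariant", {
  set.seed(4)
  x <- cbind(a = rnorm(100, sd = 2), b = rnorm(100, sd = 1),
             c = rnorm(100, sd = 0.1))
  x <- sweep(x, 2, colMeans(x))
  x <- sweep(x, 2, apply(x, 2, sd), "/")
  x <- sweep(x, 2, c(2, 1, 0.1), "*")   # exact sample sds 2, 1, 0.1
  d <- toy_table(x)
  out <- select_top_variance(d, k = 2)
  expect_identical(setdiff(names(out), "patient_id"), c("a", "b"))
  expect_equal(attr(out, "captured_variance"), 5 / 5.01, tolerance = 1e-9)

  # independent recomputation of the captured fraction from retained columns
  frac <- sum(apply(as.matrix(out[, -1]), 2, var)) /
    sum(apply(x, 2, var))
  expect_equal(attr(out, "captured_variance"), frac, tolerance = 1e-12)

  # identity when k >= n_features
  all_kept <- select_top_variance(d, k = 10)
  expect_equal(attr(all_kept, "captured_variance"), 1)
  expect_identical(names(all_kept), names(d))

  # permuting input feature order does not change the selected id set
  perm <- d[, c("patient_id", "c", "a", "b")]
  out_perm <- select_top_variance(perm, k = 2)
  expect_setequal(setdiff(names(out_perm), "patient_id"),
                  setdiff(names(out), "patient_id"))

  expect_warning(select_top_variance(d, k = 1), "variance")
})

test_that("cohort intersection sorts, aligns and is order-independent", {
  a <- toy_table(matrix(1:3, 3, 1), ids = c("C", "A", "B"))
  single <- intersect_cohort(list(a = a))
  expect_identical(single$patient_ids, c("A", "B", "C"))

  b <- toy_table(matrix(4:6, 3, 1), ids = c("B", "C", "D"))
  both <- intersect_cohort(list(a = a, b = b))
  expect_identical(both$patient_ids, c("B", "C"))
  expect_identical(both$matrices$a$patient_id, c("B", "C"))
  expect_identical(both$matrices$b$patient_id, c("B", "C"))

  # three matrices engineered to share exactly 7 ids
  common <- sprintf("S%02d", 1:7)
  m1 <- toy_table(matrix(rnorm(9), 9, 1), ids = c(common, "X1", "X2"))
  m2 <- toy_table(matrix(rnorm(8), 8, 1), ids = c(common, "Y1"))
  m3 <- toy_table(matrix(rnorm(10), 10, 1), ids = c(common, "Z1", "Z2", "Z3"))
  tri <- intersect_cohort(list(m1 = m1, m2 = m2, m3 = m3))
  expect_length(tri$patient_ids, 7)

  # order-independence and idempotence
  rev_order <- intersect_cohort(list(m3 = m3, m1 = m1, m2 = m2))
  expect_identical(rev_order$patient_ids, tri$patient_ids)
  again <- intersect_cohort(tri$matrices)
  expect_identical(again$patient_ids, tri$patient_ids)

  disjoint <- toy_table(matrix(1, 1, 1), ids = "Q")
  expect_error(intersect_cohort(list(a = a, q = disjoint)),
               class = "survfuse_validation_error")
})

test_that("the per-modality pipeline yields clean domain-valid tables", {
  prep <- tiny_prep()
  for (tag in names(prep$modalities)) {
    m <- prep$modalities[[tag]]
    expect_false(anyNA(m))
    expect_identical(names(m)[1], "patient_id")
  }
  expect_true(all(unlist(prep$modalities$cnv[, -1]) %in% -2:2))
  expect_true(all(unlist(prep$modalities$mrna[, -1]) %in% c(-1, 0, 1)))
  age <- prep$modalities$cln$age
  expect_gte(min(age), 0)
  expect_lte(max(age), 1)
  expect_named(prep$report, names(prep$modalities), ignore.order = TRUE)
})
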