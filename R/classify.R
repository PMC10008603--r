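#' Specify a classifier
#'
#' The roster covers soft-margin support vector machines with RBF, linear,
#' polynomial and sigmoid kernels, plus a random forest. Kernels that use
#' gamma follow the reciprocal rule gamma = 1 / n_features, so larger fused
#' feature spaces get smoother decision boundaries.
#'
#' @param kind One of `"rbf_svm"`, `"linear_svm"`, `"polynomial_svm"`,
#'   `"sigmoid_svm"`, `"random_forest"`.
#' @param C Soft-margin regularisation parameter (> 0); default 0.1, a
#'   deliberately small value.
#' @param degree Polynomial-kernel degree (>= 2), default 3.
#' @param n_trees Random-forest tree count, default 100.
#' @param seed Seed for the forest (SVM fits are deterministic).
#' @return A validated `classifier_spec`.
#' @export
#' @examples
#' classifier_spec("rbf_svm")
classifier_spec <- function(kind, C = 0.1, degree = 3L, n_trees = 100L,
                            seed = 0L) {
  kinds <- c("rbf_svm", "linear_svm", "polynomial_svm", "sigmoid_svm",
             "random_forest")
  if (length(kind) != 1L || !kind %in% kinds) {
    abort(paste0("unknown classifier kind: ", paste(kind, collapse = ", ")),
          class = "survfuse_config_error")
  }
  if (C <= 0) abort("invalid `C`: must be positive",
                    class = "survfuse_config_error")
  if (degree < 2) abort("invalid `degree`: must be >= 2",
                        class = "survfuse_config_error")
  if (n_trees < 1) abort("invalid `n_trees`: must be >= 1",
                         class = "survfuse_config_error")
  structure(
    list(kind = kind, C = C, degree = as.integer(degree),
         n_trees = as.integer(n_trees), gamma_rule = "reciprocal of feature count",
         seed = as.integer(seed)),
    class = "classifier_spec"
  )
}

#' Build a trainable classifier from a spec
#'
#' Resolves the spec against a feature count (fixing gamma by the reciprocal
#' rule) and returns fit/predict closures around the underlying SVM or
#' random-forest implementation.
#'
#' @param spec A [classifier_spec()].
#' @param n_features Number of input features (sets gamma).
#' @return A `survfuse_classifier`: a list with `fit(x, y)` returning a
#'   fitted model and `predict(model, x)` returning integer 0/1 labels,
#'   plus the resolved `gamma`.
#' @export
build_classifier <- function(spec, n_features) {
  stopifnot(inherits(spec, "classifier_spec"), n_features >= 1)
  gamma <- 1 / n_features
  named <- function(x) {
    if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
    x
  }
  if (spec$kind == "random_forest") {
    fit <- function(x, y) {
      ranger::ranger(
        x = named(x), y = factor(y, levels = c(0, 1)),
        num.trees = spec$n_trees,
        mtry = max(1L, floor(sqrt(ncol(x)))),
        seed = spec$seed, num.threads = 1
      )
    }
    # majority-vote ties at predict time are broken by the R RNG; pin it so
    # identical inputs give identical predictions
    pred <- function(model, x) {
      withr::with_seed(
        child_seed(spec$seed, 1L),
        as.integer(as.character(predict(model, data = named(x),
                                        num.threads = 1)$predictions))
      )
    }
  } else {
    kernel <- sub("_svm$", "", spec$kind)
    kernel <- c(rbf = "radial", linear = "linear", polynomial = "polynomial",
                sigmoid = "sigmoid")[[kernel]]
    fit <- function(x, y) {
      e1071::svm(x = x, y = factor(y, levels = c(0, 1)), kernel = kernel,
                 cost = spec$C, gamma = gamma, degree = spec$degree,
                 coef0 = 0, scale = FALSE)
    }
    pred <- function(model, x) as.integer(as.character(predict(model, x)))
  }
  structure(list(spec = spec, gamma = gamma, fit = fit, predict = pred),
            class = "survfuse_classifier")
}

#' Assign stratified cross-validation folds
#'
#' Shuffles each class separately (seeded) and deals its members across the
#' folds round-robin, so per-fold class counts differ from exact
#' proportionality by at most one sample.
#'
#' @param labels Integer 0/1 labels.
#' @param n_folds Number of folds, default 10.
#' @param seed Seed for the shuffle.
#' @return Integer fold assignment (1..n_folds) per sample.
#' @export
make_stratified_folds <- function(labels, n_folds = 10, seed = 0) {
  classes <- sort(unique(labels))
  if (length(classes) < 2) {
    abort("both classes must be present for stratified folds",
          class = "survfuse_validation_error")
  }
  counts <- table(labels)
  if (any(counts < n_folds)) {
    abort(sprintf("class %s has fewer members (%d) than folds (%d)",
                  names(counts)[which.min(counts)], min(counts), n_folds),
          class = "survfuse_validation_error")
  }
  folds <- integer(length(labels))
  withr::with_seed(child_seed(seed, 100L), {
    for (cl in classes) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

#' Upsample the minority class of a training set
#'
#' Resamples minority-class rows with replacement until the class counts are
#' equal. Applied to training folds only; every appended row is an exact
#' duplicate of an original minority row.
#'
#' @param features Feature matrix or tibble (no `patient_id` column).
#' @param labels Integer 0/1 labels, aligned to rows.
#' @param seed Seed for the resampling.
#' @return A list with balanced `features` and `labels`.
#' @export
upsample_minority <- function(features, labels, seed = 0) {
  features <- as.matrix(features)
  counts <- table(factor(labels, levels = c(0, 1)))
  if (any(counts == 0)) {
    abort("both classes must be present to upsample",
          class = "survfuse_validation_error")
  }
  if (counts[1] == counts[2]) return(list(features = features, labels = labels))
  minority <- as.integer(names(counts)[which.min(counts)])
  need <- abs(diff(counts))
  idx_min <- which(labels == minority)
  extra <- withr::with_seed(
    child_seed(seed, 200L),
    idx_min[sample.int(length(idx_min), need, replace = TRUE)]
  )
  list(
    features = rbind(features, features[extra, , drop = FALSE]),
    labels = c(labels, labels[extra])
  )
}

#' Confusion counts with short-term survivors as the positive class
#'
#' A short-term survivor (label 1) predicted short-term is a true positive;
#' a long-term survivor predicted long-term is a true negative; long-term
#' predicted short-term is a false positive; short-term predicted long-term
#' is a false negative.
#'
#' @param y_true,y_pred Integer 0/1 vectors of equal length.
#' @return A one-row tibble with `tp`, `tn`, `fp`, `fn`.
#' @export
#' @examples
#' confusion_counts(c(1, 1, 1, 0, 0, 1), c(1, 1, 1, 1, 0, 1))
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    abort("y_true and y_pred must have equal length",
          class = "survfuse_validation_error")
  }
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    abort("labels must be binary 0/1", class = "survfuse_validation_error")
  }
  tibble(
    tp = sum(y_true == 1 & y_pred == 1),
    tn = sum(y_true == 0 & y_pred == 0),
    fp = sum(y_true == 0 & y_pred == 1),
    fn = sum(y_true == 1 & y_pred == 0)
  )
}

#' Accuracy, precision, sensitivity and f1 from confusion counts
#'
#' `acc = (tp + tn) / n`, `pre = tp / (tp + fp)`, `sn = tp / (tp + fn)`,
#' `f1 = 2 * pre * sn / (pre + sn)`. Any 0/0 is defined as 0 with a warning.
#'
#' @param counts One-row tibble (or list) with `tp`, `tn`, `fp`, `fn`.
#' @return One-row tibble with `acc`, `pre`, `sn`, `f1`.
#' @export
#' @examples
#' compute_metrics(tibble::tibble(tp = 3, fp = 1, fn = 0, tn = 2))
compute_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  stopifnot(total > 0)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warn(paste0(what, " undefined (0/0); reported as 0"))
      0
    } else num / den
  }
  pre <- safe_div(tp, tp + fp, "precision")
  sn <- safe_div(tp, tp + fn, "sensitivity")
  f1 <- if (pre + sn == 0) {
    warn("f1 undefined (0/0); reported as 0")
    0
  } else 2 * pre * sn / (pre + sn)
  tibble(acc = (tp + tn) / total, pre = pre, sn = sn, f1 = f1)
}

#' Cross-validate a classifier under the survival protocol
#'
#' Ten-fold stratified cross-validation with per-fold minority upsampling of
#' the training instances. Each fold trains on the (balanced) training rows
#' only, predicts the untouched test fold, and records the confusion counts
#' and metrics; train/test disjointness is asserted in every fold.
#'
#' @param features Feature tibble (optionally with `patient_id`, which is
#'   dropped) or matrix, aligned with `labels`.
#' @param labels Integer 0/1 labels.
#' @param spec A [classifier_spec()].
#' @param n_folds Number of folds, default 10.
#' @param seed Protocol seed (fold assignment and upsampling).
#' @param feature_builder Optional `function(train_idx, test_idx)` returning
#'   `list(train, test)` feature matrices, for leakage-safe per-fold feature
#'   fitting; by default the precomputed `features` are subset.
#' @return An `eval_result` with per-fold metrics and mean/sd summaries.
#' @export
cross_validate <- function(features, labels, spec, n_folds = 10, seed = 0,
                           feature_builder = NULL) {
  if (is.data.frame(features)) {
    if (names(features)[1] == "patient_id") features <- features[, -1]
    features <- as.matrix(features)
  }
  if (!is.null(dim(features)) && nrow(features) != length(labels)) {
    abort("features and labels are not aligned",
          class = "survfuse_validation_error")
  }
  folds <- make_stratified_folds(labels, n_folds = n_folds, seed = seed)
  fold_rows <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    stopifnot(length(intersect(train_idx, test_idx)) == 0)
    if (is.null(feature_builder)) {
      x_train <- features[train_idx, , drop = FALSE]
      x_test <- features[test_idx, , drop = FALSE]
    } else {
      built <- feature_builder(train_idx, test_idx)
      x_train <- as.matrix(built$train)
      x_test <- as.matrix(built$test)
    }
    bal <- upsample_minority(x_train, labels[train_idx],
                             seed = child_seed(seed, f))
    clf <- build_classifier(spec, n_features = ncol(x_train))
    model <- clf$fit(bal$features, bal$labels)
    y_hat <- clf$predict(model, x_test)
    cc <- confusion_counts(labels[test_idx], y_hat)
    fold_rows[[f]] <- dplyr::bind_cols(tibble(fold = f), cc,
                                       suppressWarnings(compute_metrics(cc)))
  }
  folds_tbl <- dplyr::bind_rows(fold_rows)
  metric_cols <- c("acc", "pre", "sn", "f1")
  summary <- tibble(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(folds_tbl[[m]]), numeric(1)),
    sd = vapply(metric_cols, function(m) sd(folds_tbl[[m]]), numeric(1))
  )
  structure(
    list(folds = folds_tbl, summary = summary, spec = spec,
         n_folds = n_folds, seed = seed, n = length(labels)),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat("<eval_result>", x$spec$kind, "-", x$n_folds, "folds on", x$n,
      "samples\n")
  print(x$summary)
  invisible(x)
}

#' @rdname cross_validate
#' @param x An `eval_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.eval_result <- function(x, ...) x$folds

#' @rdname cross_validate
#' @exportS3Method generics::glance
glance.eval_result <- function(x, ...) {
  s <- x$summary
  out <- as.list(s$mean)
  names(out) <- s$metric
  sds <- as.list(s$sd)
  names(sds) <- paste0(s$metric, "_sd")
  dplyr::bind_cols(
    tibble(classifier = x$spec$kind, n = x$n, n_folds = x$n_folds),
    as_tibble(out), as_tibble(sds)
  )
}
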