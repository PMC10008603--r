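#' Enumerate modality combinations by arity
#'
#' All unordered subsets of the modality tags from `min_arity` to
#' `max_arity`, in deterministic order: by arity, then lexicographically.
#' With six modalities the per-arity counts follow the binomial
#' coefficients 6, 15, 20, 15, 6, 1.
#'
#' @param tags Character vector of unique modality tags.
#' @param min_arity,max_arity Inclusive arity bounds.
#' @return A list of sorted character vectors.
#' @export
#' @examples
#' length(enumerate_combinations(c("cln", "cnv", "dna", "mir", "mrna", "wsi")))
enumerate_combinations <- function(tags, min_arity = 1,
                                   max_arity = length(tags)) {
  if (anyDuplicated(tags)) {
    abort("modality tags must be unique", class = "survfuse_config_error")
  }
  if (min_arity < 1 || max_arity > length(tags) || min_arity > max_arity) {
    abort("inconsistent arity bounds", class = "survfuse_config_error")
  }
  tags <- sort(tags)
  out <- list()
  for (k in min_arity:max_arity) {
    combos <- combn(tags, k, simplify = FALSE)
    combos <- combos[order(vapply(combos, paste, character(1), collapse = "_"))]
    out <- c(out, combos)
  }
  out
}

#' Fuse per-modality feature tables over a common cohort
#'
#' Column-wise concatenation of the member modalities' feature tables in
#' sorted tag order, after checking that every table covers the cohort in
#' identical row order (misalignment is an error, never a silent reindex).
#' Feature names are prefixed with their tag so fused columns stay unique.
#'
#' @param reduced Named list of tibbles with `patient_id` first.
#' @param patient_ids Cohort patient ids defining the row order.
#' @return Tibble with `patient_id` and the concatenated feature columns.
#' @export
fuse_features <- function(reduced, patient_ids) {
  tags <- sort(names(reduced))
  blocks <- lapply(tags, function(tag) {
    m <- reduced[[tag]]
    if (!all(patient_ids %in% m$patient_id)) {
      abort(paste0("modality ", tag, " does not cover the cohort"),
            class = "survfuse_validation_error")
    }
    m <- m[match(patient_ids, m$patient_id), , drop = FALSE]
    if (!identical(m$patient_id, patient_ids)) {
      abort(paste0("row misalignment in modality ", tag),
            class = "survfuse_validation_error")
    }
    block <- m[, -1, drop = FALSE]
    names(block) <- paste(tag, names(block), sep = ".")
    block
  })
  dplyr::bind_cols(tibble(patient_id = patient_ids), blocks)
}

# Build the per-modality feature tables for one feature kind under the
# "full" fit scope (reducers fitted once on each modality's complete
# cohort, before cross-validation).
build_feature_tables <- function(processed, kind, pca_variance = 0.95,
                                 vae_configs = NULL, seed = 0) {
  tags <- names(processed)
  if (kind == "raw") return(processed)
  if (kind == "pca") {
    out <- lapply(tags, function(tag) apply_pca(fit_pca(processed[[tag]],
                                                        variance = pca_variance),
                                                processed[[tag]]))
    names(out) <- tags
    return(out)
  }
  if (kind == "vae") {
    out <- lapply(tags, function(tag) {
      cfg <- if (!is.null(vae_configs) && tag %in% names(vae_configs)) {
        vae_configs[[tag]]
      } else {
        vae_config(latent_dim = if (tag == "cln") 4L else 32L,
                   seed = child_seed(seed, 300L + match(tag, MODALITY_TAGS)))
      }
      vae_encode(fit_vae(processed[[tag]], cfg), processed[[tag]])
    })
    names(out) <- tags
    return(out)
  }
  abort(paste0("unknown feature kind: ", kind), class = "survfuse_config_error")
}

#' Run the full modality-combination ablation
#'
#' For every modality combination in the arity range: intersect the member
#' modalities on common patient ids, derive the survival labels for that
#' cohort, build each feature pathway (raw preprocessed features, PCA
#' scores, or VAE latent means), fuse, and cross-validate every classifier.
#' By default reducers are fitted once per modality on its complete cohort
#' (`fit_scope = "full"`, faithful to fitting before cross-validation);
#' `fit_scope = "per_fold"` refits the reducers inside every training fold
#' (leakage-safe, much slower).
#'
#' Record-level failures are caught and stored in the `error` column so a
#' long grid keeps running (fail-soft).
#'
#' @param cohort A `multimodal_cohort`.
#' @param feature_kinds Subset of `c("raw", "pca", "vae")`.
#' @param classifiers Named list of [classifier_spec()]s; default the full
#'   five-classifier roster.
#' @param n_folds Cross-validation folds, default 10.
#' @param seed Protocol seed.
#' @param min_arity,max_arity Combination arity range.
#' @param pca_variance PCA explained-variance target.
#' @param vae_configs Optional named list of per-modality [vae_config()]s.
#' @param fit_scope `"full"` or `"per_fold"`.
#' @param preprocess_args List of arguments passed to [preprocess_cohort()].
#' @return An `ablation_report`: `records` tibble (one row per combination x
#'   feature kind x classifier, with mean/sd metrics and nested fold
#'   metrics), plus the run configuration.
#' @export
run_ablation <- function(cohort,
                         feature_kinds = c("raw", "pca", "vae"),
                         classifiers = NULL,
                         n_folds = 10,
                         seed = 0,
                         min_arity = 1,
                         max_arity = NULL,
                         pca_variance = 0.95,
                         vae_configs = NULL,
                         fit_scope = c("full", "per_fold"),
                         preprocess_args = list()) {
  stopifnot(inherits(cohort, "multimodal_cohort"))
  fit_scope <- match.arg(fit_scope)
  if (is.null(classifiers)) {
    kinds <- c("rbf_svm", "linear_svm", "polynomial_svm", "sigmoid_svm",
               "random_forest")
    classifiers <- lapply(kinds, classifier_spec, seed = child_seed(seed, 400L))
    names(classifiers) <- kinds
  }
  prep <- do.call(preprocess_cohort, c(list(cohort), preprocess_args))
  processed <- prep$modalities
  tags <- names(processed)
  max_arity <- max_arity %||% length(tags)
  combos <- enumerate_combinations(tags, min_arity, max_arity)

  labels_tbl <- generate_labels_from_times(cohort$survival)

  features_by_kind <- list()
  if (fit_scope == "full") {
    for (kind in feature_kinds) {
      features_by_kind[[kind]] <- build_feature_tables(
        processed, kind, pca_variance = pca_variance,
        vae_configs = vae_configs, seed = seed
      )
    }
  }

  records <- list()
  for (combo in combos) {
    combo_name <- paste(combo, collapse = "_")
    inter <- intersect_cohort(processed[combo])
    lab_sub <- labels_tbl[match(inter$patient_ids, labels_tbl$patient_id), ]
    keep <- !lab_sub$excluded
    ids <- inter$patient_ids[keep]
    y <- lab_sub$label[keep]
    for (kind in feature_kinds) {
      fused <- NULL
      if (fit_scope == "full") {
        fused <- fuse_features(features_by_kind[[kind]][combo], ids)
      }
      for (cl_name in names(classifiers)) {
        rec <- tryCatch({
          res <- if (fit_scope == "full") {
            cross_validate(fused, y, classifiers[[cl_name]],
                           n_folds = n_folds, seed = seed)
          } else {
            raw_sub <- lapply(processed[combo], function(m) {
              m[match(ids, m$patient_id), , drop = FALSE]
            })
            builder <- function(train_idx, test_idx) {
              per_mod <- lapply(names(raw_sub), function(tag) {
                tr <- raw_sub[[tag]][train_idx, , drop = FALSE]
                te <- raw_sub[[tag]][test_idx, , drop = FALSE]
                if (kind == "raw") {
                  list(train = tr, test = te)
                } else if (kind == "pca") {
                  pm <- fit_pca(tr, variance = pca_variance)
                  list(train = apply_pca(pm, tr), test = apply_pca(pm, te))
                } else {
                  cfg <- if (!is.null(vae_configs) && tag %in% names(vae_configs)) {
                    vae_configs[[tag]]
                  } else {
                    vae_config(latent_dim = if (tag == "cln") 4L else 32L,
                               seed = child_seed(seed, 300L + match(tag, MODALITY_TAGS)))
                  }
                  vm <- fit_vae(tr, cfg)
                  list(train = vae_encode(vm, tr), test = vae_encode(vm, te))
                }
              })
              names(per_mod) <- names(raw_sub)
              list(
                train = as.matrix(fuse_features(
                  lapply(per_mod, `[[`, "train"), ids[train_idx])[, -1]),
                test = as.matrix(fuse_features(
                  lapply(per_mod, `[[`, "test"), ids[test_idx])[, -1])
              )
            }
            cross_validate(matrix(0, length(y), 1), y, classifiers[[cl_name]],
                           n_folds = n_folds, seed = seed,
                           feature_builder = builder)
          }
          g <- glance(res)
          tibble(
            combination = combo_name, arity = length(combo),
            feature_kind = kind, classifier = cl_name,
            cohort_size = length(ids),
            acc = g$acc, pre = g$pre, sn = g$sn, f1 = g$f1,
            acc_sd = g$acc_sd, pre_sd = g$pre_sd, sn_sd = g$sn_sd,
            f1_sd = g$f1_sd,
            folds = list(res$folds), error = NA_character_
          )
        }, error = function(e) {
          tibble(
            combination = combo_name, arity = length(combo),
            feature_kind = kind, classifier = cl_name,
            cohort_size = length(ids),
            acc = NA_real_, pre = NA_real_, sn = NA_real_, f1 = NA_real_,
            acc_sd = NA_real_, pre_sd = NA_real_, sn_sd = NA_real_,
            f1_sd = NA_real_,
            folds = list(tibble()), error = conditionMessage(e)
          )
        })
        records[[length(records) + 1L]] <- rec
      }
    }
  }
  structure(
    list(
      records = dplyr::bind_rows(records),
      preprocess_report = prep$report,
      config = list(feature_kinds = feature_kinds,
                    classifiers = names(classifiers),
                    n_folds = n_folds, seed = seed,
                    min_arity = min_arity, max_arity = max_arity,
                    pca_variance = pca_variance, fit_scope = fit_scope,
                    fusion_order = "sorted tags")
    ),
    class = "ablation_report"
  )
}

#' Aggregate ablation records by arity
#'
#' For each (arity, feature kind, classifier) cell: the mean and population
#' standard deviation of each metric's per-record mean, taken across the
#' combinations at that arity. The shrinking of these standard deviations
#' with growing arity is the stability signature of multi-modal fusion;
#' the single hexa-modal combination has standard deviation exactly 0.
#'
#' @param report An `ablation_report` (or its `records` tibble).
#' @param sample_sd Use the sample (n-1) standard deviation instead of the
#'   population one; default `FALSE`.
#' @return Tibble with one row per (arity, feature_kind, classifier) and
#'   `<metric>_mean` / `<metric>_sd` columns plus `n_combinations`.
#' @export
aggregate_by_arity <- function(report, sample_sd = FALSE) {
  records <- if (inherits(report, "ablation_report")) report$records else report
  stopifnot(nrow(records) > 0)
  pop_sd <- function(x) {
    x <- x[!is.na(x)]
    if (sample_sd) {
      if (length(x) < 2) 0 else sd(x)
    } else {
      sqrt(mean((x - mean(x))^2))
    }
  }
  records |>
    dplyr::group_by(.data$arity, .data$feature_kind, .data$classifier) |>
    dplyr::summarise(
      n_combinations = dplyr::n(),
      dplyr::across(dplyr::all_of(c("acc", "pre", "sn", "f1")),
                    list(mean = ~ mean(.x, na.rm = TRUE), sd = ~ pop_sd(.x)),
                    .names = "{.col}_{.fn}"),
      .groups = "drop"
    )
}

#' @export
print.ablation_report <- function(x, ...) {
  cat("<ablation_report>", nrow(x$records), "records;",
      length(unique(x$records$combination)), "combinations x",
      length(unique(x$records$feature_kind)), "feature kinds x",
      length(unique(x$records$classifier)), "classifiers\n")
  n_err <- sum(!is.na(x$records$error))
  if (n_err > 0) cat("  ", n_err, "record(s) failed; see records$error\n")
  invisible(x)
}

#' @rdname run_ablation
#' @param x An `ablation_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ablation_report <- function(x, ...) {
  dplyr::select(x$records, -"folds")
}

#' @rdname run_ablation
#' @exportS3Method generics::glance
glance.ablation_report <- function(x, ...) {
  tibble(
    n_records = nrow(x$records),
    n_combinations = length(unique(x$records$combination)),
    n_failed = sum(!is.na(x$records$error)),
    n_folds = x$config$n_folds,
    seed = x$config$seed,
    fit_scope = x$config$fit_scope
  )
}
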