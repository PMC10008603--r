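#' Drop features with excessive missingness
#'
#' Removes feature columns whose missing fraction strictly exceeds the
#' threshold (a feature missing exactly the threshold fraction is kept).
#' The surviving feature order is preserved; the dropped feature ids are
#' attached as the `"dropped_features"` attribute.
#'
#' @param data Tibble with `patient_id` first, then feature columns.
#' @param threshold Maximum tolerated missing fraction, default 0.10.
#' @return The filtered tibble, with attribute `dropped_features`.
#' @export
drop_high_missing_features <- function(data, threshold = 0.10) {
  stopifnot(threshold >= 0, threshold <= 1)
  x <- as_feature_matrix(data)
  frac <- colMeans(is.na(x))
  drop <- frac > threshold
  if (all(drop)) {
    abort("all features exceed the missingness threshold; empty matrix",
          class = "survfuse_empty_matrix_error")
  }
  out <- dplyr::select(data, "patient_id", dplyr::all_of(colnames(x)[!drop]))
  attr(out, "dropped_features") <- colnames(x)[drop]
  out
}

#' Impute missing cells by weighted k-nearest neighbours
#'
#' Each missing cell is filled with the inverse-distance-weighted mean of
#' the values of the `k` nearest patients (Euclidean distance over mutually
#' observed features, normalised by the number of shared features) that have
#' the feature observed. Observed cells are never modified.
#'
#' @param data Tibble with `patient_id` first.
#' @param k Number of neighbours, default 10.
#' @param eps Guard added to distances before inversion, default 1e-8.
#' @return The tibble with all missing cells imputed.
#' @export
impute_weighted_knn <- function(data, k = 10, eps = 1e-8) {
  x <- as_feature_matrix(data)
  if (!anyNA(x)) return(data)
  n <- nrow(x)
  obs <- !is.na(x)
  all_missing <- rowSums(obs) == 0
  if (any(all_missing)) {
    abort(paste0("patient(s) with all features missing: ",
                 paste(rownames(x)[all_missing], collapse = ", ")),
          class = "survfuse_validation_error")
  }
  x0 <- x
  x0[!obs] <- 0
  m <- obs * 1
  shared <- m %*% t(m)                       # shared observed feature counts
  cross <- x0 %*% t(x0)
  sq <- (x0^2) %*% t(m)
  d2 <- (sq + t(sq) - 2 * cross) / pmax(shared, 1)
  d2[shared == 0] <- Inf
  d <- sqrt(pmax(d2, 0))
  diag(d) <- Inf
  filled <- x
  for (i in which(rowSums(!obs) > 0)) {
    for (j in which(!obs[i, ])) {
      cand <- which(obs[, j] & is.finite(d[i, ]))
      if (length(cand) == 0) {
        abort(paste0("no donor patients observed for feature ", colnames(x)[j]),
              class = "survfuse_validation_error")
      }
      ord <- cand[order(d[i, cand], rownames(x)[cand])]
      nn <- head(ord, k)
      w <- 1 / (d[i, nn] + eps)
      filled[i, j] <- sum(w * x[nn, j]) / sum(w)
    }
  }
  as_modality_tibble(filled)
}

#' Min-max normalise a numeric vector to \[0, 1\]
#'
#' @param x Non-constant numeric vector.
#' @return `(x - min) / (max - min)`.
#' @export
#' @examples
#' minmax_normalize(c(30, 50, 70))
minmax_normalize <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (!is.finite(r[1]) || r[1] == r[2]) {
    abort("cannot min-max normalise a constant column",
          class = "survfuse_validation_error")
  }
  (x - r[1]) / (r[2] - r[1])
}

#' Discretise expression into under/baseline/over-expressed calls
#'
#' Standardises each gene to z-scores over patients, then maps
#' `z < -z_threshold` to -1 (under-expressed), `z > z_threshold` to +1
#' (over-expressed) and the rest to 0 (baseline). Zero-variance genes map to
#' all-0 with a warning.
#'
#' @param data Tibble with `patient_id` first, continuous values.
#' @param z_threshold Positive z-score threshold, default 1.0.
#' @return The tibble with values in \{-1, 0, 1\}.
#' @export
discretize_expression <- function(data, z_threshold = 1.0) {
  stopifnot(z_threshold > 0)
  x <- as_feature_matrix(data)
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warn(paste0(sum(sds == 0), " zero-variance gene(s) mapped to baseline 0"))
  }
  z <- scale(x, center = TRUE, scale = FALSE)
  z <- sweep(z, 2, ifelse(sds == 0, 1, sds), "/")
  out <- (z > z_threshold) - (z < -z_threshold)
  storage.mode(out) <- "double"
  rownames(out) <- rownames(x)
  colnames(out) <- colnames(x)
  as_modality_tibble(out)
}

#' Drop zero-variance features
#'
#' Removes features whose values are identical for all patients; they carry
#' no class information and can destabilise downstream scaling.
#'
#' @param data Tibble with `patient_id` first.
#' @return The filtered tibble, with attribute `dropped_features`.
#' @export
drop_constant_features <- function(data) {
  x <- as_feature_matrix(data)
  keep <- apply(x, 2, function(col) length(unique(col[!is.na(col)])) > 1)
  if (!any(keep)) {
    abort("all features are constant; empty matrix",
          class = "survfuse_empty_matrix_error")
  }
  out <- dplyr::select(data, "patient_id", dplyr::all_of(colnames(x)[keep]))
  attr(out, "dropped_features") <- colnames(x)[!keep]
  out
}

#' Keep the top-k features by variance
#'
#' Ranks features by sample variance (descending, ties broken by feature id
#' for determinism) and keeps the top `min(k, n_features)`. The fraction of
#' total variance captured by the kept features is attached as the
#' `"captured_variance"` attribute, with a warning when it falls below
#' `warn_below` (the raw-feature pathway expects the kept subset to retain
#' at least 98% of the variance).
#'
#' @param data Tibble with `patient_id` first.
#' @param k Number of features to keep, default 500.
#' @param warn_below Warn if the captured variance fraction is below this,
#'   default 0.98.
#' @return The tibble restricted to the selected features (original ranking
#'   order by variance), with attribute `captured_variance`.
#' @export
select_top_variance <- function(data, k = 500, warn_below = 0.98) {
  stopifnot(k >= 1)
  x <- as_feature_matrix(data)
  v <- apply(x, 2, var)
  ord <- order(-v, colnames(x))
  keep <- head(ord, min(k, ncol(x)))
  frac <- if (sum(v) > 0) sum(v[keep]) / sum(v) else 1
  if (frac < warn_below) {
    warn(sprintf("top-%d features capture only %.1f%% of total variance",
                 k, 100 * frac))
  }
  out <- dplyr::select(data, "patient_id", dplyr::all_of(colnames(x)[keep]))
  attr(out, "captured_variance") <- frac
  out
}

#' Intersect a set of modalities on common patient ids
#'
#' Resolves the incomplete multi-view structure: computes the sorted
#' intersection of patient ids across the supplied modality tables and
#' row-subsets every table to that cohort, in the same order.
#'
#' @param matrices Named list of tibbles with `patient_id` first.
#' @return A list with `patient_ids` (sorted character vector) and
#'   `matrices` (the aligned tibbles).
#' @export
#' @examples
#' a <- tibble::tibble(patient_id = c("A", "B", "C"), f = 1:3)
#' b <- tibble::tibble(patient_id = c("B", "C", "D"), g = 4:6)
#' intersect_cohort(list(a = a, b = b))$patient_ids
intersect_cohort <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  ids <- Reduce(intersect, lapply(matrices, function(m) unique(m$patient_id)))
  ids <- sort(ids)
  if (length(ids) == 0) {
    abort("empty patient-id intersection across modalities",
          class = "survfuse_validation_error")
  }
  aligned <- lapply(matrices, function(m) {
    m[match(ids, m$patient_id), , drop = FALSE]
  })
  list(patient_ids = ids, matrices = aligned)
}

#' Run the full preprocessing pipeline on one modality
#'
#' Applies, in fixed order: high-missingness feature removal, weighted kNN
#' imputation, the domain-specific step (min-max normalisation of the
#' continuous age column for clinical data; \{-1,0,1\} discretisation for
#' mRNA; rounding of imputed copy-number calls back to the \{-2..2\} grid),
#' constant-feature removal and, for the high-dimensional modalities (cnv
#' and mrna by default), top-k variance selection.
#'
#' @param data Tibble with `patient_id` first.
#' @param tag Modality tag.
#' @param missing_threshold Missing-fraction threshold, default 0.10.
#' @param knn_k Imputation neighbourhood size, default 10.
#' @param z_threshold mRNA discretisation threshold, default 1.0.
#' @param top_k Variance-selection size, default 500.
#' @param top_k_tags Tags the variance selection applies to.
#' @return A list with `data` (the processed tibble) and `report` (a list of
#'   dropped/kept feature ids per rule and the captured variance fraction).
#' @export
preprocess_modality <- function(data, tag,
                                missing_threshold = 0.10,
                                knn_k = 10,
                                z_threshold = 1.0,
                                top_k = 500,
                                top_k_tags = c("cnv", "mrna")) {
  domain <- modality_domain(tag)
  report <- list(modality = tag, domain = domain)
  out <- drop_high_missing_features(data, missing_threshold)
  report$dropped_high_missing <- attr(out, "dropped_features")
  out <- impute_weighted_knn(out, k = knn_k)
  if (domain == "cnv5") {
    x <- as_feature_matrix(out)
    out <- as_modality_tibble(pmin(pmax(round(x), -2), 2))
  } else if (domain == "categorical") {
    x <- as_feature_matrix(out)
    cat_cols <- setdiff(colnames(x), "age")
    x[, cat_cols] <- round(x[, cat_cols])
    if ("age" %in% colnames(x)) x[, "age"] <- minmax_normalize(x[, "age"])
    out <- as_modality_tibble(x)
  } else if (domain == "continuous") {
    out <- discretize_expression(out, z_threshold)
  }
  out <- drop_constant_features(out)
  report$dropped_constant <- attr(out, "dropped_features")
  if (tag %in% top_k_tags) {
    out <- select_top_variance(out, k = top_k)
    report$captured_variance <- attr(out, "captured_variance")
  }
  report$kept_features <- setdiff(names(out), "patient_id")
  list(data = out, report = report)
}

#' Preprocess every modality of a cohort
#'
#' Runs [preprocess_modality()] on the five tabular modalities and
#' [embed_wsi()] on the whole-slide-image patch bags, producing one aligned
#' feature table per modality (still on each modality's own cohort; the
#' per-combination intersection happens later).
#'
#' @param cohort A `multimodal_cohort`.
#' @param wsi_fraction,wsi_cap,wsi_patch_dim,wsi_final_dim Parameters passed
#'   to [embed_wsi()]; defaults scale with the cohort's generator config.
#' @param ... Passed to [preprocess_modality()].
#' @return A list with `modalities` (named list of processed tibbles) and
#'   `report` (per-modality preprocessing reports).
#' @export
preprocess_cohort <- function(cohort,
                              wsi_fraction = 0.5,
                              wsi_cap = NULL,
                              wsi_patch_dim = 32,
                              wsi_final_dim = 64,
                              ...) {
  stopifnot(inherits(cohort, "multimodal_cohort"))
  wsi_cap <- wsi_cap %||% max(2L, ceiling(cohort$config$wsi_patches / 2))
  out <- list()
  reports <- list()
  for (tag in setdiff(names(cohort$modalities), "wsi")) {
    res <- preprocess_modality(cohort$modalities[[tag]], tag, ...)
    out[[tag]] <- res$data
    reports[[tag]] <- res$report
  }
  if ("wsi" %in% names(cohort$modalities)) {
    out$wsi <- embed_wsi(cohort$modalities$wsi,
                         fraction = wsi_fraction, cap = wsi_cap,
                         patch_dim = wsi_patch_dim, final_dim = wsi_final_dim)
    reports$wsi <- list(modality = "wsi", domain = "embedding",
                        kept_features = setdiff(names(out$wsi), "patient_id"))
  }
  list(modalities = out, report = reports)
}
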