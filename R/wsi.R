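#' Select the densest patches of each whole-slide-image bag
#'
#' Keeps, per patient, the `min(cap, ceiling(fraction * n_patches))` patches
#' with the highest density score (ties broken by patch index), emulating
#' the selection of the most tissue-dense regions of interest. When fewer
#' than `cap` patches survive, the kept patches are duplicated cyclically
#' until the bag has exactly `cap` rows, so every patient contributes a
#' fixed-width concatenated vector downstream.
#'
#' @param patches Long tibble with columns `patient_id`, `patch_rank`,
#'   `density`, then embedding columns.
#' @param fraction Fraction of patches to keep, in (0, 1]; default 0.20.
#' @param cap Fixed output bag size; default 40.
#' @return Long tibble with exactly `cap` rows per patient, ordered by
#'   density rank, with a `sel_rank` column (1..cap).
#' @export
select_dense_patches <- function(patches, fraction = 0.20, cap = 40) {
  stopifnot(fraction > 0, fraction <= 1, cap >= 1)
  if (nrow(patches) == 0) {
    abort("empty patch bag", class = "survfuse_validation_error")
  }
  patches |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(df, key) {
      n_keep <- min(cap, ceiling(fraction * nrow(df)))
      kept <- df[order(-df$density, df$patch_rank), , drop = FALSE][seq_len(n_keep), ]
      idx <- rep_len(seq_len(n_keep), cap)
      out <- kept[idx, , drop = FALSE]
      out$sel_rank <- seq_len(cap)
      out
    }) |>
    dplyr::ungroup()
}

#' Reduce patch embeddings with a pooled PCA
#'
#' Fits a single PCA on the pooled patch rows of all patients (cohort-level
#' fit) and projects every patch to `min(target_dim, rank)` dimensions.
#'
#' @param patches Long tibble from [select_dense_patches()].
#' @param target_dim Target embedding dimension, default 512.
#' @return Long tibble with the embedding columns replaced by `p1..pD'`;
#'   the fitted `pca_model` is attached as attribute `"pca_model"`.
#' @export
reduce_patch_embeddings <- function(patches, target_dim = 512) {
  emb_cols <- grep("^e\\d+$", names(patches), value = TRUE)
  stopifnot(length(emb_cols) >= 1)
  pooled <- dplyr::mutate(
    patches[, c("patient_id", emb_cols)],
    patient_id = sprintf("row%06d", dplyr::row_number())
  )
  if (nrow(pooled) < target_dim) {
    warn("pooled patch count below target dimension; components capped by rank")
  }
  model <- fit_pca(pooled, n_comp = target_dim)
  scores <- apply_pca(model, pooled)[, -1, drop = FALSE]
  names(scores) <- paste0("p", seq_len(ncol(scores)))
  out <- dplyr::bind_cols(
    patches[, setdiff(names(patches), emb_cols), drop = FALSE],
    scores
  )
  attr(out, "pca_model") <- model
  out
}

#' Concatenate a patient's reduced patches into one vector
#'
#' Stacks the `cap` reduced patch embeddings of each patient in density-rank
#' order into a single row of width `cap * D'`. Patch order is semantic:
#' position encodes density rank.
#'
#' @param patches Long tibble with `sel_rank` and `p*` columns.
#' @param cap Expected rows per patient.
#' @return Tibble with `patient_id` and `v1..v(cap*D')` columns, one row per
#'   patient, rows sorted by patient id.
#' @export
assemble_wsi_vectors <- function(patches, cap) {
  p_cols <- grep("^p\\d+$", names(patches), value = TRUE)
  counts <- dplyr::count(patches, .data$patient_id)
  if (any(counts$n != cap)) {
    abort(paste0("patients without exactly ", cap, " selected patches: ",
                 paste(counts$patient_id[counts$n != cap], collapse = ", ")),
          class = "survfuse_validation_error")
  }
  long <- patches |>
    dplyr::select("patient_id", "sel_rank", dplyr::all_of(p_cols)) |>
    tidyr::pivot_longer(dplyr::all_of(p_cols), names_to = "dim",
                        values_to = "value") |>
    dplyr::mutate(dim_idx = as.integer(sub("^p", "", .data$dim)),
                  col = (.data$sel_rank - 1L) * length(p_cols) + .data$dim_idx)
  wide <- long |>
    dplyr::arrange(.data$patient_id, .data$col) |>
    dplyr::select("patient_id", "col", "value") |>
    tidyr::pivot_wider(names_from = "col", values_from = "value",
                       names_prefix = "v")
  dplyr::arrange(wide, .data$patient_id)
}

#' Reduce the concatenated WSI vectors to the final modality matrix
#'
#' A second PCA over the per-patient concatenated vectors, keeping
#' `min(target_dim, components needed for the variance target, rank)`
#' components. The result is the whole-slide-image modality matrix entering
#' fusion.
#'
#' @param vectors Tibble from [assemble_wsi_vectors()].
#' @param target_dim Maximum dimension, default 800.
#' @param variance Explained-variance target, default 0.95.
#' @return Tibble with `patient_id` and `wsi_1..wsi_m` columns; fitted
#'   `pca_model` attached as attribute `"pca_model"`.
#' @export
reduce_wsi_features <- function(vectors, target_dim = 800, variance = 0.95) {
  stopifnot(nrow(vectors) >= 2)
  model <- fit_pca(vectors, variance = variance)
  if (model$n_comp > target_dim) {
    model$components <- model$components[seq_len(target_dim), , drop = FALSE]
    model$explained_fraction <- model$explained_fraction[seq_len(target_dim)]
    model$n_comp <- as.integer(target_dim)
  }
  out <- apply_pca(model, vectors)
  names(out)[-1] <- paste0("wsi_", seq_len(ncol(out) - 1L))
  attr(out, "pca_model") <- model
  out
}

#' Whole-slide-image pathway: patch bags to one feature table
#'
#' Chains dense-patch selection, pooled patch-level PCA, per-patient
#' concatenation and the final cohort-level PCA. At real scale this maps
#' bags of 2048-dimensional patch embeddings through 512 dimensions per
#' patch, 40-patch concatenation (20,480 values) and a final 800-dimensional
#' PCA; the defaults here are the generator's scaled-down analogues.
#'
#' @param patches Long patch tibble (`patient_id`, `patch_rank`, `density`,
#'   `e*` columns).
#' @param fraction,cap Dense-patch selection parameters.
#' @param patch_dim Patch-level PCA dimension.
#' @param final_dim Final modality dimension cap.
#' @param variance Final PCA explained-variance target.
#' @return The WSI modality tibble (`patient_id` + `wsi_*` columns).
#' @export
embed_wsi <- function(patches, fraction = 0.20, cap = 40,
                      patch_dim = 512, final_dim = 800, variance = 0.95) {
  patches |>
    select_dense_patches(fraction = fraction, cap = cap) |>
    reduce_patch_embeddings(target_dim = patch_dim) |>
    assemble_wsi_vectors(cap = cap) |>
    reduce_wsi_features(target_dim = final_dim, variance = variance)
}
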