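#' Fit a PCA model at an explained-variance target
#'
#' Centres the features and computes principal components, keeping either
#' the smallest number of components whose cumulative explained-variance
#' fraction reaches `variance` (capped by the matrix rank), or exactly
#' `n_comp` components when given. Component signs follow a fixed
#' convention — the largest-magnitude loading of each component is positive
#' — so fits are reproducible across platforms.
#'
#' @param data Tibble with `patient_id` first, no missing values.
#' @param variance Explained-variance target in (0, 1], default 0.95.
#' @param n_comp Optional fixed component count (overrides `variance`).
#' @return A `pca_model`: centering vector, `n_comp x n_features` component
#'   matrix, per-component explained fractions and the full fraction vector.
#' @export
#' @examples
#' d <- tibble::tibble(patient_id = letters[1:5],
#'                     a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 8, 10) + 0.1 * rnorm(5))
#' fit_pca(d, variance = 0.95)$n_comp
fit_pca <- function(data, variance = 0.95, n_comp = NULL) {
  stopifnot(variance > 0, variance <= 1)
  x <- as_feature_matrix(data)
  if (nrow(x) < 2) abort("PCA needs at least 2 patients",
                         class = "survfuse_validation_error")
  if (anyNA(x)) abort("PCA input must have no missing values",
                      class = "survfuse_validation_error")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  total <- sum(ev)
  if (total <= 0) abort("zero-variance input; PCA undefined",
                        class = "survfuse_validation_error")
  tol <- max(ev) * 1e-12
  rank <- sum(ev > tol)
  frac <- ev / total
  m <- if (!is.null(n_comp)) {
    min(as.integer(n_comp), rank)
  } else {
    min(which(cumsum(frac) >= variance - 1e-12)[1], rank)
  }
  comp <- t(pc$rotation[, seq_len(m), drop = FALSE])   # n_comp x n_features
  # sign convention: largest |loading| positive
  for (i in seq_len(m)) {
    j <- which.max(abs(comp[i, ]))
    if (comp[i, j] < 0) comp[i, ] <- -comp[i, ]
  }
  rownames(comp) <- paste0("pc", seq_len(m))
  structure(
    list(
      mean = pc$center,
      components = comp,
      explained_fraction = frac[seq_len(m)],
      all_fractions = frac,
      n_comp = m,
      rank = rank,
      total_variance = total,
      feature_ids = colnames(x)
    ),
    class = "pca_model"
  )
}

#' Project data onto a fitted PCA model
#'
#' Applies `(x - mean) %*% t(components)`. Feature ids must match the fit
#' exactly (same names, same order); a mismatch is an error naming the
#' offending columns.
#'
#' @param model A `pca_model` from [fit_pca()].
#' @param data Tibble with `patient_id` first and the fitted features.
#' @return Tibble with `patient_id` and `pc1..pcm` score columns.
#' @export
apply_pca <- function(model, data) {
  stopifnot(inherits(model, "pca_model"))
  x <- as_feature_matrix(data)
  if (!identical(colnames(x), model$feature_ids)) {
    bad <- c(setdiff(colnames(x), model$feature_ids),
             setdiff(model$feature_ids, colnames(x)))
    abort(paste0("feature ids do not match the PCA fit: ",
                 paste(unique(bad), collapse = ", ")),
          class = "survfuse_validation_error")
  }
  scores <- sweep(x, 2, model$mean) %*% t(model$components)
  rownames(scores) <- rownames(x)
  as_modality_tibble(scores)
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model>", x$n_comp, "components over", length(x$feature_ids),
      "features; explained", sprintf("%.3f", sum(x$explained_fraction)), "\n")
  invisible(x)
}

#' @rdname fit_pca
#' @param x A `pca_model`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.pca_model <- function(x, ...) {
  tibble(
    component = rownames(x$components),
    std_dev = sqrt(x$explained_fraction * x$total_variance),
    explained_fraction = x$explained_fraction,
    cumulative_fraction = cumsum(x$explained_fraction)
  )
}

#' @rdname fit_pca
#' @exportS3Method generics::glance
glance.pca_model <- function(x, ...) {
  tibble(
    n_comp = x$n_comp,
    rank = x$rank,
    n_features = length(x$feature_ids),
    explained_fraction = sum(x$explained_fraction),
    total_variance = x$total_variance
  )
}
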