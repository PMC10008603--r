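#' Configuration for the synthetic multi-modal cohort generator
#'
#' Defines the study conditions of a simulated cohort: cohort size, class
#' prevalence at the five-year cutoff, the dimension and strength of the
#' shared latent patient signal, per-modality feature counts (scaled down
#' relative to real TCGA-style matrices), observation noise, feature-level
#' missingness, and patient-level modality absence (the incomplete
#' multi-view structure).
#'
#' The class signal is a single latent matrix `u` shared by every modality:
#' patients of the short-term class (label 1) have latent mean `+delta/2` in
#' every coordinate and long-term patients `-delta/2`, with unit variance.
#' Each modality observes a random linear map of `u` plus independent
#' Gaussian noise, squashed into its native value domain.
#'
#' @param n_patients Number of patients (>= 1).
#' @param prevalence Fraction of short-term survivors (label 1), strictly in
#'   (0, 1). Default 0.77, mirroring the near-constant precision of a
#'   predict-all-positive classifier on the real cohort.
#' @param latent_dim_true Dimension of the shared latent signal `u`.
#' @param effect_size Class separation `delta` between latent class means,
#'   per coordinate (>= 0).
#' @param n_features Named integer vector of feature counts for the tabular
#'   modalities (`cln`, `cnv`, `dna`, `mir`, `mrna`).
#' @param wsi_patches Patches per whole-slide-image bag.
#' @param wsi_dim Embedding dimension per patch.
#' @param noise_sd Observation noise standard deviation (> 0), shared across
#'   modalities.
#' @param feature_missing_rate Per-cell missingness rate in `[0, 1)` for the
#'   tabular modalities.
#' @param modality_absence_rate Named vector of per-modality patient absence
#'   rates in `[0, 1)`; absent patients lose the whole modality.
#' @param censor_short_rate Fraction of patients whose follow-up is censored
#'   before the 60-month cutoff (these cannot be labelled). Default 0.
#' @param seed Integer seed; identical configurations generate bit-identical
#'   cohorts.
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 120, seed = 7)
#' cfg$prevalence
sim_config <- function(n_patients = 600,
                       prevalence = 0.77,
                       latent_dim_true = 8,
                       effect_size = 3,
                       n_features = c(cln = 21, cnv = 600, dna = 600,
                                      mir = 200, mrna = 600),
                       wsi_patches = 8,
                       wsi_dim = 64,
                       noise_sd = 1,
                       feature_missing_rate = 0.02,
                       modality_absence_rate = c(cln = 0, cnv = 0.05,
                                                 dna = 0.05, mir = 0.05,
                                                 mrna = 0.05, wsi = 0.05),
                       censor_short_rate = 0,
                       seed = 1) {
  check_count <- function(x, field, min = 1) {
    if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
      abort(paste0("invalid `", field, "`: must be an integer >= ", min),
            class = "survfuse_config_error")
    }
  }
  check_rate <- function(x, field) {
    if (any(!is.finite(x)) || any(x < 0) || any(x >= 1)) {
      abort(paste0("invalid `", field, "`: rates must lie in [0, 1)"),
            class = "survfuse_config_error")
    }
  }
  check_count(n_patients, "n_patients")
  check_count(latent_dim_true, "latent_dim_true")
  check_count(wsi_patches, "wsi_patches")
  check_count(wsi_dim, "wsi_dim")
  check_count(seed, "seed", min = 0)
  if (length(prevalence) != 1L || !is.finite(prevalence) ||
      prevalence <= 0 || prevalence >= 1) {
    abort("invalid `prevalence`: must lie strictly in (0, 1)",
          class = "survfuse_config_error")
  }
  if (length(effect_size) != 1L || !is.finite(effect_size) || effect_size < 0) {
    abort("invalid `effect_size`: must be a non-negative real",
          class = "survfuse_config_error")
  }
  if (length(noise_sd) != 1L || !is.finite(noise_sd) || noise_sd <= 0) {
    abort("invalid `noise_sd`: must be a positive real",
          class = "survfuse_config_error")
  }
  tab_tags <- setdiff(MODALITY_TAGS, "wsi")
  if (!all(tab_tags %in% names(n_features))) {
    abort("invalid `n_features`: must name counts for cln, cnv, dna, mir, mrna",
          class = "survfuse_config_error")
  }
  for (tg in tab_tags) check_count(n_features[[tg]], paste0("n_features[", tg, "]"))
  check_rate(feature_missing_rate, "feature_missing_rate")
  if (!all(MODALITY_TAGS %in% names(modality_absence_rate))) {
    abort("invalid `modality_absence_rate`: must name all six modalities",
          class = "survfuse_config_error")
  }
  check_rate(modality_absence_rate, "modality_absence_rate")
  check_rate(censor_short_rate, "censor_short_rate")
  structure(
    list(
      n_patients = as.integer(n_patients),
      prevalence = prevalence,
      latent_dim_true = as.integer(latent_dim_true),
      effect_size = effect_size,
      n_features = vapply(n_features[tab_tags], as.integer, integer(1)),
      wsi_patches = as.integer(wsi_patches),
      wsi_dim = as.integer(wsi_dim),
      noise_sd = noise_sd,
      feature_missing_rate = feature_missing_rate,
      modality_absence_rate = modality_absence_rate[MODALITY_TAGS],
      censor_short_rate = censor_short_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_patients, "patients, prevalence", x$prevalence,
      "\n  latent dim", x$latent_dim_true, ", effect size", x$effect_size,
      ", noise sd", x$noise_sd, "\n  features:",
      paste(names(x$n_features), x$n_features, sep = "=", collapse = " "),
      paste0("wsi=", x$wsi_patches, "x", x$wsi_dim), "\n  seed", x$seed, "\n")
  invisible(x)
}
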