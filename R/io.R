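#' Read a modality table from TSV/CSV
#'
#' Expects a header row with `patient_id` first, then feature columns.
#' Empty strings and `NA` are missing markers. When a domain descriptor is
#' given, values are validated against it: `cnv5` must lie in \{-2..2\},
#' `beta` in \[0, 1\], `nonneg` must be non-negative, `trinary` in
#' \{-1, 0, 1\}.
#'
#' @param path File path; `.csv` is read as comma-separated, anything else
#'   as tab-separated.
#' @param domain Optional domain descriptor to validate against.
#' @return A tibble with `patient_id` (character) first.
#' @export
read_modality_table <- function(path, domain = NULL) {
  reader <- if (grepl("\\.csv$", path)) readr::read_csv else readr::read_tsv
  data <- reader(path, na = c("", "NA"), show_col_types = FALSE,
                 progress = FALSE)
  if (nrow(data) == 0) {
    abort(paste0("empty modality file: ", path),
          class = "survfuse_io_error")
  }
  if (names(data)[1] != "patient_id") {
    abort(paste0("first column must be `patient_id` in ", path),
          class = "survfuse_io_error")
  }
  data$patient_id <- as.character(data$patient_id)
  dup <- data$patient_id[duplicated(data$patient_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicated patient id(s): ", paste(unique(dup), collapse = ", ")),
          class = "survfuse_io_error")
  }
  feat <- data[, -1, drop = FALSE]
  non_num <- names(feat)[!vapply(feat, is.numeric, logical(1))]
  if (length(non_num) > 0) {
    abort(paste0("non-numeric feature column(s): ",
                 paste(non_num, collapse = ", ")),
          class = "survfuse_io_error")
  }
  if (!is.null(domain)) {
    vals <- unlist(feat, use.names = FALSE)
    vals <- vals[!is.na(vals)]
    ok <- switch(domain,
      cnv5 = all(vals %in% c(-2, -1, 0, 1, 2)),
      beta = all(vals >= 0 & vals <= 1),
      nonneg = all(vals >= 0),
      trinary = all(vals %in% c(-1, 0, 1)),
      TRUE
    )
    if (!ok) {
      abort(paste0("values violate the `", domain, "` domain in ", path),
            class = "survfuse_domain_error")
    }
  }
  data
}

#' Write a modality table as TSV
#'
#' @param data Tibble with `patient_id` first.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_modality_table <- function(data, path) {
  readr::write_tsv(data, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Write a simulated cohort to a directory of TSV files
#'
#' One `<tag>.tsv` per modality (the whole-slide-image bags in long format:
#' `patient_id`, `patch_rank`, `density`, embedding columns) plus
#' `survival.tsv` (`patient_id`, `time_months`, `event`).
#'
#' @param cohort A `multimodal_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "multimodal_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tag in names(cohort$modalities)) {
    write_modality_table(cohort$modalities[[tag]],
                         file.path(dir, paste0(tag, ".tsv")))
  }
  readr::write_tsv(cohort$survival, file.path(dir, "survival.tsv"),
                   progress = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `<tag>.tsv` files and `survival.tsv`.
#' @return A `multimodal_cohort` (without planted truth).
#' @export
read_cohort <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$")
  tags <- intersect(MODALITY_TAGS, sub("\\.tsv$", "", files))
  modalities <- lapply(tags, function(tag) {
    path <- file.path(dir, paste0(tag, ".tsv"))
    if (tag == "wsi") {
      # long patch format: several rows per patient
      out <- readr::read_tsv(path, na = c("", "NA"), show_col_types = FALSE,
                             progress = FALSE)
      out$patient_id <- as.character(out$patient_id)
      out
    } else {
      read_modality_table(path)
    }
  })
  names(modalities) <- tags
  survival <- readr::read_tsv(file.path(dir, "survival.tsv"),
                              show_col_types = FALSE, progress = FALSE)
  survival$patient_id <- as.character(survival$patient_id)
  structure(
    list(modalities = modalities, survival = survival, truth = NULL,
         config = NULL),
    class = "multimodal_cohort"
  )
}

#' Write an ablation report to disk
#'
#' Produces a deterministic file set: `records.csv` (flat records),
#' `aggregates.json` (per-arity aggregates), `metrics_table.csv` (one metric
#' row per arity block, classifier x feature-kind column groups) and
#' `run_manifest.json` (run configuration and seeds).
#'
#' @param report An `ablation_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ablation_report <- function(report, dir) {
  stopifnot(inherits(report, "ablation_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tidy(report), file.path(dir, "records.csv"),
                   progress = FALSE)
  agg <- aggregate_by_arity(report)
  jsonlite::write_json(agg, file.path(dir, "aggregates.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)
  wide <- report$records |>
    dplyr::select("arity", "feature_kind", "classifier",
                  dplyr::all_of(c("acc", "f1", "sn", "pre"))) |>
    dplyr::group_by(.data$arity, .data$feature_kind, .data$classifier) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop") |>
    tidyr::pivot_longer(dplyr::all_of(c("acc", "f1", "sn", "pre")),
                        names_to = "metric", values_to = "value") |>
    tidyr::pivot_wider(names_from = c("classifier", "feature_kind"),
                       values_from = "value") |>
    dplyr::arrange(.data$arity, match(.data$metric, c("acc", "f1", "sn", "pre")))
  readr::write_csv(wide, file.path(dir, "metrics_table.csv"), progress = FALSE)
  jsonlite::write_json(
    list(config = report$config,
         generated = "survfuse ablation report",
         r_version = as.character(getRversion())),
    file.path(dir, "run_manifest.json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}

#' Validated pipeline configuration
#'
#' Bundles the generator, preprocessing, reducer, protocol and ablation
#' settings of one end-to-end run into a single validated object.
#'
#' @param sim A [sim_config()].
#' @param feature_kinds Feature pathways to run.
#' @param classifiers Optional named list of [classifier_spec()]s.
#' @param n_folds Cross-validation folds.
#' @param seed Protocol seed.
#' @param min_arity,max_arity Ablation arity range.
#' @param pca_variance PCA explained-variance target.
#' @param vae_configs Optional named list of per-modality [vae_config()]s.
#' @param fit_scope `"full"` (reducers fitted before cross-validation) or
#'   `"per_fold"` (leakage-safe refit per training fold).
#' @param preprocess_args Arguments for [preprocess_cohort()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            feature_kinds = c("raw", "pca", "vae"),
                            classifiers = NULL,
                            n_folds = 10,
                            seed = 0,
                            min_arity = 1,
                            max_arity = 6,
                            pca_variance = 0.95,
                            vae_configs = NULL,
                            fit_scope = "full",
                            preprocess_args = list()) {
  stopifnot(inherits(sim, "sim_config"))
  if (!all(feature_kinds %in% c("raw", "pca", "vae"))) {
    abort("feature_kinds must be a subset of raw/pca/vae",
          class = "survfuse_config_error")
  }
  if (!fit_scope %in% c("full", "per_fold")) {
    abort("fit_scope must be 'full' or 'per_fold'",
          class = "survfuse_config_error")
  }
  structure(
    list(sim = sim, feature_kinds = feature_kinds, classifiers = classifiers,
         n_folds = n_folds, seed = as.integer(seed), min_arity = min_arity,
         max_arity = max_arity, pca_variance = pca_variance,
         vae_configs = vae_configs, fit_scope = fit_scope,
         preprocess_args = preprocess_args),
    class = "pipeline_config"
  )
}

#' Run the full pipeline end to end
#'
#' Simulate (or accept) a cohort, preprocess every modality, embed the
#' whole-slide-image bags, build the feature pathways, run the
#' modality-combination ablation, and optionally write the report files.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional pre-built `multimodal_cohort`; by default one is
#'   simulated from `config$sim`.
#' @param out_dir Optional output directory for [write_ablation_report()].
#' @return The `ablation_report`, invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(config, cohort = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- cohort %||% simulate_cohort(config$sim)
  report <- run_ablation(
    cohort,
    feature_kinds = config$feature_kinds,
    classifiers = config$classifiers,
    n_folds = config$n_folds,
    seed = config$seed,
    min_arity = config$min_arity,
    max_arity = min(config$max_arity, length(cohort$modalities)),
    pca_variance = config$pca_variance,
    vae_configs = config$vae_configs,
    fit_scope = config$fit_scope,
    preprocess_args = config$preprocess_args
  )
  if (!is.null(out_dir)) {
    write_ablation_report(report, out_dir)
    return(invisible(report))
  }
  report
}
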