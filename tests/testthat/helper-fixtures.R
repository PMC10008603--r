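# Shared fixtures, built once per test run and cached. All fixtures are
# generated in code from fixed seeds; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Small cohort for unit tests: full modality structure at toy dimensions.
tiny_sim_config <- function(seed = 42, ...) {
  sim_config(
    n_patients = 120,
    n_features = c(cln = 21, cnv = 60, dna = 60, mir = 40, mrna = 60),
    wsi_patches = 6, wsi_dim = 16,
    seed = seed, ...
  )
}

tiny_cohort <- function() {
  fixture("tiny_cohort", function() simulate_cohort(tiny_sim_config()))
}

tiny_prep <- function() {
  fixture("tiny_prep", function() {
    suppressWarnings(
      preprocess_cohort(tiny_cohort(), wsi_patch_dim = 8, wsi_final_dim = 16)
    )
  })
}

tiny_labels <- function() {
  fixture("tiny_labels", function() generate_labels_from_times(tiny_cohort()$survival))
}

# Study conditions: the default generator config (n = 600, six modalities,
# effect size 3, noise sd 1) with scaled-down VAE fits (hidden width 96,
# 60 epochs) — the problem sizes the methods vignette documents.
study_seed <- 101L

study_vae_configs <- function(seed = study_seed) {
  cfgs <- lapply(MODALITY_TAGS_TEST, function(tag) {
    vae_config(
      latent_dim = if (tag == "cln") 4L else 32L,
      hidden_widths = 96L, epochs = 60L, patience = 10L,
      seed = seed + match(tag, MODALITY_TAGS_TEST)
    )
  })
  names(cfgs) <- MODALITY_TAGS_TEST
  cfgs
}

MODALITY_TAGS_TEST <- c("cln", "cnv", "dna", "mir", "mrna", "wsi")

study_cohort <- function() {
  fixture("study_cohort", function() simulate_cohort(sim_config(seed = study_seed)))
}

# VAE-pathway random-forest ablation over all 63 combinations of the study
# cohort; the basis for the recovery and stability checks.
study_vae_rf_ablation <- function() {
  fixture("study_vae_rf_ablation", function() {
    suppressWarnings(run_ablation(
      study_cohort(),
      feature_kinds = "vae",
      classifiers = list(random_forest = classifier_spec("random_forest",
                                                         seed = study_seed)),
      n_folds = 10,
      seed = study_seed,
      vae_configs = study_vae_configs(),
      preprocess_args = list(wsi_patch_dim = 32, wsi_final_dim = 64)
    ))
  })
}

# Tiny hand-buildable modality tables for preprocessing unit tests.
toy_table <- function(values, ids = NULL) {
  values <- as.matrix(values)
  ids <- ids %||% sprintf("P%02d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("f", seq_len(ncol(values)))
  dplyr::bind_cols(tibble::tibble(patient_id = ids),
                   tibble::as_tibble(values))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
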