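#' Simulate the shared latent patient signal and class labels
#'
#' Draws binary survival-class labels with the configured prevalence, then a
#' latent matrix `u` whose rows are Gaussian with unit variance and class-
#' dependent mean: `+effect_size/2` in every coordinate for short-term
#' patients (label 1), `-effect_size/2` for long-term patients (label 0).
#' All downstream modalities are rendered from this one signal, so the
#' modalities carry complementary noisy views of the same prognosis.
#'
#' @param config A [sim_config()].
#' @return A list with `patient_id` (character), `labels` (integer 0/1) and
#'   `u` (`n_patients x latent_dim_true` matrix, rownames = patient ids).
#' @export
#' @examples
#' lat <- simulate_latents(sim_config(n_patients = 50, seed = 1))
#' table(lat$labels)
simulate_latents <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  d <- config$latent_dim_true
  withr::with_seed(child_seed(config$seed, 1L), {
    labels <- rbinom(n, 1L, config$prevalence)
    shift <- ifelse(labels == 1L, config$effect_size / 2, -config$effect_size / 2)
    u <- matrix(rnorm(n * d), n, d) + shift
  })
  ids <- sprintf("P%05d", seq_len(n))
  rownames(u) <- ids
  list(patient_id = ids, labels = as.integer(labels), u = u)
}

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Render one modality from the latent signal
#'
#' Applies a seeded random linear map to the latent matrix, adds Gaussian
#' observation noise, and squashes the result into the modality's native
#' value domain: thresholded copy-number calls in \{-2,...,2\} (`cnv`),
#' logistic-squashed methylation beta values in (0,1) (`dna`), softplus
#' non-negative expression (`mir`), continuous expression (`mrna`; the
#' \{-1,0,1\} discretisation happens in preprocessing), small categorical
#' integers plus one continuous age column (`cln`), or a per-patient bag of
#' noisy patch embeddings with a positive density score per patch (`wsi`).
#'
#' @param u Latent matrix from [simulate_latents()].
#' @param labels Integer class labels (unused by most domains; kept so
#'   label-dependent rendering variants stay possible).
#' @param tag Modality tag, one of `cln`, `cnv`, `dna`, `mir`, `mrna`, `wsi`.
#' @param config The [sim_config()] that produced `u`.
#' @return For tabular modalities, a tibble with `patient_id` then feature
#'   columns. For `wsi`, a long tibble with columns `patient_id`,
#'   `patch_rank`, `density`, `e1..e<wsi_dim>`.
#' @export
render_modality <- function(u, labels, tag, config) {
  stopifnot(inherits(config, "sim_config"))
  domain <- modality_domain(tag)  # errors on unknown tag
  n <- nrow(u)
  d <- ncol(u)
  ids <- rownames(u)
  tag_idx <- match(tag, MODALITY_TAGS)
  seed <- child_seed(config$seed, 10L + tag_idx)

  if (tag == "wsi") {
    p <- config$wsi_dim
    k <- config$wsi_patches
    return(withr::with_seed(seed, {
      W <- matrix(rnorm(p * d, sd = 1 / sqrt(d)), p, d)
      centre <- u %*% t(W)                       # n x p patient-level embedding
      rows <- lapply(seq_len(n), function(i) {
        emb <- matrix(rep(centre[i, ], each = k), k, p) +
          matrix(rnorm(k * p, sd = config$noise_sd), k, p)
        colnames(emb) <- paste0("e", seq_len(p))
        dplyr::bind_cols(
          tibble(
            patient_id = ids[i],
            patch_rank = seq_len(k),
            density = rgamma(k, shape = 2, rate = 2) + 0.05
          ),
          as_tibble(emb)
        )
      })
      dplyr::bind_rows(rows)
    }))
  }

  p <- config$n_features[[tag]]
  withr::with_seed(seed, {
    W <- matrix(rnorm(p * d, sd = 1 / sqrt(d)), p, d)
    raw <- u %*% t(W) + matrix(rnorm(n * p, sd = config$noise_sd), n, p)
  })
  vals <- switch(domain,
    cnv5 = {
      m <- matrix(findInterval(raw, c(-1.5, -0.5, 0.5, 1.5)) - 2L, n, p)
      storage.mode(m) <- "double"
      m
    },
    beta = plogis(raw),
    nonneg = softplus(raw),
    continuous = raw,
    categorical = {
      m <- matrix(findInterval(raw, c(-1, 0, 1)), n, p)
      storage.mode(m) <- "double"
      # first column is continuous age in years, min-max normalised later
      m[, 1] <- pmin(pmax(55 + 8 * raw[, 1], 25), 95)
      m
    },
    abort(paste0("unsupported domain for rendering: ", domain))
  )
  colnames(vals) <- if (tag == "cln") {
    c("age", sprintf("cf%02d", seq_len(p - 1) + 1L))
  } else {
    sprintf("%s_f%04d", tag, seq_len(p))
  }
  rownames(vals) <- ids
  as_modality_tibble(vals)
}

# Survival times consistent with the planted labels: short-term patients die
# before 60 months (event = 1), long-term patients survive past 60 months
# (exponential tail, censoring after the cutoff allowed). Optionally a
# fraction of patients is censored before the cutoff and cannot be labelled.
simulate_survival <- function(labels, ids, config) {
  n <- length(labels)
  withr::with_seed(child_seed(config$seed, 3L), {
    time <- numeric(n)
    event <- integer(n)
    short <- labels == 1L
    time[short] <- runif(sum(short), 1, 59.9)
    event[short] <- 1L
    time[!short] <- 60 + rexp(sum(!short), rate = 1 / 40)
    event[!short] <- rbinom(sum(!short), 1L, 0.5)
    if (config$censor_short_rate > 0) {
      cens <- runif(n) < config$censor_short_rate
      time[cens] <- runif(sum(cens), 1, 59.9)
      event[cens] <- 0L
    }
  })
  tibble(patient_id = ids, time_months = time, event = event)
}

#' Derive binary survival labels at a follow-up cutoff
#'
#' Labels patients as short-term survivors (1) when the event occurred
#' before the cutoff and long-term survivors (0) when follow-up reached the
#' cutoff. Patients censored before the cutoff carry no information about
#' which side of the cutoff they fall on; by default they are flagged as
#' excluded (`label` is `NA`), or optionally kept as long-term.
#'
#' @param survival Tibble with columns `patient_id`, `time_months`, `event`.
#' @param cutoff_months Cutoff in months; default 60 (five years).
#' @param censored_as_long_term If `TRUE`, patients censored before the
#'   cutoff are labelled 0 instead of excluded.
#' @return The survival tibble with added integer `label` (1 short-term,
#'   0 long-term, `NA` if excluded) and logical `excluded` columns.
#' @export
#' @examples
#' surv <- tibble::tibble(patient_id = c("a", "b", "c"),
#'                        time_months = c(30, 80, 30), event = c(1, 0, 0))
#' generate_labels_from_times(surv)
generate_labels_from_times <- function(survival, cutoff_months = 60,
                                       censored_as_long_term = FALSE) {
  stopifnot(all(c("patient_id", "time_months", "event") %in% names(survival)))
  if (any(survival$time_months < 0)) {
    abort("negative survival times are invalid", class = "survfuse_validation_error")
  }
  lab <- dplyr::case_when(
    survival$event == 1 & survival$time_months < cutoff_months ~ 1L,
    survival$time_months >= cutoff_months ~ 0L,
    TRUE ~ NA_integer_
  )
  excluded <- is.na(lab)
  if (censored_as_long_term) {
    lab[excluded] <- 0L
    excluded <- rep(FALSE, length(lab))
  }
  dplyr::mutate(as_tibble(survival), label = lab, excluded = excluded)
}

#' Inject feature-level and patient-level missingness
#'
#' Sets feature cells to `NA` independently at the configured rate in the
#' tabular modalities (never in the survival table, the patient ids, or the
#' patch embeddings), and removes whole patients from individual modalities
#' at the per-modality absence rates, producing the incomplete multi-view
#' structure the intersection step later resolves. The planted truth is
#' retained.
#'
#' @param cohort A `multimodal_cohort` from [simulate_cohort()].
#' @param config The cohort's [sim_config()].
#' @return The cohort with missingness applied.
#' @export
inject_missingness <- function(cohort, config) {
  stopifnot(inherits(cohort, "multimodal_cohort"), inherits(config, "sim_config"))
  withr::with_seed(child_seed(config$seed, 20L), {
    for (tag in names(cohort$modalities)) {
      m <- cohort$modalities[[tag]]
      if (tag != "wsi" && config$feature_missing_rate > 0) {
        x <- as_feature_matrix(m)
        mask <- matrix(runif(length(x)) < config$feature_missing_rate,
                       nrow(x), ncol(x))
        x[mask] <- NA_real_
        m <- as_modality_tibble(x)
      }
      rate <- config$modality_absence_rate[[tag]]
      if (rate > 0) {
        ids <- unique(m$patient_id)
        drop <- ids[runif(length(ids)) < rate]
        m <- dplyr::filter(m, !.data$patient_id %in% drop)
      }
      cohort$modalities[[tag]] <- m
    }
  })
  cohort
}

#' Simulate a complete multi-modal cohort
#'
#' Runs the full generator: latent signal and labels, all six modalities,
#' survival times consistent with the labels, then feature- and
#' patient-level missingness. Identical configurations (including the seed)
#' produce bit-identical cohorts.
#'
#' @param config A [sim_config()].
#' @return A `multimodal_cohort`: a list with `modalities` (named list of
#'   tibbles, `wsi` in long patch format), `survival` (tibble `patient_id`,
#'   `time_months`, `event`), `truth` (list with `u` and `labels`, retained
#'   for recovery tests) and `config`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 40, seed = 2))
#' names(cohort$modalities)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lat <- simulate_latents(config)
  modalities <- lapply(MODALITY_TAGS, function(tag) {
    render_modality(lat$u, lat$labels, tag, config)
  })
  names(modalities) <- MODALITY_TAGS
  survival <- simulate_survival(lat$labels, lat$patient_id, config)
  cohort <- structure(
    list(
      modalities = modalities,
      survival = survival,
      truth = list(u = lat$u, labels = lat$labels),
      config = config
    ),
    class = "multimodal_cohort"
  )
  inject_missingness(cohort, config)
}

#' @export
print.multimodal_cohort <- function(x, ...) {
  cat("<multimodal_cohort>", nrow(x$survival), "patients\n")
  for (tag in names(x$modalities)) {
    m <- x$modalities[[tag]]
    n_pat <- length(unique(m$patient_id))
    cat(sprintf("  %-4s %4d patients x %d columns\n", tag, n_pat, ncol(m) - 1L))
  }
  invisible(x)
}
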