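#' Configuration for the log-cosh variational autoencoder
#'
#' The VAE encodes each modality as a diagonal-Gaussian posterior over a
#' low-dimensional latent space (4 dimensions for the clinical modality,
#' 32 for all others) and is trained to minimise the sum of a log-cosh
#' reconstruction loss and the Kullback-Leibler divergence from the
#' standard-normal prior.
#'
#' @param latent_dim Latent dimension; 4 for clinical, 32 otherwise.
#' @param hidden_widths Integer vector of hidden-layer widths for the
#'   (symmetric) encoder/decoder stacks; `NULL` defaults to
#'   `min(512, n_features)` at fit time.
#' @param a Positive sharpness of the log-cosh loss; the loss behaves like
#'   `a * r^2 / 2` for small residuals and `|r| - log(2)/a` for large ones.
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param patience Early-stopping patience (epochs without improvement).
#' @param seed Seed for initialisation, shuffling and the reparameterisation
#'   noise; identical configs and data give identical fits.
#' @return A validated `vae_config` list.
#' @export
vae_config <- function(latent_dim = 32, hidden_widths = NULL, a = 10,
                       epochs = 200, batch_size = 64, learning_rate = 1e-3,
                       patience = 20, seed = 0) {
  if (latent_dim < 1 || latent_dim != round(latent_dim)) {
    abort("invalid `latent_dim`: must be a positive integer",
          class = "survfuse_config_error")
  }
  if (!is.null(hidden_widths) &&
      (length(hidden_widths) < 1 || any(hidden_widths < 1))) {
    abort("invalid `hidden_widths`: must be positive counts",
          class = "survfuse_config_error")
  }
  if (a <= 0) abort("invalid `a`: must be positive",
                    class = "survfuse_config_error")
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0, patience >= 1)
  structure(
    list(latent_dim = as.integer(latent_dim),
         hidden_widths = if (is.null(hidden_widths)) NULL else as.integer(hidden_widths),
         a = a, epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, patience = as.integer(patience),
         seed = as.integer(seed)),
    class = "vae_config"
  )
}

#' Log-cosh reconstruction loss
#'
#' `(1/a) * sum_i log(cosh(a * (x_i - xhat_i)))`, summed over features and
#' averaged over the batch. Computed overflow-safely via
#' `log(cosh(t)) = |t| + log(1 + exp(-2|t|)) - log(2)`. The loss is
#' quadratic (`a r^2 / 2`) near zero residual and linear (`|r| - log(2)/a`)
#' in the tails, combining the benefits of squared-L2 and L1 losses.
#'
#' @param x,xhat Matrices (or vectors) of equal shape: data and
#'   reconstruction.
#' @param a Positive sharpness parameter.
#' @return A non-negative scalar.
#' @export
#' @examples
#' logcosh_loss(1, 0, a = 1)  # log((exp(1) + exp(-1)) / 2)
logcosh_loss <- function(x, xhat, a = 10) {
  x <- as.matrix(x); xhat <- as.matrix(xhat)
  if (!all(dim(x) == dim(xhat))) {
    abort("x and xhat must have identical shapes",
          class = "survfuse_validation_error")
  }
  stopifnot(a > 0)
  t <- a * (x - xhat)
  lc <- abs(t) + log1p(exp(-2 * abs(t))) - log(2)
  sum(lc) / (a * nrow(x))
}

#' Kullback-Leibler divergence from the standard-normal prior
#'
#' Closed form for a diagonal-Gaussian posterior `N(mu, diag(sigma^2))`
#' against `N(0, I)`: per sample `0.5 * sum_j (mu_j^2 + sigma_j^2 - 1 -
#' log sigma_j^2)`, averaged over the batch.
#'
#' @param mu,logvar Matrices (or vectors) of posterior means and
#'   log-variances, one row per sample.
#' @return A non-negative scalar, zero only at the standard normal.
#' @export
#' @examples
#' kl_standard_normal(1, 0)  # 0.5
kl_standard_normal <- function(mu, logvar) {
  mu <- as.matrix(mu); logvar <- as.matrix(logvar)
  stopifnot(all(dim(mu) == dim(logvar)))
  sum(0.5 * (mu^2 + exp(logvar) - 1 - logvar)) / nrow(mu)
}

#' Total VAE objective
#'
#' The unweighted sum of the log-cosh reconstruction loss and the KL
#' regulariser — the quantity the VAE training minimises.
#'
#' @inheritParams logcosh_loss
#' @inheritParams kl_standard_normal
#' @return A scalar.
#' @export
vae_total_loss <- function(x, xhat, mu, logvar, a = 10) {
  logcosh_loss(x, xhat, a) + kl_standard_normal(mu, logvar)
}

# Initialise MLP parameters (Xavier-style) for the symmetric
# encoder/decoder; tanh hidden activations keep the objective smooth.
vae_init_params <- function(n_features, hidden, latent_dim) {
  rmat <- function(nin, nout, scale = sqrt(1 / nin)) {
    matrix(rnorm(nin * nout, sd = scale), nin, nout)
  }
  params <- list()
  widths <- c(n_features, hidden)
  for (i in seq_along(hidden)) {
    params[[paste0("enc", i, "_W")]] <- rmat(widths[i], widths[i + 1])
    params[[paste0("enc", i, "_b")]] <- numeric(widths[i + 1])
  }
  hk <- hidden[length(hidden)]
  params$mu_W <- rmat(hk, latent_dim, scale = sqrt(1 / hk))
  params$mu_b <- numeric(latent_dim)
  params$lv_W <- rmat(hk, latent_dim, scale = 0.01)
  params$lv_b <- numeric(latent_dim)
  dwidths <- c(latent_dim, rev(hidden))
  for (i in seq_along(hidden)) {
    params[[paste0("dec", i, "_W")]] <- rmat(dwidths[i], dwidths[i + 1])
    params[[paste0("dec", i, "_b")]] <- numeric(dwidths[i + 1])
  }
  params$out_W <- rmat(dwidths[length(dwidths)], n_features,
                       scale = sqrt(1 / dwidths[length(dwidths)]))
  params$out_b <- numeric(n_features)
  params
}

# Forward pass with fixed reparameterisation noise eps (B x latent_dim).
# Returns activations needed for the backward pass.
vae_forward <- function(params, x, eps, n_hidden) {
  act <- list(x)
  a_cur <- x
  for (i in seq_len(n_hidden)) {
    a_cur <- tanh(sweep(a_cur %*% params[[paste0("enc", i, "_W")]], 2,
                        params[[paste0("enc", i, "_b")]], "+"))
    act[[i + 1]] <- a_cur
  }
  mu <- sweep(a_cur %*% params$mu_W, 2, params$mu_b, "+")
  lv <- sweep(a_cur %*% params$lv_W, 2, params$lv_b, "+")
  zlat <- mu + exp(0.5 * lv) * eps
  dact <- list(zlat)
  d_cur <- zlat
  for (i in seq_len(n_hidden)) {
    d_cur <- tanh(sweep(d_cur %*% params[[paste0("dec", i, "_W")]], 2,
                        params[[paste0("dec", i, "_b")]], "+"))
    dact[[i + 1]] <- d_cur
  }
  xhat <- sweep(d_cur %*% params$out_W, 2, params$out_b, "+")
  list(enc_act = act, mu = mu, lv = lv, z = zlat,
       dec_act = dact, xhat = xhat)
}

# Loss and analytic gradients for one batch under fixed eps.
vae_loss_grad <- function(params, x, eps, a, n_hidden) {
  fw <- vae_forward(params, x, eps, n_hidden)
  B <- nrow(x)
  recon <- logcosh_loss(x, fw$xhat, a)
  kl <- kl_standard_normal(fw$mu, fw$lv)
  grads <- list()
  # decoder output
  dxhat <- -tanh(a * (x - fw$xhat)) / B
  grads$out_W <- t(fw$dec_act[[n_hidden + 1]]) %*% dxhat
  grads$out_b <- colSums(dxhat)
  d_up <- dxhat %*% t(params$out_W)
  for (i in rev(seq_len(n_hidden))) {
    dz <- d_up * (1 - fw$dec_act[[i + 1]]^2)
    grads[[paste0("dec", i, "_W")]] <- t(fw$dec_act[[i]]) %*% dz
    grads[[paste0("dec", i, "_b")]] <- colSums(dz)
    d_up <- dz %*% t(params[[paste0("dec", i, "_W")]])
  }
  dzlat <- d_up
  dmu <- dzlat + fw$mu / B
  dlv <- dzlat * eps * 0.5 * exp(0.5 * fw$lv) + 0.5 * (exp(fw$lv) - 1) / B
  hk_act <- fw$enc_act[[n_hidden + 1]]
  grads$mu_W <- t(hk_act) %*% dmu
  grads$mu_b <- colSums(dmu)
  grads$lv_W <- t(hk_act) %*% dlv
  grads$lv_b <- colSums(dlv)
  d_up <- dmu %*% t(params$mu_W) + dlv %*% t(params$lv_W)
  for (i in rev(seq_len(n_hidden))) {
    dz <- d_up * (1 - fw$enc_act[[i + 1]]^2)
    grads[[paste0("enc", i, "_W")]] <- t(fw$enc_act[[i]]) %*% dz
    grads[[paste0("enc", i, "_b")]] <- colSums(dz)
    d_up <- dz %*% t(params[[paste0("enc", i, "_W")]])
  }
  list(total = recon + kl, recon = recon, kl = kl, grads = grads)
}

# Loss only, for finite-difference verification of the gradients.
vae_loss_only <- function(params, x, eps, a, n_hidden) {
  fw <- vae_forward(params, x, eps, n_hidden)
  vae_total_loss(x, fw$xhat, fw$mu, fw$lv, a)
}

#' Fit a log-cosh VAE on one modality
#'
#' Features are min-max scaled to \[0, 1\] per feature (scaling parameters are
#' stored with the model; constant features scale to 0), then the
#' encoder/decoder multilayer perceptrons are trained by minibatch Adam on
#' the reparameterised objective (log-cosh reconstruction + KL), with early
#' stopping once the epoch loss has not improved for `patience` epochs.
#'
#' @param data Tibble with `patient_id` first, no missing values.
#' @param config A [vae_config()].
#' @return A `vae_model` with encoder/decoder parameters, the config, the
#'   stored scaling, and a per-epoch `history` tibble of total,
#'   reconstruction and KL losses.
#' @export
fit_vae <- function(data, config = vae_config()) {
  stopifnot(inherits(config, "vae_config"))
  x <- as_feature_matrix(data)
  if (anyNA(x)) abort("VAE input must have no missing values",
                      class = "survfuse_validation_error")
  n <- nrow(x); p <- ncol(x)
  mins <- apply(x, 2, min)
  ranges <- apply(x, 2, max) - mins
  ranges[ranges == 0] <- 1
  xs <- sweep(sweep(x, 2, mins), 2, ranges, "/")
  hidden <- config$hidden_widths %||% min(512L, p)
  n_hidden <- length(hidden)
  history <- vector("list", config$epochs)
  withr::with_seed(config$seed, {
    params <- vae_init_params(p, hidden, config$latent_dim)
    m_adam <- lapply(params, function(p0) p0 * 0)
    v_adam <- lapply(params, function(p0) p0 * 0)
    step <- 0L
    b1 <- 0.9; b2 <- 0.999; eps_adam <- 1e-8
    best <- Inf; best_epoch <- 0L
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      tot <- rec <- klv <- 0
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, n)]
        xb <- xs[idx, , drop = FALSE]
        epsb <- matrix(rnorm(length(idx) * config$latent_dim),
                       length(idx), config$latent_dim)
        lg <- vae_loss_grad(params, xb, epsb, config$a, n_hidden)
        if (!is.finite(lg$total)) {
          abort(sprintf("non-finite VAE loss at epoch %d (recon %.4g, KL %.4g)",
                        epoch, lg$recon, lg$kl),
                class = "survfuse_training_error")
        }
        step <- step + 1L
        for (nm in names(params)) {
          g <- lg$grads[[nm]]
          m_adam[[nm]] <- b1 * m_adam[[nm]] + (1 - b1) * g
          v_adam[[nm]] <- b2 * v_adam[[nm]] + (1 - b2) * g^2
          mhat <- m_adam[[nm]] / (1 - b1^step)
          vhat <- v_adam[[nm]] / (1 - b2^step)
          params[[nm]] <- params[[nm]] -
            config$learning_rate * mhat / (sqrt(vhat) + eps_adam)
        }
        w <- length(idx) / n
        tot <- tot + w * lg$total; rec <- rec + w * lg$recon
        klv <- klv + w * lg$kl
      }
      history[[epoch]] <- tibble(epoch = epoch, total = tot,
                                 reconstruction = rec, kl = klv)
      if (tot < best - 1e-8) { best <- tot; best_epoch <- epoch }
      if (epoch - best_epoch >= config$patience) break
    }
  })
  structure(
    list(params = params, config = config,
         hidden_widths = hidden,
         scaling = list(min = mins, range = ranges),
         feature_ids = colnames(x),
         history = dplyr::bind_rows(history)),
    class = "vae_model"
  )
}

#' Encode data to posterior means
#'
#' Deterministically maps patients through the trained encoder and returns
#' the posterior means `mu` (no sampling), the latent features used for
#' fusion and classification.
#'
#' @param model A `vae_model` from [fit_vae()].
#' @param data Tibble with `patient_id` first and the fitted feature ids.
#' @return Tibble with `patient_id` and `z1..z<latent_dim>` columns.
#' @export
vae_encode <- function(model, data) {
  stopifnot(inherits(model, "vae_model"))
  x <- as_feature_matrix(data)
  if (!identical(colnames(x), model$feature_ids)) {
    bad <- c(setdiff(colnames(x), model$feature_ids),
             setdiff(model$feature_ids, colnames(x)))
    abort(paste0("feature ids do not match the VAE fit: ",
                 paste(unique(bad), collapse = ", ")),
          class = "survfuse_validation_error")
  }
  xs <- sweep(sweep(x, 2, model$scaling$min), 2, model$scaling$range, "/")
  a_cur <- xs
  for (i in seq_along(model$hidden_widths)) {
    a_cur <- tanh(sweep(a_cur %*% model$params[[paste0("enc", i, "_W")]], 2,
                        model$params[[paste0("enc", i, "_b")]], "+"))
  }
  mu <- sweep(a_cur %*% model$params$mu_W, 2, model$params$mu_b, "+")
  colnames(mu) <- paste0("z", seq_len(ncol(mu)))
  rownames(mu) <- rownames(x)
  as_modality_tibble(mu)
}

#' Posterior mean and log-variance for each patient
#'
#' Like [vae_encode()] but returns both heads of the encoder.
#'
#' @inheritParams vae_encode
#' @return A list with matrices `mu` and `logvar` (`n x latent_dim`).
#' @export
vae_posterior <- function(model, data) {
  x <- as_feature_matrix(data)
  xs <- sweep(sweep(x, 2, model$scaling$min), 2, model$scaling$range, "/")
  a_cur <- xs
  for (i in seq_along(model$hidden_widths)) {
    a_cur <- tanh(sweep(a_cur %*% model$params[[paste0("enc", i, "_W")]], 2,
                        model$params[[paste0("enc", i, "_b")]], "+"))
  }
  list(
    mu = sweep(a_cur %*% model$params$mu_W, 2, model$params$mu_b, "+"),
    logvar = sweep(a_cur %*% model$params$lv_W, 2, model$params$lv_b, "+")
  )
}

#' @export
print.vae_model <- function(x, ...) {
  cat("<vae_model>", length(x$feature_ids), "features ->",
      x$config$latent_dim, "latent dims; hidden",
      paste(x$hidden_widths, collapse = "/"), "\n  trained",
      nrow(x$history), "epochs; final loss",
      sprintf("%.4f", x$history$total[nrow(x$history)]), "\n")
  invisible(x)
}

#' @rdname fit_vae
#' @param x A `vae_model`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.vae_model <- function(x, ...) x$history

#' @rdname fit_vae
#' @exportS3Method generics::glance
glance.vae_model <- function(x, ...) {
  h <- x$history
  tibble(
    n_features = length(x$feature_ids),
    latent_dim = x$config$latent_dim,
    epochs_trained = nrow(h),
    final_loss = h$total[nrow(h)],
    final_reconstruction = h$reconstruction[nrow(h)],
    final_kl = h$kl[nrow(h)]
  )
}
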