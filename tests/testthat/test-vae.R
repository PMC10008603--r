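test_that("log-cosh loss matches its analytic values and regimes", {
  # zero at equality
  x <- matrix(rnorm(20), 4, 5)
  expect_equal(logcosh_loss(x, x, a = 3), 0)

  # single residual r = 1 at a = 1: log((e + 1/e) / 2)
  expect_equal(logcosh_loss(1, 0, a = 1), log((exp(1) + exp(-1)) / 2),
               tolerance = 1e-9)

  # evenness in the residual
  r <- matrix(runif(12, -2, 2), 3, 4)
  expect_equal(logcosh_loss(r, 0 * r, a = 2), logcosh_loss(-r, 0 * r, a = 2))

  # quadratic regime: |a r| <= 1e-3 behaves as a r^2 / 2
  for (a in c(0.5, 1, 10)) {
    r_small <- 1e-3 / a
    expect_lt(abs(logcosh_loss(r_small, 0, a) / (a * r_small^2 / 2) - 1), 1e-6)
  }

  # linear regime: |a r| >= 20 behaves as |r| - log(2)/a
  for (a in c(1, 10)) {
    r_big <- 25 / a
    expect_equal(logcosh_loss(r_big, 0, a), r_big - log(2) / a,
                 tolerance = 1e-8)
  }

  # strictly increasing in |residual|
  rs <- seq(0, 5, by = 0.25)
  vals <- vapply(rs, function(r) logcosh_loss(r, 0, a = 2), numeric(1))
  expect_true(all(diff(vals) > 0))

  expect_error(logcosh_loss(matrix(0, 2, 2), matrix(0, 2, 3), a = 1),
               class = "survfuse_validation_error")
})

test_that("Gaussian KL closed form matches known values and Monte Carlo", {
  expect_equal(kl_standard_normal(0, 0), 0)
  expect_equal(kl_standard_normal(1, 0), 0.5)
  expect_gte(kl_standard_normal(matrix(rnorm(10), 5, 2),
                                matrix(rnorm(10), 5, 2)), 0)

  # Monte-Carlo oracle at moderate size (the large-sample sweep runs in the
  # acceptance suite)
  withr::with_seed(21, {
    mu <- 0.7; lv <- -0.4
    n_mc <- 2e5
    z <- rnorm(n_mc, mean = mu, sd = exp(0.5 * lv))
    log_ratio <- dnorm(z, mu, exp(0.5 * lv), log = TRUE) -
      dnorm(z, 0, 1, log = TRUE)
    se <- sd(log_ratio) / sqrt(n_mc)
    expect_lt(abs(kl_standard_normal(mu, lv) - mean(log_ratio)), 3 * se)
  })
})

test_that("the total objective is the exact sum of its two terms", {
  withr::with_seed(22, {
    x <- matrix(runif(15), 3, 5)
    xhat <- matrix(runif(15), 3, 5)
    mu <- matrix(rnorm(6), 3, 2)
    lv <- matrix(rnorm(6, sd = 0.3), 3, 2)
  })
  expect_identical(vae_total_loss(x, xhat, mu, lv, a = 4),
                   logcosh_loss(x, xhat, a = 4) + kl_standard_normal(mu, lv))
  expect_equal(vae_total_loss(x, x, 0 * mu, 0 * lv, a = 4), 0)
})

test_that("analytic gradients match central finite differences", {
  withr::with_seed(23, {
    p <- 5; latent <- 2; hidden <- 4; B <- 6; a <- 10
    params <- survfuse:::vae_init_params(p, hidden, latent)
    x <- matrix(runif(B * p), B, p)
    eps <- matrix(rnorm(B * latent), B, latent)
  })
  lg <- survfuse:::vae_loss_grad(params, x, eps, a, 1)
  flat <- unlist(params)
  h <- 1e-5
  num <- vapply(seq_along(flat), function(i) {
    up <- flat; up[i] <- up[i] + h
    dn <- flat; dn[i] <- dn[i] - h
    (survfuse:::vae_loss_only(utils::relist(up, params), x, eps, a, 1) -
       survfuse:::vae_loss_only(utils::relist(dn, params), x, eps, a, 1)) / (2 * h)
  }, numeric(1))
  ana <- unlist(lg$grads[names(params)])
  expect_lt(max(abs(ana - num)) / max(abs(num)), 1e-4)
})

test_that("training is seeded, convergent and recovers planted structure", {
  # planted low-rank data: exact linear image of a latent_dim source.
  # Enough observed features are needed for the reconstruction term to
  # outweigh the KL cost of an informative code (as in the real pathways,
  # where modalities carry hundreds of features).
  withr::with_seed(24, {
    src <- matrix(rnorm(150 * 3), 150, 3)
    lift <- matrix(rnorm(3 * 100), 3, 100)
    x <- src %*% lift + matrix(rnorm(150 * 100, sd = 0.02), 150, 100)
  })
  d <- toy_table(x, ids = sprintf("P%03d", 1:150))
  cfg <- vae_config(latent_dim = 3, hidden_widths = 32, epochs = 400,
                    patience = 60, batch_size = 16, learning_rate = 3e-3,
                    seed = 6)
  vm <- fit_vae(d, cfg)

  # identical seeds give identical histories; different seeds differ
  vm2 <- fit_vae(d, cfg)
  expect_identical(vm$history, vm2$history)

  # smoothed training loss trends downward to convergence
  sm <- stats::filter(vm$history$total, rep(1 / 5, 5), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_lt(sm[length(sm)], sm[1])
  expect_lte(vm$history$total[nrow(vm$history)], vm$history$total[1])

  # reconstruction error well below the data variance on the [0,1] scale
  xs <- sweep(sweep(x, 2, vm$scaling$min), 2, vm$scaling$range, "/")
  post <- vae_posterior(vm, d)
  fw <- survfuse:::vae_forward(vm$params, xs, 0 * post$mu,
                               length(vm$hidden_widths))
  resid_frac <- mean((xs - fw$xhat)^2) / mean(scale(xs, scale = FALSE)^2)
  expect_lt(resid_frac, 0.1)
})

test_that("the encoder emits the configured latent widths deterministically", {
  prep <- tiny_prep()
  cln_cfg <- vae_config(latent_dim = 4, hidden_widths = 16, epochs = 15,
                        seed = 3)
  vm_cln <- fit_vae(prep$modalities$cln, cln_cfg)
  z_cln <- vae_encode(vm_cln, prep$modalities$cln)
  expect_equal(ncol(z_cln) - 1L, 4)

  other_cfg <- vae_config(latent_dim = 32, hidden_widths = 16, epochs = 15,
                          seed = 3)
  vm_mir <- fit_vae(prep$modalities$mir, other_cfg)
  z_mir <- vae_encode(vm_mir, prep$modalities$mir)
  expect_equal(ncol(z_mir) - 1L, 32)

  # mu and logvar heads double the latent width
  expect_equal(ncol(vm_mir$params$mu_W) + ncol(vm_mir$params$lv_W), 2 * 32)

  # encoding is deterministic
  expect_identical(z_mir, vae_encode(vm_mir, prep$modalities$mir))

  # feature mismatch is an error
  bad <- prep$modalities$mir
  names(bad)[2] <- "oops"
  expect_error(vae_encode(vm_mir, bad), "oops",
               class = "survfuse_validation_error")

  # a linear probe on mu beats chance on planted-signal data
  lab <- tiny_labels()
  y <- lab$label[match(z_mir$patient_id, lab$patient_id)]
  keep <- !is.na(y)
  fit <- suppressWarnings(glm(y[keep] ~ ., family = binomial,
                              data = as.data.frame(z_mir[keep, -1])))
  acc <- mean((fitted(fit) > 0.5) == y[keep])
  expect_gt(acc, 0.7)
})

test_that("invalid VAE configurations are rejected", {
  expect_error(vae_config(latent_dim = 0), class = "survfuse_config_error")
  expect_error(vae_config(a = 0), class = "survfuse_config_error")
  expect_error(vae_config(hidden_widths = c(8, 0)),
               class = "survfuse_config_error")
})
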