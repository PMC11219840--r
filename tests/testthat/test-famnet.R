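test_that("datasets have the condition-grid geometry and are reproducible", {
  cfg <- familiarity_config(seed = 71)
  d <- make_dataset(cfg)
  expect_equal(dim(d$X), c(400, 10))          # 4k trials at k = 100
  expect_setequal(unique(d$direction), c(-1, 1))
  expect_setequal(unique(d$speed), c(-1, 1))
  d2 <- make_dataset(cfg)
  expect_identical(d$X, d2$X)
  ## zero input noise collapses to exactly four distinct input vectors
  cfg0 <- familiarity_config(sigma_inp = 0, seed = 72)
  d0 <- make_dataset(cfg0)
  expect_equal(nrow(unique(round(d0$X, 10))), 4)
})

test_that("forward pass has the declared shapes and ReLU nonnegativity", {
  cfg <- familiarity_config(N_hidden = 7, seed = 73)
  d <- make_dataset(cfg)
  par <- famnet_init(cfg)
  fw <- famnet_forward(par, d$X, sigma_neu = 0)
  expect_equal(dim(fw$H), c(400, 7))
  expect_equal(dim(fw$recon), c(400, 10))
  expect_length(fw$logit, 400)
  expect_true(all(fw$H >= 0))                 # noiseless hidden is ReLU output
  ## zero weights: hidden all zero, reconstruction equals the output bias
  par0 <- lapply(par, function(p) p * 0)
  par0$b2 <- seq_len(10) / 10
  fw0 <- famnet_forward(par0, d$X, sigma_neu = 0)
  expect_true(all(fw0$H == 0))
  expect_equal(fw0$recon, matrix(par0$b2, 400, 10, byrow = TRUE))
})

test_that("loss components behave linearly and vanish where expected", {
  cfg <- familiarity_config(seed = 74)
  d <- make_dataset(cfg)
  par <- famnet_init(cfg)
  fw <- famnet_forward(par, d$X, sigma_neu = 0)
  L <- famnet_loss(fw, d$X, d$direction, cfg)
  expect_equal(L$total,
               cfg$beta_r * L$recon + cfg$beta_c * L$ce + cfg$beta_s * L$sparsity)
  ## beta_c = beta_s = 0 leaves the pure reconstruction term
  cfg_r <- familiarity_config(beta_c = 0, beta_s = 0, seed = 74)
  Lr <- famnet_loss(fw, d$X, d$direction, cfg_r)
  expect_equal(Lr$total, cfg_r$beta_r * Lr$recon)
  ## doubling beta_s doubles the sparsity contribution
  cfg_s2 <- familiarity_config(beta_s = 2, seed = 74)
  L2 <- famnet_loss(fw, d$X, d$direction, cfg_s2)
  expect_equal(L2$total - famnet_loss(fw, d$X, d$direction,
                                      familiarity_config(beta_s = 1, seed = 74))$total,
               L2$sparsity)
  ## perfect reconstruction, silent hidden layer: only cross-entropy remains
  parI <- par
  fwI <- list(H = matrix(0, 400, cfg$N_hidden), recon = d$X,
              logit = d$direction * 30, relu_mask = matrix(FALSE, 400, cfg$N_hidden))
  LI <- famnet_loss(fwI, d$X, d$direction, cfg)
  expect_lt(LI$total, 1e-10)
})

test_that("analytic gradients match finite differences", {
  cfg <- familiarity_config(k_trials_per_condition = 3, N_inp = 4,
                            N_hidden = 3, sigma_inp = 0.5, seed = 75)
  d <- make_dataset(cfg)
  par <- famnet_init(cfg)
  fw <- famnet_forward(par, d$X, sigma_neu = 0)       # deterministic pass
  g <- dnmspop:::.famnet_grad(par, fw, d$X, d$direction, cfg)
  eps <- 1e-6
  for (nm in c("W1", "W2", "wc", "b1", "b2", "bc")) {
    p <- par[[nm]]
    idx <- if (length(p) > 1) c(1, length(p)) else 1
    for (i in idx) {
      up <- par; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- par; dn[[nm]][i] <- dn[[nm]][i] - eps
      fd <- (famnet_loss(famnet_forward(up, d$X, 0), d$X, d$direction, cfg)$total -
             famnet_loss(famnet_forward(dn, d$X, 0), d$X, d$direction, cfg)$total) /
        (2 * eps)
      expect_equal(as.numeric(g[[nm]])[i], fd, tolerance = 1e-4)
    }
  }
})

test_that("training reduces the loss, is reproducible, and zero betas freeze weights", {
  cfg <- familiarity_config(k_trials_per_condition = 20, epochs = 10, seed = 76)
  d <- make_dataset(cfg)
  tr1 <- famnet_train(cfg, d)
  tr2 <- famnet_train(cfg, d)
  expect_identical(tr1$loss, tr2$loss)
  expect_identical(tr1$par, tr2$par)
  ## smoothed loss decreases
  expect_lt(mean(utils::tail(tr1$loss$total, 3)), mean(utils::head(tr1$loss$total, 3)))
  ## all-zero loss weights: zero gradient, weights never move
  cfg0 <- familiarity_config(beta_r = 0, beta_c = 0, beta_s = 0,
                             k_trials_per_condition = 5, epochs = 2, seed = 77)
  d0 <- make_dataset(cfg0)
  tr0 <- famnet_train(cfg0, d0)
  expect_equal(tr0$par, famnet_init(cfg0), tolerance = 1e-12)
})

test_that("reconstruction-only training drives the error toward the noise floor", {
  cfg <- familiarity_config(beta_r = 1, beta_c = 0, beta_s = 0, lr = 0.01,
                            k_trials_per_condition = 25, epochs = 30,
                            sigma_neu = 0, seed = 78)
  d <- make_dataset(cfg)
  tr <- famnet_train(cfg, d)
  expect_lt(utils::tail(tr$loss$recon, 1), 0.1 * tr$loss$recon[1])
})

test_that("familiarity of a perfect-identity model is uninformative", {
  cfg <- familiarity_config(k_trials_per_condition = 25, seed = 79)
  d <- make_dataset(cfg)
  fam <- replicate(3, matrix(0, 400, 10), simplify = FALSE)
  ro <- familiarity_readout(fam, d$direction, d$speed, folds = 5, seed = 1)
  expect_true(all(abs(ro$direction_acc - 0.5) < 0.12))
  expect_true(all(abs(ro$speed_acc - 0.5) < 0.12))
})

test_that("single-simulation experiments match a direct train+readout run", {
  cfg <- familiarity_config(k_trials_per_condition = 10, epochs = 5,
                            n_sims = 1, seed = 80)
  ex <- run_experiment(cfg, "full", n_sims = 1)
  sim_seed <- dnmspop:::.split_seed(cfg$seed, 5001)
  cfg2 <- cfg
  cfg2[c("beta_r", "beta_c", "beta_s", "lr")] <- list(0.1, 1, 1, 0.002)
  d <- make_dataset(cfg2, seed = sim_seed)
  tr <- famnet_train(cfg2, d, seed = sim_seed)
  ro <- familiarity_readout(tr$familiarity, d$direction, d$speed,
                            folds = cfg$readout_folds, seed = sim_seed)
  expect_equal(ex$curves$direction_mean, ro$direction_acc)
  expect_equal(ex$curves$speed_mean, ro$speed_acc)
  expect_equal(unique(ex$curves$epoch), 1:5)
})
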