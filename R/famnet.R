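#' Configuration of the autoencoder familiarity model
#'
#' A small noisy-ReLU autoencoder reconstructs stimulus inputs while an
#' auxiliary read-out unit classifies the direction of motion from the
#' hidden layer, imposing an asymmetry between direction and speed. The
#' familiarity signal is the signed difference between reconstruction and
#' input, and a downstream linear classifier probes what that signal
#' carries as training progresses.
#'
#' Defaults follow the model's published constants: four condition
#' prototypes at the corners of `{-1, 1}^2` (direction x speed), `k = 100`
#' trials per condition, input noise `sigma_inp = 0.5` expanded by a random
#' projection to `N_inp = 10` dimensions, hidden noise `sigma_neu = 1`,
#' loss weights `beta_r = 0.1`, `beta_c = 1`, `beta_s = 1`, ADAM with
#' learning rate 0.002 and batch size 10 for 50 epochs, a 5-fold
#' cross-validated readout, and 100 independent simulations. The hidden
#' width is not a published constant; the default matches `N_inp`.
#'
#' @param k_trials_per_condition,sigma_inp,N_inp,N_hidden,sigma_neu Data
#'   and architecture settings.
#' @param beta_r,beta_c,beta_s Loss weights (reconstruction,
#'   cross-entropy, hidden-layer L1 sparsity).
#' @param lr,batch_size,epochs ADAM settings.
#' @param n_sims Independent simulations to average.
#' @param readout_folds Cross-validation folds of the familiarity readout.
#' @param seed Master seed.
#' @return A `familiarity_config` list.
#' @export
familiarity_config <- function(k_trials_per_condition = 100, sigma_inp = 0.5,
                               N_inp = 10, N_hidden = 10, sigma_neu = 1,
                               beta_r = 0.1, beta_c = 1, beta_s = 1,
                               lr = 0.002, batch_size = 10, epochs = 50,
                               n_sims = 100, readout_folds = 5, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$sigma_inp >= 0, cfg$sigma_neu >= 0, cfg$epochs >= 1,
            cfg$beta_r >= 0, cfg$beta_c >= 0, cfg$beta_s >= 0)
  structure(cfg, class = "familiarity_config")
}

#' Build one simulated stimulus dataset
#'
#' Each trial is one of the four condition prototypes `[-1,-1]`, `[-1,1]`,
#' `[1,-1]`, `[1,1]` (direction = first coordinate, speed = second) plus
#' 2-D Gaussian noise of sd `sigma_inp`, expanded by a fixed random linear
#' projection (iid standard-normal entries, not orthonormalized) to
#' `N_inp` dimensions.
#'
#' @param cfg A [familiarity_config()].
#' @param seed Seed for noise and projection.
#' @return List: `X` (`4k x N_inp`), `direction`, `speed` (each in
#'   `{-1, 1}`), `projection` (`2 x N_inp`).
#' @export
make_dataset <- function(cfg, seed = cfg$seed) {
  rng <- .local_rng(.split_seed(seed, 61))
  proto <- rbind(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  k <- cfg$k_trials_per_condition
  cond <- rep(1:4, each = k)
  Z <- proto[cond, , drop = FALSE] +
    matrix(rng$rnorm(4 * k * 2, 0, cfg$sigma_inp), ncol = 2)
  P <- matrix(rng$rnorm(2 * cfg$N_inp), 2, cfg$N_inp)
  list(X = Z %*% P, direction = proto[cond, 1], speed = proto[cond, 2],
       projection = P)
}

#' Initialize autoencoder parameters
#'
#' @param cfg A [familiarity_config()].
#' @param seed Seed for the small centered-Gaussian initialization.
#' @return Parameter list `W1, b1, W2, b2, wc, bc`.
#' @export
famnet_init <- function(cfg, seed = cfg$seed) {
  rng <- .local_rng(.split_seed(seed, 67))
  ## centered Gaussian scaled by 1/sqrt(fan_in), the standard dense-layer
  ## initialization
  list(W1 = matrix(rng$rnorm(cfg$N_hidden * cfg$N_inp, 0, 1 / sqrt(cfg$N_inp)),
                   cfg$N_hidden, cfg$N_inp),
       b1 = numeric(cfg$N_hidden),
       W2 = matrix(rng$rnorm(cfg$N_inp * cfg$N_hidden, 0, 1 / sqrt(cfg$N_hidden)),
                   cfg$N_inp, cfg$N_hidden),
       b2 = numeric(cfg$N_inp),
       wc = rng$rnorm(cfg$N_hidden, 0, 1 / sqrt(cfg$N_hidden)),
       bc = 0)
}

#' Forward pass of the autoencoder
#'
#' `hidden = ReLU(W1 x + b1) + noise`, `reconstruction = W2 hidden + b2`,
#' `direction_logit = wc . hidden + bc`. Hidden noise (sd `sigma_neu`) is
#' applied at both training and readout time.
#'
#' @param par Parameter list from [famnet_init()] or [famnet_train()].
#' @param X Inputs, trials x `N_inp`.
#' @param sigma_neu Hidden noise sd.
#' @param rng Optional RNG stream (private); `NULL` disables noise.
#' @return List: `H` (trials x hidden), `recon`, `logit`, and `relu_mask`
#'   used by the backward pass.
#' @export
famnet_forward <- function(par, X, sigma_neu = 0, rng = NULL) {
  pre <- sweep(X %*% t(par$W1), 2, par$b1, "+")
  mask <- pre > 0
  H <- pre * mask
  if (!is.null(rng) && sigma_neu > 0)
    H <- H + matrix(rng$rnorm(length(H), 0, sigma_neu), nrow(H), ncol(H))
  recon <- sweep(H %*% t(par$W2), 2, par$b2, "+")
  logit <- drop(H %*% par$wc) + par$bc
  list(H = H, recon = recon, logit = logit, relu_mask = mask)
}

#' Composite training loss
#'
#' `Loss = beta_r * MSE(input, reconstruction) + beta_c * cross-entropy of
#' the direction logit + beta_s * mean L1 norm of hidden activity`. The
#' MSE and the sparsity term are means over trials and units; the
#' cross-entropy is the mean binomial deviance of a single sigmoid logit
#' against direction coded as `{0, 1}`.
#'
#' @param fw Forward-pass output of [famnet_forward()].
#' @param X Inputs.
#' @param direction Direction labels in `{-1, 1}`.
#' @param cfg A [familiarity_config()].
#' @return List: `total`, `recon`, `ce`, `sparsity` components.
#' @export
famnet_loss <- function(fw, X, direction, cfg) {
  ydir <- (direction + 1) / 2
  mse <- mean((X - fw$recon)^2)
  p <- 1 / (1 + exp(-fw$logit))
  eps <- 1e-12
  ce <- -mean(ydir * log(p + eps) + (1 - ydir) * log(1 - p + eps))
  sp <- mean(abs(fw$H))
  list(total = cfg$beta_r * mse + cfg$beta_c * ce + cfg$beta_s * sp,
       recon = mse, ce = ce, sparsity = sp)
}

## analytic gradients of famnet_loss w.r.t. all parameters (batch mean)
.famnet_grad <- function(par, fw, X, direction, cfg) {
  n <- nrow(X); n_inp <- ncol(X); n_hid <- ncol(fw$H)
  ydir <- (direction + 1) / 2
  ## d total / d recon: beta_r * 2 (recon - X) / (n * n_inp)
  d_recon <- cfg$beta_r * 2 * (fw$recon - X) / (n * n_inp)
  ## d / d logit: beta_c * (sigmoid - y) / n
  p <- 1 / (1 + exp(-fw$logit))
  d_logit <- cfg$beta_c * (p - ydir) / n
  ## d / d H
  d_H <- d_recon %*% par$W2 + outer(d_logit, par$wc) +
    cfg$beta_s * sign(fw$H) / (n * n_hid)
  d_pre <- d_H * fw$relu_mask
  list(W1 = t(d_pre) %*% X, b1 = colSums(d_pre),
       W2 = t(d_recon) %*% fw$H, b2 = colSums(d_recon),
       wc = drop(t(fw$H) %*% d_logit), bc = sum(d_logit))
}

#' Train the autoencoder and record per-epoch familiarity
#'
#' Minibatch ADAM on the composite loss. After every epoch the familiarity
#' signal (reconstruction minus input, with fresh hidden noise) is
#' evaluated on the full dataset and stored, along with the epoch's mean
#' loss components. Training aborts if the loss turns non-finite.
#'
#' @param cfg A [familiarity_config()].
#' @param data Dataset from [make_dataset()].
#' @param seed Seed for initialization, batch order and hidden noise.
#' @return List: `par` (final parameters), `familiarity` (list of
#'   trials x `N_inp` matrices, one per epoch), `loss` (per-epoch
#'   data.frame of components).
#' @export
famnet_train <- function(cfg, data, seed = cfg$seed) {
  par <- famnet_init(cfg, seed)
  rng <- .local_rng(.split_seed(seed, 71))
  m <- lapply(par, function(p) p * 0)   # ADAM moments
  v <- lapply(par, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0
  n <- nrow(data$X)
  fam <- vector("list", cfg$epochs)
  loss_log <- matrix(NA_real_, cfg$epochs, 4,
                     dimnames = list(NULL, c("total", "recon", "ce", "sparsity")))
  for (ep in seq_len(cfg$epochs)) {
    ord <- rng$sample_perm(n)
    batch_losses <- c(0, 0, 0, 0)
    nb <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      Xb <- data$X[idx, , drop = FALSE]
      fw <- famnet_forward(par, Xb, cfg$sigma_neu, rng)
      L <- famnet_loss(fw, Xb, data$direction[idx], cfg)
      if (!is.finite(L$total)) stop("training diverged (non-finite loss)")
      g <- .famnet_grad(par, fw, Xb, data$direction[idx], cfg)
      step <- step + 1
      for (nm in names(par)) {
        m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g[[nm]]
        v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g[[nm]]^2
        mhat <- m[[nm]] / (1 - b1^step)
        vhat <- v[[nm]] / (1 - b2^step)
        par[[nm]] <- par[[nm]] - cfg$lr * mhat / (sqrt(vhat) + eps)
      }
      batch_losses <- batch_losses + c(L$total, L$recon, L$ce, L$sparsity)
      nb <- nb + 1
    }
    loss_log[ep, ] <- batch_losses / nb
    fw_full <- famnet_forward(par, data$X, cfg$sigma_neu, rng)
    fam[[ep]] <- fw_full$recon - data$X
  }
  list(par = par, familiarity = fam, loss = as.data.frame(loss_log))
}

#' Decode direction and speed from the familiarity signal
#'
#' For each training epoch an independent linear classifier (logistic
#' regression) is trained on the familiarity population — reconstruction
#' minus input — with stratified cross-validation, separately for the
#' direction and the speed label. Accuracy is the mean over folds.
#'
#' @param fam List of per-epoch familiarity matrices from [famnet_train()].
#' @param direction,speed Labels in `{-1, 1}`.
#' @param folds CV folds (default 5).
#' @param seed Fold-assignment seed.
#' @return `data.frame`: `epoch`, `direction_acc`, `speed_acc`.
#' @export
familiarity_readout <- function(fam, direction, speed, folds = 5, seed = 1L) {
  out <- data.frame(epoch = seq_along(fam),
                    direction_acc = NA_real_, speed_acc = NA_real_)
  for (ep in seq_along(fam)) {
    out$direction_acc[ep] <- .logreg_cv(fam[[ep]], direction, folds,
                                        .split_seed(seed, ep))
    out$speed_acc[ep] <- .logreg_cv(fam[[ep]], speed, folds,
                                    .split_seed(seed, 1000 + ep))
  }
  out
}

## cross-validated L2-regularized logistic-regression accuracy.
## The penalty matches the standard logistic-regression default of the
## scientific-python stack (C = 1 on the summed log loss, i.e. an
## average-loss ridge weight of 1/n, unscaled features).
.logreg_cv <- function(X, y, folds, seed) {
  ybin <- as.integer(y > 0)
  fold_id <- .stratified_folds(as.character(ybin), folds, seed)
  if (all(apply(X, 2, stats::sd) == 0)) {
    ## featureless familiarity (e.g. an identity map): majority-class rule
    maj <- as.integer(mean(ybin) >= 0.5)
    return(mean(ybin == maj))
  }
  acc <- vapply(seq_len(max(fold_id)), function(f) {
    tr <- fold_id != f
    fit <- glmnet::glmnet(X[tr, , drop = FALSE], ybin[tr],
                          family = "binomial", alpha = 0,
                          lambda = 1 / sum(tr), standardize = FALSE)
    pr <- stats::predict(fit, newx = X[!tr, , drop = FALSE],
                         type = "response")[, 1]
    mean((pr > 0.5) == (ybin[!tr] == 1))
  }, numeric(1))
  mean(acc)
}

#' Run a multi-simulation familiarity experiment
#'
#' Runs `n_sims` independent simulations — fresh dataset, random
#' projection and initialization per simulation — of a model variant, and
#' aggregates the per-epoch direction and speed decoding curves (mean and
#' SEM over simulations).
#'
#' Variants preset the loss weights and learning rate: `full`
#' (`beta_r = 0.1, beta_c = 1, beta_s = 1, lr = 0.002`), `recon_only`
#' (`1, 0, 0, lr = 0.01`), `recon_ce` (`1, 1, 0, lr = 0.01`) and
#' `high_sparsity` (`0.1, 1, 20, lr = 0.002`).
#'
#' @param cfg A [familiarity_config()]; the variant overrides its
#'   `beta_*` and `lr` fields.
#' @param variant One of `"full"`, `"recon_only"`, `"recon_ce"`,
#'   `"high_sparsity"`.
#' @param n_sims Number of simulations (defaults to `cfg$n_sims`).
#' @return List of class `epoch_curve`: `curves` (`data.frame` with epoch,
#'   per-label mean and SEM), `per_sim` (list of readout data.frames),
#'   `cfg`, `variant`.
#' @export
run_experiment <- function(cfg = familiarity_config(),
                           variant = c("full", "recon_only", "recon_ce",
                                       "high_sparsity"),
                           n_sims = cfg$n_sims) {
  variant <- match.arg(variant)
  preset <- switch(variant,
    full = list(beta_r = 0.1, beta_c = 1, beta_s = 1, lr = 0.002),
    recon_only = list(beta_r = 1, beta_c = 0, beta_s = 0, lr = 0.01),
    recon_ce = list(beta_r = 1, beta_c = 1, beta_s = 0, lr = 0.01),
    high_sparsity = list(beta_r = 0.1, beta_c = 1, beta_s = 20, lr = 0.002))
  cfg[names(preset)] <- preset
  per_sim <- vector("list", n_sims)
  for (sim in seq_len(n_sims)) {
    sim_seed <- .split_seed(cfg$seed, 5000 + sim)
    data <- make_dataset(cfg, seed = sim_seed)
    trained <- famnet_train(cfg, data, seed = sim_seed)
    per_sim[[sim]] <- familiarity_readout(trained$familiarity,
                                          data$direction, data$speed,
                                          folds = cfg$readout_folds,
                                          seed = sim_seed)
  }
  dir_mat <- sapply(per_sim, `[[`, "direction_acc")
  spd_mat <- sapply(per_sim, `[[`, "speed_acc")
  if (is.null(dim(dir_mat))) { dir_mat <- matrix(dir_mat, ncol = n_sims)
                               spd_mat <- matrix(spd_mat, ncol = n_sims) }
  sem <- function(M) apply(M, 1, stats::sd) / sqrt(ncol(M))
  curves <- data.frame(epoch = seq_len(cfg$epochs),
                       direction_mean = rowMeans(dir_mat),
                       direction_sem = sem(dir_mat),
                       speed_mean = rowMeans(spd_mat),
                       speed_sem = sem(spd_mat))
  structure(list(curves = curves, per_sim = per_sim, cfg = cfg,
                 variant = variant),
            class = "epoch_curve")
}
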