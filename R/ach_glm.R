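#' Task-variable design matrix for the acetylcholine GLM
#'
#' Builds the frames x covariates matrix of task-variable time courses:
#' boxcars (0/1) for the pre-stimulus period, anterior and posterior
#' stimulus direction (sample plus test frames of the matching direction),
#' the post-trial interval, and a 300 ms boxcar from the point of reward
#' delivery. The lick train is expressed at the imaging frame rate,
#' convolved with a 10-sample Gaussian kernel (sd 2 samples, unit mass)
#' and split into pre-reward licking (all licks before the reward on hit
#' trials, and all licks on miss/FA/CR trials) and post-reward licking
#' (licks from reward delivery onward on hit trials).
#'
#' @param trials Trial table with periods, outcomes, licks and rewards.
#' @param frame_rate_hz Frame rate; defaults to the table's attribute.
#' @return Matrix with columns `pre_stimulus`, `stim_dir_anterior`,
#'   `stim_dir_posterior`, `reward`, `lick_pre`, `lick_post`, `post_trial`.
#' @export
build_design <- function(trials, frame_rate_hz = attr(trials, "frame_rate_hz")) {
  n_frames <- attr(trials, "n_frames")
  X <- matrix(0, n_frames,  7,
              dimnames = list(NULL, c("pre_stimulus", "stim_dir_anterior",
                                      "stim_dir_posterior", "reward",
                                      "lick_pre", "lick_post", "post_trial")))
  reward_len <- as.integer(round(0.3 * frame_rate_hz))
  lick_pre <- numeric(n_frames); lick_post <- numeric(n_frames)
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    X[(tr$pre_stim_start + 1L):tr$pre_stim_end, "pre_stimulus"] <- 1
    X[(tr$post_start + 1L):tr$post_end, "post_trial"] <- 1
    for (dd in c("A", "P")) {
      col <- if (dd == "A") "stim_dir_anterior" else "stim_dir_posterior"
      if (tr$sample_dir == dd)
        X[(tr$sample_start + 1L):tr$sample_end, col] <- 1
      if (tr$test_dir == dd)
        X[(tr$test_start + 1L):tr$test_end, col] <- 1
    }
    licks <- trials$lick_frames[[i]]
    if (tr$outcome == "hit" && !is.na(tr$reward_frame)) {
      rw_end <- min(tr$reward_frame + reward_len, n_frames)
      X[(tr$reward_frame + 1L):rw_end, "reward"] <- 1
      pre <- licks[licks < tr$reward_frame]
      post <- licks[licks >= tr$reward_frame]
    } else {
      pre <- licks; post <- integer(0)
    }
    lick_pre[pre + 1L] <- lick_pre[pre + 1L] + 1
    lick_post[post + 1L] <- lick_post[post + 1L] + 1
  }
  kern <- .lick_kernel()
  ## clip FFT round-off: the true convolution of nonnegative signals is >= 0
  X[, "lick_pre"] <- pmax(.conv_same(lick_pre, kern), 0)
  X[, "lick_post"] <- pmax(.conv_same(lick_post, kern), 0)
  X
}

## 10-sample Gaussian lick kernel, sd 2 samples, unit mass
.lick_kernel <- function() {
  k <- stats::dnorm(seq(-4.5, 4.5), 0, 2)
  k / sum(k)
}

#' L1-penalised Normal GLM of an acetylcholine trace
#'
#' Fits the identity-link Gaussian model `y_hat_t = sum_i w_i x_i(t)` with
#' an L1 penalty path of 6 values of the penalty gamma (log-spaced over
#' three decades down from the smallest all-zeroing penalty) and selects
#' gamma by minimum 4-fold cross-validated deviance. The deviance of the
#' selected fit on all data is the residual sum of squares (unit
#' dispersion, so AIC differences across nested fits are well defined).
#'
#' @param y Normalized acetylcholine trace (finite, one value per frame).
#' @param X Design matrix from [build_design()].
#' @param n_penalties Number of penalty values (default 6).
#' @param folds Cross-validation folds (default 4).
#' @param seed Fold-assignment seed.
#' @param count_all_params Count all covariates in `k` rather than only
#'   those with nonzero fitted weights.
#' @return List of class `glm_fit`: `weights` (named, incl. dropped-to-zero
#'   entries), `intercept`, `deviance`, `k`, `gamma` (selected penalty),
#'   `cv_deviance` (per penalty), `penalties`.
#' @export
fit_glm <- function(y, X, n_penalties = 6, folds = 4, seed = 1L,
                    count_all_params = FALSE) {
  stopifnot(all(is.finite(y)), nrow(X) == length(y))
  if (stats::sd(y) == 0) {
    return(structure(list(weights = stats::setNames(numeric(ncol(X)),
                                                    colnames(X)),
                          intercept = y[1], deviance = 0, k = 1L, gamma = 0,
                          cv_deviance = NA_real_, penalties = NA_real_),
                     class = "glm_fit"))
  }
  if (ncol(X) == 0 || all(X == 0)) {
    warning("empty design: intercept-only fit")
    mu <- mean(y)
    return(structure(list(weights = stats::setNames(numeric(ncol(X)),
                                                    colnames(X)),
                          intercept = mu, deviance = sum((y - mu)^2),
                          k = 1L, gamma = 0,
                          cv_deviance = NA_real_, penalties = NA_real_),
                     class = "glm_fit"))
  }
  ## lambda_max: smallest penalty zeroing every weight (glmnet convention)
  n <- length(y)
  Xs <- scale(X)
  Xs[!is.finite(Xs)] <- 0
  lam_max <- max(abs(crossprod(Xs, y - mean(y)))) / n
  pens <- lam_max * 10^seq(0, -3, length.out = n_penalties)

  rng <- .local_rng(.split_seed(seed, 73))
  fold_id <- rep_len(seq_len(folds), n)[rng$sample_perm(n)]
  cv_dev <- numeric(n_penalties)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    fit_f <- .glmnet_fit(X[tr, , drop = FALSE], y[tr], pens)
    pred <- .glmnet_predict(fit_f, X[!tr, , drop = FALSE], pens)
    cv_dev <- cv_dev + colSums((y[!tr] - pred)^2)
  }
  best <- which.min(cv_dev)
  fit <- .glmnet_fit(X, y, pens)
  co <- .glmnet_coef(fit, pens[best], colnames(X))
  yhat <- drop(X %*% co$w) + co$b
  dev <- sum((y - yhat)^2)
  k <- if (count_all_params) ncol(X) + 1L else sum(co$w != 0) + 1L
  structure(list(weights = co$w, intercept = co$b, deviance = dev,
                 k = as.integer(k), gamma = pens[best],
                 cv_deviance = cv_dev, penalties = pens),
            class = "glm_fit")
}

## glmnet wrappers (gaussian, our own lambda sequence); single-column
## designs fall back to penalty-free least squares
.glmnet_fit <- function(X, y, pens) {
  if (ncol(X) >= 2)
    glmnet::glmnet(X, y, family = "gaussian", lambda = pens,
                   standardize = TRUE)
  else {
    fit <- stats::lm.fit(cbind(1, X), y)
    structure(list(coef = fit$coefficients), class = "lsq_fallback")
  }
}

.glmnet_predict <- function(fit, X, pens) {
  if (inherits(fit, "lsq_fallback")) {
    p <- drop(cbind(1, X) %*% fit$coef)
    matrix(rep(p, length(pens)), ncol = length(pens))
  } else {
    stats::predict(fit, newx = X, s = pens, exact = FALSE)
  }
}

.glmnet_coef <- function(fit, pen, nms) {
  if (inherits(fit, "lsq_fallback")) {
    w <- fit$coef[-1]; names(w) <- nms
    list(w = w, b = unname(fit$coef[1]))
  } else {
    cf <- as.numeric(stats::coef(fit, s = pen))
    list(w = stats::setNames(cf[-1], nms), b = cf[1])
  }
}

#' Akaike information criterion of a fitted GLM
#'
#' `AIC = 2k + deviance`, where `k` is the number of model parameters
#' (nonzero fitted weights plus the intercept under L1 selection, unless
#' the all-parameters mode was used) and the deviance is the Gaussian
#' deviance at unit dispersion, i.e. `-2 ln L` up to an additive constant
#' held fixed across full and partial models.
#'
#' @param fit A `glm_fit`.
#' @return AIC, a scalar.
#' @export
aic <- function(fit) 2 * fit$k + fit$deviance

#' Default covariate-to-factor grouping
#'
#' Each task variable is its own factor, except the two stimulus-direction
#' covariates, which form one `stimulus_direction` factor.
#'
#' @return Named list mapping factor names to covariate names.
#' @export
default_factors <- function() {
  list(pre_stimulus = "pre_stimulus",
       stimulus_direction = c("stim_dir_anterior", "stim_dir_posterior"),
       reward = "reward",
       lick_pre = "lick_pre",
       lick_post = "lick_post",
       post_trial = "post_trial")
}

#' Task-factor importance by delta-AIC
#'
#' For each task factor, a partial model excluding that factor's covariates
#' is fit with the same penalty-path and cross-validation procedure, and
#' `delta AIC = AIC_partial - AIC_full`. Larger values mean the factor
#' explains more of the signal; a factor with no true contribution gives a
#' small non-positive value (the bookkeeping cost of the removed
#' parameters).
#'
#' @param y Acetylcholine trace.
#' @param X Design matrix.
#' @param grouping Factor grouping; must partition `colnames(X)`.
#' @param ... Passed to [fit_glm()].
#' @return `data.frame` with `factor`, `delta_aic`, `aic_partial`,
#'   `aic_full`, sorted by decreasing `delta_aic`.
#' @export
factor_delta_aic <- function(y, X, grouping = default_factors(), ...) {
  covs <- unlist(grouping, use.names = FALSE)
  if (!setequal(covs, colnames(X)) || anyDuplicated(covs))
    stop("grouping must partition the design-matrix covariates")
  full <- fit_glm(y, X, ...)
  a_full <- aic(full)
  out <- data.frame(factor = names(grouping), delta_aic = NA_real_,
                    aic_partial = NA_real_, aic_full = a_full,
                    stringsAsFactors = FALSE)
  for (i in seq_along(grouping)) {
    keep <- setdiff(colnames(X), grouping[[i]])
    part <- fit_glm(y, X[, keep, drop = FALSE], ...)
    out$aic_partial[i] <- aic(part)
    out$delta_aic[i] <- aic(part) - a_full
  }
  out[order(-out$delta_aic), ]
}
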