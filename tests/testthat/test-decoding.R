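test_that("window features average the window and z-score across trials", {
  ## two trials, two neurons, hand-computed z-scores
  tab <- generate_trial_schedule(stage_config("T2"), 2, seed = 51)
  n_frames <- attr(tab, "n_frames")
  s_hat <- matrix(0, 2, n_frames)
  ## neuron 1: sample-window means 2 and 4; neuron 2: constant
  s_hat[1, (tab$sample_start[1] + 1):tab$sample_end[1]] <- 2
  s_hat[1, (tab$sample_start[2] + 1):tab$sample_end[2]] <- 4
  s_hat[2, ] <- 7
  f <- window_features(s_hat, tab, "sample")
  ## z-scores of c(2, 4): +/- 1/sqrt(2) under sd with n-1 denominator
  expect_equal(f$X[, 1], c(-1, 1) / sqrt(2))
  expect_equal(f$X[, 2], c(0, 0))           # zero-variance column rule
  raw <- window_features(s_hat, tab, "sample", zscore = FALSE)
  expect_equal(raw$X[, 1], c(2, 4))
  expect_error(window_features(s_hat, tab, "nonsense"), "unknown")
})

test_that("decoder separates separable data and matches chance on shuffled labels", {
  set.seed(52)
  n <- 60
  X <- rbind(matrix(rnorm(n / 2 * 4, -1), ncol = 4),
             matrix(rnorm(n / 2 * 4, 1), ncol = 4))
  y <- rep(c("a", "b"), each = n / 2)
  m <- fit_decoder(X, y, folds = 10, seed = 1)
  expect_gte(m$accuracy, 0.95)
  expect_length(m$w, 4)
  ## label-independent features: inside the shuffle band
  Xn <- matrix(rnorm(200 * 5), 200, 5)
  yn <- rep(c("a", "b"), 100)
  mn <- fit_decoder(Xn, yn, folds = 10, seed = 2)
  null <- label_shuffle_null(Xn, yn, folds = 10, n = 200, seed = 3)
  expect_gte(mn$accuracy, null$pct5 - 0.03)
  expect_lte(mn$accuracy, null$pct95 + 0.03)
  expect_lt(abs(mean(null$samples) - 0.5), 3 * stats::sd(null$samples) / sqrt(200))
  expect_lte(null$pct5, stats::median(null$samples))
  expect_gte(null$pct95, stats::median(null$samples))
  expect_error(fit_decoder(X, rep("a", n)), "two label classes")
})

test_that("decoder agrees with a brute-force hard-margin search in 2-D", {
  ## brute force: scan separator angles, maximize the margin
  set.seed(53)
  X <- rbind(c(0, 1), c(1, 2), c(0.5, 1.8), c(2, 0), c(3, 1), c(2.5, -0.5))
  y <- c("a", "a", "a", "b", "b", "b")
  thetas <- seq(0, pi, length.out = 5000)
  best <- -Inf; w_bf <- NULL
  for (th in thetas) {
    w <- c(cos(th), sin(th))
    pa <- X[y == "a", ] %*% w; pb <- X[y == "b", ] %*% w
    for (sgn in c(1, -1)) {
      m <- (min(sgn * pb) - max(sgn * pa)) / 2
      if (m > best) { best <- m; w_bf <- sgn * w }
    }
  }
  m <- fit_decoder(X, y, folds = 3, cost = 1e6, seed = 1)
  cosang <- sum(m$w * w_bf) / sqrt(sum(m$w^2))
  expect_gt(abs(cosang), 0.999)   # same separator direction up to scale
  ## decision values classify the training set perfectly
  expect_true(all((X %*% m$w + m$b > 0) == (y == "b")))
})

test_that("minority resampling removes imbalance bias", {
  set.seed(54)
  ## balanced informative data: resampled equals plain within tolerance
  X <- rbind(matrix(rnorm(40 * 3, -1), ncol = 3),
             matrix(rnorm(40 * 3, 1), ncol = 3))
  y <- rep(c("a", "b"), each = 40)
  acc_plain <- fit_decoder(X, y, folds = 5, seed = 1)$accuracy
  acc_rs <- fit_decoder_resampled(X, y, folds = 5, n_resamples = 20, seed = 1)$accuracy
  expect_lt(abs(acc_plain - acc_rs), 0.1)
  ## 95/5 imbalance with informative minority: above the null band
  n <- 120
  y_im <- c(rep("a", round(0.95 * n)), rep("b", n - round(0.95 * n)))
  X_im <- matrix(rnorm(n * 4), n, 4) + ifelse(y_im == "b", 2.5, 0)
  m_im <- fit_decoder_resampled(X_im, y_im, folds = 5, n_resamples = 10, seed = 2)
  null_im <- label_shuffle_null(X_im, y_im, folds = 5, n = 100, seed = 3,
                                resample = TRUE, n_resamples = 3)
  expect_gt(m_im$accuracy, null_im$pct95)
  expect_error(fit_decoder_resampled(X_im, rep("a", n)), "two label classes")
})

test_that("cross-temporal decoding localizes a planted reward signal", {
  run_ct <- function(lead) {
    fx <- planted_effects(n_neurons = 24, frac_direction = 0, frac_speed = 0,
                          frac_expected = 0, frac_reward = 0.5,
                          reward_onset_lead_s_by_stage =
                            c(T1 = lead, T2 = lead, T3 = lead,
                              T4 = lead, T5 = lead),
                          seed = 55)
    b <- simulate_session(stage_config("T4"), 100, fx, seed = 55)
    ev <- estimate_events(b$F, b$frame_rate_hz)
    y <- ifelse(b$trials$outcome == "hit", "hit", "non-hit")
    list(b = b, ev = ev, y = y,
         ct = cross_temporal(ev, b$trials, y, "report", folds = 5,
                             n_null = 150, seed = 55))
  }
  r6 <- run_ct(0.6); r0 <- run_ct(0)
  onset6 <- decodable_onset(r6$ct); onset0 <- decodable_onset(r0$ct)
  expect_false(is.na(onset6)); expect_false(is.na(onset0))
  ## a 0.6 s planted lead moves the onset ~0.6 s earlier (reward-time
  ## jitter cancels in the difference; tolerance two window steps)
  expect_lt(abs((onset0 - onset6) - 0.6), 0.2 + 1e-9)
  ct <- r6$ct; b <- r6$b; ev <- r6$ev; y <- r6$y
  fr <- b$frame_rate_hz
  ## pre-stimulus windows carry no decodable signal
  pre <- ct$starts_s < 0.7
  expect_lt(mean(ct$accuracy[pre]), 0.63)
  ## train == test window reproduces the plain decoder within CV noise
  ## (windows fully inside the report period, where the signal lives)
  rep_start <- (b$trials$report_start[1] - b$trials$pre_stim_start[1]) / fr
  rep_end <- (b$trials$report_end[1] - b$trials$pre_stim_start[1]) / fr
  inside <- ct$starts_s >= rep_start & ct$starts_s + 0.3 <= rep_end
  plain <- fit_decoder(window_features(ev, b$trials, "report"), y,
                       folds = 5, seed = 55)
  expect_lt(abs(mean(ct$accuracy[inside]) - plain$accuracy), 0.15)
})

test_that("decodable onset handles empty and saturated significance patterns", {
  ct <- structure(list(starts_s = seq(0, 2, 0.1),
                       sig_above = rep(FALSE, 21),
                       test_start_s = 0.5, report_end_s = 2),
                  class = "cross_temporal_result")
  expect_true(is.na(decodable_onset(ct)))
  ct$sig_above <- rep(TRUE, 21)
  expect_equal(decodable_onset(ct), 0.5)   # clamps to the test-period start
  ## single isolated window is ignored by the default two-window rule
  ct$sig_above <- c(rep(FALSE, 6), TRUE, rep(FALSE, 14))
  expect_true(is.na(decodable_onset(ct)))
  expect_equal(decodable_onset(ct, n_consecutive = 1), 0.6)
})

test_that("cross-session decoding transfers a stable code and rejects a redrawn one", {
  fx <- planted_effects(n_neurons = 20, frac_direction = 0, frac_speed = 0,
                        frac_expected = 0, frac_reward = 0.25, seed = 56)
  b1 <- simulate_session(stage_config("T2"), 80, fx, seed = 561)
  b2 <- simulate_session(stage_config("T2"), 80, fx, seed = 562)
  ev1 <- estimate_events(b1$F, b1$frame_rate_hz)
  ev2 <- estimate_events(b2$F, b2$frame_rate_hz)
  y1 <- ifelse(b1$trials$outcome == "hit", "hit", "non-hit")
  y2 <- ifelse(b2$trials$outcome == "hit", "hit", "non-hit")
  m <- fit_decoder(window_features(ev1, b1$trials, "report"), y1,
                   folds = 5, seed = 1)
  ## same session: cross-session equals within-session accuracy
  cs_same <- cross_session(m, ev1, b1$trials, y1, "report", n_null = 150, seed = 2)
  expect_lt(abs(cs_same$accuracy - m$accuracy), 0.1)
  ## same planted code in a second session: transfers above the null
  cs <- cross_session(m, ev2, b2$trials, y2, "report", n_null = 150, seed = 3)
  expect_true(cs$sig_above)
  ## an independently re-drawn code (different neuron assignment) does not
  fx_shuf <- planted_effects(n_neurons = 20, frac_direction = 0.5,
                             frac_speed = 0, frac_expected = 0,
                             frac_reward = 0, seed = 57)
  b3 <- simulate_session(stage_config("T2"), 80, fx_shuf, seed = 563)
  ev3 <- estimate_events(b3$F, b3$frame_rate_hz)
  y3 <- ifelse(b3$trials$outcome == "hit", "hit", "non-hit")
  cs_ind <- cross_session(m, ev3, b3$trials, y3, "report", n_null = 150, seed = 4)
  expect_lte(cs_ind$accuracy, cs_ind$pct95 + 0.05)
  expect_error(cross_session(m, ev3$s_hat[1:10, ], b3$trials, y3, "report"),
               "neuron count")
})

test_that("significant-weight masks are calibrated and detect tuned neurons", {
  set.seed(58)
  n <- 80
  X <- matrix(rnorm(n * 20), n, 20)
  y <- rep(c("a", "b"), n / 2)
  X[, 1] <- X[, 1] + ifelse(y == "b", 1.5, -1.5)   # one strongly tuned neuron
  m <- fit_decoder(X, y, folds = 5, seed = 1)
  mask <- significant_weights(m, X, y, n = 300, seed = 2)
  expect_length(mask, 20)
  expect_true(mask[1])
  ## pure-noise neurons flagged at roughly the two-tailed 10% rate
  expect_lt(mean(mask[-1]), 0.35)
})

test_that("decision-variable projection separates outcomes and reverses on sign-flip cells", {
  fx <- planted_effects(n_neurons = 24, frac_direction = 0, frac_speed = 0,
                        frac_reward = 0, frac_expected = 0.5,
                        expected_sign_flip = TRUE, seed = 59)
  b <- simulate_session(stage_config("T2"), 120, fx, seed = 59)
  ev <- estimate_events(b$F, b$frame_rate_hz)
  y <- ifelse(b$trials$outcome == "hit", "hit", "non-hit")
  m <- fit_decoder(window_features(ev, b$trials, "pre_stim"), y,
                   folds = 5, seed = 1)
  pj <- project_decision_variable(ev, b$trials, m)
  fr <- b$frame_rate_hz
  tr1 <- b$trials[1, ]
  pre_i <- seq_len(tr1$pre_stim_end - tr1$pre_stim_start)
  rep_i <- (tr1$report_start - tr1$pre_stim_start + 3):
           (tr1$report_end - tr1$pre_stim_start)
  other <- setdiff(rownames(pj$trajectory), "hit")
  gap_pre <- mean(pj$trajectory["hit", pre_i]) -
    mean(colMeans(pj$trajectory[other, pre_i, drop = FALSE]))
  gap_rep <- mean(pj$trajectory["hit", rep_i]) -
    mean(colMeans(pj$trajectory[other, rep_i, drop = FALSE]))
  ## hit and non-hit trajectories separate before the stimulus and cross to
  ## the opposite side at the report period (planted sign reversal)
  expect_lt(gap_pre * gap_rep, 0)
  expect_gt(abs(gap_pre), 0.2)
  expect_gt(abs(gap_rep), 0.2)
  ## zero-weight model projects flat at the bias
  m0 <- m; m0$w[] <- 0; m0$b <- 0.3
  pj0 <- project_decision_variable(ev, b$trials, m0)
  expect_true(all(abs(pj0$trajectory - 0.3) < 1e-12))
})

test_that("performance correlation matches the closed-form Pearson r", {
  x <- c(0.5, 0.6, 0.7, 0.9); y <- c(1.1, 1.0, 1.6, 1.9)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  pc <- performance_correlation(x, y)
  expect_equal(pc$r, r_hand)
  expect_equal(performance_correlation(x, x)$r, 1)
  expect_equal(performance_correlation(x, -x)$r, -1)
  expect_error(performance_correlation(x, rep(1, 4)), "zero-variance")
  expect_error(performance_correlation(x[1:2], y[1:2]))
})
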