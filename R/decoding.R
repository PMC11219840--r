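#' Trial-windowed, z-scored population features
#'
#' Averages each neuron's calcium event estimate over a time window of each
#' trial, then z-scores each neuron across all trials in session time.
#' Zero-variance columns map to zero. The window is either a named trial
#' period (`"pre_stim"`, `"sample"`, `"delay"`, `"test"`, `"report"`,
#' `"post"`) or a numeric `c(start_s, width_s)` offset from trial start;
#' numeric windows extending past a trial's end are truncated with a
#' warning.
#'
#' @param s_hat Neurons x frames event-estimate matrix (or an
#'   `event_matrix` from [estimate_events()]).
#' @param trials Trial table.
#' @param window Period name or `c(start_s, width_s)`.
#' @param zscore Z-score across trials (default `TRUE`).
#' @return List of class `labeled_features`: `X` (trials x neurons),
#'   `window`, `trial_ids`.
#' @export
window_features <- function(s_hat, trials, window, zscore = TRUE) {
  if (inherits(s_hat, "event_matrix")) s_hat <- s_hat$s_hat
  fr <- attr(trials, "frame_rate_hz")
  n_tr <- nrow(trials)
  idx <- .window_frames(trials, window, fr)
  X <- t(vapply(seq_len(n_tr), function(i)
    rowMeans(s_hat[, idx[[i]], drop = FALSE]), numeric(nrow(s_hat))))
  if (n_tr == 1) X <- matrix(X, nrow = 1)
  if (zscore) X <- .zscore_cols(X)
  structure(list(X = X, window = window, trial_ids = trials$trial_id),
            class = "labeled_features")
}

## 1-based frame indices per trial for a window spec
.window_frames <- function(trials, window, fr) {
  if (is.character(window)) {
    st <- trials[[paste0(window, "_start")]]
    en <- trials[[paste0(window, "_end")]]
    if (is.null(st)) stop("unknown trial period: ", window)
    if (any(en <= st)) stop("empty window: ", window)
    lapply(seq_len(nrow(trials)), function(i) (st[i] + 1L):en[i])
  } else {
    stopifnot(is.numeric(window), length(window) == 2, window[2] > 0)
    off <- as.integer(floor(window[1] * fr))
    wid <- as.integer(floor(window[2] * fr))
    if (wid < 1) stop("window narrower than one frame")
    truncated <- FALSE
    out <- lapply(seq_len(nrow(trials)), function(i) {
      a <- trials$pre_stim_start[i] + off
      b <- min(a + wid, trials$post_end[i])
      if (b < a + wid) truncated <<- TRUE
      if (b <= a) return(integer(0))
      (a + 1L):b
    })
    if (any(lengths(out) == 0)) stop("window falls entirely outside a trial")
    if (truncated) warning("test window truncated at trial end")
    out
  }
}

.zscore_cols <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  Xc <- sweep(X, 2, mu)
  sd[!is.finite(sd) | sd == 0] <- Inf   # zero-variance columns -> 0
  sweep(Xc, 2, sd, "/")
}

#' Fit a linear max-margin session decoder
#'
#' Trains a linear maximum-margin (support-vector) classifier on trial
#' features and reports mean held-out accuracy over stratified
#' cross-validation folds; the returned weights are refit on all trials.
#' A decision value of exactly zero is classified as the negative class.
#'
#' @param X Trials x neurons feature matrix (z-scored), or a
#'   `labeled_features` list.
#' @param y Binary labels (any two-level vector).
#' @param folds Number of cross-validation folds (default 10).
#' @param cost Soft-margin penalty of the max-margin fit (default 1).
#' @param seed Seed for the fold assignment.
#' @return List of class `decoder_model`: `w`, `b`, `levels` (negative,
#'   positive), `accuracy`, `folds`, `n_resamples`.
#' @export
fit_decoder <- function(X, y, folds = 10, cost = 1, seed = 1L) {
  if (inherits(X, "labeled_features")) X <- X$X
  y <- as.character(y)
  lev <- sort(unique(y))
  if (length(lev) != 2) stop("exactly two label classes are required")
  fold_id <- .stratified_folds(y, folds, seed)
  acc <- vapply(seq_len(max(fold_id)), function(f) {
    tr <- fold_id != f
    if (length(unique(y[tr])) < 2) return(NA_real_)  # degenerate fold
    m <- .svm_linear(X[tr, , drop = FALSE], y[tr], lev, cost)
    mean(.svm_predict(m, X[!tr, , drop = FALSE]) == y[!tr])
  }, numeric(1))
  if (all(is.na(acc))) stop("no fold had both classes in training")
  acc <- acc[!is.na(acc)]
  full <- .svm_linear(X, y, lev, cost)
  structure(list(w = full$w, b = full$b, levels = lev,
                 accuracy = mean(acc), fold_accuracy = acc,
                 folds = folds, n_resamples = 1L, cost = cost),
            class = "decoder_model")
}

#' Minority-resampled decoder for imbalanced labels
#'
#' As [fit_decoder()], but within each training split the minority class is
#' resampled with replacement to match the majority class before fitting;
#' the whole cross-validation is repeated `n_resamples` times and the
#' reported accuracy is the average. Used for labels (stimulus speed,
#' choice) whose minority condition is rare.
#'
#' @inheritParams fit_decoder
#' @param n_resamples Number of resampling repetitions (default 100).
#' @return A `decoder_model`; weights are fit on one balanced resample of
#'   the full data.
#' @export
fit_decoder_resampled <- function(X, y, folds = 10, n_resamples = 100,
                                  cost = 1, seed = 1L) {
  if (inherits(X, "labeled_features")) X <- X$X
  y <- as.character(y)
  lev <- sort(unique(y))
  if (length(lev) != 2) stop("exactly two label classes are required")
  if (min(table(y)) < 2)
    stop("the minority class needs at least two trials")
  ## cap folds so every training split keeps at least one minority trial
  folds <- max(2L, min(folds, min(table(y))))
  rng <- .local_rng(.split_seed(seed, 17))
  accs <- numeric(n_resamples)
  for (r in seq_len(n_resamples)) {
    fold_id <- .stratified_folds(y, folds, .split_seed(seed, 100 + r))
    acc <- vapply(seq_len(max(fold_id)), function(f) {
      tr_i <- which(fold_id != f)
      if (length(unique(y[tr_i])) < 2) return(NA_real_)
      bal <- .balance_upsample(tr_i, y, rng)
      m <- .svm_linear(X[bal, , drop = FALSE], y[bal], lev, cost)
      mean(.svm_predict(m, X[fold_id == f, , drop = FALSE]) == y[fold_id == f])
    }, numeric(1))
    accs[r] <- mean(acc, na.rm = TRUE)
  }
  bal <- .balance_upsample(seq_along(y), y, rng)
  full <- .svm_linear(X[bal, , drop = FALSE], y[bal], lev, cost)
  structure(list(w = full$w, b = full$b, levels = lev,
                 accuracy = mean(accs), fold_accuracy = accs,
                 folds = folds, n_resamples = n_resamples, cost = cost),
            class = "decoder_model")
}

#' Label-shuffle null distribution of decoder accuracy
#'
#' Repeats the decoding with trial labels randomly permuted before
#' classification and returns the null accuracies with their 5th and 95th
#' percentiles (linear-interpolation percentiles). Observed accuracies
#' above the 95th or below the 5th percentile are deemed significant.
#'
#' @inheritParams fit_decoder
#' @param n Number of shuffles (default 1000).
#' @param resample Use the minority-resampled decoder in each shuffle.
#' @param n_resamples Resampling repetitions per shuffle when `resample`.
#' @return List of class `null_distribution`: `samples`, `pct5`, `pct95`,
#'   `kind = "label_shuffle"`.
#' @export
label_shuffle_null <- function(X, y, folds = 10, n = 1000, cost = 1,
                               seed = 1L, resample = FALSE, n_resamples = 5) {
  if (inherits(X, "labeled_features")) X <- X$X
  y <- as.character(y)
  rng <- .local_rng(.split_seed(seed, 29))
  samples <- vapply(seq_len(n), function(r) {
    yp <- y[rng$sample_perm(length(y))]
    m <- if (resample)
      fit_decoder_resampled(X, yp, folds, n_resamples, cost,
                            seed = .split_seed(seed, 200 + r))
    else fit_decoder(X, yp, folds, cost, seed = .split_seed(seed, 200 + r))
    m$accuracy
  }, numeric(1))
  structure(list(samples = samples,
                 pct5 = stats::quantile(samples, 0.05, names = FALSE),
                 pct95 = stats::quantile(samples, 0.95, names = FALSE),
                 kind = "label_shuffle"),
            class = "null_distribution")
}

#' Cross-temporal decoding with weight-shuffle calibration
#'
#' Trains a decoder on one trial window (a named period or a sliding 1000
#' ms window) and tests it, by stratified cross-validation, on sliding test
#' windows (default 300 ms wide, 100 ms step) spanning the trial.
#' Significance per test window is assessed against a weight-shuffle null:
#' the full-data weight vector is randomly permuted across neurons (bias
#' kept) and re-applied, and accuracies above the 95th or below the 5th
#' percentile of the resulting distribution are flagged separately.
#'
#' @inheritParams fit_decoder
#' @param trials Trial table.
#' @param train_window Period name or `c(start_s, width_s)`.
#' @param test_width_s Width of sliding test windows in seconds.
#' @param step_s Step between test-window starts in seconds.
#' @param n_null Weight-shuffle repetitions (default 1000).
#' @param resample Use minority resampling for the training fits.
#' @param n_resamples Resampling repetitions when `resample`.
#' @return List of class `cross_temporal_result`: `starts_s`, `accuracy`,
#'   `pct5`, `pct95`, `sig_above`, `sig_below`, `model`, plus the aligned
#'   `test_start_s`/`report_end_s` anchors used by [decodable_onset()].
#' @export
cross_temporal <- function(s_hat, trials, y, train_window,
                           test_width_s = 0.3, step_s = 0.1,
                           folds = 10, n_null = 1000, cost = 1, seed = 1L,
                           resample = FALSE, n_resamples = 5) {
  if (inherits(s_hat, "event_matrix")) s_hat <- s_hat$s_hat
  fr <- attr(trials, "frame_rate_hz")
  y <- as.character(y)
  lev <- sort(unique(y))
  feat_train <- window_features(s_hat, trials, train_window)

  ## sliding test windows across the shortest trial
  trial_len_s <- min(trials$post_end - trials$pre_stim_start) / fr
  starts <- seq(0, trial_len_s - test_width_s, by = step_s)
  feats <- suppressWarnings(lapply(starts, function(s0)
    window_features(s_hat, trials, c(s0, test_width_s))$X))

  fold_id <- .stratified_folds(y, folds, seed)
  rng <- .local_rng(.split_seed(seed, 31))
  acc <- numeric(length(starts))
  fold_models <- vector("list", max(fold_id))
  for (f in seq_len(max(fold_id))) {
    tr_i <- which(fold_id != f); te_i <- which(fold_id == f)
    if (length(unique(y[tr_i])) < 2)
      stop("a training fold lost one class; use fewer folds")
    fit_i <- if (resample) .balance_upsample(tr_i, y, rng) else tr_i
    m <- .svm_linear(feat_train$X[fit_i, , drop = FALSE], y[fit_i], lev, cost)
    fold_models[[f]] <- m
    for (k in seq_along(starts)) {
      pred <- .svm_predict(m, feats[[k]][te_i, , drop = FALSE])
      acc[k] <- acc[k] + sum(pred == y[te_i])
    }
  }
  acc <- acc / length(y)

  ## weight-shuffle null with the same cross-validated structure as the
  ## observed statistic: one neuron permutation per repetition, applied to
  ## every fold model and scored on that fold's held-out trials
  rng_n <- .local_rng(.split_seed(seed, 37))
  n_neu <- ncol(feat_train$X)
  null_mat <- matrix(0, n_null, length(starts))
  for (r in seq_len(n_null)) {
    p <- rng_n$sample_perm(n_neu)
    row <- numeric(length(starts))
    for (f in seq_len(max(fold_id))) {
      te_i <- which(fold_id == f)
      m <- fold_models[[f]]
      wp <- m$w[p]
      for (k in seq_along(starts)) {
        dv <- drop(feats[[k]][te_i, , drop = FALSE] %*% wp) + m$b
        row[k] <- row[k] + sum(ifelse(dv > 0, lev[2], lev[1]) == y[te_i])
      }
    }
    null_mat[r, ] <- row / length(y)
  }
  full <- .svm_linear(feat_train$X, y, lev, cost)
  pct5 <- apply(null_mat, 2, stats::quantile, 0.05, names = FALSE)
  pct95 <- apply(null_mat, 2, stats::quantile, 0.95, names = FALSE)

  structure(list(
    starts_s = starts, accuracy = acc, pct5 = pct5, pct95 = pct95,
    sig_above = acc > pct95, sig_below = acc < pct5,
    test_width_s = test_width_s, step_s = step_s,
    model = structure(list(w = full$w, b = full$b, levels = lev,
                           accuracy = mean(acc), folds = folds,
                           n_resamples = 1L, cost = cost),
                      class = "decoder_model"),
    test_start_s = .modal_anchor(trials, fr, "test_start"),
    report_end_s = .modal_anchor(trials, fr, "report_end")),
    class = "cross_temporal_result")
}

## modal trial-relative time (s) of a period boundary
.modal_anchor <- function(trials, fr, col) {
  rel <- (trials[[col]] - trials$pre_stim_start) / fr
  as.numeric(names(sort(-table(rel))))[1]
}

## accuracy of weight-permuted decoders, one row per shuffle
.weight_shuffle_null <- function(full, feats, y, lev, n_null, seed) {
  rng <- .local_rng(seed)
  n_neu <- length(full$w)
  out <- vapply(seq_len(n_null), function(r) {
    wp <- full$w[rng$sample_perm(n_neu)]
    vapply(feats, function(Xk) {
      dv <- drop(Xk %*% wp) + full$b
      mean(ifelse(dv > 0, lev[2], lev[1]) == y)
    }, numeric(1))
  }, numeric(length(feats)))
  ## n_null rows x n_windows columns, also when there is a single window
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  t(out)
}

#' Decodable onset of a cross-temporal decoder
#'
#' The start of the first run of `n_consecutive` test windows, within the
#' test-through-report interval, whose accuracy is significantly above the
#' weight-shuffle null. Because each window is tested at a calibrated 5%
#' false-positive rate and adjacent 300 ms windows share most of their
#' frames, a single-window rule (`n_consecutive = 1`, the literal "first
#' significant time point") is biased early by clustered false positives;
#' the package default requires two consecutive significant windows, which
#' does not delay detection of a sustained signal. Returns `NA` when no
#' qualifying run exists.
#'
#' @param ct A `cross_temporal_result`.
#' @param n_consecutive Consecutive significant windows required (default 2).
#' @return Onset time in seconds from trial start, or `NA`.
#' @export
decodable_onset <- function(ct, n_consecutive = 2) {
  ok <- ct$sig_above &
    ct$starts_s >= ct$test_start_s - 1e-9 &
    ct$starts_s <= ct$report_end_s + 1e-9
  runs <- rle(ok)
  starts <- cumsum(c(1L, runs$lengths[-length(runs$lengths)]))
  hit <- which(runs$values & runs$lengths >= n_consecutive)
  if (length(hit) == 0) return(NA_real_)
  ct$starts_s[starts[hit[1]]]
}

#' Cross-session decoding with a frozen model
#'
#' Applies a decoder trained in one session to the same trial-period window
#' of a different session of the same neuronal population (features are
#' z-scored within the test session), with a weight-shuffle null.
#'
#' @param model A `decoder_model` trained on session N.
#' @param s_hat,trials Event estimates and trial table of session M.
#' @param y Labels in session M.
#' @param window Trial window (as in [window_features()]).
#' @param n_null Weight-shuffle repetitions.
#' @param seed Seed for the null.
#' @return List: `accuracy`, `pct5`, `pct95`, `sig_above`, `samples`.
#' @export
cross_session <- function(model, s_hat, trials, y, window,
                          n_null = 1000, seed = 1L) {
  if (inherits(s_hat, "event_matrix")) s_hat <- s_hat$s_hat
  if (nrow(s_hat) != length(model$w))
    stop("neuron count differs between model and session")
  y <- as.character(y)
  X <- window_features(s_hat, trials, window)$X
  dv <- drop(X %*% model$w) + model$b
  acc <- mean(ifelse(dv > 0, model$levels[2], model$levels[1]) == y)
  null_mat <- .weight_shuffle_null(model, list(X), y, model$levels,
                                   n_null, .split_seed(seed, 41))
  samples <- null_mat[, 1]
  list(accuracy = acc,
       pct5 = stats::quantile(samples, 0.05, names = FALSE),
       pct95 = stats::quantile(samples, 0.95, names = FALSE),
       sig_above = acc > stats::quantile(samples, 0.95, names = FALSE),
       samples = samples)
}

#' Cross-condition (AP vs PA) generalization of the outcome decoder
#'
#' Nonmatch trials are split by stimulus condition into a training set (the
#' `train_cond` condition) and a testing set (the other); match trials are
#' randomly halved between the two. A hit vs non-hit decoder is trained on
#' report-period activity of the training set, its within-set accuracy is
#' estimated by stratified cross-validation, and it is then tested
#' cross-temporally (300 ms sliding windows) on the held-out condition.
#' The accuracy of the 300 ms window ending at the end of the test period
#' summarises cross-condition strength.
#'
#' @param s_hat Event-estimate matrix or `event_matrix`.
#' @param trials Trial table containing both nonmatch conditions.
#' @param train_cond `"AP"` or `"PA"`.
#' @param test_width_s,step_s Sliding test-window geometry.
#' @param folds,cost,seed As in [fit_decoder()].
#' @return List: `same_accuracy` (CV within the training set),
#'   `cross_starts_s`, `cross_accuracy` (time course on the held-out
#'   condition), `cross_at_test_end` (the summary window), `model`.
#' @export
cross_condition <- function(s_hat, trials, train_cond = c("AP", "PA"),
                            test_width_s = 0.3, step_s = 0.1,
                            folds = 10, cost = 1, seed = 1L) {
  train_cond <- match.arg(train_cond)
  if (inherits(s_hat, "event_matrix")) s_hat <- s_hat$s_hat
  fr <- attr(trials, "frame_rate_hz")
  pair <- paste0(trials$sample_dir, trials$test_dir)
  other <- setdiff(c("AP", "PA"), train_cond)
  if (!any(pair == other)) stop("both nonmatch conditions are required (stage >= T3)")
  rng <- .local_rng(.split_seed(seed, 43))
  match_i <- which(trials$category == "match")
  half <- rng$sample_perm(length(match_i))[seq_len(floor(length(match_i) / 2))]
  train_i <- sort(c(which(pair == train_cond), match_i[half]))
  test_i <- sort(c(which(pair == other), setdiff(match_i, match_i[half])))

  y <- ifelse(trials$outcome == "hit", "hit", "non-hit")
  Xrep <- window_features(s_hat, trials, "report")$X
  mdl <- fit_decoder(Xrep[train_i, , drop = FALSE], y[train_i],
                     folds = folds, cost = cost, seed = seed)

  trial_len_s <- min(trials$post_end - trials$pre_stim_start) / fr
  starts <- seq(0, trial_len_s - test_width_s, by = step_s)
  cross_acc <- vapply(starts, function(s0) {
    Xk <- suppressWarnings(window_features(s_hat, trials, c(s0, test_width_s))$X)
    dv <- drop(Xk[test_i, , drop = FALSE] %*% mdl$w) + mdl$b
    mean(ifelse(dv > 0, mdl$levels[2], mdl$levels[1]) == y[test_i])
  }, numeric(1))

  t_end <- .modal_anchor(trials, fr, "test_end")
  k_end <- which.min(abs(starts + test_width_s - t_end))
  list(same_accuracy = mdl$accuracy, cross_starts_s = starts,
       cross_accuracy = cross_acc, cross_at_test_end = cross_acc[k_end],
       model = mdl)
}

#' Neurons with significant decoder weights
#'
#' Refits the decoder on label-shuffled data and flags each neuron whose
#' observed weight lies above the 95th or below the 5th percentile of its
#' own shuffled-weight distribution.
#'
#' @inheritParams fit_decoder
#' @param model Fitted `decoder_model` for the observed weights.
#' @param n Number of label shuffles (default 1000).
#' @return Logical mask of length `n_neurons`.
#' @export
significant_weights <- function(model, X, y, n = 1000, cost = 1, seed = 1L) {
  if (inherits(X, "labeled_features")) X <- X$X
  y <- as.character(y)
  lev <- sort(unique(y))
  rng <- .local_rng(.split_seed(seed, 47))
  W <- t(vapply(seq_len(n), function(r) {
    yp <- y[rng$sample_perm(length(y))]
    .svm_linear(X, yp, lev, cost)$w
  }, numeric(ncol(X))))
  lo <- apply(W, 2, stats::quantile, 0.05, names = FALSE)
  hi <- apply(W, 2, stats::quantile, 0.95, names = FALSE)
  model$w > hi | model$w < lo
}

#' Project population activity along the decision-variable axis
#'
#' For each frame of trial-aligned time, the mean over trials of each
#' outcome class of `w . x(t) + b`, where `x(t)` is the per-neuron activity
#' z-scored across all session frames. Reveals when classes separate and
#' whether trajectories cross (as a planted sign reversal makes them do at
#' the report period).
#'
#' @param s_hat Event-estimate matrix or `event_matrix`.
#' @param trials Trial table.
#' @param model A `decoder_model`.
#' @return List: `time_s` (trial-aligned), `trajectory` (condition x time
#'   matrix, rows named by outcome).
#' @export
project_decision_variable <- function(s_hat, trials, model) {
  if (inherits(s_hat, "event_matrix")) s_hat <- s_hat$s_hat
  fr <- attr(trials, "frame_rate_hz")
  Z <- t(scale(t(s_hat)))
  Z[!is.finite(Z)] <- 0
  len <- min(trials$post_end - trials$pre_stim_start)
  conds <- intersect(c("hit", "miss", "FA", "CR"), unique(trials$outcome))
  traj <- matrix(NA_real_, length(conds), len, dimnames = list(conds, NULL))
  for (ci in seq_along(conds)) {
    rows <- which(trials$outcome == conds[ci])
    acc <- matrix(0, length(rows), len)
    for (k in seq_along(rows)) {
      i0 <- trials$pre_stim_start[rows[k]]
      acc[k, ] <- drop(model$w %*% Z[, (i0 + 1L):(i0 + len)]) + model$b
    }
    traj[ci, ] <- colMeans(acc)
  }
  list(time_s = (seq_len(len) - 1) / fr, trajectory = traj)
}

#' Correlation between decoder and behavioral performance
#'
#' Pearson correlation (with two-sided p value) between per-session decoder
#' accuracies and per-session behavioral d-primes.
#'
#' @param decoder_acc,dprimes Equal-length numeric vectors (length >= 3).
#' @return List with `r` and `p`.
#' @export
performance_correlation <- function(decoder_acc, dprimes) {
  stopifnot(length(decoder_acc) == length(dprimes), length(dprimes) >= 3)
  if (stats::sd(decoder_acc) == 0 || stats::sd(dprimes) == 0)
    stop("correlation undefined for zero-variance input")
  ct <- stats::cor.test(decoder_acc, dprimes, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

## ---- internal decoding helpers --------------------------------------------

## linear SVM via libsvm; returns w, b with the convention
## dv = X w + b, dv > 0 -> lev[2], else lev[1]
.svm_linear <- function(X, y, lev, cost) {
  yf <- factor(y, levels = lev)
  m <- e1071::svm(X, yf, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(m$coefs) %*% m$SV)
  b <- -m$rho
  ## libsvm's positive decision value corresponds to the first factor level
  ## encountered in the data; align signs so dv > 0 <-> lev[2]
  dv <- drop(X %*% w) + b
  pred <- ifelse(dv > 0, lev[2], lev[1])
  if (mean(pred == as.character(stats::predict(m, X))) < 0.5) {
    w <- -w; b <- -b
  }
  list(w = w, b = b, lev = lev)
}

## decision value exactly 0 falls to the negative class
.svm_predict <- function(m, X) {
  dv <- drop(X %*% m$w) + m$b
  ifelse(dv > 0, m$lev[2], m$lev[1])
}

## stratified fold assignment, shuffled within class
.stratified_folds <- function(y, folds, seed) {
  rng <- .local_rng(.split_seed(seed, 53))
  id <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[rng$sample_perm(length(idx))]
    id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  id
}

## upsample the minority class among indices tr_i to match the majority
.balance_upsample <- function(tr_i, y, rng) {
  tab <- table(y[tr_i])
  if (length(tab) < 2 || min(tab) == 0) stop("minority class empty in training split")
  if (tab[1] == tab[2]) return(tr_i)
  minority <- names(tab)[which.min(tab)]
  min_i <- tr_i[y[tr_i] == minority]
  need <- max(tab) - length(min_i)
  extra <- min_i[rng$sample_int(length(min_i), need)]
  c(tr_i, extra)
}
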