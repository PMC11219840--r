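#' Floor fluorescence traces at the per-neuron baseline
#'
#' Values below the bottom 10th percentile of each neuron's signal intensity
#' are raised to that percentile (linear-interpolation percentile, base R
#' type 7). Flooring rather than zeroing preserves the baseline level that
#' the shot-noise estimate and the deconvolution operate on.
#'
#' @param F_mat Neurons x frames fluorescence matrix.
#' @param prob Baseline percentile (default 0.10).
#' @return Matrix of the same shape with sub-baseline values floored.
#' @export
threshold_baseline <- function(F_mat, prob = 0.10) {
  F_mat <- .as_fmatrix(F_mat)
  q <- apply(F_mat, 1, stats::quantile, probs = prob, names = FALSE)
  pmax(F_mat, q)
}

#' Per-neuron photon shot-noise level
#'
#' The noise level of each fluorescence trace is the median absolute
#' difference between subsequent time points divided by the square root of
#' the frame rate:
#' \deqn{v = \mathrm{median}_t |F_{t+1} - F_t| / \sqrt{f_r}}
#'
#' @param F_mat Neurons x frames fluorescence matrix (at least 2 frames).
#' @param frame_rate_hz Acquisition frame rate \eqn{f_r} in Hz.
#' @return Numeric vector of per-neuron noise levels `v >= 0`.
#' @export
estimate_noise <- function(F_mat, frame_rate_hz) {
  F_mat <- .as_fmatrix(F_mat)
  if (ncol(F_mat) < 2) stop("at least two frames are required")
  stopifnot(frame_rate_hz > 0)
  d <- abs(F_mat[, -1, drop = FALSE] - F_mat[, -ncol(F_mat), drop = FALSE])
  apply(d, 1, stats::median) / sqrt(frame_rate_hz)
}

#' Fit an AR(1) calcium-decay kernel per neuron
#'
#' The decay coefficient gamma of the autoregressive kernel is estimated
#' from the ratio of the lag-2 to lag-1 autocovariance of each trace (which
#' is robust to additive white measurement noise, since that noise inflates
#' only lag 0) and clipped to (0.5, 0.999). Degenerate traces (no usable
#' autocovariance, or a ratio outside (0, 1)) fall back to the default
#' gamma implied by a 0.5 s decay time constant and are flagged.
#'
#' @param F_mat Neurons x frames matrix, normally baseline-thresholded.
#' @param frame_rate_hz Frame rate, used for the fallback decay constant.
#' @param fallback_decay_s Decay time constant of the fallback kernel.
#' @return A list with `gamma` (per-neuron coefficient) and `fallback`
#'   (logical vector flagging neurons on the default kernel).
#' @export
fit_kernel <- function(F_mat, frame_rate_hz, fallback_decay_s = 0.5) {
  F_mat <- .as_fmatrix(F_mat)
  g_default <- exp(-1 / (fallback_decay_s * frame_rate_hz))
  n <- nrow(F_mat)
  gamma <- numeric(n)
  fallback <- logical(n)
  for (i in seq_len(n)) {
    x <- F_mat[i, ] - mean(F_mat[i, ])
    T_len <- length(x)
    if (T_len < 4 || stats::sd(x) == 0) {
      gamma[i] <- g_default; fallback[i] <- TRUE; next
    }
    ac1 <- sum(x[-1] * x[-T_len]) / T_len
    ac2 <- sum(x[-(1:2)] * x[1:(T_len - 2)]) / T_len
    g <- if (abs(ac1) < .Machine$double.eps) NA_real_ else ac2 / ac1
    if (!is.finite(g) || g <= 0 || g >= 1) {
      gamma[i] <- g_default; fallback[i] <- TRUE
    } else {
      gamma[i] <- min(max(g, 0.5 + 1e-6), 0.999)
    }
  }
  list(gamma = gamma, fallback = fallback)
}

#' AR(1) constrained sparse deconvolution (pool adjacent violators)
#'
#' Solves, independently per neuron, the nonnegative sparse deconvolution
#' problem
#' \deqn{\min_{s \ge 0} \tfrac12 \|F - c\|^2 + \lambda \|s\|_1, \quad
#'       c_t = \gamma c_{t-1} + s_t,}
#' by the online active-set / pool-adjacent-violators scheme: the L1 penalty
#' is absorbed into the target trace, each frame starts as its own pool, and
#' adjacent pools are merged whenever the decaying extrapolation of one pool
#' would overshoot the start of the next (a violated `s >= 0` constraint),
#' exactly as in isotonic regression.
#'
#' @param F_mat Neurons x frames matrix (baseline-thresholded).
#' @param gamma Per-neuron AR(1) coefficients in (0, 1) (recycled if scalar).
#' @param lambda Sparsity penalty per neuron (recycled). The package default
#'   used by [estimate_events()] is `v * sqrt(n_frames)`, scaling the penalty
#'   with the shot-noise level.
#' @return List with `s` (raw event matrix, `>= 0`) and `c` (fitted
#'   calcium trace matrix).
#' @export
deconvolve <- function(F_mat, gamma, lambda = 0) {
  F_mat <- .as_fmatrix(F_mat)
  n <- nrow(F_mat); T_len <- ncol(F_mat)
  gamma <- rep_len(gamma, n); lambda <- rep_len(lambda, n)
  if (any(gamma <= 0 | gamma >= 1)) stop("gamma must lie in (0, 1)")
  if (any(lambda < 0)) stop("lambda must be nonnegative")
  s <- matrix(0, n, T_len); cfit <- matrix(0, n, T_len)
  for (i in seq_len(n)) {
    ci <- .oasis_ar1(F_mat[i, ], gamma[i], lambda[i])
    cfit[i, ] <- ci
    s[i, ] <- c(ci[1], ci[-1] - gamma[i] * ci[-T_len])
  }
  s[s < 0 & s > -1e-12] <- 0   # clip numerical dust
  list(s = s, c = cfit)
}

## Single-trace OASIS AR(1) solver. The L1 term lambda*||s||_1 equals
## lambda * sum_t c_t (1 - gamma) + lambda * c_T * gamma (telescoping with
## s_t = c_t - gamma c_{t-1}), so subtracting mu_t = lambda(1-gamma)
## (mu_T = lambda) from y leaves an unpenalised isotone-type problem.
.oasis_ar1 <- function(y, g, lam) {
  T_len <- length(y)
  mu <- rep(lam * (1 - g), T_len); mu[T_len] <- lam
  yt <- y - mu
  ## pools: value v (c at pool start), weight w, start t, length l
  v <- numeric(T_len); w <- numeric(T_len)
  tstart <- integer(T_len); plen <- integer(T_len)
  np <- 0L
  for (t in seq_len(T_len)) {
    np <- np + 1L
    v[np] <- yt[t]; w[np] <- 1; tstart[np] <- t; plen[np] <- 1L
    while (np > 1L && v[np] < g^plen[np - 1L] * v[np - 1L]) {
      ## merge pool np into np-1
      gl <- g^plen[np - 1L]
      vm <- (w[np - 1L] * v[np - 1L] + gl * w[np] * v[np]) /
            (w[np - 1L] + gl^2 * w[np])
      w[np - 1L] <- w[np - 1L] + gl^2 * w[np]
      plen[np - 1L] <- plen[np - 1L] + plen[np]
      v[np - 1L] <- vm
      np <- np - 1L
    }
  }
  v[seq_len(np)] <- pmax(v[seq_len(np)], 0)
  cfit <- numeric(T_len)
  for (p in seq_len(np)) {
    idx <- tstart[p]:(tstart[p] + plen[p] - 1L)
    cfit[idx] <- v[p] * g^(seq_along(idx) - 1L)
  }
  cfit
}

#' Normalize raw events by the shot-noise level
#'
#' Divides each neuron's raw deconvolved events by its noise level `v`,
#' yielding the calcium event estimate \eqn{\hat s} in signal-to-noise
#' units. Neurons with `v = 0` are admissible only if their events are all
#' zero (the estimate is then all zero); otherwise the ratio is undefined.
#'
#' @param s Raw event matrix (neurons x frames, nonnegative).
#' @param v Per-neuron noise vector from [estimate_noise()].
#' @return Event-estimate matrix `s_hat`, nonnegative.
#' @export
normalize_events <- function(s, v) {
  s <- .as_fmatrix(s)
  stopifnot(length(v) == nrow(s), all(v >= 0))
  zero_v <- v == 0
  if (any(zero_v & rowSums(s != 0) > 0))
    stop("zero noise level with nonzero events: s_hat undefined")
  out <- s / ifelse(zero_v, 1, v)
  out
}

#' Full calcium event estimation chain
#'
#' Baseline thresholding, shot-noise measurement, AR(1) kernel fit,
#' OASIS-style deconvolution and signal-to-noise normalisation in one call.
#'
#' @param F_mat Neurons x frames raw fluorescence.
#' @param frame_rate_hz Frame rate in Hz.
#' @param lambda `"auto"` for the noise-scaled default `v * sqrt(n_frames)`,
#'   or a numeric penalty (recycled per neuron).
#' @param gamma Optional fixed AR(1) coefficient(s); fitted when `NULL`.
#' @return A list of class `event_matrix`: `s_hat`, raw `s`, fitted `c`,
#'   `v`, `kernel` (fit_kernel output), `lambda`, `frame_rate_hz`.
#' @export
estimate_events <- function(F_mat, frame_rate_hz, lambda = "auto", gamma = NULL) {
  F_mat <- .as_fmatrix(F_mat)
  Fth <- threshold_baseline(F_mat)
  v <- estimate_noise(Fth, frame_rate_hz)
  kern <- if (is.null(gamma)) {
    fit_kernel(Fth, frame_rate_hz)
  } else {
    list(gamma = rep_len(gamma, nrow(Fth)), fallback = rep(FALSE, nrow(Fth)))
  }
  lam <- if (identical(lambda, "auto")) v * sqrt(ncol(Fth)) else rep_len(lambda, nrow(Fth))
  ## deconvolve the baseline-subtracted trace so pools start near zero
  base <- apply(Fth, 1, stats::quantile, probs = 0.10, names = FALSE)
  dec <- deconvolve(Fth - base, kern$gamma, lam)
  structure(list(s_hat = normalize_events(dec$s, v), s = dec$s, c = dec$c,
                 v = v, kernel = kern, lambda = lam,
                 frame_rate_hz = frame_rate_hz),
            class = "event_matrix")
}

## coerce to a numeric matrix with neurons on rows
.as_fmatrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!all(is.finite(x))) stop("fluorescence values must be finite")
  x
}
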