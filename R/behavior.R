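#' Signal-detection sensitivity (d-prime) from hit and false-alarm rates
#'
#' Computes `d' = qnorm(HR) - qnorm(FAR)` for a go/no-go discrimination.
#' Degenerate rates of exactly 0 or 1 are undefined under the inverse-normal
#' transform; when trial counts are supplied, rates are clamped to
#' `[1/(2N), 1 - 1/(2N)]` (the standard half-count correction) before the
#' transform. Without counts, rates are clamped to `[1e-6, 1 - 1e-6]`.
#'
#' Under a symmetric criterion (HR = 1 - FAR), 80% correct corresponds to
#' d' of about 1.68 and 70% correct to about 1.05.
#'
#' @param hit_rate Hit rate on no-match (go) trials, in `[0, 1]`.
#' @param fa_rate False-alarm rate on match (no-go) trials, in `[0, 1]`.
#' @param n_go,n_nogo Optional trial counts used for rate clamping.
#' @return d-prime, a scalar.
#' @examples
#' dprime(0.8, 0.2)   # ~1.68
#' dprime(0.7, 0.3)   # ~1.05
#' @export
dprime <- function(hit_rate, fa_rate, n_go = NULL, n_nogo = NULL) {
  stopifnot(hit_rate >= 0, hit_rate <= 1, fa_rate >= 0, fa_rate <= 1)
  clamp <- function(r, n) {
    lo <- if (is.null(n)) 1e-6 else 1 / (2 * n)
    min(max(r, lo), 1 - lo)
  }
  stats::qnorm(clamp(hit_rate, n_go)) - stats::qnorm(clamp(fa_rate, n_nogo))
}

#' d-prime of a completed trial table
#'
#' @param trials A trial table with filled `outcome` column
#'   (`hit`/`miss`/`FA`/`CR`).
#' @return d-prime computed from empirical hit and false-alarm rates, with
#'   half-count clamping.
#' @export
dprime_trials <- function(trials) {
  n_go <- sum(trials$category == "nonmatch")
  n_nogo <- sum(trials$category == "match")
  if (n_go == 0 || n_nogo == 0) stop("need both match and nonmatch trials")
  hr <- sum(trials$outcome == "hit") / n_go
  far <- sum(trials$outcome == "FA") / n_nogo
  dprime(hr, far, n_go, n_nogo)
}

#' Stage-advancement decision
#'
#' A training stage is completed when session d-prime exceeds the stage's
#' threshold for a required number of consecutive sessions (default two):
#' 0.45 for the naive stage T1 and 1.68 for the learned stages T2 onward.
#'
#' @param dprime_history Numeric vector of per-session d-primes, oldest first.
#' @param stage Stage id, `"T1"`..`"T5"`.
#' @param thresholds Named vector of advancement thresholds per stage.
#' @param n_consecutive Number of consecutive criterion sessions required.
#' @return `TRUE` if the advancement criterion is met.
#' @export
stage_advance <- function(dprime_history, stage,
                          thresholds = c(T1 = 0.45, T2 = 1.68, T3 = 1.68,
                                         T4 = 1.68, T5 = Inf),
                          n_consecutive = 2L) {
  stopifnot(length(dprime_history) >= 1, stage %in% names(thresholds))
  if (length(dprime_history) < n_consecutive) return(FALSE)
  tail_d <- utils::tail(dprime_history, n_consecutive)
  all(tail_d > thresholds[[stage]])
}

#' Initial adaptive-training state
#'
#' @return A `bias_state` list: `timeout_s` (2-10 s), `airpuffs` (0-5),
#'   `p_nonmatch`, `p_within_nonmatch` (probability of AP among nonmatch),
#'   `p_within_match` (probability of AA among match).
#' @export
bias_state <- function() {
  structure(list(timeout_s = 2, airpuffs = 0,
                 p_nonmatch = 0.5, p_within_nonmatch = 0.5,
                 p_within_match = 0.5),
            class = "bias_state")
}

#' Adaptive punishment and stimulus-probability update
#'
#' Applies the automated correct-choice reinforcement rules to the current
#' training state, given recent trial history:
#'
#' * Punishment (50-trial window): below 70% correct (d' ~ 1.05) increases
#'   the timeout by 1 s (10 s max) and, once the timeout exceeds 7 s, adds
#'   one air puff (5 max). More than 50% misses decreases the timeout by 2 s
#'   and removes 2 air puffs (floored at the 2 s / 0 minima).
#' * Report bias (20-trial window): with X the fraction of trials on the
#'   favored (licked) report and Y on the neglected one, X - Y > 0.25 moves
#'   the nonmatch/match split to 0.35/0.65 in favor of the neglected
#'   response; X - Y > 0.5 moves it to 0.2/0.8.
#' * Primacy/recency bias (20-trial window): within nonmatch (and match)
#'   conditions, with X the fraction correct on the favored stimulus and Y
#'   on the neglected one, moderate bias shifts the within-category split to
#'   0.4/0.6 and severe bias to 0.3/0.7 (favored/neglected). The printed
#'   criterion is literally `(X/Y - 0.5) > 0.55` (moderate) and `> 0.6`
#'   (severe); `mode = "difference"` instead uses `X - Y` against the same
#'   cutoffs, in case the printed ratio form is a typo.
#'
#' Windows shorter than required leave the corresponding rule untouched,
#' with a warning.
#'
#' @param trials Recent trial table (outcomes filled), most recent last.
#' @param state A `bias_state`.
#' @param mode `"literal"` (ratio form, default) or `"difference"` for the
#'   primacy/recency criterion.
#' @return Updated `bias_state`.
#' @export
bias_update <- function(trials, state, mode = c("literal", "difference")) {
  mode <- match.arg(mode)
  st <- state

  ## punishment: 50-trial sliding window
  if (nrow(trials) >= 50) {
    w <- utils::tail(trials, 50)
    correct <- mean(w$outcome %in% c("hit", "CR"))
    miss_frac <- mean(w$outcome == "miss")
    if (miss_frac > 0.5) {
      st$timeout_s <- max(2, st$timeout_s - 2)
      st$airpuffs <- max(0, st$airpuffs - 2)
    } else if (correct < 0.7) {
      st$timeout_s <- min(10, st$timeout_s + 1)
      if (st$timeout_s > 7) st$airpuffs <- min(5, st$airpuffs + 1)
    }
  } else {
    warning("punishment window (<50 trials) unavailable; rule skipped")
  }

  ## bias rules: 20-trial sliding window
  if (nrow(trials) >= 20) {
    w <- utils::tail(trials, 20)
    ## report bias: favored report = lick (hit+FA) vs no-lick (miss+CR)
    licked <- mean(w$outcome %in% c("hit", "FA"))
    x <- max(licked, 1 - licked); y <- 1 - x
    lick_favored <- licked >= 0.5
    if (x - y > 0.5) {
      ## severe: 0.2 toward the favored-report category, 0.8 the other
      st$p_nonmatch <- if (lick_favored) 0.2 else 0.8
    } else if (x - y > 0.25) {
      st$p_nonmatch <- if (lick_favored) 0.35 else 0.65
    }
    ## primacy/recency within nonmatch and within match
    st$p_within_nonmatch <- .within_bias(w, c("AP", "PA"), st$p_within_nonmatch, mode)
    st$p_within_match <- .within_bias(w, c("AA", "PP"), st$p_within_match, mode)
  } else {
    warning("bias window (<20 trials) unavailable; rules skipped")
  }
  st
}

## within-category stimulus-probability adjustment (Table-3 primacy/recency)
.within_bias <- function(w, conds, p_first, mode) {
  cond <- paste0(w$sample_dir, w$test_dir)
  ok <- w$outcome %in% c("hit", "CR")
  n1 <- sum(cond == conds[1]); n2 <- sum(cond == conds[2])
  if (n1 == 0 || n2 == 0) return(p_first)
  c1 <- sum(ok[cond == conds[1]]) / n1
  c2 <- sum(ok[cond == conds[2]]) / n2
  x <- max(c1, c2); y <- min(c1, c2)
  stat <- if (mode == "literal") {
    if (y == 0) Inf else x / y - 0.5
  } else x - y
  new_split <- if (stat > 0.6) 0.3 else if (stat > 0.55) 0.4 else return(p_first)
  ## favored condition (higher % correct) gets the smaller share
  if (c1 >= c2) new_split else 1 - new_split
}
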