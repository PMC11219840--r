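#' Stage configuration for the head-fixed DNMS task
#'
#' Returns the per-stage task settings of the five-stage training course:
#' nonmatch/match stimulus split (with the optional T1 ramp from 0.9/0.1 to
#' 0.5/0.5 over the first five sessions), whether the held-out
#' posterior-anterior (PA) nonmatch condition is in the stimulus set (T3
#' onward), the fast/slow speed split (95/5 through T4, 75/25 at T5), the
#' delay options (100 ms through T3, 2 s at T4, and the 2/3/4 s mixture with
#' probabilities 0.5/0.25/0.25 at T5), and a default behavioral sensitivity
#' for the stage.
#'
#' Trial-period durations are not part of the task tables; the defaults are
#' pre-stimulus 1.0 s, sample 1.0 s, test 1.0 s, report 1.5 s and a 1.0 s
#' post-trial interval at a 32.6 Hz frame rate, all configurable.
#'
#' @param stage Stage id, one of `"T1"`..`"T5"`.
#' @param session_index Session number within the stage (drives the T1 ramp).
#' @param ramp_T1 Ramp the T1 nonmatch probability 0.9 to 0.5 over 5 sessions.
#' @param frame_rate_hz Imaging frame rate.
#' @return A `stage_config` list.
#' @export
stage_config <- function(stage = c("T1", "T2", "T3", "T4", "T5"),
                         session_index = 1L, ramp_T1 = TRUE,
                         frame_rate_hz = 32.6) {
  stage <- match.arg(stage)
  p_nm <- 0.5
  if (stage == "T1" && ramp_T1) {
    ramp <- seq(0.9, 0.5, length.out = 5)
    p_nm <- ramp[min(session_index, 5L)]
  }
  delay <- switch(stage,
    T1 = , T2 = , T3 = list(ms = 100, p = 1),
    T4 = list(ms = 2000, p = 1),
    T5 = list(ms = c(2000, 3000, 4000), p = c(0.5, 0.25, 0.25)))
  cfg <- list(
    stage_id = stage,
    session_index = as.integer(session_index),
    p_nonmatch = p_nm,
    include_PA = stage %in% c("T3", "T4", "T5"),
    p_slow = if (stage == "T5") 0.25 else 0.05,
    delay_options_ms = delay,
    frame_rate_hz = frame_rate_hz,
    period_durations_s = c(pre_stim = 1.0, sample = 1.0, test = 1.0,
                           report = 1.5, post = 1.0),
    behavioral_dprime = switch(stage, T1 = 0.45, T2 = 1.05, 1.68))
  validate_stage_config(cfg)
  structure(cfg, class = "stage_config")
}

#' @rdname stage_config
#' @param cfg A stage configuration list.
#' @export
validate_stage_config <- function(cfg) {
  probs <- c(cfg$p_nonmatch, cfg$p_slow, cfg$delay_options_ms$p)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("stage_config: probabilities must lie in [0, 1]")
  if (abs(sum(cfg$delay_options_ms$p) - 1) > 1e-8)
    stop("stage_config: delay probabilities must sum to 1")
  if (cfg$frame_rate_hz <= 0) stop("stage_config: frame rate must be positive")
  invisible(cfg)
}

#' Generate a stage-structured trial schedule
#'
#' Draws trial conditions from the stage configuration: category
#' (nonmatch/match), the direction pair (AP and, from T3, PA for nonmatch;
#' AA/PP for match), rotor speed (fast/slow) and the sample-test delay.
#' Period frame windows (half-open, 0-based `[start, end)`) are laid out
#' contiguously per trial — pre-stimulus, sample, delay, test, report,
#' post-trial — and trials are concatenated in session time.
#'
#' @param cfg A [stage_config()].
#' @param n_trials Number of trials (`0` yields an empty, valid table).
#' @param seed Integer seed; the schedule is bit-reproducible.
#' @return A `data.frame` trial table. `lick_frames` is a list column,
#'   empty until [simulate_licks()].
#' @export
generate_trial_schedule <- function(cfg, n_trials, seed = 1L) {
  validate_stage_config(cfg)
  stopifnot(n_trials >= 0)
  cols <- c("trial_id", "session_index", "stage", "sample_dir", "test_dir",
            "speed", "category", "delay_ms", "outcome")
  if (n_trials == 0) {
    tab <- data.frame(trial_id = integer(), session_index = integer(),
                      stage = character(), sample_dir = character(),
                      test_dir = character(), speed = character(),
                      category = character(), delay_ms = numeric(),
                      outcome = character(), stringsAsFactors = FALSE)
    for (p in c("pre_stim", "sample", "delay", "test", "report", "post")) {
      tab[[paste0(p, "_start")]] <- integer()
      tab[[paste0(p, "_end")]] <- integer()
    }
    tab$reward_frame <- integer()
    tab$lick_frames <- I(list())
    return(tab)
  }
  rng <- .local_rng(seed)
  category <- ifelse(rng$runif(n_trials) < cfg$p_nonmatch, "nonmatch", "match")
  nm_pair <- if (cfg$include_PA) {
    ifelse(rng$runif(n_trials) < 0.5, "AP", "PA")
  } else rep("AP", n_trials)
  m_pair <- ifelse(rng$runif(n_trials) < 0.5, "AA", "PP")
  pair <- ifelse(category == "nonmatch", nm_pair, m_pair)
  speed <- ifelse(rng$runif(n_trials) < cfg$p_slow, "slow", "fast")
  d_idx <- rng$sample_int(length(cfg$delay_options_ms$ms), n_trials,
                          prob = cfg$delay_options_ms$p)
  delay_ms <- cfg$delay_options_ms$ms[d_idx]

  fr <- cfg$frame_rate_hz
  dur <- cfg$period_durations_s
  nf <- function(s) as.integer(floor(s * fr))
  pre_n <- nf(dur["pre_stim"]); sam_n <- nf(dur["sample"])
  tst_n <- nf(dur["test"]); rep_n <- nf(dur["report"]); post_n <- nf(dur["post"])
  del_n <- vapply(delay_ms / 1000, nf, integer(1))

  tab <- data.frame(
    trial_id = seq_len(n_trials), session_index = cfg$session_index,
    stage = cfg$stage_id,
    sample_dir = substr(pair, 1, 1), test_dir = substr(pair, 2, 2),
    speed = speed, category = category, delay_ms = delay_ms,
    outcome = NA_character_, stringsAsFactors = FALSE)

  len <- pre_n + sam_n + del_n + tst_n + rep_n + post_n
  t0 <- c(0L, cumsum(len)[-n_trials])
  tab$pre_stim_start <- t0;                tab$pre_stim_end <- t0 + pre_n
  tab$sample_start <- tab$pre_stim_end;    tab$sample_end <- tab$sample_start + sam_n
  tab$delay_start <- tab$sample_end;       tab$delay_end <- tab$delay_start + del_n
  tab$test_start <- tab$delay_end;         tab$test_end <- tab$test_start + tst_n
  tab$report_start <- tab$test_end;        tab$report_end <- tab$report_start + rep_n
  tab$post_start <- tab$report_end;        tab$post_end <- tab$post_start + post_n
  tab$reward_frame <- NA_integer_
  tab$lick_frames <- I(vector("list", n_trials))
  attr(tab, "frame_rate_hz") <- fr
  attr(tab, "n_frames") <- sum(len)
  tab
}

#' Simulate go/no-go choices at a target sensitivity
#'
#' Fills trial outcomes with a symmetric-criterion observer: the lick (go)
#' probability is `pnorm(d'/2)` on nonmatch trials (hits vs. misses) and
#' `pnorm(-d'/2)` on match trials (false alarms vs. correct rejections), so
#' hit rate and correct-rejection rate coincide and the empirical d-prime
#' recovers the input. d' of 1.68 corresponds to about 80% correct and
#' 1.05 to about 70%.
#'
#' @param trials Trial table from [generate_trial_schedule()].
#' @param dprime Target sensitivity, `>= 0`.
#' @param seed Integer seed.
#' @return The trial table with `outcome` filled.
#' @export
simulate_choices <- function(trials, dprime, seed = 1L) {
  stopifnot(dprime >= 0)
  n <- nrow(trials)
  if (n == 0) return(trials)
  rng <- .local_rng(seed)
  go <- rng$runif(n) < ifelse(trials$category == "nonmatch",
                              stats::pnorm(dprime / 2),
                              stats::pnorm(-dprime / 2))
  trials$outcome <- ifelse(trials$category == "nonmatch",
                           ifelse(go, "hit", "miss"),
                           ifelse(go, "FA", "CR"))
  trials
}

#' Simulate lick trains and reward times
#'
#' Licking is a baseline Poisson train whose rate outside the report period
#' decreases over training stages (licking becomes restricted to the
#' reporting period as the task is learned), plus a report-period go burst
#' on hit and false-alarm trials. On hit trials the water reward is
#' delivered at the first report-period lick, which is always present; the
#' burst continues through reward consumption.
#'
#' @param trials Trial table with outcomes filled.
#' @param stage Stage id, sets the out-of-report baseline rate.
#' @param seed Integer seed.
#' @param base_rate_hz Optional named override of the per-stage baseline
#'   lick rate (Hz) outside the report period.
#' @param burst_rate_hz Report-period lick rate on go trials.
#' @return Trial table with `lick_frames` and `reward_frame` filled.
#' @export
simulate_licks <- function(trials, stage = trials$stage[1], seed = 1L,
                           base_rate_hz = NULL, burst_rate_hz = 7) {
  if (nrow(trials) == 0) return(trials)
  if (any(is.na(trials$outcome))) stop("outcomes must be filled first")
  fr <- attr(trials, "frame_rate_hz")
  rates <- c(T1 = 1.5, T2 = 1.0, T3 = 0.6, T4 = 0.35, T5 = 0.2)
  base <- if (is.null(base_rate_hz)) rates[[stage]] else base_rate_hz
  rng <- .local_rng(seed)
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    out_frames <- setdiff(tr$pre_stim_start:(tr$post_end - 1L),
                          tr$report_start:(tr$report_end - 1L))
    licks <- out_frames[rng$runif(length(out_frames)) < base / fr]
    go <- tr$outcome %in% c("hit", "FA")
    rep_frames <- tr$report_start:(tr$report_end - 1L)
    if (go) {
      burst <- rep_frames[rng$runif(length(rep_frames)) < burst_rate_hz / fr]
      if (length(burst) == 0) burst <- rep_frames[1]
      licks <- c(licks, burst)
      if (tr$outcome == "hit") trials$reward_frame[i] <- min(burst)
    } else {
      ## withheld licking: rare baseline-level stray licks only
      stray <- rep_frames[rng$runif(length(rep_frames)) < 0.25 * base / fr]
      licks <- c(licks, stray)
    }
    trials$lick_frames[[i]] <- sort(unique(as.integer(licks)))
  }
  trials
}

#' Planted population effects
#'
#' Parameters of the synthetic population: cell-type fractions, per-stage
#' gains shaping the planted signals, calcium-kernel and noise settings.
#' The defaults emulate the learning trajectory the analyses are designed
#' to detect: direction coding on correct trials decays to nothing by T5
#' (but is retained at the naive gain on error trials), speed coding grows
#' with learning and acquires an error-trial bias after T1, the
#' reward-locked signal starts at the reward and leads it by progressively
#' more seconds across stages (retrograde expansion), and expected-outcome
#' cells carry a weak pre-stimulus offset by future outcome whose preferred
#' class reverses in the report window.
#'
#' @param n_neurons Population size.
#' @param frac_direction,frac_speed,frac_reward,frac_expected Cell-type
#'   proportions (sum `<= 1`; the remainder is untuned).
#' @param direction_gain_by_stage,speed_gain_by_stage Named per-stage gains.
#' @param speed_error_bias Extra speed-cell gain on error trials, applied
#'   from T2 onward.
#' @param reward_onset_lead_s_by_stage Seconds the reward signal precedes
#'   reward delivery, per stage (non-decreasing by default).
#' @param reward_ap_pa_overlap Alignment of the reward code across the two
#'   nonmatch conditions: `1` (default) plants one shared code (every reward
#'   cell responds on all hit trials), `0` plants disjoint AP- and PA-specific
#'   subspaces, intermediate values interpolate the off-condition gain.
#' @param expected_gain Gain of the expected-outcome offset.
#' @param expected_sign_flip Reverse the preferred outcome class at report.
#' @param spike_baseline_hz Baseline firing rate of every neuron.
#' @param bump_rate_hz Rate increase at gain 1.
#' @param kernel_decay_s Calcium-kernel decay time constant.
#' @param photon_noise_sd SD of additive Gaussian fluorescence noise.
#' @param seed Master seed, split deterministically per neuron.
#' @return A `planted_effects` list.
#' @export
planted_effects <- function(n_neurons = 60,
                            frac_direction = 0.25, frac_speed = 0.25,
                            frac_reward = 0.20, frac_expected = 0.15,
                            direction_gain_by_stage =
                              c(T1 = 1, T2 = 0.75, T3 = 0.5, T4 = 0.25, T5 = 0),
                            speed_gain_by_stage =
                              c(T1 = 0.2, T2 = 0.4, T3 = 0.6, T4 = 0.8, T5 = 1),
                            speed_error_bias = 0.75,
                            reward_onset_lead_s_by_stage =
                              c(T1 = 0, T2 = 0.4, T3 = 0.8, T4 = 1.2, T5 = 1.6),
                            reward_ap_pa_overlap = 1,
                            expected_gain = 0.6,
                            expected_sign_flip = TRUE,
                            spike_baseline_hz = 0.4,
                            bump_rate_hz = 4,
                            kernel_decay_s = 0.5,
                            photon_noise_sd = 0.1,
                            seed = 1L) {
  fx <- list(n_neurons = as.integer(n_neurons),
             frac_direction = frac_direction, frac_speed = frac_speed,
             frac_reward = frac_reward, frac_expected = frac_expected,
             direction_gain_by_stage = direction_gain_by_stage,
             speed_gain_by_stage = speed_gain_by_stage,
             speed_error_bias = speed_error_bias,
             reward_onset_lead_s_by_stage = reward_onset_lead_s_by_stage,
             reward_ap_pa_overlap = reward_ap_pa_overlap,
             expected_gain = expected_gain,
             expected_sign_flip = expected_sign_flip,
             spike_baseline_hz = spike_baseline_hz,
             bump_rate_hz = bump_rate_hz,
             kernel_decay_s = kernel_decay_s,
             photon_noise_sd = photon_noise_sd,
             seed = as.integer(seed))
  gains <- c(fx$direction_gain_by_stage, fx$speed_gain_by_stage,
             fx$reward_onset_lead_s_by_stage, fx$expected_gain,
             fx$speed_error_bias)
  if (any(gains < 0)) stop("planted gains must be nonnegative")
  fracs <- c(frac_direction, frac_speed, frac_reward, frac_expected)
  if (any(fracs < 0) || sum(fracs) > 1 + 1e-9)
    stop("cell-type proportions must be nonnegative and sum to at most 1")
  structure(fx, class = "planted_effects")
}

#' Cell-type assignment implied by planted effects
#'
#' @param fx A [planted_effects()] list.
#' @return Character vector of length `n_neurons` with entries in
#'   `direction`, `speed`, `reward`, `expected`, `untuned`, plus a
#'   `pref` attribute carrying each tuned cell's preferred condition.
#' @export
cell_types <- function(fx) {
  n <- fx$n_neurons
  ## per-index low-discrepancy assignment: neuron i's type never depends on
  ## the population size, so enlarging the population leaves existing
  ## neurons (and their RNG streams) untouched; realised proportions track
  ## the requested fractions to within O(1/n)
  cuts <- cumsum(c(fx$frac_direction, fx$frac_speed, fx$frac_reward,
                   fx$frac_expected))
  u <- (seq_len(n) * 0.6180339887498949) %% 1
  types <- c("direction", "speed", "reward", "expected",
             "untuned")[findInterval(u, cuts) + 1L]
  ## fixed preferred conditions, alternating within type
  pref <- character(n)
  for (ty in c("direction", "speed")) {
    idx <- which(types == ty)
    opts <- if (ty == "direction") c("A", "P") else c("slow", "fast")
    pref[idx] <- opts[1 + (seq_along(idx) %% 2)]
  }
  ## reward cells alternate an AP/PA condition assignment, used only when
  ## the reward code is not fully shared across nonmatch conditions
  idx <- which(types == "reward")
  pref[idx] <- c("AP", "PA")[1 + (seq_along(idx) %% 2)]
  pref[types == "expected"] <- "hit"
  attr(types, "pref") <- pref
  types
}

#' Simulate a synthetic neural population for a trial table
#'
#' Spike counts are Poisson per frame: a baseline rate plus
#' condition-dependent rate bumps whose placement and per-stage gains are
#' defined by [planted_effects()]. Direction cells respond during the
#' sample and test windows of their preferred direction, scaled by the
#' stage gain on correct trials and by the naive (T1) gain on error trials.
#' Speed cells respond during sample and test on their preferred speed,
#' with gain growing across stages and an extra error-trial bias after T1.
#' Reward cells respond on hit trials from `reward_frame - lead` to the end
#' of the report window. Expected-outcome cells carry a weak pre-stimulus
#' rate offset for future-hit trials, and (when `expected_sign_flip`) the
#' preferred class reverses to non-hit in the report window.
#' Fluorescence is the AR(1) convolution of the spikes plus additive
#' Gaussian photon noise on a unit baseline.
#'
#' Each neuron uses an independent RNG stream derived from the master seed,
#' so enlarging the population does not perturb existing neurons.
#'
#' @param trials Trial table with outcomes and licks filled.
#' @param fx A [planted_effects()] list.
#' @return A `session_bundle` list: `trials`, `F` (fluorescence),
#'   `spikes` (ground truth), `ach` (`NULL` until [simulate_ach()]),
#'   `effects`, `cell_type`, `frame_rate_hz`.
#' @export
simulate_population <- function(trials, fx = planted_effects()) {
  if (any(is.na(trials$outcome))) stop("outcomes must be filled first")
  fr <- attr(trials, "frame_rate_hz")
  n_frames <- attr(trials, "n_frames")
  if (is.null(n_frames)) stop("trial table lacks frame sizing attributes")
  stage <- trials$stage[1]
  types <- cell_types(fx)
  pref <- attr(types, "pref")
  g_dir <- fx$direction_gain_by_stage[[stage]]
  g_dir_naive <- fx$direction_gain_by_stage[["T1"]]
  g_spd <- fx$speed_gain_by_stage[[stage]]
  lead_n <- as.integer(round(fx$reward_onset_lead_s_by_stage[[stage]] * fr))
  gamma <- exp(-1 / (fx$kernel_decay_s * fr))
  correct <- trials$outcome %in% c("hit", "CR")

  spikes <- matrix(0L, fx$n_neurons, n_frames)
  F_mat <- matrix(0, fx$n_neurons, n_frames)
  for (j in seq_len(fx$n_neurons)) {
    rng <- .local_rng(.split_seed(fx$seed, j))
    rate <- rep(fx$spike_baseline_hz, n_frames)
    ty <- types[j]
    for (i in seq_len(nrow(trials))) {
      tr <- trials[i, ]
      if (ty == "direction") {
        g <- if (correct[i]) g_dir else g_dir_naive
        if (g > 0) {
          if (tr$sample_dir == pref[j])
            rate[(tr$sample_start + 1L):tr$sample_end] <-
              rate[(tr$sample_start + 1L):tr$sample_end] + g * fx$bump_rate_hz
          if (tr$test_dir == pref[j])
            rate[(tr$test_start + 1L):tr$test_end] <-
              rate[(tr$test_start + 1L):tr$test_end] + g * fx$bump_rate_hz
        }
      } else if (ty == "speed") {
        g <- g_spd
        if (!correct[i] && stage != "T1") g <- g * (1 + fx$speed_error_bias)
        if (tr$speed == pref[j] && g > 0) {
          idx <- c((tr$sample_start + 1L):tr$sample_end,
                   (tr$test_start + 1L):tr$test_end)
          rate[idx] <- rate[idx] + g * fx$bump_rate_hz
        }
      } else if (ty == "reward") {
        if (tr$outcome == "hit" && !is.na(tr$reward_frame)) {
          ov <- if (is.null(fx$reward_ap_pa_overlap)) 1 else fx$reward_ap_pa_overlap
          cond <- paste0(tr$sample_dir, tr$test_dir)
          g <- if (cond == pref[j]) 1 else ov
          if (g > 0) {
            from <- max(tr$pre_stim_start + 1L, tr$reward_frame + 1L - lead_n)
            rate[from:tr$report_end] <- rate[from:tr$report_end] +
              g * fx$bump_rate_hz
          }
        }
      } else if (ty == "expected") {
        is_hit <- tr$outcome == "hit"
        if (is_hit)
          rate[(tr$pre_stim_start + 1L):tr$pre_stim_end] <-
            rate[(tr$pre_stim_start + 1L):tr$pre_stim_end] +
            fx$expected_gain * fx$bump_rate_hz
        flip_pref_hit <- !fx$expected_sign_flip
        if (is_hit == flip_pref_hit)
          rate[(tr$report_start + 1L):tr$report_end] <-
            rate[(tr$report_start + 1L):tr$report_end] +
            fx$expected_gain * fx$bump_rate_hz
      }
    }
    sp <- rng$rpois(n_frames, rate / fr)
    spikes[j, ] <- sp
    cal <- stats::filter(sp, gamma, method = "recursive")
    F_mat[j, ] <- 1 + as.numeric(cal) + rng$rnorm(n_frames, 0, fx$photon_noise_sd)
  }
  structure(list(trials = trials, F = F_mat, spikes = spikes, ach = NULL,
                 effects = fx, cell_type = types, frame_rate_hz = fr),
            class = "session_bundle")
}

#' Simulate a bulk acetylcholine trace
#'
#' The trace is the sum of a pre-stimulus transient present on every trial,
#' a lick-locked component driven only by pre-reward licks (licking before
#' reward delivery; on non-hit trials all licks count), and Gaussian noise.
#' There is deliberately no component locked to reward consumption. The
#' trace is z-scored per trial, as bulk cholinergic fluorescence is in the
#' analysis chain.
#'
#' @param trials Trial table with licks filled.
#' @param seed Integer seed.
#' @param amp_pre Amplitude of the pre-stimulus transient.
#' @param amp_lick Amplitude per pre-reward lick impulse.
#' @param noise_sd Additive noise SD before z-scoring.
#' @return Numeric vector of length `n_frames`.
#' @export
simulate_ach <- function(trials, seed = 1L, amp_pre = 1.5, amp_lick = 1.0,
                         noise_sd = 0.4) {
  n_frames <- attr(trials, "n_frames")
  fr <- attr(trials, "frame_rate_hz")
  rng <- .local_rng(seed)
  tr_sig <- numeric(n_frames)
  lick_imp <- numeric(n_frames)
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    tr_sig[(tr$pre_stim_start + 1L):tr$pre_stim_end] <- amp_pre
    licks <- trials$lick_frames[[i]]
    if (tr$outcome == "hit" && !is.na(tr$reward_frame))
      licks <- licks[licks < tr$reward_frame]
    lick_imp[licks + 1L] <- lick_imp[licks + 1L] + amp_lick
  }
  kern <- stats::dnorm(seq(-4.5, 4.5), 0, 2); kern <- kern / sum(kern)
  lick_sig <- .conv_same(lick_imp, kern)
  ach <- tr_sig + lick_sig + rng$rnorm(n_frames, 0, noise_sd)
  ## z-score per trial over the trial's own frames
  for (i in seq_len(nrow(trials))) {
    idx <- (trials$pre_stim_start[i] + 1L):trials$post_end[i]
    ach[idx] <- (ach[idx] - mean(ach[idx])) / stats::sd(ach[idx])
  }
  ach
}

#' Simulate a complete session
#'
#' Convenience wrapper chaining schedule, choices, licks, population and
#' acetylcholine generation with deterministically split seeds.
#'
#' @param cfg A [stage_config()].
#' @param n_trials Number of trials.
#' @param fx A [planted_effects()] list (its `seed` is overridden).
#' @param seed Master seed for the session.
#' @param dprime Behavioral sensitivity; defaults to the stage's.
#' @return A `session_bundle` with `ach` filled.
#' @export
simulate_session <- function(cfg, n_trials, fx = planted_effects(), seed = 1L,
                             dprime = cfg$behavioral_dprime) {
  tab <- generate_trial_schedule(cfg, n_trials, seed = .split_seed(seed, 1))
  tab <- simulate_choices(tab, dprime, seed = .split_seed(seed, 2))
  tab <- simulate_licks(tab, cfg$stage_id, seed = .split_seed(seed, 3))
  fx$seed <- .split_seed(seed, 4)
  bundle <- simulate_population(tab, fx)
  bundle$ach <- simulate_ach(tab, seed = .split_seed(seed, 5))
  bundle
}

## ---- internal RNG plumbing -------------------------------------------------

## A private RNG stream that never touches the global .Random.seed.
.local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  local_do <- function(fn) {
    force(fn)
    function(...) {
      old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
      on.exit({
        if (is.null(old)) {
          if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
      })
      if (is.null(env$state)) set.seed(seed) else
        assign(".Random.seed", env$state, envir = globalenv())
      out <- fn(...)
      env$state <- get(".Random.seed", globalenv())
      out
    }
  }
  list(runif = local_do(stats::runif),
       rnorm = local_do(stats::rnorm),
       rpois = local_do(stats::rpois),
       sample_int = local_do(function(n, size, prob = NULL)
         sample.int(n, size, replace = TRUE, prob = prob)),
       sample_perm = local_do(function(n) sample.int(n, n, replace = FALSE)))
}

## deterministic 32-bit seed splitting (stays below 2^31)
.split_seed <- function(seed, k) {
  s <- (as.double(seed) * 48271 + as.double(k) * 30269) %% 2147483647
  as.integer(s)
}

## linear convolution truncated to the input length, kernel centered
.conv_same <- function(x, kern) {
  full <- stats::convolve(x, rev(kern), type = "open")
  off <- (length(kern) - 1L) %/% 2L
  full[(off + 1L):(off + length(x))]
}
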