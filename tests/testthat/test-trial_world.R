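test_that("schedules match stage probabilities within 3 binomial SDs", {
  n <- 10000
  ## T4: slow fraction ~ 5%
  tab <- generate_trial_schedule(stage_config("T4"), n, seed = 11)
  p <- mean(tab$speed == "slow")
  expect_lt(abs(p - 0.05), 3 * sqrt(0.05 * 0.95 / n))
  ## T5: delay mixture 2/3/4 s with probabilities .5/.25/.25, slow 25%
  tab5 <- generate_trial_schedule(stage_config("T5"), n, seed = 12)
  h <- table(tab5$delay_ms) / n
  expect_lt(abs(h[["2000"]] - 0.50), 3 * sqrt(0.25 / n))
  expect_lt(abs(h[["3000"]] - 0.25), 3 * sqrt(0.25 * 0.75 / n))
  expect_lt(abs(h[["4000"]] - 0.25), 3 * sqrt(0.25 * 0.75 / n))
  expect_lt(abs(mean(tab5$speed == "slow") - 0.25), 3 * sqrt(0.25 * 0.75 / n))
  ## nonmatch share ~ 50% outside the T1 ramp
  expect_lt(abs(mean(tab$category == "nonmatch") - 0.5), 3 * sqrt(0.25 / n))
})

test_that("PA trials appear only from T3 and the T1 ramp follows the table", {
  tab2 <- generate_trial_schedule(stage_config("T2"), 2000, seed = 13)
  pair2 <- paste0(tab2$sample_dir, tab2$test_dir)
  expect_false("PA" %in% pair2)
  tab3 <- generate_trial_schedule(stage_config("T3"), 2000, seed = 13)
  expect_true("PA" %in% paste0(tab3$sample_dir, tab3$test_dir))
  ## T1 session 1 ramps at 0.9 nonmatch; session 5 reaches 0.5
  t1a <- generate_trial_schedule(stage_config("T1", session_index = 1), 5000, seed = 14)
  t1e <- generate_trial_schedule(stage_config("T1", session_index = 5), 5000, seed = 14)
  expect_lt(abs(mean(t1a$category == "nonmatch") - 0.9), 0.02)
  expect_lt(abs(mean(t1e$category == "nonmatch") - 0.5), 0.03)
})

test_that("empty schedules and invalid configs are handled", {
  tab <- generate_trial_schedule(stage_config("T2"), 0)
  expect_equal(nrow(tab), 0)
  expect_true(all(c("trial_id", "category", "pre_stim_start", "lick_frames")
                  %in% names(tab)))
  cfg <- stage_config("T2")
  cfg$p_nonmatch <- 1.4
  expect_error(generate_trial_schedule(cfg, 10), "probabilities")
})

test_that("trial tables keep period windows ordered, contiguous and outcome-consistent", {
  tab <- generate_trial_schedule(stage_config("T5"), 300, seed = 15)
  tab <- simulate_choices(tab, 1.68, seed = 16)
  expect_true(all((tab$category == "nonmatch") ==
                  (tab$sample_dir != tab$test_dir)))
  expect_true(all(tab$outcome[tab$category == "nonmatch"] %in% c("hit", "miss")))
  expect_true(all(tab$outcome[tab$category == "match"] %in% c("FA", "CR")))
  ## contiguous half-open windows
  expect_true(all(tab$sample_start == tab$pre_stim_end))
  expect_true(all(tab$delay_start == tab$sample_end))
  expect_true(all(tab$test_start == tab$delay_end))
  expect_true(all(tab$report_start == tab$test_end))
  expect_true(all(tab$post_end[-nrow(tab)] == tab$pre_stim_start[-1]))
  ## reward frames exist exactly on hit trials, inside the report window
  tab <- simulate_licks(tab, "T5", seed = 17)
  hit <- tab$outcome == "hit"
  expect_true(all(!is.na(tab$reward_frame[hit])))
  expect_true(all(is.na(tab$reward_frame[!hit])))
  expect_true(all(tab$reward_frame[hit] >= tab$report_start[hit] &
                  tab$reward_frame[hit] < tab$report_end[hit]))
})

test_that("simulated choices recover the requested sensitivity", {
  tab <- generate_trial_schedule(stage_config("T2"), 10000, seed = 18)
  ## d' = 0: chance
  t0 <- simulate_choices(tab, 0, seed = 19)
  expect_lt(abs(mean(t0$outcome %in% c("hit", "CR")) - 0.5), 0.02)
  ## d' = 1.68: ~80% correct, empirical d' within 0.1
  t1 <- simulate_choices(tab, 1.68, seed = 20)
  expect_lt(abs(mean(t1$outcome %in% c("hit", "CR")) - 0.80), 0.02)
  expect_lt(abs(dprime_trials(t1) - 1.68), 0.1)
  ## saturation
  t6 <- simulate_choices(tab, 6, seed = 21)
  expect_gt(mean(t6$outcome %in% c("hit", "CR")), 0.99)
})

test_that("licking concentrates into the report period across stages", {
  cfg <- stage_config("T2", ramp_T1 = FALSE)
  base <- generate_trial_schedule(cfg, 150, seed = 22)
  base <- simulate_choices(base, 1.0, seed = 23)
  rate_outside <- function(tab, stage) {
    tab <- simulate_licks(tab, stage, seed = 24)
    n_licks <- vapply(seq_len(nrow(tab)), function(i) {
      lf <- tab$lick_frames[[i]]
      sum(lf < tab$report_start[i] | lf >= tab$report_end[i])
    }, numeric(1))
    sum(n_licks)
  }
  expect_gt(rate_outside(base, "T1"), rate_outside(base, "T5"))
  ## hit and FA trials always lick in report; CR trials stay near baseline
  t5 <- simulate_licks(base, "T5", seed = 25)
  go <- t5$outcome %in% c("hit", "FA")
  rep_licks <- vapply(seq_len(nrow(t5)), function(i) {
    lf <- t5$lick_frames[[i]]
    sum(lf >= t5$report_start[i] & lf < t5$report_end[i])
  }, numeric(1))
  expect_true(all(rep_licks[go] >= 1))
  expect_lt(mean(rep_licks[t5$outcome == "CR"]), mean(rep_licks[go]))
  ## zero baseline still yields the reward-triggering lick on hits
  t0 <- simulate_licks(base, "T5", seed = 26, base_rate_hz = 0)
  hit <- t0$outcome == "hit"
  expect_true(all(vapply(which(hit), function(i) {
    any(t0$lick_frames[[i]] >= t0$report_start[i])
  }, logical(1))))
})

test_that("generators are bit-reproducible and neuron streams are stable", {
  a <- tiny_session("T2", n_trials = 12, n_neurons = 6, seed = 31)
  b <- tiny_session("T2", n_trials = 12, n_neurons = 6, seed = 31)
  expect_identical(a$F, b$F)
  expect_identical(a$trials, b$trials)
  expect_identical(a$ach, b$ach)
  ## enlarging the population does not perturb existing neurons
  fx6 <- planted_effects(n_neurons = 6, seed = 32)
  fx9 <- planted_effects(n_neurons = 9, seed = 32)
  tab <- simulate_licks(simulate_choices(
    generate_trial_schedule(stage_config("T2"), 10, seed = 33), 1.68, 34), "T2", 35)
  s6 <- simulate_population(tab, fx6)
  s9 <- simulate_population(tab, fx9)
  expect_identical(s6$F, s9$F[1:6, ])
  expect_identical(s6$spikes, s9$spikes[1:6, ])
})

test_that("cell-type proportions track the requested fractions", {
  fx <- planted_effects(n_neurons = 400, seed = 36)
  ty <- cell_types(fx)
  expect_lt(abs(mean(ty == "direction") - 0.25), 0.02)
  expect_lt(abs(mean(ty == "speed") - 0.25), 0.02)
  expect_lt(abs(mean(ty == "reward") - 0.20), 0.02)
  expect_lt(abs(mean(ty == "expected") - 0.15), 0.02)
  expect_error(planted_effects(frac_direction = 0.8, frac_speed = 0.4),
               "proportions")
})

test_that("acetylcholine traces are z-scored per trial with no reward component", {
  cfg <- stage_config("T3")
  tab <- generate_trial_schedule(cfg, 60, seed = 37)
  tab <- simulate_choices(tab, 1.68, seed = 38)
  tab <- simulate_licks(tab, "T3", seed = 39)
  ach <- simulate_ach(tab, seed = 40)
  expect_equal(length(ach), attr(tab, "n_frames"))
  for (i in c(1, 10, 30)) {
    idx <- (tab$pre_stim_start[i] + 1):tab$post_end[i]
    expect_lt(abs(mean(ach[idx])), 1e-10)
    expect_equal(stats::sd(ach[idx]), 1, tolerance = 1e-10)
  }
  ## pre-stimulus frames carry the dominant transient
  pre <- unlist(lapply(seq_len(nrow(tab)), function(i)
    (tab$pre_stim_start[i] + 1):tab$pre_stim_end[i]))
  post_rew <- unlist(lapply(which(tab$outcome == "hit"), function(i)
    (tab$reward_frame[i] + 3):(tab$reward_frame[i] + 8)))
  expect_gt(mean(ach[pre]), mean(ach[post_rew]))
})

test_that("an all-zero-gain population is undecodable", {
  fx <- noise_effects(n_neurons = 10, seed = 41)
  b <- simulate_session(stage_config("T2"), 60, fx, seed = 41)
  ev <- estimate_events(b$F, b$frame_rate_hz)
  feats <- window_features(ev, b$trials, "sample")
  m <- fit_decoder(feats, b$trials$sample_dir, folds = 5, seed = 1)
  null <- label_shuffle_null(feats$X, b$trials$sample_dir, folds = 5,
                             n = 100, seed = 2)
  expect_gte(m$accuracy, null$pct5 - 0.05)
  expect_lte(m$accuracy, null$pct95 + 0.05)
})
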