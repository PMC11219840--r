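#' Write and re-read a session bundle
#'
#' Serialises a `session_bundle` to a directory of plain-text files — the
#' trial table as CSV (lick frames semicolon-packed), the fluorescence,
#' spike and acetylcholine arrays as shortest-round-trip CSV matrices, and
#' the planted effects plus frame metadata as JSON — and reads it back.
#' The text representation is lossless for IEEE doubles, so a round trip
#' returns arrays that are exactly equal.
#'
#' @param bundle A `session_bundle`.
#' @param path Directory to write into (created if missing).
#' @return `write_session_bundle` returns `path` invisibly;
#'   `read_session_bundle` returns the reconstructed bundle.
#' @export
write_session_bundle <- function(bundle, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tab <- bundle$trials
  tab$lick_frames <- vapply(tab$lick_frames, paste, character(1), collapse = ";")
  data.table::fwrite(tab, file.path(path, "trials.csv"))
  .write_matrix(bundle$F, file.path(path, "F.csv"))
  .write_matrix(bundle$spikes, file.path(path, "spikes.csv"))
  if (!is.null(bundle$ach))
    .write_matrix(matrix(bundle$ach, ncol = 1), file.path(path, "ach.csv"))
  meta <- list(frame_rate_hz = bundle$frame_rate_hz,
               n_frames = attr(bundle$trials, "n_frames"),
               cell_type = bundle$cell_type,
               effects = unclass(bundle$effects),
               schema = 1L)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_session_bundle
#' @export
read_session_bundle <- function(path) {
  f_trials <- file.path(path, "trials.csv")
  f_F <- file.path(path, "F.csv")
  if (!file.exists(f_trials) || !file.exists(f_F))
    stop("session bundle schema error: missing trials.csv or F.csv at ", path)
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  if (is.null(meta$schema) || meta$schema != 1L)
    stop("session bundle schema error: unsupported schema version")
  tab <- as.data.frame(data.table::fread(f_trials))
  tab$lick_frames <- I(lapply(strsplit(as.character(tab$lick_frames), ";"),
                              function(v) as.integer(v[nzchar(v)])))
  attr(tab, "frame_rate_hz") <- meta$frame_rate_hz
  attr(tab, "n_frames") <- meta$n_frames
  F_mat <- as.matrix(data.table::fread(f_F, header = FALSE))
  dimnames(F_mat) <- NULL
  spikes <- as.matrix(data.table::fread(file.path(path, "spikes.csv"),
                                        header = FALSE))
  dimnames(spikes) <- NULL
  ach <- if (file.exists(file.path(path, "ach.csv")))
    unname(drop(as.matrix(data.table::fread(file.path(path, "ach.csv"),
                                            header = FALSE)))) else NULL
  fx <- meta$effects
  class(fx) <- "planted_effects"
  structure(list(trials = tab, F = F_mat, spikes = spikes, ach = ach,
                 effects = fx, cell_type = meta$cell_type,
                 frame_rate_hz = meta$frame_rate_hz),
            class = "session_bundle")
}

## 17-significant-digit CSV: round-trips IEEE doubles exactly
.write_matrix <- function(m, path) {
  lines <- vapply(seq_len(nrow(m)), function(i)
    paste(sprintf("%.17g", m[i, ]), collapse = ","), character(1))
  writeLines(lines, path)
}

#' Default replica-course configuration
#'
#' @param stages Stage ids to run, in order.
#' @param sessions_per_stage Sessions simulated per stage.
#' @param n_trials Trials per session.
#' @param effects A [planted_effects()] list shared across stages.
#' @param n_null Shuffle repetitions for significance bands.
#' @param folds Decoder cross-validation folds.
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(stages = c("T1", "T2", "T3", "T4", "T5"),
                       sessions_per_stage = 2, n_trials = 150,
                       effects = planted_effects(), n_null = 200,
                       folds = 10, seed = 1L) {
  stopifnot(all(stages %in% c("T1", "T2", "T3", "T4", "T5")),
            !is.unsorted(match(stages, c("T1", "T2", "T3", "T4", "T5"))))
  structure(list(stages = stages, sessions_per_stage = sessions_per_stage,
                 n_trials = n_trials, effects = effects, n_null = n_null,
                 folds = folds, seed = as.integer(seed)),
            class = "run_config")
}

#' Analyse one simulated session end to end
#'
#' Runs the event-estimation chain and the per-session analyses on a
#' bundle: direction decoding (sample window, correct trials), resampled
#' speed decoding, the reward-outcome cross-temporal decoder with its
#' decodable onset, the expected-outcome decoder trained on pre-stimulus
#' activity and tested at the report period, the choice-selectivity index
#' over speed-significant neurons, and the acetylcholine GLM factor
#' ranking.
#'
#' @param bundle A `session_bundle`.
#' @param n_null Shuffle repetitions.
#' @param folds Decoder folds.
#' @param seed Analysis seed.
#' @param analyses Character subset of
#'   `c("direction", "speed", "reward", "expected", "selectivity", "ach")`.
#' @return Named list of per-analysis results plus a one-row `summary`
#'   data.frame.
#' @export
analyze_session <- function(bundle, n_null = 200, folds = 10, seed = 1L,
                            analyses = c("direction", "speed", "reward",
                                         "expected", "selectivity", "ach")) {
  ev <- estimate_events(bundle$F, bundle$frame_rate_hz)
  tr <- bundle$trials
  res <- list()
  summ <- list(stage = tr$stage[1], session_index = tr$session_index[1],
               dprime = tryCatch(dprime_trials(tr), error = function(e) NA_real_))

  if ("direction" %in% analyses) {
    ok <- tr$outcome %in% c("hit", "CR")
    feats <- window_features(ev, tr[ok, ], "sample")
    res$direction <- fit_decoder(feats, tr$sample_dir[ok], folds = folds,
                                 seed = .split_seed(seed, 1))
    summ$direction_acc <- res$direction$accuracy
  }
  if ("speed" %in% analyses) {
    if (length(unique(tr$speed)) == 2 && min(table(tr$speed)) >= 2) {
      feats <- window_features(ev, tr, "sample")
      res$speed <- fit_decoder_resampled(feats, tr$speed, folds = folds,
                                         n_resamples = 20,
                                         seed = .split_seed(seed, 2))
      summ$speed_acc <- res$speed$accuracy
    } else {
      summ$speed_acc <- NA_real_     # too few minority-speed trials
    }
  }
  if ("reward" %in% analyses) {
    y <- ifelse(tr$outcome == "hit", "hit", "non-hit")
    res$reward_ct <- cross_temporal(ev, tr, y, "report", folds = folds,
                                    n_null = n_null,
                                    seed = .split_seed(seed, 3))
    summ$reward_onset_s <- decodable_onset(res$reward_ct)
    summ$reward_acc <- res$reward_ct$model$accuracy
  }
  if ("expected" %in% analyses) {
    y <- ifelse(tr$outcome == "hit", "hit", "non-hit")
    res$expected_ct <- cross_temporal(ev, tr, y, "pre_stim", folds = folds,
                                      n_null = n_null,
                                      seed = .split_seed(seed, 4))
    in_report <- res$expected_ct$starts_s >=
      .modal_anchor(tr, bundle$frame_rate_hz, "report_start")
    summ$expected_pre_acc <- mean(res$expected_ct$accuracy[
      res$expected_ct$starts_s < 1.0])
    summ$expected_report_acc <- mean(res$expected_ct$accuracy[in_report])
    summ$expected_report_below <- any(res$expected_ct$sig_below[in_report])
  }
  if ("selectivity" %in% analyses &&
      length(unique(tr$speed)) == 2 && min(table(tr$speed)) >= 2) {
    feats <- window_features(ev, tr, "sample")
    spd_model <- fit_decoder_resampled(feats, tr$speed, folds = folds,
                                       n_resamples = 10,
                                       seed = .split_seed(seed, 5))
    mask <- significant_weights(spd_model, feats, tr$speed,
                                n = min(n_null, 500),
                                seed = .split_seed(seed, 6))
    recs <- selectivity_records(ev, tr, "test",
                                mask = if (any(mask)) mask else NULL)
    res$selectivity <- recs
    summ$mean_cs <- mean(recs$CS)
  }
  if ("ach" %in% analyses && !is.null(bundle$ach)) {
    X <- build_design(tr)
    res$ach_factors <- factor_delta_aic(bundle$ach, X,
                                        seed = .split_seed(seed, 7))
    summ$ach_top_factor <- res$ach_factors$factor[1]
  }
  res$summary <- as.data.frame(summ, stringsAsFactors = FALSE)
  res
}

#' Run the full synthetic training-course replica
#'
#' Simulates sessions across the configured stages and runs the complete
#' analysis chain on each, writing stage-resolved summary tables and a
#' manifest to the output directory. With a fixed master seed the run is
#' bit-reproducible.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory (`NULL` for no file output).
#' @param analyses Analyses to run per session (see [analyze_session()]).
#' @return List: `summary` (one row per session), `sessions` (per-session
#'   result lists), `manifest`.
#' @export
run_course <- function(cfg = run_config(), out_dir = NULL,
                       analyses = c("direction", "speed", "reward",
                                    "expected", "selectivity", "ach")) {
  rows <- list(); sessions <- list(); files <- character(0)
  for (si in seq_along(cfg$stages)) {
    stage <- cfg$stages[si]
    for (k in seq_len(cfg$sessions_per_stage)) {
      t0 <- proc.time()["elapsed"]
      scfg <- stage_config(stage, session_index = k, ramp_T1 = FALSE)
      seed_sk <- .split_seed(cfg$seed, si * 100 + k)
      bundle <- simulate_session(scfg, cfg$n_trials, cfg$effects,
                                 seed = seed_sk)
      res <- analyze_session(bundle, n_null = cfg$n_null, folds = cfg$folds,
                             seed = seed_sk, analyses = analyses)
      rows[[length(rows) + 1]] <- res$summary
      sessions[[paste0(stage, "_s", k)]] <- res
      message(sprintf("[%s session %d] %.1fs", stage, k,
                      proc.time()["elapsed"] - t0))
    }
  }
  summary <- do.call(rbind, rows)
  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    f <- file.path(out_dir, "course_summary.csv")
    data.table::fwrite(summary, f)
    files <- basename(f)
    manifest <- list(seed = cfg$seed,
                     files = lapply(files, function(fn)
                       list(file = fn, producer = "run_course",
                            seed = cfg$seed)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(summary = summary, sessions = sessions, manifest = manifest)
}
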