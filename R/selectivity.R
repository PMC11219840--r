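#' Peak stimulus response of each neuron
#'
#' For a subset of trials, the trial-averaged event-estimate time course is
#' formed per neuron over the sample or test period, and the stimulus
#' response (SR) is its maximum.
#'
#' @param s_hat Neurons x frames event-estimate matrix or `event_matrix`.
#' @param trials Trial table.
#' @param subset Logical or integer index of trials to average over.
#' @param period `"sample"` or `"test"`.
#' @return Per-neuron SR vector (`>= 0` for nonnegative inputs).
#' @export
stimulus_response <- function(s_hat, trials, subset, period = c("sample", "test")) {
  period <- match.arg(period)
  if (inherits(s_hat, "event_matrix")) s_hat <- s_hat$s_hat
  rows <- trials[subset, , drop = FALSE]
  if (nrow(rows) == 0) stop("trial subset is empty")
  st <- rows[[paste0(period, "_start")]]
  en <- rows[[paste0(period, "_end")]]
  len <- min(en - st)
  avg <- matrix(0, nrow(s_hat), len)
  for (i in seq_len(nrow(rows)))
    avg <- avg + s_hat[, (st[i] + 1L):(st[i] + len), drop = FALSE]
  apply(avg / nrow(rows), 1, max)
}

#' Choice-selectivity index
#'
#' `CS = (SR_error - SR_correct) / (SR_error + SR_correct)`, in `[-1, 1]`:
#' positive values mark neurons responding more on error trials. Neurons
#' with a zero denominator have an undefined index and are returned as
#' `NA` (callers drop them).
#'
#' @param SR_error,SR_correct Nonnegative per-neuron peak responses.
#' @return Per-neuron CS vector with `NA` for undefined records.
#' @export
choice_selectivity <- function(SR_error, SR_correct) {
  stopifnot(length(SR_error) == length(SR_correct))
  if (any(SR_error < 0) || any(SR_correct < 0))
    stop("stimulus responses must be nonnegative")
  den <- SR_error + SR_correct
  ifelse(den > 0, (SR_error - SR_correct) / den, NA_real_)
}

#' Choice selectivity of speed-coding neurons in a session
#'
#' Runs the full chain: peak responses on correct (hit, CR) and error
#' (miss, FA) trials for the requested period, the CS index, and an
#' optional restriction to neurons with significant speed-decoder weights.
#'
#' @param s_hat Event estimates.
#' @param trials Trial table with outcomes.
#' @param period `"sample"` or `"test"`.
#' @param mask Optional logical neuron mask (e.g. from
#'   [significant_weights()] on speed labels); `NULL` keeps all neurons.
#' @return `data.frame` with `neuron_id`, `SR_correct`, `SR_error`, `CS`,
#'   `period`; undefined records are dropped.
#' @export
selectivity_records <- function(s_hat, trials, period = c("sample", "test"),
                                mask = NULL) {
  period <- match.arg(period)
  if (inherits(s_hat, "event_matrix")) s_hat <- s_hat$s_hat
  correct <- trials$outcome %in% c("hit", "CR")
  sr_c <- stimulus_response(s_hat, trials, correct, period)
  sr_e <- stimulus_response(s_hat, trials, !correct, period)
  cs <- choice_selectivity(sr_e, sr_c)
  out <- data.frame(neuron_id = seq_along(cs), SR_correct = sr_c,
                    SR_error = sr_e, CS = cs, period = period,
                    stringsAsFactors = FALSE)
  if (!is.null(mask)) out <- out[mask, , drop = FALSE]
  dropped <- is.na(out$CS)
  if (any(dropped))
    message(sum(dropped), " neuron(s) dropped: zero-denominator CS")
  out[!dropped, , drop = FALSE]
}
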