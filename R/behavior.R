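#' Assign trial outcomes from lick times
#'
#' A "response" is at least one lick inside the half-open response window
#' `(response_signal, response_signal + response_window_s)`. Go + response
#' -> Hit, Go + no response -> Miss, NoGo + response -> FA, NoGo + no
#' response -> CR. Licks before the response signal never count.
#'
#' @param trials a `trial_table`.
#' @param response_window_s response window length in seconds after the
#'   response signal (default 1.7 s, so the response period spans
#'   800-2500 ms after stimulus onset).
#' @return The trial table with the `outcome` column (re)assigned.
#' @export
assign_outcomes <- function(trials, response_window_s = 1.7) {
  licked <- mapply(function(licks, rs) {
    any(licks > rs & licks < rs + response_window_s)
  }, trials$lick_times, trials$response_signal_s)
  trials$outcome <- ifelse(trials$stimulus == "Go",
                           ifelse(licked, "Hit", "Miss"),
                           ifelse(licked, "FA", "CR"))
  trials
}

#' Discard trials after the session's last lick
#'
#' Trials whose stimulus onset falls after the final lick of their session
#' are removed (motivation guard: a mouse that has stopped licking is no
#' longer doing the task). A session with no licks at all loses every trial,
#' with a warning.
#'
#' @param trials a `trial_table`.
#' @return The truncated trial table.
#' @export
truncate_after_last_lick <- function(trials) {
  keep <- rep(TRUE, nrow(trials))
  for (s in unique(trials$session_id)) {
    in_s <- trials$session_id == s
    licks <- unlist(trials$lick_times[in_s])
    if (length(licks) == 0L) {
      warning("session ", s, " has no licks; all its trials removed")
      keep[in_s] <- FALSE
    } else {
      keep[in_s] <- trials$stim_onset_s[in_s] <= max(licks)
    }
  }
  out <- trials[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Behavioral discriminability d'
#'
#' `d' = qnorm(hit_rate) - qnorm(fa_rate)`. Rates must already carry any
#' finite-sample correction (see [sliding_dprime()]); rates of exactly 0 or
#' 1 give infinite d'.
#'
#' @param hit_rate,fa_rate probabilities in `[0, 1]`.
#' @return d' (vectorised).
#' @export
compute_dprime <- function(hit_rate, fa_rate) {
  stats::qnorm(hit_rate) - stats::qnorm(fa_rate)
}

# log-linear finite-sample correction: counts k of n -> (k + 0.5)/(n + 1)
.corrected_rate <- function(k, n) {
  (k + 0.5) / (n + 1)
}

#' Sliding-window d' per trial
#'
#' For trial i, hit and FA rates are computed over trials
#' `[i - halfwidth, i + halfwidth]` of the same session (the index trial
#' included; edge windows clipped to the session bounds). Counts are
#' corrected by the log-linear rule `(k + 0.5)/(n + 1)` before the normal
#' quantile, keeping d' finite in perfect windows. d' is undefined (NA)
#' where the window lacks either a Go or a NoGo trial.
#'
#' @param trials a `trial_table` with outcomes assigned.
#' @param halfwidth window half-width in trials (default 10).
#' @return The trial table with `dprime`, `win_hit_rate`, `win_fa_rate`
#'   columns added.
#' @export
sliding_dprime <- function(trials, halfwidth = 10) {
  n <- nrow(trials)
  dp <- hr <- fr <- rep(NA_real_, n)
  for (s in unique(trials$session_id)) {
    idx <- which(trials$session_id == s)
    is_go <- trials$stimulus[idx] == "Go"
    is_hit <- trials$outcome[idx] == "Hit"
    is_fa <- trials$outcome[idx] == "FA"
    m <- length(idx)
    cg <- cumsum(is_go); ch <- cumsum(is_hit); cf <- cumsum(is_fa)
    for (j in seq_len(m)) {
      a <- max(1L, j - halfwidth); b <- min(m, j + halfwidth)
      lo <- if (a > 1L) a - 1L else 0L
      n_go <- cg[b] - (if (lo) cg[lo] else 0L)
      n_nogo <- (b - a + 1L) - n_go
      if (n_go == 0L || n_nogo == 0L) next
      k_hit <- ch[b] - (if (lo) ch[lo] else 0L)
      k_fa <- cf[b] - (if (lo) cf[lo] else 0L)
      h <- .corrected_rate(k_hit, n_go)
      f <- .corrected_rate(k_fa, n_nogo)
      hr[idx[j]] <- h; fr[idx[j]] <- f
      dp[idx[j]] <- compute_dprime(h, f)
    }
  }
  trials$win_hit_rate <- hr
  trials$win_fa_rate <- fr
  trials$dprime <- dp
  trials
}

#' Classify a trial's learning stage from its d'
#'
#' d' < 2 -> "early", d' > 3 -> "expert", anything between (or undefined)
#' -> "excluded".
#'
#' @param dprime numeric vector (NA allowed).
#' @return character vector of stage labels.
#' @export
classify_stage <- function(dprime) {
  out <- rep("excluded", length(dprime))
  out[!is.na(dprime) & dprime < 2] <- "early"
  out[!is.na(dprime) & dprime > 3] <- "expert"
  out
}

#' Full behavioral labeling pass
#'
#' Assign outcomes, truncate after the last lick, compute sliding d' and
#' stage labels — the standard preprocessing applied before every neural
#' analysis.
#'
#' @param trials a `trial_table`.
#' @param config an [analysis_config()].
#' @return Labeled trial table with `dprime` and `stage` columns.
#' @export
label_behavior <- function(trials, config = analysis_config()) {
  trials <- assign_outcomes(trials,
                            response_window_s = config$response_window_s)
  trials <- truncate_after_last_lick(trials)
  trials <- sliding_dprime(trials, halfwidth = config$sliding_halfwidth)
  trials$stage <- classify_stage(trials$dprime)
  trials
}
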