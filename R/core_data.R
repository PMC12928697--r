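#' Canonical mesoscale region set
#'
#' The ten cortical and subcortical regions covered by the recording design:
#' frontal (mPFC, OFC, ACC), motor (M1, M2), visual (V1, V2M, V2L) and
#' subcortical (STR = striatum, MDTh = mediodorsal thalamus). The list is
#' ordered and fixed per dataset; any region vector of length >= 2 is
#' accepted by the constructors, this is merely the default.
#'
#' @return Character vector of region labels.
#' @export
mesoscale_regions <- function() {
  c("mPFC", "OFC", "ACC", "M1", "M2", "V1", "V2M", "V2L", "STR", "MDTh")
}

#' Construct a spike dataset
#'
#' A spike dataset holds per-unit spike times (seconds, session clock) with a
#' region label per unit. Spike times are stored in one long data frame and
#' sorted within unit; a units table gives the unit -> region map.
#'
#' @param spikes data.frame with columns `unit_id`, `region`, `time_s`.
#' @param region_list character vector of allowed region labels (ordered).
#' @param session_id session identifier.
#' @return Object of class `spike_dataset`: list with `session_id`,
#'   `region_list`, `units` (data.frame `unit_id`, `region`) and `spikes`
#'   (data.frame `unit_id`, `time_s`, sorted within unit).
#' @export
spike_dataset <- function(spikes, region_list = mesoscale_regions(),
                          session_id = "s1") {
  stopifnot(is.data.frame(spikes))
  need <- c("unit_id", "region", "time_s")
  miss <- setdiff(need, names(spikes))
  if (length(miss) > 0L) {
    stop("spike table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (length(region_list) < 2L) stop("region_list must have length >= 2")
  spikes$unit_id <- as.character(spikes$unit_id)
  spikes$region <- as.character(spikes$region)
  bad <- setdiff(unique(spikes$region), region_list)
  if (length(bad) > 0L) {
    stop("unknown region label(s): ", paste(bad, collapse = ", "))
  }
  if (any(!is.finite(spikes$time_s))) stop("non-finite spike times")
  if (any(spikes$time_s < 0)) stop("negative spike times")
  units <- spikes[!duplicated(spikes$unit_id), c("unit_id", "region")]
  if (any(spikes$region != units$region[match(spikes$unit_id,
                                              units$unit_id)])) {
    stop("unit assigned to more than one region")
  }
  o <- order(match(spikes$unit_id, units$unit_id), spikes$time_s)
  if (is.unsorted(o)) spikes <- spikes[o, , drop = FALSE]
  rownames(spikes) <- NULL
  structure(
    list(session_id = session_id, region_list = region_list,
         units = units[order(match(units$region, region_list),
                             units$unit_id), , drop = FALSE],
         spikes = spikes[, c("unit_id", "time_s")]),
    class = "spike_dataset"
  )
}

#' @export
print.spike_dataset <- function(x, ...) {
  cat(sprintf("<spike_dataset> session %s: %d units, %d regions, %d spikes\n",
              x$session_id, nrow(x$units),
              length(unique(x$units$region)), nrow(x$spikes)))
  invisible(x)
}

#' Spike times of one unit
#' @param dataset a `spike_dataset`.
#' @param unit_id unit identifier.
#' @return Numeric vector of spike times (s).
#' @export
unit_spikes <- function(dataset, unit_id) {
  dataset$spikes$time_s[dataset$spikes$unit_id == unit_id]
}

#' Construct a trial table
#'
#' Trials are ordered by stimulus onset within session. The response signal
#' is always 0.8 s after stimulus onset (the stimulus duration); it is
#' derived, never stored independently. Lick times are absolute (session
#' clock), held in a list column.
#'
#' @param trials data.frame with columns `trial_id`, `session_id`,
#'   `stimulus` ("Go"/"NoGo"), `stim_onset_s`, `lick_times` (list of numeric
#'   vectors) and optionally `outcome`.
#' @return data.frame of class `trial_table` with derived
#'   `response_signal_s` column.
#' @export
trial_table <- function(trials) {
  stopifnot(is.data.frame(trials))
  need <- c("trial_id", "session_id", "stimulus", "stim_onset_s", "lick_times")
  miss <- setdiff(need, names(trials))
  if (length(miss) > 0L) {
    stop("trial table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(trials$stimulus %in% c("Go", "NoGo"))) {
    stop("stimulus must be 'Go' or 'NoGo'")
  }
  for (s in unique(trials$session_id)) {
    ids <- trials$trial_id[trials$session_id == s]
    if (anyDuplicated(ids)) stop("duplicate trial_id within session ", s)
  }
  trials <- trials[order(trials$session_id, trials$stim_onset_s), ,
                   drop = FALSE]
  trials$response_signal_s <- trials$stim_onset_s + 0.8
  if (is.null(trials$outcome)) trials$outcome <- NA_character_
  rownames(trials) <- NULL
  class(trials) <- c("trial_table", "data.frame")
  trials
}

#' Read a spike table from CSV
#'
#' Expected columns: `unit_id,region,spike_time_s` (header mandatory, comma
#' delimited, '.' decimal). Non-monotonic times within a unit are sorted with
#' a warning; unknown regions and negative times are errors.
#'
#' @param path file path.
#' @param region_list allowed region labels.
#' @param session_id session identifier to attach.
#' @return A [spike_dataset()].
#' @export
read_spike_table <- function(path, region_list = mesoscale_regions(),
                             session_id = "s1") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("unit_id", "region", "spike_time_s")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("spike table missing column(s): ", paste(miss, collapse = ", "))
  }
  unsorted <- tapply(df$spike_time_s, df$unit_id, is.unsorted)
  if (any(unsorted)) {
    warning("non-monotonic spike times sorted for unit(s): ",
            paste(names(unsorted)[unsorted], collapse = ", "))
  }
  spike_dataset(
    data.frame(unit_id = df$unit_id, region = df$region,
               time_s = df$spike_time_s, stringsAsFactors = FALSE),
    region_list = region_list, session_id = session_id
  )
}

#' Write a spike table to CSV
#' @param dataset a `spike_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(dataset, path) {
  df <- data.frame(
    unit_id = dataset$spikes$unit_id,
    region = dataset$units$region[match(dataset$spikes$unit_id,
                                        dataset$units$unit_id)],
    spike_time_s = dataset$spikes$time_s,
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.parse_licks <- function(x) {
  if (is.na(x) || !nzchar(x)) return(numeric(0))
  out <- suppressWarnings(as.numeric(strsplit(x, ";", fixed = TRUE)[[1]]))
  if (any(is.na(out))) stop("unparseable lick time list: '", x, "'")
  out
}

.format_licks <- function(x) {
  vapply(x, function(v) paste(format(v, trim = TRUE, scientific = FALSE,
                                     digits = 15),
                              collapse = ";"),
         character(1))
}

#' Read a trial table from CSV
#'
#' Expected columns: `trial_id,session_id,stimulus,stim_onset_s,lick_times_s`
#' and optionally `outcome`. Lick times are a semicolon-joined list (possibly
#' empty). If an `outcome` column is present it is re-derived from the lick
#' times via [assign_outcomes()] and a warning is emitted on any mismatch —
#' the lick record, not the stored label, is the source of truth.
#'
#' @param path file path.
#' @param response_window_s length of the response window (s) used to
#'   validate stored outcomes.
#' @return A [trial_table()].
#' @export
read_trial_table <- function(path, response_window_s = 1.7) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(lick_times_s = "character"))
  need <- c("trial_id", "session_id", "stimulus", "stim_onset_s",
            "lick_times_s")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("trial table missing column(s): ", paste(miss, collapse = ", "))
  }
  licks <- lapply(df$lick_times_s, .parse_licks)
  tt <- trial_table(data.frame(
    trial_id = df$trial_id, session_id = as.character(df$session_id),
    stimulus = df$stimulus, stim_onset_s = df$stim_onset_s,
    lick_times = I(licks), stringsAsFactors = FALSE
  ))
  stored <- if ("outcome" %in% names(df)) {
    df$outcome[order(df$session_id, df$stim_onset_s)]
  } else NULL
  tt <- assign_outcomes(tt, response_window_s = response_window_s)
  if (!is.null(stored)) {
    bad <- which(!is.na(stored) & stored != tt$outcome)
    if (length(bad) > 0L) {
      warning(length(bad), " stored outcome(s) disagree with lick record; ",
              "re-derived outcomes kept")
    }
  }
  if ("dprime" %in% names(df)) {
    tt$dprime <- df$dprime[order(df$session_id, df$stim_onset_s)]
  }
  if ("stage" %in% names(df)) {
    tt$stage <- df$stage[order(df$session_id, df$stim_onset_s)]
  }
  tt
}

#' Write a trial table to CSV
#' @param trials a `trial_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  df <- data.frame(
    trial_id = trials$trial_id, session_id = trials$session_id,
    stimulus = trials$stimulus,
    stim_onset_s = trials$stim_onset_s,
    lick_times_s = .format_licks(trials$lick_times),
    outcome = trials$outcome,
    stringsAsFactors = FALSE
  )
  if (!is.null(trials$dprime)) df$dprime <- trials$dprime
  if (!is.null(trials$stage)) df$stage <- trials$stage
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align spikes to stimulus onset
#'
#' For every (unit, trial) pair, returns the spikes falling inside
#' `span_ms` relative to the trial's stimulus onset, as relative times in
#' milliseconds (0 = onset, negative = pre-stimulus). Intervals are
#' half-open: a spike is kept iff `span_ms[1] <= t < span_ms[2]`.
#'
#' @param dataset a `spike_dataset`.
#' @param trials a `trial_table` (may carry extra columns such as stage).
#' @param span_ms numeric length-2, window relative to onset in ms.
#' @return data.frame with columns `unit_id`, `region`, `trial_id`, `t_ms`.
#' @export
align_spikes <- function(dataset, trials, span_ms = c(-600, 2800)) {
  stopifnot(length(span_ms) == 2L, span_ms[1] < span_ms[2])
  if (span_ms[1] < -5000 || span_ms[2] > 10000) {
    stop("span must lie within (-5 s, +10 s) of onset")
  }
  empty <- data.frame(unit_id = character(0), region = character(0),
                      trial_id = integer(0), t_ms = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(trials) == 0L) return(empty)
  onsets <- trials$stim_onset_s
  if (any(diff(sort(onsets)) * 1000 < diff(span_ms))) {
    warning("trial spans overlap; spikes may appear in two trials")
  }
  lo <- onsets + span_ms[1] / 1000
  hi <- onsets + span_ms[2] / 1000
  t_all <- dataset$spikes$time_s
  u_all <- dataset$spikes$unit_id
  # spikes are sorted within unit, not globally; sort once globally here
  og <- order(t_all)
  t_all <- t_all[og]; u_all <- u_all[og]
  i0 <- findInterval(lo, t_all, left.open = TRUE)
  i1 <- findInterval(hi, t_all, left.open = TRUE)
  m <- pmax(i1 - i0, 0L)
  if (sum(m) == 0L) return(empty)
  idx <- sequence(m) + rep.int(i0, m)
  trial_rep <- rep.int(seq_len(nrow(trials)), m)
  out <- data.frame(
    unit_id = u_all[idx],
    trial_id = trials$trial_id[trial_rep],
    t_ms = (t_all[idx] - onsets[trial_rep]) * 1000,
    stringsAsFactors = FALSE
  )
  out$region <- dataset$units$region[match(out$unit_id,
                                           dataset$units$unit_id)]
  out[, c("unit_id", "region", "trial_id", "t_ms")]
}

#' Analysis configuration
#'
#' Bundles every fixed analysis parameter. Defaults follow the study design:
#' 1-ms spike bins, 25-ms rate windows, 200-ms connectivity/encoding
#' windows, baseline -500-0 ms, analysis span -600 to +2800 ms around
#' stimulus onset, trial periods (0,400)/(400,800)/(800,1800)/(1800,2800) ms,
#' excitatory-delay cutoff 20 ms, alpha 0.05, 500 bootstraps of 50 trials
#' per condition, at least 5 trials of each of the four outcome types,
#' d' < 2 early / d' > 3 expert staging, sliding-window half-width 10
#' trials, and >= 3 consecutive significant windows for an activity onset.
#'
#' @param ... named overrides of any default.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    rate_bin_ms = 1,
    rate_window_ms = 25,
    conn_window_ms = 200,
    baseline_ms = c(-500, 0),
    span_ms = c(-600, 2800),
    periods = list(early_stim = c(0, 400), late_stim = c(400, 800),
                   early_resp = c(800, 1800), late_resp = c(1800, 2800)),
    max_delay_ms = 20,
    alpha = 0.05,
    n_surrogates = 200,
    n_boot = 500,
    n_shuffle = 200,
    trials_per_condition = 50,
    min_trials_per_type = 5,
    dprime_early_max = 2,
    dprime_expert_min = 3,
    sliding_halfwidth = 10,
    onset_consecutive = 3,
    response_window_s = 1.7,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  stopifnot(cfg$alpha > 0, cfg$alpha < 1,
            cfg$baseline_ms[1] < cfg$baseline_ms[2],
            cfg$span_ms[1] < cfg$span_ms[2])
  p <- do.call(rbind, cfg$periods)
  if (any(p[, 1] >= p[, 2]) ||
      any(abs(p[-1, 1] - p[-nrow(p), 2]) > 1e-9)) {
    stop("periods must have positive width and tile contiguously")
  }
  structure(cfg, class = c("analysis_config", "list"))
}

#' TSPE scoring configuration
#'
#' Parameters of the total-spiking-probability-edge cross-correlation score:
#' edge-filter flank width `a`, centre plateau width `b`, running-total
#' (boxcar) width `c`, all in ms; the score sums the filtered responses over
#' the whole `(a, b, c)` grid. `b` and `c` must be odd so every kernel has
#' an exact centre bin. `max_lag_ms` must cover `max_delay + max(a)` plus
#' the boxcar half-width.
#'
#' @param a flank widths (ms).
#' @param b centre plateau widths (ms, odd).
#' @param c_run running-total widths (ms, odd).
#' @param cc_bin_ms correlogram bin (ms).
#' @param max_lag_ms correlogram half-span (ms).
#' @return list of class `tspe_config`.
#' @export
tspe_config <- function(a = c(2, 4, 6), b = c(1, 3), c_run = c(3, 5),
                        cc_bin_ms = 1, max_lag_ms = 30) {
  stopifnot(all(a > 0), all(b > 0), all(c_run > 0),
            all(b %% 2 == 1), all(c_run %% 2 == 1))
  grid <- expand.grid(a = a, b = b, c_run = c_run)
  if (nrow(grid) == 0L) stop("empty TSPE parameter grid")
  structure(list(a = a, b = b, c_run = c_run, grid = grid,
                 cc_bin_ms = cc_bin_ms, max_lag_ms = max_lag_ms),
            class = c("tspe_config", "list"))
}

#' Read analysis + TSPE configuration from a YAML file
#'
#' Field names mirror [analysis_config()] and [tspe_config()]; the file may
#' contain top-level keys `analysis:` and `tspe:`, each holding overrides.
#'
#' @param path YAML file path.
#' @return list with elements `analysis` and `tspe`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  an <- raw$analysis
  if (!is.null(an$periods)) an$periods <- lapply(an$periods, as.numeric)
  list(
    analysis = do.call(analysis_config, if (is.null(an)) list() else an),
    tspe = do.call(tspe_config,
                   if (is.null(raw$tspe)) list() else raw$tspe)
  )
}

#' Non-overlapping window starts tiling a span
#' @param span_ms length-2 span (ms).
#' @param width_ms window width (ms).
#' @return numeric vector of window start times (ms).
#' @export
window_starts <- function(span_ms, width_ms) {
  seq(span_ms[1], span_ms[2] - width_ms, by = width_ms)
}

#' Sidak adjustment for m simultaneous comparisons
#' @param p raw p-values.
#' @param m family size.
#' @return adjusted p-values, `1 - (1 - p)^m`.
#' @export
sidak_adjust <- function(p, m) {
  pmin(1, 1 - (1 - p)^m)
}
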