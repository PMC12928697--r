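#' Per-trial spike counts in tiled rate windows
#'
#' Bins one unit's aligned spikes (ms relative to stimulus onset) into
#' non-overlapping windows of `width_ms` tiling `span_ms`, per trial.
#' Windows are half-open `[start, start + width)`.
#'
#' @param t_ms aligned spike times (ms) for one unit.
#' @param trial_of trial id of each spike.
#' @param trial_ids trials to include (rows of the output, in this order).
#' @param span_ms analysis span (ms).
#' @param width_ms window width (ms).
#' @return integer matrix `length(trial_ids)` x number of windows.
#' @export
window_count_matrix <- function(t_ms, trial_of, trial_ids,
                                span_ms = c(-600, 2800), width_ms = 25) {
  starts <- window_starts(span_ms, width_ms)
  n_w <- length(starts)
  n_t <- length(trial_ids)
  keep <- t_ms >= span_ms[1] & t_ms < span_ms[2] & trial_of %in% trial_ids
  counts <- matrix(0L, n_t, n_w,
                   dimnames = list(as.character(trial_ids), starts))
  if (!any(keep)) return(counts)
  w <- floor((t_ms[keep] - span_ms[1]) / width_ms) + 1L
  r <- match(trial_of[keep], trial_ids)
  tab <- tabulate((r - 1L) * n_w + w, nbins = n_t * n_w)
  counts[] <- matrix(tab, n_t, n_w, byrow = TRUE)
  counts
}

.col_sems <- function(m) {
  n <- nrow(m)
  if (n < 2L) return(rep(NA_real_, ncol(m)))
  sqrt(apply(m, 2, stats::var) / n)
}

#' Trial-averaged firing-rate trace
#'
#' Rate per 25-ms window and trial is count / 0.025 s; the trace is the mean
#' over trials with its SEM.
#'
#' @param aligned output of [align_spikes()] restricted as desired.
#' @param unit_id the unit.
#' @param trial_ids trials to average (e.g. all Hit trials of a stage).
#' @param config an [analysis_config()].
#' @return data.frame `window_start_ms`, `time_ms` (window centre),
#'   `rate_hz`, `sem`; zero rows if `trial_ids` is empty.
#' @export
compute_rate_trace <- function(aligned, unit_id, trial_ids,
                               config = analysis_config()) {
  if (length(trial_ids) == 0L) {
    return(data.frame(window_start_ms = numeric(0), time_ms = numeric(0),
                      rate_hz = numeric(0), sem = numeric(0)))
  }
  sel <- aligned$unit_id == unit_id
  counts <- window_count_matrix(aligned$t_ms[sel], aligned$trial_id[sel],
                                trial_ids, config$span_ms,
                                config$rate_window_ms)
  rates <- counts / (config$rate_window_ms / 1000)
  starts <- window_starts(config$span_ms, config$rate_window_ms)
  data.frame(window_start_ms = starts,
             time_ms = starts + config$rate_window_ms / 2,
             rate_hz = colMeans(rates), sem = .col_sems(rates))
}

#' Bootstrap-resampled rate traces
#'
#' Each replicate samples `n_per_session` trials with replacement from every
#' included session and recomputes the trial-mean trace over the pooled
#' sample; used to check that rate-trace differences are not artifacts of
#' unequal trial counts.
#'
#' @param aligned output of [align_spikes()].
#' @param unit_id the unit.
#' @param trials labeled `trial_table` rows to draw from (must contain
#'   `trial_id` and `session_id`).
#' @param config an [analysis_config()].
#' @param n_per_session trials resampled per session per replicate.
#' @param n_reps number of replicates.
#' @param seed optional RNG seed.
#' @return list with `reps` (matrix n_reps x windows) and `mean_trace`.
#' @export
bootstrap_rate_traces <- function(aligned, unit_id, trials,
                                  config = analysis_config(),
                                  n_per_session = 5, n_reps = 500,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sel <- aligned$unit_id == unit_id
  starts <- window_starts(config$span_ms, config$rate_window_ms)
  sessions <- split(trials$trial_id, trials$session_id)
  sessions <- sessions[lengths(sessions) > 0L]
  all_ids <- unlist(sessions, use.names = FALSE)
  counts <- window_count_matrix(aligned$t_ms[sel], aligned$trial_id[sel],
                                all_ids, config$span_ms,
                                config$rate_window_ms)
  rates <- counts / (config$rate_window_ms / 1000)
  row_of <- stats::setNames(seq_along(all_ids), all_ids)
  reps <- matrix(NA_real_, n_reps, length(starts),
                 dimnames = list(NULL, starts))
  for (r in seq_len(n_reps)) {
    drawn <- unlist(lapply(sessions, function(ids) {
      ids[sample.int(length(ids), n_per_session, replace = TRUE)]
    }), use.names = FALSE)
    reps[r, ] <- colMeans(rates[row_of[as.character(drawn)], ,
                                drop = FALSE])
  }
  list(reps = reps, mean_trace = colMeans(reps), window_start_ms = starts)
}

# paired t-test p-values of per-window rates against per-trial baseline
# means, vectorised over windows; degenerate (zero-variance) windows get
# p = 1
.onset_pvalues <- function(counts, starts, config) {
  width_s <- config$rate_window_ms / 1000
  base_cols <- which(starts >= config$baseline_ms[1] &
                       starts < config$baseline_ms[2])
  if (length(base_cols) == 0L) stop("baseline window outside analysis span")
  base_rate <- rowSums(counts[, base_cols, drop = FALSE]) /
    (length(base_cols) * width_s)
  rates <- counts / width_s
  d <- rates - base_rate
  n <- nrow(counts)
  mu <- colMeans(d)
  sdv <- sqrt(apply(d, 2, stats::var))
  p <- rep(1, ncol(counts))
  ok <- sdv > 0
  tstat <- mu[ok] / (sdv[ok] / sqrt(n))
  p[ok] <- 2 * stats::pt(-abs(tstat), df = n - 1)
  p
}

#' Detect a unit's activity onset time
#'
#' Per 25-ms window, across-trial rates are compared to the trial's mean
#' baseline rate (-500-0 ms) by a two-sided paired t-test. The onset is the
#' start of the first window of the earliest run of at least
#' `onset_consecutive` consecutive windows with p < alpha, searched from the
#' beginning of the analysis span; `NA` if no such run exists. Both rate
#' increases and decreases qualify.
#'
#' @param aligned output of [align_spikes()].
#' @param unit_id the unit.
#' @param trial_ids trials of one type/stage (>= 2 required).
#' @param config an [analysis_config()].
#' @return list with `onset_ms` (window start or NA), `p_values` and
#'   `window_start_ms`.
#' @export
detect_onset <- function(aligned, unit_id, trial_ids,
                         config = analysis_config()) {
  stopifnot(length(trial_ids) >= 2L)
  sel <- aligned$unit_id == unit_id
  counts <- window_count_matrix(aligned$t_ms[sel], aligned$trial_id[sel],
                                trial_ids, config$span_ms,
                                config$rate_window_ms)
  starts <- window_starts(config$span_ms, config$rate_window_ms)
  p <- .onset_pvalues(counts, starts, config)
  list(onset_ms = .first_run_start(p < config$alpha,
                                   config$onset_consecutive, starts),
       p_values = p, window_start_ms = starts)
}

# start of the earliest run of >= k consecutive TRUEs, NA if none
.first_run_start <- function(sig, k, starts) {
  r <- rle(sig)
  hit <- which(r$values & r$lengths >= k)
  if (length(hit) == 0L) return(NA_real_)
  first <- sum(r$lengths[seq_len(hit[1] - 1L)]) + 1L
  starts[first]
}

#' Regional peak activation times
#'
#' For each region, histograms the units' onset windows and returns the
#' window with the highest proportion of units exhibiting onset (ties:
#' earliest window). Regions with zero detected onsets get an NA peak.
#'
#' @param onsets data.frame with columns `unit_id`, `region`, `onset_ms`
#'   (NA for units without onset).
#' @param config an [analysis_config()].
#' @return data.frame `region`, `n_onsets`, `peak_ms`.
#' @export
regional_peak_activation <- function(onsets, config = analysis_config()) {
  starts <- window_starts(config$span_ms, config$rate_window_ms)
  regions <- unique(onsets$region)
  peak <- vapply(regions, function(r) {
    o <- onsets$onset_ms[onsets$region == r]
    o <- o[!is.na(o)]
    if (length(o) == 0L) return(NA_real_)
    h <- table(factor(o, levels = starts))
    starts[which.max(h)]      # which.max takes the earliest tie
  }, numeric(1))
  n_on <- vapply(regions, function(r) {
    sum(!is.na(onsets$onset_ms[onsets$region == r]))
  }, numeric(1))
  data.frame(region = regions, n_onsets = n_on, peak_ms = unname(peak),
             stringsAsFactors = FALSE)
}

#' Temporal-compression statistic of an activation sequence
#'
#' Mean and SD of the absolute pairwise differences of regional peak
#' activation times; smaller values mean a more temporally compressed
#' activation sequence.
#'
#' @param peaks numeric vector of per-region peak times (ms); NAs dropped.
#' @return list with `mean_ms`, `sd_ms`, `n_pairs`; NAs if fewer than two
#'   defined peaks.
#' @export
compression_spread <- function(peaks) {
  peaks <- peaks[!is.na(peaks)]
  if (length(peaks) < 2L) {
    return(list(mean_ms = NA_real_, sd_ms = NA_real_, n_pairs = 0L))
  }
  d <- abs(as.numeric(stats::dist(matrix(peaks, ncol = 1))))
  list(mean_ms = mean(d), sd_ms = stats::sd(d), n_pairs = length(d))
}

#' Compare onset times between learning stages, per region
#'
#' Two-sided two-sample t-test on unit onset times per region, Sidak
#' adjusted over the number of regions tested. Regions with fewer than two
#' onsets in either stage are reported but skipped (NA p).
#'
#' @param onsets_early,onsets_expert data.frames as in
#'   [regional_peak_activation()].
#' @return data.frame `region`, `n_early`, `n_expert`, `mean_early_ms`,
#'   `mean_expert_ms`, `p_raw`, `p_sidak`.
#' @export
compare_onsets_between_stages <- function(onsets_early, onsets_expert) {
  regions <- union(onsets_early$region, onsets_expert$region)
  rows <- lapply(regions, function(r) {
    a <- onsets_early$onset_ms[onsets_early$region == r]
    b <- onsets_expert$onset_ms[onsets_expert$region == r]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    p <- if (length(a) >= 2L && length(b) >= 2L &&
             (stats::sd(a) > 0 || stats::sd(b) > 0)) {
      stats::t.test(a, b)$p.value
    } else NA_real_
    data.frame(region = r, n_early = length(a), n_expert = length(b),
               mean_early_ms = if (length(a)) mean(a) else NA_real_,
               mean_expert_ms = if (length(b)) mean(b) else NA_real_,
               p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  m <- sum(!is.na(out$p_raw))
  out$p_sidak <- ifelse(is.na(out$p_raw), NA_real_,
                        sidak_adjust(out$p_raw, max(m, 1L)))
  out
}
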