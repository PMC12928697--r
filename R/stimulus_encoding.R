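#' Inclusion rule for the ROC analysis
#'
#' A unit enters the encoding analysis only if its session provides at
#' least `min_trials` trials of each of the four outcome types (Hit, Miss,
#' CR, FA) — otherwise balanced resampling is meaningless.
#'
#' @param outcomes character vector of trial outcomes available to a unit.
#' @param min_trials minimum per type (default 5).
#' @return TRUE/FALSE.
#' @export
check_inclusion <- function(outcomes, min_trials = 5) {
  counts <- table(factor(outcomes, levels = c("Hit", "Miss", "CR", "FA")))
  all(counts >= min_trials)
}

#' Balanced bootstrap resample of trials
#'
#' Draws `n_per_condition` trials with replacement from each of Hit, Miss,
#' CR and FA. The stimulus groups formed downstream — Go = Hit + Miss,
#' NoGo = CR + FA — therefore contain equally many lick and no-lick trials,
#' balancing behavioral choice within each stimulus group.
#'
#' @param outcomes character vector of trial outcomes (defines the pools).
#' @param n_per_condition trials drawn per type (default 50).
#' @return integer vector of trial indices, ordered Hit, Miss, CR, FA
#'   blocks of `n_per_condition` each.
#' @export
balanced_resample <- function(outcomes, n_per_condition = 50) {
  idx_by <- split(seq_along(outcomes),
                  factor(outcomes, levels = c("Hit", "Miss", "CR", "FA")))
  if (any(lengths(idx_by) == 0L)) {
    stop("balanced_resample requires >= 1 trial of every type")
  }
  unlist(lapply(idx_by, function(ix) {
    ix[sample.int(length(ix), n_per_condition, replace = TRUE)]
  }), use.names = FALSE)
}

#' Area under the ROC curve for two spike-count groups
#'
#' `auROC = P(X2 > X1) + 0.5 P(X2 = X1)` over all cross-group pairs — the
#' Mann-Whitney identity, computed from midranks. 0.5 means
#' indistinguishable distributions, 1 means every group-2 count exceeds
#' every group-1 count.
#'
#' @param counts1,counts2 spike counts of the two groups (nonempty).
#' @return auROC in `[0, 1]`.
#' @export
auroc <- function(counts1, counts2) {
  n1 <- length(counts1); n2 <- length(counts2)
  stopifnot(n1 > 0L, n2 > 0L)
  r <- rank(c(counts1, counts2))
  (sum(r[n1 + seq_len(n2)]) - n2 * (n2 + 1) / 2) / (n1 * n2)
}

#' ROC selectivity
#' @param auroc_value auROC in `[0, 1]`.
#' @return `2 * |auROC - 0.5|`, in `[0, 1]`.
#' @export
roc_selectivity <- function(auroc_value) {
  2 * abs(auroc_value - 0.5)
}

#' Classify a unit's stimulus selectivity in one time window
#'
#' The double-95% rule: `n_boot` balanced bootstraps are drawn and each
#' yields the Go-vs-NoGo ROC selectivity of the resampled spike counts. The
#' shuffle null runs the identical balanced-resample pipeline on
#' trial-label-permuted data (`n_shuffle` permutations of the outcome
#' labels across trials), so observed and null selectivities share the
#' duplication structure of resampling with replacement. The unit is
#' selective in the window iff at least 95% of the bootstraps exceed the
#' 95th percentile of the shuffled selectivities.
#'
#' @param counts per-trial spike counts in the window.
#' @param outcomes per-trial outcomes ("Hit"/"Miss"/"CR"/"FA").
#' @param config an [analysis_config()] (`n_boot`, `n_shuffle`,
#'   `trials_per_condition`, `min_trials_per_type`).
#' @param seed optional RNG seed.
#' @return list: `included`, `selective`, `frac_significant`,
#'   `median_auroc`, `median_selectivity`.
#' @export
classify_selective <- function(counts, outcomes,
                               config = analysis_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!check_inclusion(outcomes, config$min_trials_per_type)) {
    return(list(included = FALSE, selective = FALSE,
                frac_significant = NA_real_, median_auroc = NA_real_,
                median_selectivity = NA_real_))
  }
  n_per <- config$trials_per_condition
  n_grp <- 2L * n_per                 # Go = Hit+Miss, NoGo = CR+FA
  nogo_pos <- n_grp + seq_len(n_grp)
  mw_off <- n_grp * (n_grp + 1) / 2
  mw_den <- n_grp * n_grp
  resample_auc <- function(out_vec) {
    draw <- balanced_resample(out_vec, n_per)
    r <- rank(counts[draw])
    (sum(r[nogo_pos]) - mw_off) / mw_den
  }
  sel_shuf <- vapply(seq_len(config$n_shuffle), function(k) {
    roc_selectivity(resample_auc(sample(outcomes)))
  }, numeric(1))
  thr <- sort(sel_shuf)[ceiling(0.95 * config$n_shuffle)]
  aucs <- vapply(seq_len(config$n_boot), function(b) {
    resample_auc(outcomes)
  }, numeric(1))
  sig <- roc_selectivity(aucs) > thr
  list(included = TRUE, selective = mean(sig) >= 0.95,
       frac_significant = mean(sig), median_auroc = stats::median(aucs),
       median_selectivity = roc_selectivity(stats::median(aucs)))
}

#' Per-unit selectivity profiles over 200-ms windows
#'
#' Runs [classify_selective()] for every unit and every 200-ms window
#' tiling the analysis span (pre-stimulus windows included — pre-onset
#' encoding reflects trial history and is reported, not suppressed).
#' Inclusion is evaluated per unit's session.
#'
#' @param aligned output of [align_spikes()].
#' @param units data.frame `unit_id`, `region`.
#' @param trials labeled `trial_table` (outcomes assigned).
#' @param config an [analysis_config()].
#' @param seed optional RNG seed.
#' @return data.frame `unit_id`, `region`, `window_start_ms`, `included`,
#'   `selective`, `frac_significant`, `median_auroc`.
#' @export
encode_profiles <- function(aligned, units, trials,
                            config = analysis_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  starts <- window_starts(config$span_ms, config$conn_window_ms)
  out <- vector("list", nrow(units) * length(starts))
  k <- 0L
  for (i in seq_len(nrow(units))) {
    u <- units$unit_id[i]
    sel <- aligned$unit_id == u & aligned$trial_id %in% trials$trial_id
    counts <- window_count_matrix(aligned$t_ms[sel], aligned$trial_id[sel],
                                  trials$trial_id, config$span_ms,
                                  config$conn_window_ms)
    for (w in seq_along(starts)) {
      res <- classify_selective(counts[, w], trials$outcome, config)
      k <- k + 1L
      out[[k]] <- data.frame(
        unit_id = u, region = units$region[i], window_start_ms = starts[w],
        included = res$included, selective = res$selective,
        frac_significant = res$frac_significant,
        median_auroc = res$median_auroc, stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Percentage of stimulus-selective neurons per (region, window)
#'
#' @param profiles output of [encode_profiles()].
#' @return data.frame `region`, `window_start_ms`, `n_included`,
#'   `n_selective`, `pct_selective` (NA where no unit was included).
#' @export
selective_fractions <- function(profiles) {
  grp <- interaction(profiles$region, profiles$window_start_ms, drop = TRUE)
  rows <- lapply(split(profiles, grp), function(d) {
    n_inc <- sum(d$included)
    data.frame(region = d$region[1], window_start_ms = d$window_start_ms[1],
               n_included = n_inc, n_selective = sum(d$selective & d$included),
               pct_selective = if (n_inc == 0L) NA_real_ else
                 100 * sum(d$selective & d$included) / n_inc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$region, out$window_start_ms), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Peak encoding time of a region within a trial period
#'
#' Centre of the window with the highest percentage of stimulus-selective
#' neurons among the period's windows (ties: earliest window); NA when the
#' period has no window with a defined percentage.
#'
#' @param fractions one region's rows of [selective_fractions()].
#' @param period_ms length-2 period bounds (ms).
#' @param window_ms window width (ms).
#' @return peak time (ms) or NA.
#' @export
peak_encoding_time <- function(fractions, period_ms, window_ms = 200) {
  in_p <- fractions$window_start_ms >= period_ms[1] &
    fractions$window_start_ms < period_ms[2] &
    !is.na(fractions$pct_selective)
  if (!any(in_p)) return(NA_real_)
  d <- fractions[in_p, , drop = FALSE]
  d <- d[order(d$window_start_ms), , drop = FALSE]
  d$window_start_ms[which.max(d$pct_selective)] + window_ms / 2
}

#' Correlation between region rank and encoding peak time
#'
#' Pearson correlation (two-sided) of per-region network rank against the
#' region's peak encoding time; a negative r means higher-ranked regions
#' reach their encoding peak earlier.
#'
#' @param ranks named numeric: period-mean rank per region.
#' @param peak_times named numeric: peak encoding time (ms) per region.
#' @return list `r`, `p`, `n` (NA r/p with fewer than 3 complete regions
#'   or zero variance).
#' @export
rank_latency_correlation <- function(ranks, peak_times) {
  common <- intersect(names(ranks)[!is.na(ranks)],
                      names(peak_times)[!is.na(peak_times)])
  if (length(common) < 3L) {
    return(list(r = NA_real_, p = NA_real_, n = length(common)))
  }
  x <- ranks[common]; y <- peak_times[common]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(common)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(common))
}
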