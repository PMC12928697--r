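#' Rank regions 1..R by strength
#'
#' Ascending tie-averaged ranks: the strongest region gets rank R (= 10 for
#' the full design), so high rank = network hub. Ties receive the average of
#' the tied positions, which makes the mean rank exactly `(R + 1)/2` — the
#' exchangeability baseline. Regions with undefined strength (zero recorded
#' units) are excluded and the remaining ranks are linearly rescaled onto
#' `[1, R]`; the result is flagged with attribute `rescaled`.
#'
#' @param strengths named numeric vector, one value per region (NA =
#'   undefined).
#' @return named numeric ranks (NA for excluded regions).
#' @export
rank_regions <- function(strengths) {
  R <- length(strengths)
  ok <- !is.na(strengths)
  out <- rep(NA_real_, R)
  names(out) <- names(strengths)
  Rp <- sum(ok)
  if (Rp > 0L) {
    r <- rank(strengths[ok], ties.method = "average")
    if (Rp == 1L) {
      r <- (R + 1) / 2
    } else if (Rp < R) {
      r <- 1 + (r - 1) * (R - 1) / (Rp - 1)
    }
    out[ok] <- r
  }
  attr(out, "rescaled") <- Rp < R
  out
}

#' Summed regional input/output strength
#'
#' Output strength of region r is the row sum of the strength matrix
#' (connections r leads); input strength of region s is the column sum
#' (connections s receives). The absent diagonal does not contribute;
#' regions whose every entry is undefined stay NA.
#'
#' @param S strength matrix from [strength_matrix()].
#' @param direction `"output"` (row sums) or `"input"` (column sums).
#' @return named numeric vector per region.
#' @export
summed_region_strength <- function(S, direction = c("output", "input")) {
  direction <- match.arg(direction)
  M <- if (direction == "output") S else t(S)
  apply(M, 1, function(v) {
    if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
  })
}

#' Decile connection ranks of a strength matrix
#'
#' All N = R(R-1) interregional entries are sorted ascending; the entry at
#' (tie-averaged) sort position k gets rank `ceiling(10 k / N)`, so rank 1
#' is the weakest 10% of connections in the window and rank 10 the
#' strongest. With all entries equal, the shared position 45.5 of 90 gives
#' rank 6 — the documented behavior of the tie rule.
#'
#' @param S strength matrix (diagonal NA).
#' @return integer matrix of ranks, NA diagonal.
#' @export
decile_rank <- function(S) {
  out <- S
  idx <- which(!is.na(S))
  v <- S[idx]
  N <- length(v)
  pos <- rank(v, ties.method = "average")
  out[idx] <- as.integer(ceiling(10 * pos / N))
  out
}

# period label of a window start, NA if outside all periods
.period_of <- function(window_start_ms, periods) {
  lab <- rep(NA_character_, length(window_start_ms))
  for (p in names(periods)) {
    in_p <- window_start_ms >= periods[[p]][1] &
      window_start_ms < periods[[p]][2]
    lab[in_p] <- p
  }
  lab
}

#' Region rank trajectories over windows and periods
#'
#' Applies [rank_regions()] to the summed input or output strength of every
#' (trial, window) strength matrix, then summarises: per-window mean rank
#' with SEM over trials, and per-(region, period) means where a trial's
#' period rank is the mean of its ranks over the period's windows.
#'
#' @param conn long data.frame with columns `trial_id`, `window_start_ms`,
#'   `region_out`, `region_in`, `strength` (one row per ordered region
#'   pair; NA strength = undefined).
#' @param direction `"output"` or `"input"`.
#' @param config an [analysis_config()] (supplies the trial periods).
#' @param region_list ordered region labels.
#' @return list of class `rank_trajectory` with `direction`, `ranks` (long
#'   per (trial, window, region)), `window_summary`, `period_trial` (per-
#'   trial period means) and `period_summary`.
#' @export
rank_trajectories <- function(conn, direction = c("output", "input"),
                              config = analysis_config(),
                              region_list = mesoscale_regions()) {
  direction <- match.arg(direction)
  reg <- if (direction == "output") conn$region_out else conn$region_in
  grp <- paste(conn$trial_id, conn$window_start_ms, sep = "\r")
  sums <- tapply(conn$strength, list(grp, factor(reg, levels = region_list)),
                 function(v) if (all(is.na(v))) NA_real_ else
                   sum(v, na.rm = TRUE))
  ranks_m <- t(apply(sums, 1, rank_regions))
  keys <- do.call(rbind, strsplit(rownames(sums), "\r", fixed = TRUE))
  long <- data.frame(
    trial_id = rep(keys[, 1], ncol(ranks_m)),
    window_start_ms = rep(as.numeric(keys[, 2]), ncol(ranks_m)),
    region = rep(region_list, each = nrow(ranks_m)),
    rank = as.vector(ranks_m),
    stringsAsFactors = FALSE
  )
  long <- long[!is.na(long$rank), , drop = FALSE]
  ws <- stats::aggregate(rank ~ region + window_start_ms, long, mean)
  names(ws)[names(ws) == "rank"] <- "mean_rank"
  sem <- stats::aggregate(rank ~ region + window_start_ms, long,
                          function(v) stats::sd(v) / sqrt(length(v)))
  ws$sem <- sem$rank
  ws$n_trials <- stats::aggregate(rank ~ region + window_start_ms, long,
                                  length)$rank
  long$period <- .period_of(long$window_start_ms, config$periods)
  lp <- long[!is.na(long$period), , drop = FALSE]
  pt <- stats::aggregate(rank ~ region + period + trial_id, lp, mean)
  ps <- stats::aggregate(rank ~ region + period, pt, mean)
  names(ps)[names(ps) == "rank"] <- "mean_rank"
  ps$sem <- stats::aggregate(rank ~ region + period, pt,
                             function(v) stats::sd(v) / sqrt(length(v)))$rank
  ps$n_trials <- stats::aggregate(rank ~ region + period, pt, length)$rank
  structure(list(direction = direction, ranks = long, window_summary = ws,
                 period_trial = pt, period_summary = ps),
            class = c("rank_trajectory", "list"))
}

#' Rank change between learning stages
#'
#' `ΔRank = expert period mean - early period mean` per (region, period);
#' NA where either stage lacks the period. When no region was excluded from
#' ranking, ΔRank sums to zero over regions within each period (rank-sum
#' conservation).
#'
#' @param early,expert `rank_trajectory` objects of the same direction.
#' @return data.frame `region`, `period`, `rank_early`, `rank_expert`,
#'   `delta_rank`.
#' @export
delta_rank <- function(early, expert) {
  stopifnot(early$direction == expert$direction)
  m <- merge(early$period_summary[, c("region", "period", "mean_rank")],
             expert$period_summary[, c("region", "period", "mean_rank")],
             by = c("region", "period"), all = TRUE,
             suffixes = c("_early", "_expert"))
  names(m) <- c("region", "period", "rank_early", "rank_expert")
  m$delta_rank <- m$rank_expert - m$rank_early
  m
}

#' Stage comparison of per-trial period ranks
#'
#' Two-sided two-sample t-test per (region, period) on the per-trial period
#' ranks, Sidak adjusted over the whole family (regions x periods within
#' this direction). Degenerate variance gives p = 1.
#'
#' @param early,expert `rank_trajectory` objects of the same direction.
#' @param m family size for the Sidak adjustment; default = number of
#'   (region, period) cells tested.
#' @return data.frame `region`, `period`, `delta_rank`, `n_early`,
#'   `n_expert`, `p_raw`, `p_sidak`.
#' @export
compare_stage_ranks <- function(early, expert, m = NULL) {
  stopifnot(early$direction == expert$direction)
  key <- function(x) paste(x$region, x$period, sep = "\r")
  cells <- intersect(unique(key(early$period_trial)),
                     unique(key(expert$period_trial)))
  rows <- lapply(cells, function(cl) {
    a <- early$period_trial$rank[key(early$period_trial) == cl]
    b <- expert$period_trial$rank[key(expert$period_trial) == cl]
    p <- if (length(a) >= 2L && length(b) >= 2L &&
             (stats::sd(a) > 0 || stats::sd(b) > 0)) {
      stats::t.test(a, b)$p.value
    } else if (length(a) >= 2L && length(b) >= 2L) 1 else NA_real_
    parts <- strsplit(cl, "\r", fixed = TRUE)[[1]]
    data.frame(region = parts[1], period = parts[2],
               delta_rank = mean(b) - mean(a),
               n_early = length(a), n_expert = length(b), p_raw = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(m)) m <- sum(!is.na(out$p_raw))
  out$p_sidak <- ifelse(is.na(out$p_raw), NA_real_,
                        sidak_adjust(out$p_raw, max(m, 1L)))
  out
}

#' Long-format strengths from a list of per-trial matrices
#'
#' Convenience bridge from [strength_matrices()] output to the long format
#' consumed by [rank_trajectories()].
#'
#' @param mats named list of strength matrices (names = trial ids).
#' @param window_start_ms the window these matrices belong to.
#' @return long data.frame `trial_id`, `window_start_ms`, `region_out`,
#'   `region_in`, `strength`.
#' @export
strengths_to_long <- function(mats, window_start_ms) {
  out <- lapply(names(mats), function(tr) {
    S <- mats[[tr]]
    rl <- rownames(S)
    g <- expand.grid(region_out = rl, region_in = rl,
                     stringsAsFactors = FALSE)
    g <- g[g$region_out != g$region_in, , drop = FALSE]
    g$trial_id <- tr
    g$window_start_ms <- window_start_ms
    g$strength <- S[cbind(g$region_out, g$region_in)]
    g
  })
  res <- do.call(rbind, out)
  res[, c("trial_id", "window_start_ms", "region_out", "region_in",
          "strength")]
}
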