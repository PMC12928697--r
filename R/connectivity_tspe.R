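#' Cross-correlogram of two spike trains
#'
#' Counts ordered spike pairs by their time difference (target - source):
#' the bin at lag `l` counts pairs with a difference in `[l, l + bin)` ms,
#' for `l` from `-max_lag` to `max_lag - bin`. Both trains must be sorted
#' and on a common clock.
#'
#' @param src_ms,tgt_ms sorted spike times (ms) of source and target.
#' @param bin_ms bin width (ms).
#' @param max_lag_ms correlogram half-span (ms).
#' @return list with `counts` (integer vector) and `lag_ms` (left bin
#'   edges).
#' @export
cross_correlogram <- function(src_ms, tgt_ms, bin_ms = 1, max_lag_ms = 30) {
  n_bins <- as.integer(2 * max_lag_ms / bin_ms)
  lags <- seq(-max_lag_ms, max_lag_ms - bin_ms, by = bin_ms)
  if (length(src_ms) == 0L || length(tgt_ms) == 0L) {
    return(list(counts = integer(n_bins), lag_ms = lags))
  }
  before <- findInterval(src_ms - max_lag_ms, tgt_ms, left.open = TRUE)
  upto <- findInterval(src_ms + max_lag_ms, tgt_ms, left.open = TRUE)
  m <- upto - before
  if (sum(m) == 0L) return(list(counts = integer(n_bins), lag_ms = lags))
  idx <- sequence(m) + rep.int(before, m)
  d <- tgt_ms[idx] - rep.int(src_ms, m)
  b <- floor((d + max_lag_ms) / bin_ms) + 1L
  list(counts = tabulate(b[b >= 1L & b <= n_bins], nbins = n_bins),
       lag_ms = lags)
}

# full (polynomial-style) convolution of two kernels
.conv_full <- function(x, y) {
  out <- numeric(length(x) + length(y) - 1L)
  for (i in seq_along(x)) {
    j <- i + seq_along(y) - 1L
    out[j] <- out[j] + x[i] * y
  }
  out
}

#' Combined TSPE detection kernel
#'
#' For each `(a, b, c)` in the parameter grid: a zero-sum peak-detection
#' edge filter (flanks of width `a` at height `-b`, centre plateau of width
#' `b` at `+2a`) convolved with a running-total boxcar of width `c`.
#' Integer coefficients keep the zero-sum property exact in floating point,
#' so a flat correlogram scores exactly 0. Because every step is linear,
#' the whole grid collapses into one summed kernel applied once per
#' correlogram. All kernels are centred (odd `b`, `c` enforced by
#' [tspe_config()]).
#'
#' @param tspe_cfg a [tspe_config()].
#' @return list with `kernel` (numeric, odd length) and `halfwidth` (bins).
#' @export
tspe_kernel <- function(tspe_cfg = tspe_config()) {
  grid <- tspe_cfg$grid
  hw <- max((2 * grid$a + grid$b + grid$c_run - 2) / 2)
  K <- numeric(2 * hw + 1)
  for (i in seq_len(nrow(grid))) {
    a <- grid$a[i]; b <- grid$b[i]; cr <- grid$c_run[i]
    edge <- c(rep(-b, a), rep(2 * a, b), rep(-b, a))
    k <- .conv_full(edge, rep(1, cr))
    h <- (length(k) - 1L) / 2L
    at <- (hw - h + 1L):(hw + h + 1L)
    K[at] <- K[at] + k
  }
  list(kernel = K, halfwidth = as.integer(hw))
}

# centred "same"-length convolution of a series with a kernel of halfwidth h
.filter_same <- function(g, K, h) {
  gpad <- c(rep(0, h), g, rep(0, h))
  as.vector(stats::embed(gpad, 2L * h + 1L) %*% rev(K))
}

#' TSPE cross-correlation score of a correlogram
#'
#' The correlogram is normalized by the geometric pairing scale
#' (`min(n_src, n_tgt)`), filtered with the summed TSPE kernel stack, and
#' the score is the filtered value at the lag with maximal absolute
#' response within `(0, max_delay]` ms. The sign is preserved: positive =
#' putative excitation (correlogram peak), negative = putative inhibition
#' (trough). Either train empty scores exactly 0.
#'
#' @param corr output of [cross_correlogram()].
#' @param n_src,n_tgt spike counts of the two trains in the scored segment.
#' @param tspe_cfg a [tspe_config()].
#' @param max_delay_ms largest lag considered (ms).
#' @param kern optional precomputed [tspe_kernel()] (for tight loops).
#' @return list with `score` and `best_delay_ms` (left bin edge; NA when
#'   the score is 0).
#' @export
tspe_score <- function(corr, n_src, n_tgt, tspe_cfg = tspe_config(),
                       max_delay_ms = 20, kern = NULL) {
  if (n_src == 0L || n_tgt == 0L) {
    return(list(score = 0, best_delay_ms = NA_real_))
  }
  if (is.null(kern)) kern <- tspe_kernel(tspe_cfg)
  # filter the raw (integer) counts first: integer kernel x integer counts
  # keeps the zero-sum cancellation exact, then normalize
  y <- .filter_same(corr$counts, kern$kernel, kern$halfwidth) /
    min(n_src, n_tgt)
  sel <- which(corr$lag_ms >= 1 & corr$lag_ms <= max_delay_ms)
  i <- sel[which.max(abs(y[sel]))]
  score <- y[i]
  list(score = score,
       best_delay_ms = if (score == 0) NA_real_ else corr$lag_ms[i])
}

# jitter every spike uniformly within +/- jitter_ms, clipped to the
# segment; sorting is skipped for source trains (the correlogram only
# requires the target train sorted)
.jitter_train <- function(t_ms, seg_ms, jitter_ms = 25, resort = TRUE) {
  if (length(t_ms) == 0L) return(t_ms)
  j <- t_ms + stats::runif(length(t_ms), -jitter_ms, jitter_ms)
  j <- pmin(pmax(j, seg_ms[1]), seg_ms[2] - 1e-9)
  if (resort) sort(j) else j
}

# score one (possibly multi-segment) pair: segments is a list of
# list(src, tgt, seg) entries; correlograms are summed across segments
.pair_score_segments <- function(segs, tspe_cfg, max_delay_ms, kern) {
  n_bins <- as.integer(2 * tspe_cfg$max_lag_ms / tspe_cfg$cc_bin_ms)
  counts <- integer(n_bins)
  n_src <- 0L; n_tgt <- 0L
  lags <- NULL
  for (sg in segs) {
    cc <- cross_correlogram(sg$src, sg$tgt, tspe_cfg$cc_bin_ms,
                            tspe_cfg$max_lag_ms)
    counts <- counts + cc$counts
    lags <- cc$lag_ms
    n_src <- n_src + length(sg$src); n_tgt <- n_tgt + length(sg$tgt)
  }
  tspe_score(list(counts = counts, lag_ms = lags), n_src, n_tgt,
             tspe_cfg, max_delay_ms, kern = kern)
}

#' Surrogate 95th-percentile score threshold for one pair
#'
#' Each surrogate independently jitters every spike of both trains
#' uniformly within +/- 25 ms (clipped to the segment) — destroying <= 20 ms
#' timing structure while preserving segment rates — and recomputes the
#' TSPE score. Returns the 95th percentile (the `ceiling(0.95 n)`-th order
#' statistic) of the surrogate scores.
#'
#' @param segs list of segments, each `list(src, tgt, seg)` with spike
#'   times (ms) and the segment bounds.
#' @param tspe_cfg a [tspe_config()].
#' @param max_delay_ms largest lag considered (ms).
#' @param n_surrogates number of surrogates.
#' @param kern optional precomputed [tspe_kernel()].
#' @return list with `threshold` and `scores` (all surrogate scores).
#' @export
surrogate_threshold <- function(segs, tspe_cfg = tspe_config(),
                                max_delay_ms = 20, n_surrogates = 200,
                                kern = NULL) {
  if (is.null(kern)) kern <- tspe_kernel(tspe_cfg)
  scores <- vapply(seq_len(n_surrogates), function(k) {
    jsegs <- lapply(segs, function(sg) {
      list(src = .jitter_train(sg$src, sg$seg, resort = FALSE),
           tgt = .jitter_train(sg$tgt, sg$seg), seg = sg$seg)
    })
    .pair_score_segments(jsegs, tspe_cfg, max_delay_ms, kern)$score
  }, numeric(1))
  list(threshold = sort(scores)[ceiling(0.95 * n_surrogates)],
       scores = scores)
}

#' All ordered interregional unit pairs
#' @param units data.frame `unit_id`, `region`.
#' @return data.frame `src`, `tgt`, `region_src`, `region_tgt`.
#' @export
interregional_pairs <- function(units) {
  g <- expand.grid(src = units$unit_id, tgt = units$unit_id,
                   stringsAsFactors = FALSE)
  g$region_src <- units$region[match(g$src, units$unit_id)]
  g$region_tgt <- units$region[match(g$tgt, units$unit_id)]
  g[g$region_src != g$region_tgt, , drop = FALSE]
}

#' Per-trial functional connection detection in one 200-ms window
#'
#' For every ordered interregional unit pair and every trial, computes the
#' TSPE score of the pair's spike trains inside `window_ms` (relative to
#' stimulus onset). A shared null per pair is built from jitter surrogates
#' drawn by cycling across the trials; a trial's connection is significant
#' if its score exceeds the null's 95th percentile, is positive, and its
#' best delay lies in `(0, max_delay]` ms (the excitatory filter).
#'
#' @param aligned output of [align_spikes()].
#' @param units data.frame `unit_id`, `region` (the pair universe).
#' @param trial_ids trials of one (type, stage).
#' @param window_ms length-2 window relative to onset (ms).
#' @param config an [analysis_config()].
#' @param tspe_cfg a [tspe_config()].
#' @param seed optional RNG seed.
#' @return data.frame `src`, `tgt`, `region_src`, `region_tgt`, `trial_id`,
#'   `score`, `best_delay_ms`, `significant`.
#' @export
detect_connections <- function(aligned, units, trial_ids, window_ms,
                               config = analysis_config(),
                               tspe_cfg = tspe_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  kern <- tspe_kernel(tspe_cfg)
  pairs <- interregional_pairs(units)
  n_tr <- length(trial_ids)
  in_win <- aligned$t_ms >= window_ms[1] & aligned$t_ms < window_ms[2] &
    aligned$trial_id %in% trial_ids
  sub <- aligned[in_win, , drop = FALSE]
  key <- paste(sub$unit_id, sub$trial_id, sep = "\r")
  spl <- split(sub$t_ms, key)
  get_train <- function(u, tr) {
    t <- spl[[paste(u, tr, sep = "\r")]]
    if (is.null(t)) numeric(0) else sort(t)
  }
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    src_tr <- lapply(trial_ids, function(tr) get_train(pairs$src[i], tr))
    tgt_tr <- lapply(trial_ids, function(tr) get_train(pairs$tgt[i], tr))
    sc <- numeric(n_tr); dl <- rep(NA_real_, n_tr)
    for (k in seq_len(n_tr)) {
      s <- .pair_score_segments(
        list(list(src = src_tr[[k]], tgt = tgt_tr[[k]], seg = window_ms)),
        tspe_cfg, config$max_delay_ms, kern)
      sc[k] <- s$score; dl[k] <- s$best_delay_ms
    }
    null_scores <- vapply(seq_len(config$n_surrogates), function(k) {
      j <- ((k - 1L) %% n_tr) + 1L
      .pair_score_segments(
        list(list(src = .jitter_train(src_tr[[j]], window_ms,
                                      resort = FALSE),
                  tgt = .jitter_train(tgt_tr[[j]], window_ms),
                  seg = window_ms)),
        tspe_cfg, config$max_delay_ms, kern)$score
    }, numeric(1))
    thr <- sort(null_scores)[ceiling(0.95 * config$n_surrogates)]
    out[[i]] <- data.frame(
      src = pairs$src[i], tgt = pairs$tgt[i],
      region_src = pairs$region_src[i], region_tgt = pairs$region_tgt[i],
      trial_id = trial_ids, score = sc, best_delay_ms = dl,
      significant = sc > thr & sc > 0 & !is.na(dl) &
        dl >= 1 & dl <= config$max_delay_ms,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pooled-mode connection detection on session-clock segments
#'
#' Correlograms are summed over the given segments before scoring (one
#' score per pair) — the low-rate alternative to per-trial scoring. Each
#' pair gets its own jitter-surrogate null at `n_surrogates` surrogates.
#'
#' Two edge-calling rules are provided. `"q95"` (default) is the
#' strength-pipeline rule: a connection is significant if its score exceeds
#' the 95th percentile of its surrogates; the ~5% per-pair false-positive
#' baseline it admits washes out of the downstream proportion and rank
#' statistics. `"max"` is the conservative network-recovery rule for
#' calling individual edges: the score must exceed every surrogate (exact
#' permutation p = 1/(n_surrogates + 1)), which keeps the expected number
#' of false edges near zero even across a thousand candidate pairs. Both
#' rules additionally require the excitatory filter (positive score, best
#' delay within (0, max_delay]).
#'
#' @param dataset a [spike_dataset()].
#' @param segments_s data.frame/matrix with columns `start`, `end`
#'   (seconds, session clock).
#' @param config an [analysis_config()].
#' @param tspe_cfg a [tspe_config()].
#' @param edge_rule `"q95"` or `"max"` (see above).
#' @param seed optional RNG seed.
#' @return data.frame `src`, `tgt`, `region_src`, `region_tgt`, `score`,
#'   `best_delay_ms`, `threshold`, `significant`.
#' @export
detect_connections_pooled <- function(dataset, segments_s,
                                      config = analysis_config(),
                                      tspe_cfg = tspe_config(),
                                      edge_rule = c("q95", "max"),
                                      seed = NULL) {
  edge_rule <- match.arg(edge_rule)
  if (!is.null(seed)) set.seed(seed)
  kern <- tspe_kernel(tspe_cfg)
  segments_s <- as.data.frame(segments_s)
  pairs <- interregional_pairs(dataset$units)
  trains <- split(dataset$spikes$time_s * 1000, dataset$spikes$unit_id)
  seg_trains <- lapply(trains, function(t) {
    lapply(seq_len(nrow(segments_s)), function(k) {
      s0 <- segments_s$start[k] * 1000; s1 <- segments_s$end[k] * 1000
      t[t >= s0 & t < s1]
    })
  })
  seg_bounds <- lapply(seq_len(nrow(segments_s)), function(k) {
    c(segments_s$start[k], segments_s$end[k]) * 1000
  })
  empty_segs <- lapply(seg_bounds, function(b) numeric(0))
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    st <- seg_trains[[pairs$src[i]]]; tt <- seg_trains[[pairs$tgt[i]]]
    if (is.null(st)) st <- empty_segs
    if (is.null(tt)) tt <- empty_segs
    segs <- lapply(seq_along(seg_bounds), function(k) {
      list(src = st[[k]], tgt = tt[[k]], seg = seg_bounds[[k]])
    })
    s <- .pair_score_segments(segs, tspe_cfg, config$max_delay_ms, kern)
    st <- surrogate_threshold(segs, tspe_cfg, config$max_delay_ms,
                              config$n_surrogates, kern = kern)
    thr <- if (edge_rule == "max") max(st$scores) else st$threshold
    out[[i]] <- data.frame(
      src = pairs$src[i], tgt = pairs$tgt[i],
      region_src = pairs$region_src[i], region_tgt = pairs$region_tgt[i],
      score = s$score, best_delay_ms = s$best_delay_ms, threshold = thr,
      significant = s$score > thr & s$score > 0 & !is.na(s$best_delay_ms) &
        s$best_delay_ms >= 1 & s$best_delay_ms <= config$max_delay_ms,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Region-by-region functional strength matrix
#'
#' `S[r, s]` is the proportion of significant excitatory pairs from region
#' r to region s among all ordered interregional (r, s) unit pairs. The
#' diagonal and any row/column of a region with zero units are NA, never 0.
#'
#' @param pair_scores data.frame with `region_src`, `region_tgt`,
#'   `significant` (one row per scored pair, e.g. one trial's slice of
#'   [detect_connections()] output).
#' @param units data.frame `unit_id`, `region` (defines the denominators).
#' @param region_list ordered region labels.
#' @return numeric matrix R x R with `dimnames` = region_list.
#' @export
strength_matrix <- function(pair_scores, units,
                            region_list = mesoscale_regions()) {
  n_units <- table(factor(units$region, levels = region_list))
  denom <- outer(as.numeric(n_units), as.numeric(n_units))
  diag(denom) <- NA_real_
  denom[denom == 0] <- NA_real_
  sig <- pair_scores[pair_scores$significant, , drop = FALSE]
  num <- table(factor(sig$region_src, levels = region_list),
               factor(sig$region_tgt, levels = region_list))
  S <- as.numeric(num) / denom
  matrix(S, length(region_list), length(region_list),
         dimnames = list(region_list, region_list))
}

#' Strength matrices per trial
#'
#' @param pair_scores output of [detect_connections()] (has `trial_id`).
#' @param units data.frame `unit_id`, `region`.
#' @param region_list ordered region labels.
#' @return named list of matrices, one per trial id.
#' @export
strength_matrices <- function(pair_scores, units,
                              region_list = mesoscale_regions()) {
  lapply(split(pair_scores, pair_scores$trial_id), strength_matrix,
         units = units, region_list = region_list)
}
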