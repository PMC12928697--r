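#' Simulation configuration for the synthetic cohort
#'
#' Defaults define the cohort's study conditions: 10 regions with 3 units
#' each, 5 Hz baseline firing, 20 Hz evoked response decaying with a 200-ms
#' time constant, 300 trials per session, 4 sessions (first half early
#' stage, second half expert), and hit/FA schedules producing a rising
#' correct-rejection rate: early sessions sit near d' ~ 1, expert sessions
#' are near error-free. The expert rates look extreme but are forced by the
#' staging rule itself: a 21-trial sliding window under the log-linear
#' count correction tops out at d' ~ 3.4 and a single error inside the
#' window already drops it below the d' > 3 threshold, so "expert" trials
#' are by definition stretches of essentially perfect performance. Lick
#' latency is ~350 ms after the response signal.
#'
#' @param ... named overrides of any default.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    region_list = mesoscale_regions(),
    n_units_per_region = 3,
    base_rate = 5,            # Hz
    evoked_rate = 20,         # Hz peak above baseline
    evoked_tau_s = 0.2,       # decay time constant
    n_trials = 300,           # per session
    n_sessions = 4,
    hit_rates = NULL,         # default derived from n_sessions below
    fa_rates = NULL,
    lick_latency_mean_s = 0.35,
    lick_latency_sd_s = 0.15,
    edge_jitter_sd_ms = 0.5,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown sim config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  n_early <- floor(cfg$n_sessions / 2)
  n_expert <- cfg$n_sessions - n_early
  if (is.null(cfg$hit_rates)) {
    cfg$hit_rates <- c(rep(0.95, n_early), rep(0.9995, n_expert))
  }
  if (is.null(cfg$fa_rates)) {
    cfg$fa_rates <- c(seq(0.75, 0.65, length.out = n_early),
                      rep(0.0005, n_expert))
  }
  stopifnot(cfg$base_rate > 0, cfg$evoked_rate > 0,
            all(cfg$hit_rates >= 0 & cfg$hit_rates <= 1),
            all(cfg$fa_rates >= 0 & cfg$fa_rates <= 1),
            length(cfg$hit_rates) == cfg$n_sessions,
            length(cfg$fa_rates) == cfg$n_sessions)
  structure(cfg, class = c("sim_config", "list"))
}

#' Ground truth for one simulated session
#'
#' @param planted_edges data.frame with columns `src`, `tgt` (unit ids),
#'   `p` (spike-transfer probability) and `delay_ms` in `[1, 20]`.
#' @param region_latency named numeric: stimulus-response latency (ms) per
#'   region.
#' @param stage "early" or "expert".
#' @param region_gain evoked-rate multipliers per trial type: a list with
#'   named numeric elements `Go` and `NoGo` (per region). `NULL` = 1
#'   everywhere (no planted stimulus selectivity).
#' @return list of class `ground_truth`.
#' @export
ground_truth <- function(planted_edges, region_latency, stage = "early",
                         region_gain = NULL) {
  if (nrow(planted_edges) > 0L) {
    stopifnot(all(planted_edges$p >= 0 & planted_edges$p <= 1),
              all(planted_edges$delay_ms >= 1 &
                    planted_edges$delay_ms <= 20))
  }
  stopifnot(all(region_latency >= 0))
  if (is.null(region_gain)) {
    ones <- stats::setNames(rep(1, length(region_latency)),
                            names(region_latency))
    region_gain <- list(Go = ones, NoGo = ones)
  }
  structure(list(planted_edges = planted_edges,
                 region_latency = region_latency, stage = stage,
                 region_gain = region_gain),
            class = c("ground_truth", "list"))
}

#' Pseudo-random balanced Go/NoGo stimulus sequence
#'
#' Every disjoint block of six consecutive trials contains exactly 3 Go and
#' 3 NoGo stimuli, in uniformly random within-block order; a final partial
#' block is filled by a random prefix of a balanced block.
#'
#' @param n_trials number of trials.
#' @param seed optional RNG seed.
#' @return character vector of "Go"/"NoGo" labels.
#' @export
generate_trial_sequence <- function(n_trials, seed = NULL) {
  stopifnot(n_trials > 0)
  if (!is.null(seed)) set.seed(seed)
  n_blocks <- ceiling(n_trials / 6)
  out <- unlist(lapply(seq_len(n_blocks), function(i) {
    block <- rep("NoGo", 6)
    block[sample.int(6, 3)] <- "Go"
    block
  }))
  out[seq_len(n_trials)]
}

# lick latency after the response signal, truncated into the window
.lick_latency <- function(n, mean_s, sd_s, window_s) {
  lat <- stats::rnorm(n, mean_s, sd_s)
  pmin(pmax(lat, 0.05), window_s - 0.05)
}

#' Generate behavior (lick times, trial timing) for a stimulus sequence
#'
#' Each Go trial is licked with probability `hit_rate`, each NoGo trial with
#' probability `fa_rate`; licks fall inside the response window (a short
#' burst starting at the latency draw). Trial onsets advance by the 800-ms
#' stimulus, the 1.7-s response window and an inter-trial interval
#' randomized in 4-6 s, shortened by 2 s after a correct rejection and
#' extended by an 8-s timeout after a false alarm.
#'
#' @param stimuli character vector of "Go"/"NoGo".
#' @param hit_rate,fa_rate response probabilities.
#' @param sim a [sim_config()].
#' @param session_id session label.
#' @param t0 clock time (s) of the first stimulus onset.
#' @param seed optional RNG seed.
#' @return A [trial_table()] with outcomes assigned.
#' @export
generate_behavior <- function(stimuli, hit_rate, fa_rate,
                              sim = sim_config(), session_id = "s1",
                              t0 = 10, seed = NULL) {
  stopifnot(hit_rate >= 0, hit_rate <= 1, fa_rate >= 0, fa_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(stimuli)
  resp_win <- 1.7
  respond <- stats::runif(n) < ifelse(stimuli == "Go", hit_rate, fa_rate)
  onsets <- numeric(n)
  licks <- vector("list", n)
  t <- t0
  for (k in seq_len(n)) {
    onsets[k] <- t
    rs <- t + 0.8
    if (respond[k]) {
      lat <- .lick_latency(1, sim$lick_latency_mean_s,
                           sim$lick_latency_sd_s, resp_win)
      burst <- rs + lat + 0.12 * (seq_len(1 + stats::rpois(1, 1)) - 1)
      licks[[k]] <- burst[burst < rs + resp_win]
    } else {
      licks[[k]] <- numeric(0)
    }
    iti <- stats::runif(1, 4, 6)
    if (stimuli[k] == "NoGo") {
      iti <- if (respond[k]) min(iti + 8, 30) else max(iti - 2, 0)
    }
    t <- rs + resp_win + iti
  }
  tt <- trial_table(data.frame(
    trial_id = seq_len(n), session_id = session_id, stimulus = stimuli,
    stim_onset_s = onsets, lick_times = I(licks), stringsAsFactors = FALSE
  ))
  assign_outcomes(tt, response_window_s = resp_win)
}

# inverse-CDF draw from a truncated exponential decay of horizon h, tau
.evoked_times <- function(n, tau, horizon) {
  u <- stats::runif(n)
  -tau * log(1 - u * (1 - exp(-horizon / tau)))
}

#' Generate spike trains for one session
#'
#' Each unit emits a homogeneous Poisson baseline over the session, plus an
#' evoked component per trial: from `region_latency[r]` ms after stimulus
#' onset the rate steps up by `evoked_rate` and decays exponentially
#' (`evoked_tau_s`). Then every planted edge (a -> b, p, d) lets each spike
#' of a independently insert a spike in b at delay d plus sub-ms Gaussian
#' jitter. Trains are re-sorted at the end.
#'
#' @param trials a `trial_table` for the session.
#' @param truth a [ground_truth()].
#' @param sim a [sim_config()].
#' @param session_id session label.
#' @param seed optional RNG seed.
#' @return A [spike_dataset()].
#' @export
generate_spikes <- function(trials, truth, sim = sim_config(),
                            session_id = "s1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  regions <- sim$region_list
  t_end <- max(trials$stim_onset_s) + 10
  t_start <- max(min(trials$stim_onset_s) - 10, 0)
  horizon <- 5 * sim$evoked_tau_s
  unit_ids <- as.vector(t(outer(regions, seq_len(sim$n_units_per_region),
                                function(r, i) paste(r, i, sep = "_"))))
  unit_region <- rep(regions, each = sim$n_units_per_region)
  names(unit_region) <- unit_ids
  trains <- vector("list", length(unit_ids))
  names(trains) <- unit_ids
  for (i in seq_along(unit_ids)) {
    r <- unit_region[i]
    n_base <- stats::rpois(1, sim$base_rate * (t_end - t_start))
    base <- t_start + stats::runif(n_base) * (t_end - t_start)
    lat_s <- truth$region_latency[[r]] / 1000
    gain <- vapply(trials$stimulus, function(st) {
      g <- truth$region_gain[[st]][[r]]
      if (is.null(g)) 1 else g
    }, numeric(1))
    mean_evoked <- gain * sim$evoked_rate * sim$evoked_tau_s *
      (1 - exp(-horizon / sim$evoked_tau_s))
    n_ev <- stats::rpois(nrow(trials), mean_evoked)
    ev <- trials$stim_onset_s[rep.int(seq_len(nrow(trials)), n_ev)] +
      lat_s + .evoked_times(sum(n_ev), sim$evoked_tau_s, horizon)
    trains[[i]] <- c(base, ev)
  }
  edges <- truth$planted_edges
  if (!is.null(edges) && nrow(edges) > 0L) {
    inserted <- vector("list", nrow(edges))
    for (e in seq_len(nrow(edges))) {
      src <- trains[[edges$src[e]]]
      hit <- stats::runif(length(src)) < edges$p[e]
      if (!any(hit)) next
      d <- edges$delay_ms[e] / 1000 +
        stats::rnorm(sum(hit), 0, sim$edge_jitter_sd_ms / 1000)
      inserted[[e]] <- data.frame(unit_id = edges$tgt[e],
                                  time_s = src[hit] + d,
                                  stringsAsFactors = FALSE)
    }
    inserted <- do.call(rbind,
                        inserted[!vapply(inserted, is.null, logical(1))])
    if (!is.null(inserted)) {
      for (u in unique(inserted$unit_id)) {
        trains[[u]] <- c(trains[[u]],
                         inserted$time_s[inserted$unit_id == u])
      }
    }
  }
  spikes <- data.frame(
    unit_id = rep(unit_ids, lengths(trains)),
    region = rep(unname(unit_region), lengths(trains)),
    time_s = pmax(unlist(trains, use.names = FALSE), 0),
    stringsAsFactors = FALSE
  )
  spike_dataset(spikes, region_list = regions, session_id = session_id)
}

# region activation order used to assign latencies: visual first, then
# association/frontal, then motor and subcortical
.activation_order <- function(regions) {
  pref <- c("V1", "V2L", "V2M", "ACC", "OFC", "mPFC", "M2", "M1",
            "MDTh", "STR")
  c(intersect(pref, regions), setdiff(regions, pref))
}

# default stage profiles: latency spreads chosen so the mean pairwise
# difference of regional latencies is ~170 ms (early) vs ~57 ms (expert);
# visual->frontal edges exist only in the expert stage; stimulus
# discrimination (Go vs NoGo evoked gain) is confined to the visual
# regions early and spreads network-wide with expertise
.stage_profile <- function(stage, sim) {
  regions <- sim$region_list
  ord <- .activation_order(regions)
  R <- length(regions)
  step <- if (stage == "expert") 15.5 else 46
  base <- if (stage == "expert") 40 else 50
  lat <- stats::setNames(base + step * (seq_len(R) - 1), ord)[regions]
  base_motifs <- list(c("V1", "V2M"), c("ACC", "M2"), c("MDTh", "STR"))
  vf_motifs <- list(c("V1", "OFC"), c("V1", "mPFC"), c("V2M", "OFC"),
                    c("V2M", "M2"))
  motifs <- if (stage == "expert") c(base_motifs, vf_motifs) else base_motifs
  motifs <- Filter(function(m) all(m %in% regions), motifs)
  selective <- if (stage == "expert") regions else {
    intersect(c("V1", "V2M", "V2L"), regions)
  }
  go <- stats::setNames(rep(1, R), regions)
  nogo <- go
  go[selective] <- 1.3
  nogo[selective] <- 0.7
  list(latency = lat, motifs = motifs,
       gain = list(Go = go, NoGo = nogo))
}

# expand region-level motifs to all unit-level ordered pairs
.motif_edges <- function(motifs, n_per_region) {
  if (length(motifs) == 0L) {
    return(data.frame(src = character(0), tgt = character(0),
                      p = numeric(0), delay_ms = numeric(0)))
  }
  out <- lapply(motifs, function(m) {
    grid <- expand.grid(i = seq_len(n_per_region), j = seq_len(n_per_region))
    data.frame(src = paste(m[1], grid$i, sep = "_"),
               tgt = paste(m[2], grid$j, sep = "_"),
               p = stats::runif(nrow(grid), 0.25, 0.4),
               delay_ms = sample(2:15, nrow(grid), replace = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Generate a multi-session learning cohort
#'
#' Sessions share one clock (each starts 100 s after the previous ends) and
#' units are not tracked across sessions (unit ids are session-prefixed).
#' The first half of the sessions uses the early-stage profile — broad
#' regional latency spread (mean pairwise difference ~170 ms), only baseline
#' planted edges, and hit/FA schedules giving low d' — and the second half
#' the expert profile: compressed, earlier latencies (~57 ms spread),
#' additional visual-to-frontal planted edges, and near-perfect behavior so
#' sliding d' exceeds 3.
#'
#' @param sim a [sim_config()].
#' @param seed RNG seed (defaults to `sim$seed`).
#' @return list with `spikes` (one merged [spike_dataset()]), `trials` (one
#'   merged [trial_table()]) and `truth` (per-session [ground_truth()]s).
#' @export
generate_learning_dataset <- function(sim = sim_config(), seed = sim$seed) {
  stopifnot(sim$n_sessions >= 2)
  set.seed(seed)
  n_early <- floor(sim$n_sessions / 2)
  t0 <- 10
  all_spikes <- list(); all_trials <- list(); truths <- list()
  for (k in seq_len(sim$n_sessions)) {
    stage <- if (k <= n_early) "early" else "expert"
    sid <- paste0("s", k)
    prof <- .stage_profile(stage, sim)
    truth <- ground_truth(.motif_edges(prof$motifs, sim$n_units_per_region),
                          prof$latency, stage = stage,
                          region_gain = prof$gain)
    stimuli <- generate_trial_sequence(sim$n_trials)
    tt <- generate_behavior(stimuli, sim$hit_rates[k], sim$fa_rates[k],
                            sim = sim, session_id = sid, t0 = t0)
    ds <- generate_spikes(tt, truth, sim = sim, session_id = sid)
    # session-prefix unit ids so sessions never share units
    ds$units$unit_id <- paste(sid, ds$units$unit_id, sep = "_")
    ds$spikes$unit_id <- paste(sid, ds$spikes$unit_id, sep = "_")
    truth$planted_edges$src <- paste(sid, truth$planted_edges$src, sep = "_")
    truth$planted_edges$tgt <- paste(sid, truth$planted_edges$tgt, sep = "_")
    all_spikes[[k]] <- ds
    all_trials[[k]] <- tt
    truths[[sid]] <- truth
    t0 <- max(ds$spikes$time_s) + 100
  }
  merged_spikes <- spike_dataset(
    do.call(rbind, lapply(all_spikes, function(d) {
      data.frame(unit_id = d$spikes$unit_id,
                 region = d$units$region[match(d$spikes$unit_id,
                                               d$units$unit_id)],
                 time_s = d$spikes$time_s, stringsAsFactors = FALSE)
    })),
    region_list = sim$region_list, session_id = "cohort"
  )
  merged_trials <- do.call(rbind, all_trials)
  class(merged_trials) <- c("trial_table", "data.frame")
  rownames(merged_trials) <- NULL
  list(spikes = merged_spikes, trials = merged_trials, truth = truths)
}

#' Continuous benchmark network with planted excitatory edges
#'
#' Generates a trial-free recording of independent Poisson units in a few
#' regions and plants directed spike-transfer edges between disjoint unit
#' pairs (every unit is the endpoint of at most one edge, sources and
#' targets drawn from different region halves). Disjointness removes
#' common-input correlations, so recovered edges can be compared one-to-one
#' against the planted set — the standard benchmark for the pooled
#' connectivity detector. Correlational detectors cannot distinguish a
#' direct edge from shared drive; that inherent limitation is assessed
#' separately, not baked into this fixture.
#'
#' @param regions region labels (units split evenly).
#' @param n_per_region units per region.
#' @param rate_hz baseline Poisson rate.
#' @param t_max_s recording length (s).
#' @param n_edges number of planted edges.
#' @param p spike-transfer probability per source spike.
#' @param delays_ms candidate delays (ms), sampled per edge.
#' @param jitter_sd_ms Gaussian jitter SD of the transferred spike (ms).
#' @param seed optional RNG seed.
#' @return list with `dataset` (a [spike_dataset()]) and `edges`
#'   (data.frame `src`, `tgt`, `delay_ms`).
#' @export
simulate_edge_network <- function(regions = c("A", "B", "C", "D"),
                                  n_per_region = 10, rate_hz = 5,
                                  t_max_s = 100, n_edges = 20, p = 0.3,
                                  delays_ms = 2:15, jitter_sd_ms = 0.3,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_units <- length(regions) * n_per_region
  stopifnot(n_edges <= n_units / 2)
  units <- data.frame(
    unit_id = sprintf("u%03d", seq_len(n_units)),
    region = rep(regions, each = n_per_region), stringsAsFactors = FALSE)
  trains <- lapply(seq_len(n_units), function(i) {
    sort(stats::runif(stats::rpois(1, rate_hz * t_max_s), 0, t_max_s))
  })
  names(trains) <- units$unit_id
  half <- n_units / 2
  edges <- data.frame(
    src = sample(units$unit_id[seq_len(half)], n_edges),
    tgt = sample(units$unit_id[half + seq_len(half)], n_edges),
    delay_ms = sample(delays_ms, n_edges, replace = TRUE),
    stringsAsFactors = FALSE)
  for (e in seq_len(n_edges)) {
    src <- trains[[edges$src[e]]]
    keep <- stats::runif(length(src)) < p
    ins <- src[keep] + edges$delay_ms[e] / 1000 +
      stats::rnorm(sum(keep), 0, jitter_sd_ms / 1000)
    trains[[edges$tgt[e]]] <- sort(c(trains[[edges$tgt[e]]], ins))
  }
  dataset <- spike_dataset(data.frame(
    unit_id = rep(units$unit_id, lengths(trains)),
    region = rep(units$region, lengths(trains)),
    time_s = pmax(unlist(trains, use.names = FALSE), 0),
    stringsAsFactors = FALSE), region_list = regions)
  list(dataset = dataset, edges = edges)
}

#' Write a simulated cohort to disk
#'
#' Writes `spikes.csv`, `trials.csv` and `truth.json` (planted edges,
#' regional latencies and stage per session) under `dir`.
#'
#' @param cohort output of [generate_learning_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_spike_table(cohort$spikes, file.path(dir, "spikes.csv"))
  write_trial_table(cohort$trials, file.path(dir, "trials.csv"))
  truth <- lapply(cohort$truth, function(tr) {
    list(stage = tr$stage,
         region_latency_ms = as.list(tr$region_latency),
         region_gain = lapply(tr$region_gain, as.list),
         planted_edges = tr$planted_edges)
  })
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
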