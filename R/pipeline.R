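#' Deterministic per-stage seed derivation
#'
#' Every pipeline stage draws its randomness from a seed derived from the
#' single config seed and the stage name, so stages can be re-run
#' individually and still reproduce the full-run output exactly.
#'
#' @param seed integer master seed.
#' @param stage stage name.
#' @return integer seed in `[1, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483562) + 1L
}

# units active in a session = units with any spike inside the session's
# trial span (units are not tracked across sessions)
.session_units <- function(dataset, trials, session) {
  tr <- trials[trials$session_id == session, , drop = FALSE]
  if (nrow(tr) == 0L) return(dataset$units[0, , drop = FALSE])
  lo <- min(tr$stim_onset_s) - 10
  hi <- max(tr$stim_onset_s) + 10
  in_s <- dataset$spikes$time_s >= lo & dataset$spikes$time_s <= hi
  ids <- unique(dataset$spikes$unit_id[in_s])
  dataset$units[dataset$units$unit_id %in% ids, , drop = FALSE]
}

# majority stage of a session's labeled trials ("excluded" if no early or
# expert labels at all)
.session_stage <- function(trials) {
  vapply(split(trials$stage, trials$session_id), function(st) {
    n_early <- sum(st == "early"); n_expert <- sum(st == "expert")
    if (n_early == 0L && n_expert == 0L) return("excluded")
    if (n_expert > n_early) "expert" else "early"
  }, character(1))
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes behavior labeling, rate/onset analysis, TSPE connectivity,
#' rank dynamics, stimulus encoding and the rank-latency correlation on one
#' spikes + trials pair, writing every stage's tables as CSV under
#' `out_dir` plus a `manifest.json` (seed, input digests, output digests,
#' version). All randomness derives from `config$seed` via [stage_seed()],
#' so identical inputs and seed give byte-identical CSV outputs.
#'
#' @param spikes_path path to `spikes.csv`.
#' @param trials_path path to `trials.csv`.
#' @param out_dir output directory (created if needed).
#' @param config an [analysis_config()].
#' @param tspe_cfg a [tspe_config()].
#' @param region_list ordered region labels.
#' @param windows_ms connectivity/encoding window starts (ms); default all
#'   200-ms windows tiling the analysis span.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(spikes_path, trials_path, out_dir,
                         config = analysis_config(),
                         tspe_cfg = tspe_config(),
                         region_list = mesoscale_regions(),
                         windows_ms = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(windows_ms)) {
    windows_ms <- window_starts(config$span_ms, config$conn_window_ms)
  }
  run_stage <- function(stage, fn) {
    set.seed(stage_seed(config$seed, stage))
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  outputs <- character(0)

  ## behavior -----------------------------------------------------------
  trials <- run_stage("behavior", function() {
    tt <- read_trial_table(trials_path,
                           response_window_s = config$response_window_s)
    label_behavior(tt, config)
  })
  outputs <- c(outputs,
               .write_csv(data.frame(
                 trial_id = trials$trial_id, session_id = trials$session_id,
                 stimulus = trials$stimulus,
                 stim_onset_s = trials$stim_onset_s,
                 outcome = trials$outcome, dprime = round(trials$dprime, 6),
                 stage = trials$stage),
                 file.path(out_dir, "trials_labeled.csv")))

  dataset <- read_spike_table(spikes_path, region_list = region_list)
  aligned <- align_spikes(dataset, trials, config$span_ms)
  sessions <- unique(trials$session_id)
  sess_units <- lapply(stats::setNames(sessions, sessions), function(s) {
    .session_units(dataset, trials, s)
  })
  groups <- expand.grid(stage = c("early", "expert"),
                        type = c("CR", "Hit"), stringsAsFactors = FALSE)

  ## rates + onsets -----------------------------------------------------
  ro <- run_stage("rates_onsets", function() {
    rate_rows <- list(); onset_rows <- list()
    for (g in seq_len(nrow(groups))) {
      st <- groups$stage[g]; ty <- groups$type[g]
      for (s in sessions) {
        tr <- trials[trials$session_id == s & trials$stage == st &
                       trials$outcome == ty, , drop = FALSE]
        if (nrow(tr) < 2L) next
        for (u in sess_units[[s]]$unit_id) {
          res <- detect_onset(aligned, u, tr$trial_id, config)
          onset_rows[[length(onset_rows) + 1L]] <- data.frame(
            stage = st, type = ty, session_id = s, unit_id = u,
            region = dataset$units$region[dataset$units$unit_id == u],
            onset_ms = res$onset_ms, stringsAsFactors = FALSE)
          trace <- compute_rate_trace(aligned, u, tr$trial_id, config)
          rate_rows[[length(rate_rows) + 1L]] <- data.frame(
            stage = st, type = ty, unit_id = u,
            region = dataset$units$region[dataset$units$unit_id == u],
            window_start_ms = trace$window_start_ms,
            rate_hz = trace$rate_hz, stringsAsFactors = FALSE)
        }
      }
    }
    list(onsets = do.call(rbind, onset_rows),
         rates = do.call(rbind, rate_rows))
  })
  if (!is.null(ro$rates)) {
    reg_rates <- stats::aggregate(
      rate_hz ~ stage + type + region + window_start_ms, ro$rates, mean)
    reg_rates$rate_hz <- round(reg_rates$rate_hz, 6)
    outputs <- c(outputs, .write_csv(reg_rates,
                                     file.path(out_dir, "rates.csv")))
  }
  if (!is.null(ro$onsets)) {
    outputs <- c(outputs, .write_csv(ro$onsets,
                                     file.path(out_dir, "onsets.csv")))
    peak_rows <- list(); comp_rows <- list(); test_rows <- list()
    for (g in seq_len(nrow(groups))) {
      st <- groups$stage[g]; ty <- groups$type[g]
      on <- ro$onsets[ro$onsets$stage == st & ro$onsets$type == ty, ,
                      drop = FALSE]
      if (nrow(on) == 0L) next
      pk <- regional_peak_activation(on, config)
      pk$stage <- st; pk$type <- ty
      peak_rows[[length(peak_rows) + 1L]] <- pk
      cs <- compression_spread(stats::setNames(pk$peak_ms, pk$region))
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        stage = st, type = ty, mean_ms = cs$mean_ms, sd_ms = cs$sd_ms,
        n_pairs = cs$n_pairs, stringsAsFactors = FALSE)
    }
    for (ty in unique(groups$type)) {
      oe <- ro$onsets[ro$onsets$stage == "early" & ro$onsets$type == ty, ]
      ox <- ro$onsets[ro$onsets$stage == "expert" & ro$onsets$type == ty, ]
      if (nrow(oe) > 0L && nrow(ox) > 0L) {
        cmp <- compare_onsets_between_stages(oe, ox)
        cmp$type <- ty
        test_rows[[length(test_rows) + 1L]] <- cmp
      }
    }
    if (length(peak_rows)) {
      outputs <- c(outputs, .write_csv(
        do.call(rbind, peak_rows), file.path(out_dir, "regional_peaks.csv")))
    }
    if (length(comp_rows)) {
      outputs <- c(outputs, .write_csv(
        do.call(rbind, comp_rows), file.path(out_dir, "compression.csv")))
    }
    if (length(test_rows)) {
      outputs <- c(outputs, .write_csv(
        do.call(rbind, test_rows),
        file.path(out_dir, "onset_stage_tests.csv")))
    }
  }

  ## connectivity -------------------------------------------------------
  conn <- run_stage("connectivity", function() {
    rows <- list()
    for (g in seq_len(nrow(groups))) {
      st <- groups$stage[g]; ty <- groups$type[g]
      for (s in sessions) {
        tr <- trials[trials$session_id == s & trials$stage == st &
                       trials$outcome == ty, , drop = FALSE]
        if (nrow(tr) < 2L || nrow(sess_units[[s]]) < 2L) next
        for (w0 in windows_ms) {
          ps <- detect_connections(aligned, sess_units[[s]], tr$trial_id,
                                   c(w0, w0 + config$conn_window_ms),
                                   config, tspe_cfg)
          mats <- strength_matrices(ps, sess_units[[s]], region_list)
          lg <- strengths_to_long(mats, w0)
          lg$stage <- st; lg$type <- ty; lg$session_id <- s
          rows[[length(rows) + 1L]] <- lg
        }
      }
    }
    do.call(rbind, rows)
  })
  if (!is.null(conn)) {
    conn_out <- conn
    conn_out$strength <- round(conn_out$strength, 6)
    outputs <- c(outputs, .write_csv(conn_out,
                                     file.path(out_dir, "conn.csv")))
  }

  ## rank dynamics ------------------------------------------------------
  rk <- run_stage("ranks", function() {
    if (is.null(conn)) return(NULL)
    traj <- list(); dr_rows <- list(); test_rows <- list()
    win_rows <- list(); per_rows <- list()
    for (ty in unique(groups$type)) {
      for (dir in c("input", "output")) {
        by_stage <- list()
        for (st in c("early", "expert")) {
          cc <- conn[conn$stage == st & conn$type == ty, , drop = FALSE]
          if (nrow(cc) == 0L) next
          tj <- rank_trajectories(cc, dir, config, region_list)
          by_stage[[st]] <- tj
          ws <- tj$window_summary; ws$stage <- st; ws$type <- ty
          ws$direction <- dir
          win_rows[[length(win_rows) + 1L]] <- ws
          ps <- tj$period_summary; ps$stage <- st; ps$type <- ty
          ps$direction <- dir
          per_rows[[length(per_rows) + 1L]] <- ps
        }
        if (!is.null(by_stage$early) && !is.null(by_stage$expert)) {
          dr <- delta_rank(by_stage$early, by_stage$expert)
          dr$type <- ty; dr$direction <- dir
          dr_rows[[length(dr_rows) + 1L]] <- dr
          ct <- compare_stage_ranks(by_stage$early, by_stage$expert)
          ct$type <- ty; ct$direction <- dir
          test_rows[[length(test_rows) + 1L]] <- ct
        }
        traj[[paste(ty, dir, sep = "_")]] <- by_stage
      }
    }
    list(traj = traj,
         windows = if (length(win_rows)) do.call(rbind, win_rows),
         periods = if (length(per_rows)) do.call(rbind, per_rows),
         delta = if (length(dr_rows)) do.call(rbind, dr_rows),
         tests = if (length(test_rows)) do.call(rbind, test_rows))
  })
  round_cols <- function(df, cols) {
    for (cl in intersect(cols, names(df))) df[[cl]] <- round(df[[cl]], 6)
    df
  }
  if (!is.null(rk$windows)) {
    outputs <- c(outputs, .write_csv(
      round_cols(rk$windows, c("mean_rank", "sem")),
      file.path(out_dir, "ranks_window.csv")))
  }
  if (!is.null(rk$periods)) {
    outputs <- c(outputs, .write_csv(
      round_cols(rk$periods, c("mean_rank", "sem")),
      file.path(out_dir, "ranks_period.csv")))
  }
  if (!is.null(rk$delta)) {
    outputs <- c(outputs, .write_csv(
      round_cols(rk$delta, c("rank_early", "rank_expert", "delta_rank")),
      file.path(out_dir, "delta_rank.csv")))
  }
  if (!is.null(rk$tests)) {
    outputs <- c(outputs, .write_csv(
      round_cols(rk$tests, c("delta_rank", "p_raw", "p_sidak")),
      file.path(out_dir, "rank_stage_tests.csv")))
  }

  ## stimulus encoding --------------------------------------------------
  enc <- run_stage("encoding", function() {
    st_of_session <- .session_stage(trials)
    prof_rows <- list()
    for (st in c("early", "expert")) {
      for (s in sessions[st_of_session[sessions] == st]) {
        tr <- trials[trials$session_id == s, , drop = FALSE]
        un <- sess_units[[s]]
        if (nrow(tr) == 0L || nrow(un) == 0L) next
        pr <- encode_profiles(aligned, un, tr, config)
        pr <- pr[pr$window_start_ms %in% windows_ms, , drop = FALSE]
        pr$stage <- st; pr$session_id <- s
        prof_rows[[length(prof_rows) + 1L]] <- pr
      }
    }
    if (length(prof_rows) == 0L) return(NULL)
    do.call(rbind, prof_rows)
  })
  enc_summ <- NULL
  if (!is.null(enc)) {
    enc_out <- round_cols(enc, c("frac_significant", "median_auroc"))
    outputs <- c(outputs, .write_csv(enc_out,
                                     file.path(out_dir, "encoding.csv")))
    summ_rows <- lapply(c("early", "expert"), function(st) {
      pr <- enc[enc$stage == st, , drop = FALSE]
      if (nrow(pr) == 0L) return(NULL)
      sf <- selective_fractions(pr)
      sf$stage <- st
      sf
    })
    enc_summ <- do.call(rbind, summ_rows[!vapply(summ_rows, is.null,
                                                 logical(1))])
    if (!is.null(enc_summ)) {
      outputs <- c(outputs, .write_csv(
        round_cols(enc_summ, "pct_selective"),
        file.path(out_dir, "encoding_summary.csv")))
    }
  }

  ## rank-latency correlation -------------------------------------------
  corr <- run_stage("correlation", function() {
    if (is.null(enc_summ) || is.null(rk$periods)) return(NULL)
    fams <- list(stim = c(0, 800), resp = c(800, 2800))
    rows <- list()
    for (dir in c("input", "output")) {
      pr <- rk$periods[rk$periods$stage == "expert" &
                         rk$periods$type == "CR" &
                         rk$periods$direction == dir, , drop = FALSE]
      if (nrow(pr) == 0L) next
      rank_by_region <- tapply(pr$mean_rank, pr$region, mean)
      ef <- enc_summ[enc_summ$stage == "expert", , drop = FALSE]
      if (nrow(ef) == 0L) next
      for (fam in names(fams)) {
        peaks <- vapply(unique(ef$region), function(r) {
          peak_encoding_time(ef[ef$region == r, , drop = FALSE],
                             fams[[fam]], config$conn_window_ms)
        }, numeric(1))
        ct <- rank_latency_correlation(rank_by_region, peaks)
        rows[[length(rows) + 1L]] <- data.frame(
          direction = dir, period = fam, r = ct$r, p = ct$p, n = ct$n,
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows) == 0L) return(NULL)
    do.call(rbind, rows)
  })
  if (!is.null(corr)) {
    outputs <- c(outputs, .write_csv(round_cols(corr, c("r", "p")),
                                     file.path(out_dir, "correlation.csv")))
  }

  ## manifest -----------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("mesorank")),
    seed = config$seed,
    inputs = list(spikes = unname(tools::md5sum(spikes_path)),
                  trials = unname(tools::md5sum(trials_path))),
    outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                      basename(outputs))),
    config = unclass(config),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Consolidated pipeline report
#'
#' Reads the tables written by [run_pipeline()] and writes `report.md`
#' summarising the five result families (rate traces, onset timing /
#' compression, rank trajectories, rank changes, stimulus encoding plus the
#' rank-latency correlation); missing stages are flagged as absent. The
#' report is regenerated idempotently from the tables.
#'
#' @param out_dir a [run_pipeline()] output directory.
#' @return path to `report.md`, invisibly.
#' @export
make_report <- function(out_dir) {
  rd <- function(f) {
    p <- file.path(out_dir, f)
    if (file.exists(p)) utils::read.csv(p, stringsAsFactors = FALSE)
    else NULL
  }
  lines <- c("# mesorank pipeline report", "")
  tl <- rd("trials_labeled.csv")
  if (!is.null(tl)) {
    st <- table(tl$stage)
    lines <- c(lines, "## Behavior",
               sprintf("- %d trials; stage counts: %s", nrow(tl),
                       paste(names(st), as.integer(st), sep = "=",
                             collapse = ", ")), "")
  } else lines <- c(lines, "## Behavior", "- ABSENT", "")
  rt <- rd("rates.csv")
  lines <- c(lines, "## Firing rates",
             if (is.null(rt)) "- ABSENT" else
               sprintf("- rate traces for %d (stage, type, region) groups",
                       nrow(unique(rt[, c("stage", "type", "region")]))), "")
  on <- rd("onsets.csv"); cp <- rd("compression.csv")
  if (!is.null(on)) {
    lines <- c(lines, "## Activity onsets",
               sprintf("- %d (unit, stage, type) onset records, %d with onset",
                       nrow(on), sum(!is.na(on$onset_ms))))
    if (!is.null(cp)) {
      for (i in seq_len(nrow(cp))) {
        lines <- c(lines, sprintf(
          "- %s %s: peak-time spread %.1f +/- %.1f ms", cp$stage[i],
          cp$type[i], cp$mean_ms[i], cp$sd_ms[i]))
      }
    }
    lines <- c(lines, "")
  } else lines <- c(lines, "## Activity onsets", "- ABSENT", "")
  rp <- rd("ranks_period.csv"); dr <- rd("delta_rank.csv")
  lines <- c(lines, "## Rank trajectories",
             if (is.null(rp)) "- ABSENT" else
               sprintf("- period-mean ranks for %d (stage, type, direction) groups",
                       nrow(unique(rp[, c("stage", "type", "direction")]))),
             "")
  if (!is.null(dr)) {
    top <- dr[order(-abs(dr$delta_rank)), ][1, ]
    lines <- c(lines, "## Rank changes (expert - early)",
               sprintf("- %d (region, period, type, direction) cells; largest |dRank|: %s %s %s %s = %+.2f",
                       nrow(dr), top$region, top$period, top$type,
                       top$direction, top$delta_rank), "")
  } else lines <- c(lines, "## Rank changes (expert - early)", "- ABSENT", "")
  es <- rd("encoding_summary.csv"); cr <- rd("correlation.csv")
  if (!is.null(es)) {
    mx <- es[which.max(es$pct_selective), ]
    lines <- c(lines, "## Stimulus encoding",
               sprintf("- selective fractions for %d (stage, region, window) cells; max %.1f%% (%s, %s stage, %g ms)",
                       nrow(es), mx$pct_selective, mx$region, mx$stage,
                       mx$window_start_ms))
    if (!is.null(cr)) {
      for (i in seq_len(nrow(cr))) {
        lines <- c(lines, sprintf(
          "- rank vs encoding peak (%s, %s period): r = %.3f, p = %.4f, n = %d",
          cr$direction[i], cr$period[i], cr$r[i], cr$p[i], cr$n[i]))
      }
    }
    lines <- c(lines, "")
  } else lines <- c(lines, "## Stimulus encoding", "- ABSENT", "")
  path <- file.path(out_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
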