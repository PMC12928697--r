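# aligned-spike data frame built directly (bypasses alignment; all times ms)
make_aligned <- function(t_ms, trial_id, unit_id = "u1", region = "V1") {
  data.frame(unit_id = unit_id, region = region, trial_id = trial_id,
             t_ms = t_ms, stringsAsFactors = FALSE)
}

# aligned spikes for homogeneous Poisson units, n_trials trials
poisson_aligned <- function(n_units, n_trials, rate_hz,
                            span_ms = c(-600, 2800)) {
  dur_s <- diff(span_ms) / 1000
  rows <- lapply(seq_len(n_units), function(u) {
    n_per <- rpois(n_trials, rate_hz * dur_s)
    data.frame(
      unit_id = sprintf("u%04d", u), region = "V1",
      trial_id = rep.int(seq_len(n_trials), n_per),
      t_ms = runif(sum(n_per), span_ms[1], span_ms[2]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

test_that("rate traces convert counts to Hz and average over trials", {
  cfg <- analysis_config()
  al <- make_aligned(t_ms = 10, trial_id = 1)
  tr <- compute_rate_trace(al, "u1", 1, cfg)
  w <- which(tr$window_start_ms == 0)
  expect_equal(tr$rate_hz[w], 40)        # 1 spike / 0.025 s
  expect_equal(sum(tr$rate_hz > 0), 1)
  expect_equal(tr$time_ms, tr$window_start_ms + 12.5)
  expect_equal(nrow(compute_rate_trace(al, "u1", integer(0), cfg)), 0)
})

test_that("rate traces match a brute-force per-trial average and conserve counts", {
  set.seed(41)
  cfg <- analysis_config()
  al <- poisson_aligned(1, 30, 12)
  tr <- compute_rate_trace(al, "u0001", 1:30, cfg)
  # brute force: per trial, count spikes per window with a double loop
  starts <- window_starts(cfg$span_ms, 25)
  brute <- matrix(0, 30, length(starts))
  for (k in 1:30) {
    tk <- al$t_ms[al$trial_id == k]
    for (w in seq_along(starts)) {
      brute[k, w] <- sum(tk >= starts[w] & tk < starts[w] + 25) / 0.025
    }
  }
  expect_equal(tr$rate_hz, colMeans(brute))
  # integrating rate x window over the span returns each trial's count
  expect_equal(sum(brute[7, ] * 0.025), sum(al$trial_id == 7))
  # homogeneous 10 Hz: all windows near the true rate
  al2 <- poisson_aligned(1, 200, 10)
  tr2 <- compute_rate_trace(al2, "u0001", 1:200, cfg)
  expect_true(all(abs(tr2$rate_hz - 10) < 6))
  expect_true(all(tr2$rate_hz >= 0))
})

test_that("bootstrap traces resample 5 trials per session with replacement", {
  set.seed(42)
  cfg <- analysis_config()
  al <- poisson_aligned(1, 20, 8)
  trials <- data.frame(trial_id = 1:20,
                       session_id = rep(c("s1", "s2"), each = 10))
  bt <- bootstrap_rate_traces(al, "u0001", trials, cfg, n_reps = 100,
                              seed = 5)
  expect_equal(dim(bt$reps), c(100, length(bt$window_start_ms)))
  # unbiased: rep-mean close to the all-trials mean
  full <- compute_rate_trace(al, "u0001", 1:20, cfg)
  expect_lt(mean(abs(bt$mean_trace - full$rate_hz)), 1.5)
  # determinism under the seed
  bt2 <- bootstrap_rate_traces(al, "u0001", trials, cfg, n_reps = 100,
                               seed = 5)
  expect_identical(bt$reps, bt2$reps)
  # a single trial per session collapses every rep onto that trial
  bt1 <- bootstrap_rate_traces(al, "u0001", trials[1, , drop = FALSE], cfg,
                               n_reps = 10, seed = 6)
  expect_true(all(apply(bt1$reps, 2, function(v) length(unique(v)) == 1)))
})

test_that("onset detection needs three consecutive significant windows", {
  cfg <- analysis_config()
  set.seed(43)
  # stationary unit: no onset
  al <- poisson_aligned(1, 60, 6)
  expect_true(is.na(detect_onset(al, "u0001", 1:60, cfg)$onset_ms))
  # planted step 2 -> 30 Hz at 100 ms: onset within one window of truth
  n_tr <- 100
  base <- poisson_aligned(1, n_tr, 2)
  n_ev <- rpois(n_tr, 30 * 0.9)
  ev <- data.frame(unit_id = "u0001", region = "V1",
                   trial_id = rep.int(seq_len(n_tr), n_ev),
                   t_ms = runif(sum(n_ev), 100, 1000),
                   stringsAsFactors = FALSE)
  res <- detect_onset(rbind(base, ev), "u0001", 1:n_tr, cfg)
  expect_true(res$onset_ms %in% c(75, 100, 125))
  expect_equal(res$window_start_ms,
               window_starts(cfg$span_ms, cfg$rate_window_ms))
})

test_that("two isolated significant windows never define an onset", {
  # build counts directly through the aligned interface: two separated
  # high-rate windows only
  cfg <- analysis_config()
  set.seed(44)
  n_tr <- 80
  base <- poisson_aligned(1, n_tr, 4)
  burst <- function(w0) data.frame(
    unit_id = "u0001", region = "V1",
    trial_id = rep(seq_len(n_tr), each = 3),
    t_ms = runif(3 * n_tr, w0, w0 + 25), stringsAsFactors = FALSE)
  # bursts in windows [200,225) and [250,275) with a quiet gap between
  al <- rbind(base, burst(200), burst(250))
  res <- detect_onset(al, "u0001", 1:n_tr, cfg)
  p <- res$p_values
  w <- res$window_start_ms
  expect_lt(p[w == 200], 0.05)
  expect_lt(p[w == 250], 0.05)
  # runs of length >= 3 are required; the onset cannot sit in the bursts
  # unless the gap window went significant too
  if (!is.na(res$onset_ms) && res$onset_ms %in% c(200, 225, 250)) {
    expect_lt(p[w == 225], 0.05)
  }
})

test_that("regional peaks and the compression statistic follow their rules", {
  cfg <- analysis_config()
  on <- data.frame(unit_id = c("a", "b", "c", "d"),
                   region = c("V1", "V1", "V1", "M1"),
                   onset_ms = c(100, 100, 200, NA),
                   stringsAsFactors = FALSE)
  pk <- regional_peak_activation(on, cfg)
  expect_equal(pk$peak_ms[pk$region == "V1"], 100)
  expect_true(is.na(pk$peak_ms[pk$region == "M1"]))
  expect_equal(pk$n_onsets, c(3, 0))
  # tie -> earliest window
  on2 <- data.frame(unit_id = c("a", "b"), region = "V1",
                    onset_ms = c(300, 100), stringsAsFactors = FALSE)
  expect_equal(regional_peak_activation(on2, cfg)$peak_ms, 100)

  expect_equal(compression_spread(c(100, 100))$mean_ms, 0)
  expect_equal(compression_spread(c(100, 300))$mean_ms, 200)
  cs <- compression_spread(c(0, 100, 200))
  expect_equal(cs$mean_ms, (100 + 200 + 100) / 3)
  expect_equal(cs$n_pairs, 3)
  expect_true(is.na(compression_spread(c(100, NA))$mean_ms))
})

test_that("staggered planted latencies are recovered in peak order", {
  set.seed(45)
  cfg <- analysis_config()
  lat <- c(V1 = 50, ACC = 200, M1 = 400)
  rows <- list()
  for (r in names(lat)) {
    for (u in 1:8) {
      uid <- paste(r, u, sep = "_")
      base <- poisson_aligned(1, 60, 3)
      base$unit_id <- uid; base$region <- r
      n_ev <- rpois(60, 25 * 0.3)
      ev <- data.frame(unit_id = uid, region = r,
                       trial_id = rep.int(1:60, n_ev),
                       t_ms = lat[[r]] + rexp(sum(n_ev), 1 / 150),
                       stringsAsFactors = FALSE)
      rows[[uid]] <- rbind(base, ev)
    }
  }
  al <- do.call(rbind, rows)
  units <- unique(al[, c("unit_id", "region")])
  on <- do.call(rbind, lapply(seq_len(nrow(units)), function(i) {
    data.frame(unit_id = units$unit_id[i], region = units$region[i],
               onset_ms = detect_onset(al, units$unit_id[i], 1:60,
                                       cfg)$onset_ms,
               stringsAsFactors = FALSE)
  }))
  pk <- regional_peak_activation(on, cfg)
  pk <- pk[match(names(lat), pk$region), ]
  expect_true(all(diff(pk$peak_ms) > 0))  # V1 < ACC < M1
})

test_that("stage comparison of onsets applies the Sidak correction", {
  expect_equal(sidak_adjust(0.01, 10), 1 - 0.99^10)
  expect_equal(sidak_adjust(0.3, 1), 0.3)
  set.seed(46)
  oe <- data.frame(unit_id = paste0("e", 1:10), region = "V1",
                   onset_ms = 25 * round(rnorm(10, 16, 2)),
                   stringsAsFactors = FALSE)
  ox <- oe; ox$unit_id <- paste0("x", 1:10)
  cmp <- compare_onsets_between_stages(oe, ox)
  expect_gt(cmp$p_sidak, 0.99)   # identical groups
  ox2 <- ox; ox2$onset_ms <- ox$onset_ms - 200
  cmp2 <- compare_onsets_between_stages(oe, ox2)
  expect_lt(cmp2$p_sidak, 0.01)
  # insufficient group reported but not tested
  cmp3 <- compare_onsets_between_stages(oe[1, ], ox)
  expect_true(is.na(cmp3$p_raw))
})
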