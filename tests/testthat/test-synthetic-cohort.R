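test_that("stimulus sequence is balanced in every block of six", {
  s6 <- generate_trial_sequence(6, seed = 1)
  expect_equal(sum(s6 == "Go"), 3)
  expect_equal(sum(s6 == "NoGo"), 3)
  s12 <- generate_trial_sequence(12, seed = 2)
  expect_equal(unname(table(s12[1:6])["Go"]), 3)
  expect_equal(unname(table(s12[7:12])["Go"]), 3)
  # determinism
  expect_identical(generate_trial_sequence(60, seed = 9),
                   generate_trial_sequence(60, seed = 9))
})

test_that("all 20 within-block orders occur uniformly", {
  set.seed(42)
  n_blocks <- 10000
  s <- generate_trial_sequence(6 * n_blocks)
  blocks <- matrix(s == "Go", nrow = 6)
  codes <- apply(blocks, 2, function(b) paste(as.integer(b), collapse = ""))
  freq <- table(codes) / n_blocks
  expect_equal(length(freq), choose(6, 3))
  expect_true(all(abs(freq - 0.05) < 0.01))
})

test_that("behavioral rates hit their targets and extremes are exact", {
  tt1 <- generate_behavior(generate_trial_sequence(60, seed = 1), 1, 0,
                           seed = 2)
  expect_true(all(tt1$outcome[tt1$stimulus == "Go"] == "Hit"))
  expect_true(all(tt1$outcome[tt1$stimulus == "NoGo"] == "CR"))
  tt0 <- generate_behavior(generate_trial_sequence(60, seed = 1), 0, 0,
                           seed = 2)
  expect_true(all(tt0$outcome[tt0$stimulus == "Go"] == "Miss"))

  # empirical frequencies within binomial 95% CI at n = 600
  h <- 0.8; f <- 0.3
  tt <- generate_behavior(generate_trial_sequence(600, seed = 3), h, f,
                          seed = 4)
  n_go <- sum(tt$stimulus == "Go")
  n_nogo <- 600 - n_go
  hit_hat <- mean(tt$outcome[tt$stimulus == "Go"] == "Hit")
  fa_hat <- mean(tt$outcome[tt$stimulus == "NoGo"] == "FA")
  expect_lt(abs(hit_hat - h), 1.96 * sqrt(h * (1 - h) / n_go))
  expect_lt(abs(fa_hat - f), 1.96 * sqrt(f * (1 - f) / n_nogo))
})

test_that("trial timing follows the ITI reward/punishment rules", {
  tt <- generate_behavior(generate_trial_sequence(120, seed = 5), 0.9, 0.5,
                          seed = 6)
  gaps <- diff(tt$stim_onset_s) - 2.5     # stimulus + response window
  out <- tt$outcome[-nrow(tt)]
  expect_true(all(gaps[out %in% c("Hit", "Miss")] >= 4 - 1e-9 &
                    gaps[out %in% c("Hit", "Miss")] <= 6 + 1e-9))
  expect_true(all(gaps[out == "CR"] >= 2 - 1e-9 &
                    gaps[out == "CR"] <= 4 + 1e-9))
  expect_true(all(gaps[out == "FA"] >= 12 - 1e-9))
})

test_that("baseline spike counts are Poisson at the configured rate", {
  sim <- sim_config(n_units_per_region = 1, base_rate = 5,
                    evoked_rate = 1e-9)
  truth <- ground_truth(
    data.frame(src = character(0), tgt = character(0), p = numeric(0),
               delay_ms = numeric(0)),
    setNames(rep(0, 10), mesoscale_regions())
  )
  # trials at 10 s and 110 s make the session span [0, 120] s; the evoked
  # rate is negligible, so counts are pure baseline Poisson
  tt <- toy_trials(onsets = c(10, 110), stimulus = c("Go", "Go"),
                   licks = list(numeric(0), numeric(0)))
  set.seed(11)
  ds <- generate_spikes(tt, truth, sim)
  lam <- 5 * 120
  for (u in ds$units$unit_id) {
    n <- length(unit_spikes(ds, u))
    expect_true(abs(n - lam) < 2.58 * sqrt(lam) + 3,
                label = paste("unit", u, "count", n))
  }
})

test_that("a p = 1 edge copies the source train at its delay", {
  regions <- c("V1", "OFC")
  sim <- sim_config(region_list = regions, n_units_per_region = 1,
                    base_rate = 4, evoked_rate = 1e-9,
                    edge_jitter_sd_ms = 1e-9)
  truth <- ground_truth(
    data.frame(src = "V1_1", tgt = "OFC_1", p = 1, delay_ms = 5,
               stringsAsFactors = FALSE),
    c(V1 = 0, OFC = 0)
  )
  tt <- toy_trials(onsets = c(100, 400), stimulus = c("Go", "Go"),
                   licks = list(numeric(0), numeric(0)))
  set.seed(12)
  ds <- generate_spikes(tt, truth, sim)
  src <- unit_spikes(ds, "V1_1")
  tgt <- unit_spikes(ds, "OFC_1")
  # every source spike appears in the target shifted by exactly +5 ms
  copied <- src + 0.005
  matched <- vapply(copied, function(t) any(abs(tgt - t) < 1e-6), logical(1))
  expect_true(all(matched))
  expect_gte(length(tgt), length(src))
})

test_that("planted-edge cross-correlogram peaks at the planted delay", {
  regions <- c("V1", "OFC")
  sim <- sim_config(region_list = regions, n_units_per_region = 1,
                    base_rate = 8, evoked_rate = 1e-9,
                    edge_jitter_sd_ms = 0.3)
  truth <- ground_truth(
    data.frame(src = "V1_1", tgt = "OFC_1", p = 0.6, delay_ms = 7,
               stringsAsFactors = FALSE),
    c(V1 = 0, OFC = 0)
  )
  tt <- toy_trials(onsets = 500, stimulus = "Go", licks = list(numeric(0)))
  set.seed(13)
  ds <- generate_spikes(tt, truth, sim)
  cc <- cross_correlogram(unit_spikes(ds, "V1_1") * 1000,
                          unit_spikes(ds, "OFC_1") * 1000)
  # symmetric sub-ms jitter around +7 ms splits mass over bins [6,7) and
  # [7,8); the peak must be one of them
  expect_true(cc$lag_ms[which.max(cc$counts)] %in% c(6, 7))
})

test_that("edge-triggered insertions are Binomial(source count, p)", {
  regions <- c("V1", "OFC")
  # session span [0, 1010] s: long enough for a tight relative CI
  tt <- toy_trials(onsets = c(10, 1000), stimulus = c("Go", "Go"),
                   licks = list(numeric(0), numeric(0)))
  t_span <- 1010
  for (p in c(0.2, 0.5, 1.0)) {
    sim <- sim_config(region_list = regions, n_units_per_region = 1,
                      base_rate = 6, evoked_rate = 1e-9)
    truth <- ground_truth(
      data.frame(src = "V1_1", tgt = "OFC_1", p = p, delay_ms = 5,
                 stringsAsFactors = FALSE),
      c(V1 = 0, OFC = 0)
    )
    set.seed(100 + round(100 * p))
    ds <- generate_spikes(tt, truth, sim)
    n_src <- length(unit_spikes(ds, "V1_1"))
    n_tgt <- length(unit_spikes(ds, "OFC_1"))
    # both units share the baseline rate, so (target - source) counts =
    # inserted spikes + difference of two Poisson baselines
    inserted <- n_tgt - n_src
    expected <- p * n_src
    tol <- 2.58 * sqrt(n_src * p * (1 - p) + 2 * 6 * t_span)
    expect_lt(abs(inserted - expected), tol)
  }
})

test_that("the learning cohort obeys its stage design", {
  coh <- generate_learning_dataset(
    sim_config(n_units_per_region = 1, n_trials = 40, n_sessions = 2,
               hit_rates = c(0.9, 0.99), fa_rates = c(0.7, 0.01)),
    seed = 3)
  expect_s3_class(coh$spikes, "spike_dataset")
  expect_equal(length(coh$truth), 2)
  expect_equal(coh$truth$s1$stage, "early")
  expect_equal(coh$truth$s2$stage, "expert")
  # expert latency spread strictly smaller by construction
  spread <- function(l) mean(abs(as.numeric(dist(matrix(l, ncol = 1)))))
  expect_lt(spread(coh$truth$s2$region_latency),
            spread(coh$truth$s1$region_latency))
  # expert planted motif set strictly contains the early motifs, with the
  # designated visual-frontal pairs added
  pair_of <- function(e) unique(paste(sub("^s\\d+_([A-Za-z0-9]+)_.*", "\\1", e$src),
                                      sub("^s\\d+_([A-Za-z0-9]+)_.*", "\\1", e$tgt)))
  early_pairs <- pair_of(coh$truth$s1$planted_edges)
  expert_pairs <- pair_of(coh$truth$s2$planted_edges)
  expect_true(all(early_pairs %in% expert_pairs))
  expect_true(all(c("V1 OFC", "V1 mPFC", "V2M OFC") %in% expert_pairs))
  # identical seed reproduces byte-identical output
  coh2 <- generate_learning_dataset(
    sim_config(n_units_per_region = 1, n_trials = 40, n_sessions = 2,
               hit_rates = c(0.9, 0.99), fa_rates = c(0.7, 0.01)),
    seed = 3)
  expect_identical(coh$spikes$spikes, coh2$spikes$spikes)
  expect_identical(coh$trials$stim_onset_s, coh2$trials$stim_onset_s)
})

test_that("the cohort writes and re-reads from disk", {
  coh <- generate_learning_dataset(
    sim_config(n_units_per_region = 1, n_trials = 20, n_sessions = 2),
    seed = 4)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(all(file.exists(file.path(dir, c("spikes.csv", "trials.csv",
                                               "truth.json")))))
  back <- read_spike_table(file.path(dir, "spikes.csv"))
  expect_equal(nrow(back$spikes), nrow(coh$spikes$spikes))
  tr <- read_trial_table(file.path(dir, "trials.csv"))
  expect_equal(tr$outcome, coh$trials$outcome)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$s1$stage, "early")
})
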