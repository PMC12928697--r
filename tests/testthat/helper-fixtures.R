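# shared fixture builders; everything is generated in code at test time

# small spike dataset with fixed, hand-checkable content
toy_dataset <- function() {
  spike_dataset(data.frame(
    unit_id = c("a", "a", "a", "b", "b"),
    region = c("V1", "V1", "V1", "M2", "M2"),
    time_s = c(0.1, 0.2, 0.3, 0.15, 0.25),
    stringsAsFactors = FALSE
  ))
}

# trial table with explicit onsets/licks
toy_trials <- function(onsets = c(10, 30), stimulus = c("Go", "NoGo"),
                       licks = list(11.2, numeric(0))) {
  trial_table(data.frame(
    trial_id = seq_along(onsets), session_id = "s1", stimulus = stimulus,
    stim_onset_s = onsets, lick_times = I(licks), stringsAsFactors = FALSE
  ))
}

# random spike dataset over a fixed region set
random_dataset <- function(n_units = 50, rate_hz = 5, t_max = 100,
                           regions = mesoscale_regions(), seed = 1) {
  set.seed(seed)
  reg <- sample(regions, n_units, replace = TRUE)
  rows <- lapply(seq_len(n_units), function(i) {
    n <- rpois(1, rate_hz * t_max)
    data.frame(unit_id = sprintf("u%02d", i), region = reg[i],
               time_s = sort(runif(n, 0, t_max)), stringsAsFactors = FALSE)
  })
  spike_dataset(do.call(rbind, rows), region_list = regions)
}

# homogeneous Poisson train in ms over [0, t_max_ms)
poisson_train_ms <- function(rate_hz, t_max_ms) {
  n <- rpois(1, rate_hz * t_max_ms / 1000)
  sort(runif(n, 0, t_max_ms))
}

# brute-force cross-correlogram: double loop over all spike pairs
brute_correlogram <- function(src_ms, tgt_ms, bin_ms = 1, max_lag_ms = 30) {
  lags <- seq(-max_lag_ms, max_lag_ms - bin_ms, by = bin_ms)
  counts <- integer(length(lags))
  for (s in src_ms) {
    for (t in tgt_ms) {
      d <- t - s
      if (d >= -max_lag_ms && d < max_lag_ms) {
        b <- floor((d + max_lag_ms) / bin_ms) + 1L
        counts[b] <- counts[b] + 1L
      }
    }
  }
  list(counts = counts, lag_ms = lags)
}

# independent direct TSPE computation: explicit per-(a,b,c) convolution
# loops, no shared code with the package implementation
direct_tspe <- function(corr, n_src, n_tgt, tspe_cfg = tspe_config(),
                        max_delay_ms = 20) {
  g <- corr$counts / min(n_src, n_tgt)
  n <- length(g)
  total <- numeric(n)
  for (i in seq_len(nrow(tspe_cfg$grid))) {
    a <- tspe_cfg$grid$a[i]; b <- tspe_cfg$grid$b[i]
    cr <- tspe_cfg$grid$c_run[i]
    edge <- c(rep(-b, a), rep(2 * a, b), rep(-b, a))
    eh <- (length(edge) - 1) / 2
    f1 <- numeric(n)
    for (l in seq_len(n)) {
      acc <- 0
      for (j in seq_along(edge)) {
        p <- l + (j - 1) - eh
        if (p >= 1 && p <= n) acc <- acc + edge[j] * g[p]
      }
      f1[l] <- acc
    }
    ch <- (cr - 1) / 2
    f2 <- numeric(n)
    for (l in seq_len(n)) {
      acc <- 0
      for (j in seq_len(cr)) {
        p <- l + (j - 1) - ch
        if (p >= 1 && p <= n) acc <- acc + f1[p]
      }
      f2[l] <- acc
    }
    total <- total + f2
  }
  sel <- which(corr$lag_ms >= 1 & corr$lag_ms <= max_delay_ms)
  i <- sel[which.max(abs(total[sel]))]
  list(score = total[i], best_delay_ms = corr$lag_ms[i])
}

# exhaustive Mann-Whitney auROC: loop over all cross-group pairs
brute_auroc <- function(x1, x2) {
  wins <- 0
  for (a in x1) for (b in x2) {
    wins <- wins + (b > a) + 0.5 * (b == a)
  }
  wins / (length(x1) * length(x2))
}

# standard-normal quantile by root finding (independent of qnorm)
quantile_oracle <- function(p) {
  vapply(p, function(pp) {
    uniroot(function(x) pnorm(x) - pp, c(-10, 10), tol = 1e-12)$root
  }, numeric(1))
}

# small cohort for end-to-end pipeline runs: an error-rich early session
# (passes the ROC inclusion rule) and a near-perfect expert session
pipeline_sim <- function() {
  sim_config(n_units_per_region = 2, n_trials = 200, n_sessions = 2,
             hit_rates = c(0.9, 0.995), fa_rates = c(0.7, 0.01),
             region_list = c("mPFC", "OFC", "ACC", "M2", "V1"))
}

# reduced-cost analysis config for pipeline tests
pipeline_config <- function(seed = 7) {
  analysis_config(n_surrogates = 30, n_boot = 60, n_shuffle = 60,
                  seed = seed)
}

# one cached pipeline cohort + run shared across test files
.pipe_env <- new.env()

pipeline_fixture <- function() {
  if (!is.null(.pipe_env$res)) return(.pipe_env$res)
  coh <- generate_learning_dataset(pipeline_sim(), seed = 11)
  dir <- file.path(tempdir(), "mesorank-pipe")
  write_cohort(coh, dir)
  out <- file.path(dir, "run1")
  cfg <- pipeline_config()
  man <- run_pipeline(file.path(dir, "spikes.csv"),
                      file.path(dir, "trials.csv"), out,
                      config = cfg, region_list = pipeline_sim()$region_list,
                      windows_ms = c(-200, 0, 200, 400, 800, 1000))
  .pipe_env$res <- list(dir = dir, out = out, cfg = cfg, manifest = man,
                        coh = coh)
  .pipe_env$res
}
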