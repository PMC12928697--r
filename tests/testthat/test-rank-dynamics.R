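# random strength matrix over the full region set
random_strength <- function(region_list = mesoscale_regions()) {
  R <- length(region_list)
  S <- matrix(runif(R * R), R, R, dimnames = list(region_list, region_list))
  diag(S) <- NA
  S
}

# long-format strengths for synthetic per-(trial, window) matrices drawn by
# `draw(trial, window)`
long_strengths <- function(trials, windows, draw) {
  rows <- list()
  for (tr in trials) for (w in windows) {
    S <- draw(tr, w)
    lg <- strengths_to_long(setNames(list(S), tr), w)
    rows[[length(rows) + 1L]] <- lg
  }
  do.call(rbind, rows)
}

test_that("region ranking is ascending, tie-averaged and conserves the mean", {
  v <- setNames(seq(0.01, 0.1, 0.01), mesoscale_regions())
  r <- rank_regions(v)
  expect_equal(as.vector(r), 1:10, ignore_attr = TRUE)
  expect_false(attr(r, "rescaled"))
  # all equal -> all 5.5
  r2 <- rank_regions(setNames(rep(0.3, 10), mesoscale_regions()))
  expect_true(all(r2 == 5.5))
  # one tied pair at sort positions 3-4 -> both 3.5
  v3 <- setNames(c(1, 2, 3, 3, 5, 6, 7, 8, 9, 10) / 100,
                 mesoscale_regions())
  r3 <- rank_regions(v3)
  expect_equal(unname(r3[3:4]), c(3.5, 3.5))
  # mean rank is exactly (R + 1)/2
  set.seed(61)
  for (i in 1:20) {
    expect_equal(mean(rank_regions(setNames(runif(10),
                                            mesoscale_regions()))), 5.5)
  }
})

test_that("excluded regions are rescaled onto 1..R and flagged", {
  v <- setNames(c(NA, seq(0.1, 0.9, 0.1)), mesoscale_regions())
  r <- rank_regions(v)
  expect_true(attr(r, "rescaled"))
  expect_true(is.na(r[1]))
  expect_equal(range(r, na.rm = TRUE), c(1, 10))
  expect_equal(unname(diff(sort(r))), rep(9 / 8, 8))
})

test_that("summed strengths are row/column sums of the matrix", {
  region_list <- mesoscale_regions()
  S <- matrix(0, 10, 10, dimnames = list(region_list, region_list))
  diag(S) <- NA
  expect_true(all(summed_region_strength(S, "output") == 0))
  S["mPFC", "OFC"] <- 0.2
  out <- summed_region_strength(S, "output")
  inp <- summed_region_strength(S, "input")
  expect_equal(unname(out["mPFC"]), 0.2)
  expect_equal(unname(inp["OFC"]), 0.2)
  expect_equal(sum(out), 0.2)
  # brute-force check on a random matrix
  set.seed(62)
  S2 <- random_strength()
  for (r in region_list) {
    expect_equal(unname(summed_region_strength(S2, "output")[r]),
                 sum(S2[r, ], na.rm = TRUE))
    expect_equal(unname(summed_region_strength(S2, "input")[r]),
                 sum(S2[, r], na.rm = TRUE))
  }
  # all-NA region propagates NA
  S2["V1", ] <- NA; S2[, "V1"] <- NA
  expect_true(is.na(summed_region_strength(S2, "output")["V1"]))
})

test_that("decile ranks follow the ceiling tie rule", {
  set.seed(63)
  region_list <- mesoscale_regions()
  # 90 distinct values -> exactly 9 connections per decile
  S <- matrix(NA_real_, 10, 10, dimnames = list(region_list, region_list))
  S[row(S) != col(S)] <- sample(seq(0.01, 0.9, 0.01))
  d <- decile_rank(S)
  expect_equal(as.integer(table(d[!is.na(d)])), rep(9L, 10))
  # all equal -> shared position 45.5 -> rank 6
  S6 <- matrix(0.5, 10, 10, dimnames = list(region_list, region_list))
  diag(S6) <- NA
  expect_true(all(decile_rank(S6) == 6, na.rm = TRUE))
  # invariance under strictly monotone transforms
  expect_identical(decile_rank(S), decile_rank(sqrt(S)))
  expect_identical(decile_rank(S), decile_rank(S * 100 + 3))
})

test_that("rank trajectories summarise windows and periods over trials", {
  cfg <- analysis_config()
  region_list <- mesoscale_regions()
  set.seed(64)
  S_fix <- random_strength()
  conn <- long_strengths(as.character(1:5), c(0, 200),
                         function(tr, w) S_fix)
  tj <- rank_trajectories(conn, "output", cfg, region_list)
  # identical matrices every trial -> zero SEM, ranks constant
  expect_true(all(tj$window_summary$sem == 0))
  expect_equal(sort(unique(tj$window_summary$n_trials)), 5)
  expect_equal(mean(tj$period_summary$mean_rank), 5.5)
  # per-(trial, window) mean rank is exactly 5.5
  by_tw <- tapply(tj$ranks$rank,
                  paste(tj$ranks$trial_id, tj$ranks$window_start_ms), mean)
  expect_true(all(abs(by_tw - 5.5) < 1e-12))
})

test_that("exchangeable strengths give flat 5.5 trajectories; a boosted hub tops them", {
  cfg <- analysis_config()
  region_list <- mesoscale_regions()
  set.seed(65)
  conn <- long_strengths(as.character(1:40), seq(0, 600, 200),
                         function(tr, w) random_strength())
  tj <- rank_trajectories(conn, "output", cfg, region_list)
  ps <- tj$period_summary
  expect_true(all(abs(ps$mean_rank - 5.5) <= 3 * ps$sem + 1e-9))
  # doubling one region's outgoing strengths makes it the top output rank
  conn2 <- long_strengths(as.character(1:40), seq(0, 600, 200),
                          function(tr, w) {
                            S <- random_strength()
                            S["V1", ] <- 0.5 + S["V1", ]  # systematic boost
                            S
                          })
  tj2 <- rank_trajectories(conn2, "output", cfg, region_list)
  top <- tapply(tj2$ranks$rank,
                list(paste(tj2$ranks$trial_id, tj2$ranks$window_start_ms),
                     tj2$ranks$region), identity)
  v1_top <- mean(vapply(split(tj2$ranks,
                              paste(tj2$ranks$trial_id,
                                    tj2$ranks$window_start_ms)),
                        function(d) d$region[which.max(d$rank)] == "V1",
                        logical(1)))
  expect_gt(v1_top, 0.9)
})

test_that("delta ranks subtract period means and conserve the rank sum", {
  cfg <- analysis_config()
  region_list <- mesoscale_regions()
  set.seed(66)
  conn_e <- long_strengths(as.character(1:10), c(0, 200),
                           function(tr, w) random_strength())
  conn_x <- long_strengths(as.character(1:10), c(0, 200),
                           function(tr, w) {
                             S <- random_strength()
                             S["OFC", ] <- S["OFC", ] + 1
                             S
                           })
  te <- rank_trajectories(conn_e, "output", cfg, region_list)
  tx <- rank_trajectories(conn_x, "output", cfg, region_list)
  dr <- delta_rank(te, tx)
  expect_gt(dr$delta_rank[dr$region == "OFC"], 2)
  # rank-sum conservation: deltas cancel over regions within a period
  expect_equal(sum(dr$delta_rank), 0, tolerance = 1e-9)
  # identical stages -> all zero
  dr0 <- delta_rank(te, te)
  expect_true(all(dr0$delta_rank == 0))
})

test_that("stage rank comparisons use the Sidak family", {
  expect_equal(sidak_adjust(0.001, 40), 1 - 0.999^40)
  cfg <- analysis_config()
  region_list <- mesoscale_regions()
  set.seed(67)
  conn_e <- long_strengths(as.character(1:30), c(0, 200, 400, 600),
                           function(tr, w) random_strength())
  conn_x <- long_strengths(as.character(1:30), c(0, 200, 400, 600),
                           function(tr, w) {
                             S <- random_strength()
                             S["V2M", ] <- S["V2M", ] + 2
                             S
                           })
  te <- rank_trajectories(conn_e, "output", cfg, region_list)
  tx <- rank_trajectories(conn_x, "output", cfg, region_list)
  ct <- compare_stage_ranks(te, tx)
  expect_true(all(ct$p_sidak[ct$region == "V2M"] < 0.05))
  # identical stages: adjusted p near 1
  ct0 <- compare_stage_ranks(te, te)
  expect_true(all(ct0$p_sidak > 0.9, na.rm = TRUE))
})
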