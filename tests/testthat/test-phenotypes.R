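test_that("percent_migrated_series implements the ratio-to-average-loading definition", {
  # 12 cells in the reservoir at one frame over a mean loading count of 120
  # must read 10%
  n <- 132
  frames <- 2
  tr <- expand.grid(cell_id = seq_len(n), frame = seq_len(frames))
  tr$t_min <- (tr$frame - 1) * 2.5
  tr$x_um <- 0; tr$y_um <- 0
  tr$region <- "loading"
  # frame 2: cells 1..12 have reached the fMLP reservoir, 120 remain loading
  sel <- tr$frame == 2 & tr$cell_id <= 12
  tr$region[sel] <- "reservoir_fmlp"
  tr$x_um[sel] <- 1000
  s <- percent_migrated_series(tr, "reservoir_fmlp")
  # mean loading count = (132 + 120) / 2 = 126
  expect_equal(s$percent, c(0, 100 * 12 / 126))
  # no cell ever leaves -> identically zero series
  tr0 <- tr; tr0$region <- "loading"
  expect_true(all(percent_migrated_series(tr0, "reservoir_fmlp")$percent == 0))
  # empty loading channel -> undefined denominator
  trr <- tr; trr$region <- "reservoir_fmlp"
  expect_error(percent_migrated_series(trr, "reservoir_fmlp"), "denominator")
})

test_that("rate_of_accumulation returns the steepest 1-h OLS slope per hour", {
  t <- seq(0, 120, by = 2.5)
  # linear rise 0 -> 20% over 2 h: every window slope = 10 %/h
  s <- data.frame(t_min = t, percent = 20 * t / 120)
  expect_equal(rate_of_accumulation(s), 10, tolerance = 1e-10)
  # constant series: 0 %/h
  expect_equal(rate_of_accumulation(data.frame(t_min = t, percent = 5)), 0)
  # piecewise: flat then rising at 12 %/h -> max window slope 12
  p <- ifelse(t < 60, 0, (t - 60) * 0.2)
  expect_equal(rate_of_accumulation(data.frame(t_min = t, percent = p)), 12,
               tolerance = 1e-10)
  expect_error(rate_of_accumulation(data.frame(t_min = t[1:10],
                                               percent = p[1:10])), "window")
})

test_that("cell_velocity is path length over elapsed time with the in-channel scope", {
  # straight 25-um step per 2.5-min frame = 10 um/min
  tr <- make_track(x = c(60, 85, 110, 135),
                   region = rep("channel_fmlp", 4))
  expect_equal(cell_velocity(tr), 10)
  expect_equal(cell_velocity(tr, scope = "whole_track"), 10)
  # stationary track: 0
  tr0 <- make_track(x = rep(60, 4), region = rep("channel_fmlp", 4))
  expect_equal(cell_velocity(tr0), 0)
  # loading samples are excluded from the in-channel scope
  tr2 <- make_track(x = c(0, 30, 60, 85, 110),
                    region = c("loading", "loading", "channel_fmlp",
                               "channel_fmlp", "channel_fmlp"))
  expect_equal(cell_velocity(tr2), 10)
  expect_equal(cell_velocity(tr2, scope = "whole_track"), 110 / 10)
  # velocity is invariant under time reversal
  tr_rev <- tr
  tr_rev$x_um <- rev(tr_rev$x_um)
  expect_equal(cell_velocity(tr_rev), cell_velocity(tr))
  # fewer than 2 in-scope samples: NA
  tr3 <- make_track(x = c(0, 30), region = c("loading", "channel_fmlp"))
  expect_true(is.na(cell_velocity(tr3)))
})

test_that("count_direction_changes applies the jitter floor and counts sign flips on both axes", {
  # monotone x: no changes
  expect_equal(count_direction_changes(make_track(x = c(0, 5, 10, 15))), 0L)
  # the worked example: x = (0, 5, 2, 7, 3) at threshold 2 -> 3 changes
  expect_equal(count_direction_changes(make_track(x = c(0, 5, 2, 7, 3)),
                                       jitter_threshold = 2), 3L)
  # sub-threshold jitter is ignored
  expect_equal(count_direction_changes(make_track(x = c(0, 5, 4.5, 9, 8.5)),
                                       jitter_threshold = 2), 0L)
  # x and y axes both contribute
  tr <- make_track(x = c(0, 5, 0, 5), y = c(0, 5, 0, 5))
  expect_equal(count_direction_changes(tr), 4L)
  # short tracks return 0
  expect_equal(count_direction_changes(make_track(x = c(0, 5))), 0L)
})

test_that("direction-change counter equals a brute-force recount on random walks", {
  brute <- function(x, y, thr) {
    tot <- 0L
    for (comp in list(diff(x), diff(y))) {
      comp <- comp[abs(comp) >= thr]
      if (length(comp) >= 2)
        tot <- tot + sum(sign(comp[-1]) != sign(comp[-length(comp)]))
    }
    tot
  }
  set.seed(99)
  for (rep in 1:25) {
    x <- cumsum(stats::rnorm(30, 0, 4))
    y <- cumsum(stats::rnorm(30, 0, 4))
    thr <- stats::runif(1, 0.5, 5)
    expect_identical(count_direction_changes(make_track(x, y), thr),
                     brute(x, y, thr))
  }
})

test_that("classify_track sets independent non-exclusive flags", {
  geom <- fixture_geometry()
  # straight loading -> channel -> reservoir: directional only
  straight <- make_track(x = c(0, 40, seq(60, 940, by = 25), 960),
                         y = rep(geom$channel_centers_y[5], 39))
  cl <- classify_track(straight, geom)
  expect_true(cl$directional)
  expect_false(cl$non_directional)
  expect_false(cl$oscillatory)
  expect_equal(cl$side, "fmlp")
  # a visit to a maze rung marks the cell as lost
  yc <- geom$channel_centers_y
  maze <- make_track(
    x = c(0, 40, 60, 100, 150, 200, 200, 200, 200),
    y = c(rep(yc[5], 6), yc[5] + 10, yc[5] + 25, yc[5] + 10))
  clm <- classify_track(maze, geom)
  expect_true(clm$non_directional)
  # 4 reversals confined to a channel: oscillatory but not lost
  osc <- make_track(x = c(60, 90, 60, 90, 60, 90),
                    y = rep(yc[5], 6))
  clo <- classify_track(osc, geom)
  expect_true(clo$oscillatory)
  expect_false(clo$non_directional)
  # a cell that never leaves loading is none of the three
  stay <- make_track(x = rep(0, 5), region = rep("loading", 5))
  cls <- classify_track(stay, geom)
  expect_false(any(cls$directional, cls$non_directional, cls$oscillatory))
})

test_that("decision_ratio handles equal, typical and degenerate endpoints", {
  expect_equal(decision_ratio(10, 10), 1)
  expect_equal(decision_ratio(9.157, 4.811), 9.157 / 4.811)
  r <- decision_ratio(5, 0)
  expect_identical(unname(r[1]), Inf)
  expect_true(attr(r, "undefined"))
  r0 <- decision_ratio(0, 0)
  expect_true(is.nan(r0))
})

test_that("spontaneous_fraction requires the no-chemoattractant condition", {
  run <- simulate_experiment(lps_presets()$unstimulated,
                             fields = fixture_fields(60),
                             n_cells = 30, duration = 60, seed = 1)
  expect_error(spontaneous_fraction(run), "no-chemoattractant")
})

test_that("metrics are invariant under rigid translation of tracks with the geometry", {
  run <- simulate_experiment(lps_presets()$superlow_lps,
                             fields = fixture_fields(120),
                             n_cells = 120, duration = 120, seed = 21)
  m0 <- migration_metrics(run)
  # translation = relabelling coordinates; regions already attached move along
  tr <- run$tracks
  tr$x_um <- tr$x_um + 1000
  tr$y_um <- tr$y_um - 500
  m1 <- migration_metrics(tr)
  expect_equal(m1$endpoint_pct, m0$endpoint_pct)
  expect_equal(m1$velocity_mean, m0$velocity_mean)
  expect_equal(m1$n_oscillatory, m0$n_oscillatory)
  expect_equal(m1$decision_ratio, m0$decision_ratio)
})

test_that("reservoir percent series is non-decreasing under absorbing reservoirs", {
  run <- simulate_experiment(lps_presets()$high_lps,
                             fields = fixture_fields(120),
                             n_cells = 150, duration = 120, seed = 22)
  s <- percent_migrated_series(run, "reservoir_fmlp")
  expect_true(all(diff(s$percent) >= -1e-12))
})

test_that("assign_regions errors for positions outside the device unless snapping", {
  tr <- make_track(x = c(0, 2000))
  expect_error(assign_regions(tr), "outside")
  tr2 <- make_track(x = c(0, 51), y = c(0, 200))  # 1 um into the wall
  out <- assign_regions(tr2, snap = 3)
  expect_equal(out$region, c("loading", "loading"))
})
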