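test_that("preprocessing drops, removes and interpolates as specified", {
  # clean constant series: identity, empty mask
  pose <- fixture_pose(rep(50, 20), rep(60, 20))
  tr <- preprocess(pose, "left_hindpaw_mid")
  expect_equal(tr$x, rep(50, 20))
  expect_false(any(tr$interpolated))
  # single 50 px spike: removed, filled with the neighbors' midpoint
  x <- rep(100, 21); x[11] <- 150
  tr2 <- preprocess(fixture_pose(x, rep(100, 21)), "left_hindpaw_mid")
  expect_equal(tr2$x[11], 100)
  expect_true(tr2$interpolated[11])
  expect_equal(sum(tr2$interpolated), 1)
  # likelihood floor is strict and protocol-dependent
  lik <- rep(0.95, 20); lik[7] <- 0.82
  pose3 <- fixture_pose(rep(10, 20), rep(10, 20), lik)
  expect_false(preprocess(pose3, "left_hindpaw_mid", 0.8)$interpolated[7])
  expect_true(preprocess(pose3, "left_hindpaw_mid", 0.85)$interpolated[7])
  # boundary gaps are masked, never extrapolated
  lik2 <- rep(0.95, 10); lik2[1:2] <- 0.1
  tr4 <- preprocess(fixture_pose(1:10, rep(0, 10), lik2), "left_hindpaw_mid")
  expect_true(all(tr4$missing[1:2]))
  expect_false(any(tr4$interpolated[1:2]))
})

test_that("speed converts displacement per frame time through the scale factor", {
  # constant 1 px/frame at 30 fps, scale 0.45 -> 13.5 mm/s
  tr <- fixture_traj(seq(0, 99), rep(0, 100))
  sp <- speed(tr, scale_mm_per_px = 0.45)
  expect_equal(stats::median(sp$speed_px, na.rm = TRUE), 30)
  expect_equal(stats::median(sp$speed_mm, na.rm = TRUE), 13.5)
  # static: zero everywhere
  sp0 <- speed(fixture_traj(rep(5, 50), rep(5, 50)))
  expect_true(all(sp0$speed_px[-1] == 0))
  # a preprocessed glitch leaves no spike in the smoothed trace
  x <- seq(0, 49); x[25] <- x[25] + 100
  pose <- fixture_pose(x, rep(0, 50))
  spg <- speed(preprocess(pose, "left_hindpaw_mid"))
  expect_lt(max(spg$speed_px, na.rm = TRUE), 60)
  bad <- fixture_traj(1:5, 1:5); bad$time[3] <- bad$time[2]
  expect_error(speed(bad), "frame interval")
})

test_that("speed categories use lower-inclusive upper-exclusive bins", {
  v <- c(0, 19.9, 20, 119.9, 120, 219.9, 220, 500)
  expect_equal(as.character(categorize_speed(v)),
               c("stationary", "stationary", "low", "low", "medium",
                 "medium", "high", "high"))
  expect_error(categorize_speed(-1), "non-negative")
})

test_that("gait segmentation returns exact durations on a square-wave fixture", {
  # plateaus of 6 frames, moves of 3 frames, step 30 px per moving frame:
  # per 9-frame cycle the displacement pattern is 5 zeros then 4 moves
  x <- c(0, cumsum(rep(c(rep(0, 5), rep(30, 4)), 10)))
  g <- gait_phases(fixture_traj(x, rep(0, length(x))))
  seg <- g$segments[-c(1, nrow(g$segments)), ]
  expect_true(all(seg$duration_ms[seg$phase == "stance"] == 200))
  expect_true(all(seg$duration_ms[seg$phase == "swing"] == 100))
  # always-static: a single stance segment spanning all frames
  g2 <- gait_phases(fixture_traj(rep(3, 40), rep(3, 40)))
  expect_equal(nrow(g2$segments), 1)
  expect_equal(g2$segments$n_frames, 40)
  expect_equal(g2$segments$phase, "stance")
  # too-short trajectory reports insufficient data
  expect_true(gait_phases(fixture_traj(1:2, 1:2))$insufficient)
})

test_that("ROI motion energy suppresses below 3 intensity units and masks the circle", {
  f1 <- matrix(0, 64, 64)
  f2a <- f1; f2a[33, 33] <- 2
  f2b <- f1; f2b[33, 33] <- 3
  fs_a <- frame_stack(list(f1, f2a)); fs_b <- frame_stack(list(f1, f2b))
  expect_equal(as.numeric(me_roi_trace(fs_a, anchor = c(32, 32))), 0)
  expect_equal(as.numeric(me_roi_trace(fs_b, anchor = c(32, 32))), 3)
  # change outside the radius is invisible
  f2c <- f1; f2c[5, 5] <- 200
  expect_equal(as.numeric(me_roi_trace(frame_stack(list(f1, f2c)),
                                       anchor = c(32, 32), radius = 15)), 0)
  # brute-force oracle for a blob leaving the ROI
  pose <- fixture_pose(x = c(30, 38, 48), y = c(32, 32, 32),
                       frame_size = c(64, 64))
  stack <- render_frames(pose, blob_sd = 2)
  tr <- me_roi_trace(stack, anchor = c(30, 32), radius = 10)
  mask <- outer((0:63 - 32)^2, (0:63 - 30)^2, "+") <= 100
  oracle <- vapply(1:2, function(i) {
    d <- abs(stack$frames[[i + 1]] - stack$frames[[i]]) * mask
    d[d < 3] <- 0; sum(d)
  }, numeric(1))
  expect_equal(as.numeric(tr), oracle)
  expect_warning(me_roi_trace(stack, anchor = c(2, 2), radius = 15),
                 "clipped")
})

test_that("motion-energy latency implements refine, artifact zeroing and idle gating", {
  fps <- 30
  tgrid <- seq(-9.8, 9.8, by = 1 / fps)
  flat <- rep(0, length(tgrid))
  r0 <- me_latency(flat, tgrid, fps)
  expect_false(r0$responded)
  expect_equal(r0$exclusion, "none")
  # clean 2000-unit sustained step at +4.74 s (flash artifact at onset)
  mk <- function(onset, level = 2000, artifact = 6000) {
    tr <- rep(0, length(tgrid))
    tr[which.min(abs(tgrid))] <- artifact
    tr[tgrid >= onset] <- level
    tr
  }
  r1 <- me_latency(mk(4.74), tgrid, fps)
  expect_true(r1$responded)
  expect_lt(abs(r1$latency - 4.74), 1.5 / fps)
  # a 1500-unit burst at +0.8 s excludes the trial as not idle
  tr2 <- mk(4.74)
  tr2[tgrid >= 0.8 & tgrid <= 1.0] <- 1500
  r2 <- me_latency(tr2, tgrid, fps)
  expect_false(r2$responded)
  expect_equal(r2$exclusion, "not_idle")
  # the single-frame artifact alone never triggers a response
  tr3 <- rep(0, length(tgrid)); tr3[which.min(abs(tgrid))] <- 50000
  expect_false(me_latency(tr3, tgrid, fps)$responded)
  expect_error(me_latency(rep(0, 30), seq(0, 1, length.out = 30), fps),
               "window too short")
})

test_that("latency pipelines are exact over an exhaustive onset grid", {
  fps <- 30
  tgrid <- seq(-9.8, 9.8, by = 1 / fps)
  for (onset in seq(1.6, 9.7, by = 0.45)) {
    tr <- rep(0, length(tgrid))
    tr[which.min(abs(tgrid))] <- 6000
    tr[tgrid >= onset] <- 2500
    r <- me_latency(tr, tgrid, fps)
    expect_true(r$responded)
    expect_lt(abs(r$latency - onset), 1.5 / fps)
  }
  pgrid <- seq(-2, 10, by = 1 / fps)
  for (onset in seq(0.1, 9.7, by = 0.4)) {
    traj <- data.frame(time = pgrid, x = 100 + 10 * (pgrid >= onset),
                       y = 100, likelihood = 0.95)
    r <- pose_latency(traj)
    expect_true(r$responded)
    expect_lt(abs(r$latency - onset), 1.01 / fps)
  }
})

test_that("pose latency uses a strict 3 px rule and likelihood gating", {
  tgrid <- seq(-2, 10, by = 1 / 30)
  static <- data.frame(time = tgrid, x = 100, y = 100, likelihood = 0.95)
  expect_false(pose_latency(static)$responded)
  # drift reaching exactly 3 px is not a response
  drift <- static; drift$x <- 100 + 3 * (tgrid > 0)
  expect_false(pose_latency(drift)$responded)
  step <- static; step$x <- 100 + 5 * (tgrid >= 0.81)
  r <- pose_latency(step)
  expect_true(r$responded)
  expect_lt(abs(r$latency - 0.81), 1.01 / 30)
  lowlik <- static; lowlik$likelihood[tgrid < 0] <- 0.5
  expect_equal(pose_latency(lowlik)$exclusion, "low_likelihood")
})

test_that("heading coherence matches closed forms and circular oracles", {
  # straight line: R = 1
  expect_equal(heading_coherence(fixture_traj(1:100, 1:100)), 1)
  # exact alternating reversals, no smoothing: cancellation to 0
  x <- rep(c(0, 1), 40)
  expect_lt(heading_coherence(fixture_traj(x, rep(0, 80)),
                              smooth_window = 1), 1e-10)
  # isotropic random headings: R matches the Rayleigh expectation
  with_seed(71, {
    Rs <- vapply(1:200, function(i) {
      th <- runif(61, 0, 2 * pi)
      xy <- cbind(cumsum(cos(th)), cumsum(sin(th)))
      heading_coherence(fixture_traj(c(0, xy[, 1]), c(0, xy[, 2])),
                        smooth_window = 1, eval_window = 2)
    }, numeric(1))
    # E[R] for n=60 iid unit vectors is ~ sqrt(pi)/(2 sqrt(60))
    expect_equal(mean(Rs), sqrt(pi) / 2 / sqrt(60), tolerance = 0.15)
  })
  # invariance under global rotation and translation
  with_seed(72, {
    th <- cumsum(rnorm(70, 0, 0.4))
    xy <- cbind(cumsum(cos(th)), cumsum(sin(th)))
    traj <- fixture_traj(xy[, 1], xy[, 2])
    R0 <- heading_coherence(traj)
    a <- 0.7
    rot <- fixture_traj(cos(a) * xy[, 1] - sin(a) * xy[, 2] + 50,
                        sin(a) * xy[, 1] + cos(a) * xy[, 2] - 20)
    expect_equal(heading_coherence(rot), R0, tolerance = 1e-10)
    sp0 <- speed(traj); spr <- speed(rot)
    expect_equal(spr$speed_px, sp0$speed_px, tolerance = 1e-10)
  })
  # zero-displacement frames carry the last defined heading forward
  x2 <- c(0, 1, 2, 2, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  expect_equal(heading_coherence(fixture_traj(x2, rep(0, 13)),
                                 smooth_window = 1, eval_window = 1), 1)
})

test_that("two point-mass states are clustered exactly with semantic labels", {
  sp <- c(rep(90, 30), rep(30, 20))
  co <- c(rep(0.9, 30), rep(0.1, 20))
  with_seed(73, {
    spj <- sp + rnorm(50, 0, 0.01)
    coj <- co + rnorm(50, 0, 0.001)
  })
  cl <- cluster_states(spj, coj, seed = 74)
  expect_equal(as.character(cl$labels),
               rep(c("fast-direct", "slow-assess"), c(30, 20)))
  expect_equal(cl$proportions, c(0.6, 0.4))
  expect_equal(sum(cl$proportions), 1)
  expect_false(cl$degenerate)
  # label permutation invariance: flipping the input order of the two
  # states leaves the semantic labeling tied to mean speed
  cl2 <- cluster_states(rev(spj), rev(coj), seed = 74)
  expect_equal(as.character(cl2$labels),
               rep(c("slow-assess", "fast-direct"), c(20, 30)))
  expect_error(cluster_states(1:5, 1:5 / 10, seed = 75), "at least 10")
})

test_that("clustering is deterministic given the seed", {
  tl <- generate_state_trials(state_trajectory_params(), 40, seed = 76)
  ft <- trial_features(tl)
  a <- cluster_states(ft$pre_speed, ft$pre_coherence, seed = 77)
  b <- cluster_states(ft$pre_speed, ft$pre_coherence, seed = 77)
  expect_identical(a$labels, b$labels)
  expect_identical(a$means, b$means)
})

test_that("state dependence handles zero, degenerate and constructed effects", {
  ft0 <- data.frame(pre_speed = rep(50, 12), post_speed = rep(50, 12),
                    pre_coherence = rep(0.5, 12),
                    post_coherence = rep(0.5, 12))
  lab <- factor(rep(c("fast-direct", "slow-assess"), each = 6),
                levels = c("fast-direct", "slow-assess"))
  sd0 <- state_dependence(ft0, lab)
  expect_true(all(sd0$per_cluster$t == 0))
  expect_true(all(sd0$per_cluster$p == 1))
  # constant nonzero deltas: undefined, flagged
  ft1 <- ft0; ft1$post_speed <- ft1$pre_speed - 1
  sd1 <- state_dependence(ft1, lab)
  sp_rows <- sd1$per_cluster[sd1$per_cluster$metric == "speed", ]
  expect_true(all(sp_rows$flag == "undefined"))
  expect_true(all(is.na(sp_rows$t)))
  # a constructed slowing effect in the fast cluster gives negative t
  tl <- generate_state_trials(state_trajectory_params(), 60, seed = 78)
  ft <- trial_features(tl)
  cl <- cluster_states(ft$pre_speed, ft$pre_coherence, seed = 79)
  sd2 <- state_dependence(ft, cl$labels)
  fast_sp <- sd2$per_cluster[sd2$per_cluster$cluster == "fast-direct" &
                               sd2$per_cluster$metric == "speed", ]
  expect_lt(fast_sp$mean_delta, 0)
  expect_lt(fast_sp$t, 0)
  slow_co <- sd2$per_cluster[sd2$per_cluster$cluster == "slow-assess" &
                               sd2$per_cluster$metric == "coherence", ]
  expect_gt(slow_co$mean_delta, 0)
})

test_that("footprint histograms localize stance dwell", {
  # static paw: a single occupied bin
  h0 <- footprint_histogram(fixture_traj(rep(10, 50), rep(10, 50)),
                            bin_px = 5)
  expect_equal(sum(h0$counts > 0), 1)
  expect_equal(max(h0$counts), 50)
  # simulated gait: dwell peaks match the number of stance epochs
  pr <- gait_params(stance_mean = 400, stance_sd = 0, swing_mean = 200,
                    swing_sd = 0, body_speed = 200)
  pose <- simulate_gait(pr, 10, 30, seed = 80)
  g <- gait_phases(fixture_traj(pose$x[, "left_hindpaw_mid"],
                                pose$y[, "left_hindpaw_mid"]))
  seg <- g$segments
  n_interior <- sum(seg$phase[-c(1, nrow(seg))] == "stance")
  n_total <- sum(seg$phase == "stance")
  h <- footprint_histogram(fixture_traj(pose$x[, "left_hindpaw_mid"],
                                        pose$y[, "left_hindpaw_mid"]),
                           bin_px = 8)
  pk <- find_dwell_peaks(h, min_count = 6)
  # boundary-censored stance epochs may fall under the count floor
  expect_gte(nrow(pk), n_interior)
  expect_lte(nrow(pk), n_total)
  # uniform scatter: no bin dominates
  with_seed(81, {
    hu <- footprint_histogram(data.frame(x = runif(10000, 0, 500),
                                         y = runif(10000, 0, 500)),
                              bin_px = 50)
  })
  expect_lt(max(hu$counts), 3 * 10000 / length(hu$counts))
})
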