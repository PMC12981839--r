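test_that("pokes deliver only at armed ports and the two-condition re-arm holds", {
  topo <- maze_topology()
  st <- maze_state_init(topo, seed = 61, timeout_range = c(5, 5))
  zc <- function(nm) {
    z <- topo$zones[topo$zones$zone == nm, ]
    c((z$x0 + z$x1) / 2, (z$y0 + z$y1) / 2)
  }
  # walk legally: entry chamber -> corridor -> junction -> left corridor
  # -> left reward
  path <- list(zc("entry_chamber"), zc("entry_corridor"), zc("junction"),
               c(800, 50), zc("left_corridor"), zc("left_reward"))
  tt <- 0
  for (p in path) {
    res <- maze_step(st, topo, p, tt); st <- res$state; tt <- tt + 1
  }
  expect_equal(st$zone, "left_reward")
  # poke at the armed port delivers and disarms
  res <- maze_step(st, topo, zc("left_reward"), tt, poke = list(side = "left"))
  st <- res$state
  expect_true("reward" %in% res$events$kind)
  expect_false(st$ports$left$armed)
  # poke during timeout: nothing
  res <- maze_step(st, topo, zc("left_reward"), tt + 1,
                   poke = list(side = "left"))
  st <- res$state
  expect_false("reward" %in% res$events$kind)
  # timeout elapsed but never exited: still no reward
  res <- maze_step(st, topo, zc("left_reward"), tt + 10,
                   poke = list(side = "left"))
  st <- res$state
  expect_false("reward" %in% res$events$kind)
  # exit, circle round legally, poke again after re-entry: reward
  reentry <- list(zc("entry_chamber"), zc("entry_corridor"), zc("junction"),
                  c(800, 50), zc("left_corridor"), zc("left_reward"))
  t2 <- tt + 11
  for (p in reentry) {
    res <- maze_step(st, topo, p, t2); st <- res$state; t2 <- t2 + 1
  }
  res <- maze_step(st, topo, zc("left_reward"), t2, poke = list(side = "left"))
  expect_true("reward" %in% res$events$kind)
})

test_that("forbidden transitions are logged as glitches and ignored", {
  topo <- maze_topology()
  st <- maze_state_init(topo, seed = 62)
  # teleport from the entry chamber straight into a reward chamber
  res <- maze_step(st, topo, c(100, 50), 1)
  expect_equal(res$events$kind, "glitch")
  expect_equal(res$state$zone, "entry_chamber")
  # wrong way through the junction one-way door
  st2 <- res$state; st2$zone <- "junction"
  res2 <- maze_step(st2, topo, c(450, 200), 2)   # junction -> entry corridor
  expect_equal(res2$events$kind, "glitch")
  expect_equal(res2$state$zone, "junction")
})

test_that("corridor stimulation fires on entry and then at the paired frequency", {
  proto <- corridor_protocol(frequencies = c(left_corridor = 5,
                                             right_corridor = 1))
  fps <- 30
  run_dwell <- function(corridor, dwell_s) {
    stim <- NULL; n_cmd <- 0
    for (f in 0:(dwell_s * fps - 1)) {
      res <- corridor_stim_step(stim, corridor, f / fps, proto)
      stim <- res$state
      n_cmd <- n_cmd + nrow(res$commands)
    }
    n_cmd
  }
  expect_equal(run_dwell("left_corridor", 2), 10)   # 5 Hz for 2 s
  expect_equal(run_dwell("right_corridor", 0.4), 1) # fire-on-entry
  expect_equal(run_dwell("junction", 2), 0)
  expect_error(corridor_protocol(frequencies = c(left_corridor = 0)),
               "must be > 0")
})

test_that("trial segmentation keys rewards to their corridor entries", {
  mk <- function(...) do.call(rbind, list(...))
  ev <- event_records(
    time = c(1, 5, 8, 10, 14, 17, 20, 24, 27),
    kind = rep(c("zone_entry", "zone_entry", "reward"), 3),
    payload = list(list(zone = "left_corridor"), list(zone = "left_reward"),
                   list(side = "left"),
                   list(zone = "right_corridor"), list(zone = "right_reward"),
                   list(side = "right"),
                   list(zone = "left_corridor"), list(zone = "left_reward"),
                   list(side = "left")))
  tr <- segment_trials(ev)
  expect_equal(tr$side, c("left", "right", "left"))
  expect_equal(tr$entry_time, c(1, 10, 20))
  # aborted left entry before a right reward belongs to the right trial
  ev2 <- event_records(
    time = c(1, 3, 6, 9),
    kind = c("zone_entry", "zone_entry", "zone_entry", "reward"),
    payload = list(list(zone = "left_corridor"), list(zone = "junction"),
                   list(zone = "right_corridor"), list(side = "right")))
  tr2 <- segment_trials(ev2)
  expect_equal(nrow(tr2), 1)
  expect_equal(tr2$side, "right")
  expect_equal(tr2$entry_time, 6)
  expect_equal(nrow(segment_trials(event_records())), 0)
  bad <- event_records(1, "reward", list(list(side = "left")))
  expect_error(segment_trials(bad), "without a preceding")
})

test_that("transition matrices count consecutive trial pairs", {
  tr <- data.frame(side = c("left", "right", "left", "right"))
  m <- transition_matrix(tr)
  expect_equal(unname(m["left", "right"]), 1)
  expect_equal(unname(m["right", "left"]), 1)
  allL <- data.frame(side = c("left", "left", "left"))
  expect_equal(unname(transition_matrix(allL)["left", "left"]), 1)
  m2 <- transition_matrix(data.frame(side = c("left", "left", "right",
                                              "left")))
  expect_equal(unname(m2["left", ]), c(0.5, 0.5))
  expect_equal(unname(m2["right", "left"]), 1)
  expect_error(transition_matrix(data.frame(side = "left")), "fewer than 2")
})

test_that("Euler tours cover every ordered condition pair exactly once", {
  expect_error(euler_tour_order("A", seed = 1), "at least 2")
  t2 <- euler_tour_order(c("A", "B"), seed = 1)
  expect_equal(length(t2), 3)
  expect_equal(t2[1], t2[3])
  for (n in 2:6) for (s in 1:50) {
    tour <- euler_tour_order(paste0("c", 1:n), seed = s)
    expect_equal(length(tour), n * (n - 1) + 1)
    expect_equal(tour[1], tour[length(tour)])
    pairs <- paste(tour[-length(tour)], tour[-1])
    expect_false(any(duplicated(pairs)))       # each pair at most once
    expect_equal(length(pairs), n * (n - 1))   # hence exactly once
    expect_false(any(tour[-length(tour)] == tour[-1]))  # no self-loops
  }
})

test_that("simulated sessions satisfy the one-way and reward invariants", {
  topo <- maze_topology()
  for (sd0 in c(63, 64)) {
    ms <- simulate_maze_session(topo, duration = 600, fps = 30, seed = sd0,
                                protocol = corridor_protocol())
    expect_equal(sum(ms$events$kind == "glitch"), 0)
    # zone-event sequence only traverses allowed edges
    ze <- ms$events[ms$events$kind == "zone_entry", ]
    zx <- ms$events[ms$events$kind == "zone_exit", ]
    expect_equal(nrow(ze), nrow(zx))
    for (i in seq_len(nrow(ze))) {
      from <- zx$payload[[i]]$zone; to <- ze$payload[[i]]$zone
      expect_true(any(topo$edges$from == from & topo$edges$to == to))
    }
    # per-port inter-reward interval at least the timeout, with an exit
    # logged in between
    rw <- ms$events[ms$events$kind == "reward", ]
    for (side in c("left", "right")) {
      tt <- rw$time[vapply(rw$payload, function(p) p$side, "") == side]
      if (length(tt) > 1) {
        expect_true(all(diff(tt) >= 45))
        for (i in seq_len(length(tt) - 1)) {
          exits <- zx$time[vapply(zx$payload, function(p)
            identical(p$zone, paste0(side, "_reward")), logical(1))]
          expect_true(any(exits > tt[i] & exits < tt[i + 1]))
        }
      }
    }
    # trials alternate predominantly
    if (nrow(ms$trials) >= 10) {
      m <- transition_matrix(ms$trials)
      expect_gt(m["left", "right"] + m["right", "left"], 1.2)
    }
  }
})
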