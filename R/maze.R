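# Alternation-maze task engine: one-way-door topology, reward-port state
# machine, corridor stimulation protocols, trial segmentation, transition
# matrix, and Euler-tour condition ordering.

#' Default alternation-maze topology
#'
#' Seven named rectangular zones in platform pixels with a directed
#' allowed-transition graph encoding the one-way doors: the junction is
#' entered one-way from the entry corridor, and each reward chamber exits
#' one-way to the entry chamber, so after a left/right decision the mouse
#' must circle back through the junction to re-enter a reward chamber.
#' Zone membership is evaluated on the snout keypoint (the poke sensor is
#' nose-based).
#'
#' @param zones optional data.frame overriding the default zone rectangles
#'   (`zone`, `x0`, `x1`, `y0`, `y1`; 0-based pixels, upper bounds
#'   exclusive).
#' @return object of class `maze_topology` with `zones` and directed
#'   `edges` (`from`, `to`).
#' @export
maze_topology <- function(zones = NULL) {
  if (is.null(zones))
    zones <- data.frame(
      zone = c("left_reward", "left_corridor", "entry_chamber",
               "entry_corridor", "junction", "right_corridor",
               "right_reward"),
      x0 = c(0, 200, 0, 200, 700, 200, 0),
      x1 = c(200, 700, 200, 700, 900, 700, 200),
      y0 = c(0, 0, 100, 150, 0, 300, 300),
      y1 = c(100, 100, 300, 250, 400, 400, 400))
  edges <- rbind(
    data.frame(from = "entry_chamber", to = "entry_corridor"),
    data.frame(from = "entry_corridor", to = "entry_chamber"),
    data.frame(from = "entry_corridor", to = "junction"),   # one-way door
    data.frame(from = "junction", to = "left_corridor"),
    data.frame(from = "left_corridor", to = "junction"),
    data.frame(from = "junction", to = "right_corridor"),
    data.frame(from = "right_corridor", to = "junction"),
    data.frame(from = "left_corridor", to = "left_reward"),
    data.frame(from = "right_corridor", to = "right_reward"),
    data.frame(from = "left_reward", to = "entry_chamber"),  # one-way door
    data.frame(from = "right_reward", to = "entry_chamber")) # one-way door
  structure(list(zones = zones, edges = edges), class = "maze_topology")
}

#' Zone containing a point
#'
#' @param topology a [maze_topology].
#' @param xy length-2 `(x, y)` pixel coordinate.
#' @return zone name, or `NA_character_` if the point falls in no zone
#'   (callers keep the previous zone).
#' @export
zone_of <- function(topology, xy) {
  z <- topology$zones
  hit <- which(xy[1] >= z$x0 & xy[1] < z$x1 & xy[2] >= z$y0 & xy[2] < z$y1)
  if (!length(hit)) NA_character_ else z$zone[hit[1]]
}

edge_allowed <- function(topology, from, to) {
  any(topology$edges$from == from & topology$edges$to == to)
}

#' Initialize maze session state
#'
#' Port timeouts are drawn once per session, uniformly in
#' `timeout_range` seconds per port.
#'
#' @param topology a [maze_topology].
#' @param seed integer seed (timeout draws).
#' @param timeout_range reward timeout bounds `c(lo, hi)`, seconds.
#' @param start_zone initial zone.
#' @return list of class `maze_state`.
#' @export
maze_state_init <- function(topology, seed, timeout_range = c(45, 60),
                            start_zone = "entry_chamber") {
  tm <- with_seed(seed, stats::runif(2, timeout_range[1], timeout_range[2]))
  port <- function(timeout) list(armed = TRUE, timeout = timeout,
                                 reward_time = -Inf, exited = TRUE)
  structure(list(zone = start_zone, time = 0,
                 ports = list(left = port(tm[1]), right = port(tm[2]))),
            class = "maze_state")
}

#' Advance the maze state machine by one observation
#'
#' Validates the zone transition against the one-way graph (a forbidden or
#' non-adjacent jump is logged as a tracking glitch and the state is left
#' unchanged), re-arms reward ports whose timeout has elapsed *and* whose
#' chamber has been exited since the last reward, and processes nose
#' pokes: a poke at an armed port delivers a reward and disarms it until
#' both conditions hold again.
#'
#' @param state a `maze_state`.
#' @param topology a [maze_topology].
#' @param snout_xy snout keypoint `(x, y)`, pixels.
#' @param time observation time, seconds.
#' @param poke `NULL`, or a list with `side` (`"left"`/`"right"`).
#' @return list with updated `state` and `events` (an `event_log`).
#' @export
maze_step <- function(state, topology, snout_xy, time, poke = NULL) {
  ev_t <- numeric(); ev_k <- character(); ev_p <- list()
  add <- function(kind, payload = list()) {
    ev_t[[length(ev_t) + 1L]] <<- time
    ev_k[[length(ev_k) + 1L]] <<- kind
    ev_p[[length(ev_p) + 1L]] <<- payload
  }
  z <- zone_of(topology, snout_xy)
  if (!is.na(z) && z != state$zone) {
    if (edge_allowed(topology, state$zone, z)) {
      add("zone_exit", list(zone = state$zone))
      add("zone_entry", list(zone = z))
      for (side in c("left", "right"))
        if (state$zone == paste0(side, "_reward"))
          state$ports[[side]]$exited <- TRUE
      state$zone <- z
    } else {
      add("glitch", list(from = state$zone, to = z))
    }
  }
  for (side in c("left", "right")) {
    p <- state$ports[[side]]
    if (!p$armed && p$exited && time - p$reward_time >= p$timeout)
      state$ports[[side]]$armed <- TRUE
  }
  if (!is.null(poke)) {
    side <- poke$side
    add("poke", list(side = side))
    if (state$ports[[side]]$armed &&
        state$zone == paste0(side, "_reward")) {
      add("reward", list(side = side))
      state$ports[[side]]$armed <- FALSE
      state$ports[[side]]$reward_time <- time
      state$ports[[side]]$exited <- FALSE
    }
  }
  state$time <- time
  list(state = state,
       events = event_records(ev_t, ev_k, ev_p))
}

#' Corridor stimulation protocol
#'
#' @param frequencies named numeric vector of pulse frequencies (Hz) per
#'   stimulation corridor, e.g. `c(left_corridor = 5, right_corridor = 1)`.
#' @param pulse_ms pulse duration, ms.
#' @param power_mw_mm2 power density.
#' @param target_bodypart stimulated keypoint (contralateral hind paw).
#' @return list of class `corridor_protocol`.
#' @export
corridor_protocol <- function(frequencies = c(left_corridor = 5,
                                              right_corridor = 1),
                              pulse_ms = 3, power_mw_mm2 = 40,
                              target_bodypart = "right_hindpaw_mid") {
  if (any(frequencies <= 0)) stopf("corridor frequencies must be > 0")
  structure(list(frequencies = frequencies, pulse_ms = pulse_ms,
                 power_mw_mm2 = power_mw_mm2,
                 target_bodypart = target_bodypart),
            class = "corridor_protocol")
}

#' Step the corridor stimulation clock
#'
#' While the tracked mouse occupies a stimulation corridor, pulse commands
#' are issued at the corridor's frequency, the first on entry; commands
#' cease on zone exit and the clock resets.
#'
#' @param stim_state `NULL` (fresh) or the state returned previously.
#' @param zone current zone name.
#' @param time current time, seconds.
#' @param protocol a [corridor_protocol].
#' @return list with `state` and `commands` (data.frame `time`,
#'   `corridor`, `frequency`; zero rows when no pulse is due).
#' @export
corridor_stim_step <- function(stim_state, zone, time, protocol) {
  if (is.null(stim_state)) stim_state <- list(zone = NA_character_,
                                              next_pulse = Inf)
  cmds <- data.frame(time = numeric(), corridor = character(),
                     frequency = numeric())
  in_stim <- !is.na(zone) && zone %in% names(protocol$frequencies)
  if (!in_stim) {
    stim_state$zone <- if (is.na(zone)) stim_state$zone else zone
    stim_state$next_pulse <- Inf
    return(list(state = stim_state, commands = cmds))
  }
  f <- protocol$frequencies[[zone]]
  if (!identical(stim_state$zone, zone)) {       # fire on entry
    cmds <- data.frame(time = time, corridor = zone, frequency = f)
    stim_state$zone <- zone
    stim_state$next_pulse <- time + 1 / f
  } else if (time >= stim_state$next_pulse - 1e-9) {
    cmds <- data.frame(time = time, corridor = zone, frequency = f)
    stim_state$next_pulse <- stim_state$next_pulse + 1 / f
  }
  list(state = stim_state, commands = cmds)
}

#' Segment a session's events into reward trials
#'
#' One trial per reward; the trial's corridor entry is the last entry into
#' that side's corridor preceding the reward.
#'
#' @param events an `event_log` containing `zone_entry` and `reward`
#'   events (e.g. accumulated from [maze_step]).
#' @return data.frame with columns `side`, `entry_time`, `reward_time`,
#'   `n_stimuli` (stimulus events between entry and reward, if logged).
#' @export
segment_trials <- function(events) {
  rw <- which(events$kind == "reward")
  ent <- which(events$kind == "zone_entry")
  stim_t <- events$time[events$kind == "stimulus"]
  if (!length(rw))
    return(data.frame(side = character(), entry_time = numeric(),
                      reward_time = numeric(), n_stimuli = integer()))
  rows <- lapply(rw, function(i) {
    side <- events$payload[[i]]$side
    corridor <- paste0(side, "_corridor")
    prior <- ent[events$time[ent] <= events$time[i] &
                   vapply(events$payload[ent], function(p)
                     identical(p$zone, corridor), logical(1))]
    if (!length(prior))
      stopf("reward at t=%.2f without a preceding %s entry",
            events$time[i], corridor)
    entry_time <- events$time[max(prior)]
    data.frame(side = side, entry_time = entry_time,
               reward_time = events$time[i],
               n_stimuli = sum(stim_t >= entry_time &
                                 stim_t <= events$time[i]))
  })
  do.call(rbind, rows)
}

#' Side-to-side transition matrix over consecutive trials
#'
#' @param trials data.frame from [segment_trials] (>= 2 trials).
#' @return 2 x 2 row-normalized matrix `P(next side | current side)`,
#'   rows/cols `left`, `right`; a row is `NaN` if its side never occurs
#'   as a current side.
#' @export
transition_matrix <- function(trials) {
  if (nrow(trials) < 2)
    stopf("transition matrix undefined for fewer than 2 trials")
  s <- trials$side
  cnt <- matrix(0, 2, 2, dimnames = list(c("left", "right"),
                                         c("left", "right")))
  for (i in seq_len(length(s) - 1))
    cnt[s[i], s[i + 1]] <- cnt[s[i], s[i + 1]] + 1
  sweep(cnt, 1, rowSums(cnt), "/")
}

#' Euler-tour ordering of stimulation conditions
#'
#' Returns a condition sequence realizing an Eulerian circuit on the
#' complete directed graph over the conditions (no self-loops): every
#' ordered pair of distinct conditions occurs exactly once as adjacent
#' elements, balancing first-order carryover.  Length is
#' `n * (n - 1) + 1`.  Tie-breaking among outgoing edges is seeded.
#'
#' @param conditions vector of >= 2 distinct condition labels.
#' @param seed integer seed.
#' @return vector of conditions (a closed walk; first equals last).
#' @export
euler_tour_order <- function(conditions, seed) {
  conditions <- unique(conditions)
  n <- length(conditions)
  if (n < 2) stopf("need at least 2 distinct conditions")
  with_seed(seed, {
    # shuffled outgoing-neighbor lists; Hierholzer's algorithm
    out_edges <- lapply(seq_len(n), function(v) {
      nb <- setdiff(seq_len(n), v)
      nb[sample.int(length(nb))]
    })
    ptr <- rep(1L, n)
    start <- sample.int(n, 1)
    stack <- start
    circuit <- integer()
    while (length(stack)) {
      v <- stack[length(stack)]
      if (ptr[v] <= length(out_edges[[v]])) {
        w <- out_edges[[v]][ptr[v]]
        ptr[v] <- ptr[v] + 1L
        stack <- c(stack, w)
      } else {
        circuit <- c(circuit, v)
        stack <- stack[-length(stack)]
      }
    }
    conditions[rev(circuit)]
  })
}

#' Simulate a maze session with a scripted agent
#'
#' A waypoint-following virtual mouse runs laps of the maze: entry chamber
#' to junction, a left/right decision (mostly alternating), a dash to the
#' reward port, a poke, and a one-way exit back to the entry chamber.  The
#' agent moves at constant speed along straight segments between zone
#' centers and pokes on arrival at a port; it is driven through
#' [maze_step] frame by frame, so all one-way and reward invariants are
#' enforced and logged.
#'
#' @param topology a [maze_topology].
#' @param duration session length, seconds.
#' @param fps frame rate.
#' @param seed integer seed (decisions, dwell times, timeouts).
#' @param speed_px agent speed, px/s.
#' @param p_alternate probability of alternating sides on each lap.
#' @param protocol optional [corridor_protocol]; pulse commands are logged
#'   as `stimulus` events.
#' @param timeout_range reward timeout bounds, seconds.
#' @return list with `events` (an `event_log`), `trials`
#'   (from [segment_trials]), and the tail of the `state`.
#' @export
simulate_maze_session <- function(topology, duration = 600, fps = 30, seed,
                                  speed_px = 250, p_alternate = 0.8,
                                  protocol = NULL,
                                  timeout_range = c(45, 60)) {
  check_seed(seed)
  zc <- function(name) {
    z <- topology$zones[topology$zones$zone == name, ]
    c((z$x0 + z$x1) / 2, (z$y0 + z$y1) / 2)
  }
  state <- maze_state_init(topology, seed = seed + 1L,
                           timeout_range = timeout_range)
  with_seed(seed, {
    n <- floor(duration * fps)
    pos <- zc("entry_chamber")
    route <- list()        # queued waypoints
    last_side <- sample(c("left", "right"), 1)
    dwell_until <- -1
    stim_state <- NULL
    ev <- list()
    plan_lap <- function(last_side) {
      side <- if (stats::runif(1) < p_alternate)
        setdiff(c("left", "right"), last_side) else last_side
      corr <- zc(paste0(side, "_corridor"))
      jn <- zc("junction")
      # route through the junction mouth so the path never clips a
      # non-adjacent zone corner
      wps <- list(zc("entry_corridor"), jn, c(jn[1], corr[2]), corr,
                  zc(paste0(side, "_reward")))
      list(side = side, wps = wps)
    }
    lap <- plan_lap(last_side)
    wp_i <- 1L
    phase <- "outbound"   # outbound -> poking -> homebound
    for (f in seq_len(n)) {
      tt <- (f - 1) / fps
      poke <- NULL
      if (phase == "outbound") {
        target <- lap$wps[[wp_i]]
        d <- target - pos
        dist <- sqrt(sum(d^2))
        step <- speed_px / fps
        if (dist <= step) {
          pos <- target
          if (wp_i == length(lap$wps)) {
            phase <- "poking"
            dwell_until <- tt + stats::runif(1, 0.3, 1.2)
          } else wp_i <- wp_i + 1L
        } else pos <- pos + d / dist * step
      } else if (phase == "poking") {
        if (tt >= dwell_until) {
          poke <- list(side = lap$side)
          phase <- "homebound"
          dwell_until <- tt + stats::runif(1, 0.5, 2)
        }
      } else { # homebound: wait a moment, then exit one-way to entry chamber
        if (tt >= dwell_until) {
          target <- zc("entry_chamber")
          d <- target - pos
          dist <- sqrt(sum(d^2))
          step <- speed_px / fps
          if (dist <= step) {
            pos <- target
            last_side <- lap$side
            lap <- plan_lap(last_side)
            wp_i <- 1L
            phase <- "outbound"
          } else pos <- pos + d / dist * step
        }
      }
      st <- maze_step(state, topology, pos, tt, poke)
      state <- st$state
      if (nrow(st$events)) ev[[length(ev) + 1L]] <- st$events
      if (!is.null(protocol)) {
        cs <- corridor_stim_step(stim_state, state$zone, tt, protocol)
        stim_state <- cs$state
        if (nrow(cs$commands))
          ev[[length(ev) + 1L]] <- event_records(
            cs$commands$time, "stimulus",
            list(list(corridor = cs$commands$corridor[1],
                      frequency = cs$commands$frequency[1])))
      }
    }
    events <- if (length(ev)) do.call(rbind, ev) else event_records()
    class(events) <- c("event_log", "data.frame")
    list(events = events, trials = segment_trials(events), state = state)
  })
}
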