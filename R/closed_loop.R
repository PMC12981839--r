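# The control loop: stillness/likelihood trigger rule, refractory
# accounting, keypoint -> voltage targeting with modeled delays, and
# hit/confusion adjudication against ground truth.

PAW_PARTS <- c("left_forepaw", "right_forepaw", "left_hindpaw_mid",
               "right_hindpaw_mid")

#' Trigger parameters for stillness-contingent stimulation
#'
#' `v` is a positional dispersion bound interpreted as a standard deviation
#' in pixels (the stillness protocol: keypoint SD < 1 px and likelihood
#' > 0.8 throughout 2 s).  Both inequalities are strict.
#'
#' @param v max keypoint standard deviation, pixels (> 0).
#' @param t required still duration, seconds (> 0).
#' @param l minimum likelihood, in (0, 1].
#' @param refractory minimum inter-stimulus interval, seconds.
#' @param target_bodypart keypoint to target.
#' @return list of class `trigger_params`.
#' @export
trigger_params <- function(v = 1.0, t = 2.0, l = 0.8, refractory = 0.5,
                           target_bodypart = "left_hindpaw_mid") {
  if (v <= 0) stopf("v must be > 0")
  if (t <= 0) stopf("t must be > 0")
  if (l <= 0 || l > 1) stopf("l must lie in (0, 1]")
  if (refractory < 0) stopf("refractory must be >= 0")
  structure(list(v = v, t = t, l = l, refractory = refractory,
                 target_bodypart = target_bodypart),
            class = "trigger_params")
}

#' Evaluate the stillness trigger on a pose window
#'
#' True iff, over the window, the population standard deviations of the
#' target keypoint's x and y are both strictly below `v` and every frame's
#' likelihood is strictly above `l`.  Windows spanning less than `t`
#' seconds are refused (error), not reported as `FALSE`.
#'
#' @param window a [pose_series] slice covering at least `t` seconds.
#' @param params a [trigger_params].
#' @return logical scalar.
#' @export
stillness_trigger <- function(window, params) {
  j <- match(params$target_bodypart, window$bodyparts)
  if (is.na(j)) stopf("body part '%s' not in series", params$target_bodypart)
  n_w <- round(params$t * window$fps)
  if (n_frames(window) < n_w)
    stopf("window spans %d frames < required %d (t = %g s at %g fps)",
          n_frames(window), n_w, params$t, window$fps)
  x <- window$x[, j]; y <- window$y[, j]; lik <- window$likelihood[, j]
  pop_sd(x) < params$v && pop_sd(y) < params$v && all(lik > params$l)
}

#' Run a closed-loop stimulation session against a virtual rig
#'
#' Per frame, the trigger is evaluated on the trailing `t`-second window of
#' the target keypoint.  When it fires (and the refractory interval since
#' the previous stimulus has strictly elapsed), processing and actuation
#' delays are sampled, voltages are predicted for the keypoint *at the
#' trigger frame* (the loop cannot see the future), and the realized spot
#' is adjudicated against the ground-truth pose at the fire time: a hit if
#' within `footprint_radius` of the intended paw, a confusion if instead
#' within another paw's footprint.  After each stimulus the stillness
#' window re-arms from the fire frame, so one long still epoch cannot yield
#' a burst.
#'
#' @param pose ground-truth [pose_series] (e.g. from [simulate_gait]).
#' @param map a [fit_map] calibration.
#' @param optics the ground-truth [optics_model].
#' @param latency a [latency_model].
#' @param params a [trigger_params].
#' @param protocol list with at least `pulse_ms` and `power_mw_mm2`
#'   (`train_hz` optional); refusal without a pulse spec.
#' @param seed integer seed (delays and spot noise).
#' @param footprint_radius paw footprint radius for adjudication, pixels.
#' @return object of class `session_log`: `stimuli` (one row per
#'   stimulation), `events` (an `event_log`), the pose reference, params,
#'   protocol and seed.
#' @export
run_session <- function(pose, map, optics, latency, params, protocol,
                        seed, footprint_radius = 5) {
  if (is.null(protocol$pulse_ms) || is.null(protocol$power_mw_mm2))
    stopf("protocol must specify a pulse spec (pulse_ms, power_mw_mm2)")
  j <- match(params$target_bodypart, pose$bodyparts)
  if (is.na(j)) stopf("target body part '%s' missing", params$target_bodypart)
  n <- n_frames(pose)
  fps <- pose$fps
  n_w <- round(params$t * fps)
  if (n < n_w) stopf("session shorter than one trigger window")
  x <- pose$x[, j]; y <- pose$y[, j]; lik <- pose$likelihood[, j]
  ok <- roll_sd_pop(x, n_w) < params$v &
    roll_sd_pop(y, n_w) < params$v &
    roll_all(lik > params$l, n_w)
  ok[is.na(ok)] <- FALSE
  cand <- which(ok)

  with_seed(seed, {
    rows <- list()
    armed_from <- 1L
    last_fire <- -Inf
    paw_idx <- match(intersect(PAW_PARTS, pose$bodyparts), pose$bodyparts)
    for (f in cand) {
      if (f - n_w + 1L < armed_from) next
      tt <- pose$time[f]
      if (!(tt - last_fire > params$refractory)) next
      pr <- rtnorm(1, latency$proc_mean, latency$proc_sd, lower = 0)
      ac <- rtnorm(1, latency$act_mean, latency$act_sd, lower = 0)
      fire_time <- tt + pr + ac
      fire_frame <- min(floor(fire_time * fps + 1e-9) + 1L, n)
      target <- c(x[f], y[f])
      v <- predict_voltage(map, target, clamp = TRUE)
      nf_optics <- optics; nf_optics$noise_sd <- 0
      spot <- optics_forward(v, nf_optics)[1, ]
      if (optics$noise_sd > 0)
        spot <- spot + stats::rnorm(2, 0, optics$noise_sd)
      dx <- pose$x[fire_frame, paw_idx] - spot[1]
      dy <- pose$y[fire_frame, paw_idx] - spot[2]
      dist_paws <- sqrt(dx^2 + dy^2)
      names(dist_paws) <- pose$bodyparts[paw_idx]
      d_target <- dist_paws[params$target_bodypart]
      hit <- unname(d_target <= footprint_radius)
      confusion <- !hit && any(dist_paws[names(dist_paws) !=
                                           params$target_bodypart] <=
                                 footprint_radius)
      rows[[length(rows) + 1L]] <- data.frame(
        trigger_frame = f, trigger_time = tt,
        fire_time = fire_time, fire_frame = fire_frame,
        target_x = target[1], target_y = target[2],
        vx = v[1, 1], vy = v[1, 2],
        spot_x = spot[1], spot_y = spot[2],
        delay_processing = pr, delay_actuation = ac,
        hit = hit, confusion = confusion,
        targeting_error_px = unname(d_target))
      last_fire <- fire_time
      armed_from <- fire_frame + 1L
    }
    stimuli <- if (length(rows)) do.call(rbind, rows) else
      data.frame(trigger_frame = integer(), trigger_time = numeric(),
                 fire_time = numeric(), fire_frame = integer(),
                 target_x = numeric(), target_y = numeric(),
                 vx = numeric(), vy = numeric(),
                 spot_x = numeric(), spot_y = numeric(),
                 delay_processing = numeric(), delay_actuation = numeric(),
                 hit = logical(), confusion = logical(),
                 targeting_error_px = numeric())
    ev_t <- c(stimuli$trigger_time, stimuli$fire_time)
    ev_k <- c(rep("trigger", nrow(stimuli)), rep("stimulus", nrow(stimuli)))
    o <- order(ev_t)
    events <- event_records(ev_t[o], ev_k[o],
                            rep(list(list()), length(ev_t))[o])
    structure(list(stimuli = stimuli, events = events, pose = pose,
                   params = params, protocol = protocol, seed = seed,
                   footprint_radius = footprint_radius),
              class = "session_log")
  })
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log> %d stimuli over %.1f s (%d frames), target %s\n",
              nrow(x$stimuli), max(x$pose$time), n_frames(x$pose),
              x$params$target_bodypart))
  invisible(x)
}

# Tail-base speed in px/s with a 10-frame rolling mean, as used when
# binning hit accuracy by speed category.
body_speed_px <- function(pose, part = "tail_base", smooth_window = 10) {
  j <- match(part, pose$bodyparts)
  if (is.na(j)) stopf("body part '%s' missing", part)
  d <- sqrt(diff(pose$x[, j])^2 + diff(pose$y[, j])^2)
  sp <- c(NA, d / diff(pose$time))
  sm <- zoo::rollapply(sp, smooth_window, mean, na.rm = TRUE,
                       fill = NA, align = "center", partial = TRUE)
  as.numeric(sm)
}

#' Adjudicate stimulation events against ground truth
#'
#' Tabulates hit accuracy per tail-base speed category at the trigger
#' frame, the confusion fraction (spots landing in a non-target paw's
#' footprint), and the mean targeting error over hits.
#'
#' @param events `stimuli` data.frame from [run_session] (or a
#'   `session_log`).
#' @param ground_truth the [pose_series] the session ran against.
#' @param footprint_radius paw footprint radius, pixels.
#' @param scale_mm_per_px scale factor for the mm conversion.
#' @return list with `by_category` (data.frame category/n/hits/accuracy),
#'   `n`, `confusion_n`, `confusion_frac`, `mae_px`, `mae_mm`.
#' @export
adjudicate <- function(events, ground_truth, footprint_radius = 5,
                       scale_mm_per_px = 0.45) {
  if (inherits(events, "session_log")) events <- events$stimuli
  if (nrow(events) &&
      (max(events$fire_time) > max(ground_truth$time) + 1 / ground_truth$fps ||
       min(events$trigger_time) < min(ground_truth$time)))
    stopf("events fall outside the pose time range")
  sp <- body_speed_px(ground_truth)
  categ <- categorize_speed(pmax(sp, 0))
  ev_cat <- categ[events$trigger_frame]
  lv <- levels(categ)
  by_cat <- do.call(rbind, lapply(lv, function(cc) {
    sel <- which(ev_cat == cc)
    data.frame(category = cc, n = length(sel),
               hits = sum(events$hit[sel]),
               accuracy = if (length(sel)) mean(events$hit[sel]) else NA_real_)
  }))
  mae_px <- if (any(events$hit)) mean(events$targeting_error_px[events$hit])
    else NA_real_
  list(by_category = by_cat, n = nrow(events),
       confusion_n = sum(events$confusion),
       confusion_frac = if (nrow(events)) mean(events$confusion) else NA_real_,
       mae_px = mae_px, mae_mm = mae_px * scale_mm_per_px)
}
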