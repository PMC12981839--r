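# Hardware stand-in: gait-realistic keypoint trajectories, rendered
# grayscale frames, a forward optics model (voltage -> pixel with smooth
# nonlinear distortion), latency models, and synthetic trial generators for
# the latency and movement-state analyses.

#' Gait generator parameters
#'
#' Defaults reproduce locomotor hind-paw timing: stance 350 +/- 44 ms,
#' swing 100 +/- 1 ms, with left and right hind paws half a cycle out of
#' phase.
#'
#' @param stance_mean,stance_sd stance-phase duration mean and SD (ms).
#' @param swing_mean,swing_sd swing-phase duration mean and SD (ms).
#' @param body_speed body (tail base) speed along the path, px/s.
#' @param phase_offset_lr left/right phase offset as a fraction of one gait
#'   cycle (0.5 = strictly out of phase).
#' @param dropout_frac optional fraction of frames per body part whose
#'   likelihood is dropped to 0.3, exercising the likelihood-threshold
#'   path (0 by default: likelihood is a constant 0.95).
#' @return list of class `gait_params`.
#' @export
gait_params <- function(stance_mean = 350, stance_sd = 44,
                        swing_mean = 100, swing_sd = 1,
                        body_speed = 150, phase_offset_lr = 0.5,
                        dropout_frac = 0) {
  if (stance_mean <= 0 || swing_mean <= 0)
    stopf("phase durations must be positive")
  if (phase_offset_lr < 0 || phase_offset_lr >= 1)
    stopf("phase_offset_lr must lie in [0, 1)")
  structure(list(stance_mean = stance_mean, stance_sd = stance_sd,
                 swing_mean = swing_mean, swing_sd = swing_sd,
                 body_speed = body_speed, phase_offset_lr = phase_offset_lr,
                 dropout_frac = dropout_frac),
            class = "gait_params")
}

#' Gait presets by speed category
#'
#' Stance duration shortens as body speed rises (the swing clock is nearly
#' fixed), so the fraction of static hind-paw frames falls from near 1 when
#' the animal is stationary to roughly 0.6 at high speed.
#'
#' @param category one of `"stationary"`, `"low"`, `"medium"`, `"high"`.
#' @return a [gait_params] preset.
#' @export
gait_preset <- function(category = c("stationary", "low", "medium", "high")) {
  category <- match.arg(category)
  switch(category,
    stationary = gait_params(stance_mean = 20000, stance_sd = 2000,
                             body_speed = 6),
    low = gait_params(stance_mean = 2200, stance_sd = 200, body_speed = 70),
    medium = gait_params(stance_mean = 383, stance_sd = 44, body_speed = 170),
    high = gait_params(stance_mean = 150, stance_sd = 15, body_speed = 300))
}

# Alternating stance/swing schedule for one paw, covering [0, duration].
# Returns touchdown and lift times (s); first touchdown may be < 0.  The
# drawn durations are rescaled to realize the stated mean/SD exactly in
# the sample (the session *is* the stated gait statistics, up to the few
# cycles extending past the session end).
sample_gait_schedule <- function(params, duration, t0) {
  cyc <- (params$stance_mean + params$swing_mean) / 1000
  n_cyc <- ceiling((duration - t0) / max(cyc, 1e-3)) + 3
  stance <- pmax(standardize_to(stats::rnorm(n_cyc), params$stance_mean,
                                params$stance_sd), 40) / 1000
  swing <- pmax(standardize_to(stats::rnorm(n_cyc), params$swing_mean,
                               params$swing_sd), 30) / 1000
  touchdown <- t0 + cumsum(c(0, (stance + swing)[-n_cyc]))
  # extend if the randomized durations fall short of the session
  while (touchdown[length(touchdown)] < duration) {
    m <- length(touchdown)
    touchdown <- c(touchdown, touchdown[m] + stance[m] + swing[m])
    stance <- c(stance,
                max(stats::rnorm(1, params$stance_mean, params$stance_sd),
                    40) / 1000)
    swing <- c(swing,
               max(stats::rnorm(1, params$swing_mean, params$swing_sd),
                   30) / 1000)
  }
  list(touchdown = touchdown, lift = touchdown + stance)
}

#' Simulate gait-realistic keypoint trajectories
#'
#' The virtual mouse walks along a circular path at constant body speed.
#' Tail base and snout advance continuously; each hind paw alternates
#' between a static stance (anchored to the platform) and a swing that
#' linearly translates it to its next anchor.  Only the stance/swing timing
#' statistics are contractual; the swing trajectory shape is a convenience.
#'
#' @param params a [gait_params].
#' @param duration session length, seconds (>= 1).
#' @param fps frame rate, Hz (>= 10).
#' @param seed explicit integer seed (required).
#' @param frame_size `c(width, height)` pixels.
#' @return a [pose_series] with body parts `snout`, `left_forepaw`,
#'   `right_forepaw`, `left_hindpaw_mid`, `right_hindpaw_mid`, `tail_base`.
#'   Ground-truth gait schedules are attached as attribute `"gait"`.
#' @export
simulate_gait <- function(params, duration, fps = 30, seed,
                          frame_size = c(1100, 1100)) {
  if (missing(seed)) stopf("simulate_gait requires an explicit seed")
  if (duration < 1) stopf("duration must be >= 1 s")
  if (fps < 10) stopf("fps must be >= 10")
  with_seed(seed, {
    n <- floor(duration * fps) + 1L
    tt <- (seq_len(n) - 1) / fps
    w <- frame_size[1]; h <- frame_size[2]
    radius <- max(min(w, h) / 2 - 160, min(w, h) / 4)
    cx <- w / 2; cy <- h / 2
    v <- params$body_speed
    a0 <- stats::runif(1, 0, 2 * pi)
    ang <- function(t) a0 + v * t / radius
    path <- function(t, along = 0, lateral = 0) {
      a <- ang(t) + along / radius
      px <- cx + radius * cos(a)
      py <- cy + radius * sin(a)
      # lateral offset: toward/away from circle center
      cbind(px + lateral * cos(a + pi / 2), py + lateral * sin(a + pi / 2))
    }
    tail_base <- path(tt)
    snout <- path(tt, along = 80)
    fore_l <- path(tt, along = 55, lateral = -18)
    fore_r <- path(tt, along = 55, lateral = 18)

    # The stated stance/swing durations are measurements under the
    # displacement-threshold convention (static when < 20 px/s): a frame
    # interval straddling a phase boundary is still labeled static while
    # its swing overlap stays below threshold/v_swing, which inflates
    # measured stance by 2 * dt * threshold / v_swing.  The latent
    # schedule is shifted by that slack so the measured durations realize
    # the stated ones.
    params_eff <- params
    if (v > 0) {
      cyc_s <- (params$stance_mean + params$swing_mean) / 1000
      v_swing <- v * cyc_s / (params$swing_mean / 1000)  # px/s during swing
      slack_ms <- 2 * (1 / fps) * 20 / v_swing * 1000
      slack_ms <- min(slack_ms, params$stance_mean / 2)
      params_eff$stance_mean <- params$stance_mean - slack_ms
      params_eff$swing_mean <- params$swing_mean + slack_ms
    }
    paw_track <- function(side) {
      lateral <- if (side == "left") -22 else 22
      if (v <= 0) return(path(rep(0, n), along = -15, lateral = lateral))
      cyc <- (params_eff$stance_mean + params_eff$swing_mean) / 1000
      t0 <- -stats::runif(1, 0, cyc)
      if (side == "right") t0 <- t0 - params$phase_offset_lr * cyc
      sch <- sample_gait_schedule(params_eff, duration, t0)
      anchor_t <- (sch$touchdown + sch$lift) / 2  # paw under body mid-stance
      anchors <- path(anchor_t, along = -15, lateral = lateral)
      k <- findInterval(tt, sch$touchdown)
      k[k < 1] <- 1
      in_stance <- tt < sch$lift[k]
      frac <- (tt - sch$lift[k]) / (sch$touchdown[k + 1] - sch$lift[k])
      frac <- pmin(pmax(frac, 0), 1)
      xy <- anchors[k, , drop = FALSE]
      nxt <- anchors[pmin(k + 1, nrow(anchors)), , drop = FALSE]
      sw <- !in_stance
      xy[sw, ] <- anchors[k[sw], , drop = FALSE] * (1 - frac[sw]) +
        nxt[sw, , drop = FALSE] * frac[sw]
      attr(xy, "schedule") <- sch
      xy
    }
    hind_l <- paw_track("left")
    hind_r <- paw_track("right")

    parts <- list(snout = snout, left_forepaw = fore_l,
                  right_forepaw = fore_r, left_hindpaw_mid = hind_l,
                  right_hindpaw_mid = hind_r, tail_base = tail_base)
    x <- do.call(cbind, lapply(parts, function(m) m[, 1]))
    y <- do.call(cbind, lapply(parts, function(m) m[, 2]))
    colnames(x) <- colnames(y) <- names(parts)
    lik <- matrix(0.95, n, length(parts), dimnames = list(NULL, names(parts)))
    n_drop <- floor(params$dropout_frac * n)
    if (n_drop > 0)
      for (j in seq_along(parts))
        lik[sample.int(n, n_drop), j] <- 0.3
    pose <- pose_series(x, y, lik, fps = fps, frame_size = frame_size)
    attr(pose, "gait") <- list(
      left = attr(hind_l, "schedule"), right = attr(hind_r, "schedule"),
      body_speed = v)
    pose
  })
}

#' Render a pose series as grayscale frames
#'
#' Each tracked body part becomes an isotropic Gaussian intensity blob at
#' its keypoint; optional Gaussian background noise is added per pixel.
#' Intensities are 8-bit (0-255).
#'
#' @param pose a [pose_series]; keypoints must lie inside the frame.
#' @param blob_sd blob standard deviation, pixels (> 0).
#' @param amplitude peak blob intensity before clipping.
#' @param background_noise_sd per-pixel Gaussian noise SD (0 disables).
#' @param seed required when `background_noise_sd > 0`.
#' @return a [frame_stack].
#' @export
render_frames <- function(pose, blob_sd = 3, amplitude = 200,
                          background_noise_sd = 0, seed = NULL) {
  if (blob_sd <= 0) stopf("blob_sd must be > 0")
  w <- pose$frame_size[1]; h <- pose$frame_size[2]
  tracked <- pose$likelihood > 0
  if (any(pose$x[tracked] < 0 | pose$x[tracked] >= w |
          pose$y[tracked] < 0 | pose$y[tracked] >= h))
    stopf("pose keypoints exceed frame_size; cannot render")
  n <- n_frames(pose)
  half <- ceiling(4 * blob_sd)
  win <- seq(-half, half)
  kern <- exp(-(win^2) / (2 * blob_sd^2))
  blob <- amplitude * outer(kern, kern)
  render_one <- function(i) {
    f <- matrix(0, h, w)
    for (j in seq_along(pose$bodyparts)) {
      if (!tracked[i, j]) next
      px <- round(pose$x[i, j]); py <- round(pose$y[i, j])
      rows <- (py + 1 + win); cols <- (px + 1 + win)
      ok_r <- rows >= 1 & rows <= h; ok_c <- cols >= 1 & cols <= w
      f[rows[ok_r], cols[ok_c]] <- f[rows[ok_r], cols[ok_c]] +
        blob[ok_r, ok_c]
    }
    f
  }
  frames <- lapply(seq_len(n), render_one)
  if (background_noise_sd > 0) {
    check_seed(seed)
    frames <- with_seed(seed, lapply(frames, function(f)
      f + matrix(stats::rnorm(length(f), 0, background_noise_sd),
                 nrow(f), ncol(f))))
  }
  frames <- lapply(frames, function(f) {
    f <- round(f); f[f < 0] <- 0; f[f > 255] <- 255
    f
  })
  frame_stack(frames, fps = pose$fps, time = pose$time)
}

#' Forward optics model: steering voltages to spot pixel
#'
#' The ground-truth inverse of the calibration problem.  A commanded
#' voltage pair maps to a pixel through a linear gain plus a smooth 2D
#' polynomial distortion of bounded magnitude, with optional sub-pixel
#' observation noise on the detected spot.
#'
#' @param gain volts per pixel, per axis (length 2).
#' @param dist_coef_x,dist_coef_y coefficient matrices for the distortion
#'   polynomials (in pixels); entry `[i, j]` multiplies
#'   `(x/width)^(i-1) * (y/height)^(j-1)`.  `NULL` means no distortion.
#' @param noise_sd spot observation noise SD, pixels.
#' @param platform_px `c(width, height)` of the addressable region.
#' @return list of class `optics_model`.
#' @export
optics_model <- function(gain = c(0.008, 0.008), dist_coef_x = NULL,
                         dist_coef_y = NULL, noise_sd = 0,
                         platform_px = c(1100, 1100)) {
  if (any(gain <= 0)) stopf("gains must be positive")
  m <- structure(list(gain = gain, dist_coef_x = dist_coef_x,
                      dist_coef_y = dist_coef_y, noise_sd = noise_sd,
                      platform_px = platform_px,
                      voltage_bounds = list(
                        x = c(-0.05, 1.05) * gain[1] * platform_px[1],
                        y = c(-0.05, 1.05) * gain[2] * platform_px[2])),
                 class = "optics_model")
  d <- distortion_field(m, as.matrix(expand.grid(
    x = seq(0, platform_px[1], length.out = 21),
    y = seq(0, platform_px[2], length.out = 21))))
  if (max(abs(d)) >= 0.05 * max(platform_px))
    stopf("distortion magnitude %.1f px exceeds 5%% of the platform width",
          max(abs(d)))
  m
}

#' A reproducible randomly-distorted optics model
#'
#' Draws smooth degree-2 distortion surfaces with a controlled peak
#' magnitude, emulating galvanometer projection distortion.
#'
#' @param seed integer seed.
#' @param magnitude_px approximate peak distortion, pixels.
#' @param noise_sd spot observation noise SD, pixels.
#' @param platform_px addressable region, pixels.
#' @return an [optics_model].
#' @export
random_optics <- function(seed, magnitude_px = 15, noise_sd = 0.3,
                          platform_px = c(1100, 1100)) {
  with_seed(seed, {
    grid <- expand.grid(nx = seq(-0.1, 1.1, length.out = 25),
                        ny = seq(-0.1, 1.1, length.out = 25))
    rc <- function() {
      m <- matrix(stats::runif(9, -1, 1), 3, 3)
      # normalize by the realized field so the peak distortion over (and
      # slightly beyond) the platform equals magnitude_px
      field <- rep(0, nrow(grid))
      for (i in 1:3) for (j in 1:3)
        field <- field + m[i, j] * grid$nx^(i - 1) * grid$ny^(j - 1)
      m * magnitude_px / max(1e-9, max(abs(field)))
    }
    optics_model(dist_coef_x = rc(), dist_coef_y = rc(),
                 noise_sd = noise_sd, platform_px = platform_px)
  })
}

distortion_field <- function(model, pix) {
  out <- matrix(0, nrow(pix), 2)
  ev <- function(coef) {
    if (is.null(coef)) return(rep(0, nrow(pix)))
    nx <- pix[, 1] / model$platform_px[1]
    ny <- pix[, 2] / model$platform_px[2]
    acc <- rep(0, nrow(pix))
    for (i in seq_len(nrow(coef)))
      for (j in seq_len(ncol(coef)))
        if (coef[i, j] != 0)
          acc <- acc + coef[i, j] * nx^(i - 1) * ny^(j - 1)
    acc
  }
  out[, 1] <- ev(model$dist_coef_x)
  out[, 2] <- ev(model$dist_coef_y)
  out
}

#' Realize the laser spot pixel for commanded voltages
#'
#' @param voltages numeric length-2 vector or n-by-2 matrix of `(vx, vy)`.
#' @param model an [optics_model].
#' @param seed required when the model has observation noise.
#' @return n-by-2 matrix of spot pixels (sub-pixel).
#' @export
optics_forward <- function(voltages, model, seed = NULL) {
  v <- if (is.null(dim(voltages))) matrix(voltages, ncol = 2) else
    as.matrix(voltages)
  vb <- model$voltage_bounds
  if (any(v[, 1] < vb$x[1] | v[, 1] > vb$x[2] |
          v[, 2] < vb$y[1] | v[, 2] > vb$y[2]))
    stopf("commanded voltages outside the configured steering range")
  p_lin <- cbind(v[, 1] / model$gain[1], v[, 2] / model$gain[2])
  p <- p_lin + distortion_field(model, p_lin)
  if (model$noise_sd > 0) {
    check_seed(seed)
    p <- with_seed(seed,
      p + matrix(stats::rnorm(length(p), 0, model$noise_sd), nrow(p), 2))
  }
  colnames(p) <- c("x", "y")
  p
}

#' Processing/actuation latency model
#'
#' Defaults follow the measured closed-loop characterization: frame
#' acquisition to targeting 84 +/- 12 ms, galvanometer-to-laser actuation
#' 3.3 +/- 0.5 ms; samples are truncated at zero.
#'
#' @param proc_mean,proc_sd processing delay mean and SD, seconds.
#' @param act_mean,act_sd actuation delay mean and SD, seconds.
#' @return list of class `latency_model`.
#' @export
latency_model <- function(proc_mean = 0.084, proc_sd = 0.012,
                          act_mean = 0.0033, act_sd = 0.0005) {
  structure(list(proc_mean = proc_mean, proc_sd = proc_sd,
                 act_mean = act_mean, act_sd = act_sd),
            class = "latency_model")
}

#' Sample per-event closed-loop delays
#'
#' @param model a [latency_model].
#' @param n number of events.
#' @param seed integer seed.
#' @return data.frame with columns `processing`, `actuation`, `total` (s).
#' @export
sample_delays <- function(model, n, seed) {
  with_seed(seed, {
    pr <- rtnorm(n, model$proc_mean, model$proc_sd, lower = 0)
    ac <- rtnorm(n, model$act_mean, model$act_sd, lower = 0)
    data.frame(processing = pr, actuation = ac, total = pr + ac)
  })
}

#' Two-state movement trajectory parameters
#'
#' State 1 is the faster, directionally coherent state; state 2 the slower,
#' incoherent one.  Defaults are the printed movement-state statistics:
#' speeds 90.8 +/- 28.3 and 32.5 +/- 13.9 mm/s, heading coherences
#' 0.9 +/- 0.1 and 0.1 +/- 0.1, mixture weight 0.681 for the fast state.
#'
#' @param speed_mean,speed_sd per-state mean/SD of pre-window speed (mm/s).
#' @param coherence_mean,coherence_sd per-state mean/SD of pre-window
#'   heading coherence (mean resultant length, 0-1).
#' @param weight fast-state mixture weight in (0, 1).
#' @param duration trial length, seconds (2 s pre + 2 s post by default).
#' @param fps frame rate.
#' @param scale_mm_per_px platform scale factor.
#' @param post_speed_scale per-state multiplicative change of speed after
#'   stimulation (fast-direct trials slow down).
#' @param post_coherence per-state post-stimulation coherence target
#'   (slow-assess trials become more direct).
#' @param response_delay_s behavioral response onset after the stimulus,
#'   seconds; the pre-stimulation movement regime persists this long
#'   (withdrawal-scale latency, ~0.1 s).
#' @return list of class `state_trajectory_params`.
#' @export
state_trajectory_params <- function(speed_mean = c(90.8, 32.5),
                                    speed_sd = c(28.3, 13.9),
                                    coherence_mean = c(0.9, 0.1),
                                    coherence_sd = c(0.1, 0.1),
                                    weight = 0.681, duration = 4, fps = 30,
                                    scale_mm_per_px = 0.45,
                                    post_speed_scale = c(0.5, 1.1),
                                    post_coherence = c(0.45, 0.65),
                                    response_delay_s = 0.1) {
  if (weight <= 0 || weight >= 1) stopf("weight must lie in (0, 1)")
  if (any(coherence_mean < 0 | coherence_mean > 1))
    stopf("coherence targets must lie in [0, 1]")
  if (any(speed_mean <= 0 & coherence_mean > 0.3))
    stopf("infeasible state: non-trivial coherence requires positive speed")
  structure(list(speed_mean = speed_mean, speed_sd = speed_sd,
                 coherence_mean = coherence_mean,
                 coherence_sd = coherence_sd, weight = weight,
                 duration = duration, fps = fps,
                 scale_mm_per_px = scale_mm_per_px,
                 post_speed_scale = post_speed_scale,
                 post_coherence = post_coherence,
                 response_delay_s = response_delay_s),
            class = "state_trajectory_params")
}

# Map a target mean-resultant-length (as measured by heading_coherence,
# i.e. after 10-frame circular smoothing) to the angular SD of iid
# wrapped-normal heading jitter.  Built once per (fps, smooth_window) by
# simulation with a fixed internal seed and cached; monotone-decreasing by
# construction.
.stimloop_cache <- new.env(parent = emptyenv())

coherence_jitter_sd <- function(R_target, fps = 30, smooth_window = 10,
                                eval_window = 2) {
  key <- sprintf("coh_%g_%d_%g", fps, smooth_window, eval_window)
  if (is.null(.stimloop_cache[[key]])) {
    s_grid <- exp(seq(log(0.015), log(8), length.out = 36))
    # mirror the trial geometry: mid-trajectory evaluation window with
    # full smoothing support on both sides
    n_fr <- 2 * round(eval_window * fps) + 1
    mid <- round(eval_window * fps) + 1
    mean_R <- with_seed(104729L, vapply(s_grid, function(s) {
      mean(vapply(seq_len(120), function(r) {
        th <- stats::rnorm(n_fr - 1, 0, s)
        xy <- cbind(cumsum(cos(th)), cumsum(sin(th)))
        traj <- data.frame(time = (seq_len(n_fr) - 1) / fps,
                           x = c(0, xy[, 1]), y = c(0, xy[, 2]))
        heading_coherence(traj, smooth_window = smooth_window,
                          eval_window = eval_window, fps = fps,
                          at = traj$time[mid])
      }, numeric(1)))
    }, numeric(1)))
    o <- order(mean_R)
    mR <- cummax(mean_R[o])  # enforce monotone for inversion
    mR <- mR + seq_along(mR) * 1e-9
    .stimloop_cache[[key]] <- stats::approxfun(mR, s_grid[o], rule = 2)
  }
  .stimloop_cache[[key]](R_target)
}

#' Generate two-state pre/post stimulation trajectories
#'
#' Each trial is a tail-base trajectory of `duration` seconds with the
#' stimulus at the midpoint.  Per-trial target speeds and coherences are
#' drawn from the state's distributions (sample moments matched exactly to
#' the stated parameters); headings follow wrapped-normal jitter whose
#' angular SD is calibrated so the measured (smoothed) mean resultant
#' length realizes the coherence target.  The state composition is fixed at
#' `round(weight * n_trials)` fast trials.
#'
#' @param params a [state_trajectory_params].
#' @param n_trials number of trials (>= 2).
#' @param seed integer seed.
#' @return list of single-part (`tail_base`) [pose_series] objects, with
#'   attributes `state` (1 = fast, 2 = slow), `target_speed`,
#'   `target_coherence`, `stim_frame` and `params`.
#' @export
generate_state_trials <- function(params, n_trials, seed) {
  if (n_trials < 2) stopf("n_trials must be >= 2")
  with_seed(seed, {
    n1 <- round(params$weight * n_trials); n2 <- n_trials - n1
    state <- sample(rep(c(1L, 2L), c(n1, n2)))
    sp <- co <- numeric(n_trials)
    for (s in 1:2) {
      idx <- which(state == s)
      sp[idx] <- pmax(standardize_to(stats::rnorm(length(idx)),
                                     params$speed_mean[s],
                                     params$speed_sd[s]), 2)
      co[idx] <- pmin(pmax(standardize_to(stats::rnorm(length(idx)),
                                          params$coherence_mean[s],
                                          params$coherence_sd[s]),
                           0.02), 0.98)
    }
    fps <- params$fps
    n_fr <- round(params$duration * fps) + 1L
    stim_frame <- round(params$duration / 2 * fps) + 1L
    big <- 4 * max(1100, ceiling(params$duration * max(sp) /
                                   params$scale_mm_per_px / fps * fps))
    trials <- vector("list", n_trials)
    delay_fr <- round((params$response_delay_s %||% 0) * fps)
    onset <- stim_frame + delay_fr      # first frame of the post regime
    for (i in seq_len(n_trials)) {
      s <- state[i]
      sd_pre <- coherence_jitter_sd(co[i], fps)
      sd_post <- coherence_jitter_sd(params$post_coherence[s], fps)
      base <- stats::runif(1, 0, 2 * pi)
      th_pre <- base + stats::rnorm(onset - 1, 0, sd_pre)
      th_post <- th_pre[length(th_pre)] +
        stats::rnorm(n_fr - onset, 0, sd_post)
      step_pre <- sp[i] / (fps * params$scale_mm_per_px)
      step_post <- step_pre * params$post_speed_scale[s]
      th <- c(th_pre, th_post)
      L <- c(rep(step_pre, onset - 1), rep(step_post, n_fr - onset))
      xy <- cbind(big / 2 + cumsum(c(0, L * cos(th))),
                  big / 2 + cumsum(c(0, L * sin(th))))
      trials[[i]] <- pose_series(
        matrix(xy[, 1], dimnames = list(NULL, "tail_base")),
        matrix(xy[, 2], dimnames = list(NULL, "tail_base")),
        matrix(0.95, n_fr, 1, dimnames = list(NULL, "tail_base")),
        fps = fps, frame_size = c(big, big))
    }
    structure(trials, state = state, target_speed = sp,
              target_coherence = co, stim_frame = stim_frame,
              params = params)
  })
}

#' Synthesize motion-energy latency trials
#'
#' Produces per-trial motion-energy traces spanning -9.8 to +9.8 s around
#' the nominal stimulation onset: sub-threshold baseline noise, a
#' single-frame flash artifact at the true onset (nominal onset plus small
#' jitter, within the +/- 0.2 s refinement search), and a sustained
#' supra-threshold rise at the drawn response latency.  Latencies are drawn
#' from a truncated normal whose location is adjusted so the truncated mean
#' equals `mean_latency`.
#'
#' @param n_trials number of trials.
#' @param mean_latency,sd_latency target latency distribution, seconds.
#' @param window detection window `c(lo, hi)` seconds relative to onset.
#' @param fps frame rate.
#' @param seed integer seed.
#' @param response_level sustained motion-energy level of the response.
#' @param baseline_max upper bound of uniform baseline noise.
#' @return list with `traces` (trials-by-samples matrix), `time` (seconds
#'   relative to nominal onset), `onset_jitter`, `latency_true`.
#' @export
simulate_me_trials <- function(n_trials, mean_latency = 4.74,
                               sd_latency = 2.48, window = c(1.5, 9.8),
                               fps = 30, seed, response_level = 2500,
                               baseline_max = 300) {
  with_seed(seed, {
    lat <- rtnorm_target_mean(n_trials, mean_latency, sd_latency,
                              lower = window[1] + 0.1,
                              upper = window[2] - 0.1)
    tgrid <- seq(-9.8, 9.8, by = 1 / fps)
    jit <- stats::runif(n_trials, -0.15, 0.15)
    jit <- round(jit * fps) / fps  # onsets land on frames
    traces <- t(vapply(seq_len(n_trials), function(i) {
      tr <- stats::runif(length(tgrid), 0, baseline_max)
      t0 <- jit[i]
      tr[which.min(abs(tgrid - t0))] <- 6000          # flash artifact
      resp <- tgrid >= t0 + lat[i] & tgrid <= t0 + lat[i] + 1.5
      tr[resp] <- tr[resp] + response_level
      tr
    }, numeric(length(tgrid))))
    list(traces = traces, time = tgrid, onset_jitter = jit,
         latency_true = lat)
  })
}

#' Synthesize pose-based latency trials
#'
#' Each trial is a toe-keypoint trajectory over the window -2 to +10 s
#' around the stimulus: static (with sub-pixel jitter) until the response
#' onset, then a rapid >3 px withdrawal.  Latencies are drawn from a
#' truncated normal whose truncated mean equals `mean_latency`.
#'
#' @param n_trials number of trials.
#' @param mean_latency,sd_latency target latency distribution, seconds.
#' @param fps frame rate.
#' @param seed integer seed.
#' @param jitter_sd sub-pixel positional jitter SD while static.
#' @return list with `trials` (list of data.frames `time`, `x`, `y`,
#'   `likelihood`; stimulus at time 0) and `latency_true`.
#' @export
simulate_pose_trials <- function(n_trials, mean_latency = 0.81,
                                 sd_latency = 1.65, fps = 30, seed,
                                 jitter_sd = 0.05) {
  with_seed(seed, {
    lat <- rtnorm_target_mean(n_trials, mean_latency, sd_latency,
                              lower = 0.05, upper = 9.5)
    tgrid <- seq(-2, 10, by = 1 / fps)
    trials <- lapply(seq_len(n_trials), function(i) {
      nfr <- length(tgrid)
      x <- 100 + stats::rnorm(nfr, 0, jitter_sd)
      y <- 100 + stats::rnorm(nfr, 0, jitter_sd)
      moved <- tgrid >= lat[i]
      ramp <- pmin(cumsum(moved) * 5, 15)  # 5 px/frame, plateau at 15 px
      x <- x + ramp
      data.frame(time = tgrid, x = x, y = y, likelihood = 0.95)
    })
    list(trials = trials, latency_true = lat)
  })
}
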