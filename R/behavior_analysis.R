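# Post-hoc analysis suite: trajectory preprocessing, speed and speed
# categories, stance/swing gait segmentation, motion-energy and pose-based
# response latency, heading coherence, movement-state clustering and
# paired pre/post state-dependence statistics.

#' Clean a keypoint trajectory
#'
#' Frames with likelihood at or below `likelihood_min` are dropped, frames
#' whose Euclidean jump from the last retained frame exceeds `jump_px` are
#' removed as tracking errors, and interior gaps are filled by linear
#' interpolation anchored on the mean of up to three valid frames on each
#' side.  Gaps touching a sequence boundary are left missing (masked), not
#' extrapolated.
#'
#' @param series a [pose_series].
#' @param bodypart body-part name to extract.
#' @param likelihood_min likelihood floor (strictly greater-than is kept);
#'   0.8 for the open arena, 0.85 for the maze.
#' @param jump_px single-frame jump removal threshold, pixels.
#' @param scale_mm_per_px platform scale factor, stored for downstream use.
#' @return data.frame of class `clean_trajectory`: `time`, `x`, `y`,
#'   `likelihood`, `interpolated` (fill mask), `missing`; attributes
#'   `fps`, `scale_mm_per_px`.
#' @export
preprocess <- function(series, bodypart, likelihood_min = 0.8, jump_px = 30,
                       scale_mm_per_px = 0.45) {
  j <- match(bodypart, series$bodyparts)
  if (is.na(j)) stopf("body part '%s' not in series", bodypart)
  n <- n_frames(series)
  if (!n) stopf("empty series")
  x <- series$x[, j]; y <- series$y[, j]; lik <- series$likelihood[, j]
  valid <- lik > likelihood_min & !is.na(x) & !is.na(y)
  # single-frame jump removal: the test only applies between immediately
  # consecutive retained frames (across a gap, displacement is not "in a
  # single frame" and large jumps are legitimate motion)
  last <- NA_integer_
  for (i in which(valid)) {
    if (!is.na(last) && i - last == 1L) {
      jump <- sqrt((x[i] - x[last])^2 + (y[i] - y[last])^2)
      if (jump > jump_px) { valid[i] <- FALSE; next }
    }
    last <- i
  }
  fx <- ifelse(valid, x, NA_real_)
  fy <- ifelse(valid, y, NA_real_)
  interpolated <- rep(FALSE, n)
  vi <- which(valid)
  if (length(vi) >= 2) {
    gaps <- which(!valid)
    gaps <- gaps[gaps > min(vi) & gaps < max(vi)]
    for (g in split(gaps, cumsum(c(1, diff(gaps) != 1))[seq_along(gaps)])) {
      left <- utils::tail(vi[vi < min(g)], 3)
      right <- utils::head(vi[vi > max(g)], 3)
      ax <- c(mean(left), mean(right))  # anchor indices
      fx[g] <- stats::approx(ax, c(mean(x[left]), mean(x[right])),
                             xout = g, rule = 2)$y
      fy[g] <- stats::approx(ax, c(mean(y[left]), mean(y[right])),
                             xout = g, rule = 2)$y
      interpolated[g] <- TRUE
    }
  }
  out <- data.frame(time = series$time, x = fx, y = fy, likelihood = lik,
                    interpolated = interpolated,
                    missing = is.na(fx))
  attr(out, "fps") <- series$fps
  attr(out, "scale_mm_per_px") <- scale_mm_per_px
  class(out) <- c("clean_trajectory", "data.frame")
  out
}

#' Per-frame speed from a cleaned trajectory
#'
#' Euclidean displacement over the frame interval, smoothed with a rolling
#' median (window 10 by default), reported in px/s and, via the scale
#' factor, mm/s.
#'
#' @param traj a `clean_trajectory` (or any data.frame with `time`, `x`,
#'   `y`).
#' @param median_window rolling-median window, samples.
#' @param scale_mm_per_px scale factor; defaults to the trajectory's.
#' @return data.frame `time`, `speed_px` (px/s), `speed_mm` (mm/s); the
#'   first frame has no displacement and is `NA`.
#' @export
speed <- function(traj, median_window = 10, scale_mm_per_px = NULL) {
  if (nrow(traj) < 2) stopf("speed needs at least 2 frames")
  scale_mm_per_px <- scale_mm_per_px %||%
    attr(traj, "scale_mm_per_px") %||% 0.45
  dt <- diff(traj$time)
  if (any(dt <= 0)) stopf("non-positive frame interval in timebase")
  d <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  sp <- c(NA_real_, d / dt)
  if (median_window > 1) {
    sm <- zoo::rollapply(sp, median_window, stats::median, na.rm = TRUE,
                         fill = NA, align = "center", partial = TRUE)
    sm[is.nan(sm)] <- NA_real_
  } else sm <- sp
  data.frame(time = traj$time, speed_px = as.numeric(sm),
             speed_mm = as.numeric(sm) * scale_mm_per_px)
}

#' Categorize speeds into locomotor classes
#'
#' Half-open bins in px/s: stationary `[0, 20)`, low `[20, 120)`, medium
#' `[120, 220)`, high `[220, Inf)` (lower-inclusive, upper-exclusive).
#'
#' @param speed_px numeric speeds, px/s (non-negative; `NA` passes through).
#' @return factor with levels `stationary`, `low`, `medium`, `high`.
#' @export
categorize_speed <- function(speed_px) {
  if (any(speed_px < 0, na.rm = TRUE)) stopf("speeds must be non-negative")
  cut(speed_px, breaks = c(0, 20, 120, 220, Inf), right = FALSE,
      labels = c("stationary", "low", "medium", "high"))
}

#' Stance/swing gait segmentation of a paw trajectory
#'
#' A frame is labeled static when either adjacent per-frame displacement
#' corresponds to a speed below the stationary threshold (20 px/s); with
#' this convention the frame count of a phase times the frame interval is
#' an unbiased duration estimate.  Contiguous runs become stance (static)
#' and swing (moving) segments.  Boundary-censored segments (first/last)
#' are excluded from the duration means when interior segments exist.
#'
#' @param paw_traj a `clean_trajectory` (or data.frame `time`, `x`, `y`).
#' @param body_speed_px optional per-frame body (tail base) speed trace in
#'   px/s for the per-category static-frame fractions.
#' @param threshold_px_s static displacement threshold, px/s.
#' @return list with `frame_static` (per-frame logical), `segments`
#'   (data.frame `phase`, `start`, `n_frames`, `duration_ms`),
#'   `stance_ms`, `swing_ms` (means), `stance_sd`, `swing_sd`,
#'   `static_fraction`, `by_category` (data.frame), `insufficient`.
#' @export
gait_phases <- function(paw_traj, body_speed_px = NULL,
                        threshold_px_s = 20) {
  n <- nrow(paw_traj)
  if (n < 3)
    return(list(frame_static = rep(NA, n), segments = NULL,
                stance_ms = NA_real_, swing_ms = NA_real_,
                stance_sd = NA_real_, swing_sd = NA_real_,
                static_fraction = NA_real_, by_category = NULL,
                insufficient = TRUE))
  dt <- diff(paw_traj$time)
  d <- sqrt(diff(paw_traj$x)^2 + diff(paw_traj$y)^2)
  trans_static <- (d / dt) < threshold_px_s
  trans_static[is.na(trans_static)] <- FALSE
  frame_static <- c(trans_static, FALSE) | c(FALSE, trans_static)
  r <- rle(frame_static)
  start <- cumsum(c(1, r$lengths))[seq_along(r$lengths)]
  fi <- mean(dt)
  segments <- data.frame(
    phase = ifelse(r$values, "stance", "swing"),
    start = start, n_frames = r$lengths,
    duration_ms = r$lengths * fi * 1000)
  interior <- if (nrow(segments) > 2) segments[-c(1, nrow(segments)), ]
    else segments
  st <- interior$duration_ms[interior$phase == "stance"]
  sw <- interior$duration_ms[interior$phase == "swing"]
  by_category <- NULL
  if (!is.null(body_speed_px)) {
    categ <- categorize_speed(pmax(body_speed_px, 0))
    tab <- tapply(frame_static, categ, mean)
    by_category <- data.frame(category = names(tab),
                              static_fraction = as.numeric(tab),
                              n_frames = as.numeric(table(categ)))
  }
  list(frame_static = frame_static, segments = segments,
       stance_ms = if (length(st)) mean(st) else NA_real_,
       swing_ms = if (length(sw)) mean(sw) else NA_real_,
       stance_sd = if (length(st) > 1) stats::sd(st) else NA_real_,
       swing_sd = if (length(sw) > 1) stats::sd(sw) else NA_real_,
       static_fraction = mean(frame_static),
       by_category = by_category, insufficient = FALSE)
}

#' Motion energy inside a circular ROI anchored to a keypoint
#'
#' Absolute frame-to-frame differences are masked to a circular ROI
#' (anchored to the keypoint at the frame just before nominal stimulation
#' onset and fixed thereafter), values strictly below `suppress` intensity
#' units are zeroed, and the remainder summed per transition.
#'
#' @param frames a [frame_stack].
#' @param anchor `(x, y)` ROI center, pixels (0-based).
#' @param radius ROI radius, pixels.
#' @param suppress suppression level, intensity units.
#' @return numeric trace of length `n_frames - 1`; attribute `clipped` is
#'   `TRUE` when the ROI ran off the frame edge.
#' @export
me_roi_trace <- function(frames, anchor, radius = 15, suppress = 3) {
  d <- dim(frames$frames[[1]])
  xs <- 0:(d[2] - 1); ys <- 0:(d[1] - 1)
  mask <- outer((ys - anchor[2])^2, (xs - anchor[1])^2, "+") <= radius^2
  clipped <- anchor[1] - radius < 0 || anchor[2] - radius < 0 ||
    anchor[1] + radius > d[2] - 1 || anchor[2] + radius > d[1] - 1
  if (clipped)
    warning("ROI partially outside the frame; clipped", call. = FALSE)
  n <- length(frames$frames)
  if (n < 2) stopf("need at least 2 frames")
  out <- numeric(n - 1)
  prev <- frames$frames[[1]]
  for (i in 2:n) {
    cur <- frames$frames[[i]]
    df <- abs(cur - prev) * mask
    df[df < suppress] <- 0
    out[i - 1] <- sum(df)
    prev <- cur
  }
  attr(out, "clipped") <- clipped
  out
}

gauss_kernel <- function(len = 7, sd = 2) {
  half <- (len - 1) / 2
  k <- exp(-((-half:half)^2) / (2 * sd^2))
  k / sum(k)
}

smooth_me <- function(x, fps) {
  m <- stats::runmed(x, 3, endrule = "median")
  k <- gauss_kernel(7, 2)
  half <- 3
  xp <- c(rep(m[1], half), m, rep(m[length(m)], half))
  as.numeric(stats::filter(xp, k, sides = 2))[(half + 1):(half + length(m))]
}

#' Response latency from a motion-energy trace
#'
#' The nominal onset is refined to the largest motion-energy peak within
#' +/- 0.2 s (the stimulus flash artifact); the trace is re-windowed
#' around the refined onset, the single-frame artifact at t = 0 zeroed,
#' and denoised with a 3-sample median then a 7-sample Gaussian (sd = 2
#' samples).  Trials with any threshold crossing in 0-1.5 s are excluded
#' as not idle; a trial responds iff the trace first reaches the threshold
#' (>= 1000 summed units) within 1.5-9.8 s, and the latency is that
#' crossing time relative to the refined onset.
#'
#' @param trace motion-energy trace spanning -9.8 to +9.8 s around the
#'   nominal onset.
#' @param time sample times, seconds relative to the nominal onset.
#' @param fps frame rate.
#' @param threshold response threshold, summed motion-energy units.
#' @param detect_window response window, seconds.
#' @return list of class `response_result`: `responded`, `latency` (s or
#'   `NA`), `refined_onset` (s, relative to nominal), `exclusion`
#'   (`"none"`, `"not_idle"`).
#' @export
me_latency <- function(trace, time, fps = 30, threshold = 1000,
                       detect_window = c(1.5, 9.8)) {
  if (length(trace) != length(time)) stopf("trace/time length mismatch")
  if (min(time) > -9.8 + 0.2 || max(time) < 9.8 - 0.2)
    stopf("trace window too short: need -9.8 to +9.8 s around onset")
  near <- which(abs(time) <= 0.2)
  refined <- time[near[which.max(trace[near])]]
  rel <- time - refined
  keep <- rel >= -9.8 - 1e-9 & rel <= 9.8 + 1e-9
  rel <- rel[keep]; tr <- trace[keep]
  tr[which.min(abs(rel))] <- 0          # single-frame flash artifact
  sm <- smooth_me(tr, fps)
  if (any(sm[rel > 0 & rel < detect_window[1]] >= threshold))
    return(structure(list(responded = FALSE, latency = NA_real_,
                          refined_onset = refined, exclusion = "not_idle"),
                     class = "response_result"))
  win <- which(rel >= detect_window[1] & rel <= detect_window[2])
  cross <- win[sm[win] >= threshold]
  if (length(cross))
    structure(list(responded = TRUE, latency = rel[cross[1]],
                   refined_onset = refined, exclusion = "none"),
              class = "response_result")
  else
    structure(list(responded = FALSE, latency = NA_real_,
                   refined_onset = refined, exclusion = "none"),
              class = "response_result")
}

#' Response latency from a toe-keypoint trajectory
#'
#' Euclidean distance of the keypoint from its mean baseline coordinate
#' (the -2 to 0 s window) is evaluated over the trial window using only
#' frames with likelihood above the floor; the trial is a response iff the
#' distance strictly exceeds 3 px within (0, 10] s, with latency at the
#' first exceedance.
#'
#' @param traj data.frame `time`, `x`, `y`, `likelihood`; stimulus at
#'   time 0, window -2 to +10 s.
#' @param threshold_px response threshold, pixels (strict).
#' @param likelihood_min likelihood floor (strict).
#' @return a `response_result`; `exclusion = "low_likelihood"` when no
#'   baseline frame passes the likelihood floor.
#' @export
pose_latency <- function(traj, threshold_px = 3, likelihood_min = 0.8) {
  ok <- traj$likelihood > likelihood_min
  base <- ok & traj$time >= -2 & traj$time < 0
  if (!any(base))
    return(structure(list(responded = FALSE, latency = NA_real_,
                          refined_onset = 0,
                          exclusion = "low_likelihood"),
                     class = "response_result"))
  bx <- mean(traj$x[base]); by <- mean(traj$y[base])
  post <- which(ok & traj$time > 0 & traj$time <= 10)
  d <- sqrt((traj$x[post] - bx)^2 + (traj$y[post] - by)^2)
  hit <- post[d > threshold_px]
  if (length(hit))
    structure(list(responded = TRUE, latency = traj$time[hit[1]],
                   refined_onset = 0, exclusion = "none"),
              class = "response_result")
  else
    structure(list(responded = FALSE, latency = NA_real_,
                   refined_onset = 0, exclusion = "none"),
              class = "response_result")
}

#' Heading coherence (mean resultant length)
#'
#' Per-frame headings from consecutive displacements are turned into unit
#' vectors and circularly smoothed by a moving vector average over
#' `smooth_window` frames; the coherence is the mean resultant length of
#' the smoothed vectors over the evaluation window: 1 for a perfectly
#' straight path, near 0 for incoherent headings.  (The smoothed vectors
#' are not renormalized: directionally incoherent windows must be able to
#' yield R near 0, which renormalized overlapping averages cannot.)
#' Zero-displacement frames have no heading and carry the last defined
#' heading forward.
#'
#' @param traj data.frame `time`, `x`, `y` (e.g. a `clean_trajectory`).
#' @param smooth_window circular smoothing window, frames.
#' @param eval_window evaluation span, seconds.
#' @param fps frame rate; inferred from the timebase when `NULL`.
#' @param at end time of the evaluation window (defaults to the last
#'   frame); the window is `(at - eval_window, at]`.
#' @return coherence R in \[0, 1\] (`NA` if no heading is defined).
#' @export
heading_coherence <- function(traj, smooth_window = 10, eval_window = 2,
                              fps = NULL, at = NULL) {
  n <- nrow(traj)
  if (n < 3) stopf("need at least 3 frames")
  fps <- fps %||% 1 / stats::median(diff(traj$time))
  dx <- diff(traj$x); dy <- diff(traj$y)
  disp <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  th[disp < 1e-12] <- NA
  th <- zoo::na.locf(th, na.rm = FALSE)        # carry last defined heading
  def <- !is.na(th)
  if (!any(def)) return(NA_real_)
  ht <- traj$time[-1]                           # heading at the later frame
  u <- cbind(cos(th), sin(th))
  if (smooth_window > 1) {
    mc <- zoo::rollapply(u[, 1], smooth_window, mean, na.rm = TRUE,
                         fill = NA, align = "center", partial = TRUE)
    ms <- zoo::rollapply(u[, 2], smooth_window, mean, na.rm = TRUE,
                         fill = NA, align = "center", partial = TRUE)
    keep <- !is.na(mc) & !is.na(ms)
    u <- cbind(mc[keep], ms[keep])
    ht <- ht[keep]
  } else {
    u <- u[def, , drop = FALSE]
    ht <- ht[def]
  }
  at <- at %||% max(ht)
  # half-frame slack selects exactly eval_window * fps headings on a
  # regular timebase
  sel <- ht > at - eval_window + 0.5 / fps & ht <= at + 0.5 / fps
  if (!any(sel)) return(NA_real_)
  sqrt(mean(u[sel, 1])^2 + mean(u[sel, 2])^2)
}

#' Pre/post speed and coherence features per trial
#'
#' Convenience wrapper for trials from [generate_state_trials] (or any
#' single-part pose series with a known stimulation frame): mean tail-base
#' speed (mm/s, 10-frame rolling median) and heading coherence in the 2 s
#' windows immediately before and after the stimulus.
#'
#' @param trials list of single-part [pose_series] trials.
#' @param stim_frame stimulation frame index (defaults to the
#'   `stim_frame` attribute of `trials`).
#' @param scale_mm_per_px scale factor.
#' @param window window length, seconds.
#' @return data.frame `pre_speed`, `pre_coherence`, `post_speed`,
#'   `post_coherence` (one row per trial).
#' @export
trial_features <- function(trials, stim_frame = NULL,
                           scale_mm_per_px = 0.45, window = 2) {
  stim_frame <- stim_frame %||% attr(trials, "stim_frame")
  if (is.null(stim_frame)) stopf("stim_frame not given and not an attribute")
  rows <- lapply(trials, function(tr) {
    traj <- data.frame(time = tr$time, x = tr$x[, 1], y = tr$y[, 1])
    sp <- speed(traj, scale_mm_per_px = scale_mm_per_px)
    t_stim <- tr$time[stim_frame]
    pre <- sp$time > t_stim - window & sp$time <= t_stim
    post <- sp$time > t_stim & sp$time <= t_stim + window
    data.frame(
      pre_speed = mean(sp$speed_mm[pre], na.rm = TRUE),
      pre_coherence = heading_coherence(traj, eval_window = window,
                                        at = t_stim),
      post_speed = mean(sp$speed_mm[post], na.rm = TRUE),
      post_coherence = heading_coherence(traj, eval_window = window,
                                         at = t_stim + window))
  })
  do.call(rbind, rows)
}

#' Two-state Gaussian-mixture clustering of movement features
#'
#' Standardizes the (speed, coherence) features, fits a two-component
#' Gaussian mixture with full covariance, and labels the component with
#' the higher mean speed `fast-direct`, the other `slow-assess` (semantic
#' labels never depend on component index).  A mean silhouette below zero
#' flags degenerate, effectively single-cluster data.
#'
#' @param speed_mm pre-window speeds, mm/s.
#' @param coherence pre-window coherences.
#' @param seed integer seed.
#' @return list with `labels` (factor `fast-direct`/`slow-assess`),
#'   `means`, `sds` (per-cluster data.frames), `proportions`,
#'   `silhouette`, `degenerate`.
#' @export
cluster_states <- function(speed_mm, coherence, seed) {
  if (length(speed_mm) < 10) stopf("need at least 10 trials to cluster")
  X <- scale(cbind(speed = speed_mm, coherence = coherence))
  fit <- with_seed(seed,
    Mclust(X, G = 2, modelNames = "VVV", verbose = FALSE))
  cl <- fit$classification
  mu_sp <- tapply(speed_mm, cl, mean)
  fast_comp <- as.integer(names(mu_sp)[which.max(mu_sp)])
  labels <- factor(ifelse(cl == fast_comp, "fast-direct", "slow-assess"),
                   levels = c("fast-direct", "slow-assess"))
  stat <- function(f) vapply(split(seq_along(cl), labels),
                             function(i) f(i), numeric(1))
  means <- data.frame(
    cluster = levels(labels),
    speed = as.numeric(stat(function(i) mean(speed_mm[i]))),
    coherence = as.numeric(stat(function(i) mean(coherence[i]))))
  sds <- data.frame(
    cluster = levels(labels),
    speed = as.numeric(stat(function(i) stats::sd(speed_mm[i]))),
    coherence = as.numeric(stat(function(i) stats::sd(coherence[i]))))
  # mean silhouette on the standardized features
  D <- as.matrix(stats::dist(X))
  sil <- vapply(seq_along(cl), function(i) {
    own <- labels == labels[i]; own[i] <- FALSE
    a <- if (any(own)) mean(D[i, own]) else 0
    b <- mean(D[i, labels != labels[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  list(labels = labels, means = means, sds = sds,
       proportions = as.numeric(prop.table(table(labels))),
       silhouette = mean(sil), degenerate = mean(sil) < 0)
}

#' Paired pre/post state-dependence statistics
#'
#' Per-trial deltas (post - pre) of speed and coherence are summarized per
#' cluster: a one-sample t of the deltas against zero change, and Welch's
#' unequal-variance t between the clusters' deltas.  All-zero deltas give
#' t = 0, p = 1; nonzero constant deltas (zero variance) are reported as
#' undefined with a flag.  Clusters with fewer than 2 trials are omitted.
#'
#' @param features data.frame from [trial_features].
#' @param labels factor from [cluster_states].
#' @return list with `per_cluster` (data.frame `cluster`, `metric`,
#'   `mean_delta`, `t`, `p`, `flag`) and `between` (Welch t between
#'   clusters per metric).
#' @export
state_dependence <- function(features, labels) {
  deltas <- data.frame(speed = features$post_speed - features$pre_speed,
                       coherence = features$post_coherence -
                         features$pre_coherence)
  one_sample <- function(d) {
    if (length(d) < 2)
      return(c(t = NA_real_, p = NA_real_, flag = 1))
    if (all(d == 0)) return(c(t = 0, p = 1, flag = 0))
    if (stats::sd(d) == 0) return(c(t = NA_real_, p = NA_real_, flag = 1))
    tt <- stats::t.test(d)
    c(t = unname(tt$statistic), p = tt$p.value, flag = 0)
  }
  rows <- list()
  for (cl in levels(labels)) {
    sel <- labels == cl
    if (sum(sel) < 2) next
    for (m in c("speed", "coherence")) {
      s <- one_sample(deltas[[m]][sel])
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, metric = m, n = sum(sel),
        mean_delta = mean(deltas[[m]][sel]),
        t = s[["t"]], p = s[["p"]],
        flag = if (s[["flag"]] == 1) "undefined" else "none")
    }
  }
  between <- lapply(c(speed = "speed", coherence = "coherence"),
                    function(m) {
    g1 <- deltas[[m]][labels == levels(labels)[1]]
    g2 <- deltas[[m]][labels == levels(labels)[2]]
    if (length(g1) < 2 || length(g2) < 2 ||
        (stats::sd(g1) == 0 && stats::sd(g2) == 0))
      return(c(t = NA_real_, p = NA_real_))
    tt <- stats::t.test(g1, g2, var.equal = FALSE)
    c(t = unname(tt$statistic), p = tt$p.value)
  })
  list(per_cluster = do.call(rbind, rows), between = between)
}

#' 2D dwell histogram of a paw keypoint ("footprints")
#'
#' Stance positions appear as local occupancy maxima in keypoint space.
#'
#' @param traj data.frame `x`, `y`.
#' @param bin_px bin edge length, pixels.
#' @return list with `counts` (matrix, rows = y bins), `xbreaks`,
#'   `ybreaks`.
#' @export
footprint_histogram <- function(traj, bin_px = 5) {
  ok <- !is.na(traj$x) & !is.na(traj$y)
  x <- traj$x[ok]; y <- traj$y[ok]
  xb <- seq(floor(min(x)), ceiling(max(x)) + bin_px, by = bin_px)
  yb <- seq(floor(min(y)), ceiling(max(y)) + bin_px, by = bin_px)
  xi <- findInterval(x, xb, rightmost.closed = TRUE)
  yi <- findInterval(y, yb, rightmost.closed = TRUE)
  counts <- matrix(0, length(yb) - 1, length(xb) - 1)
  for (i in seq_along(xi)) counts[yi[i], xi[i]] <- counts[yi[i], xi[i]] + 1
  list(counts = counts, xbreaks = xb, ybreaks = yb)
}

#' Dwell peaks of a footprint histogram
#'
#' @param hist result of [footprint_histogram].
#' @param min_count minimum occupancy for a peak.
#' @return data.frame `row`, `col`, `count` of local maxima (cells at
#'   least as occupied as all 8 neighbors).
#' @export
find_dwell_peaks <- function(hist, min_count = 3) {
  m <- hist$counts
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  peaks <- which(m >= min_count, arr.ind = TRUE)
  keep <- vapply(seq_len(nrow(peaks)), function(i) {
    r <- peaks[i, 1]; cc <- peaks[i, 2]
    nb <- pad[r:(r + 2), cc:(cc + 2)]
    m[r, cc] >= max(nb[-5])
  }, logical(1))
  peaks <- peaks[keep, , drop = FALSE]
  data.frame(row = peaks[, 1], col = peaks[, 2],
             count = m[peaks])
}
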