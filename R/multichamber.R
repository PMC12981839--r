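# Random-access multi-animal stimulation: per-chamber motion energy, idle
# detection, pseudo-random chamber scheduling with refractory, and ROI
# cropping with exact coordinate translation.

#' Build a chamber grid
#'
#' Chambers are laid out row-major on the full frame as non-overlapping
#' rectangular ROIs (default 3 x 3 of 230 x 230 px crops).
#'
#' @param rows,cols grid shape (product >= 1).
#' @param roi_px `c(width, height)` of each chamber crop, pixels.
#' @param origin `c(x, y)` of the first chamber's top-left corner (0-based).
#' @param gap_px spacing between adjacent ROIs, pixels.
#' @param frame_size full-frame `c(width, height)`; ROIs must fit inside.
#' @return object of class `chamber_grid` with a `rois` data.frame
#'   (`chamber`, `x0`, `y0`, `w`, `h`).
#' @export
chamber_grid <- function(rows = 3, cols = 3, roi_px = c(230, 230),
                         origin = c(0, 0), gap_px = 0,
                         frame_size = c(1100, 1100)) {
  if (rows < 1 || cols < 1) stopf("rows * cols must be >= 1")
  idx <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  rois <- data.frame(
    chamber = seq_len(nrow(idx)),
    x0 = origin[1] + (idx$col - 1) * (roi_px[1] + gap_px),
    y0 = origin[2] + (idx$row - 1) * (roi_px[2] + gap_px),
    w = roi_px[1], h = roi_px[2])
  if (any(rois$x0 < 0 | rois$y0 < 0 |
          rois$x0 + rois$w > frame_size[1] |
          rois$y0 + rois$h > frame_size[2]))
    stopf("chamber ROIs do not fit inside the frame")
  structure(list(rois = rois, rows = rows, cols = cols,
                 frame_size = frame_size),
            class = "chamber_grid")
}

roi_of <- function(grid, chamber) {
  if (!chamber %in% grid$rois$chamber) stopf("invalid chamber id %s", chamber)
  grid$rois[grid$rois$chamber == chamber, ]
}

#' Per-transition motion energy within an ROI
#'
#' For every consecutive frame pair, the absolute pixel difference inside
#' the ROI is computed, values strictly below `noise_floor` are zeroed, and
#' the remainder summed.
#'
#' @param frames a [frame_stack] (>= 2 frames).
#' @param roi list or one-row data.frame with `x0`, `y0`, `w`, `h`
#'   (0-based pixels); `NULL` uses the full frame.
#' @param noise_floor background suppression level, intensity units.
#' @return numeric trace of length `n_frames - 1`.
#' @export
motion_energy <- function(frames, roi = NULL, noise_floor = 10) {
  n <- length(frames$frames)
  if (n < 2) stopf("motion energy needs at least 2 frames")
  d <- dim(frames$frames[[1]])
  if (is.null(roi)) roi <- list(x0 = 0, y0 = 0, w = d[2], h = d[1])
  if (roi$x0 < 0 || roi$y0 < 0 || roi$x0 + roi$w > d[2] ||
      roi$y0 + roi$h > d[1])
    stopf("ROI extends outside the frame")
  rows <- (roi$y0 + 1):(roi$y0 + roi$h)
  cols <- (roi$x0 + 1):(roi$x0 + roi$w)
  prev <- frames$frames[[1]][rows, cols]
  out <- numeric(n - 1)
  for (i in 2:n) {
    cur <- frames$frames[[i]][rows, cols]
    df <- abs(cur - prev)
    df[df < noise_floor] <- 0
    out[i - 1] <- sum(df)
    prev <- cur
  }
  out
}

#' Per-frame idle flags from a motion-energy trace
#'
#' Frame `f` is idle iff every transition in the trailing `window` seconds
#' (strictly) stays below `threshold`.  Frames without a full trailing
#' window are reported not idle (warm-up).
#'
#' @param trace motion-energy trace (length `n_frames - 1`).
#' @param threshold idle threshold, summed motion-energy units.  The
#'   default (30,000) is the 8-bit / 230 x 230 px preset; other bit depths
#'   or ROI areas need re-tuning.
#' @param window trailing window, seconds.
#' @param fps frame rate.
#' @return logical vector of length `length(trace) + 1` (per frame).
#' @export
detect_idle <- function(trace, threshold = 30000, window = 2, fps = 30) {
  n_w <- round(window * fps)
  if (length(trace) < n_w)
    stopf("trace shorter than the idle window (%d transitions)", n_w)
  quiet <- trace < threshold
  c(FALSE, roll_all(quiet, n_w))
}

#' Pseudo-randomly select an eligible chamber
#'
#' Eligible chambers are idle and have not been stimulated within the
#' scheduler refractory.  Selection is uniform over the eligible set from
#' a seeded stream.
#'
#' @param grid a [chamber_grid].
#' @param idle logical vector, one flag per chamber (current idle state).
#' @param last_stim numeric vector of last-stimulus times per chamber
#'   (`-Inf` if never stimulated).
#' @param now current time, seconds.
#' @param refractory minimum time since a chamber's last stimulus, seconds.
#' @param seed integer seed.
#' @return a chamber id, or `NA_integer_` if none is eligible.
#' @export
schedule_chamber <- function(grid, idle, last_stim, now, refractory = 10,
                             seed) {
  k <- nrow(grid$rois)
  if (length(idle) != k || length(last_stim) != k)
    stopf("idle and last_stim must have one entry per chamber")
  eligible <- which(idle & (now - last_stim > refractory))
  if (!length(eligible)) return(NA_integer_)
  with_seed(seed, eligible[sample.int(length(eligible), 1)])
}

#' Crop a frame to one chamber's ROI
#'
#' @param frame intensity matrix (`[row = y + 1, col = x + 1]`).
#' @param grid a [chamber_grid].
#' @param chamber chamber id.
#' @return the ROI submatrix (exact extraction).
#' @export
crop_chamber <- function(frame, grid, chamber) {
  r <- roi_of(grid, chamber)
  frame[(r$y0 + 1):(r$y0 + r$h), (r$x0 + 1):(r$x0 + r$w)]
}

#' Translate keypoint coordinates between ROI-local and full-frame pixels
#'
#' Keypoints estimated on a cropped chamber must be translated back to
#' full-frame pixels before targeting; the round trip is exact.
#'
#' @param xy length-2 vector or n-by-2 matrix of `(x, y)`.
#' @param grid a [chamber_grid].
#' @param chamber chamber id.
#' @param to `"full"` (local -> full frame) or `"local"`.
#' @return translated coordinates, same shape as `xy`.
#' @export
translate_coords <- function(xy, grid, chamber, to = c("full", "local")) {
  to <- match.arg(to)
  r <- roi_of(grid, chamber)
  off <- c(r$x0, r$y0)
  if (to == "local") off <- -off
  if (is.null(dim(xy))) xy + off
  else sweep(as.matrix(xy), 2, off, "+")
}

#' Run the random-access multi-chamber scheduling loop
#'
#' Consumes per-chamber motion-energy traces, maintains idle flags, and on
#' each frame pseudo-randomly stimulates at most one eligible chamber
#' (idle, outside its refractory).  This is the scheduling skeleton the
#' full rig wraps around per-chamber pose estimation and targeting.
#'
#' @param grid a [chamber_grid].
#' @param traces matrix of motion-energy traces, one column per chamber
#'   (`n_frames - 1` rows).
#' @param fps frame rate.
#' @param threshold idle threshold (see [detect_idle]).
#' @param window idle window, seconds.
#' @param refractory scheduler refractory per chamber, seconds.
#' @param seed integer seed.
#' @return data.frame of stimulations (`time`, `frame`, `chamber`).
#' @export
run_chamber_loop <- function(grid, traces, fps = 30, threshold = 30000,
                             window = 2, refractory = 10, seed) {
  k <- nrow(grid$rois)
  if (ncol(traces) != k) stopf("need one trace column per chamber")
  idle <- vapply(seq_len(k), function(j)
    detect_idle(traces[, j], threshold, window, fps), logical(nrow(traces) + 1))
  with_seed(seed, {
    last_stim <- rep(-Inf, k)
    out <- list()
    for (f in seq_len(nrow(idle))) {
      now <- (f - 1) / fps
      eligible <- which(idle[f, ] & (now - last_stim > refractory))
      if (!length(eligible)) next
      ch <- eligible[sample.int(length(eligible), 1)]
      last_stim[ch] <- now
      out[[length(out) + 1L]] <- data.frame(time = now, frame = f,
                                            chamber = ch)
    }
    if (length(out)) do.call(rbind, out) else
      data.frame(time = numeric(), frame = integer(), chamber = integer())
  })
}
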