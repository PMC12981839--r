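# Domain containers and file formats: pose time series in the three-header
# CSV dialect of markerless pose estimators, grayscale frame stacks, event
# logs, and declarative rig configuration.

EVENT_KINDS <- c("trigger", "stimulus", "reward", "poke", "door",
                 "zone_entry", "zone_exit", "glitch")

#' Construct a pose time series
#'
#' A `pose_series` holds per-frame keypoint coordinates and likelihoods for
#' a named, ordered set of body parts, plus the frame timebase.  Coordinates
#' use 0-based pixel indices with the origin at the top-left corner, x
#' rightward and y downward; physical units are obtained only through a
#' scale factor (mm/pixel).
#'
#' @param x,y numeric frame-by-bodypart matrices of pixel coordinates.
#' @param likelihood matrix of tracking confidences in \[0, 1\]; `NA`
#'   likelihoods are coerced to 0 (never interpolated here).
#' @param fps frames per second (> 0); timestamps are `(frame - 1) / fps`
#'   unless `time` is supplied.
#' @param time optional explicit timestamps (seconds, strictly increasing).
#' @param frame_size `c(width, height)` in pixels.
#' @param bodyparts character vector of part names (defaults to column
#'   names of `x`).
#' @return object of class `pose_series` with fields `x`, `y`,
#'   `likelihood`, `time`, `fps`, `frame_size`, `bodyparts`.
#' @export
pose_series <- function(x, y, likelihood, fps = 30, time = NULL,
                        frame_size = c(1100, 1100), bodyparts = colnames(x)) {
  x <- as.matrix(x); y <- as.matrix(y); likelihood <- as.matrix(likelihood)
  if (is.null(bodyparts)) bodyparts <- paste0("part", seq_len(ncol(x)))
  if (!all(dim(x) == dim(y)) || !all(dim(x) == dim(likelihood)))
    stopf("x, y and likelihood must have identical dimensions")
  if (fps <= 0) stopf("fps must be > 0")
  likelihood[is.na(likelihood)] <- 0
  if (any(likelihood < 0 | likelihood > 1))
    stopf("likelihoods must lie in [0, 1]")
  n <- nrow(x)
  if (is.null(time)) time <- (seq_len(n) - 1) / fps
  if (n > 1 && any(diff(time) <= 0))
    stopf("timestamps must be strictly increasing")
  colnames(x) <- colnames(y) <- colnames(likelihood) <- bodyparts
  structure(list(x = x, y = y, likelihood = likelihood,
                 time = as.numeric(time), fps = fps,
                 frame_size = as.numeric(frame_size),
                 bodyparts = bodyparts),
            class = "pose_series")
}

#' @export
print.pose_series <- function(x, ...) {
  cat(sprintf("<pose_series> %d frames x %d body parts @ %g fps (%gx%g px)\n",
              nrow(x$x), length(x$bodyparts), x$fps,
              x$frame_size[1], x$frame_size[2]))
  cat("  parts:", paste(x$bodyparts, collapse = ", "), "\n")
  invisible(x)
}

n_frames <- function(pose) nrow(pose$x)

#' Extract a frame window from a pose series
#'
#' @param pose a `pose_series`.
#' @param frames integer vector of frame indices (1-based) to keep.
#' @return a `pose_series` restricted to those frames.
#' @export
pose_window <- function(pose, frames) {
  pose_series(pose$x[frames, , drop = FALSE], pose$y[frames, , drop = FALSE],
              pose$likelihood[frames, , drop = FALSE], fps = pose$fps,
              time = pose$time[frames], frame_size = pose$frame_size,
              bodyparts = pose$bodyparts)
}

#' Construct a grayscale frame stack
#'
#' @param frames list of integer matrices (8-bit intensities 0-255), all
#'   the same shape, indexed `[row = y + 1, col = x + 1]`.
#' @param fps frames per second; used to synthesize timestamps.
#' @param time optional explicit timestamps.
#' @return object of class `frame_stack`.
#' @export
frame_stack <- function(frames, fps = 30, time = NULL) {
  if (!length(frames)) stopf("frame stack must contain at least one frame")
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
    stopf("all frames must share one shape")
  if (is.null(time)) time <- (seq_along(frames) - 1) / fps
  structure(list(frames = frames, frame_size = c(d[2], d[1]),
                 time = as.numeric(time), fps = fps),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("<frame_stack> %d frames of %gx%g px @ %g fps\n",
              length(x$frames), x$frame_size[1], x$frame_size[2], x$fps))
  invisible(x)
}

#' Read a pose table in the three-header-row CSV dialect
#'
#' The layout is the one emitted by common markerless pose estimators:
#' three header rows (`scorer`, `bodyparts`, `coords`) followed by one row
#' per frame, with an `x`, `y` and `likelihood` column for every body part.
#' Timestamps are synthesized from the frame index and `fps` (the file
#' carries none).
#'
#' @param path CSV file path.
#' @param fps frame rate used to synthesize timestamps.
#' @param frame_size `c(width, height)` pixels for the returned series.
#' @return a [pose_series].
#' @export
read_pose_table <- function(path, fps = 30, frame_size = c(1100, 1100)) {
  if (!file.exists(path)) stopf("pose table not found: %s", path)
  hdr <- readLines(path, n = 3)
  if (length(hdr) < 3) stopf("malformed pose table: fewer than 3 header rows")
  split_row <- function(s) strsplit(s, ",", fixed = TRUE)[[1]]
  h1 <- split_row(hdr[1]); h2 <- split_row(hdr[2]); h3 <- split_row(hdr[3])
  if (tolower(h1[1]) != "scorer")
    stopf("malformed header row 1: expected 'scorer', got '%s'", h1[1])
  if (tolower(h2[1]) != "bodyparts")
    stopf("malformed header row 2: expected 'bodyparts', got '%s'", h2[1])
  if (tolower(h3[1]) != "coords")
    stopf("malformed header row 3: expected 'coords', got '%s'", h3[1])
  parts_cols <- h2[-1]; coords <- h3[-1]
  if (length(parts_cols) != length(coords))
    stopf("malformed header: bodyparts and coords rows differ in length")
  bad <- setdiff(unique(coords), c("x", "y", "likelihood"))
  if (length(bad))
    stopf("malformed header row 3: unknown coord label '%s'", bad[1])
  parts <- unique(parts_cols)
  for (p in parts) {
    have <- sort(coords[parts_cols == p])
    if (!identical(have, c("likelihood", "x", "y")))
      stopf("malformed header: body part '%s' lacks x/y/likelihood columns", p)
  }
  raw <- utils::read.csv(path, skip = 3, header = FALSE,
                         colClasses = "character",
                         stringsAsFactors = FALSE)
  if (ncol(raw) != length(parts_cols) + 1)
    stopf("data rows have %d columns, header implies %d",
          ncol(raw), length(parts_cols) + 1)
  nf <- nrow(raw)
  num <- function(col, j) {
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v) & !(col %in% c("", "NA")))
    if (length(bad))
      stopf("non-numeric cell '%s' in column %d at frame %d",
            col[bad[1]], j, bad[1])
    v
  }
  mk <- function(coord) {
    m <- matrix(NA_real_, nf, length(parts), dimnames = list(NULL, parts))
    for (p in parts) {
      j <- which(parts_cols == p & coords == coord) + 1L
      m[, p] <- num(raw[[j]], j)
    }
    m
  }
  x <- mk("x"); y <- mk("y"); l <- mk("likelihood")
  pose_series(x, y, l, fps = fps, frame_size = frame_size, bodyparts = parts)
}

#' Write a pose table in the three-header-row CSV dialect
#'
#' @param pose a [pose_series].
#' @param path output CSV path.
#' @param scorer scorer label for the first header row.
#' @return `path`, invisibly.
#' @export
write_pose_table <- function(pose, path, scorer = "stimloop") {
  parts <- pose$bodyparts
  n <- n_frames(pose)
  h1 <- paste(c("scorer", rep(scorer, 3 * length(parts))), collapse = ",")
  h2 <- paste(c("bodyparts", rep(parts, each = 3)), collapse = ",")
  h3 <- paste(c("coords", rep(c("x", "y", "likelihood"), length(parts))),
              collapse = ",")
  cols <- vector("list", 3 * length(parts))
  for (i in seq_along(parts)) {
    cols[[3 * i - 2]] <- pose$x[, i]
    cols[[3 * i - 1]] <- pose$y[, i]
    cols[[3 * i]] <- pose$likelihood[, i]
  }
  body <- do.call(cbind, c(list(seq_len(n) - 1L),
                           lapply(cols, function(v) sprintf("%.17g", v))))
  lines <- c(h1, h2, h3, apply(body, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Create an event record table
#'
#' Event records are the common currency of session logs: a time in
#' seconds, a kind from a closed vocabulary, and a kind-specific payload.
#'
#' @param time numeric seconds (non-negative).
#' @param kind character, each from `trigger`, `stimulus`, `reward`,
#'   `poke`, `door`, `zone_entry`, `zone_exit`, `glitch`.
#' @param payload list of named lists (one per event); may be empty lists.
#' @return data.frame of class `event_log` with columns `time`, `kind`,
#'   `payload` (a list column).
#' @export
event_records <- function(time = numeric(), kind = character(),
                          payload = NULL) {
  if (is.null(payload)) payload <- rep(list(list()), length(time))
  if (length(time) != length(kind) || length(time) != length(payload))
    stopf("time, kind and payload must have equal length")
  if (length(time) && any(time < 0)) stopf("event times must be non-negative")
  bad <- setdiff(unique(kind), EVENT_KINDS)
  if (length(bad)) stopf("unknown event kind '%s'", bad[1])
  df <- data.frame(time = as.numeric(time), kind = as.character(kind),
                   stringsAsFactors = FALSE)
  df$payload <- payload
  class(df) <- c("event_log", "data.frame")
  df
}

#' Write an event log as CSV with a JSON payload column
#'
#' @param events an `event_log` (see [event_records]); must be time-sorted
#'   (ties keep input order).
#' @param path output path; a `.jsonl` extension selects the JSON-lines
#'   variant, anything else the CSV variant.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  if (nrow(events) > 1 && any(diff(events$time) < 0))
    stopf("events must be sorted by time before writing")
  pj <- vapply(events$payload, function(p)
    as.character(jsonlite::toJSON(p, auto_unbox = TRUE, digits = NA)),
    character(1))
  if (grepl("\\.jsonl$", path)) {
    lines <- vapply(seq_len(nrow(events)), function(i)
      as.character(jsonlite::toJSON(list(time = events$time[i],
                                         kind = events$kind[i],
                                         payload = events$payload[[i]]),
                                    auto_unbox = TRUE, digits = NA)),
      character(1))
    writeLines(lines, path)
  } else {
    lines <- c("time,kind,payload",
               if (nrow(events)) sprintf('%.17g,%s,"%s"', events$time,
                                         events$kind,
                                         gsub('"', '""', pj)))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read an event log written by [write_event_log]
#'
#' @param path CSV or JSON-lines event log path.
#' @return an `event_log` data.frame.
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) stopf("event log not found: %s", path)
  if (grepl("\\.jsonl$", path)) {
    lines <- readLines(path)
    recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
    return(event_records(vapply(recs, `[[`, numeric(1), "time"),
                         vapply(recs, `[[`, character(1), "kind"),
                         lapply(recs, function(r) as.list(r$payload))))
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c("numeric", "character", "character"))
  payload <- lapply(raw$payload, function(s)
    as.list(jsonlite::fromJSON(s, simplifyVector = TRUE)))
  event_records(raw$time, raw$kind, payload)
}

#' Default rig configuration
#'
#' Houses the user-defined quantities the control loop consumes: rig
#' geometry, trigger parameters (dispersion bound `v` in pixels, still
#' duration `t` in seconds, likelihood floor `l`), protocol presets and
#' seeds.  The trigger defaults follow the open-arena stillness protocol
#' (keypoint standard deviation < 1 px and likelihood > 0.8 throughout 2 s).
#'
#' @return nested list of class `stimloop_config`.
#' @export
default_config <- function() {
  structure(list(
    rig = list(platform_mm = c(500, 500), resolution = c(1100, 1100),
               fps = 30, scale_mm_per_px = 0.45),
    trigger = list(v = 1.0, t = 2.0, l = 0.8, refractory = 0.5,
                   target_bodypart = "left_hindpaw_mid"),
    protocol = list(pulse_ms = 10, power_mw_mm2 = 40, train_hz = 0,
                    footprint_radius_px = 5),
    chambers = list(rows = 3, cols = 3, roi_px = c(230, 230),
                    idle_threshold = 30000, idle_window_s = 2,
                    scheduler_refractory_s = 10,
                    noise_floor = 10),
    seeds = list(session = 1)
  ), class = "stimloop_config")
}

#' Read and validate a declarative configuration file
#'
#' @param path YAML configuration file.
#' @return validated config list (class `stimloop_config`).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' Validate a configuration list against the schema
#'
#' @param cfg nested configuration list.
#' @return `cfg` (classed), or an error naming the offending key.
#' @export
validate_config <- function(cfg) {
  base <- unclass(default_config())
  for (section in names(base)) {
    if (is.null(cfg[[section]])) cfg[[section]] <- list()
    for (key in names(base[[section]]))
      cfg[[section]][[key]] <- cfg[[section]][[key]] %||% base[[section]][[key]]
  }
  if (cfg$rig$fps <= 0) stopf("config rig.fps must be > 0")
  if (cfg$rig$scale_mm_per_px <= 0)
    stopf("config rig.scale_mm_per_px must be > 0")
  if (cfg$trigger$v <= 0) stopf("config trigger.v must be > 0")
  if (cfg$trigger$t <= 0) stopf("config trigger.t must be > 0")
  if (cfg$trigger$l <= 0 || cfg$trigger$l > 1)
    stopf("config trigger.l must lie in (0, 1]")
  if (cfg$trigger$refractory < 0) stopf("config trigger.refractory must be >= 0")
  structure(cfg, class = "stimloop_config")
}

#' Write a configuration file
#'
#' @param cfg configuration list.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
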