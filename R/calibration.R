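# Pixel <-> steering-voltage calibration: raster acquisition, spot
# detection, two-dimensional polynomial surface fitting, lookup, drift QC
# and geometric summary statistics.

#' Build a regular raster of commanded voltage pairs
#'
#' @param nx,ny grid sizes (>= 2); the default 100 x 100 raster has exactly
#'   10,000 points.
#' @param voltage_bounds list with `x = c(lo, hi)`, `y = c(lo, hi)`.
#' @return data.frame with columns `vx`, `vy` (nx * ny rows, x fastest).
#' @export
make_raster <- function(nx = 100, ny = 100,
                        voltage_bounds = list(x = c(0, 8.8), y = c(0, 8.8))) {
  if (nx < 2 || ny < 2) stopf("raster sizes must be >= 2")
  bx <- voltage_bounds$x; by <- voltage_bounds$y
  if (diff(bx) == 0 || diff(by) == 0)
    stopf("degenerate voltage bounds: zero extent")
  g <- expand.grid(vx = seq(bx[1], bx[2], length.out = nx),
                   vy = seq(by[1], by[2], length.out = ny))
  g[, c("vx", "vy")]
}

#' Detect the laser spot in an intensity frame
#'
#' Returns the intensity-weighted centroid (sub-pixel, 0-based) of the
#' connected region (8-connectivity) around the global maximum.  When
#' several connected components attain the global maximum, the component
#' with the larger summed intensity wins; exact ties break toward the
#' component whose peak has the smaller `(y, x)` lexicographically.
#'
#' @param frame intensity matrix (`[row = y + 1, col = x + 1]`).
#' @param floor background floor; pixels at or below it are ignored.
#' @return named numeric `c(x, y)` in 0-based pixels.
#' @export
detect_spot <- function(frame, floor = 0) {
  mx <- max(frame)
  if (mx <= floor) stopf("no spot: frame maximum does not exceed the floor")
  above <- frame > floor
  lab <- label_components(above)
  peaks <- which(frame == mx, arr.ind = TRUE)
  cand <- unique(lab[peaks])
  if (length(cand) > 1) {
    sums <- vapply(cand, function(k) sum(frame[lab == k]), numeric(1))
    cand <- cand[sums == max(sums)]
    if (length(cand) > 1) {
      # tie: smaller (y, x) of the component's peak
      key <- vapply(cand, function(k) {
        pk <- peaks[lab[peaks] == k, , drop = FALSE]
        o <- order(pk[, 1], pk[, 2])[1]
        pk[o, 1] * (ncol(frame) + 1) + pk[o, 2]
      }, numeric(1))
      cand <- cand[which.min(key)]
    }
  }
  sel <- which(lab == cand[1], arr.ind = TRUE)
  wts <- frame[lab == cand[1]]
  cx <- sum((sel[, 2] - 1) * wts) / sum(wts)
  cy <- sum((sel[, 1] - 1) * wts) / sum(wts)
  c(x = cx, y = cy)
}

# Label 8-connected components of a logical matrix (0 = background).
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- (p - 1L) %% nr + 1L; cc <- (p - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; c2 <- cc + dc
        if (rr < 1 || rr > nr || c2 < 1 || c2 > nc) next
        q <- (c2 - 1L) * nr + rr
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

poly2d_exponents <- function(degree) {
  ex <- expand.grid(i = 0:degree, j = 0:degree)
  ex[ex$i + ex$j <= degree, , drop = FALSE]
}

poly2d_basis <- function(x, y, degree, domain) {
  # domain normalization to [-1, 1] keeps the monomial basis conditioned
  nx <- 2 * (x - domain$x[1]) / diff(domain$x) - 1
  ny <- 2 * (y - domain$y[1]) / diff(domain$y) - 1
  ex <- poly2d_exponents(degree)
  B <- matrix(1, length(x), nrow(ex))
  for (k in seq_len(nrow(ex)))
    B[, k] <- nx^ex$i[k] * ny^ex$j[k]
  B
}

#' Fit the pixel-to-voltage calibration surfaces
#'
#' Ordinary least squares on the full bivariate monomial basis of the given
#' degree, fitted separately for each voltage axis as a function of the
#' observed spot pixel.  The default degree (3) is the lowest that drives
#' held-out error on a distorted simulated rig below the pixel-scale
#' tolerance used for rig QC.
#'
#' @param observations data.frame with columns `vx`, `vy` (commanded
#'   voltages) and `px`, `py` (observed spot pixel).
#' @param degree polynomial order (>= 1).
#' @return object of class `calibration_map`: coefficients per axis,
#'   degree, pixel-domain bounds, held-in residual MAE (pixels and volts),
#'   creation time.
#' @export
fit_map <- function(observations, degree = 3) {
  obs <- observations
  need <- c("vx", "vy", "px", "py")
  if (!all(need %in% names(obs))) stopf("observations need columns vx,vy,px,py")
  if (degree < 1) stopf("degree must be >= 1")
  ncoef <- nrow(poly2d_exponents(degree))
  if (nrow(obs) < ncoef)
    stopf("need at least %d observations for degree %d", ncoef, degree)
  domain <- list(x = range(obs$px), y = range(obs$py))
  B <- poly2d_basis(obs$px, obs$py, degree, domain)
  qrB <- qr(B)
  if (qrB$rank < ncol(B))
    stopf("rank-deficient fit: observations span rank %d < %d coefficients (collinear raster?)",
          qrB$rank, ncol(B))
  cx <- qr.coef(qrB, obs$vx)
  cy <- qr.coef(qrB, obs$vy)
  rx <- obs$vx - B %*% cx
  ry <- obs$vy - B %*% cy
  # local volts-per-pixel gains (central finite difference at domain centre)
  gx <- local_gain(cx, cy, degree, domain)
  res_px <- sqrt((rx / gx[1])^2 + (ry / gx[2])^2)
  structure(list(degree = degree, coef_vx = cx, coef_vy = cy,
                 domain = domain,
                 residual_mae_px = mean(res_px),
                 residual_mae_volt = mean(sqrt(rx^2 + ry^2)),
                 n_obs = nrow(obs),
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            class = "calibration_map")
}

local_gain <- function(cx, cy, degree, domain) {
  mid <- c(mean(domain$x), mean(domain$y))
  h <- c(diff(domain$x), diff(domain$y)) / 1000
  ev <- function(coef, px, py)
    as.numeric(poly2d_basis(px, py, degree, domain) %*% coef)
  gx <- (ev(cx, mid[1] + h[1], mid[2]) - ev(cx, mid[1] - h[1], mid[2])) /
    (2 * h[1])
  gy <- (ev(cy, mid[1], mid[2] + h[2]) - ev(cy, mid[1], mid[2] - h[2])) /
    (2 * h[2])
  c(abs(gx), abs(gy))
}

#' @export
print.calibration_map <- function(x, ...) {
  cat(sprintf(
    "<calibration_map> degree %d, %d obs, residual MAE %.3f px, domain x [%g, %g] y [%g, %g]\n",
    x$degree, x$n_obs, x$residual_mae_px, x$domain$x[1], x$domain$x[2],
    x$domain$y[1], x$domain$y[2]))
  invisible(x)
}

#' Look up steering voltages for a pixel coordinate
#'
#' @param map a [fit_map] result.
#' @param pixel length-2 vector or n-by-2 matrix of `(x, y)` pixels.
#' @param clamp clamp out-of-domain pixels to the domain boundary instead
#'   of erroring (default off).
#' @return n-by-2 matrix of `(vx, vy)`.
#' @export
predict_voltage <- function(map, pixel, clamp = FALSE) {
  p <- if (is.null(dim(pixel))) matrix(pixel, ncol = 2) else as.matrix(pixel)
  d <- map$domain
  out_dom <- p[, 1] < d$x[1] | p[, 1] > d$x[2] |
    p[, 2] < d$y[1] | p[, 2] > d$y[2]
  if (any(out_dom)) {
    if (!clamp)
      stopf("%d pixel(s) outside the calibrated domain (set clamp = TRUE to clamp)",
            sum(out_dom))
    p[, 1] <- pmin(pmax(p[, 1], d$x[1]), d$x[2])
    p[, 2] <- pmin(pmax(p[, 2], d$y[1]), d$y[2])
  }
  B <- poly2d_basis(p[, 1], p[, 2], map$degree, d)
  cbind(vx = as.numeric(B %*% map$coef_vx),
        vy = as.numeric(B %*% map$coef_vy))
}

#' Evaluate a calibration map on held-out targets
#'
#' For every held-out observation the map predicts voltages for the
#' observed spot pixel; the ground-truth optics realize those voltages as a
#' spot, and the mean Euclidean distance between realized and observed
#' pixels is the held-out MAE.  A weekly-drift QC flag is raised when the
#' MAE (in mm) exceeds `remap_threshold_mm`.
#'
#' @param map a [fit_map] result.
#' @param heldout data.frame with columns `px`, `py` (and optionally the
#'   commanded `vx`, `vy`, unused).
#' @param optics the ground-truth [optics_model] (evaluated noise-free).
#' @param scale_mm_per_px scale factor for the mm conversion.
#' @param remap_threshold_mm drift level that should prompt a remap
#'   (default: the measured weekly platform drift, 1.94 mm).
#' @return list with `mae_px`, `mae_mm`, `remap_recommended`, `n`.
#' @export
evaluate_map <- function(map, heldout, optics, scale_mm_per_px = 0.45,
                         remap_threshold_mm = 1.94) {
  if (!nrow(heldout)) stopf("held-out set is empty")
  v <- predict_voltage(map, cbind(heldout$px, heldout$py), clamp = TRUE)
  noise_free <- optics
  noise_free$noise_sd <- 0
  realized <- optics_forward(v, noise_free)
  d <- sqrt((realized[, 1] - heldout$px)^2 + (realized[, 2] - heldout$py)^2)
  mae_px <- mean(d)
  list(mae_px = mae_px, mae_mm = mae_px * scale_mm_per_px,
       remap_recommended = mae_px * scale_mm_per_px > remap_threshold_mm,
       n = nrow(heldout))
}

#' Acquire calibration observations from a (virtual) rig
#'
#' Rasters the commanded voltages through the forward optics and records
#' the observed spot pixel for each, i.e. the virtual equivalent of raster
#' stepping the laser and detecting the peak-intensity pixel per step.
#'
#' @param raster data.frame from [make_raster].
#' @param optics an [optics_model].
#' @param seed seed for spot observation noise.
#' @return data.frame `vx`, `vy`, `px`, `py` (one row per raster point).
#' @export
acquire_raster <- function(raster, optics, seed) {
  p <- optics_forward(as.matrix(raster), optics,
                      seed = if (optics$noise_sd > 0) seed else NULL)
  data.frame(vx = raster$vx, vy = raster$vy, px = p[, 1], py = p[, 2])
}

#' Chessboard scale factor
#'
#' Computes the mm/pixel scale from a detected chessboard corner grid:
#' `square_size / mean inter-corner spacing`, pooling the Euclidean
#' norms of row-wise and column-wise neighbor offsets; also reports the
#' min-max spacing range (a sub-pixel range indicates negligible camera
#' distortion) and flags irregular grids.
#'
#' @param corner_grid numeric array `rows x cols x 2` of corner pixels
#'   (`[, , 1] = x`, `[, , 2] = y`).
#' @param square_size physical square edge, mm.
#' @return list with `scale_mm_per_px`, `mean_spacing_px`,
#'   `spacing_range_px`, `irregular` (spacing CV > 10%).
#' @export
chessboard_scale <- function(corner_grid, square_size = 20) {
  if (square_size <= 0) stopf("square_size must be > 0")
  d <- dim(corner_grid)
  if (length(d) != 3 || d[1] < 2 || d[2] < 2 || d[3] != 2)
    stopf("corner_grid must be a rows x cols x 2 array, at least 2x2")
  sx <- corner_grid[, , 1]; sy <- corner_grid[, , 2]
  sp_cols <- sqrt(diff(t(sx))^2 + diff(t(sy))^2)  # along rows
  sp_rows <- sqrt(diff(sx)^2 + diff(sy)^2)        # along columns
  spacing <- c(sp_cols, sp_rows)
  m <- mean(spacing)
  list(scale_mm_per_px = square_size / m,
       mean_spacing_px = m,
       spacing_range_px = diff(range(spacing)),
       irregular = stats::sd(spacing) / m > 0.10)
}

#' Focal-length (beam path length) variability over a planar region
#'
#' With the steering optics a height `h` below the stimulation plane, the
#' beam path to a point at radial distance `r` is `sqrt(h^2 + r^2)`; the
#' variability is the max-min path difference relative to the min, in
#' percent.
#'
#' @param height optics-to-platform distance (same units as radii).
#' @param radial_max largest radial offset reached in the region.
#' @param radial_min smallest radial offset (0 for a region containing the
#'   point directly above the optics).
#' @return percent variability (>= 0), monotone in `radial_max`.
#' @export
focal_length_variability <- function(height, radial_max, radial_min = 0) {
  if (height <= 0) stopf("height must be > 0")
  lo <- sqrt(height^2 + radial_min^2)
  hi <- sqrt(height^2 + radial_max^2)
  (hi - lo) / lo * 100
}

#' Coefficient of variation of grid measurements
#'
#' Population SD divided by the mean; used to summarize optical power and
#' power-density uniformity across the platform.
#'
#' @param measurements numeric vector (>= 2 values).
#' @return unitless CV.
#' @export
uniformity_stats <- function(measurements) {
  if (length(measurements) < 2) stopf("need at least 2 measurements")
  m <- mean(measurements)
  if (m == 0) stopf("coefficient of variation undefined for zero mean")
  pop_sd(measurements) / m
}

#' Serialize a calibration map to JSON
#'
#' @param map a `calibration_map`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(map, path) {
  obj <- list(degree = map$degree,
              coef_vx = as.numeric(map$coef_vx),
              coef_vy = as.numeric(map$coef_vy),
              domain = map$domain,
              residual_mae_px = map$residual_mae_px,
              residual_mae_volt = map$residual_mae_volt,
              n_obs = map$n_obs, created = map$created)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration map written by [write_calibration]
#'
#' @param path JSON path.
#' @return a `calibration_map`.
#' @export
read_calibration <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(degree = o$degree, coef_vx = o$coef_vx, coef_vy = o$coef_vy,
                 domain = list(x = o$domain$x, y = o$domain$y),
                 residual_mae_px = o$residual_mae_px,
                 residual_mae_volt = o$residual_mae_volt,
                 n_obs = o$n_obs, created = o$created),
            class = "calibration_map")
}
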