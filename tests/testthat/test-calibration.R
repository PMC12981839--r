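test_that("rasters enumerate a regular inclusive grid", {
  r <- make_raster()
  expect_equal(nrow(r), 10000)
  r4 <- make_raster(2, 2, list(x = c(0, 1), y = c(0, 1)))
  expect_equal(sort(paste(r4$vx, r4$vy)),
               c("0 0", "0 1", "1 0", "1 1"))
  r6 <- make_raster(3, 2, list(x = c(0, 1), y = c(0, 1)))
  expect_equal(nrow(r6), 6)
  expect_equal(sort(unique(r6$vx)), c(0, 0.5, 1))
  expect_error(make_raster(1, 3), ">= 2")
  expect_error(make_raster(3, 3, list(x = c(2, 2), y = c(0, 1))),
               "degenerate")
})

test_that("spot detection returns sub-pixel centroids and honors tie rules", {
  f <- matrix(0, 50, 50)
  f[21, 11] <- 200                       # (x=10, y=20) 0-based
  expect_equal(detect_spot(f), c(x = 10, y = 20))
  # symmetric blob centered between pixels
  xs <- 0:49
  blob <- 200 * exp(-(outer((xs - 40.5)^2, (xs - 30.5)^2, "+")) / (2 * 4))
  expect_lt(max(abs(detect_spot(blob, floor = 1) - c(30.5, 40.5))), 0.1)
  # two equal maxima in separate components: brighter component wins
  g <- matrix(0, 20, 20)
  g[5, 5] <- 100; g[5, 6] <- 50          # component sum 150
  g[15, 15] <- 100                       # component sum 100
  expect_equal(unname(detect_spot(g)[2]), 4)  # y of the brighter blob
  # exact tie: smaller (y, x) lexicographic
  h <- matrix(0, 20, 20)
  h[3, 9] <- 100; h[17, 2] <- 100
  expect_equal(unname(detect_spot(h)), c(8, 2))
  expect_error(detect_spot(matrix(0, 5, 5)), "no spot")
})

test_that("linear optics fit exactly at degree 1; distorted rigs need higher degree", {
  lin <- optics_model(gain = c(0.008, 0.008))
  obs <- acquire_raster(make_raster(15, 15, list(x = c(0.4, 8.4),
                                                 y = c(0.4, 8.4))),
                        lin, seed = 1)
  m1 <- fit_map(obs, degree = 1)
  expect_lt(m1$residual_mae_px, 1e-8)
  ev <- evaluate_map(m1, obs, lin)
  expect_lt(ev$mae_px, 1e-8)
  expect_false(ev$remap_recommended)
})

test_that("a degree-2 distorted rig is recovered below the pixel scale at degree 3", {
  rig <- fixture_rig(seed = 21, nx = 40, ny = 40, noise_sd = 0)
  held <- acquire_raster(make_raster(23, 19, rig$bounds), rig$optics,
                         seed = 22)
  ev <- evaluate_map(rig$map, held, rig$optics)
  expect_lt(ev$mae_px, 0.5)
})

test_that("training residual MAE is non-increasing in polynomial degree", {
  rig <- fixture_rig(seed = 23, nx = 30, ny = 30, noise_sd = 0.3)
  res <- vapply(1:5, function(d)
    fit_map(rig$obs, degree = d)$residual_mae_px, numeric(1))
  expect_true(all(diff(res) <= 1e-9))
})

test_that("rank-deficient observations are refused with a named deficiency", {
  obs <- data.frame(vx = 1:20 / 10, vy = 1:20 / 10, px = 1:20, py = 1:20)
  expect_error(fit_map(obs, degree = 2), "rank")
  expect_error(fit_map(obs[1:3, ], degree = 3), "at least")
})

test_that("voltage lookup is continuous, domain-guarded, and inverts the optics", {
  rig <- fixture_rig(seed = 24, nx = 40, ny = 40, noise_sd = 0)
  d <- rig$map$domain
  corner <- predict_voltage(rig$map, c(d$x[1], d$y[1]))
  expect_true(all(is.finite(corner)))
  expect_error(predict_voltage(rig$map, c(d$x[2] + 50, d$y[1])), "domain")
  expect_silent(predict_voltage(rig$map, c(d$x[2] + 50, d$y[1]),
                                clamp = TRUE))
  # round trip: command the predicted voltages, land on the pixel
  targets <- cbind(seq(d$x[1] + 50, d$x[2] - 50, length.out = 7),
                   seq(d$y[1] + 50, d$y[2] - 50, length.out = 7))
  nf <- rig$optics; nf$noise_sd <- 0
  realized <- optics_forward(predict_voltage(rig$map, targets), nf)
  err <- sqrt(rowSums((realized - targets)^2))
  expect_lt(mean(err), max(rig$map$residual_mae_px, 0.2))
})

test_that("lookup agrees with a brute-force nearest-observation oracle within one cell", {
  rig <- fixture_rig(seed = 25, nx = 20, ny = 20, noise_sd = 0)
  cell <- c(diff(rig$bounds$x) / 19, diff(rig$bounds$y) / 19)
  d <- rig$map$domain
  with_seed(26, {
    q <- cbind(runif(40, d$x[1], d$x[2]), runif(40, d$y[1], d$y[2]))
    v <- predict_voltage(rig$map, q, clamp = TRUE)
    for (i in seq_len(nrow(q))) {
      nn <- which.min((rig$obs$px - q[i, 1])^2 + (rig$obs$py - q[i, 2])^2)
      expect_lt(abs(v[i, 1] - rig$obs$vx[nn]), cell[1] * 1.01)
      expect_lt(abs(v[i, 2] - rig$obs$vy[nn]), cell[2] * 1.01)
    }
  })
})

test_that("evaluation measures injected offsets exactly and is order-invariant", {
  rig <- fixture_rig(seed = 27, nx = 25, ny = 25, noise_sd = 0)
  held <- acquire_raster(make_raster(11, 11, rig$bounds), rig$optics,
                         seed = 28)
  base <- evaluate_map(rig$map, held, rig$optics)$mae_px
  # platform drift: the realized spot lands one pixel off everywhere
  # (stale map evaluated against shifted optics)
  drift1 <- rig$optics
  drift1$dist_coef_x[1, 1] <- drift1$dist_coef_x[1, 1] + 1
  ev <- evaluate_map(rig$map, held, drift1)
  expect_equal(ev$mae_px, 1, tolerance = 0.1)
  perm <- held[sample.int(nrow(held)), ]
  expect_equal(evaluate_map(rig$map, perm, drift1)$mae_px, ev$mae_px)
  # weekly-drift QC: a >2 mm rigid translation recommends a remap
  drift2 <- rig$optics
  drift2$dist_coef_x[1, 1] <- drift2$dist_coef_x[1, 1] + 5
  drift2$dist_coef_y[1, 1] <- drift2$dist_coef_y[1, 1] + 5   # ~3.2 mm
  expect_true(evaluate_map(rig$map, held, drift2)$remap_recommended)
  expect_error(evaluate_map(rig$map, held[0, ], rig$optics), "empty")
})

test_that("chessboard scale recovers mm/pixel and flags irregular grids", {
  mk_grid <- function(spacing, rows = 10, cols = 14) {
    g <- array(0, c(rows, cols, 2))
    for (r in 1:rows) for (cc in 1:cols) {
      g[r, cc, 1] <- cc * spacing
      g[r, cc, 2] <- r * spacing
    }
    g
  }
  res <- chessboard_scale(mk_grid(44.44444), square_size = 20)
  expect_equal(res$scale_mm_per_px, 0.45, tolerance = 1e-6)
  expect_false(res$irregular)
  res2 <- chessboard_scale(mk_grid(20), square_size = 20)
  expect_equal(res2$scale_mm_per_px, 1.0)
  # one corner perturbed half a pixel: spacing range stays sub-pixel
  g <- mk_grid(44.44444)
  g[5, 5, 1] <- g[5, 5, 1] + 0.5
  res3 <- chessboard_scale(g, 20)
  expect_lt(res3$spacing_range_px, 1)
  expect_gt(res3$spacing_range_px, 0)
  # grossly irregular grid (alternating spacing) warns through the QC flag
  gg <- mk_grid(40, rows = 4, cols = 4)
  gg[, , 1] <- gg[, , 1] + 25 * (col(gg[, , 1]) %% 2)
  expect_true(chessboard_scale(gg, 20)$irregular)
})

test_that("focal length variability follows the closed form and is monotone", {
  expect_equal(focal_length_variability(1, 0), 0)
  expect_equal(focal_length_variability(1, 0.25),
               (sqrt(1.0625) - 1) * 100, tolerance = 1e-10)
  expect_gt(focal_length_variability(1, 0.5),
            focal_length_variability(1, 0.25))
  expect_error(focal_length_variability(0, 1), "height")
})

test_that("uniformity CV is population SD over mean", {
  expect_equal(uniformity_stats(rep(3, 10)), 0)
  expect_equal(uniformity_stats(c(1, 1, 1, 3)), 0.8660254 / 1.5,
               tolerance = 1e-6)
  expect_error(uniformity_stats(c(-1, 1)), "zero mean")
  expect_error(uniformity_stats(3), "at least 2")
  # a 16-point draw at CV 0.035 is estimated within 2 SEM
  vals <- with_seed(29, rnorm(16, 100, 3.5))
  est <- uniformity_stats(vals)
  sem <- 0.035 / sqrt(2 * 15)       # asymptotic SEM of a CV estimate
  expect_lt(abs(est - 0.035), 2 * sem + 0.005)
})

test_that("calibration maps serialize to JSON and back", {
  rig <- fixture_rig(seed = 30, nx = 15, ny = 15)
  f <- withr::local_tempfile(fileext = ".json")
  write_calibration(rig$map, f)
  m2 <- read_calibration(f)
  expect_equal(m2$coef_vx, as.numeric(rig$map$coef_vx))
  expect_equal(m2$domain, rig$map$domain)
  p <- c(mean(rig$map$domain$x), mean(rig$map$domain$y))
  expect_equal(predict_voltage(m2, p), predict_voltage(rig$map, p))
})
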