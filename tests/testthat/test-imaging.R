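test_that("flat-field correction inverts the rendering model", {
  set.seed(5)
  nr <- 60; nc <- 80
  signal <- matrix(runif(nr * nc, 0, 200), nr, nc)
  illum <- mtcontract:::build_illumination(nr, nc, c(0.2, 0.1))
  raw <- 100 + illum * signal
  st <- frame_stack(list(raw), pixel_size = 3.25, camera_offset = 100,
                    illumination = illum)
  corr <- flatfield_correct(st)
  expect_equal(corr$frames[[1]], signal, tolerance = 1e-12)

  # a frame equal to the offset corrects to zero
  st0 <- frame_stack(list(matrix(100, nr, nc)), pixel_size = 3.25,
                     camera_offset = 100, illumination = illum)
  expect_true(all(flatfield_correct(st0)$frames[[1]] == 0))

  # noisy movie: per-pixel residual mean ~ 0 across 100 frames
  frames <- lapply(1:100, function(k)
    100 + illum * signal + matrix(rnorm(nr * nc, sd = 5), nr, nc))
  stn <- frame_stack(frames, pixel_size = 3.25, camera_offset = 100,
                     illumination = illum)
  res <- Reduce(`+`, flatfield_correct(stn)$frames) / 100 - signal
  expect_lt(abs(mean(res)), 5 / sqrt(100 * nr * nc) * 4)

  bad <- frame_stack(list(raw), pixel_size = 3.25, camera_offset = 100,
                     illumination = illum - 1)
  expect_error(flatfield_correct(bad), class = "mtc_calibration_error")
})

test_that("segmentation isolates the network band", {
  f <- band_frame(80, 120, 25:55, fg = 500, bg = 100)
  m <- segment_network(f)
  expect_true(all(m$mask[25:55, ]))
  expect_true(!any(m$mask[c(1:24, 56:80), ]))
  expect_equal(unname(m$top), rep(25, 120))
  expect_equal(unname(m$bottom), rep(55, 120))

  # monomer background stays outside the mask
  f2 <- band_frame(80, 120, 25:55, fg = 500, bg = 100) +
    matrix(rnorm(80 * 120, sd = 10), 80, 120)
  m2 <- segment_network(f2)
  expect_gt(mean(m2$mask[25:55, ]), 0.95)
  expect_lt(mean(m2$mask[c(1:20, 60:80), ]), 0.05)

  # pure noise carries no network
  set.seed(9)
  noise <- matrix(rnorm(80 * 120, mean = 100, sd = 10), 80, 120)
  expect_error(segment_network(noise), class = "mtc_no_network_error")
})

test_that("rotation detection follows the slope rule and conserves intensity", {
  nr <- 150; nc <- 600
  m_true <- tan(0.5 * pi / 180)
  f <- matrix(50, nr, nc)
  for (j in 1:nc) {
    r0 <- 40 + m_true * j
    f[round(r0):round(r0 + 52.37), j] <- 300
  }
  st <- frame_stack(list(f), pixel_size = 3.25)
  msk <- segment_network(f)
  slope <- (msk$slope_top + msk$slope_bottom) / 2
  expect_lt(abs(slope - m_true) / m_true, 0.05)

  st2 <- correct_rotation(st, msk)
  expect_gt(abs(attr(st2, "rotation_applied")), 0)
  # conservative reassignment preserves total intensity
  expect_lt(abs(sum(st2$frames[[1]]) - sum(f)) / sum(f), 1e-6)
  # residual slope below the detection threshold
  m2 <- segment_network(st2$frames[[1]])
  expect_lt(abs((m2$slope_top + m2$slope_bottom) / 2), 1 / nc)

  # below threshold: frames returned bit-identical
  flat <- band_frame(80, 200, 30:50, 300, 50)
  stf <- frame_stack(list(flat), pixel_size = 3.25)
  out <- correct_rotation(stf, segment_network(flat))
  expect_identical(out$frames[[1]], flat)
  expect_identical(attr(out, "rotation_applied"), 0)
})

test_that("width measurement matches the constructed band", {
  px <- 3.25
  rows <- 20:(20 + round(700 / px) - 1)      # ~700 um band
  f <- band_frame(300, 100, rows, 400, 60)
  m <- segment_network(f)
  expect_equal(measure_width(m, px), length(rows) * px, tolerance = 1e-12)
  expect_lt(abs(measure_width(m, px) - 700), px)

  # a full-frame mask spans the whole raster
  full <- structure(list(mask = matrix(TRUE, 50, 40),
                         top = rep(1, 40), bottom = rep(50, 40),
                         slope_top = 0, slope_bottom = 0, threshold = 0),
                    class = "network_mask")
  expect_equal(measure_width(full, 2), 100)
})

test_that("extracted widths track the generating simulation", {
  p <- model_params_from_ratios(0.82, 6.1e-6)
  sim <- simulate_contraction(p, channel_geometry(700), 0.32, t_end = 5,
                              n_cells = 128)
  opt <- optics_model(seed = 3)
  mov <- generate_movie(sim, opt, n_cols = 64)
  corr <- flatfield_correct(mov)
  masks <- lapply(corr$frames, segment_network)
  w <- measure_width(masks, mov$pixel_size)
  eps <- epsilon_curve(w, max(w))
  gt <- attr(mov, "ground_truth")
  expect_lt(max(abs(eps - gt$epsilon)), 0.02)
})

test_that("density profiles are normalized, cropped at edge peaks, and scale-free", {
  # uniform band: flat profile with unit integral across the full band
  f <- band_frame(90, 60, 30:60, 400, 60)
  st <- frame_stack(list(f), pixel_size = 3.25)
  m <- segment_network(f)
  pr <- density_profile(st, m, 1)
  expect_equal(sum(pr$intensity) * mean(diff(pr$positions)), 1,
               tolerance = 1e-6)
  expect_lt(stats::sd(pr$intensity) / mean(pr$intensity), 1e-6)
  expect_equal(length(pr$positions), 31)

  # doubling intensities leaves the normalized profile unchanged
  st2 <- frame_stack(list(2 * f), pixel_size = 3.25)
  pr2 <- density_profile(st2, segment_network(2 * f), 1)
  expect_equal(pr2$intensity, pr$intensity, tolerance = 1e-12)

  # drag-dominated mid-contraction: maxima at both edges exceed the interior
  p <- model_params_from_ratios(0.82, 6.1e-6)
  sim <- simulate_contraction(p, channel_geometry(900), 0.32, t_end = 3,
                              n_cells = 128)
  mov <- generate_movie(sim, optics_model(poisson_scale = 0, read_noise_sd = 0),
                        n_cols = 64)
  corr <- flatfield_correct(mov)
  k <- length(corr$frames)
  msk <- segment_network(corr$frames[[k]])
  prk <- density_profile(corr, msk, k)
  n <- length(prk$intensity)
  inner <- prk$intensity[(n %/% 3):(2 * n %/% 3)]
  expect_gt(prk$intensity[1], max(inner))
  expect_gt(prk$intensity[n], max(inner))
})

test_that("noiseless render-and-extract returns the simulated profile", {
  p <- model_params_from_ratios(0.82, 6.1e-6)
  sim <- simulate_contraction(p, channel_geometry(900), 0.32, t_end = 3,
                              n_cells = 128)
  mov <- generate_movie(sim, optics_model(poisson_scale = 0, read_noise_sd = 0,
                                          illumination_falloff = c(0, 0)),
                        n_cols = 48)
  corr <- flatfield_correct(mov)
  k <- length(corr$frames)
  prk <- density_profile(corr, segment_network(corr$frames[[k]]), k)
  rho <- density_at(sim, k, prk$positions)
  rho <- rho / (sum(rho) * mean(diff(prk$positions)))
  l1 <- sum(abs(prk$intensity - rho)) / sum(abs(rho))
  expect_lt(l1, 0.01)
})

test_that("PIV recovers constructed displacements", {
  pair <- generate_piv_pair(c(2, 0), dim = c(64, 96), seed = 21)
  f <- piv(pair$frame_a, pair$frame_b)
  expect_true(all(f$valid))
  expect_lt(abs(mean(f$u) - 2), 0.1)
  expect_lt(abs(mean(f$v) - 0), 0.1)

  # identical frames: zero displacement everywhere
  f0 <- piv(pair$frame_a, pair$frame_a)
  expect_lt(max(abs(c(f0$u, f0$v))), 1e-9)

  # a flat window is invalid
  a <- matrix(1, 32, 32); a[20:30, 20:30] <- runif(121)
  b <- a
  ff <- piv(a, b, window = 16, step = 16)
  expect_false(all(ff$valid))

  # linear shear: recovered slope within 5%
  shear <- function(x, y) list(u = 0.04 * y, v = matrix(0, nrow(x), ncol(x)))
  ps <- generate_piv_pair(shear, dim = c(96, 96), seed = 22)
  fs <- piv(ps$frame_a, ps$frame_b)
  sl <- coef(lm(fs$u[fs$valid] ~ fs$y[fs$valid]))[2]
  expect_lt(abs(sl - 0.04) / 0.04, 0.05)
})

test_that("PIV masking drops vectors near the network edge", {
  pair <- generate_piv_pair(c(1, 0), dim = c(96, 96), seed = 23)
  f <- piv(pair$frame_a, pair$frame_b)

  full <- matrix(TRUE, 96, 96)
  expect_identical(mask_piv(f, full, margin = 8)$valid, f$valid)

  empty <- matrix(FALSE, 96, 96)
  expect_true(!any(mask_piv(f, empty, margin = 8)$valid))

  band <- matrix(FALSE, 96, 96); band[25:72, ] <- TRUE
  fm <- mask_piv(f, band, margin = 8)
  centre_rows <- round(f$y + 0.5)
  keep_expected <- f$valid & centre_rows >= 25 + 8 & centre_rows <= 72 - 8
  expect_identical(fm$valid, keep_expected)
})
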