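#' Fluorescence frame stack
#'
#' A time-ordered stack of 2-D intensity rasters with acquisition metadata.
#' Rows run across the channel width (row 1 at top), columns along the
#' channel length.  Pixel centres sit at half-integer raster coordinates.
#'
#' @param frames list of numeric matrices (all the same shape) or a 3-D
#'   array with time as the third dimension.
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds between frames.
#' @param camera_offset camera offset, a.u.
#' @param illumination optional per-pixel gain map (same shape as a frame).
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, pixel_size, frame_interval = 20,
                        camera_offset = 0, illumination = NULL) {
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[3]), function(k) frames[, , k])
  if (!length(frames) || !all(vapply(frames, is.matrix, logical(1))))
    stop_mtc("mtc_domain_error", "frames must be matrices")
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
    stop_mtc("mtc_domain_error", "all frames must have the same shape")
  if (!(pixel_size > 0))
    stop_mtc("mtc_domain_error", "pixel_size must be positive")
  if (!is.null(illumination) && !identical(dim(illumination), d))
    stop_mtc("mtc_domain_error", "illumination map must match the frame shape")
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 camera_offset = camera_offset, illumination = illumination),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Frame stack: %d frames of %d x %d px, %.3g um/px, %g s interval\n",
              length(x$frames), d[1], d[2], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack a [frame_stack()].
#' @return Integer count.
#' @export
n_frames <- function(stack) length(stack$frames)

#' Flat-field and offset correction
#'
#' Removes the camera offset and divides out the inhomogeneous illumination:
#' `corrected = (raw - offset) / illumination`, clipped at zero.  The
#' offset and illumination map are taken from the stack metadata; a missing
#' illumination map is treated as uniform.
#'
#' @param stack a [frame_stack()].
#' @return The corrected `frame_stack` (offset 0, illumination uniform).
#' @export
flatfield_correct <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  illum <- stack$illumination
  if (!is.null(illum) && any(illum <= 0))
    stop_mtc("mtc_calibration_error",
             "illumination map must be positive everywhere")
  off <- stack$camera_offset
  frames <- lapply(stack$frames, function(f) {
    g <- f - off
    if (!is.null(illum)) g <- g / illum
    pmax(g, 0)
  })
  out <- stack
  out$frames <- frames
  out$camera_offset <- 0
  out$illumination <- NULL
  out
}

#' Segment the microtubule network in one frame
#'
#' Thresholds a corrected frame (Otsu's method by default, or an absolute
#' threshold for reproducibility), keeps the largest connected component,
#' and fits straight lines to the per-column top and bottom boundary rows
#' of the network band.  A frame whose putative foreground is not
#' meaningfully brighter than its background (mean foreground below
#' `min_contrast` times the mean background) is rejected as containing no
#' network.
#'
#' @param frame numeric matrix (offset/illumination corrected).
#' @param method `"otsu"` or `"absolute"`.
#' @param threshold absolute threshold, required when `method = "absolute"`.
#' @param min_contrast foreground/background mean-intensity ratio below
#'   which the frame is declared empty (default 1.5).
#' @return An object of class `network_mask`: logical `mask`, per-column
#'   `top` and `bottom` boundary rows (NA in empty columns), fitted
#'   `slope_top`, `slope_bottom`, and the threshold used.
#' @export
segment_network <- function(frame, method = c("otsu", "absolute"),
                            threshold = NULL, min_contrast = 1.5) {
  method <- match.arg(method)
  if (!is.matrix(frame)) stop_mtc("mtc_domain_error", "frame must be a matrix")
  rng <- range(frame)
  if (method == "otsu") {
    if (rng[2] <= rng[1])
      stop_mtc("mtc_no_network_error", "frame is constant: no network found")
    f01 <- (frame - rng[1]) / (rng[2] - rng[1])
    threshold <- rng[1] + EBImage::otsu(f01, range = c(0, 1)) * (rng[2] - rng[1])
  } else if (is.null(threshold)) {
    stop_mtc("mtc_domain_error", "absolute method requires a threshold")
  }
  mask <- frame > threshold
  if (!any(mask))
    stop_mtc("mtc_no_network_error", "threshold leaves an empty mask")
  mu_fg <- mean(frame[mask]); mu_bg <- mean(frame[!mask])
  if (!any(!mask) || mu_fg < min_contrast * mu_bg)
    stop_mtc("mtc_no_network_error",
             sprintf(paste("foreground/background contrast %.3g below %g:",
                           "no network found"),
                     mu_fg / max(mu_bg, 1e-300), min_contrast))
  lab <- EBImage::bwlabel(mask)
  if (max(lab) > 1) {
    counts <- tabulate(lab[lab > 0])
    mask <- lab == which.max(counts)
  }
  nc <- ncol(mask)
  top <- bottom <- rep(NA_real_, nc)
  for (j in seq_len(nc)) {
    rows <- which(mask[, j])
    if (length(rows)) { top[j] <- rows[1]; bottom[j] <- rows[length(rows)] }
  }
  ok <- !is.na(top)
  cols <- seq_len(nc)
  slope_top <- if (sum(ok) >= 2)
    unname(coef(lm(top[ok] ~ cols[ok]))[2]) else 0
  slope_bottom <- if (sum(ok) >= 2)
    unname(coef(lm(bottom[ok] ~ cols[ok]))[2]) else 0
  structure(list(mask = mask, top = top, bottom = bottom,
                 slope_top = slope_top, slope_bottom = slope_bottom,
                 threshold = threshold),
            class = "network_mask")
}

#' @export
print.network_mask <- function(x, ...) {
  cat(sprintf("Network mask: %d x %d px, %d foreground px, edge slopes %.4g / %.4g\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$slope_top, x$slope_bottom))
  invisible(x)
}

# conservative rotation: each source pixel is split into supersample^2
# subpixels whose intensity is reassigned to the target pixel containing the
# rotated subpixel centre.  Total intensity is preserved exactly
# (out-of-frame subpixels are clamped to the nearest edge pixel).
rotate_frame_conservative <- function(frame, theta, supersample = 4L) {
  nr <- nrow(frame); nc <- ncol(frame)
  k <- supersample
  sub <- (seq_len(k) - 0.5) / k
  rr <- rep(seq_len(nr) - 1, times = nc)         # per source pixel (col-major)
  cc <- rep(seq_len(nc) - 1, each = nr)
  w <- as.vector(frame) / (k * k)
  cr <- nr / 2; ccen <- nc / 2
  out <- numeric(nr * nc)
  ct <- cos(theta); st <- sin(theta)
  for (a in sub) for (b in sub) {
    r0 <- rr + a - cr; c0 <- cc + b - ccen
    rn <- cr + ct * r0 - st * c0
    cn <- ccen + st * r0 + ct * c0
    ri <- pmin(pmax(ceiling(rn), 1L), nr)
    ci <- pmin(pmax(ceiling(cn), 1L), nc)
    out <- out + bin_add(as.integer(ri + (ci - 1L) * nr), w, nr * nc)
  }
  matrix(out, nr, nc)
}

#' Detect and correct channel rotation
#'
#' Averages the fitted top and bottom edge slopes of the network; if the
#' mean absolute slope exceeds `1 / n_length_pixels` (one pixel of drift
#' across the image length), every frame is replaced by a rotated,
#' interpolated frame in which pixel intensities are reassigned by their
#' area fraction (a conservative scheme: the summed intensity of each frame
#' is preserved).  Below the threshold the input frames are returned
#' unchanged, bit for bit.
#'
#' @param stack a [frame_stack()].
#' @param mask a `network_mask` (or list of them, one per frame) supplying
#'   the edge slopes.
#' @param supersample subpixel subdivision factor of the conservative
#'   reassignment (default 4).
#' @return The (possibly rotated) `frame_stack`, with attribute
#'   `rotation_applied` (radians, 0 when untouched).
#' @export
correct_rotation <- function(stack, mask, supersample = 4L) {
  stopifnot(inherits(stack, "frame_stack"))
  masks <- if (inherits(mask, "network_mask")) list(mask) else mask
  slopes <- vapply(masks, function(m) (m$slope_top + m$slope_bottom) / 2,
                   numeric(1))
  mean_slope <- mean(slopes)
  nc <- ncol(stack$frames[[1]])
  if (abs(mean_slope) <= 1 / nc) {
    attr(stack, "rotation_applied") <- 0
    return(stack)
  }
  theta <- atan(mean_slope)
  if (abs(theta) > 10 * pi / 180)
    warn_mtc("mtc_geometry_warning",
             sprintf("rotation of %.1f degrees detected: check the channel geometry",
                     theta * 180 / pi))
  out <- stack
  out$frames <- lapply(stack$frames, rotate_frame_conservative,
                       theta = theta, supersample = supersample)
  if (!is.null(out$illumination))
    out$illumination <- rotate_frame_conservative(out$illumination, theta,
                                                  supersample)
  attr(out, "rotation_applied") <- theta
  out
}

#' Measure the network width
#'
#' Per frame, the width is the mean over length-columns of the vertical
#' extent of the network mask (bottom minus top boundary row, inclusive),
#' converted to micrometres.  Columns without network pixels are excluded;
#' if more than half the columns are empty the measurement is flagged as
#' unreliable.
#'
#' @param mask a `network_mask` or list of them (one per frame).
#' @param pixel_size micrometres per pixel.
#' @return Widths in micrometres, one per frame.
#' @export
measure_width <- function(mask, pixel_size) {
  masks <- if (inherits(mask, "network_mask")) list(mask) else mask
  vapply(masks, function(m) {
    ok <- !is.na(m$top)
    if (!any(ok))
      stop_mtc("mtc_no_network_error", "empty mask: cannot measure a width")
    if (mean(!ok) > 0.5)
      warn_mtc("mtc_width_warning",
               "more than half the columns have no network: width unreliable")
    mean(m$bottom[ok] - m$top[ok] + 1) * pixel_size
  }, numeric(1))
}

#' Cross-width density profile
#'
#' Construct a normalized density profile (the standard container used by
#' the profile-fitting routines).
#'
#' @param positions strictly increasing positions across the width,
#'   micrometres (conventionally centred on the network midpoint).
#' @param intensity non-negative intensities.
#' @param time acquisition time, minutes.
#' @param normalize divide by the integral so that `sum(intensity) * dx = 1`
#'   (default TRUE).
#' @return An object of class `density_profile`.
#' @export
new_density_profile <- function(positions, intensity, time = NA_real_,
                                normalize = TRUE) {
  if (length(positions) != length(intensity) || length(positions) < 2)
    stop_mtc("mtc_domain_error", "positions and intensity must match (>= 2)")
  if (any(diff(positions) <= 0))
    stop_mtc("mtc_domain_error", "positions must be strictly increasing")
  if (any(intensity < 0))
    stop_mtc("mtc_domain_error", "intensity must be non-negative")
  if (normalize) {
    tot <- sum(intensity) * mean(diff(positions))
    if (!(tot > 0))
      stop_mtc("mtc_domain_error", "cannot normalize an all-zero profile")
    intensity <- intensity / tot
  }
  structure(list(positions = positions, intensity = intensity, time = time),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("Density profile: %d positions over %.4g um, t = %g min\n",
              length(x$positions), diff(range(x$positions)), x$time))
  invisible(x)
}

#' Extract a length-averaged density profile from a frame
#'
#' Averages a corrected (and rotation-corrected) frame along the channel
#' length, subtracts the monomer background (the median intensity of
#' out-of-network pixels), identifies the density maxima nearest the top
#' and bottom network boundaries (edge peaks), retains the rows between
#' them, and normalizes the result to unit integral.  Positions are
#' centred on the midpoint between the two edge peaks.
#'
#' @param stack a corrected [frame_stack()].
#' @param mask the `network_mask` for that frame (or list, indexed by `t`).
#' @param t frame index.
#' @param min_peak_fraction local maxima below this fraction of the profile
#'   maximum are not accepted as edge peaks (default 0.05).
#' @return A [new_density_profile()] object.
#' @export
density_profile <- function(stack, mask, t = 1, min_peak_fraction = 0.05) {
  stopifnot(inherits(stack, "frame_stack"))
  m <- if (inherits(mask, "network_mask")) mask else mask[[t]]
  frame <- stack$frames[[t]]
  prof <- rowMeans(frame)
  outside <- !m$mask
  bg <- if (any(outside)) stats::median(frame[outside]) else 0
  prof <- pmax(prof - bg, 0)

  band <- range(which(rowSums(m$mask) > 0))
  lo <- band[1]; hi <- band[2]
  if (hi - lo < 2)
    stop_mtc("mtc_profile_error", "network band too narrow for a profile")
  idx <- lo:hi
  p <- prof[idx]
  n <- length(p)
  # local maxima, one-sided at the band endpoints
  is_max <- vapply(seq_len(n), function(i) {
    left <- if (i > 1) p[i] >= p[i - 1] else TRUE
    right <- if (i < n) p[i] >= p[i + 1] else TRUE
    left && right
  }, logical(1))
  is_max <- is_max & (p >= min_peak_fraction * max(p))
  cand <- which(is_max)
  if (length(cand) < 1)
    stop_mtc("mtc_profile_error", "no edge peaks found in the density profile")
  peak_top <- cand[1]
  peak_bottom <- cand[length(cand)]
  if (peak_bottom - peak_top < 1)
    stop_mtc("mtc_profile_error",
             "fewer than two edge peaks: cannot delimit the profile")
  keep <- idx[peak_top:peak_bottom]
  centre <- mean(range(keep))
  new_density_profile(positions = (keep - centre) * stack$pixel_size,
                      intensity = prof[keep],
                      time = (t - 1) * stack$frame_interval / 60)
}

#' Single-pass particle image velocimetry
#'
#' Splits the frame pair into square interrogation windows (`window` pixels,
#' spaced `step` pixels) and cross-correlates each window pair by direct
#' multiplication in the frequency domain (zero-padded, so the correlation
#' is linear rather than circular, and normalized by the overlap area of
#' each lag to remove the bias toward zero displacement).  The correlation
#' peak over lags up to half the window is the integer displacement,
#' refined on each axis with a three-point Gaussian sub-pixel estimator.
#' Windows with zero intensity variance are reported as invalid rather
#' than interpolated.
#'
#' @param frame_a,frame_b numeric matrices of equal shape.
#' @param window interrogation window size, pixels (>= 8).
#' @param step window spacing, pixels.
#' @return An object of class `piv_field`: window-centre coordinates `x`
#'   (column) and `y` (row), displacements `u` (columns) and `v` (rows) in
#'   px per frame pair, correlation peak height `peak`, and a `valid` mask.
#' @export
piv <- function(frame_a, frame_b, window = 16, step = 8) {
  if (!identical(dim(frame_a), dim(frame_b)))
    stop_mtc("mtc_domain_error", "frames must have the same shape")
  if (window < 8) stop_mtc("mtc_domain_error", "window must be at least 8 px")
  nr <- nrow(frame_a); nc <- ncol(frame_a)
  r0s <- seq(1, nr - window + 1, by = step)
  c0s <- seq(1, nc - window + 1, by = step)
  grid <- expand.grid(r0 = r0s, c0 = c0s)
  n <- nrow(grid)
  u <- v <- peak <- rep(NA_real_, n)
  valid <- rep(FALSE, n)

  subpixel <- function(cm, c0, cp) {
    if (is.na(cm) || is.na(cp) || cm <= 0 || c0 <= 0 || cp <= 0) return(0)
    den <- 2 * log(cm) - 4 * log(c0) + 2 * log(cp)
    if (den == 0) return(0)
    d <- (log(cm) - log(cp)) / den
    if (!is.finite(d) || abs(d) > 1) 0 else d
  }

  w <- window
  np <- 2L * w
  # lag s along each axis lives at padded-FFT index (s mod 2w) + 1
  lags <- c(0:(w - 1), -w:-1)
  overlap <- outer(w - abs(lags), w - abs(lags))
  search <- abs(lags) <= w / 2            # displacement search range
  idx_of <- function(s) (s %% np) + 1L

  for (i in seq_len(n)) {
    r0 <- grid$r0[i]; c0 <- grid$c0[i]
    A <- frame_a[r0:(r0 + w - 1), c0:(c0 + w - 1)]
    B <- frame_b[r0:(r0 + w - 1), c0:(c0 + w - 1)]
    sa <- stats::sd(A); sb <- stats::sd(B)
    if (sa == 0 || sb == 0) next
    PA <- PB <- matrix(0, np, np)
    PA[1:w, 1:w] <- A - mean(A)
    PB[1:w, 1:w] <- B - mean(B)
    raw <- Re(fft(Conj(fft(PA)) * fft(PB), inverse = TRUE)) /
      (length(PA) * sa * sb)
    # integer peak from the raw linear correlation (robust to noise);
    # overlap normalization only enters the sub-pixel refinement, where the
    # triangular overlap factor would otherwise bias toward zero lag
    ncc <- raw / overlap
    cc <- raw
    cc[!search, ] <- -Inf
    cc[, !search] <- -Inf
    pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    dr <- lags[pk[1]]; dc <- lags[pk[2]]
    neigh <- function(d1, d2) ncc[idx_of(d1), idx_of(d2)]
    dv_sub <- subpixel(neigh(dr - 1, dc), neigh(dr, dc), neigh(dr + 1, dc))
    du_sub <- subpixel(neigh(dr, dc - 1), neigh(dr, dc), neigh(dr, dc + 1))
    v[i] <- dr + dv_sub
    u[i] <- dc + du_sub
    peak[i] <- neigh(dr, dc)
    valid[i] <- TRUE
  }

  structure(list(x = grid$c0 + window / 2 - 0.5,
                 y = grid$r0 + window / 2 - 0.5,
                 u = u, v = v, peak = peak, valid = valid,
                 window = window, step = step, dim = c(nr, nc)),
            class = "piv_field")
}

#' @export
print.piv_field <- function(x, ...) {
  cat(sprintf("PIV field: %d vectors (%d valid), window %d px, step %d px\n",
              length(x$u), sum(x$valid), x$window, x$step))
  invisible(x)
}

#' Mask a PIV field to the network interior
#'
#' Invalidates velocity vectors whose window centre lies outside the
#' network or within `margin` pixels of its edges (the retained vectors are
#' those strictly more than `margin` pixels inside, computed by a box
#' erosion of the mask).
#'
#' @param field a [piv()] result.
#' @param mask a `network_mask` aligned with the frames.
#' @param margin exclusion margin, pixels (default 8).
#' @return The `piv_field` with its `valid` mask updated.
#' @export
mask_piv <- function(field, mask, margin = 8) {
  stopifnot(inherits(field, "piv_field"))
  m <- if (inherits(mask, "network_mask")) mask$mask else mask
  if (margin > 0) {
    brush <- EBImage::makeBrush(2 * margin + 1, shape = "box")
    m <- EBImage::erode(m * 1, brush) > 0.5
  }
  ri <- pmin(pmax(round(field$y + 0.5), 1), nrow(m))
  ci <- pmin(pmax(round(field$x + 0.5), 1), ncol(m))
  inside <- m[cbind(ri, ci)]
  field$valid <- field$valid & inside
  field
}
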