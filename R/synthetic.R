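#' Synthetic-microscopy optics model
#'
#' Parameters of the rendering pipeline that turns a simulated density
#' field into fluorescence frames:
#' `intensity = offset + illumination * (gain * rho + monomer) + noise`.
#' The illumination is a separable centred vignette
#' `(1 - f_y * yhat^2)(1 - f_x * xhat^2)`; the noise is Gaussian with
#' variance `poisson_scale * signal + read_noise_sd^2`, a Gaussian
#' approximation to shot noise plus read noise appropriate for EMCCD-like
#' cameras at these intensity scales.  Identical seeds give bit-identical
#' renders.
#'
#' @param camera_offset camera offset, a.u.
#' @param network_gain fluorescence per density unit, a.u.
#' @param monomer_level uniform monomeric-tubulin background, a.u.
#' @param illumination_falloff length-2 vector of vignette falloffs (width,
#'   length axes), each in `[0, 1)`.
#' @param poisson_scale shot-noise variance per a.u. of signal.
#' @param read_noise_sd read-noise standard deviation, a.u.
#' @param rotation_angle channel-to-camera rotation, degrees.
#' @param speckle_contrast relative contrast of the material-attached
#'   speckle texture (0 disables it); the texture advects with the network
#'   and makes the movies trackable by PIV.
#' @param speckle_scale_um correlation length of the speckle, micrometres.
#' @param seed integer RNG seed.
#' @return An object of class `optics_model`.
#' @export
optics_model <- function(camera_offset = 100, network_gain = 500,
                         monomer_level = 75,
                         illumination_falloff = c(0.15, 0.15),
                         poisson_scale = 1, read_noise_sd = 2,
                         rotation_angle = 0, speckle_contrast = 0,
                         speckle_scale_um = 12, seed = 1L) {
  if (network_gain <= 0 || monomer_level < 0)
    stop_mtc("mtc_domain_error", "gains must be positive, monomer_level >= 0")
  if (poisson_scale < 0 || read_noise_sd < 0)
    stop_mtc("mtc_domain_error", "noise variances must be non-negative")
  if (any(illumination_falloff < 0) || any(illumination_falloff >= 1))
    stop_mtc("mtc_domain_error", "illumination_falloff must be in [0, 1)")
  structure(list(camera_offset = camera_offset, network_gain = network_gain,
                 monomer_level = monomer_level,
                 illumination_falloff = illumination_falloff,
                 poisson_scale = poisson_scale, read_noise_sd = read_noise_sd,
                 rotation_angle = rotation_angle,
                 speckle_contrast = speckle_contrast,
                 speckle_scale_um = speckle_scale_um,
                 seed = as.integer(seed)),
            class = "optics_model")
}

#' @export
print.optics_model <- function(x, ...) {
  cat(sprintf("Optics model: offset %g, gain %g, monomer %g, noise var %g*S + %g, rot %g deg, seed %d\n",
              x$camera_offset, x$network_gain, x$monomer_level,
              x$poisson_scale, x$read_noise_sd^2, x$rotation_angle, x$seed))
  invisible(x)
}

# separable vignette gain map
build_illumination <- function(nr, nc, falloff) {
  yh <- (2 * (seq_len(nr) - (nr + 1) / 2) / nr)
  xh <- (2 * (seq_len(nc) - (nc + 1) / 2) / nc)
  outer(1 - falloff[1] * yh^2, 1 - falloff[2] * xh^2)
}

#' Generate a noisy fraction-contracted time series
#'
#' Evaluates the exponential-relaxation curve
#' `epsilon(t) = max(0, eps_inf * (1 - exp(-(t - Tc)/tau)))` and adds
#' i.i.d. Gaussian noise.  Seeded and deterministic.
#'
#' @param epsilon_inf,tau,Tc curve parameters (final fraction, minutes,
#'   minutes).
#' @param times sample times, minutes.
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @param seed integer seed.
#' @return List with `times`, `epsilon`, and the generating `truth`.
#' @export
generate_epsilon_data <- function(epsilon_inf, tau, Tc, times,
                                  noise_sd = 0, seed = 1L) {
  if (noise_sd < 0) stop_mtc("mtc_domain_error", "noise_sd must be >= 0")
  clean <- pmax(0, epsilon_inf * (1 - exp(-(times - Tc) / tau)))
  eps <- if (noise_sd > 0)
    with_seed(seed, clean + rnorm(length(times), sd = noise_sd)) else clean
  list(times = times, epsilon = eps,
       truth = list(epsilon_inf = epsilon_inf, tau = tau, Tc = Tc,
                    noise_sd = noise_sd, seed = seed))
}

#' Render a simulation into a synthetic fluorescence movie
#'
#' For each recorded snapshot, the simulated density field is painted into
#' a band across the frame (rows map to positions across the channel
#' width), the uniform monomer background is added everywhere, an optional
#' material-attached speckle texture modulates the network signal, the
#' channel content is optionally rotated (conservative interpolation),
#' the vignette and camera offset are applied, and seeded Gaussian
#' shot/read noise is added.  The generating simulation, band extents and
#' fraction contracted are attached as ground truth.
#'
#' @param sim a [simulate_contraction()] result.
#' @param optics an [optics_model()].
#' @param n_cols frame width (along the channel length), pixels.
#' @param n_rows frame height (across the channel), pixels; defaults to
#'   1.25 times the initial network width.
#' @param pixel_size micrometres per pixel (default 3.25, a 2x-objective
#'   scale).
#' @param frame_indices which snapshots to render (default all).
#' @return A [frame_stack()] carrying the optics metadata (so that
#'   [flatfield_correct()] inverts the rendering exactly) and a
#'   `ground_truth` attribute.
#' @export
generate_movie <- function(sim, optics, n_cols = 96, n_rows = NULL,
                           pixel_size = 3.25, frame_indices = NULL) {
  stopifnot(inherits(sim, "simulation_result"), inherits(optics, "optics_model"))
  W0 <- sim$geometry$W0
  if (is.null(n_rows)) n_rows <- ceiling(W0 * 1.25 / pixel_size)
  if (n_rows * pixel_size < W0)
    stop_mtc("mtc_geometry_error",
             "frame height is smaller than the initial network width")
  if (is.null(frame_indices)) frame_indices <- seq_along(sim$times)
  y <- (seq_len(n_rows) - (n_rows + 1) / 2) * pixel_size  # row centres, um
  illum <- build_illumination(n_rows, n_cols, optics$illumination_falloff)
  theta <- optics$rotation_angle * pi / 180

  with_seed(optics$seed, {
    speckle <- NULL
    if (optics$speckle_contrast > 0) {
      n_mu <- max(8, ceiling(W0 / optics$speckle_scale_um))
      n_xg <- max(8, ceiling(n_cols * pixel_size / optics$speckle_scale_um))
      speckle <- matrix(rnorm(n_mu * n_xg), n_mu, n_xg)
    }
    frames <- lapply(frame_indices, function(k) {
      st <- sim$states[[k]]
      rho <- density_at(sim, k, y)
      band <- outer(rho, rep(1, n_cols)) * optics$network_gain
      if (!is.null(speckle)) {
        # material (mass-fraction) coordinate of each pixel row
        Mcum <- c(0, cumsum(st$cell_masses))
        Mtot <- Mcum[length(Mcum)]
        mu <- rep(NA_real_, n_rows)
        inside <- rho > 0
        ci <- findInterval(y[inside], st$node_positions, rightmost.closed = TRUE)
        ci <- pmin(pmax(ci, 1), length(st$cell_densities))
        mu[inside] <- (Mcum[ci] + st$cell_densities[ci] *
                         (y[inside] - st$node_positions[ci])) / Mtot
        mod <- matrix(0, n_rows, n_cols)
        if (any(inside)) {
          n_mu <- nrow(speckle); n_xg <- ncol(speckle)
          gi <- pmax(pmin(mu[inside] * (n_mu - 1) + 1, n_mu), 1)
          gx <- pmax(pmin(seq_len(n_cols) / n_cols * (n_xg - 1) + 1, n_xg), 1)
          fi <- floor(gi); wi <- gi - fi; fi2 <- pmin(fi + 1, n_mu)
          fx <- floor(gx); wx <- gx - fx; fx2 <- pmin(fx + 1, n_xg)
          t1 <- speckle[fi, fx, drop = FALSE] * (1 - wi) +
            speckle[fi2, fx, drop = FALSE] * wi
          t2 <- speckle[fi, fx2, drop = FALSE] * (1 - wi) +
            speckle[fi2, fx2, drop = FALSE] * wi
          tex <- sweep(t1, 2, 1 - wx, "*") + sweep(t2, 2, wx, "*")
          mod[inside, ] <- optics$speckle_contrast * tex
        }
        band <- band * (1 + mod)
      }
      content <- pmax(band, 0) + optics$monomer_level
      if (theta != 0) content <- rotate_frame_conservative(content, theta)
      signal <- illum * content
      noise_sd <- sqrt(optics$poisson_scale * pmax(signal, 0) +
                         optics$read_noise_sd^2)
      noise <- if (optics$poisson_scale > 0 || optics$read_noise_sd > 0)
        matrix(rnorm(n_rows * n_cols), n_rows, n_cols) * noise_sd else 0
      optics$camera_offset + signal + noise
    })
    frame_interval <- if (length(sim$times) > 1)
      diff(sim$times[1:2]) * 60 else 20
    stack <- frame_stack(frames, pixel_size = pixel_size,
                         frame_interval = frame_interval,
                         camera_offset = optics$camera_offset,
                         illumination = illum)
    attr(stack, "ground_truth") <- list(
      times = sim$times[frame_indices],
      epsilon = sim$epsilon[frame_indices],
      widths = sim$widths[frame_indices],
      rho_init_ratio = sim$rho_init_ratio,
      params = sim$params, geometry = sim$geometry,
      optics = optics, pixel_size = pixel_size, y_positions = y,
      frame_indices = frame_indices)
    stack
  })
}

#' Generate synthetic density profiles with known ground truth
#'
#' Simulates the contraction at the given parameters, samples the density
#' field on a pixel grid across the channel at each requested time, applies
#' optional multiplicative pixel noise, and normalizes each profile to unit
#' integral -- the same convention produced by [density_profile()].
#'
#' @param params a [model_params()].
#' @param rho_init_ratio initial density ratio.
#' @param geometry a [channel_geometry()].
#' @param times profile times, minutes (first one defines t = 0 alignment).
#' @param pixel_size grid spacing, micrometres.
#' @param noise_cv coefficient of variation of multiplicative Gaussian
#'   pixel noise (default 0).
#' @param n_cells simulation grid cells.
#' @param seed integer seed.
#' @return List with `profiles` (list of [new_density_profile()]) and the
#'   generating `truth`.
#' @export
generate_profile_data <- function(params, rho_init_ratio, geometry, times,
                                  pixel_size = 3.25, noise_cv = 0,
                                  n_cells = 128, seed = 1L) {
  stopifnot(inherits(params, "model_params"), inherits(geometry, "channel_geometry"))
  sim <- simulate_contraction(params, geometry, rho_init_ratio,
                              out_times = times - times[1], n_cells = n_cells)
  grid <- seq(-geometry$W0 / 2 + pixel_size / 2, geometry$W0 / 2,
              by = pixel_size)
  profiles <- with_seed(seed, lapply(seq_along(times), function(j) {
    rho <- density_pixels(sim, j, grid, pixel_size)
    keep <- rho > 0
    y <- rho[keep]
    if (noise_cv > 0)
      y <- pmax(y * (1 + rnorm(length(y), sd = noise_cv)), 0)
    new_density_profile(grid[keep], y, time = times[j])
  }))
  list(profiles = profiles,
       truth = list(eta_ratio = eta_ratio(params),
                    gamma_ratio = gamma_ratio(params),
                    rho_init_ratio = rho_init_ratio,
                    times = times, noise_cv = noise_cv, seed = seed))
}

#' Generate a dose-response table (and optionally full curves)
#'
#' Contraction timescales across inhibitor doses follow the four-parameter
#' logistic `tau(c) = tau_low + (tau_high - tau_low)/(1 + (ec50/c)^hill)`,
#' with optional multiplicative log-normal noise of coefficient of
#' variation `noise_cv`.  With `simulate = TRUE`, full fraction-contracted
#' curves are generated per dose by running the contraction model with the
#' active-stress strength scaled by `1/(1 + (c/ec50)^hill)` -- motor
#' inhibition reduces `s` but not the preferred density, so the final
#' fraction contracted is dose-independent while the timescale stretches.
#'
#' @param ec50 half-maximal inhibitor concentration, micromolar.
#' @param hill Hill coefficient.
#' @param tau_low,tau_high uninhibited and saturating plateaus, minutes.
#' @param concentrations doses, micromolar (>= 0).
#' @param noise_cv multiplicative noise CV on tau (default 0).
#' @param seed integer seed.
#' @param simulate also run the contraction model per dose.
#' @param params,geometry,rho_init_ratio simulation inputs for
#'   `simulate = TRUE` (defaults: experiment-scale ratios, 900 um channel).
#' @param n_cells simulation grid cells.
#' @return List with `table` (data frame `concentration`, `tau`,
#'   `tau_true`) and, when simulated, `curves` (per dose: `times`,
#'   `epsilon`, `s_scale`).
#' @export
generate_dose_response <- function(ec50 = 0.22, hill = 2, tau_low = 3,
                                   tau_high = 75, concentrations,
                                   noise_cv = 0, seed = 1L, simulate = FALSE,
                                   params = model_params_from_ratios(0.82, 1e-5),
                                   geometry = channel_geometry(900, H0 = 125),
                                   rho_init_ratio = 0.32, n_cells = 96) {
  if (any(concentrations < 0))
    stop_mtc("mtc_domain_error", "concentrations must be non-negative")
  tau_true <- ifelse(concentrations > 0,
                     tau_low + (tau_high - tau_low) /
                       (1 + (ec50 / concentrations)^hill),
                     tau_low)
  tau <- tau_true
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    tau <- with_seed(seed, tau_true *
                       exp(rnorm(length(tau_true), -sdlog^2 / 2, sdlog)))
  }
  out <- list(table = data.frame(concentration = concentrations,
                                 tau = tau, tau_true = tau_true),
              truth = list(ec50 = ec50, hill = hill, tau_low = tau_low,
                           tau_high = tau_high, noise_cv = noise_cv,
                           seed = seed))
  if (simulate) {
    out$curves <- lapply(concentrations, function(cc) {
      s_scale <- 1 / (1 + (cc / ec50)^hill)
      p <- model_params(eta = params$eta, gamma = params$gamma,
                        s = params$s * s_scale, rho0 = params$rho0)
      # snapshot cadence follows the rescaled dynamics so that curves across
      # doses are identical up to the time rescaling tau -> tau / s_scale
      sim <- simulate_contraction(p, geometry, rho_init_ratio,
                                  n_cells = n_cells,
                                  out_dt = eta_ratio(p) / 10,
                                  stop_completion = 0.999)
      list(concentration = cc, s_scale = s_scale,
           times = sim$times, epsilon = sim$epsilon)
    })
  }
  out
}

#' Generate a synthetic PIV image pair
#'
#' Builds a Gaussian-speckle texture (a seeded sum of Gaussian spots) and
#' advects it by the given displacement field with exact sub-pixel
#' evaluation: `frame_b(x) = texture(x - d(x))`.  The ground-truth field is
#' attached.
#'
#' @param displacement either a length-2 vector `c(u, v)` (uniform shift,
#'   columns then rows, pixels) or a `function(x, y)` of pixel-centre
#'   matrices returning `list(u =, v =)`.
#' @param dim frame dimensions `c(rows, cols)`.
#' @param n_speckles number of Gaussian spots (default fills ~5% of
#'   pixels).
#' @param speckle_sd spot standard deviation, pixels.
#' @param window reference interrogation window used for the aliasing
#'   check: displacements above `window/2` trigger a warning.
#' @param seed integer seed.
#' @return List with `frame_a`, `frame_b`, and `truth` (`u`, `v` matrices).
#' @export
generate_piv_pair <- function(displacement, dim = c(64, 64),
                              n_speckles = NULL, speckle_sd = 1,
                              window = 16, seed = 1L) {
  nr <- dim[1]; nc <- dim[2]
  if (is.null(n_speckles)) n_speckles <- ceiling(nr * nc / 20)
  xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  if (is.function(displacement)) {
    d <- displacement(xs, ys)
    u <- d$u; v <- d$v
  } else {
    u <- matrix(displacement[1], nr, nc)
    v <- matrix(displacement[2], nr, nc)
  }
  if (max(abs(c(u, v))) > window / 2)
    warn_mtc("mtc_aliasing_warning",
             "displacements exceed half the interrogation window: PIV will alias")
  with_seed(seed, {
    cx <- runif(n_speckles, -2 * speckle_sd, nc + 2 * speckle_sd)
    cy <- runif(n_speckles, -2 * speckle_sd, nr + 2 * speckle_sd)
    amp <- runif(n_speckles, 0.5, 1)
    texture <- function(px, py) {
      out <- matrix(0, nrow(px), ncol(px))
      for (k in seq_len(n_speckles))
        out <- out + amp[k] *
          exp(-((px - cx[k])^2 + (py - cy[k])^2) / (2 * speckle_sd^2))
      out
    }
    frame_a <- texture(xs, ys)
    frame_b <- texture(xs - u, ys - v)
    list(frame_a = frame_a, frame_b = frame_b,
         truth = list(u = u, v = v, seed = seed))
  })
}
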