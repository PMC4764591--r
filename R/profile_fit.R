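#' Fit model parameters to measured density profiles
#'
#' Least-squares matching of simulated to measured cross-width density
#' profiles.  The three reduced parameters -- `eta/(s rho0^2)`,
#' `gamma/(s rho0^2)` and `rho_init/rho0` -- are adjusted so that the
#' simulated density field `rho(x, t)`, normalized exactly like the
#' measurements (unit integral between the edge peaks), most closely
#' matches the measured profiles in summed squared difference.  Simulation
#' time zero is aligned to the first measured profile; the lag before
#' contraction is absorbed by that alignment.
#'
#' Optimization is a deterministic Nelder-Mead from a small set of fixed
#' starts on transformed coordinates (log10 for the two ratios, logit for
#' the density ratio), followed by a refinement start from the best point.
#' Standard errors come from the numeric Hessian of the objective at the
#' optimum (Gauss-Newton approximation).
#'
#' @param profiles list of [new_density_profile()] objects (unit integral).
#' @param times acquisition times of the profiles, minutes; defaults to the
#'   `time` fields of the profiles.
#' @param geometry a [channel_geometry()] giving the initial width.
#' @param optimizer list of settings: `n_cells` (simulation grid, default
#'   128), `starts` (matrix of starting values, one row per start, columns
#'   `eta_ratio`, `gamma_ratio`, `rho_init_ratio`), `maxit`, `reltol`.
#' @return An object of class `profile_fit_result` with the three fitted
#'   parameters, standard errors, the objective value, and flags
#'   (`degenerate` when the profiles carry no dynamics, `at_boundary` when
#'   the optimum sits at an extreme of the transformed space).
#' @export
fit_density_profiles <- function(profiles, times = NULL, geometry,
                                 optimizer = list()) {
  stopifnot(inherits(geometry, "channel_geometry"))
  if (length(profiles) < 3)
    stop_mtc("mtc_domain_error", "need at least 3 profiles at distinct times")
  if (is.null(times))
    times <- vapply(profiles, function(p) p$time, numeric(1))
  if (anyNA(times) || any(duplicated(times)))
    stop_mtc("mtc_domain_error", "profiles must carry distinct times")
  ord <- order(times)
  profiles <- profiles[ord]; times <- times[ord]

  opt <- utils::modifyList(
    list(n_cells = 128, maxit = 400, reltol = 1e-10,
         starts = rbind(c(0.5, 2e-6, 0.45), c(1.5, 2e-5, 0.25))),
    optimizer)

  # degenerate when the profiles carry no time variation (static field)
  flat <- vapply(profiles, function(p) stats::sd(p$intensity) /
                   max(mean(p$intensity), 1e-300), numeric(1))
  span <- stats::sd(vapply(profiles, function(p) diff(range(p$positions)),
                           numeric(1)))
  degenerate <- all(flat < 1e-2) && span < 1e-6 * geometry$W0
  if (degenerate)
    warn_mtc("mtc_degenerate_fit_warning",
             paste("profiles are static and uniform: the viscosity and drag",
                   "ratios are not identifiable from these data"))

  sim_times <- times - times[1]
  # each measured profile is extended with zeros onto the full channel-width
  # pixel grid, so the mismatch penalizes a simulation that over- or
  # under-shoots the measured network width symmetrically
  grid_out <- function(from, to, by)
    if (from > to) numeric(0) else seq(from, to, by = by)
  padded <- lapply(profiles, function(p) {
    dx <- mean(diff(p$positions))
    lo <- -rev(grid_out(-p$positions[1] + dx, geometry$W0 / 2, dx))
    hi <- grid_out(p$positions[length(p$positions)] + dx, geometry$W0 / 2, dx)
    list(positions = c(lo, p$positions, hi),
         intensity = c(numeric(length(lo)), p$intensity, numeric(length(hi))),
         dx = dx)
  })
  objective <- function(theta) {
    er <- 10^theta[1]; gr <- 10^theta[2]; r <- stats::plogis(theta[3])
    p <- model_params_from_ratios(er, gr)
    sim <- tryCatch(
      simulate_contraction(p, geometry, r, out_times = sim_times,
                           n_cells = opt$n_cells),
      error = function(e) NULL)
    if (is.null(sim)) return(1e10)
    ss <- 0
    for (j in seq_along(padded)) {
      q <- density_pixels(sim, j, padded[[j]]$positions, padded[[j]]$dx)
      tot <- sum(q) * padded[[j]]$dx
      q <- if (tot > 0) q / tot else q
      ss <- ss + sum((q - padded[[j]]$intensity)^2)
    }
    ss
  }

  to_theta <- function(p) c(log10(p[1]), log10(p[2]), stats::qlogis(p[3]))
  best <- NULL
  for (i in seq_len(nrow(opt$starts))) {
    o <- optim(to_theta(opt$starts[i, ]), objective, method = "Nelder-Mead",
               control = list(maxit = opt$maxit, reltol = opt$reltol))
    if (is.null(best) || o$value < best$value) best <- o
  }
  # refinement pass from the incumbent
  best <- optim(best$par, objective, method = "Nelder-Mead",
                control = list(maxit = opt$maxit, reltol = opt$reltol))

  th <- best$par
  est <- c(eta_ratio = 10^th[1], gamma_ratio = 10^th[2],
           rho_init_ratio = stats::plogis(th[3]))
  at_boundary <- abs(th[3]) > stats::qlogis(0.995) ||
    th[1] < -6 || th[1] > 3 || th[2] < -10 || th[2] > 0
  if (at_boundary)
    warn_mtc("mtc_boundary_warning",
             "profile fit converged at an extreme of the search space")

  se <- rep(NA_real_, 3)
  if (!degenerate) {
    H <- tryCatch(stats::optimHess(th, objective), error = function(e) NULL)
    if (!is.null(H)) {
      n_obs <- sum(vapply(profiles, function(p) length(p$intensity), numeric(1)))
      sigma2 <- best$value / max(1, n_obs - 3)
      cov_th <- tryCatch(solve(H / 2) * sigma2, error = function(e) NULL)
      if (!is.null(cov_th)) {
        # delta method back to natural scale
        g <- c(log(10) * est[1], log(10) * est[2],
               est[3] * (1 - est[3]))
        se <- sqrt(pmax(diag(cov_th), 0)) * g
      }
    }
  }

  structure(list(eta_ratio = unname(est[1]), gamma_ratio = unname(est[2]),
                 rho_init_ratio = unname(est[3]),
                 se = setNames(se, names(est)),
                 objective = best$value, degenerate = degenerate,
                 at_boundary = at_boundary, n_profiles = length(profiles),
                 optimizer = opt["n_cells"]),
            class = "profile_fit_result")
}

#' @export
print.profile_fit_result <- function(x, ...) {
  cat("Density-profile fit\n")
  cat(sprintf("  eta/(s rho0^2)   = %.4g min (se %.2g)\n", x$eta_ratio, x$se[1]))
  cat(sprintf("  gamma/(s rho0^2) = %.4g min/um^2 (se %.2g)\n",
              x$gamma_ratio, x$se[2]))
  cat(sprintf("  rho_init/rho0    = %.4g (se %.2g)\n", x$rho_init_ratio, x$se[3]))
  cat(sprintf("  objective = %.4g over %d profiles%s\n", x$objective,
              x$n_profiles,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}
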