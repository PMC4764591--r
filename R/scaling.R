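#' Contraction-timescale scaling law
#'
#' Near equilibrium the contraction timescale obeys
#' `tau(W0) = alpha * eta/(s rho0^2) + beta * gamma/(s rho0^2) * W0^2`:
#' a width-independent viscous term plus a drag term quadratic in channel
#' width.  This interpolates between the two rejected single-mechanism
#' pictures (a purely viscoelastic time, constant in `W0`, and a purely
#' poroelastic time, proportional to `W0^2`).
#'
#' @param W0 channel width(s), micrometres.
#' @param eta_ratio reduced viscosity `eta/(s rho0^2)`, minutes.
#' @param gamma_ratio reduced drag `gamma/(s rho0^2)`, min/um^2.
#' @param constants a [scaling_constants()] object (dimensionless
#'   `alpha`, `beta`).
#' @return tau in minutes, same length as `W0`.
#' @export
tau_of_width <- function(W0, eta_ratio, gamma_ratio, constants) {
  stopifnot(inherits(constants, "scaling_constants"))
  if (any(W0 <= 0)) stop_mtc("mtc_domain_error", "W0 must be positive")
  if (eta_ratio < 0 || gamma_ratio < 0)
    stop_mtc("mtc_domain_error", "parameter ratios must be non-negative")
  constants$alpha * eta_ratio + constants$beta * gamma_ratio * W0^2
}

#' Dimensionless constants of the scaling law
#'
#' @param alpha dimensionless intercept coefficient (multiplies the reduced
#'   viscosity).
#' @param beta dimensionless slope coefficient (multiplies the reduced drag
#'   times `W0^2`).
#' @param fit_residual residual standard error of the regression that
#'   produced the constants, if any.
#' @return An object of class `scaling_constants`.
#' @export
scaling_constants <- function(alpha, beta, fit_residual = NA_real_) {
  if (!(alpha > 0) || !(beta > 0))
    stop_mtc("mtc_domain_error", "alpha and beta must be positive")
  structure(list(alpha = alpha, beta = beta, fit_residual = fit_residual),
            class = "scaling_constants")
}

#' @export
print.scaling_constants <- function(x, ...) {
  cat(sprintf("Scaling constants: alpha = %.4g, beta = %.4g", x$alpha, x$beta))
  if (is.finite(x$fit_residual)) cat(sprintf(" (fit residual %.3g)", x$fit_residual))
  cat("\n")
  invisible(x)
}

#' Determine the scaling constants numerically from full simulations
#'
#' Runs the full free-boundary simulation for each channel width, computes
#' the fraction contracted, fits each curve with the exponential-relaxation
#' form (using only timepoints with `epsilon > threshold`, the same rule
#' applied to experimental curves), and linearly regresses the fitted `tau`
#' on `(1, W0^2)`.  Then `alpha = intercept / eta_ratio` and
#' `beta = slope / gamma_ratio`.
#'
#' Each width is simulated until the fraction contracted reaches
#' `completion` times its mass-conservation asymptote `1 - rho_init_ratio`,
#' so the fitted curve sees the full contraction including the plateau; the
#' fitted `tau` at strongly drag-dominated widths depends measurably on this
#' window (see [alpha_beta_sensitivity()]).
#'
#' @param params a [model_params()]; the regression is reported relative to
#'   its reduced ratios.
#' @param rho_init_ratio initial-to-preferred density ratio (default 0.32,
#'   the value inferred from density-profile fits).
#' @param widths channel widths, micrometres; must span both the
#'   viscosity-dominated (small `W0`) and drag-dominated (large `W0`)
#'   regimes.  Default: 8 log-spaced widths from 100 to 3000 um.
#' @param fit_protocol list of protocol settings: `threshold` (epsilon
#'   cutoff for the curve fit, default 0.1), `completion` (fraction of the
#'   asymptotic contraction to simulate to, default 0.999), `out_dt`
#'   (snapshot interval, min), `n_cells`.
#' @return A `scaling_constants` object with an attached `scan` data frame
#'   (`W0`, `tau`, `eps_inf`, `Tc`) and the regression fit.
#' @export
determine_alpha_beta <- function(params, rho_init_ratio = 0.32,
                                 widths = exp(seq(log(100), log(3000),
                                                  length.out = 8)),
                                 fit_protocol = list()) {
  stopifnot(inherits(params, "model_params"))
  if (length(widths) < 4)
    stop_mtc("mtc_domain_error", "need at least 4 widths spanning both regimes")
  fp <- utils::modifyList(list(threshold = 0.1, completion = 0.999,
                               out_dt = 1 / 3, n_cells = 200), fit_protocol)
  er <- eta_ratio(params); gr <- gamma_ratio(params)

  scan <- do.call(rbind, lapply(widths, function(W0) {
    sim <- simulate_contraction(params, channel_geometry(W0), rho_init_ratio,
                                n_cells = fp$n_cells, out_dt = fp$out_dt,
                                stop_completion = fp$completion)
    fit <- fit_contraction_curve(sim$times, sim$epsilon, threshold = fp$threshold)
    data.frame(W0 = W0, tau = fit$tau, eps_inf = fit$epsilon_inf, Tc = fit$Tc)
  }))

  # regime coverage: drag term vs viscous term across the scan
  ratio <- gr * widths^2 / er
  if (gr > 0 && (max(ratio) < 1 || min(ratio) > 1)) {
    X <- cbind(1, widths^2)
    kappa <- kappa(crossprod(scale(X, center = FALSE)))
    warn_mtc("mtc_regime_warning",
             sprintf(paste("widths cover only one regime (drag/viscous term",
                           "ratio %.3g-%.3g); regression condition number %.3g"),
                     min(ratio), max(ratio), kappa))
  }

  reg <- lm(tau ~ I(W0^2), data = scan)
  alpha <- unname(coef(reg)[1]) / er
  beta <- if (gr > 0) unname(coef(reg)[2]) / gr else NA_real_
  out <- scaling_constants(alpha, if (is.na(beta)) 1e-12 else beta,
                           fit_residual = summary(reg)$sigma)
  out$beta <- beta
  attr(out, "scan") <- scan
  attr(out, "regression") <- reg
  attr(out, "protocol") <- c(fp, list(rho_init_ratio = rho_init_ratio,
                                      eta_ratio = er, gamma_ratio = gr))
  out
}

#' Report sensitivity of the scaling constants to protocol choices
#'
#' The numerical determination of `alpha` and `beta` depends on two choices
#' that the underlying experiments leave open: the initial density ratio and
#' how much of the contraction record (including the final plateau) enters
#' the exponential fit.  This runs the full protocol over a grid of both and
#' tabulates the constants.
#'
#' @param params a [model_params()].
#' @param rho_init_ratios vector of initial density ratios to scan.
#' @param completions vector of completion fractions to scan.
#' @param fit_protocol base protocol settings (the scanned `completion`
#'   overrides its entry).
#' @param ... passed to [determine_alpha_beta()] (e.g. `widths`).
#' @return Data frame with columns `rho_init_ratio`, `completion`, `alpha`,
#'   `beta`.
#' @export
alpha_beta_sensitivity <- function(params,
                                   rho_init_ratios = c(0.2, 0.32, 0.5),
                                   completions = c(0.99, 0.999, 0.9999),
                                   fit_protocol = list(), ...) {
  grid <- expand.grid(rho_init_ratio = rho_init_ratios, completion = completions)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    fp <- utils::modifyList(fit_protocol, list(completion = grid$completion[i]))
    sc <- determine_alpha_beta(params, rho_init_ratio = grid$rho_init_ratio[i],
                               fit_protocol = fp, ...)
    c(alpha = sc$alpha, beta = sc$beta)
  })
  cbind(grid, do.call(rbind, res))
}

#' Slowest linear relaxation time of the free-boundary system
#'
#' Linearizes the discrete Lagrangian dynamics about the uniform equilibrium
#' `rho = rho0` on a domain of width `W` (free, total-stress-free
#' boundaries) and returns `1/lambda_min`, the reciprocal of the slowest
#' non-zero decay rate of the Jacobian (rigid translations are a neutral
#' direction and are excluded).  Limits: as `gamma -> 0` the slowest mode is
#' uniform dilation with `tau = eta/(s rho0^2)`; as `eta -> 0` the
#' linearized dynamics is density diffusion with `D = s rho0^2 / gamma` and
#' absorbing (zero-stress) edges, whose slowest mode gives
#' `tau = gamma W^2 / (pi^2 s rho0^2)`.
#'
#' @param params a [model_params()].
#' @param W domain width, micrometres.
#' @param n_grid number of cells for the discretization (default 256).
#' @return tau_lin in minutes.
#' @export
linear_relaxation_time <- function(params, W, n_grid = 256) {
  stopifnot(inherits(params, "model_params"))
  if (!(W > 0)) stop_mtc("mtc_domain_error", "W must be positive")
  n <- n_grid
  x0 <- seq(-W / 2, W / 2, length.out = n + 1)
  mass <- params$rho0 * diff(x0)
  fun <- function(x) fb_core(x, mass / diff(x), params$eta, params$gamma,
                             params$s, params$rho0)
  h <- 1e-6 * W / n
  J <- matrix(0, n + 1, n + 1)
  for (j in seq_len(n + 1)) {
    xp <- x0; xp[j] <- xp[j] + h
    xm <- x0; xm[j] <- xm[j] - h
    J[, j] <- (fun(xp) - fun(xm)) / (2 * h)
  }
  ev <- tryCatch(eigen(J),
                 error = function(e)
                   stop_mtc("mtc_numerical_error",
                            paste("eigensolve failed; try refining n_grid:",
                                  conditionMessage(e))))
  # a rigid translation leaves densities (and so forces) unchanged: J has an
  # exact zero mode with a constant eigenvector.  Identify it by the
  # constancy of the eigenvector rather than by eigenvalue magnitude, which
  # finite-difference noise makes unreliable.
  vecs <- ev$vectors
  constancy <- abs(colSums(vecs))^2 / (ncol(vecs) * colSums(Mod(vecs)^2))
  keep <- constancy < 0.99
  rates <- -Re(ev$values[keep])
  rates <- rates[rates > 0]
  if (!length(rates))
    stop_mtc("mtc_numerical_error",
             "no decaying mode found; try refining n_grid")
  1 / min(rates)
}

#' Fit the scaling law to tau-versus-width data
#'
#' Least squares of `tau = alpha * eta_ratio + beta * gamma_ratio * W0^2`,
#' linear in `(1, W0^2)`, given known dimensionless constants.  Returns the
#' inferred parameter ratios with standard errors propagated from the
#' regression coefficients.
#'
#' @param widths channel widths, micrometres (>= 3 values).
#' @param taus fitted contraction timescales, minutes.
#' @param constants a [scaling_constants()].
#' @param weights optional regression weights.
#' @return An object of class `scaling_fit`: `eta_ratio`, `gamma_ratio`,
#'   `eta_ratio_se`, `gamma_ratio_se`, `unphysical` flag.
#' @export
fit_tau_vs_width <- function(widths, taus, constants, weights = NULL) {
  stopifnot(inherits(constants, "scaling_constants"))
  if (length(widths) < 3 || length(widths) != length(taus))
    stop_mtc("mtc_domain_error", "need >= 3 matched (width, tau) pairs")
  d <- data.frame(tau = taus, W2 = widths^2)
  reg <- if (is.null(weights)) lm(tau ~ W2, data = d)
         else lm(tau ~ W2, data = d, weights = weights)
  cf <- coef(reg)
  se <- suppressWarnings(sqrt(diag(vcov(reg))))  # exact fits have ~zero vcov
  out <- structure(list(eta_ratio = unname(cf[1]) / constants$alpha,
                        gamma_ratio = unname(cf[2]) / constants$beta,
                        eta_ratio_se = unname(se[1]) / constants$alpha,
                        gamma_ratio_se = unname(se[2]) / constants$beta,
                        regression = reg),
                   class = "scaling_fit")
  out$unphysical <- out$eta_ratio < 0 || out$gamma_ratio < 0
  out
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("Scaling fit: eta/(s rho0^2) = %.4g +/- %.2g min, gamma/(s rho0^2) = %.4g +/- %.2g min/um^2%s\n",
              x$eta_ratio, x$eta_ratio_se, x$gamma_ratio, x$gamma_ratio_se,
              if (isTRUE(x$unphysical)) " [unphysical: negative ratio]" else ""))
  invisible(x)
}

#' Active-stress scale from a dimensional viscosity
#'
#' Converts the fitted reduced viscosity `eta/(s rho0^2)` (minutes) and an
#' independent dimensional estimate of the network viscosity `eta` (Pa s)
#' into the active-stress scale `s rho0^2 = eta / (eta/(s rho0^2))` in
#' pascals.
#'
#' @param eta_pa_s viscosity, Pa s.
#' @param eta_ratio_min fitted reduced viscosity, minutes.
#' @return Active-stress scale, Pa.
#' @examples
#' active_stress_scale(2e2, 0.82)  # ~4 Pa
#' @export
active_stress_scale <- function(eta_pa_s, eta_ratio_min) {
  if (!(eta_pa_s > 0) || !(eta_ratio_min > 0))
    stop_mtc("mtc_domain_error", "both arguments must be positive")
  eta_pa_s / (eta_ratio_min * 60)
}

#' Relative active-stress strength from contraction timescales
#'
#' Because `tau` is inversely proportional to the active-stress strength
#' `s` (at fixed geometry and other parameters), the ratio of stress
#' strengths between two conditions is the inverse ratio of their
#' contraction timescales: `s_b / s_a = tau_a / tau_b`.  Used to quantify
#' how much active stress survives motor inhibition.
#'
#' @param tau_reference timescale in the reference (uninhibited) condition,
#'   minutes.
#' @param tau_condition timescale in the test (inhibited) condition, minutes.
#' @return Dimensionless stress ratio `s_condition / s_reference`.
#' @examples
#' relative_stress_from_tau(3, 75)  # 0.04
#' @export
relative_stress_from_tau <- function(tau_reference, tau_condition) {
  if (!(tau_reference > 0) || !(tau_condition > 0))
    stop_mtc("mtc_domain_error", "timescales must be positive")
  tau_reference / tau_condition
}
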