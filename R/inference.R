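#' Fit an exponential-relaxation contraction curve
#'
#' Fits `epsilon(t) = eps_inf * (1 - exp(-(t - Tc)/tau))` (clamped at 0 for
#' `t < Tc`) to a fraction-contracted time series by nonlinear least
#' squares, using only timepoints with `epsilon > threshold` -- the same
#' rule applied to experimental contraction data, which restricts the fit to
#' the contracting phase.  `eps_inf` is the final fraction contracted,
#' `tau` the characteristic time, and `Tc` the lag before contraction
#' starts.
#'
#' Starting values follow a deterministic multi-start grid
#' (`eps_inf` in \{0.5, 0.7, 0.9\}, `tau` in \{0.5, 1, 2\} times the time to
#' half-maximal contraction, `Tc` in \{0, first threshold crossing\}); the
#' best residual sum of squares wins, ties broken by the smaller `tau`, so
#' the fit is reproducible without any random seed.
#'
#' @param times times, minutes.
#' @param epsilon fraction contracted at `times`.
#' @param threshold inclusion cutoff (default 0.1).
#' @return An object of class `contraction_fit` with fields `epsilon_inf`,
#'   `tau`, `Tc`, `rss`, `n_points_used`, and the per-parameter standard
#'   errors when available.
#' @examples
#' t <- seq(0, 20, by = 1 / 3)
#' eps <- pmax(0, 0.81 * (1 - exp(-(t - 1.06) / 3.49)))
#' fit_contraction_curve(t, eps)
#' @export
fit_contraction_curve <- function(times, epsilon, threshold = 0.1) {
  if (length(times) != length(epsilon))
    stop_mtc("mtc_domain_error", "times and epsilon must have equal length")
  use <- epsilon > threshold
  if (!any(use))
    stop_mtc("mtc_not_contracted_error",
             sprintf("no timepoints with epsilon > %g: network not contracted",
                     threshold))
  if (sum(use) < 5)
    stop_mtc("mtc_not_contracted_error",
             sprintf("only %d timepoints with epsilon > %g; need at least 5",
                     sum(use), threshold))
  tt <- times[use]; ee <- epsilon[use]

  model <- function(p, t) pmax(0, p[1] * (1 - exp(-(t - p[3]) / p[2])))
  resid_fn <- function(p) model(p, tt) - ee

  t_half <- tt[which.min(abs(ee - max(ee) / 2))]
  if (!(t_half > 0)) t_half <- max(diff(range(tt)) / 4, 1e-3)
  starts <- expand.grid(eps_inf = c(0.5, 0.7, 0.9),
                        tau = c(0.5, 1, 2) * t_half,
                        Tc = c(0, min(tt)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = as.numeric(starts[i, ]), fn = resid_fn,
                         lower = c(1e-6, 1e-6, 0),
                         upper = c(1, Inf, max(tt)),
                         control = minpack.lm::nls.lm.control(maxiter = 200,
                                                              ftol = 1e-14,
                                                              ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-14 ||
        (abs(rss - best$rss) <= 1e-14 && fit$par[2] < best$par[2]))
      best <- list(par = fit$par, rss = rss, fit = fit)
  }
  if (is.null(best))
    stop_mtc("mtc_fit_failure_error",
             "no start of the deterministic grid converged; inspect the curve")

  se <- tryCatch({
    jac <- best$fit$hessian
    sqrt(diag(solve(jac)) * best$rss / max(1, length(tt) - 3))
  }, error = function(e) rep(NA_real_, 3))

  structure(list(epsilon_inf = best$par[1], tau = best$par[2],
                 Tc = best$par[3], rss = best$rss,
                 n_points_used = length(tt),
                 se = setNames(se, c("epsilon_inf", "tau", "Tc")),
                 threshold = threshold),
            class = "contraction_fit")
}

#' @export
print.contraction_fit <- function(x, ...) {
  cat(sprintf("Contraction fit: eps_inf = %.4g, tau = %.4g min, Tc = %.4g min\n",
              x$epsilon_inf, x$tau, x$Tc))
  cat(sprintf("  rss = %.3g over %d points (epsilon > %g)\n",
              x$rss, x$n_points_used, x$threshold))
  invisible(x)
}

#' Evaluate a fitted contraction curve
#'
#' @param fit a `contraction_fit`.
#' @param times times, minutes.
#' @return The fitted `epsilon(t)`, clamped at 0 before the lag time.
#' @export
predict_contraction <- function(fit, times) {
  stopifnot(inherits(fit, "contraction_fit"))
  pmax(0, fit$epsilon_inf * (1 - exp(-(times - fit$Tc) / fit$tau)))
}

#' Fit a sigmoid dose-response of the contraction timescale
#'
#' Fits the four-parameter logistic
#' `tau(c) = tau_low + (tau_high - tau_low) / (1 + (ec50 / c)^hill)` to
#' contraction timescales measured at increasing inhibitor concentrations.
#' `tau(0) = tau_low` is the uninhibited plateau, `tau_high` the saturating
#' plateau, and at `c = ec50` the response is midway between the plateaus
#' regardless of the Hill coefficient.  The full four-parameter form is
#' used (no plateau or slope is held fixed); the parameterization is
#' recorded in the result.
#'
#' @param concentrations inhibitor concentrations, micromolar (must include
#'   0 and span to a near-saturating value; >= 4 points).
#' @param taus contraction timescales, minutes.
#' @return An object of class `sigmoid_fit`: `ec50`, `hill`, `tau_low`,
#'   `tau_high`, standard errors, residuals, and a `poor_fit` flag when the
#'   data are non-monotone beyond their scatter.
#' @export
fit_sigmoid_dose_response <- function(concentrations, taus) {
  if (length(concentrations) < 4 || length(concentrations) != length(taus))
    stop_mtc("mtc_domain_error", "need >= 4 matched (concentration, tau) pairs")
  if (!any(concentrations == 0))
    stop_mtc("mtc_domain_error", "concentrations must include 0 (uninhibited)")
  ord <- order(concentrations)
  cc <- concentrations[ord]; yy <- taus[ord]

  model <- function(p, c) {
    # p = (log ec50, log hill, tau_low, tau_high); tau(0) = tau_low exactly
    ec50 <- exp(p[1]); hill <- exp(p[2])
    ifelse(c > 0, p[3] + (p[4] - p[3]) / (1 + (ec50 / c)^hill), p[3])
  }
  resid_fn <- function(p) model(p, cc) - yy

  cpos <- cc[cc > 0]
  starts <- expand.grid(lec = log(c(min(cpos), sqrt(min(cpos) * max(cpos)), max(cpos))),
                        lh = log(c(1, 2, 4)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- c(starts$lec[i], starts$lh[i], min(yy), max(yy))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 300,
                                                              ftol = 1e-14,
                                                              ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(par = fit$par, rss = rss, fit = fit)
  }
  if (is.null(best))
    stop_mtc("mtc_fit_failure_error", "sigmoid fit failed from all starts")

  p <- best$par
  se_raw <- tryCatch(sqrt(diag(solve(best$fit$hessian)) * best$rss /
                            max(1, length(cc) - 4)),
                     error = function(e) rep(NA_real_, 4))
  # delta-method scale for the log parameters
  se <- c(ec50 = unname(se_raw[1]) * exp(p[1]),
          hill = unname(se_raw[2]) * exp(p[2]),
          tau_low = unname(se_raw[3]), tau_high = unname(se_raw[4]))

  resid <- model(p, cc) - yy
  # non-monotone beyond noise: successive decreases larger than the scatter
  drops <- -diff(yy)
  poor <- any(drops > 3 * max(stats::sd(resid), 1e-12) + 1e-12)
  if (poor)
    warn_mtc("mtc_poor_fit_warning",
             "dose-response decreases with concentration beyond the residual scatter")

  structure(list(ec50 = exp(p[1]), hill = exp(p[2]),
                 tau_low = p[3], tau_high = p[4],
                 se = se, rss = best$rss, residuals = resid,
                 concentrations = cc, taus = yy, poor_fit = poor,
                 parameterization = "4-parameter logistic, tau(0) = tau_low"),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("Sigmoid dose-response fit (%s)\n", x$parameterization))
  cat(sprintf("  EC50 = %.4g uM, hill = %.3g, tau: %.3g -> %.3g min\n",
              x$ec50, x$hill, x$tau_low, x$tau_high))
  if (isTRUE(x$poor_fit)) cat("  [poor fit: non-monotone data]\n")
  invisible(x)
}

#' Estimate the final network density from fluorescence
#'
#' Given the mean background-corrected fluorescence of the network
#' (`rho_network`) and of the surrounding monomer signal (`rho_monomer`) in
#' the frame closest to `t = tau + Tc`, the fractional tubulin
#' concentration at that time is
#' `(rho_network - rho_monomer) / (rho_network + rho_monomer)`.  Projecting
#' to `t = Inf` assumes the network contracts identically along the width
#' and the vertical direction, which multiplies the fraction by
#' `((1 - eps_inf (1 - e^-1)) / (1 - eps_inf))^2` -- the squared ratio of
#' the remaining widths at `t = tau + Tc` and at infinity, a factor greater
#' than 1 since the density keeps increasing as the network contracts.
#' Multiplying by the extract tubulin concentration gives the final network
#' tubulin concentration in micromolar.
#'
#' @param rho_network mean network fluorescence, a.u.
#' @param rho_monomer mean monomer background fluorescence, a.u.
#' @param fit a [fit_contraction_curve()] result (supplies `eps_inf`).
#' @param extract_tubulin_uM tubulin concentration of the extract,
#'   micromolar (default 18).
#' @return An object of class `final_density_estimate`.
#' @examples
#' fit <- structure(list(epsilon_inf = 0.77, tau = 3.5, Tc = 1),
#'                  class = "contraction_fit")
#' estimate_final_density(803, 400, fit)  # ~30 uM
#' @export
estimate_final_density <- function(rho_network, rho_monomer, fit,
                                   extract_tubulin_uM = 18) {
  stopifnot(inherits(fit, "contraction_fit"))
  if (!(rho_monomer >= 0))
    stop_mtc("mtc_domain_error", "rho_monomer must be non-negative")
  if (rho_network < rho_monomer)
    stop_mtc("mtc_no_network_error",
             "network fluorescence below the monomer background: no network")
  frac <- (rho_network - rho_monomer) / (rho_network + rho_monomer)
  e <- fit$epsilon_inf
  projection <- ((1 - e * (1 - exp(-1))) / (1 - e))^2
  projected <- frac * projection
  structure(list(rho_network = rho_network, rho_monomer = rho_monomer,
                 fractional_concentration = frac,
                 projection_factor = projection,
                 projected_fraction_at_infinity = projected,
                 tubulin_concentration = projected * extract_tubulin_uM,
                 extract_tubulin_uM = extract_tubulin_uM),
            class = "final_density_estimate")
}

#' @export
print.final_density_estimate <- function(x, ...) {
  cat(sprintf("Final density estimate\n  fractional concentration at t = tau + Tc: %.4g\n",
              x$fractional_concentration))
  cat(sprintf("  projection factor to t = Inf: %.4g\n", x$projection_factor))
  cat(sprintf("  final network tubulin concentration: %.3g uM (extract %.3g uM)\n",
              x$tubulin_concentration, x$extract_tubulin_uM))
  invisible(x)
}
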