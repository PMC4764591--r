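#' Physical parameters of the active-fluid contraction model
#'
#' Bundles the four coefficients of the continuum theory: the network
#' viscosity `eta`, the wall drag coefficient `gamma`, the active-stress
#' strength `s`, and the preferred (final) density `rho0` at which
#' motor-driven contraction and steric extension balance.  The dynamics of
#' the fraction contracted depend on `(eta, gamma, s)` only through the
#' reduced ratios `eta/(s rho0^2)` (a time) and `gamma/(s rho0^2)`
#' (time per squared length); see [eta_ratio()] and [gamma_ratio()].
#'
#' The active-stress strength `s` is proportional to the number of active
#' motors, while `rho0` is set by motor-filament geometry alone, so scaling
#' `s` rescales all velocities and leaves the final density unchanged.
#'
#' @param eta viscosity, stress x time units (default such that
#'   `eta/(s rho0^2)` is in minutes).
#' @param gamma drag coefficient against the channel wall, stress x time per
#'   squared micrometre; `gamma >= 0`.
#' @param s active-stress strength, stress per squared density unit.
#' @param rho0 preferred density; densities are conventionally normalized so
#'   `rho0 = 1`.
#' @return An object of class `model_params`.
#' @seealso [model_params_from_ratios()] to construct directly from the
#'   reduced ratios.
#' @examples
#' p <- model_params_from_ratios(eta_ratio = 0.82, gamma_ratio = 1e-5)
#' eta_ratio(p)
#' @export
model_params <- function(eta, gamma, s = 1, rho0 = 1) {
  if (!(is.numeric(eta) && length(eta) == 1 && eta > 0))
    stop_mtc("mtc_domain_error", "eta must be a single positive number")
  if (!(is.numeric(gamma) && length(gamma) == 1 && gamma >= 0))
    stop_mtc("mtc_domain_error", "gamma must be a single non-negative number")
  if (!(is.numeric(s) && length(s) == 1 && s > 0))
    stop_mtc("mtc_domain_error", "s must be a single positive number")
  if (!(is.numeric(rho0) && length(rho0) == 1 && rho0 > 0))
    stop_mtc("mtc_domain_error", "rho0 must be a single positive number")
  structure(list(eta = eta, gamma = gamma, s = s, rho0 = rho0),
            class = "model_params")
}

#' @rdname model_params
#' @param eta_ratio reduced viscosity `eta/(s rho0^2)`, minutes.
#' @param gamma_ratio reduced drag `gamma/(s rho0^2)`, minutes per squared
#'   micrometre.
#' @export
model_params_from_ratios <- function(eta_ratio, gamma_ratio) {
  model_params(eta = eta_ratio, gamma = gamma_ratio, s = 1, rho0 = 1)
}

#' Reduced parameter ratios
#'
#' `eta_ratio()` returns `eta/(s rho0^2)` (the viscous relaxation time, in
#' minutes under the package's unit conventions); `gamma_ratio()` returns
#' `gamma/(s rho0^2)` (min/um^2).  These two ratios, together with the
#' initial-to-preferred density ratio and the channel width, fully determine
#' the fraction-contracted dynamics.
#'
#' @param params a [model_params()] object.
#' @return A single number.
#' @export
eta_ratio <- function(params) {
  stopifnot(inherits(params, "model_params"))
  params$eta / (params$s * params$rho0^2)
}

#' @rdname eta_ratio
#' @export
gamma_ratio <- function(params) {
  stopifnot(inherits(params, "model_params"))
  params$gamma / (params$s * params$rho0^2)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Active-fluid model parameters\n")
  cat(sprintf("  eta   = %g (viscosity)\n", x$eta))
  cat(sprintf("  gamma = %g (wall drag)\n", x$gamma))
  cat(sprintf("  s     = %g (active-stress strength)\n", x$s))
  cat(sprintf("  rho0  = %g (preferred density)\n", x$rho0))
  cat(sprintf("  eta/(s rho0^2)   = %g min\n", eta_ratio(x)))
  cat(sprintf("  gamma/(s rho0^2) = %g min/um^2\n", gamma_ratio(x)))
  invisible(x)
}

#' Channel geometry
#'
#' Rectangular-channel dimensions.  Only the initial network width `W0`
#' enters the one-dimensional dynamics; the height and length are carried as
#' metadata (experimentally, the contraction timescale is independent of
#' channel height).
#'
#' @param W0 initial network width, micrometres.
#' @param H0 channel height, micrometres (metadata).
#' @param L0 channel length, micrometres (metadata).
#' @return An object of class `channel_geometry`.
#' @export
channel_geometry <- function(W0, H0 = NULL, L0 = NULL) {
  if (!(is.numeric(W0) && length(W0) == 1 && W0 > 0))
    stop_mtc("mtc_domain_error", "W0 must be a single positive number")
  if (!is.null(H0) && !(is.numeric(H0) && H0 > 0))
    stop_mtc("mtc_domain_error", "H0 must be positive when given")
  if (!is.null(L0) && !(is.numeric(L0) && L0 > 0))
    stop_mtc("mtc_domain_error", "L0 must be positive when given")
  structure(list(W0 = W0, H0 = H0, L0 = L0), class = "channel_geometry")
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("Channel geometry: W0 = %g um", x$W0))
  if (!is.null(x$H0)) cat(sprintf(", H0 = %g um", x$H0))
  if (!is.null(x$L0)) cat(sprintf(", L0 = %g um", x$L0))
  cat("\n")
  invisible(x)
}
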