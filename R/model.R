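#' Motor-generated active stress
#'
#' Isotropic active stress of the contraction model,
#' `sigma = s * rho * (rho - rho0)`.  Dynein-driven minus-end clustering
#' contributes a contractile stress linear in density, steric collisions an
#' extensile stress quadratic in density; their sum is contractile
#' (negative) for `0 < rho < rho0`, vanishes at `rho = 0` and `rho = rho0`,
#' and is extensile above the preferred density.  The minimum `-s rho0^2/4`
#' is attained at `rho = rho0/2`.
#'
#' @param rho density (vectorized), `rho >= 0`.
#' @param params a [model_params()] object.
#' @return Stress values, same length as `rho`.
#' @export
active_stress <- function(rho, params) {
  stopifnot(inherits(params, "model_params"))
  if (any(rho < 0)) stop_mtc("mtc_domain_error", "density must be non-negative")
  params$s * rho * (rho - params$rho0)
}

#' Lagrangian state of the contracting network
#'
#' A material (Lagrangian) finite-volume state: `N + 1` node positions and
#' `N` cell densities.  Cell masses `rho_i * (x_{i+1} - x_i)` are computed
#' at construction and are the conserved quantities of the scheme.
#'
#' @param node_positions strictly increasing positions, micrometres.
#' @param cell_densities positive densities, one per interval.
#' @param time time stamp, minutes.
#' @return An object of class `lagrangian_state` with fields
#'   `node_positions`, `cell_densities`, `cell_masses`, `time`.
#' @export
lagrangian_state <- function(node_positions, cell_densities, time = 0) {
  if (length(node_positions) != length(cell_densities) + 1)
    stop_mtc("mtc_invalid_state_error",
             "need one more node position than cell density")
  if (any(diff(node_positions) <= 0))
    stop_mtc("mtc_invalid_state_error",
             "node positions must be strictly increasing")
  if (any(cell_densities <= 0))
    stop_mtc("mtc_invalid_state_error", "cell densities must be positive")
  structure(list(node_positions = as.numeric(node_positions),
                 cell_densities = as.numeric(cell_densities),
                 cell_masses = as.numeric(cell_densities * diff(node_positions)),
                 time = time),
            class = "lagrangian_state")
}

#' @export
print.lagrangian_state <- function(x, ...) {
  cat(sprintf("Lagrangian state: %d cells, t = %g min, width = %g um, mass = %g\n",
              length(x$cell_densities), x$time,
              diff(range(x$node_positions)), sum(x$cell_masses)))
  invisible(x)
}

#' Solve force balance for the network velocity field
#'
#' Solves the quasi-static force balance
#' `eta * d2v/dx2 - gamma * v = d sigma / dx` on the current (generally
#' non-uniform) Lagrangian grid, with total-stress-free boundary conditions
#' `eta * dv/dx = sigma` at both free edges (an unloaded free boundary
#' carries zero total stress, so viscous and active stresses cancel there).
#' The discrete tridiagonal system is solved exactly.  With `gamma = 0` the
#' problem determines `v` only up to a rigid translation; the solution
#' returned keeps the network's centre of mass stationary.
#'
#' @param state a [lagrangian_state()].
#' @param params a [model_params()].
#' @return Node velocities, micrometres per minute (length `N + 1`).
#' @export
solve_force_balance <- function(state, params) {
  stopifnot(inherits(state, "lagrangian_state"), inherits(params, "model_params"))
  if (any(diff(state$node_positions) <= 0))
    stop_mtc("mtc_invalid_state_error", "degenerate grid spacing")
  fb_core(state$node_positions, state$cell_densities,
          params$eta, params$gamma, params$s, params$rho0)
}

#' Advance the state by one explicit step
#'
#' Nodes advect with the force-balance velocity; cell densities are updated
#' from the conserved cell masses and the new interval lengths.  Masses are
#' never modified, so total mass is conserved exactly.
#'
#' @param state a [lagrangian_state()].
#' @param params a [model_params()].
#' @param dt step, minutes; must be below the node-crossing bound.
#' @return The advanced `lagrangian_state`.
#' @export
step_state <- function(state, params, dt) {
  if (!(dt > 0)) stop_mtc("mtc_domain_error", "dt must be positive")
  v <- solve_force_balance(state, params)
  x <- state$node_positions + dt * v
  if (any(diff(x) <= 0))
    stop_mtc("mtc_step_error",
             "node crossing after step: reduce dt below the stability bound")
  out <- state
  out$node_positions <- x
  out$cell_densities <- state$cell_masses / diff(x)
  out$time <- state$time + dt
  out
}

#' Fraction contracted
#'
#' `epsilon(t) = (W0 - W(t)) / W0`, the normalized loss of network width.
#'
#' @param widths width time series `W(t)`, micrometres.
#' @param W0 initial width, micrometres.
#' @return The fraction contracted, same length as `widths`.
#' @export
epsilon_curve <- function(widths, W0) {
  if (!(is.numeric(W0) && length(W0) == 1 && W0 > 0))
    stop_mtc("mtc_domain_error", "W0 must be a single positive number")
  if (any(widths > W0 * (1 + 0.05)))
    warn_mtc("mtc_width_warning", "some widths exceed W0 by more than 5%")
  (W0 - widths) / W0
}

#' Simulate the free-boundary contraction
#'
#' Integrates the one-dimensional active-fluid system -- mass conservation
#' `d rho/dt = -d(rho v)/dx`, force balance
#' `eta d2v/dx2 - gamma v = d sigma/dx`, and active stress
#' `sigma = s rho (rho - rho0)` -- for a network that initially spans
#' `[-W0/2, W0/2]` at uniform density `rho_init_ratio * rho0`.  The scheme
#' is a Lagrangian finite volume (material nodes advect at the force-balance
#' velocity; cell masses are conserved exactly) with adaptive explicit time
#' steps `dt <= min(c1 * min_cell_width / max|dv|, c2 * eta/(s rho0^2))`.
#'
#' Snapshots are recorded every `out_dt` minutes (default 1/3 min = 20 s, a
#' typical fluorescence frame interval) up to `t_end`, or -- when
#' `stop_completion` is given -- until the fraction contracted reaches
#' `stop_completion * (1 - rho_init_ratio)`, its mass-conservation
#' asymptote.
#'
#' @param params a [model_params()].
#' @param geometry a [channel_geometry()] (only `W0` enters the dynamics).
#' @param rho_init_ratio initial density over `rho0`; values below 1
#'   contract, values above 1 expand (flagged in the result, not an error).
#' @param t_end final time, minutes (ignored when `stop_completion` is
#'   given, where it acts as a safety cap if finite).
#' @param n_cells number of material cells (`>= 16`).
#' @param out_dt snapshot interval, minutes.
#' @param out_times explicit snapshot times (overrides `out_dt`/`t_end`).
#' @param stop_completion optional fraction in (0, 1): stop once
#'   `epsilon(t) >= stop_completion * (1 - rho_init_ratio)`.
#' @param dt_control list with step-safety factors `c1` (node-crossing
#'   guard, default 0.2) and `c2` (fraction of the viscous relaxation time,
#'   default 0.05).
#' @return An object of class `simulation_result`: `times`, `states` (list
#'   of [lagrangian_state()]), `widths`, `epsilon`, `velocities` (matrix,
#'   nodes x times), the inputs, and metadata (`expanding`, `n_steps`).
#' @examples
#' p <- model_params_from_ratios(0.82, 1e-5)
#' sim <- simulate_contraction(p, channel_geometry(440), rho_init_ratio = 0.32,
#'                             t_end = 5, n_cells = 64)
#' tail(sim$epsilon, 1)
#' @export
simulate_contraction <- function(params, geometry, rho_init_ratio,
                                 t_end = NULL, n_cells = 200, out_dt = 1 / 3,
                                 out_times = NULL, stop_completion = NULL,
                                 dt_control = list(c1 = 0.2, c2 = 0.05)) {
  stopifnot(inherits(params, "model_params"), inherits(geometry, "channel_geometry"))
  if (!(rho_init_ratio > 0))
    stop_mtc("mtc_domain_error", "rho_init_ratio must be positive")
  if (n_cells < 16) stop_mtc("mtc_domain_error", "n_cells must be at least 16")
  c1 <- if (is.null(dt_control$c1)) 0.2 else dt_control$c1
  c2 <- if (is.null(dt_control$c2)) 0.05 else dt_control$c2

  W0 <- geometry$W0
  x0 <- seq(-W0 / 2, W0 / 2, length.out = n_cells + 1)
  rho0_cells <- rep(rho_init_ratio * params$rho0, n_cells)

  if (!is.null(stop_completion)) {
    if (!(stop_completion > 0 && stop_completion < 1))
      stop_mtc("mtc_domain_error", "stop_completion must be in (0, 1)")
    if (!(rho_init_ratio < 1))
      stop_mtc("mtc_domain_error",
               "stop_completion requires a contracting network (rho_init_ratio < 1)")
    eps_stop <- stop_completion * (1 - rho_init_ratio)
    t_cap <- if (is.null(t_end)) Inf else t_end
    core <- simulate_core(x0, rho0_cells, params$eta, params$gamma, params$s,
                          params$rho0, numeric(0), eps_stop, out_dt, t_cap,
                          c1, c2, 5000000L)
    if (!core$converged)
      warn_mtc("mtc_convergence_warning",
               "t_end cap reached before the requested completion fraction")
  } else {
    if (is.null(out_times)) {
      if (is.null(t_end) || !(t_end > 0))
        stop_mtc("mtc_domain_error", "t_end must be positive")
      out_times <- seq(0, t_end, by = out_dt)
      if (out_times[length(out_times)] < t_end) out_times <- c(out_times, t_end)
    }
    if (is.unsorted(out_times, strictly = TRUE) || out_times[1] < 0)
      stop_mtc("mtc_domain_error", "out_times must be strictly increasing and >= 0")
    core <- simulate_core(x0, rho0_cells, params$eta, params$gamma, params$s,
                          params$rho0, out_times, -1, out_dt, Inf,
                          c1, c2, 5000000L)
  }

  times <- core$times
  widths <- core$positions[n_cells + 1, ] - core$positions[1, ]
  states <- lapply(seq_along(times), function(j)
    lagrangian_state(core$positions[, j], core$densities[, j], time = times[j]))
  structure(list(times = times,
                 states = states,
                 widths = widths,
                 epsilon = (W0 - widths) / W0,
                 velocities = core$velocities,
                 params = params,
                 geometry = geometry,
                 rho_init_ratio = rho_init_ratio,
                 expanding = rho_init_ratio > 1,
                 n_steps = core$n_steps),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("Contraction simulation: W0 = %g um, rho_init/rho0 = %g\n",
              x$geometry$W0, x$rho_init_ratio))
  cat(sprintf("  %d snapshots over %g min (%d internal steps)%s\n",
              length(x$times), max(x$times), x$n_steps,
              if (x$expanding) " [expanding]" else ""))
  cat(sprintf("  final epsilon = %.4f\n", x$epsilon[length(x$epsilon)]))
  invisible(x)
}

#' Total conserved mass of a simulation snapshot
#'
#' @param sim a `simulation_result`.
#' @return Vector of total mass per snapshot (constant to rounding).
#' @export
total_mass <- function(sim) {
  stopifnot(inherits(sim, "simulation_result"))
  vapply(sim$states, function(s) sum(s$cell_masses), numeric(1))
}

#' Interpolate a simulated density field at given positions
#'
#' Piecewise-constant (cell-wise) evaluation of `rho(x, t)` for one
#' snapshot; positions outside the network return 0.
#'
#' @param sim a `simulation_result`.
#' @param snapshot snapshot index.
#' @param positions positions, micrometres (channel-centred coordinates).
#' @return Densities at `positions`.
#' @export
density_at <- function(sim, snapshot, positions) {
  st <- sim$states[[snapshot]]
  idx <- findInterval(positions, st$node_positions,
                      rightmost.closed = TRUE, all.inside = FALSE)
  out <- numeric(length(positions))
  inside <- idx >= 1 & idx <= length(st$cell_densities) &
    positions >= st$node_positions[1] &
    positions <= st$node_positions[length(st$node_positions)]
  out[inside] <- st$cell_densities[pmin(idx[inside], length(st$cell_densities))]
  out
}

#' Pixel-integrated simulated density
#'
#' Mean density over each pixel footprint `[p - dx/2, p + dx/2]`, computed
#' from the (piecewise-linear) cumulative mass of the snapshot.  Pixels
#' partially covered by the network get the covered mass fraction, which is
#' how a camera samples a sharp free edge; unlike the point-sampled
#' [density_at()] this varies smoothly as the edge moves across a pixel.
#'
#' @param sim a `simulation_result`.
#' @param snapshot snapshot index.
#' @param positions pixel-centre positions, micrometres.
#' @param dx pixel width, micrometres (default: spacing of `positions`).
#' @return Mean densities, one per pixel.
#' @export
density_pixels <- function(sim, snapshot, positions, dx = NULL) {
  st <- sim$states[[snapshot]]
  if (is.null(dx)) dx <- mean(diff(positions))
  cum <- c(0, cumsum(st$cell_masses))
  M <- function(x) {
    x <- pmin(pmax(x, st$node_positions[1]),
              st$node_positions[length(st$node_positions)])
    approx(st$node_positions, cum, xout = x)$y
  }
  (M(positions + dx / 2) - M(positions - dx / 2)) / dx
}
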