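test_that("active stress has the saturating sign structure", {
  p <- model_params(eta = 1, gamma = 0, s = 1, rho0 = 1)
  expect_identical(active_stress(1, p), 0)            # preferred density
  expect_identical(active_stress(0, p), 0)            # vacuum
  expect_equal(active_stress(0.5, p), -0.25)          # minimum -s rho0^2 / 4
  expect_true(all(active_stress(seq(0.05, 0.95, by = 0.1), p) < 0))
  expect_true(active_stress(1.3, p) > 0)              # extensile above rho0
  p2 <- model_params(eta = 1, gamma = 0, s = 3, rho0 = 2)
  expect_equal(active_stress(1, p2), 3 * 1 * (1 - 2))
  expect_error(active_stress(-0.1, p), class = "mtc_domain_error")
})

test_that("reduced ratios are what the dynamics depend on", {
  p <- model_params(eta = 4.1, gamma = 5e-5, s = 5, rho0 = 1)
  expect_equal(eta_ratio(p), 0.82)
  expect_equal(gamma_ratio(p), 1e-5)
  p3 <- model_params(eta = 0.82 * 4, gamma = 1e-5 * 4, s = 1, rho0 = 2)
  expect_equal(eta_ratio(p3), 0.82)
})

test_that("force balance solves the free-boundary problem", {
  # uniform rho = rho0: no stress, homogeneous BCs, v = 0
  p <- model_params(eta = 1, gamma = 2e-4, s = 1, rho0 = 1)
  st <- lagrangian_state(seq(-50, 50, length.out = 65), rep(1, 64))
  expect_lt(max(abs(solve_force_balance(st, p))), 1e-12)

  # uniform rho < rho0, gamma = 0: uniform strain rate sigma/eta, centred
  p0 <- model_params(eta = 2, gamma = 0, s = 1, rho0 = 1)
  st2 <- lagrangian_state(seq(-100, 100, length.out = 81), rep(0.4, 80))
  v <- solve_force_balance(st2, p0)
  slope <- (0.4 * (0.4 - 1)) / 2
  expect_equal(v, slope * st2$node_positions, tolerance = 1e-10)

  # mirror-symmetric density: antisymmetric velocity
  x <- seq(-60, 60, length.out = 97)
  xc <- (x[-1] + x[-97]) / 2
  rho <- 0.3 + 0.2 * cos(pi * xc / 60)^2
  st_sym <- lagrangian_state(x, rho)
  vs <- solve_force_balance(st_sym, model_params(eta = 0.5, gamma = 1e-4))
  expect_equal(vs, -rev(vs), tolerance = 1e-9)

  # gamma > 0, arbitrary smooth density: matches the independent dense solve
  set.seed(11)
  x <- sort(runif(120, -70, 70)); x <- c(-75, x, 75)
  rho <- 0.3 + 0.15 * sin(seq_along(x)[-1] / 9) + 0.05
  st3 <- lagrangian_state(x, rho)
  p3 <- model_params(eta = 0.82, gamma = 6.1e-6, s = 1, rho0 = 1)
  v3 <- solve_force_balance(st3, p3)
  vd <- fb_dense_oracle(x, rho, 0.82, 6.1e-6)
  expect_lt(max(abs(v3 - vd)) / max(abs(vd)), 1e-6)

  expect_error(lagrangian_state(c(0, 0, 1), c(1, 1)),
               class = "mtc_invalid_state_error")
})

test_that("a step advects nodes and conserves mass exactly", {
  p <- model_params(eta = 1, gamma = 0, s = 1, rho0 = 1)
  st <- lagrangian_state(seq(-50, 50, length.out = 33), rep(0.4, 32))

  # v = 0 at equilibrium: state unchanged
  st_eq <- lagrangian_state(seq(-50, 50, length.out = 33), rep(1, 32))
  out <- step_state(st_eq, p, dt = 0.1)
  expect_equal(out$node_positions, st_eq$node_positions)
  expect_equal(out$cell_densities, st_eq$cell_densities)

  # uniform strain rate e: intervals shrink by (1 + e dt), densities divide
  out2 <- step_state(st, p, dt = 0.05)
  e <- 0.4 * (0.4 - 1)   # sigma / eta
  expect_equal(diff(out2$node_positions),
               diff(st$node_positions) * (1 + e * 0.05), tolerance = 1e-12)
  expect_equal(out2$cell_densities, st$cell_densities / (1 + e * 0.05),
               tolerance = 1e-12)
  expect_identical(out2$cell_masses, st$cell_masses)

  # too large a step crosses nodes
  st_sharp <- lagrangian_state(c(-1, -0.999, 0.999, 1), c(0.2, 0.5, 0.2))
  expect_error(step_state(st_sharp, model_params(eta = 1e-4, gamma = 0), dt = 50),
               class = "mtc_step_error")
})

test_that("equilibrium initial density is a fixed point", {
  p <- model_params_from_ratios(0.82, 1e-5)
  sim <- simulate_contraction(p, channel_geometry(440), rho_init_ratio = 1,
                              t_end = 3, n_cells = 32)
  expect_lt(max(abs(sim$epsilon)), 1e-12)
  expect_equal(sim$widths, rep(440, length(sim$times)))
})

test_that("gamma = 0 runs match the uniform-contraction ODE oracle", {
  skip_if_not_installed("deSolve")
  p <- model_params_from_ratios(0.82, 0)
  W0 <- 700; r <- 0.32
  sim <- simulate_contraction(p, channel_geometry(W0), r, t_end = 6,
                              n_cells = 256)
  W_ode <- ode_width_oracle(W0, 0.82, r, sim$times)
  expect_lt(max(abs(sim$widths - W_ode) / W_ode), 1e-4)
  # density stays spatially uniform
  rng <- range(sim$states[[length(sim$states)]]$cell_densities)
  expect_lt(diff(rng) / rng[1], 1e-8)
  # asymptote from mass conservation: eps -> 1 - r
  sim_inf <- simulate_contraction(p, channel_geometry(W0), r, n_cells = 64,
                                  stop_completion = 0.9995)
  expect_equal(sim_inf$epsilon[length(sim_inf$epsilon)], 1 - r,
               tolerance = 2e-3)
})

test_that("the stepper agrees with an independent method-of-lines integration", {
  skip_if_not_installed("deSolve")
  p <- model_params_from_ratios(0.82, 6.1e-6)
  W0 <- 700; r <- 0.32
  times <- seq(0, 4, by = 1 / 3)
  sim <- simulate_contraction(p, channel_geometry(W0), r, out_times = times,
                              n_cells = 96)
  eps_mol <- mol_epsilon_oracle(0.82, 6.1e-6, W0, r, times, n_cells = 96)
  expect_lt(max(abs(sim$epsilon - eps_mol)), 1e-4)
})

test_that("mass is conserved and widths shrink monotonically", {
  p <- model_params_from_ratios(0.82, 1e-5)
  sim <- simulate_contraction(p, channel_geometry(900), 0.32, t_end = 8,
                              n_cells = 128)
  m <- total_mass(sim)
  expect_lt(diff(range(m)) / m[1], 1e-10)
  expect_true(all(diff(sim$widths) <= 1e-12))
  expect_identical(sim$epsilon[1], 0)
  expect_true(all(sim$epsilon >= 0 & sim$epsilon < 1))

  # expansion: rho_init above the preferred density
  sim_up <- simulate_contraction(p, channel_geometry(300), 1.4, t_end = 2,
                                 n_cells = 32)
  expect_true(sim_up$expanding)
  expect_true(all(diff(sim_up$widths) >= -1e-12))
})

test_that("dynamics depend on (eta, gamma, s) only through the reduced ratios", {
  g <- channel_geometry(600)
  a <- simulate_contraction(model_params(eta = 0.82, gamma = 1e-5, s = 1, rho0 = 1),
                            g, 0.32, t_end = 4, n_cells = 64)
  b <- simulate_contraction(model_params(eta = 0.82 * 7, gamma = 1e-5 * 7, s = 7,
                                         rho0 = 1),
                            g, 0.32, t_end = 4, n_cells = 64)
  expect_lt(max(abs(a$epsilon - b$epsilon)), 1e-8)
})

test_that("epsilon(t_end) is grid-converged at the default resolution", {
  p <- model_params_from_ratios(0.82, 1e-5)
  g <- channel_geometry(900)
  e256 <- simulate_contraction(p, g, 0.32, t_end = 5, n_cells = 256)$epsilon
  e512 <- simulate_contraction(p, g, 0.32, t_end = 5, n_cells = 512)$epsilon
  expect_lt(abs(tail(e256, 1) - tail(e512, 1)) / tail(e512, 1), 1e-3)
})

test_that("drag produces transient density buildup at the free edges", {
  p <- model_params_from_ratios(0.82, 6.1e-6)
  sim <- simulate_contraction(p, channel_geometry(1400), 0.32, t_end = 3,
                              n_cells = 128)
  st <- sim$states[[length(sim$states)]]
  n <- length(st$cell_densities)
  edge <- max(st$cell_densities[c(1, n)])
  interior <- max(st$cell_densities[(n %/% 2 - 10):(n %/% 2 + 10)])
  expect_gt(edge, interior)
})

test_that("the fraction contracted is computed from widths", {
  expect_identical(epsilon_curve(100, 100), 0)
  expect_equal(epsilon_curve(50, 100), 0.5)
  expect_equal(epsilon_curve(0.23 * 1400, 1400), 0.77)
  expect_error(epsilon_curve(c(1, 2), -1), class = "mtc_domain_error")
  expect_warning(epsilon_curve(120, 100), class = "mtc_width_warning")
})
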