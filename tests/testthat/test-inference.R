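test_that("the relaxation fit recovers noiseless curve parameters exactly", {
  t <- seq(0, 25, by = 1 / 3)
  d <- generate_epsilon_data(0.81, 3.49, 1.06, t)
  f <- fit_contraction_curve(d$times, d$epsilon)
  expect_lt(abs(f$epsilon_inf - 0.81) / 0.81, 1e-6)
  expect_lt(abs(f$tau - 3.49) / 3.49, 1e-6)
  expect_lt(abs(f$Tc - 1.06) / 1.06, 1e-6)
  expect_lt(f$rss, 1e-12)
  expect_equal(f$n_points_used, sum(d$epsilon > 0.1))

  # fitted curve is non-negative and non-decreasing
  pred <- predict_contraction(f, seq(-1, 30, by = 0.1))
  expect_true(all(pred >= 0))
  expect_true(all(diff(pred) >= -1e-12))
})

test_that("a flat curve raises a not-contracted error", {
  t <- seq(0, 10, by = 0.5)
  expect_error(fit_contraction_curve(t, rep(0, length(t))),
               class = "mtc_not_contracted_error")
  # too few points above threshold
  eps <- c(rep(0, 18), 0.2, 0.2, 0.2)
  expect_error(fit_contraction_curve(t, eps),
               class = "mtc_not_contracted_error")
})

test_that("the relaxation fit is robust to noise and rescaling", {
  t <- seq(0, 25, by = 1 / 3)
  clean <- generate_epsilon_data(0.77, 3.0, 1.0, t)$epsilon
  taus <- vapply(seq_len(200), function(k) {
    d <- generate_epsilon_data(0.77, 3.0, 1.0, t, noise_sd = 0.01, seed = k)
    fit_contraction_curve(d$times, d$epsilon)$tau
  }, numeric(1))
  expect_lt(abs(median(taus) - 3.0) / 3.0, 0.02)

  # time-unit equivariance: seconds in, seconds out; eps_inf unchanged
  f_min <- fit_contraction_curve(t, clean)
  f_sec <- fit_contraction_curve(t * 60, clean)
  expect_equal(f_sec$tau, f_min$tau * 60, tolerance = 1e-6)
  expect_equal(f_sec$Tc, f_min$Tc * 60, tolerance = 1e-4)
  expect_equal(f_sec$epsilon_inf, f_min$epsilon_inf, tolerance = 1e-8)
})

test_that("sigmoid dose-response fit recovers the generating logistic", {
  cc <- c(0, 0.05, 0.1, 0.2, 0.4, 0.8, 1.6, 3.2)
  tab <- generate_dose_response(0.22, 2, 3, 75, cc)$table
  f <- fit_sigmoid_dose_response(cc, tab$tau)
  expect_equal(f$ec50, 0.22, tolerance = 1e-6)
  expect_equal(f$hill, 2, tolerance = 1e-5)
  expect_equal(f$tau_low, 3, tolerance = 1e-6)
  expect_equal(f$tau_high, 75, tolerance = 1e-5)

  # at c = ec50 the response is midway between plateaus, for any hill
  for (h in c(1, 2, 4)) {
    tau_mid <- generate_dose_response(0.22, h, 3, 75, c(0, 0.22, 1, 5))$table$tau[2]
    expect_equal(tau_mid, (3 + 75) / 2, tolerance = 1e-12)
  }

  # 5% noise, 100 replicates: median EC50 within 10%
  ec <- vapply(seq_len(100), function(k) {
    tabk <- generate_dose_response(0.22, 2, 3, 75, cc, noise_cv = 0.05,
                                   seed = k)$table
    # occasional noisy draws are locally non-monotone, which rightly warns
    suppressWarnings(fit_sigmoid_dose_response(cc, tabk$tau)$ec50)
  }, numeric(1))
  expect_lt(abs(median(ec) - 0.22) / 0.22, 0.10)

  # strongly decreasing data flag a poor fit
  expect_warning(fit_sigmoid_dose_response(cc, c(75, 60, 40, 20, 10, 5, 3, 2)),
                 class = "mtc_poor_fit_warning")
})

test_that("final-density estimation projects fluorescence to t = infinity", {
  t <- seq(0, 25, by = 1 / 3)
  fit <- fit_contraction_curve(t, generate_epsilon_data(0.77, 3.49, 1.06, t)$epsilon)

  # fractional concentration 0.335 with eps_inf = 0.77: factor ~4.98, ~30 uM
  est <- estimate_final_density(200.75, 100, fit)
  expect_equal(est$fractional_concentration, 0.335, tolerance = 1e-4)
  expect_equal(est$projection_factor, 4.98, tolerance = 0.01)
  expect_equal(est$tubulin_concentration, 30, tolerance = 0.1)

  # equal network and monomer signal: zero everywhere
  est0 <- estimate_final_density(100, 100, fit)
  expect_identical(est0$fractional_concentration, 0)
  expect_identical(est0$tubulin_concentration, 0)

  # no monomer background: fraction 1
  est1 <- estimate_final_density(100, 0, fit)
  expect_identical(est1$fractional_concentration, 1)

  expect_error(estimate_final_density(90, 100, fit),
               class = "mtc_no_network_error")
})

test_that("profile fitting recovers the generating parameters", {
  p <- model_params_from_ratios(0.82, 6.1e-6)
  g <- channel_geometry(1400)
  times <- seq(2 / 3, 14 / 3, by = 1 / 3)   # one profile per 20-s frame
  gen <- generate_profile_data(p, 0.32, g, times)
  fit <- fit_density_profiles(gen$profiles, times, g)
  expect_lt(abs(fit$eta_ratio - 0.82) / 0.82, 0.01)
  expect_lt(abs(fit$gamma_ratio - 6.1e-6) / 6.1e-6, 0.01)
  expect_lt(abs(fit$rho_init_ratio - 0.32) / 0.32, 0.01)
  expect_false(fit$degenerate)

  # the objective at truth is a local minimum: perturbing any single
  # parameter away from truth increases the mismatch
  obj <- function(er, gr, r) {
    sim <- simulate_contraction(model_params_from_ratios(er, gr), g, r,
                                out_times = times - times[1], n_cells = 128)
    ss <- 0
    for (j in seq_along(gen$profiles)) {
      pos <- gen$profiles[[j]]$positions
      dx <- mean(diff(pos))
      full <- seq(-g$W0 / 2 + dx / 2, g$W0 / 2, by = dx)
      meas <- numeric(length(full))
      meas[findInterval(pos, full - dx / 2)] <- gen$profiles[[j]]$intensity
      q <- density_pixels(sim, j, full, dx)
      q <- q / (sum(q) * dx)
      ss <- ss + sum((q - meas)^2)
    }
    ss
  }
  f0 <- obj(0.82, 6.1e-6, 0.32)
  expect_lt(f0, 1e-10)
  for (d in list(c(1.05, 1, 1), c(0.95, 1, 1), c(1, 1.05, 1), c(1, 0.95, 1),
                 c(1, 1, 1.02), c(1, 1, 0.98)))
    expect_gt(obj(0.82 * d[1], 6.1e-6 * d[2], 0.32 * d[3]), f0 + 1e-8)
})

test_that("static uniform profiles are flagged as degenerate", {
  g <- channel_geometry(1400)
  pos <- seq(-690, 690, by = 3.25)
  profs <- lapply(1:4, function(k)
    new_density_profile(pos, rep(1, length(pos)), time = k))
  expect_warning(fit_density_profiles(profs, 1:4, g,
                                      optimizer = list(maxit = 20, n_cells = 32)),
                 class = "mtc_degenerate_fit_warning")
})
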