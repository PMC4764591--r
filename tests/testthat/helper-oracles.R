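# Independent oracles used to cross-check the simulator.  All are written
# against the continuum equations directly and share no code with the
# package's C++ kernel.

# Uniform-contraction ODE oracle for gamma = 0: the density stays spatially
# uniform, so dW/dt = (s/eta) rho (rho - rho0) W with rho = r rho0 W0 / W.
ode_width_oracle <- function(W0, eta_ratio, r, times) {
  rhs <- function(t, W, parms) {
    rho <- r * W0 / W
    list((1 / eta_ratio) * rho * (rho - 1) * W)
  }
  out <- deSolve::ode(y = c(W = W0), times = times, func = rhs, parms = NULL,
                      rtol = 1e-10, atol = 1e-10)
  unname(out[, "W"])
}

# Independent dense-matrix force-balance solve on a given grid (gamma > 0):
# same discretization written from scratch, solved with base::solve.
fb_dense_oracle <- function(x, rho, eta, gamma, s = 1, rho0 = 1) {
  N <- length(rho); n <- N + 1
  h <- diff(x)
  sig <- s * rho * (rho - rho0)
  A <- matrix(0, n, n); b <- numeric(n)
  A[1, 1] <- -eta / h[1]; A[1, 2] <- eta / h[1]; b[1] <- sig[1]
  A[n, n] <- eta / h[N]; A[n, n - 1] <- -eta / h[N]; b[n] <- sig[N]
  for (i in 2:(n - 1)) {
    hl <- h[i - 1]; hr <- h[i]; hm <- (hl + hr) / 2
    A[i, i - 1] <- eta / (hl * hm)
    A[i, i] <- -eta * (1 / hl + 1 / hr) / hm - gamma
    A[i, i + 1] <- eta / (hr * hm)
    b[i] <- (sig[i] - sig[i - 1]) / hm
  }
  solve(A, b)
}

# Method-of-lines oracle: node positions as the ODE state (fixed mass
# coordinates), velocities from the independent dense solve, integrated
# with lsoda.  Independent of the package's explicit stepper.
mol_epsilon_oracle <- function(eta_ratio, gamma_ratio, W0, r, times, n_cells) {
  x0 <- seq(-W0 / 2, W0 / 2, length.out = n_cells + 1)
  mass <- rep(r, n_cells) * diff(x0)
  rhs <- function(t, x, parms) {
    rho <- mass / diff(x)
    list(fb_dense_oracle(x, rho, eta_ratio, gamma_ratio))
  }
  out <- deSolve::lsoda(y = x0, times = times, func = rhs, parms = NULL,
                        rtol = 1e-8, atol = 1e-8)
  W <- out[, n_cells + 2] - out[, 2]
  (W0 - W) / W0
}

# A clean horizontal band image: rows band_rows at level `fg` over `bg`.
band_frame <- function(nr, nc, band_rows, fg, bg) {
  f <- matrix(bg, nr, nc)
  f[band_rows, ] <- fg
  f
}
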