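# Fixed-step classical 4th-order Runge-Kutta integrator, independent of the
# adaptive deSolve path. Used as the numerical oracle for solver checks.
rk4_fixed <- function(y0, t_end, dt, rhs, parms, t_out) {
  n_steps <- round(t_end / dt)
  stopifnot(abs(n_steps * dt - t_end) < 1e-9)
  y <- y0
  t <- 0
  out <- matrix(NA_real_, nrow = length(t_out), ncol = length(y0))
  k_out <- 1L
  record <- function(k_out, t, y) {
    while (k_out <= length(t_out) && t_out[k_out] <= t + 1e-12) {
      out[k_out, ] <<- y
      k_out <- k_out + 1L
    }
    k_out
  }
  k_out <- record(k_out, t, y)
  for (i in seq_len(n_steps)) {
    k1 <- rhs(t, y, parms)[[1L]]
    k2 <- rhs(t + dt / 2, y + dt / 2 * k1, parms)[[1L]]
    k3 <- rhs(t + dt / 2, y + dt / 2 * k2, parms)[[1L]]
    k4 <- rhs(t + dt, y + dt * k3, parms)[[1L]]
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- i * dt
    k_out <- record(k_out, t, y)
  }
  out
}

# Convenience: integrate one scenario with the oracle on a coarse output grid.
oracle_trajectory <- function(sc, t_out, dt = 1e-3) {
  k <- sc$constants
  V_i0 <- intracellular_volume(k$N0, k)
  parms <- list(constants = k, promoter = sc$promoter,
                total_il = (sc$il_mM / 1000) * (k$culture_volume - V_i0))
  y0 <- c(N = k$N0, S = k$S0, p = initial_pump_state(sc$promoter, k), c_i = 0)
  out <- rk4_fixed(y0, max(t_out), dt, model_rhs, parms, t_out)
  colnames(out) <- names(y0)
  out
}
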