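# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: finite differences instead of the analytic
# Jacobian, a direct tight-tolerance integration of the scalar tumor ODE
# instead of the closed form, and raw hand formulas for carrying levels.

# central finite-difference Jacobian of the healthy vector field
fd_jacobian <- function(point, params, h = 1e-6) {
  vars <- c("P", "L", "F")
  J <- matrix(0, 3, 3, dimnames = list(vars, vars))
  for (j in vars) {
    up <- point; up[j] <- up[j] + h
    dn <- point; dn[j] <- dn[j] - h
    J[, j] <- (rhs_healthy(up, params) - rhs_healthy(dn, params)) / (2 * h)
  }
  J
}

# scalar Gompertz ODE integrated on its own at very tight tolerances
gompertz_numeric <- function(times, T0, params) {
  sol <- deSolve::ode(
    y = c(T = T0), times = times,
    func = function(t, y, p) list(p$gamma_T * y * log(p$T_S / y)),
    parms = params, method = "lsoda", rtol = 1e-12, atol = 1e-14)
  sol[, "T"]
}

# random smooth interior state of the healthy model (clips inactive)
random_interior_state <- function(params) {
  hats <- derived_quantities(params)
  c(P = runif(1, 1, 2 * interior_P_star(params)),
    L = runif(1, 0.1, 0.99 * min(params$L_S, hats$L_hat)),
    F = runif(1, 0.1, 0.99 * hats$F_hat))
}

# interior target point the healthy dynamics should settle on
healthy_target <- function(params) {
  c(P = interior_P_star(params), L = params$L_min, F = params$F_max)
}
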