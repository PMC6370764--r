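# Right-hand sides of the two ODE systems, term-by-term evaluators, and the
# closed-form Gompertz solution.
#
# Healthy system (state P, L, F):
#   dP/dt = beta_P (1 - L/L_S)_+^g1 P^g2  -  mu_P P            [terms A, B]
#   dL/dt = gamma_L L (1 - L/L_hat)_+     -  mu_L L            [terms C, D]
#   dF/dt = gamma_F F (1 - F/F_hat)_+     -  mu_F F            [terms E, F]
#
# Tumor system (state P, L, F, T) adds an EMT sink/source pair and a
# plasma-cell FLC source, with Gompertz forcing:
#   dP/dt = A' - B' - gamma_F L^g3 P^g4                        [terms G, H, I]
#   dL/dt = C' + gamma_L T^g5 L^g6 - D'                        [terms J, K, L]
#   dF/dt = E' + gamma_F L^g3 P^g4 - F'                        [terms M, N, O]
#   dT/dt = gamma_T T ln(T_S / T)                              [term  P]
# Term N is, by construction, the same expression as term I.

# Negative components below this magnitude are treated as solver round-off
# and clamped to zero; anything more negative is a contract violation.
.neg_tol <- 1e-12

#' Positive-part (clipping) operator
#'
#' `clip_plus(x) = max(x, 0)`, applied to the logistic factors so that
#' growth terms never turn negative when a population overshoots its
#' carrying level (decline is the decay terms' job).
#'
#' @param x numeric vector.
#' @return `pmax(x, 0)`.
#' @examples
#' clip_plus(c(-0.5, 0, 0.37))   # 0 0 0.37
#' @export
clip_plus <- function(x) {
  pmax(x, 0)
}

# x^g with the boundary convention 0^g := 0 for all g > 0, so the origin is
# a fixed point and fractional powers are defined on the state-space boundary.
.pow0 <- function(x, g) {
  ifelse(x <= 0, 0, x^g)
}

# Clamp round-off-sized negative components to 0; error on real negatives.
.clamp_state <- function(state, what = "state") {
  bad <- state < -.neg_tol
  if (any(bad)) {
    stop(what, " has negative component(s): ",
         paste(names(state)[bad], collapse = ", "), call. = FALSE)
  }
  pmax(state, 0)
}

#' Term-by-term evaluation of the healthy system
#'
#' Evaluates the six labelled terms of the healthy three-population system
#' at a given state, mainly for documentation and testing; [rhs_healthy()]
#' assembles the rate vector from these.
#'
#' @param state named numeric vector `c(P=, L=, F=)`, all components
#'   non-negative (P percent, L mg/L, F percent).
#' @param params an `flc_params` object.
#' @return Named list of the term values `A`..`F` (signs as they enter the
#'   equations are applied in [rhs_healthy()]; all terms here are the
#'   non-negative magnitudes).
#' @export
terms_healthy <- function(state, params) {
  stopifnot(inherits(params, "flc_params"))
  s <- .clamp_state(state[c("P", "L", "F")])
  dq <- .carrying_levels(params)
  P <- s[["P"]]; L <- s[["L"]]; F <- s[["F"]]
  list(
    A = params$beta_P * clip_plus(1 - L / params$L_S)^params$g1 *
      .pow0(P, params$g2),
    B = params$mu_P * P,
    C = params$gamma_L * L * clip_plus(1 - L / dq$L_hat),
    D = params$mu_L * L,
    E = params$gamma_F * F * clip_plus(1 - F / dq$F_hat),
    F = params$mu_F * F
  )
}

#' Rate vector of the healthy three-population system
#'
#' @inheritParams terms_healthy
#' @return Named numeric vector `c(P=, L=, F=)` of time derivatives
#'   (percent/day, mg/L/day, percent/day).
#' @examples
#' p <- default_parameters()
#' rhs_healthy(c(P = 100, L = 10, F = 100), p)  # ~ (0, 0, 0): steady state
#' @export
rhs_healthy <- function(state, params) {
  tm <- terms_healthy(state, params)
  c(P = tm$A - tm$B, L = tm$C - tm$D, F = tm$E - tm$F)
}

#' Term-by-term evaluation of the tumor-forced system
#'
#' Evaluates the ten labelled terms `G`..`P` of the four-population system.
#' Term `I` (loss of proximal tubule cells to epithelial-mesenchymal
#' transition) and term `N` (the matching fibroblast gain) are the same
#' expression and are guaranteed to be bitwise equal.
#'
#' @param state named numeric vector `c(P=, L=, F=, T=)`; `T` must be
#'   strictly positive (the Gompertz log requires it).
#' @param params an `flc_params` object.
#' @return Named list of term values `G`, `H`, `I`, `J`, `K`, `L`, `M`,
#'   `N`, `O`, `P_` (the Gompertz term is named `P_` to avoid clashing with
#'   the state variable P).
#' @export
terms_tumor <- function(state, params) {
  stopifnot(inherits(params, "flc_params"))
  s <- .clamp_state(state[c("P", "L", "F")])
  T <- state[["T"]]
  if (!is.finite(T) || T <= 0) {
    stop("tumor burden T must be strictly positive (got ", T, ")",
         call. = FALSE)
  }
  dq <- .carrying_levels(params)
  P <- s[["P"]]; L <- s[["L"]]; F <- s[["F"]]
  emt <- params$gamma_F * .pow0(L, params$g3) * .pow0(P, params$g4)
  list(
    G = params$beta_P * clip_plus(1 - L / params$L_S)^params$g1 *
      .pow0(P, params$g2),
    H = params$mu_P * P,
    I = emt,
    J = params$gamma_L * L * clip_plus(1 - L / dq$L_hat),
    K = params$gamma_L * .pow0(T, params$g5) * .pow0(L, params$g6),
    L = params$mu_L * L,
    M = params$gamma_F * F * clip_plus(1 - F / dq$F_hat),
    N = emt,
    O = params$mu_F * F,
    P_ = params$gamma_T * T * log(params$T_S / T)
  )
}

#' Rate vector of the tumor-forced four-population system
#'
#' @inheritParams terms_tumor
#' @return Named numeric vector `c(P=, L=, F=, T=)` of time derivatives.
#' @examples
#' p <- default_parameters()
#' rhs_tumor(c(P = 100, L = 10, F = 100, T = 1), p)[["T"]]  # 0.05 * ln(100)
#' @export
rhs_tumor <- function(state, params) {
  tm <- terms_tumor(state, params)
  c(P = tm$G - tm$H - tm$I,
    L = tm$J + tm$K - tm$L,
    F = tm$M + tm$N - tm$O,
    T = tm$P_)
}

#' Closed-form solution of the Gompertz tumor equation
#'
#' The tumor equation `dT/dt = gamma_T T ln(T_S / T)` decouples from the
#' rest of the system and integrates exactly to
#' \deqn{T(t) = T_S \exp\{\ln(T_0/T_S)\, e^{-\gamma_T t}\}.}
#' The solution is monotone increasing towards the carrying capacity `T_S`
#' whenever `T0 < T_S`. The logarithm is natural, following Gompertz-model
#' convention.
#'
#' @param t time(s) in days, `t >= 0`; vectorised.
#' @param T0 initial tumor burden in percent, `0 < T0 <= T_S`.
#' @param params an `flc_params` object (uses `gamma_T`, `T_S`).
#' @return Tumor burden at `t`, percent.
#' @examples
#' gompertz_exact(0, 1, default_parameters())     # 1
#' gompertz_exact(1000, 1, default_parameters())  # ~ 100
#' @export
gompertz_exact <- function(t, T0, params) {
  stopifnot(inherits(params, "flc_params"))
  if (!is.numeric(T0) || length(T0) != 1 || !is.finite(T0) || T0 <= 0) {
    stop("T0 must be a strictly positive scalar", call. = FALSE)
  }
  if (T0 > params$T_S) {
    stop("T0 must not exceed the carrying capacity T_S", call. = FALSE)
  }
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  params$T_S * exp(log(T0 / params$T_S) * exp(-params$gamma_T * t))
}

# Internal RHS wrappers in deSolve's func(t, y, parms) signature. These
# tolerate the solver probing slightly outside the admissible region:
# components are floored at 0 (the exported rhs_* functions keep the strict
# contract and error instead).
.rhs_healthy_solver <- function(t, y, parms) {
  p <- parms$params
  dq <- parms$dq
  P <- max(y[[1]], 0); L <- max(y[[2]], 0); F <- max(y[[3]], 0)
  dP <- p$beta_P * max(1 - L / p$L_S, 0)^p$g1 * .pow0(P, p$g2) - p$mu_P * P
  dL <- p$gamma_L * L * max(1 - L / dq$L_hat, 0) - p$mu_L * L
  dF <- p$gamma_F * F * max(1 - F / dq$F_hat, 0) - p$mu_F * F
  list(c(dP, dL, dF))
}

.rhs_tumor_solver <- function(t, y, parms) {
  p <- parms$params
  dq <- parms$dq
  P <- max(y[[1]], 0); L <- max(y[[2]], 0); F <- max(y[[3]], 0)
  T <- max(y[[4]], 0)
  emt <- p$gamma_F * .pow0(L, p$g3) * .pow0(P, p$g4)
  dP <- p$beta_P * max(1 - L / p$L_S, 0)^p$g1 * .pow0(P, p$g2) -
    p$mu_P * P - emt
  dL <- p$gamma_L * L * max(1 - L / dq$L_hat, 0) +
    p$gamma_L * .pow0(T, p$g5) * .pow0(L, p$g6) - p$mu_L * L
  dF <- p$gamma_F * F * max(1 - F / dq$F_hat, 0) + emt - p$mu_F * F
  # T log(T_S/T) -> 0 as T -> 0+; define the limit to keep the RHS finite.
  dT <- if (T > 0) p$gamma_T * T * log(p$T_S / T) else 0
  list(c(dP, dL, dF, dT))
}
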