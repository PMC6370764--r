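# Structural enumeration of the healthy system's eight steady states,
# closed-form interior equilibrium, analytic Jacobian, and stability
# classification.
#
# Each equilibrium has every component either "off" (0) or at its nontrivial
# level: P at the closed-form P*(L), L at L_min, F at F_max. Enumerating the
# 2^3 on/off patterns reproduces the complete steady-state census of the
# clipped system without multi-start root finding (which would chase
# spurious roots of the non-smooth clip).

# Real parts closer to zero than this are treated as numerically zero when
# deciding hyperbolicity (double-precision noise floor relative to rate
# coefficients of order 1e-3).
.eig_tol <- 1e-12

#' Closed-form interior proximal-tubule-cell equilibrium
#'
#' The nonzero-P balance of growth against apoptosis,
#' `beta_P (1 - L/L_S)^g1 P^g2 = mu_P P`, solves to
#' \deqn{P^*(L) = \left(\frac{\mu_P}{\beta_P}\,
#'   \Big(1 - \frac{L}{L_S}\Big)^{-g_1}\right)^{1/(g_2 - 1)}.}
#' With the published defaults and `L = L_min = 10` mg/L this evaluates to
#' 100% -- `g2`'s 15 printed digits are calibrated for exactly that.
#'
#' @param params an `flc_params` object.
#' @param L free light chain concentration in mg/L at which to evaluate;
#'   must satisfy `L < L_S`. Defaults to `params$L_min` (the interior
#'   equilibrium's own L-component).
#' @return Equilibrium PTC level, percent.
#' @examples
#' interior_P_star(default_parameters())        # 100
#' interior_P_star(default_parameters(), L = 0) # (beta_P/mu_P)^(1/(1-g2))
#' @export
interior_P_star <- function(params, L = params$L_min) {
  stopifnot(inherits(params, "flc_params"))
  if (params$g2 == 1) {
    stop("P* is undefined when g2 = 1 (exponent 1/(g2-1) diverges)",
         call. = FALSE)
  }
  if (L >= params$L_S) {
    stop("P* requires L < L_S (growth is fully suppressed beyond L_S)",
         call. = FALSE)
  }
  (params$mu_P / params$beta_P *
     (1 - L / params$L_S)^(-params$g1))^(1 / (params$g2 - 1))
}

#' Analytic Jacobian of the healthy system
#'
#' Partial derivatives of [rhs_healthy()] at a point strictly inside the
#' smooth region: `P > 0`, `L < L_S`, `L < L_hat`, `F < F_hat` (there the
#' clips are inactive and all powers differentiable). In the state ordering
#' `(P, L, F)` the matrix is
#' \preformatted{
#'   [ beta_P g2 (1-L/L_S)^g1 P^(g2-1) - mu_P,  -beta_P g1/L_S (1-L/L_S)^(g1-1) P^g2,  0 ]
#'   [ 0,                    gamma_L (1 - 2L/L_hat) - mu_L,                           0 ]
#'   [ 0,                    0,                    gamma_F (1 - 2F/F_hat) - mu_F        ]
#' }
#' which is triangular, so its eigenvalues are the diagonal entries; at the
#' interior equilibrium these reduce to `mu_P (g2 - 1)`, `mu_L - gamma_L`
#' and `mu_F - gamma_F`.
#'
#' At `P = 0` the derivative of `P^g2` (with `g2 < 1`) is unbounded, so the
#' Jacobian does not exist there and a `boundary-point` error is signalled;
#' use the perturbation probe in [classify_stability()] instead.
#'
#' @param point named numeric vector `c(P=, L=, F=)`.
#' @param params an `flc_params` object (regime `gamma_L > mu_L`,
#'   `gamma_F > mu_F` so the carrying levels exist).
#' @return 3x3 numeric matrix with dimnames `P`, `L`, `F`.
#' @export
jacobian_healthy <- function(point, params) {
  stopifnot(inherits(params, "flc_params"))
  dq <- .carrying_levels(params)
  P <- point[["P"]]; L <- point[["L"]]; F <- point[["F"]]
  # the logistic clips are inactive iff 1 - x/hat > 0; with a negative hat
  # (decay-dominated regime) that holds for every non-negative x
  if (P <= 0 || L >= params$L_S ||
      (dq$L_hat > 0 && L >= dq$L_hat) || (dq$F_hat > 0 && F >= dq$F_hat)) {
    stop("boundary-point: Jacobian requires P > 0, L < min(L_S, L_hat), ",
         "F < F_hat", call. = FALSE)
  }
  J <- matrix(0, 3, 3, dimnames = list(c("P", "L", "F"), c("P", "L", "F")))
  sat <- 1 - L / params$L_S
  J["P", "P"] <- params$beta_P * params$g2 * sat^params$g1 *
    P^(params$g2 - 1) - params$mu_P
  J["P", "L"] <- -params$beta_P * params$g1 / params$L_S *
    sat^(params$g1 - 1) * P^params$g2
  J["L", "L"] <- params$gamma_L * (1 - 2 * L / dq$L_hat) - params$mu_L
  J["F", "F"] <- params$gamma_F * (1 - 2 * F / dq$F_hat) - params$mu_F
  J
}

# Table of the eight structural steady states and the stability requirement
# attached to each on/off pattern. P-on rows need g2 < 1; P-off rows need
# only mu_P > 0 (always true here). The gamma_L and gamma_F requirements
# flip direction with the corresponding component's on/off status.
.equilibrium_conditions <- function(P_on, L_on, F_on, params) {
  conds <- c(
    gamma_F = if (F_on) params$gamma_F > params$mu_F
              else params$gamma_F < params$mu_F,
    gamma_L = if (L_on) params$gamma_L > params$mu_L
              else params$gamma_L < params$mu_L,
    third   = if (P_on) params$g2 < 1 else params$mu_P > 0
  )
  labels <- c(
    gamma_F = if (F_on) "gamma_F > mu_F" else "gamma_F < mu_F",
    gamma_L = if (L_on) "gamma_L > mu_L" else "gamma_L < mu_L",
    third   = if (P_on) "g2 < 1" else "mu_P > 0"
  )
  list(holds = conds, labels = labels)
}

#' Enumerate the eight steady states of the healthy system
#'
#' Every combination of `P` in `{0, P*(L)}`, `L` in `{0, L_min}` and `F` in
#' `{0, F_max}` is a steady state of the healthy system, giving exactly
#' eight; only the all-nonzero one, `(P*, L_min, F_max)`, is biologically
#' meaningful for a healthy patient. Each equilibrium is returned with the
#' stability requirements attached to its structural form, its residual
#' under [rhs_healthy()], and (when `classify = TRUE`) its eigenvalue or
#' perturbation-probe classification from [classify_stability()].
#'
#' @param params an `flc_params` object.
#' @param classify logical; also run [classify_stability()] on each
#'   equilibrium (default `TRUE`).
#' @return An object of class `flc_equilibria`: a list of eight
#'   `flc_equilibrium` objects, ordered with all-nonzero first and the
#'   origin last.
#' @examples
#' eqs <- enumerate_equilibria(default_parameters())
#' eqs[[1]]$point    # ~ (100, 10, 100)
#' @export
enumerate_equilibria <- function(params, classify = TRUE) {
  stopifnot(inherits(params, "flc_params"))
  if (params$g2 == 1) {
    stop("equilibrium enumeration requires g2 != 1 (P* undefined)",
         call. = FALSE)
  }
  grid <- expand.grid(P_on = c(TRUE, FALSE), L_on = c(TRUE, FALSE),
                      F_on = c(TRUE, FALSE))
  # order: interior first, origin last
  grid <- grid[order(-(grid$P_on + grid$L_on + grid$F_on),
                     -grid$P_on, -grid$L_on), ]
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    P_on <- grid$P_on[i]; L_on <- grid$L_on[i]; F_on <- grid$F_on[i]
    L <- if (L_on) params$L_min else 0
    P <- if (P_on) interior_P_star(params, L) else 0
    F <- if (F_on) params$F_max else 0
    point <- c(P = P, L = L, F = F)
    cc <- .equilibrium_conditions(P_on, L_on, F_on, params)
    eq <- structure(
      list(point = point,
           occupied = c(P = P_on, L = L_on, F = F_on),
           conditions = cc$holds,
           condition_labels = cc$labels,
           residual = max(abs(rhs_healthy(point, params))),
           eigenvalues = NULL,
           classification = NA_character_,
           classification_method = NA_character_),
      class = "flc_equilibrium")
    if (classify) eq <- classify_stability(eq, params)
    out[[i]] <- eq
  }
  structure(out, class = "flc_equilibria")
}

#' Classify the stability of a steady state
#'
#' For equilibria with `P > 0` the vector field is smooth, so the point is
#' classified from the eigenvalues of the analytic Jacobian: `stable` if
#' every real part is below `-1e-12`, `unstable` if any exceeds `+1e-12`,
#' `boundary-nonhyperbolic` otherwise.
#'
#' At `P = 0` the sublinear growth term `P^g2` has unbounded derivative and
#' linearisation fails, so a numerical perturbation probe is used instead:
#' the healthy model is integrated from `point + 1e-3` (componentwise) over
#' 5000 days and the point is called `stable` only if the trajectory is
#' back within `1e-3` relative (absolute, for zero components). The
#' structural stability requirements (the `conditions` field) are reported
#' alongside but never forced to agree with the probe: with `g2 < 1` the
#' sublinear production beats linear apoptosis near `P = 0`, so P-off
#' equilibria are empirically repelling in the P direction even though
#' their nominal requirement is just `mu_P > 0`.
#'
#' @param eq an `flc_equilibrium` (from [enumerate_equilibria()]).
#' @param params the `flc_params` the equilibrium was computed under.
#' @return The equilibrium with `eigenvalues`, `classification` and
#'   `classification_method` filled in.
#' @export
classify_stability <- function(eq, params) {
  stopifnot(inherits(eq, "flc_equilibrium"), inherits(params, "flc_params"))
  if (eq$occupied[["P"]]) {
    J <- jacobian_healthy(eq$point, params)
    ev <- eigen(J, only.values = TRUE)$values
    re <- Re(ev)
    eq$eigenvalues <- ev
    eq$classification <- if (all(re < -.eig_tol)) "stable"
      else if (any(re > .eig_tol)) "unstable"
      else "boundary-nonhyperbolic"
    eq$classification_method <- "jacobian"
  } else {
    delta <- 1e-3
    traj <- integrate_model("healthy", eq$point + delta, params,
                            t_end = 5000, output_step = 50)
    terminal <- traj$states[nrow(traj$states), c("P", "L", "F")]
    scale <- pmax(abs(eq$point), 1)   # relative, absolute for zero comps
    eq$eigenvalues <- NULL
    eq$classification <- if (all(abs(terminal - eq$point) / scale <= 1e-3))
      "stable" else "unstable"
    eq$classification_method <- "perturbation-probe"
  }
  eq
}

#' @export
print.flc_equilibrium <- function(x, ...) {
  cat(sprintf("Steady state (P, L, F) = (%.6g, %.6g, %.6g)\n",
              x$point[["P"]], x$point[["L"]], x$point[["F"]]))
  cat("  requirements:",
      paste(sprintf("%s [%s]", x$condition_labels,
                    ifelse(x$conditions, "holds", "fails")),
            collapse = ", "), "\n")
  if (!is.null(x$eigenvalues)) {
    cat("  eigenvalues:",
        paste(format(x$eigenvalues, digits = 6), collapse = ", "), "\n")
  }
  cat(sprintf("  classification: %s (%s)\n",
              x$classification, x$classification_method))
  invisible(x)
}

#' @export
print.flc_equilibria <- function(x, ...) {
  cat("Steady-state census of the healthy system (", length(x),
      " equilibria)\n\n", sep = "")
  for (eq in x) print(eq)
  invisible(x)
}

#' Tabulate an equilibrium census
#'
#' @param x an `flc_equilibria` object.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return A data frame with one row per equilibrium: point components,
#'   eigenvalues (NA for perturbation-probed points), classification and
#'   the three structural stability-condition booleans.
#' @export
as.data.frame.flc_equilibria <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  rows <- lapply(x, function(eq) {
    ev <- eq$eigenvalues
    ev <- if (is.null(ev)) rep(NA_real_, 3) else sort(Re(ev))
    data.frame(P = eq$point[["P"]], L = eq$point[["L"]], F = eq$point[["F"]],
               eig1 = ev[1], eig2 = ev[2], eig3 = ev[3],
               classification = eq$classification,
               method = eq$classification_method,
               cond_gammaF = eq$conditions[["gamma_F"]],
               cond_gammaL = eq$conditions[["gamma_L"]],
               cond_third = eq$conditions[["third"]],
               cond_third_label = eq$condition_labels[["third"]])
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
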