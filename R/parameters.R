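# Model constants, derived carrying levels, and regime validation.
#
# Naming convention (code name -> conventional symbol, units):
#   beta_P  -> beta_P,  PTC proliferation constant        [1/days]
#   mu_P    -> mu_P,    PTC natural apoptosis rate        [1/days]
#   gamma_L -> gamma_L, FLC growth constant               [1/(% cells days)]
#   mu_L    -> mu_L,    FLC natural clearance rate        [1/days]
#   gamma_F -> gamma_F, fibroblast growth constant        [L/(mg days)]
#   mu_F    -> mu_F,    fibroblast apoptosis rate         [1/days]
#   gamma_T -> gamma_T, tumor growth constant             [1/days]
#   L_S     -> L_S,     FLC saturation constant           [mg/L]
#   L_min   -> L_min,   minimum FLC level                 [mg/L]
#   F_max   -> F_max,   maximum fibroblast population     [percent]
#   T_S     -> T_S,     tumor saturation level            [percent]
#   g1..g6  -> kinetic-order exponents                    [dimensionless]
#
# Units are metadata by convention (P, F, T in percent of baseline; L in
# mg/L; t in days) and are never converted. gamma_L and gamma_F are each a
# single scalar reused wherever the symbol recurs across terms.

.param_names <- c(
  "beta_P", "mu_P", "gamma_L", "mu_L", "gamma_F", "mu_F", "gamma_T",
  "L_S", "L_min", "F_max", "T_S",
  "g1", "g2", "g3", "g4", "g5", "g6"
)

.param_defaults <- list(
  beta_P  = 0.055,
  mu_P    = 0.045,
  gamma_L = 0.005,
  mu_L    = 0.0005,
  gamma_F = 0.004,
  mu_F    = 0.00046,
  gamma_T = 0.05,
  L_S     = 1000,
  L_min   = 10,
  F_max   = 100,
  T_S     = 100,
  g1      = 1,
  g2      = 0.958607314841775,  # full printed precision; tuned so P* = 100
  g3      = 0.5,
  g4      = 0.38,
  g5      = 0.8,
  g6      = 0.7
)

#' Construct a parameter set for the fibrosis model
#'
#' Builds a complete, validated parameter set. Any field not supplied falls
#' back to the published default (see [default_parameters()]). Unknown field
#' names are an error, so typos cannot silently leave a default in place.
#'
#' @param ... named scalar overrides of the default values. Valid names:
#'   `beta_P`, `mu_P`, `gamma_L`, `mu_L`, `gamma_F`, `mu_F`, `gamma_T`,
#'   `L_S`, `L_min`, `F_max`, `T_S`, `g1`--`g6`.
#'
#' @return An object of class `flc_params`: a named list of the 17 model
#'   constants.
#'
#' @details Structural invariants (every field a strictly positive finite
#'   scalar; `L_min < L_S`) are enforced here and violating them is an
#'   error. Dynamical *regime* requirements (e.g. `gamma_L > mu_L`) are not
#'   errors -- they are legitimate alternative regimes -- and are reported
#'   by [validate_parameters()] instead.
#'
#' @examples
#' p <- flc_params()              # published defaults
#' p2 <- flc_params(gamma_L = 0.01)
#' @seealso [default_parameters()], [validate_parameters()],
#'   [derived_quantities()]
#' @export
flc_params <- function(...) {
  overrides <- list(...)
  if (length(overrides) > 0 &&
      (is.null(names(overrides)) || any(names(overrides) == ""))) {
    stop("all parameter overrides must be named", call. = FALSE)
  }
  unknown <- setdiff(names(overrides), .param_names)
  if (length(unknown) > 0) {
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p <- .param_defaults
  for (nm in names(overrides)) {
    v <- overrides[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop("parameter '", nm, "' must be a finite numeric scalar",
           call. = FALSE)
    }
    p[[nm]] <- as.numeric(v)
  }
  bad <- names(p)[vapply(p, function(x) x <= 0, logical(1))]
  if (length(bad) > 0) {
    stop("parameter(s) must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (p$L_min >= p$L_S) {
    stop("invariant violated: L_min must be < L_S", call. = FALSE)
  }
  structure(p, class = "flc_params")
}

#' Published default parameter values
#'
#' Returns the full default parameter set used for all computational results:
#' `beta_P = 0.055`, `mu_P = 0.045`, `gamma_L = 0.005`, `mu_L = 0.0005`,
#' `gamma_F = 0.004`, `mu_F = 0.00046`, `gamma_T = 0.05`, `L_S = 1000` mg/L,
#' `L_min = 10` mg/L, `F_max = 100` percent, `T_S = 100` percent, `g1 = 1`,
#' `g2 = 0.958607314841775`, `g3 = 0.5`, `g4 = 0.38`, `g5 = 0.8`, `g6 = 0.7`.
#'
#' `g2` carries its full 15-digit precision: it is calibrated so that the
#' interior equilibrium sits exactly at 100% proximal tubule cells.
#'
#' @return An `flc_params` object.
#' @examples
#' default_parameters()$L_S   # 1000 mg/L
#' @export
default_parameters <- function() {
  flc_params()
}

#' Derived carrying levels for free light chains and fibroblasts
#'
#' The clipped-logistic growth terms use effective carrying levels
#' \deqn{\hat L = \frac{L_{min}\,\gamma_L}{\gamma_L - \mu_L}, \qquad
#'       \hat F = \frac{\gamma_F\,F_{max}}{\gamma_F - \mu_F},}
#' chosen so that after subtracting clearance/apoptosis the nontrivial
#' steady levels are exactly `L_min` and `F_max`. Both are defined only in
#' the growth-dominated regime `gamma_L > mu_L`, `gamma_F > mu_F`, where
#' `L_hat > L_min` and `F_hat > F_max` hold automatically.
#'
#' @param params an `flc_params` object.
#' @return A list with components `L_hat` (mg/L) and `F_hat` (percent).
#' @examples
#' derived_quantities(default_parameters())   # L_hat = 100/9, F_hat ~ 112.99
#' @export
derived_quantities <- function(params) {
  stopifnot(inherits(params, "flc_params"))
  if (params$gamma_L <= params$mu_L || params$gamma_F <= params$mu_F) {
    stop("degenerate-regime: carrying levels require gamma_L > mu_L and ",
         "gamma_F > mu_F", call. = FALSE)
  }
  .carrying_levels(params)
}

# The raw carrying-level formulas, valid (as algebra defining the dynamics)
# in every regime: with gamma <= mu they turn negative, the logistic factor
# (1 - x/hat) stays positive and the decay term wins near the origin. Used
# internally so decay-dominated regimes still integrate; the exported
# derived_quantities() keeps its growth-regime contract.
.carrying_levels <- function(params) {
  list(
    L_hat = params$L_min * params$gamma_L / (params$gamma_L - params$mu_L),
    F_hat = params$gamma_F * params$F_max / (params$gamma_F - params$mu_F)
  )
}

#' Check the stability requirements of the interior equilibrium
#'
#' The all-nonzero steady state `(P*, L_min, F_max)` is stable exactly when
#' `gamma_F > mu_F`, `gamma_L > mu_L` and `g2 < 1`. This function reports
#' which of those requirements (plus the structural positivity invariants)
#' a parameter set violates. Violations are data, not errors: regimes that
#' break them are meaningful (they select other steady states).
#'
#' @param params an `flc_params` object.
#' @return A character vector of violation descriptions; empty when the
#'   interior-equilibrium regime holds.
#' @examples
#' validate_parameters(default_parameters())          # character(0)
#' validate_parameters(flc_params(gamma_L = 1e-4))    # "gamma_L <= mu_L"
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "flc_params"))
  v <- character(0)
  nonpos <- names(params)[vapply(params, function(x) x <= 0, logical(1))]
  for (nm in nonpos) v <- c(v, paste0(nm, " <= 0"))
  if (params$L_min >= params$L_S) v <- c(v, "L_min >= L_S")
  if (params$gamma_F <= params$mu_F) v <- c(v, "gamma_F <= mu_F")
  if (params$gamma_L <= params$mu_L) v <- c(v, "gamma_L <= mu_L")
  if (params$g2 >= 1) v <- c(v, "g2 >= 1")
  v
}

#' @export
print.flc_params <- function(x, ...) {
  cat("Fibrosis model parameters (P, F, T in percent; L in mg/L; t in days)\n")
  w <- max(nchar(names(x)))
  for (nm in names(x)) {
    cat(sprintf("  %-*s = %s\n", w, nm, format(x[[nm]], digits = 15)))
  }
  viol <- validate_parameters(x)
  if (length(viol) == 0) {
    cat("  [interior-equilibrium regime: all stability requirements hold]\n")
  } else {
    cat("  [regime violations: ", paste(viol, collapse = "; "), "]\n",
        sep = "")
  }
  invisible(x)
}
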