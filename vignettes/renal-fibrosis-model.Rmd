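---
title: "Modeling myeloma-driven renal fibrosis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling myeloma-driven renal fibrosis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renalfib)
```

## The biological problem

In multiple myeloma, malignant plasma cells overproduce monoclonal
immunoglobulin free light chains (FLC). Circulating FLC are endocytosed by
the proximal tubule cells (PTC) lining the kidney's proximal convoluted
tubule; at high concentration this injures PTCs, triggers apoptosis and
epithelial–mesenchymal transition (EMT), and expands the interstitial
fibroblast population — the cellular signature of tubulointerstitial
fibrosis. `renalfib` implements a compact dynamical model of this cascade:
three coupled populations for the healthy kidney, plus a fourth,
decoupled tumor equation that forces the system once myeloma is present.

## The model

States are PTCs $P$ (percent of baseline), serum FLC $L$ (mg/L),
fibroblasts $F$ (percent of baseline) and, in the extended system, tumor
burden $T$ (percent of maximal spread). Time is in days. Kinetics are
power-law (S-system style): growth and loss terms are products of states
raised to kinetic-order exponents $g_1,\dots,g_6$.

Healthy system:

$$
\begin{aligned}
\dot P &= \beta_P\,\Big(1 - \tfrac{L}{L_S}\Big)_+^{g_1} P^{g_2} - \mu_P P,\\
\dot L &= \gamma_L L \Big(1 - \tfrac{L}{\hat L}\Big)_+ - \mu_L L,\\
\dot F &= \gamma_F F \Big(1 - \tfrac{F}{\hat F}\Big)_+ - \mu_F F,
\end{aligned}
$$

with $(x)_+ = \max(x, 0)$ and derived carrying levels

$$
\hat L = \frac{L_{\min}\gamma_L}{\gamma_L - \mu_L}, \qquad
\hat F = \frac{\gamma_F F_{\max}}{\gamma_F - \mu_F},
$$

chosen so that after subtracting clearance the nontrivial steady levels
are exactly $L_{\min}$ and $F_{\max}$. The clip keeps growth terms
non-negative past the carrying levels — decline is the decay terms' job.

The tumor-forced system adds an EMT sink on $P$ that reappears verbatim
as a source on $F$ ($\gamma_F L^{g_3} P^{g_4}$), an FLC production term
driven by the tumor ($\gamma_L T^{g_5} L^{g_6}$), and Gompertz growth
$\dot T = \gamma_T T \ln(T_S/T)$, which decouples and has the closed form
$T(t) = T_S \exp\{\ln(T_0/T_S)\,e^{-\gamma_T t}\}$ (`gompertz_exact()`).
We take the logarithm as natural: the Gompertz literature that the growth
term follows uses $\ln$, and only the natural log makes the closed form
above solve the ODE exactly.

## Parameters

`default_parameters()` returns the defaults; `?flc_params` documents
the name-to-symbol mapping. The values worth explaining:

* `g2 = 0.958607314841775` is kept at full precision. It is the
  calibration knob that places the interior equilibrium exactly at
  $P^* = 100$ for the default rates; rounding it moves $P^*$ visibly
  (the test suite checks $|P^* - 100| < 10^{-6}$, which the 15-digit
  value achieves and a 3-digit value would not).
* `gamma_L` and `gamma_F` are each one scalar reused everywhere their
  symbol recurs (FLC self-growth and tumor-driven production; fibroblast
  self-growth and the EMT flux). The printed units differ between those
  roles; we follow the single printed value and treat units as
  conventional metadata.
* `L_min = 10` mg/L is a normal serum FLC level; `L_S = 1000` mg/L is
  the concentration scale above which renal impairment is typically
  seen. All FLC quantities in this package are mg/L throughout; units
  are fixed by convention and never converted.
* Structural invariants (positivity, `L_min < L_S`) are constructor
  errors; *regime* conditions (`gamma_L > mu_L`, `gamma_F > mu_F`,
  `g2 < 1`) are data reported by `validate_parameters()`, because
  breaking them is how one explores the alternative steady-state
  families.

## Steady states and stability

Every steady state of the healthy system has each component either off
(0) or at its nontrivial level ($P$ at the closed form
$P^*(L) = (\mu_P/\beta_P\,(1 - L/L_S)^{-g_1})^{1/(g_2-1)}$, $L$ at
$L_{\min}$, $F$ at $F_{\max}$), so `enumerate_equilibria()` enumerates
the $2^3$ on/off patterns structurally rather than running multi-start
root finding — the clipped vector field would hand a generic root finder
spurious kinked roots, and the structural census is exactly the known
eight.

Stability is classified two ways, on purpose:

* For equilibria with $P > 0$ the field is smooth and the analytic
  Jacobian is triangular in the $(P, L, F)$ ordering, so its eigenvalues
  are the diagonal entries; at the interior equilibrium these reduce to
  $\mu_P(g_2 - 1)$, $\mu_L - \gamma_L$, $\mu_F - \gamma_F$. Real parts
  within $10^{-12}$ of zero are treated as non-hyperbolic — that
  threshold is the double-precision noise floor relative to rate
  coefficients of order $10^{-3}$.
* At $P = 0$ the derivative of $P^{g_2}$ (with $g_2 < 1$) is unbounded
  and linearization fails, so `classify_stability()` integrates from the
  point plus $10^{-3}$ componentwise over 5000 days and calls the point
  stable only if the trajectory returns to within $10^{-3}$.

The two routes genuinely disagree about the $P = 0$ face: the nominal
requirement attached to those rows is just $\mu_P > 0$, but with
$g_2 < 1$ the sublinear production $\beta_P P^{g_2}$ beats linear
apoptosis near $P = 0$, so the probe finds every $P = 0$ equilibrium
repelling in the $P$ direction. The package reports the structural
condition booleans and the probed classification side by side and does
not force agreement.

A subtlety of the decay-dominated regimes: with $\gamma_L < \mu_L$ the
carrying level $\hat L$ is negative, the logistic factor stays positive,
and $L = L_{\min}$ remains a (now unstable) fixed point. $L \to 0$ holds
from below $L_{\min}$, which is what the regime tests exercise; from far
above $L_{\min}$ the unclipped quadratic growth can dominate instead.
The exported `derived_quantities()` refuses the degenerate regime, while
the internal dynamics use the raw formula in all regimes.

## Numerical choices

* **Solver.** `deSolve::ode(method = "lsoda")` with `rtol = 1e-8`,
  `atol = 1e-10`. The rate constants span five orders of magnitude
  ($4.6\times10^{-4}$ to $5\times10^{-2}$ per day), making the system
  mildly stiff; `lsoda` switches to BDF when needed.
* **The clip kinks.** $(x)_+$ is applied exactly, with no smoothing and
  no event-splitting of the vector field: the right-hand side stays
  continuous through the kink and the tight tolerances absorb the local
  order reduction. The tolerance-robustness tests (all scenario scalars
  move by under 0.1% when tolerances tighten 100-fold) confirm this is
  adequate here.
* **Boundary powers.** $0^g := 0$ for $g > 0$, so the origin is a fixed
  point and all fractional powers are defined on the boundary. The
  solver may probe microscopically negative states; components are
  floored at zero inside the solver RHS, and the exported `rhs_*`
  functions accept round-off-sized negatives (magnitude below
  $10^{-12}$) but error on real ones.
* **Event location.** Threshold crossings are found on the output grid
  and refined by `uniroot` on a cubic Hermite interpolant built from the
  stored exact derivatives at the grid points ($O(h^4)$ on the 0.5-day
  grid, far inside the $10^{-3}$-day reporting tolerance). Crossing
  semantics are strict and upward: starting at or above the level, or
  merely touching it, is "no crossing", reported as `NULL`.
* **Horizons.** The perturbation suite runs 10,000 days: the slowest
  eigenvalue $\mu_P(g_2-1) \approx -0.00186$/day gives a 537-day time
  constant, so 10,000 days is about 19 time constants — ample for the
  0.1% convergence band. The attractor property test uses 50 random
  starts (fixed seed 20190211) over 20,000 days, sampled every 500 days
  to keep output small. The tumor scenario runs 160 days on a 0.5-day
  grid.

## What the scenarios do and do not show

`run_perturbation_suite()` and `run_tumor_scenario()` are in-silico
experiments on the model itself; there is no patient data anywhere in
the pipeline, and the parameter set is a heuristic calibration to
generic clinical expectations, not a fit. Passing tests therefore show
that the implementation reproduces the model's stated behavior —
homeostatic return from ±20% perturbations; FLC exceeding 1000 mg/L
within 160 untreated days; PTCs at 40–50% of baseline when FLC reaches
500 mg/L; fibroblasts rising above baseline — not that the model
predicts real patients. Cast nephropathy (intratubular FLC
precipitation), treatment effects, GFR and survival are outside the
model's scope.

## Known limitations

* Term K (tumor-driven FLC production) is unbounded in $L$, exactly as
  specified; at extreme FLC the model has no saturation there.
* The tumor system has no finite equilibrium for $L$ ($T \to T_S$ keeps
  production on), so steady-state analysis is only offered for the
  healthy system.
* The perturbation probe's verdict depends on its 5000-day horizon and
  $10^{-3}$ perturbation; it is an empirical classification of a
  non-smooth corner, not a theorem.

## Session info

```{r}
sessionInfo()
```
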