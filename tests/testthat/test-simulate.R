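p_tab <- default_parameters()

test_that("a trajectory started at the steady state stays there", {
  tr <- integrate_model("healthy", c(100, 10, 100), p_tab, t_end = 1000,
                        output_step = 5)
  dev <- sweep(tr$states, 2, c(100, 10, 100))
  expect_lt(max(abs(dev)), 1e-6)
})

test_that("tumor burden in the coupled system tracks the closed form", {
  tr <- integrate_model("tumor", c(100, 10, 100, 1), p_tab, t_end = 160)
  expect_lt(max(abs(tr$states[, "T"] -
                      gompertz_exact(tr$times, 1, p_tab))), 1e-5)
})

test_that("refining the output grid does not change the solution", {
  tr1 <- integrate_model("healthy", c(80, 8, 80), p_tab, t_end = 100,
                         output_step = 0.5)
  tr2 <- integrate_model("healthy", c(80, 8, 80), p_tab, t_end = 100,
                         output_step = 0.25)
  common <- match(tr1$times, tr2$times)
  expect_lt(max(abs(tr1$states - tr2$states[common, ])), 1e-6)
})

test_that("trajectories from the boundary stay in the non-negative orthant", {
  starts <- list(c(0, 5, 50), c(50, 0, 50), c(50, 5, 0), c(0, 0, 0))
  for (s in starts) {
    tr <- integrate_model("healthy", s, p_tab, t_end = 500, output_step = 5)
    expect_true(all(tr$states >= 0))
  }
})

test_that("upward-crossing semantics: strict, from below, first only", {
  tr <- integrate_model("tumor", c(100, 10, 100, 1), p_tab, t_end = 160)
  # level below the initial value: no upward crossing by definition
  expect_null(find_crossing(tr, "L", 5))
  # a variable that never reaches the level
  expect_null(find_crossing(tr, "L", 1e6))
  # constant trajectory exactly at the level: touching is not crossing
  flat <- integrate_model("healthy", c(100, 10, 100), p_tab, t_end = 50)
  expect_null(find_crossing(flat, "L", 10))
  expect_error(find_crossing(tr, "Q", 1), "unknown variable")
  # located crossing is consistent: L interpolates to the level there
  cr <- find_crossing(tr, "L", 500)
  expect_equal(cr$state[["L"]], 500, tolerance = 1e-4)
  expect_true(cr$time > 0 && cr$time < 160)
})

test_that("perturbed initial conditions return to homeostasis", {
  res <- run_perturbation_suite(p_tab)
  expect_identical(nrow(res$summary), 3L)
  expect_true(all(res$summary$converged))
  expect_equal(res$summary$P, rep(100, 3), tolerance = 1e-3)
  # unperturbed run is a fixed point to solver accuracy
  at <- res$summary[res$summary$delta == 0, ]
  expect_equal(c(at$P, at$L, at$F), c(100, 10, 100), tolerance = 1e-6)
})

test_that("untreated tumor drives FLC past 1000 mg/L and fibrosis upward", {
  res <- run_tumor_scenario(p_tab)
  s <- res$summary
  expect_gte(s$max_L, 1000)
  expect_gt(s$terminal[["F"]], 100)
  expect_equal(s$terminal[["T"]], gompertz_exact(160, 1, p_tab),
               tolerance = 1e-3)
  expect_false(is.na(s$crossing_L1000_time))
  expect_true(all(s$flags))
  # PTC between 40 and 50% when FLC reaches the kidney-damage threshold
  expect_gte(s$crossing_L500$state[["P"]], 40)
  expect_lte(s$crossing_L500$state[["P"]], 50)
})

test_that("summary scalars are robust to tolerance tightening", {
  loose <- run_tumor_scenario(p_tab)
  tr <- integrate_model("tumor", c(100, 10, 100, 1), p_tab, 160,
                        rtol = 1e-10, atol = 1e-12)
  c500 <- find_crossing(tr, "L", 500)
  expect_equal(max(tr$states[, "L"]), loose$summary$max_L,
               tolerance = 1e-3)
  expect_equal(c500$time, loose$summary$crossing_L500$time,
               tolerance = 1e-3)
  expect_equal(c500$state[["P"]], loose$summary$crossing_L500$state[["P"]],
               tolerance = 1e-3)
})

test_that("the interior equilibrium attracts random healthy states", {
  set.seed(20190211)
  target <- healthy_target(p_tab)
  for (k in 1:50) {
    s0 <- runif(3, min = 1e-6, max = 1) * 2 * target
    tr <- integrate_model("healthy", s0, p_tab, t_end = 20000,
                          output_step = 500)
    terminal <- tr$states[nrow(tr$states), ]
    expect_equal(unname(terminal), unname(target), tolerance = 1e-3)
  }
})

test_that("decay-dominated regimes extinguish the matching population", {
  # FLC clearance beats growth: L dies out from below its minimum level
  pL <- flc_params(gamma_L = 1e-4)
  trL <- integrate_model("healthy", c(100, 8, 100), pL, t_end = 30000,
                         output_step = 500)
  expect_lt(trL$states[nrow(trL$states), "L"], 0.01)
  # fibroblast apoptosis beats growth: F dies out
  pF <- flc_params(gamma_F = 1e-4)
  trF <- integrate_model("healthy", c(100, 10, 80), pF, t_end = 30000,
                         output_step = 500)
  expect_lt(trF$states[nrow(trF$states), "F"], 0.1)
})

test_that("phase projections preserve order and show the expected shapes", {
  res <- run_tumor_scenario(p_tab)
  tr <- res$trajectory
  lp <- phase_projection(tr, "L", "P")
  expect_identical(lp$t, tr$times)
  expect_identical(lp$x, unname(tr$states[, "L"]))
  # identity projection
  ll <- phase_projection(tr, "L", "L")
  expect_identical(ll$x, ll$y)
  expect_error(phase_projection(tr, "L", "Z"), "unknown variable")
  # P monotone decreasing once L has left the homeostatic band
  dq <- derived_quantities(p_tab)
  sel <- lp$x > 2 * dq$L_hat
  expect_true(all(diff(lp$y[sel]) < 0))
  # FLC surge lags the tumor: T reaches half its capacity before L reaches
  # half its day-160 value
  tl <- phase_projection(tr, "T", "L")
  t_T50 <- tr$times[which(tl$x >= 50)[1]]
  t_L50 <- tr$times[which(tl$y >= max(tl$y) / 2)[1]]
  expect_lt(t_T50, t_L50)
})
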