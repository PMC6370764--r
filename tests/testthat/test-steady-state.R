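p_tab <- default_parameters()

test_that("closed-form P* recovers 100% PTC at the normal FLC level", {
  expect_equal(interior_P_star(p_tab, L = 10), 100, tolerance = 1e-6)
  expect_equal(interior_P_star(p_tab, L = 0),
               (p_tab$beta_P / p_tab$mu_P)^(1 / (1 - p_tab$g2)),
               tolerance = 1e-12)
  expect_error(interior_P_star(p_tab, L = 1000), "L_S")
  expect_error(interior_P_star(flc_params(g2 = 1), L = 10), "g2")
})

test_that("P* satisfies the growth-death balance for random parameter draws", {
  set.seed(13)
  for (k in 1:25) {
    p <- flc_params(beta_P = runif(1, 0.01, 0.2),
                    mu_P = runif(1, 0.001, 0.1),
                    g2 = runif(1, 0.3, 0.99))
    L <- runif(1, 0, 0.9 * p$L_S)
    X <- interior_P_star(p, L)
    lhs <- p$beta_P * (1 - L / p$L_S)^p$g1 * X^p$g2
    expect_equal(lhs, p$mu_P * X, tolerance = 1e-10)
  }
})

test_that("the census holds exactly eight steady states of the stated forms", {
  eqs <- enumerate_equilibria(p_tab)
  expect_length(eqs, 8)
  pts <- t(vapply(eqs, function(e) e$point, numeric(3)))
  # interior point first, origin present
  expect_equal(unname(pts[1, ]), c(100, 10, 100), tolerance = 1e-6)
  expect_true(any(apply(pts, 1, function(r) all(r == 0))))
  # each component is 0 or its nontrivial level
  expect_true(all(pts[, "L"] %in% c(0, p_tab$L_min)))
  expect_true(all(pts[, "F"] %in% c(0, p_tab$F_max)))
  # every enumerated point zeroes the vector field
  for (e in eqs) expect_lt(e$residual, 1e-9)
})

test_that("analytic Jacobian matches the finite-difference oracle", {
  set.seed(14)
  worst <- 0
  for (k in 1:100) {
    s <- random_interior_state(p_tab)
    diffs <- abs(jacobian_healthy(s, p_tab) - fd_jacobian(s, p_tab))
    worst <- max(worst, max(diffs))
  }
  expect_lt(worst, 1e-6)
})

test_that("interior equilibrium eigenvalues reduce to the hand-derived diagonal", {
  eq <- enumerate_equilibria(p_tab)[[1]]
  ev <- sort(Re(eq$eigenvalues))
  expected <- sort(c(p_tab$mu_P * (p_tab$g2 - 1),     # ~ -0.0018627
                     p_tab$mu_L - p_tab$gamma_L,      #   -0.0045
                     p_tab$mu_F - p_tab$gamma_F))     #   -0.00354
  expect_equal(ev, expected, tolerance = 1e-9)
  expect_identical(eq$classification, "stable")
  expect_true(all(eq$conditions))
})

test_that("superlinear PTC self-growth destabilises the interior equilibrium", {
  p <- flc_params(g2 = 1.05)
  eq <- enumerate_equilibria(p)[[1]]
  expect_identical(eq$classification, "unstable")
  expect_gt(max(Re(eq$eigenvalues)), 0)
  expect_false(eq$conditions[["third"]])   # g2 < 1 fails
})

test_that("Jacobian refuses the non-smooth P = 0 corner", {
  expect_error(jacobian_healthy(c(P = 0, L = 10, F = 100), p_tab),
               "boundary-point")
})

test_that("perturbation probe finds the P = 0 face repelling despite mu_P > 0", {
  eqs <- enumerate_equilibria(p_tab)
  p0 <- Filter(function(e) !e$occupied[["P"]], eqs)
  expect_length(p0, 4)
  for (e in p0) {
    expect_identical(e$classification_method, "perturbation-probe")
    expect_identical(e$classification, "unstable")
    # the nominal structural requirement mu_P > 0 still holds and is
    # reported independently of the probe outcome
    expect_true(e$conditions[["third"]])
  }
})

test_that("regime toggles move stability between equilibrium families", {
  # FLC decay-dominated: interior family loses its gamma_L requirement,
  # the L = 0, P > 0, F = F_max point becomes the stable one
  p <- flc_params(gamma_L = 1e-4)
  eqs <- enumerate_equilibria(p)
  df <- as.data.frame(eqs)
  interior <- df[df$P > 0 & df$L > 0 & df$F > 0, ]
  expect_false(interior$cond_gammaL)
  l_off <- df[df$P > 0 & df$L == 0 & df$F > 0, ]
  expect_true(l_off$cond_gammaL)
  expect_identical(l_off$classification, "stable")
})
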