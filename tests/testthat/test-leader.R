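test_that("equilibrium payoff matches hand-computed profits", {
  g <- fisheries_game()
  # no effort, no cost: zero profit whatever the trait
  expect_equal(objective_at_eco_equilibrium(g$problem, g$model, 0, 0.4), 0)
  # H(0, 0.25) x*(0.25, 0) - c 0.25 = 0.25 * 7500 - 500 * 0.25
  expect_equal(objective_at_eco_equilibrium(g$problem, g$model, 0.25, 0),
               1750, tolerance = 1e-8)
})

test_that("best response to the symmetric trait matches the closed form", {
  g <- fisheries_game()
  cf <- fisheries_closed_forms()
  br <- leader_best_response(g$problem, g$model, 0)
  expect_equal(as.numeric(br), cf$m_star_at_u0, tolerance = 1e-7)
  expect_equal(cf$m_star_at_u0, 0.475)
  # prohibitive effort cost: harvesting never pays, best response is idle
  g2 <- fisheries_model(c = 10000)
  expect_equal(as.numeric(leader_best_response(g2$problem, g2$model, 0)), 0,
               tolerance = 1e-9)
})

test_that("a quadratic objective on a trait-neutral stock recovers its maximizer", {
  m0 <- neutral_model()
  pr <- leader_problem(function(m, u, x) -(m - 0.3)^2, m_bounds = c(0, 1))
  expect_equal(as.numeric(leader_best_response(pr, m0, 0)), 0.3,
               tolerance = 1e-8)
  # the trait response is constant, so Nash and Stackelberg both sit there
  ns <- nash_solve(pr, m0)
  ss <- stackelberg_solve(pr, m0, n_grid = 41)
  expect_equal(ns$m, 0.3, tolerance = 1e-6)
  expect_lt(abs(ns$m - ss$m), 1e-5)
})

test_that("Nash and Stackelberg strategies reproduce the harvest game", {
  sol <- fisheries_solution()
  cf <- fisheries_closed_forms()
  m_c <- sol$diagram$bifurcations$m_c
  # Nash sits beyond the bifurcation on an outer branch
  expect_true(sol$nash$converged)
  expect_gt(sol$nash$m, m_c)
  expect_gt(abs(sol$nash$u[1]), 0.1)
  expect_equal(sol$nash$m, 0.6431097056, tolerance = 1e-6)
  expect_equal(abs(sol$nash$u[1]), 0.2964593402, tolerance = 1e-5)
  expect_equal(sol$nash$Q, 1531.213847, tolerance = 1e-6)
  expect_false(is.null(sol$nash$mirror))   # symmetric twin reported
  # Stackelberg harvests exactly at the bifurcation with the neutral trait
  expect_lt(abs(sol$stackelberg$m - m_c), 1e-3)
  expect_equal(sol$stackelberg$m, cf$m_c, tolerance = 1e-6)
  expect_equal(sol$stackelberg$u[1], 0, tolerance = 1e-8)
  expect_true(sol$stackelberg$at_bifurcation)
  expect_equal(sol$stackelberg$Q, 2251.182408, tolerance = 1e-6)
})

test_that("payoffs are ordered naive <= Nash <= Stackelberg", {
  sol <- fisheries_solution()
  expect_gte(sol$stackelberg$Q, sol$nash$Q - 1e-9)
  expect_gte(sol$nash$Q, sol$naive$Q - 1e-9)
  expect_equal(sol$naive$m, 1)
  expect_equal(sol$naive$Q, 786.409116, tolerance = 1e-5)
})

test_that("first-order residuals vanish at interior optima and coincide below the bifurcation", {
  sol <- fisheries_solution()
  g <- fisheries_game()
  expect_lt(abs(sol$foc_residuals$at_nash[["nash"]]), 1e-5)
  # below m_c the trait does not respond, so the two conditions agree
  fr <- foc_residuals(g$problem, g$model, 0.3, branch_hint = "0")
  expect_equal(fr[["nash"]], fr[["stackelberg"]], tolerance = 1e-6)
  # at the bifurcation the bilevel objective is kinked: undefined residual
  m_c <- sol$diagram$bifurcations$m_c
  frk <- foc_residuals(g$problem, g$model, m_c, branch_hint = "0",
                       bifurcations = m_c)
  expect_true(is.na(frk[["stackelberg"]]))
})

test_that("the coincidence audit identifies the no-trait-response case", {
  g <- fisheries_game()
  th <- theorem41_check(g$problem, g$model, m = 0.3, branch_hint = "0")
  expect_true(th$case_a)
  expect_identical(th$verdict, "coincide")
  cc <- fisheries_cheap_cost_solution()
  # with a costlier effort the best response drops below the bifurcation
  # and the two enlightened strategies agree
  expect_lt(abs(cc$nash$m - cc$stackelberg$m), 1e-5)
  expect_equal(cc$nash$m, 0.4, tolerance = 1e-6)
  expect_equal(cc$nash$u[1], 0, tolerance = 1e-8)
})
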