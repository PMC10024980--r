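test_that("ecological equilibrium matches the closed form over the action-trait grid", {
  g <- fisheries_game()
  cf <- fisheries_closed_forms()
  for (m in c(0, 0.25, 0.6, 0.95)) {
    for (u in c(-0.8, -0.2, 0, 0.35, 1.1)) {
      x <- ecological_equilibrium(g$model, u, m)
      expect_equal(as.numeric(x), cf$x_star(m, u),
                   tolerance = 1e-8, label = sprintf("x*(%g, %g)", m, u))
      if (x > 0)
        expect_lt(abs(resident_fitness(g$model, 1, eco_evo_state(x, u), m)),
                  1e-8)
    }
  }
  # harvest beyond the intrinsic growth rate extinguishes the stock
  expect_equal(as.numeric(ecological_equilibrium(g$model, 0, 1.2)), 0)
})

test_that("ess_solve finds one ESS below and two above the pitchfork", {
  g <- fisheries_game()
  cf <- fisheries_closed_forms()
  below <- ess_solve(g$model, 0.25)
  ess_below <- Filter(function(s) s$is_ess, below)
  expect_length(ess_below, 1)
  expect_equal(ess_below[[1]]$u_star, 0, tolerance = 1e-9)

  above <- ess_solve(g$model, 0.75)
  expect_length(above, 3)
  ess_above <- Filter(function(s) s$is_ess, above)
  expect_length(ess_above, 2)
  us <- sort(vapply(ess_above, function(s) s$u_star, numeric(1)))
  expect_equal(us, cf$u_branch(0.75), tolerance = 1e-6)
  # the symmetric pair carries identical population sizes
  expect_equal(ess_above[[1]]$x_star, ess_above[[2]]$x_star,
               tolerance = 1e-8)
  # the persisting central strategy is now a fitness minimum, not an ESS
  mid <- Filter(function(s) abs(s$u_star) < 1e-8, above)[[1]]
  expect_false(mid$is_ess)
  expect_identical(mid$classification, "min")
  expect_gt(mid$second_derivative, 0)
})

test_that("invasion test certifies the ESS and names the invading trait at a minimum", {
  g <- fisheries_game()
  eq <- Filter(function(s) s$is_ess, ess_solve(g$model, 0.25))[[1]]
  expect_true(invasion_test(g$model, eq)$pass)
  # the resident trivially cannot invade itself
  expect_true(invasion_test(g$model, eq, v_grid = eq$u_star)$pass)
  mid <- Filter(function(s) abs(s$u_star) < 1e-8,
                ess_solve(g$model, 0.75))[[1]]
  inv <- invasion_test(g$model, mid)
  expect_false(inv$pass)
  expect_gt(inv$worst_fitness, 0)
  expect_gt(abs(inv$worst_v), 0.2)
  expect_lt(abs(inv$worst_v), 0.5)
})

test_that("convergence stability follows the monomorphic trait flow", {
  g <- fisheries_game()
  eq25 <- Filter(function(s) s$is_ess, ess_solve(g$model, 0.25))[[1]]
  expect_true(convergence_stability(g$model, eq25))
  sols75 <- ess_solve(g$model, 0.75)
  plus <- Filter(function(s) s$u_star > 0.1, sols75)[[1]]
  expect_true(convergence_stability(g$model, plus))
  # above the bifurcation the central minimum repels the monomorphic
  # dynamics: trajectories run to the outer branches
  mid <- Filter(function(s) abs(s$u_star) < 1e-8, sols75)[[1]]
  expect_false(convergence_stability(g$model, mid))
})

test_that("the branch diagram detects the pitchfork at the critical effort", {
  g <- fisheries_game()
  cf <- fisheries_closed_forms()
  dg <- ess_branch_diagram(g$model, seq(0, 1, by = 0.01))
  expect_equal(nrow(dg$bifurcations), 1)
  expect_identical(dg$bifurcations$kind, "pitchfork")
  expect_equal(dg$bifurcations$m_c, cf$m_c, tolerance = 1e-6)
  br <- dg$branches
  # a single central branch below the bifurcation
  expect_true(all(abs(br$u_star[br$m < dg$bifurcations$m_c]) < 1e-8))
  # symmetric outer branches with equal population sizes above it
  up <- br[br$branch_id == "u+", ]
  dn <- br[br$branch_id == "u-", ]
  shared <- intersect(up$m, dn$m)
  expect_gt(length(shared), 20)
  expect_equal(up$u_star[match(shared, up$m)],
               -dn$u_star[match(shared, dn$m)], tolerance = 1e-8)
  expect_equal(up$x_star[match(shared, up$m)],
               dn$x_star[match(shared, dn$m)], tolerance = 1e-6)
})

test_that("equal kernel widths move the bifurcation to half the growth rate", {
  g <- fisheries_model(sigma_K = 0.5, sigma_H = 0.5)
  dg <- ess_branch_diagram(g$model, seq(0.3, 0.7, by = 0.02))
  expect_equal(nrow(dg$bifurcations), 1)
  expect_equal(dg$bifurcations$m_c, 0.5, tolerance = 1e-6)
  expect_equal(fisheries_closed_forms(sigma_K = 0.5, sigma_H = 0.5)$m_c, 0.5)
})

test_that("a trait-neutral model yields one flat branch and no bifurcations", {
  m0 <- neutral_model()
  dg <- ess_branch_diagram(m0, seq(0, 0.5, by = 0.1))
  expect_equal(length(unique(dg$branches$branch_id)), 1)
  expect_true(all(dg$branches$u_star == 0))
  expect_equal(nrow(dg$bifurcations), 0)
})

test_that("integration attractors coincide with the solved equilibria", {
  g <- fisheries_game()
  targets25 <- Filter(function(s) s$is_ess, ess_solve(g$model, 0.25))
  for (u0 in c(-0.3, 0.2)) {
    tr <- integrate_darwinian(g$model, eco_evo_state(5000, u0), 0.25,
                              horizon = 1500)
    d <- min(vapply(targets25, function(s)
      abs(s$u_star - tr$final_state$u), numeric(1)))
    expect_lt(d, 1e-5)
  }
  targets75 <- Filter(function(s) s$is_ess, ess_solve(g$model, 0.75))
  for (u0 in c(0.05, -0.4)) {
    tr <- integrate_darwinian(g$model, eco_evo_state(5000, u0), 0.75,
                              horizon = 1500)
    i <- which.min(vapply(targets75, function(s)
      abs(s$u_star - tr$final_state$u), numeric(1)))
    expect_lt(abs(targets75[[i]]$u_star - tr$final_state$u), 1e-5)
    expect_lt(abs(sum(targets75[[i]]$x_star) - sum(tr$final_state$x)), 1e-2)
  }
})

test_that("two-type therapy equilibria solve the competition system", {
  cg <- cancer_model()
  # interior coexistence
  x <- ecological_equilibrium(cg$model, c(0, 0.7), 0.25)
  expect_equal(as.numeric(x), cancer_equilibrium_oracle(0.7, 0.25),
               tolerance = 1e-6)
  # sensitive type excluded at the maximum dose
  x1 <- ecological_equilibrium(cg$model, c(0, 0.92), 1)
  expect_equal(as.numeric(x1), cancer_equilibrium_oracle(0.92, 1),
               tolerance = 1e-6)
  expect_identical(x1[1], 0)
  # both types die when neither carries resistance at the maximum dose
  expect_equal(as.numeric(ecological_equilibrium(cg$model, c(0, 0), 1)),
               c(0, 0))
})

test_that("the resistant ESS matches its interior stationarity closed form", {
  cg <- cancer_model()
  for (m in c(0.4, 0.7, 1)) {
    sols <- Filter(function(s) s$is_ess, ess_solve(cg$model, m))
    expect_length(sols, 1)
    expect_equal(sols[[1]]$u_star[2], cancer_ess_oracle(m),
                 tolerance = 1e-8, label = paste("u*(", m, ")"))
  }
  # with a negligible dose the resistance cost pins the trait at zero
  low <- Filter(function(s) s$is_ess, ess_solve(cg$model, 0.001))
  expect_equal(low[[1]]$u_star[2], 0)
})
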