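test_that("resident fitness matches hand-computed values of the harvest model", {
  g <- fisheries_game()
  # at carrying capacity without harvest the growth rate is zero
  expect_equal(resident_fitness(g$model, 1, eco_evo_state(10000, 0), 0), 0)
  # an empty population grows at the intrinsic rate r
  expect_equal(resident_fitness(g$model, 1, eco_evo_state(0, 0), 0), 1)
  # at the harvested equilibrium x* = K(u)(1 - H(u, m)/r)
  expect_equal(resident_fitness(g$model, 1, eco_evo_state(7500, 0), 0.25),
               0, tolerance = 1e-12)
  # direct substitution, hand-checked: r - 0.75 exp(-0.25/0.25)
  expect_equal(mutant_fitness(g$model, 0.5, 1, eco_evo_state(0, 0), 0.75),
               1 - 0.75 * exp(-1), tolerance = 1e-12)
})

test_that("selection gradient is zero at the symmetric trait and disruptive above the bifurcation", {
  g <- fisheries_game()
  cf <- fisheries_closed_forms()
  for (m in c(0, 0.3, 0.9)) {
    x <- cf$x_star(m, 0)
    expect_identical(fitness_gradient(g$model, 1, eco_evo_state(x, 0), m), 0)
  }
  # above m_c selection pushes the trait away from 0
  x <- cf$x_star(0.75, 0.1)
  expect_gt(fitness_gradient(g$model, 1, eco_evo_state(x, 0.1), 0.75), 0)
  # finite-difference gradient (no analytic hook) agrees with the analytic one
  fd_model <- gfun_model(g$model$fitness, n_types = 1, sigma = 1,
                         trait_bounds = c(-2, 2), params = g$model$params,
                         x_scale = 10000)
  st <- eco_evo_state(cf$x_star(0.6, 0.37), 0.37)
  expect_equal(fitness_gradient(fd_model, 1, st, 0.6),
               fitness_gradient(g$model, 1, st, 0.6), tolerance = 1e-6)
})

test_that("darwinian dynamics absorb extinction and freeze zero-speed traits", {
  g <- fisheries_game()
  d <- darwinian_rhs(g$model, eco_evo_state(0, 0.3), 0.2)
  expect_identical(d$dx, 0)
  # eco-evolutionary equilibrium is a fixed point of the vector field
  d0 <- darwinian_rhs(g$model, eco_evo_state(10000, 0), 0)
  expect_equal(unlist(d0), c(dx = 0, du = 0))
  # the sensitive type of the therapy model never evolves (sigma_S = 0)
  cg <- cancer_model()
  dc <- darwinian_rhs(cg$model, eco_evo_state(c(4000, 1000), c(0, 0.4)), 0.5)
  expect_identical(dc$du[1], 0)
  expect_true(abs(dc$du[2]) > 0)
})

test_that("trajectories converge to the coupled eco-evolutionary equilibrium", {
  g <- fisheries_game()
  tr <- integrate_darwinian(g$model, eco_evo_state(5000, 0.05), m = 0.25)
  expect_true(tr$converged)
  expect_false(is.unsorted(tr$times, strictly = TRUE))
  expect_equal(tr$final_state$x, 7500, tolerance = 1e-6)
  expect_equal(tr$final_state$u, 0, tolerance = 1e-6)
  # without harvest the stock tends to K_max and the trait to 0
  tr0 <- integrate_darwinian(g$model, eco_evo_state(100, 0.3), m = 0)
  expect_equal(tr0$final_state$x, 10000, tolerance = 1e-6)
  expect_equal(tr0$final_state$u, 0, tolerance = 1e-6)
})

test_that("zero evolutionary speed leaves an ecological equilibrium fixed", {
  frozen <- fisheries_model(sigma = 0)
  x0 <- fisheries_closed_forms()$x_star(0.25, 0.3)
  tr <- integrate_darwinian(frozen$model, eco_evo_state(x0, 0.3), m = 0.25,
                            horizon = 50)
  expect_identical(tr$final_state$u, 0.3)   # bitwise frozen trait
  expect_equal(tr$final_state$x, x0, tolerance = 1e-8)
})

test_that("mirrored initial conditions give mirrored trajectories", {
  g <- fisheries_game()
  a <- integrate_darwinian(g$model, eco_evo_state(5000, 0.12), m = 0.75,
                           horizon = 100)
  b <- integrate_darwinian(g$model, eco_evo_state(5000, -0.12), m = 0.75,
                           horizon = 100)
  expect_equal(a$u, -b$u, tolerance = 1e-8)
  expect_equal(a$x, b$x, tolerance = 1e-8)
})

test_that("trajectory tables round-trip as CSV", {
  g <- fisheries_game()
  tr <- integrate_darwinian(g$model, eco_evo_state(5000, 0.05), m = 0.25,
                            horizon = 10, n_out = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- read.csv(path)
  expect_named(back, c("t", "x_1", "u_1"))
  expect_equal(back$x_1, as.numeric(tr$x[, 1]))
})
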