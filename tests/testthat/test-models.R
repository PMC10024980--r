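test_that("fisheries closed forms agree with their derivations", {
  cf <- fisheries_closed_forms()
  expect_equal(cf$m_c, 0.25 / 0.5525, tolerance = 1e-12)
  expect_equal(round(cf$m_c, 2), 0.45)
  expect_equal(cf$m_star_at_u0, 0.475)
  expect_equal(cf$u_branch(0.75), c(-1, 1) * 0.5 * sqrt(log(0.75 / cf$m_c)),
               tolerance = 1e-12)
  expect_length(cf$u_branch(0.4), 0)     # below the bifurcation: no branches
  expect_equal(cf$x_star(0.25, 0), 7500)
  expect_equal(fisheries_closed_forms(sigma_K = 0.5, sigma_H = 0.5)$m_c, 0.5)
})

test_that("outcome classification brackets the progression threshold", {
  expect_identical(classify_outcome(0), "extinction")
  expect_identical(classify_outcome(7000), "stabilization")  # closed boundary
  expect_identical(classify_outcome(8000), "progression")
  expect_identical(classify_outcome(c(0, 500, 9000)),
                   c("extinction", "stabilization", "progression"))
})

test_that("evolved resistance monotonically blunts the drug kill term", {
  cg <- cancer_model()
  st <- eco_evo_state(c(3000, 2000), c(0, 0.5))
  vs <- seq(0, 2, by = 0.25)
  kill <- mutant_fitness(cg$model, vs, 2, st, 1) -
    mutant_fitness(cg$model, vs, 2, st, 0)
  expect_true(all(diff(kill) > 0))
  expect_equal(kill, -1 / (2 + 10 * vs), tolerance = 1e-12)
})

test_that("the therapy game reproduces the dose-comparison narrative", {
  ca <- cancer_solution_4a()
  sol <- ca$sol
  # the evolutionarily enlightened dose is lower, induces less resistance
  # and yields the better quality of life than the ecologically enlightened
  expect_lt(sol$stackelberg$m, sol$nash$m)
  expect_lt(sol$stackelberg$u[2], sol$nash$u[2])
  expect_gt(sol$stackelberg$Q, sol$nash$Q)
  expect_identical(sol$nash$outcome, "stabilization")
  expect_identical(sol$stackelberg$outcome, "stabilization")
  # frozen values from an independent numerical oracle of the same model
  expect_equal(sol$stackelberg$m, 0.65995564, tolerance = 1e-5)
  expect_equal(sol$nash$m, 0.75029427, tolerance = 1e-5)
  expect_equal(sol$stackelberg$Q, 0.46582866, tolerance = 1e-6)
  expect_equal(sol$nash$Q, 0.46308054, tolerance = 1e-6)
  expect_equal(sol$stackelberg$u[2], 0.874920, tolerance = 1e-4)
  expect_equal(sol$nash$u[2], 0.891277, tolerance = 1e-4)
})

test_that("the maximum tolerable dose drives the burden to its closed-form equilibrium", {
  ca <- cancer_solution_4a()
  u_mtd <- cancer_ess_oracle(1)
  x_mtd <- cancer_equilibrium_oracle(u_mtd, 1)
  expect_equal(ca$sol$naive$m, 1)
  expect_equal(ca$sol$naive$u[2], u_mtd, tolerance = 1e-6)
  expect_equal(sum(ca$sol$naive$x), sum(x_mtd), tolerance = 1e-4)
  expect_equal(sum(x_mtd), 5394.12, tolerance = 1e-4)
})

test_that("equilibrium burden is stationary in the resistance trait at the ESS", {
  cg <- cancer_model()
  for (m in c(0.6, 1)) {
    u <- Filter(function(s) s$is_ess, ess_solve(cg$model, m))[[1]]$u_star[2]
    h <- 1e-3
    K <- cg$model$params$K
    tot <- function(uu)
      sum(ecological_equilibrium(cg$model, c(0, uu), m)) / K
    expect_lt(abs((tot(u + h) - tot(u - h)) / (2 * h)), 1e-5)
  }
})

test_that("dropping the resistance penalty makes the enlightened strategies coincide", {
  cz <- cancer_solution_c2zero()
  expect_lt(abs(cz$nash$m - cz$stackelberg$m), 1e-5)
  th <- theorem41_check(cz$game$problem, cz$game$model, m = cz$nash$m)
  expect_false(th$case_a)
  expect_true(th$case_b)
  expect_identical(th$verdict, "coincide")
})

test_that("constructors validate their parameters", {
  expect_error(fisheries_model(r = -1))
  expect_error(cancer_model(delta = 1.2))
  expect_error(gfun_model(function(...) 0, sigma = -1), "sigma")
  expect_error(eco_evo_state(-1, 0), "x")
})
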