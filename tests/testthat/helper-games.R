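# Shared fixtures: built-in games plus lazily cached heavy solves, so that
# expensive Nash/Stackelberg computations run at most once per suite.

.seg_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .seg_cache))
    assign(key, expr, envir = .seg_cache)
  get(key, envir = .seg_cache)
}

fisheries_game <- function(...) fisheries_model(...)

fisheries_solution <- function() cached("fisheries_solution", {
  g <- fisheries_model()
  seg_solve(g$problem, g$model)
})

fisheries_cheap_cost_solution <- function() cached("fisheries_c2000", {
  g <- fisheries_model(c = 2000)
  list(nash = nash_solve(g$problem, g$model),
       stackelberg = stackelberg_solve(g$problem, g$model),
       game = g)
})

cancer_solution_4a <- function() cached("cancer_4a", {
  g <- cancer_model()
  list(sol = seg_solve(g$problem, g$model), game = g)
})

cancer_solution_c2zero <- function() cached("cancer_c2zero", {
  g <- cancer_model(c1 = 0.68, c2 = 0, c3 = 0.32)
  list(nash = nash_solve(g$problem, g$model),
       stackelberg = stackelberg_solve(g$problem, g$model),
       game = g)
})

# a trait-neutral single-type model: logistic growth, no selection
neutral_model <- function(r = 1, K = 1000) {
  gfun_model(function(v, i, u, x, m, params) r * (1 - x[1] / K) - m,
             n_types = 1L, sigma = 1, trait_bounds = c(-1, 1),
             x_scale = K, name = "neutral")
}

# interior closed-form resistant ESS of the cancer model (hand-derived):
# stationarity of G in v at the ecological equilibrium gives
# g d w^2 + g m w - m b = 0 with w = k + b u
cancer_ess_oracle <- function(m, g = 0.8, d = 0.01, k = 2, b = 10) {
  if (m <= 0) return(0)
  w <- (-g * m + sqrt(g^2 * m^2 + 4 * g * d * m * b)) / (2 * g * d)
  max((w - k) / b, 0)
}

# equilibrium of the two-type competition system at fixed (u_R, m):
# interior solve of alpha x = K c, else the single-type corner
cancer_equilibrium_oracle <- function(uR, m, r_max = 0.45, g = 0.8,
                                      K = 10000, d = 0.01, k = 2, b = 10,
                                      alpha = matrix(c(1, 0.1, 0.9, 1),
                                                     2, 2, byrow = TRUE)) {
  cS <- 1 - (d + m / k) / r_max
  cR <- 1 - (d + m / (k + b * uR)) / (r_max * exp(-g * uR))
  x <- solve(alpha, K * c(cS, cR))
  if (all(x > 0)) return(x)
  for (cand in list(c(max(K * cS, 0), 0), c(0, max(K * cR, 0)))) {
    GS <- r_max * (1 - sum(alpha[1, ] * cand) / K) - d - m / k
    GR <- r_max * exp(-g * uR) * (1 - sum(alpha[2, ] * cand) / K) - d -
      m / (k + b * uR)
    if ((cand[1] > 0 || GS <= 1e-12) && (cand[2] > 0 || GR <= 1e-12))
      return(cand)
  }
  c(0, 0)
}
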