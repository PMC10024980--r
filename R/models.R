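#' Fisheries harvest game with an evolving catchability trait
#'
#' A single fish stock grows logistically with a trait-dependent carrying
#' capacity `K(v) = K_max exp(-v^2 / sigma_K^2)` and is harvested at rate
#' `H(v, m) = m exp(-v^2 / sigma_H^2)`, so that
#' `G(v, u, x, m) = r (1 - x / K(v)) - H(v, m)`.
#' The trait `u = 0` simultaneously maximizes carrying capacity and
#' catchability: without harvest the stock is under stabilizing selection
#' toward 0, while harvesting selects disruptively away from 0.  The
#' manager's profit is `Q(m, u, x) = H(u, m) x - c m` (harvest revenue
#' minus effort cost).
#'
#' @param r intrinsic growth rate (per time).
#' @param K_max maximal carrying capacity (biomass).
#' @param sigma_K carrying-capacity kernel width (trait units).
#' @param sigma_H harvesting kernel width (trait units).
#' @param c cost per unit harvesting effort.
#' @param sigma evolutionary speed of the catchability trait.
#' @return A list with components `model` (a [gfun_model()], trait bounds
#'   `[-2, 2]`) and `problem` (a [leader_problem()], actions in `[0, 1]`).
#' @seealso [fisheries_closed_forms()] for the analytic oracles.
#' @export
fisheries_model <- function(r = 1.0, K_max = 10000, sigma_K = 0.55,
                            sigma_H = 0.50, c = 500, sigma = 1) {
  stopifnot(r > 0, K_max > 0, sigma_K > 0, sigma_H > 0, c > 0)
  p <- list(r = r, K_max = K_max, sigma_K = sigma_K, sigma_H = sigma_H,
            c = c)
  fitness <- function(v, i, u, x, m, params) {
    K <- params$K_max * exp(-v^2 / params$sigma_K^2)
    H <- m * exp(-v^2 / params$sigma_H^2)
    params$r * (1 - x[1] / K) - H
  }
  gradient <- function(v, i, u, x, m, params) {
    K <- params$K_max * exp(-v^2 / params$sigma_K^2)
    H <- m * exp(-v^2 / params$sigma_H^2)
    -params$r * x[1] * (2 * v / params$sigma_K^2) / K +
      H * (2 * v / params$sigma_H^2)
  }
  model <- gfun_model(fitness, n_types = 1L, sigma = sigma,
                      trait_bounds = c(-2, 2), params = p,
                      gradient = gradient, u_ref = 0, x_scale = K_max,
                      name = "fisheries")
  objective <- function(m, u, x)
    m * exp(-u[1]^2 / sigma_H^2) * x[1] - c * m
  problem <- leader_problem(objective, m_bounds = c(0, 1), m_max = 1,
                            name = "fisheries manager")
  list(model = model, problem = problem)
}

#' Closed-form oracles for the fisheries game
#'
#' Hand-derived analytic solutions of the fisheries model, used as
#' independent checks of the generic numerical solvers:
#'
#' * `x_star(m, u) = K(u) (1 - H(u, m) / r)` (clipped at 0): the ecological
#'   equilibrium, from `G|v=u = 0`.
#' * `m_c = r sigma_H^2 / (sigma_K^2 + sigma_H^2)`: the critical harvesting
#'   effort; solving `d2G/dv2 = 0` at `u = 0`, `x = K_max (1 - m/r)` gives
#'   the pitchfork point of the ESS.
#' * `u_branch(m) = +- sigma_H sqrt(log(m / m_c))` for `m > m_c`: setting
#'   the selection gradient `2u [H/sigma_H^2 - (r - H)/sigma_K^2]` to zero
#'   for `u != 0` requires `H(u, m) = m_c`.
#' * `m_star_at_u0 = (r/2)(1 - c/K_max)`: the leader's best response to
#'   `u = 0`, from `dQ/dm = K_max (1 - 2 m / r) - c = 0`.
#'
#' @inheritParams fisheries_model
#' @return A list with function `x_star(m, u)`, number `m_c`, function
#'   `u_branch(m)` (returns `c(-u, +u)` above the bifurcation, an empty
#'   vector at or below it) and number `m_star_at_u0`.
#' @export
fisheries_closed_forms <- function(r = 1.0, K_max = 10000, sigma_K = 0.55,
                                   sigma_H = 0.50, c = 500) {
  m_c <- r * sigma_H^2 / (sigma_K^2 + sigma_H^2)
  list(
    x_star = function(m, u) {
      K <- K_max * exp(-u^2 / sigma_K^2)
      pmax(K * (1 - m * exp(-u^2 / sigma_H^2) / r), 0)
    },
    m_c = m_c,
    u_branch = function(m) {
      if (m <= m_c) return(numeric(0))
      u <- sigma_H * sqrt(log(m / m_c))
      c(-u, u)
    },
    m_star_at_u0 = (r / 2) * (1 - c / K_max)
  )
}

#' Adaptive cancer-therapy game with sensitive and resistant cells
#'
#' Two cancer-cell types compete under Lotka-Volterra competition: type S
#' (drug-sensitive, frozen trait `u_S = 0`) and type R whose resistance
#' trait `u_R >= 0` evolves.  The G-function for a focal cell of type `i`
#' with resistance trait `v` is
#' `G = r(v) (1 - sum_j alpha[i, j] x_j / K) - d - m / (k + b v)`, where
#' `r(v) = r_max exp(-g v)` carries the cost of resistance, `k` is innate
#' resistance present before drug exposure, and `b` scales how strongly
#' evolved resistance blunts the therapy.  The physician doses in
#' `m` between 0 (no dose) and 1 (maximum tolerable dose, MTD) and
#' maximizes quality of life
#' `Q = Q_max - c1 (x_total/K)^2 - c2 u_R^2 - c3 m^2`,
#' penalising tumour burden, evolved resistance and toxicity.  The
#' equilibrium burden classifies the outcome (see [classify_outcome()]).
#'
#' @param r_max maximal proliferation rate.
#' @param g cost-of-resistance coefficient.
#' @param K carrying capacity (cells).
#' @param d natural death rate.
#' @param k innate resistance.
#' @param b benefit of evolved resistance in reducing therapy efficacy.
#' @param alpha 2x2 competition matrix, `alpha[i, j]` = effect of type `j`
#'   on type `i`, rows/cols ordered (S, R).
#' @param sigma_S,sigma_R evolutionary speeds (the sensitive type does not
#'   evolve: `sigma_S = 0`).
#' @param delta progression threshold as a fraction of `K`.
#' @param Q_max,c1,c2,c3 quality-of-life weights: maximum quality and the
#'   penalties on squared relative burden, resistance and dose.
#' @return A list with components `model` (types ordered S, R; trait
#'   bounds `[0, 5]`) and `problem` (dose in `[0, 1]`, naive `m_max = 1`,
#'   outcome classification attached).
#' @export
cancer_model <- function(r_max = 0.45, g = 0.8, K = 10000, d = 0.01,
                         k = 2, b = 10,
                         alpha = matrix(c(1, 0.1, 0.9, 1), 2, 2,
                                        byrow = TRUE),
                         sigma_S = 0, sigma_R = 1, delta = 0.7,
                         Q_max = 1, c1 = 0.54, c2 = 0.21, c3 = 0.25) {
  stopifnot(r_max > 0, g >= 0, K > 0, d >= 0, k > 0, b >= 0,
            all(dim(alpha) == c(2, 2)), delta > 0, delta < 1)
  p <- list(r_max = r_max, g = g, K = K, d = d, k = k, b = b,
            alpha = alpha)
  fitness <- function(v, i, u, x, m, params) {
    comp <- sum(params$alpha[i, ] * x)
    params$r_max * exp(-params$g * v) * (1 - comp / params$K) -
      params$d - m / (params$k + params$b * v)
  }
  gradient <- function(v, i, u, x, m, params) {
    comp <- sum(params$alpha[i, ] * x)
    -params$g * params$r_max * exp(-params$g * v) *
      (1 - comp / params$K) +
      m * params$b / (params$k + params$b * v)^2
  }
  model <- gfun_model(fitness, n_types = 2L, sigma = c(sigma_S, sigma_R),
                      trait_bounds = matrix(c(0, 5, 0, 5), 2, 2,
                                            byrow = TRUE),
                      params = p, gradient = gradient, u_ref = c(0, 0),
                      x_scale = c(K, K) / 2, name = "cancer")
  objective <- function(m, u, x)
    Q_max - c1 * (sum(x) / K)^2 - c2 * u[2]^2 - c3 * m^2
  problem <- leader_problem(objective, m_bounds = c(0, 1), m_max = 1,
                            outcome_fn = function(x)
                              classify_outcome(sum(x), delta = delta,
                                               K = K),
                            name = "physician")
  list(model = model, problem = problem)
}

#' Classify a tumour-burden outcome
#'
#' Maps the total equilibrium burden to one of three outcomes: extinction
#' (`x* <= 0`, cancer cured), progression (`x* > delta K`), or
#' stabilization (`0 < x* <= delta K`, chronic control); the boundary
#' `x* = delta K` counts as stabilization (closed interval).
#'
#' @param x_total total equilibrium population (finite scalar or vector).
#' @param delta progression threshold fraction in (0, 1).
#' @param K carrying capacity.
#' @param tol numerical slack below which a burden counts as extinct.
#' @return Character vector in `c("extinction", "stabilization",
#'   "progression")`.
#' @export
classify_outcome <- function(x_total, delta = 0.7, K = 10000, tol = 1e-9) {
  stopifnot(all(is.finite(x_total)), delta > 0, delta < 1)
  ifelse(x_total <= tol, "extinction",
         ifelse(x_total > delta * K, "progression", "stabilization"))
}
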