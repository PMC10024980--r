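#' Declare a fitness-generating (G-function) follower model
#'
#' A G-function model describes the fitness of a rare focal individual with
#' scalar trait `v` and type `i` in a resident population with trait vector
#' `u`, population vector `x`, under a scalar leader action `m`.  Substituting
#' `v = u[i]` yields the per-capita growth rate of residents of type `i`, and
#' the coupled Darwinian dynamics follow (see [darwinian_rhs()]).
#'
#' @param fitness function `(v, i, u, x, m, params)` returning the per-capita
#'   growth rate of a focal individual of type `i` with trait `v`.  Must be
#'   finite for admissible arguments.
#' @param n_types number of follower types.
#' @param sigma per-type evolutionary speeds (heritability times additive
#'   variance scale), finite and non-negative.  A type with `sigma[i] = 0`
#'   has a frozen trait.
#' @param trait_bounds closed admissible trait interval, either a length-2
#'   vector recycled to all types or an `n_types x 2` matrix.
#' @param params named list of model parameters, passed to `fitness`.
#' @param gradient optional analytic derivative `dG/dv`, same signature as
#'   `fitness`.  When absent, derivatives are taken by central finite
#'   differences.
#' @param u_ref reference trait values; frozen types keep these values and
#'   they seed trait searches.
#' @param x_scale characteristic population scale per type
#'   (carrying-capacity scale); used for default initial conditions and for
#'   normalising population-sensitivity diagnostics.
#' @param sigma_mode `"constant"` (default) treats `sigma` as constant;
#'   `"linear_x"` uses the adaptive-dynamics style speed
#'   `sigma[i] * x[i]`.
#' @param name model label used in printing and run manifests.
#'
#' @return An object of class `gfun_model`.
#' @seealso [fisheries_model()], [cancer_model()] for built-in instances.
#' @export
gfun_model <- function(fitness, n_types = 1L, sigma = 1,
                       trait_bounds = c(-Inf, Inf), params = list(),
                       gradient = NULL, u_ref = rep(0, n_types),
                       x_scale = rep(1, n_types),
                       sigma_mode = c("constant", "linear_x"),
                       name = "gfun_model") {
  stopifnot(is.function(fitness), n_types >= 1)
  sigma_mode <- match.arg(sigma_mode)
  sigma <- rep_len(as.numeric(sigma), n_types)
  if (any(!is.finite(sigma)) || any(sigma < 0))
    stop("'sigma' entries must be finite and >= 0")
  if (is.matrix(trait_bounds)) {
    stopifnot(nrow(trait_bounds) == n_types, ncol(trait_bounds) == 2)
  } else {
    stopifnot(length(trait_bounds) == 2)
    trait_bounds <- matrix(rep(trait_bounds, each = n_types), n_types, 2)
  }
  if (any(trait_bounds[, 1] > trait_bounds[, 2]))
    stop("trait_bounds must satisfy lower <= upper")
  u_ref <- rep_len(as.numeric(u_ref), n_types)
  x_scale <- rep_len(as.numeric(x_scale), n_types)
  structure(list(fitness = fitness, n_types = as.integer(n_types),
                 sigma = sigma, trait_bounds = trait_bounds, params = params,
                 gradient = gradient, u_ref = u_ref, x_scale = x_scale,
                 sigma_mode = sigma_mode, name = name),
            class = "gfun_model")
}

#' @export
print.gfun_model <- function(x, ...) {
  cat("<gfun_model> ", x$name, "\n", sep = "")
  cat("  types: ", x$n_types,
      ";  evolutionary speeds: ", paste(signif(x$sigma, 4), collapse = ", "),
      "\n", sep = "")
  cat("  trait bounds: ",
      paste(apply(x$trait_bounds, 1, function(b)
        sprintf("[%g, %g]", b[1], b[2])), collapse = "  "), "\n", sep = "")
  if (length(x$params))
    cat("  params: ", paste(names(x$params), unlist(x$params), sep = " = ",
                            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Eco-evolutionary state
#'
#' Bundles population sizes and trait values at a time point.
#'
#' @param x non-negative population sizes per type.
#' @param u trait value per type.
#' @param t time (default 0).
#' @return An object of class `eco_evo_state`.
#' @export
eco_evo_state <- function(x, u, t = 0) {
  x <- as.numeric(x); u <- as.numeric(u)
  if (length(x) != length(u))
    stop("'x' and 'u' must have the same length")
  if (any(!is.finite(x)) || any(x < 0))
    stop("population sizes 'x' must be finite and >= 0")
  structure(list(x = x, u = u, t = as.numeric(t)), class = "eco_evo_state")
}

#' @export
print.eco_evo_state <- function(x, ...) {
  cat(sprintf("<eco_evo_state> t = %g\n  x: %s\n  u: %s\n", x$t,
              paste(signif(x$x, 6), collapse = ", "),
              paste(signif(x$u, 6), collapse = ", ")))
  invisible(x)
}

as_state <- function(model, state) {
  if (inherits(state, "eco_evo_state")) {
    if (length(state$x) != model$n_types)
      stop("state length does not match model n_types")
    return(state)
  }
  stop("'state' must be an eco_evo_state")
}

eval_fitness <- function(model, v, i, u, x, m) {
  g <- model$fitness(v, i, u, x, m, model$params)
  if (any(!is.finite(g))) {
    pp <- paste(names(model$params), unlist(model$params), sep = " = ",
                collapse = ", ")
    stop(sprintf(paste0("non-finite fitness in model '%s' at v = %g, ",
                        "type %d, m = %g (params: %s)"),
                 model$name, v[1], i, m, pp))
  }
  g
}

#' Fitness of a resident follower
#'
#' Evaluates the G-function at `v = u[i]`, i.e. the per-capita growth rate
#' of residents of type `i`.  At any positive ecological equilibrium this is
#' zero for every extant type.
#'
#' @param model a [gfun_model()].
#' @param type focal type index.
#' @param state an [eco_evo_state()].
#' @param m scalar leader action.
#' @return Per-capita growth rate (scalar).
#' @export
resident_fitness <- function(model, type = 1L, state, m) {
  state <- as_state(model, state)
  stopifnot(type >= 1, type <= model$n_types)
  eval_fitness(model, state$u[type], type, state$u, state$x, m)
}

#' Fitness of a rare mutant
#'
#' Evaluates the G-function at an arbitrary mutant trait `v` for a focal
#' individual of the given type, holding residents fixed.
#'
#' @inheritParams resident_fitness
#' @param v mutant trait value (vectorised).
#' @return Per-capita growth rate(s) of the mutant.
#' @export
mutant_fitness <- function(model, v, type = 1L, state, m) {
  state <- as_state(model, state)
  vapply(v, function(vv) eval_fitness(model, vv, type, state$u, state$x, m),
         numeric(1))
}

#' Selection gradient dG/dv at the resident trait
#'
#' Uses the model's analytic derivative when supplied, otherwise a central
#' finite difference with step `1e-6 * max(1, |u_i|)`.  Near a trait bound a
#' one-sided difference is used (with a warning).
#'
#' @inheritParams resident_fitness
#' @param h finite-difference step; default `1e-6 * max(1, |u_i|)`.
#' @return The selection gradient (scalar).
#' @export
fitness_gradient <- function(model, type = 1L, state, m, h = NULL) {
  state <- as_state(model, state)
  ui <- state$u[type]
  if (!is.null(model$gradient)) {
    g <- model$gradient(ui, type, state$u, state$x, m, model$params)
    if (!is.finite(g)) stop("non-finite analytic gradient")
    return(g)
  }
  if (is.null(h)) h <- 1e-6 * max(1, abs(ui))
  lb <- model$trait_bounds[type, 1]; ub <- model$trait_bounds[type, 2]
  # shrink the step to stay inside the admissible interval when possible
  room <- min(ui - lb, ub - ui)
  if (room > 0 && room < h) h <- room
  f <- function(v) eval_fitness(model, v, type, state$u, state$x, m)
  if (ui - h >= lb && ui + h <= ub) {
    (f(ui + h) - f(ui - h)) / (2 * h)
  } else if (ui + h <= ub) {
    warning("trait at lower bound; using one-sided difference")
    (f(ui + h) - f(ui)) / h
  } else {
    warning("trait at upper bound; using one-sided difference")
    (f(ui) - f(ui - h)) / h
  }
}

#' Curvature d2G/dv2 at the resident trait
#'
#' Second derivative of mutant fitness in the mutant trait, residents and
#' populations held fixed; the sign classifies a singular strategy as a
#' fitness maximum (ESS candidate) or minimum.
#'
#' @inheritParams resident_fitness
#' @param h finite-difference step (default `1e-4 * max(1, |u_i|)`).
#' @return Second derivative (scalar).
#' @export
fitness_curvature <- function(model, type = 1L, state, m, h = NULL) {
  state <- as_state(model, state)
  ui <- state$u[type]
  if (is.null(h)) h <- 1e-4 * max(1, abs(ui))
  f <- function(v) eval_fitness(model, v, type, state$u, state$x, m)
  (f(ui + h) - 2 * f(ui) + f(ui - h)) / h^2
}

#' Right-hand side of the Darwinian dynamics
#'
#' The coupled eco-evolutionary dynamics: `dx_i/dt = x_i G|v=u_i` and
#' `du_i/dt = sigma_i dG/dv|v=u_i` (with speed `sigma_i x_i` under the
#' `"linear_x"` mode).  Extinct types stay extinct (`x_i = 0` implies
#' `dx_i/dt = 0`) and frozen traits (`sigma_i = 0`) do not move.
#'
#' @inheritParams resident_fitness
#' @return A list with components `dx` and `du`.
#' @export
darwinian_rhs <- function(model, state, m) {
  state <- as_state(model, state)
  n <- model$n_types
  dx <- numeric(n); du <- numeric(n)
  for (i in seq_len(n)) {
    if (state$x[i] > 0)
      dx[i] <- state$x[i] * eval_fitness(model, state$u[i], i,
                                         state$u, state$x, m)
    if (model$sigma[i] > 0) {
      sp <- if (model$sigma_mode == "linear_x")
        model$sigma[i] * state$x[i] else model$sigma[i]
      du[i] <- sp * fitness_gradient(model, i, state, m)
    }
  }
  list(dx = dx, du = du)
}

#' Integrate the Darwinian dynamics
#'
#' Numerically integrates the coupled population/trait system with an
#' adaptive stiff-capable scheme (`deSolve::ode`, method `lsoda`).  The
#' trajectory is flagged converged when the sup-norm of the right-hand side
#' falls below `conv_tol` at the last two reported times.  Populations that
#' numerically step below zero are clipped at zero (with a note).
#'
#' @inheritParams resident_fitness
#' @param initial initial [eco_evo_state()].
#' @param horizon integration time (must be positive).
#' @param n_out number of reported time points.
#' @param rtol,atol relative/absolute integration tolerances.
#' @param conv_tol convergence threshold on the sup-norm of the
#'   right-hand side.
#' @return An object of class `eco_evo_trajectory` with components `times`,
#'   `x` and `u` (matrices, rows are time points), `converged`, `rhs_norm`
#'   and `final_state`.
#' @export
integrate_darwinian <- function(model, initial, m, horizon = 500,
                                n_out = 201, rtol = 1e-9, atol = 1e-10,
                                conv_tol = 1e-8) {
  initial <- as_state(model, initial)
  stopifnot(horizon > 0)
  n <- model$n_types
  y0 <- c(initial$x, initial$u)
  deriv <- function(t, y, parms) {
    st <- list(x = pmax(y[seq_len(n)], 0), u = y[n + seq_len(n)], t = t)
    class(st) <- "eco_evo_state"
    d <- darwinian_rhs(model, st, m)
    list(c(d$dx, d$du))
  }
  times <- seq(0, horizon, length.out = n_out)
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("stiff integration failure: retry with a smaller horizon, looser ",
         "tolerances or an implicit method")
  xs <- sol[, 1 + seq_len(n), drop = FALSE]
  us <- sol[, 1 + n + seq_len(n), drop = FALSE]
  if (any(xs < -atol))
    message("note: negative populations of magnitude ",
            signif(-min(xs), 3), " clipped at 0")
  xs[xs < 0] <- 0
  sup_rhs <- function(k) {
    st <- eco_evo_state(xs[k, ], us[k, ], sol[k, 1])
    max(abs(unlist(darwinian_rhs(model, st, m))))
  }
  nr <- nrow(sol)
  rhs_norm <- sup_rhs(nr)
  converged <- rhs_norm < conv_tol && sup_rhs(nr - 1) < conv_tol
  structure(list(times = sol[, 1], x = xs, u = us, converged = converged,
                 rhs_norm = rhs_norm, m = m,
                 final_state = eco_evo_state(xs[nr, ], us[nr, ], sol[nr, 1])),
            class = "eco_evo_trajectory")
}

#' @export
print.eco_evo_trajectory <- function(x, ...) {
  cat(sprintf(paste0("<eco_evo_trajectory> m = %g, t in [0, %g], ",
                     "%d points, converged: %s (|rhs| = %.3g)\n"),
              x$m, max(x$times), length(x$times), x$converged, x$rhs_norm))
  print(x$final_state)
  invisible(x)
}

#' @export
as.data.frame.eco_evo_trajectory <- function(x, ...) {
  n <- ncol(x$x)
  out <- data.frame(t = x$times)
  for (i in seq_len(n)) out[[paste0("x_", i)]] <- x$x[, i]
  for (i in seq_len(n)) out[[paste0("u_", i)]] <- x$u[, i]
  out
}

#' Write a trajectory as CSV
#'
#' Columns are `t, x_1..x_n, u_1..u_n`, plain `.` decimal.
#'
#' @param trajectory an `eco_evo_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}
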