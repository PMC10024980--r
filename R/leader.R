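#' Declare the leader's optimization problem
#'
#' @param objective function `(m, u, x)` returning the leader's payoff `Q`;
#'   must be finite and differentiable on the admissible set, evaluated at
#'   the followers' ecological equilibrium.
#' @param m_bounds closed admissible interval for the leader action.
#' @param m_max the naive (aggressive) action; defaults to the upper bound.
#' @param outcome_fn optional function mapping the follower population
#'   vector to a qualitative outcome label (used e.g. for therapy outcome
#'   classification).
#' @param name label used in printing and manifests.
#' @return An object of class `leader_problem`.
#' @export
leader_problem <- function(objective, m_bounds = c(0, 1), m_max = NULL,
                           outcome_fn = NULL, name = "leader") {
  stopifnot(is.function(objective), length(m_bounds) == 2,
            m_bounds[1] < m_bounds[2])
  m_max <- m_max %||% m_bounds[2]
  stopifnot(m_max >= m_bounds[1], m_max <= m_bounds[2])
  structure(list(objective = objective, m_bounds = m_bounds, m_max = m_max,
                 outcome_fn = outcome_fn, name = name),
            class = "leader_problem")
}

#' @export
print.leader_problem <- function(x, ...) {
  cat(sprintf("<leader_problem> %s: m in [%g, %g], naive m_max = %g\n",
              x$name, x$m_bounds[1], x$m_bounds[2], x$m_max))
  invisible(x)
}

#' Leader objective evaluated at the ecological equilibrium
#'
#' Computes `Q(m, u, x*(m, u))`, the payoff an ecologically enlightened
#' leader anticipates for fixed follower traits.
#'
#' @param problem a [leader_problem()].
#' @param model a [gfun_model()].
#' @param m scalar leader action.
#' @param u trait vector of the followers.
#' @param init_x starting populations for the equilibrium solve.
#' @return Scalar payoff.
#' @export
objective_at_eco_equilibrium <- function(problem, model, m, u,
                                         init_x = NULL) {
  x <- ecological_equilibrium(model, u, m, init_x = init_x)
  q <- problem$objective(m, u, x)
  if (!is.finite(q)) stop("non-finite leader objective at m = ", m)
  q
}

#' Leader's best response to fixed follower traits
#'
#' Maximizes `Q(m, u, x*(m, u))` over the admissible action interval with
#' the followers' traits held fixed: a uniform grid scan followed by local
#' refinement.  A flat objective returns the lower bound with a warning;
#' payoff ties are broken toward the smaller (less aggressive) action.
#'
#' @inheritParams objective_at_eco_equilibrium
#' @param n_grid number of grid points in the initial scan.
#' @param tol refinement tolerance in `m`.
#' @return The maximizing action, with attribute `"Q"` (its payoff).
#' @export
leader_best_response <- function(problem, model, u, n_grid = 201,
                                 tol = 1e-10) {
  mb <- problem$m_bounds
  ms <- seq(mb[1], mb[2], length.out = n_grid)
  qs <- numeric(n_grid)
  xw <- NULL
  for (k in seq_len(n_grid)) {
    x <- ecological_equilibrium(model, u, ms[k], init_x = xw)
    if (any(x > 0)) xw <- pmax(x, 1e-3 * model$x_scale)
    qs[k] <- problem$objective(ms[k], u, x)
  }
  if (max(qs) - min(qs) < 1e-12) {
    warning("leader objective is flat in m; returning the lower bound")
    m0 <- mb[1]
    attr(m0, "Q") <- qs[1]
    return(m0)
  }
  near <- which(qs > max(qs) - 1e-12)
  if (length(near) > 1)
    message("note: leader payoff ties broken toward the smaller action")
  k <- min(near)
  lo <- ms[max(1, k - 1)]; hi <- ms[min(n_grid, k + 1)]
  f <- function(m) objective_at_eco_equilibrium(problem, model, m, u)
  opt <- optimize(f, c(lo, hi), maximum = TRUE, tol = tol)
  cand_m <- c(opt$maximum, lo, hi, ms[k])
  cand_q <- c(opt$objective, f(lo), f(hi), qs[k])
  best <- which(cand_q > max(cand_q) - 1e-12)
  j <- best[which.min(cand_m[best])]
  m_star <- cand_m[j]
  attr(m_star, "Q") <- cand_q[j]
  m_star
}

# pick the follower ESS at action m on the requested branch
follower_response <- function(model, m, branch_hint = "+", u_fixed = NULL) {
  sols <- ess_solve(model, m, u_fixed = u_fixed)
  ess <- Filter(function(s) isTRUE(s$is_ess), sols)
  pool <- if (length(ess)) ess else sols
  if (length(pool) == 0L) return(NULL)
  us <- vapply(pool, function(s) s$u_star[s$evolving], numeric(1))
  j <- if (is.numeric(branch_hint)) which.min(abs(us - branch_hint))
  else switch(branch_hint,
              "+" = which.max(us), "-" = which.min(us),
              "0" = which.min(abs(us)), which.max(us))
  pool[[j]]
}

# bilevel objective Q(m, u*(m), x*(m, u*(m))) continued from a trait hint
bilevel_objective <- function(problem, model, m, u_hint, u_fixed = NULL) {
  ev <- evolving_index(model)
  u_fixed <- rep_len(as.numeric(u_fixed %||% model$u_ref), model$n_types)
  gfun <- resident_gradient_fun(model, m, u_fixed)
  u <- track_singular(model, gfun, u_hint)
  if (!is.finite(u)) return(list(Q = -Inf, u = NA_real_, x = NULL))
  uv <- u_fixed; uv[ev] <- u
  x <- ecological_equilibrium(model, uv, m)
  list(Q = problem$objective(m, uv, x), u = u, x = x, u_vec = uv)
}

strategy_record <- function(name, m, eq, problem, converged = TRUE,
                            extra = list()) {
  x <- eq$x_star; uv <- eq$u_star
  rec <- list(strategy = name, m = m, u = uv, x = x,
              Q = problem$objective(m, uv, x), converged = converged)
  if (!is.null(problem$outcome_fn)) rec$outcome <- problem$outcome_fn(x)
  c(rec, extra)
}

#' The naive (constant aggressive) leader strategy
#'
#' The leader plays the constant action `m_max`, ignoring the followers'
#' dynamics; the realized payoff is evaluated at the followers'
#' eco-evolutionary response (their ESS at `m_max`).
#'
#' @inheritParams objective_at_eco_equilibrium
#' @param branch_hint which ESS branch the followers settle on when several
#'   coexist: `"+"`, `"-"`, `"0"` or a numeric trait hint.
#' @return A list with the action, follower response, payoff and (when the
#'   problem defines one) the qualitative outcome.
#' @export
naive_strategy <- function(problem, model, branch_hint = "+") {
  m <- problem$m_max
  eq <- follower_response(model, m, branch_hint)
  if (is.null(eq)) stop("no follower response found at m_max = ", m)
  strategy_record("naive", m, eq, problem)
}

#' Nash (ecologically enlightened) leader strategy
#'
#' Solves for an intersection of the leader's best-response curve
#' `m = m*(u)` and the followers' ESS response `u = u*(m)` by damped
#' fixed-point iteration, then refines the fixed point with undamped
#' alternation at tight tolerance.  At the solution no player improves by a
#' unilateral deviation.  When the followers' response has several
#' branches, `branch_hint` selects the branch (for a trait-symmetric model
#' the mirrored solution is also reported in `$mirror`).
#'
#' @inheritParams naive_strategy
#' @param m_init starting action (default: midpoint of the bounds).
#' @param damping damping factor of the fixed-point iteration in (0, 1].
#' @param max_iter maximum damped iterations.
#' @param tol convergence tolerance on the action.
#' @return A list with `m`, `u`, `x`, `Q`, `converged`, `iterations` and
#'   `history`; non-convergence is reported in `history` (last iterates).
#' @export
nash_solve <- function(problem, model, branch_hint = "+", m_init = NULL,
                       damping = 0.5, max_iter = 60, tol = 1e-9) {
  mb_bounds <- problem$m_bounds
  m <- m_init %||% mean(mb_bounds)
  hist <- numeric(0)
  converged <- FALSE
  eq <- NULL
  u_hint <- branch_hint
  # phase 1: damped alternation locks onto a branch and approaches the
  # intersection of the two best-response curves
  for (it in seq_len(max_iter)) {
    eq <- follower_response(model, m, u_hint)
    if (is.null(eq)) stop("follower response vanished at m = ", m,
                          " during Nash iteration")
    u_hint <- eq$u_star[eq$evolving]      # stay on the same branch
    mb <- leader_best_response(problem, model, eq$u_star)
    hist <- c(hist, m)
    delta <- as.numeric(mb) - m
    if (abs(delta) < 2e-3 * diff(mb_bounds)) { converged <- TRUE; break }
    m <- min(max(m + damping * delta, mb_bounds[1]), mb_bounds[2])
  }
  # phase 2: the fixed point is a root of psi(m) = m*(u*(m)) - m; bracket it
  # around the damped iterate and solve to tight tolerance
  psi <- function(mm) {
    u <- bilevel_objective(problem, model, mm, u_hint)$u
    if (!is.finite(u)) return(NA_real_)
    uv <- eq$u_star; uv[eq$evolving] <- u
    as.numeric(leader_best_response(problem, model, uv, tol = 1e-12)) - mm
  }
  if (converged) {
    converged <- FALSE
    p0 <- psi(m)
    if (is.finite(p0) && abs(p0) < tol) {
      converged <- TRUE
    } else if (is.finite(p0)) {
      dlt <- max(4 * abs(p0), 1e-6)
      a <- m; b <- m; pa <- p0; pb <- p0
      for (tries in 1:10) {
        if (p0 > 0) { b <- min(b + dlt, mb_bounds[2]); pb <- psi(b) }
        else { a <- max(a - dlt, mb_bounds[1]); pa <- psi(a) }
        if (is.finite(pa) && is.finite(pb) && pa * pb <= 0) break
        dlt <- dlt * 3
      }
      if (is.finite(pa) && is.finite(pb) && pa * pb <= 0) {
        m <- uniroot(psi, c(a, b), f.lower = pa, f.upper = pb,
                     tol = 1e-11)$root
        converged <- TRUE
      } else if (abs(p0) < 1e-6) {
        # fixed point pinned at an action bound
        m <- if (p0 > 0) mb_bounds[2] else mb_bounds[1]
        converged <- TRUE
      }
    }
    # phase 3: polish by zeroing the stationarity condition in m (trait
    # re-tracked between passes), so the reported first-order residual
    # vanishes to root tolerance
    if (m > mb_bounds[1] + 1e-3 && m < mb_bounds[2] - 1e-3) {
      h <- 1e-4
      for (pass in 1:3) {
        uv <- bilevel_objective(problem, model, m, u_hint)$u_vec
        if (is.null(uv)) break
        r <- function(mm) {
          f <- function(z)
            objective_at_eco_equilibrium(problem, model, z, uv)
          (f(mm + h) - f(mm - h)) / (2 * h)
        }
        a <- max(m - 4e-4, mb_bounds[1]); b <- min(m + 4e-4, mb_bounds[2])
        ra <- r(a); rb <- r(b)
        if (!is.finite(ra) || !is.finite(rb) || ra * rb > 0) break
        m_new <- uniroot(r, c(a, b), f.lower = ra, f.upper = rb,
                         tol = 1e-12)$root
        done <- abs(m_new - m) < 1e-11
        m <- m_new
        if (done) break
      }
    }
    eq <- follower_response(model, m, u_hint)
  }
  if (!converged)
    warning("Nash iteration did not converge after ", max_iter,
            " iterations; last actions: ",
            paste(signif(tail(hist, 5), 8), collapse = ", "),
            if (length(hist) > 3 &&
                sd(tail(hist, 4)) > 10 * tol) " (oscillation)" else "")
  rec <- strategy_record("nash", m, eq, problem, converged,
                         list(iterations = length(hist), history = hist))
  # mirrored branch solution for symmetric responses
  ev <- eq$evolving
  if (abs(eq$u_star[ev]) > 1e-8) {
    twin <- follower_response(model, m, -eq$u_star[ev])
    if (!is.null(twin) &&
        abs(twin$u_star[ev] + eq$u_star[ev]) < 1e-6 &&
        abs(problem$objective(m, twin$u_star, twin$x_star) - rec$Q) < 1e-9)
      rec$mirror <- list(m = m, u = twin$u_star, x = twin$x_star, Q = rec$Q)
  }
  rec
}

#' Stackelberg (evolutionarily enlightened) leader strategy
#'
#' Maximizes the bilevel objective `Q(m, u*(m), x*(m, u*(m)))` along every
#' ESS branch of the followers' response.  The objective is only piecewise
#' smooth: each branch segment is scanned on the diagram grid and refined
#' locally, and branch endpoints and bifurcation points enter as explicit
#' candidates.  When the maximizer sits at a bifurcation or segment
#' endpoint this is reported (`at_bifurcation` / `at_endpoint`).
#'
#' @inheritParams naive_strategy
#' @param diagram an [ess_branch_diagram()] over the admissible actions;
#'   computed with `n_grid` points when not supplied.
#' @param n_grid grid resolution used when `diagram` is `NULL`.
#' @return A list with `m`, `u`, `x`, `Q`, `branch_id`, `at_bifurcation`,
#'   `at_endpoint` and the `diagram` used.
#' @export
stackelberg_solve <- function(problem, model, diagram = NULL, n_grid = 201) {
  mb <- problem$m_bounds
  if (is.null(diagram))
    diagram <- ess_branch_diagram(model, seq(mb[1], mb[2],
                                             length.out = n_grid))
  br <- diagram$branches
  ess <- br[br$is_ess, , drop = FALSE]
  if (nrow(ess) == 0L) stop("no ESS branch available over the leader bounds")
  n <- model$n_types
  xcols <- paste0("x_", seq_len(n))
  qrow <- function(r) {
    uv <- model$u_ref; uv[evolving_index(model)] <- r$u_star
    problem$objective(r$m, uv, as.numeric(r[1, xcols]))
  }
  cand <- data.frame(m = numeric(0), u_hint = numeric(0),
                     branch_id = character(0), endpoint = logical(0),
                     stringsAsFactors = FALSE)
  for (id in unique(ess$branch_id)) {
    seg <- ess[ess$branch_id == id, , drop = FALSE]
    seg <- seg[order(seg$m), , drop = FALSE]
    qs <- vapply(seq_len(nrow(seg)), function(i) qrow(seg[i, ]), numeric(1))
    k <- which.max(qs)
    lo <- seg$m[max(1, k - 1)]; hi <- seg$m[min(nrow(seg), k + 1)]
    if (hi > lo) {
      opt <- optimize(function(m)
        bilevel_objective(problem, model, m,
                          u_hint = approx(seg$m, seg$u_star, m,
                                          rule = 2)$y)$Q,
        c(lo, hi), maximum = TRUE, tol = 1e-10)
      cand <- rbind(cand, data.frame(m = opt$maximum,
                                     u_hint = approx(seg$m, seg$u_star,
                                                     opt$maximum,
                                                     rule = 2)$y,
                                     branch_id = id, endpoint = FALSE))
    }
    cand <- rbind(cand,
                  data.frame(m = c(seg$m[1], seg$m[nrow(seg)]),
                             u_hint = c(seg$u_star[1],
                                        seg$u_star[nrow(seg)]),
                             branch_id = id, endpoint = TRUE))
    # bifurcation points adjoining this branch are candidate kink maxima
    if (nrow(diagram$bifurcations))
      for (mc in diagram$bifurcations$m_c) {
        u_hint <- approx(seg$m, seg$u_star, mc, rule = 2)$y
        cand <- rbind(cand, data.frame(m = mc, u_hint = u_hint,
                                       branch_id = id, endpoint = TRUE))
      }
  }
  vals <- lapply(seq_len(nrow(cand)), function(i)
    bilevel_objective(problem, model, cand$m[i], cand$u_hint[i]))
  qs <- vapply(vals, function(v) v$Q, numeric(1))
  best <- which(qs > max(qs) - 1e-12)
  j <- best[which.min(cand$m[best])]
  v <- vals[[j]]
  eq <- list(u_star = v$u_vec, x_star = v$x, evolving = evolving_index(model))
  at_bif <- nrow(diagram$bifurcations) > 0 &&
    any(abs(diagram$bifurcations$m_c - cand$m[j]) < 1e-8)
  strategy_record("stackelberg", cand$m[j], eq, problem, TRUE,
                  list(branch_id = cand$branch_id[j],
                       at_bifurcation = at_bif,
                       at_endpoint = cand$endpoint[j], diagram = diagram))
}

#' First-order-condition residuals of the leader
#'
#' Evaluates, by central finite differences along the followers' response,
#' the two first-order stationarity conditions of the leader: the Nash
#' condition (total derivative of `Q` in `m` with the follower trait held
#' fixed at `u*(m)`) and the Stackelberg condition (total derivative of the
#' bilevel objective including the trait response `du*/dm`).  At an
#' interior Nash (resp. Stackelberg) solution the first (resp. second)
#' residual vanishes.  Within `h` of a detected bifurcation the Stackelberg
#' residual is undefined (`NA`) because the response is not differentiable
#' there.
#'
#' @inheritParams naive_strategy
#' @param m action at which to evaluate the residuals.
#' @param h finite-difference step in `m`.
#' @param bifurcations optional vector of bifurcation actions (e.g. from an
#'   [ess_branch_diagram()]).
#' @return Named numeric vector `c(nash = ..., stackelberg = ...)`.
#' @export
foc_residuals <- function(problem, model, m, branch_hint = "+", h = 1e-4,
                          bifurcations = NULL) {
  mb <- problem$m_bounds
  eq <- follower_response(model, m, branch_hint)
  if (is.null(eq)) stop("no follower response at m = ", m)
  u0 <- eq$u_star
  if (m - h < mb[1] || m + h > mb[2]) {
    warning("action within a step of the admissible bounds; ",
            "using one-sided differences")
    h2 <- c(max(m - h, mb[1]), min(m + h, mb[2]))
  } else h2 <- c(m - h, m + h)
  f_nash <- function(mm) objective_at_eco_equilibrium(problem, model, mm, u0)
  nash_res <- (f_nash(h2[2]) - f_nash(h2[1])) / (h2[2] - h2[1])
  if (!is.null(bifurcations) && length(bifurcations) &&
      any(abs(bifurcations - m) <= h)) {
    stack_res <- NA_real_
  } else {
    f_st <- function(mm)
      bilevel_objective(problem, model, mm, u0[eq$evolving])$Q
    stack_res <- (f_st(h2[2]) - f_st(h2[1])) / (h2[2] - h2[1])
  }
  c(nash = nash_res, stackelberg = stack_res)
}

#' Check the Nash/Stackelberg coincidence conditions
#'
#' Audits the two sufficient conditions under which the Nash and
#' Stackelberg strategies of the leader provably coincide:
#' (a) the follower trait does not respond to the action
#' (`du*/dm = 0`), and (b) the objective does not depend on the trait
#' (`dQ/du = 0`) while additionally either the objective does not depend on
#' the population (`dQ/dx = 0`) or the equilibrium population is stationary
#' in the trait at the ESS (`dx*/du = 0`, the envelope property of purely
#' density-dependent competition).  Population sensitivities are reported
#' on the model's population scale (`x / x_scale`).
#'
#' @inheritParams naive_strategy
#' @param m action at which the conditions are evaluated (typically a
#'   candidate Nash action).  Ignored when `solution` is given.
#' @param solution optional [seg_solve()] result; enables the cross-check
#'   of the predicted verdict against `|m_N - m_S|`.
#' @param deriv_tol tolerance below which a derivative counts as zero.
#' @param coincide_tol tolerance in `m` for the cross-check verdict.
#' @param h step for `du*/dm`; population/trait sensitivities use `10 h`.
#' @return Object of class `theorem41_report`: holds the measured
#'   derivatives, which of cases (a)/(b) hold, the predicted verdict, and
#'   (when `solution` is given) the observed `|m_N - m_S|` and agreement.
#' @export
theorem41_check <- function(problem, model, m = NULL, solution = NULL,
                            branch_hint = "+", deriv_tol = 1e-6,
                            coincide_tol = 1e-5, h = 1e-4) {
  if (is.null(m)) {
    if (is.null(solution)) stop("supply either 'm' or 'solution'")
    m <- solution$nash$m
    branch_hint <- solution$nash$u[evolving_index(model)]
  }
  ev <- evolving_index(model)
  eq <- follower_response(model, m, branch_hint)
  u0 <- eq$u_star[ev]
  resp <- function(mm) {
    gfun <- resident_gradient_fun(model, mm, eq$u_star)
    track_singular(model, gfun, u0)
  }
  dudm <- (resp(m + h) - resp(m - h)) / (2 * h)
  hu <- 10 * h
  uv <- function(u) { v <- eq$u_star; v[ev] <- u; v }
  dQdu <- (problem$objective(m, uv(u0 + hu), eq$x_star) -
             problem$objective(m, uv(u0 - hu), eq$x_star)) / (2 * hu)
  n <- model$n_types
  dQdx <- vapply(seq_len(n), function(i) {
    hx <- 1e-4 * max(1, model$x_scale[i])
    xp <- eq$x_star; xp[i] <- xp[i] + hx
    xm <- eq$x_star; xm[i] <- max(xm[i] - hx, 0)
    (problem$objective(m, eq$u_star, xp) -
        problem$objective(m, eq$u_star, xm)) / (xp[i] - xm[i]) *
      model$x_scale[i]           # payoff change per x_scale of population
  }, numeric(1))
  xs <- function(u) ecological_equilibrium(model, uv(u), m) / model$x_scale
  dxdu <- (xs(u0 + hu) - xs(u0 - hu)) / (2 * hu)
  case_a <- abs(dudm) < deriv_tol
  case_b <- abs(dQdu) < deriv_tol &&
    (max(abs(dQdx)) < deriv_tol || max(abs(dxdu)) < 10 * deriv_tol)
  verdict <- if (case_a || case_b) "coincide" else "differ"
  rep <- list(m = m, du_dm = dudm, dQ_du = dQdu, dQ_dx = dQdx,
              dx_du = dxdu, case_a = case_a, case_b = case_b,
              verdict = verdict, gap = NA_real_, consistent = NA)
  if (!is.null(solution)) {
    rep$gap <- abs(solution$nash$m - solution$stackelberg$m)
    rep$consistent <- if (verdict == "coincide") rep$gap < coincide_tol
    else rep$gap >= coincide_tol
  }
  structure(rep, class = "theorem41_report")
}

#' @export
print.theorem41_report <- function(x, ...) {
  cat(sprintf("<theorem41_report> at m = %.6f\n", x$m))
  cat(sprintf("  du*/dm = %.3g; dQ/du = %.3g; max|dQ/dx| = %.3g; ",
              x$du_dm, x$dQ_du, max(abs(x$dQ_dx))))
  cat(sprintf("max|dx*/du| = %.3g\n", max(abs(x$dx_du))))
  cat(sprintf("  case (a): %s;  case (b): %s;  verdict: %s\n",
              x$case_a, x$case_b, x$verdict))
  if (!is.na(x$gap))
    cat(sprintf("  observed |m_N - m_S| = %.3g (%sconsistent)\n", x$gap,
                if (isTRUE(x$consistent)) "" else "IN"))
  invisible(x)
}

#' Solve a full Stackelberg evolutionary game
#'
#' Computes the leader's three strategies - naive ([naive_strategy()]),
#' Nash ([nash_solve()]) and Stackelberg ([stackelberg_solve()]) - together
#' with first-order-condition residuals and the coincidence audit
#' ([theorem41_check()]).  The Stackelberg payoff can never fall below the
#' Nash payoff; this dominance is asserted on every solved instance.
#'
#' @inheritParams naive_strategy
#' @param n_grid resolution of the branch diagram and grid scans.
#' @param m_init starting action for the Nash iteration.
#' @return Object of class `seg_solution` with components `naive`, `nash`,
#'   `stackelberg`, `foc_residuals`, `theorem41` and `diagram`.
#' @export
seg_solve <- function(problem, model, branch_hint = "+", n_grid = 201,
                      m_init = NULL) {
  mb <- problem$m_bounds
  diagram <- ess_branch_diagram(model, seq(mb[1], mb[2],
                                           length.out = n_grid))
  naive <- naive_strategy(problem, model, branch_hint)
  nash <- nash_solve(problem, model, branch_hint, m_init = m_init)
  stack <- stackelberg_solve(problem, model, diagram = diagram)
  if (stack$Q < nash$Q - 1e-6)
    warning("Stackelberg payoff fell below the Nash payoff; ",
            "the bilevel search likely missed a branch")
  bifs <- diagram$bifurcations$m_c
  res_n <- foc_residuals(problem, model, nash$m,
                         branch_hint = nash$u[evolving_index(model)],
                         bifurcations = bifs)
  res_s <- foc_residuals(problem, model, stack$m,
                         branch_hint = stack$u[evolving_index(model)],
                         bifurcations = bifs)
  sol <- structure(list(naive = naive, nash = nash, stackelberg = stack,
                        foc_residuals = list(at_nash = res_n,
                                             at_stackelberg = res_s),
                        diagram = diagram, problem = problem$name,
                        model = model$name),
                   class = "seg_solution")
  sol$theorem41 <- theorem41_check(problem, model, solution = sol)
  sol
}

#' @export
print.seg_solution <- function(x, ...) {
  cat("<seg_solution>", x$model, "vs", x$problem, "\n")
  fmt <- function(s) {
    ev_u <- paste(signif(s$u, 6), collapse = ", ")
    cat(sprintf("  %-12s m = %-10.6g Q = %-12.6g u = (%s)  x = (%s)%s\n",
                s$strategy, s$m, s$Q, ev_u,
                paste(signif(s$x, 6), collapse = ", "),
                if (!is.null(s$outcome)) paste0("  [", s$outcome, "]")
                else ""))
  }
  fmt(x$naive); fmt(x$nash); fmt(x$stackelberg)
  if (isTRUE(x$stackelberg$at_bifurcation))
    cat("  Stackelberg optimum sits at a bifurcation (kink maximizer)\n")
  cat(sprintf("  coincidence audit: %s (case a: %s, case b: %s)\n",
              x$theorem41$verdict, x$theorem41$case_a, x$theorem41$case_b))
  invisible(x)
}

#' @export
as.data.frame.seg_solution <- function(x, ...) {
  one <- function(s) {
    data.frame(strategy = s$strategy, m = s$m,
               u = paste(signif(s$u, 10), collapse = ";"),
               x = paste(signif(s$x, 10), collapse = ";"),
               Q = s$Q,
               outcome = s$outcome %||% NA_character_,
               stringsAsFactors = FALSE)
  }
  rbind(one(x$naive), one(x$nash), one(x$stackelberg))
}

#' Serialize a game solution
#'
#' Writes the solved strategies to a CSV summary and a JSON file carrying
#' the full numeric detail (residuals and theorem flags included).
#'
#' @param solution a `seg_solution`.
#' @param csv_path,json_path output paths (`NULL` to skip either).
#' @return The written paths, invisibly.
#' @export
write_seg_solution <- function(solution, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    write.csv(as.data.frame(solution), csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    strip <- function(s) s[setdiff(names(s), c("history", "diagram"))]
    payload <- list(model = solution$model, problem = solution$problem,
                    naive = strip(solution$naive),
                    nash = strip(solution$nash),
                    stackelberg = strip(solution$stackelberg),
                    foc_residuals = solution$foc_residuals,
                    theorem41 = unclass(solution$theorem41))
    jsonlite::write_json(sort_keys(payload), json_path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  }
  invisible(c(csv_path, json_path))
}

# recursively sort list names so serialized manifests diff cleanly
sort_keys <- function(x) {
  if (is.list(x) && !is.null(names(x)) && length(x))
    x <- lapply(x[order(names(x))], sort_keys)
  x
}
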