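#' Ecological equilibrium x*(m, u)
#'
#' Solves for non-negative population sizes at which every extant type has
#' zero per-capita growth, for fixed traits `u` and leader action `m`.
#' Candidate equilibria are found by Newton iteration on every subset of
#' extant types (extinct types held at zero), then screened: extant types
#' must be positive with `|G| <` `tol`, absent types must not be able to
#' invade (`G <= 0`), and the ecological Jacobian must be stable.  If more
#' than one screened candidate survives, the one reached by forward
#' integration of the ecological dynamics from `init_x` is returned, which
#' resolves equilibrium multiplicity in `x`.
#'
#' @param model a [gfun_model()].
#' @param u trait vector (length `n_types`), within trait bounds.
#' @param m scalar leader action.
#' @param init_x starting population vector; default is the model's
#'   carrying-capacity-scale `x_scale`.
#' @param tol residual tolerance on `G` at extant types.
#' @return Non-negative population vector `x*` with attribute
#'   `"extant"` (logical vector).  Types with no admissible positive root
#'   are returned as 0.
#' @export
ecological_equilibrium <- function(model, u, m, init_x = NULL, tol = 1e-12) {
  n <- model$n_types
  u <- rep_len(as.numeric(u), n)
  init_x <- rep_len(as.numeric(init_x %||% model$x_scale), n)
  gvec <- function(x, idx) {
    vapply(idx, function(i) eval_fitness(model, u[i], i, u, x, m), numeric(1))
  }
  candidates <- list()
  subsets <- subset_list(n)
  for (S in subsets) {
    x <- eco_newton(model, u, m, S, init_x, gvec, tol)
    if (is.null(x)) next
    if (valid_equilibrium(model, u, m, x, S, gvec, tol)) {
      dup <- any(vapply(candidates, function(c0)
        max(abs(c0 - x)) < 1e-6 * max(1, max(model$x_scale)), logical(1)))
      if (!dup) candidates[[length(candidates) + 1L]] <- x
    }
  }
  # the all-extinct state is valid only when no type can invade it
  x0 <- numeric(n)
  if (all(gvec(x0, seq_len(n)) <= tol + 1e-9))
    candidates[[length(candidates) + 1L]] <- x0
  if (length(candidates) == 0L) {
    x <- eco_integrate_fallback(model, u, m, init_x)
    if (is.null(x))
      stop("ecological root-finding failed to converge for m = ", m,
           "; no stable non-negative equilibrium located from init_x = ",
           paste(signif(init_x, 4), collapse = ", "))
    candidates <- list(x)
  }
  x <- if (length(candidates) == 1L) candidates[[1L]] else {
    xi <- eco_integrate_fallback(model, u, m, init_x) %||% candidates[[1L]]
    d <- vapply(candidates, function(c0) max(abs(c0 - xi)), numeric(1))
    candidates[[which.min(d)]]
  }
  attr(x, "extant") <- x > 0
  x
}

# non-empty subsets of 1:n in decreasing size order (2^n - 1 of them)
subset_list <- function(n) {
  subs <- list()
  for (k in (2^n - 1):1) {
    S <- which(bitwAnd(k, 2^(seq_len(n) - 1)) > 0)
    subs[[length(subs) + 1L]] <- S
  }
  subs[order(-lengths(subs))]
}

# Newton solve of G_i(x) = 0 for i in S with x_{-S} = 0; NULL on failure
eco_newton <- function(model, u, m, S, init_x, gvec, tol, max_iter = 60L) {
  n <- model$n_types
  x <- numeric(n)
  x[S] <- pmax(init_x[S], 1e-3 * model$x_scale[S])
  for (it in seq_len(max_iter)) {
    f <- gvec(x, S)
    if (any(!is.finite(f))) return(NULL)
    if (max(abs(f)) < tol) return(x)
    J <- matrix(0, length(S), length(S))
    for (j in seq_along(S)) {
      h <- 1e-7 * max(model$x_scale[S[j]], abs(x[S[j]]))
      xp <- x; xp[S[j]] <- x[S[j]] + h
      xm <- x; xm[S[j]] <- max(x[S[j]] - h, 0)
      J[, j] <- (gvec(xp, S) - gvec(xm, S)) / (xp[S[j]] - xm[S[j]])
    }
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    repeat {
      xn <- x
      xn[S] <- x[S] - lam * step
      if (all(xn[S] > 0)) {
        fn <- gvec(xn, S)
        if (all(is.finite(fn)) &&
            (max(abs(fn)) < max(abs(f)) || lam < 1 / 64)) break
      }
      lam <- lam / 2
      if (lam < 1 / 1024) return(NULL)
    }
    x <- xn
  }
  if (max(abs(gvec(x, S))) < 1e-8) x else NULL
}

valid_equilibrium <- function(model, u, m, x, S, gvec, tol) {
  n <- model$n_types
  if (any(x[S] <= 1e-9 * model$x_scale[S])) return(FALSE)
  out <- setdiff(seq_len(n), S)
  if (length(out) && any(gvec(x, out) > 1e-8)) return(FALSE)
  ev <- eco_jacobian_eigen(model, u, m, x)
  all(Re(ev) <= 1e-7)
}

# eigenvalues of the Jacobian of f_i = x_i G_i at x
eco_jacobian_eigen <- function(model, u, m, x) {
  n <- model$n_types
  f <- function(xx) vapply(seq_len(n), function(i)
    xx[i] * eval_fitness(model, u[i], i, u, xx, m), numeric(1))
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- 1e-7 * max(model$x_scale[j], abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- max(x[j] - h, 0)
    J[, j] <- (f(xp) - f(xm)) / (xp[j] - xm[j])
  }
  eigen(J, only.values = TRUE)$values
}

# forward integration of the ecological subsystem (traits frozen)
eco_integrate_fallback <- function(model, u, m, init_x, conv_tol = 1e-9) {
  n <- model$n_types
  deriv <- function(t, y, parms) {
    x <- pmax(y, 0)
    list(vapply(seq_len(n), function(i)
      x[i] * eval_fitness(model, u[i], i, u, x, m), numeric(1)))
  }
  y <- pmax(init_x, 0)
  horizon <- 200
  for (rep in 1:6) {
    sol <- deSolve::ode(y, c(0, horizon), deriv, NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-10 * max(model$x_scale))
    y <- pmax(sol[nrow(sol), -1], 0)
    d <- unlist(deriv(0, y, NULL))
    if (max(abs(d)) < conv_tol * max(model$x_scale)) {
      y[y < 1e-9 * model$x_scale] <- 0
      return(as.numeric(y))
    }
    horizon <- horizon * 4
  }
  NULL
}

evolving_index <- function(model) {
  ev <- which(model$sigma > 0)
  if (length(ev) == 0L)
    stop("model has no evolving type (all sigma are 0)")
  if (length(ev) > 1L)
    stop("ESS search is implemented for a single evolving scalar trait; ",
         "model has ", length(ev), " evolving types")
  ev
}

# selection gradient along the resident-equilibrium manifold, as a function
# of the evolving trait; NA when the evolving type is extinct there
resident_gradient_fun <- function(model, m, u_fixed, init_x = NULL) {
  ev <- evolving_index(model)
  force(init_x)
  function(u) {
    uv <- u_fixed; uv[ev] <- u
    x <- ecological_equilibrium(model, uv, m, init_x = init_x)
    if (x[ev] <= 0) return(NA_real_)
    # grid scans legitimately touch the trait bounds: one-sided steps there
    # are expected, not worth a warning per evaluation
    suppressWarnings(fitness_gradient(model, ev, eco_evo_state(x, uv), m))
  }
}

#' Solve for singular strategies and ESSs at a fixed leader action
#'
#' Finds all solutions of the coupled system (selection gradient zero at the
#' resident trait, ecological equilibrium at that trait) by multi-start
#' root-finding over a uniform grid on the evolving type's trait bounds,
#' together with boundary-pinned candidates where selection pushes against a
#' trait bound.  Candidates are deduplicated within `dedup_tol` and each is
#' classified by the curvature of mutant fitness, a grid invasion test
#' ([invasion_test()]) and convergence stability
#' ([convergence_stability()]).  Only entries passing the invasion test with
#' non-positive curvature are flagged `is_ess`.
#'
#' Exactly one type may have a positive evolutionary speed (assumption of a
#' single evolving scalar trait); other types keep their `u_ref` traits.
#' If the selection gradient vanishes over the whole grid (a trait-neutral
#' model) a single representative entry at the reference trait is returned.
#'
#' @param model a [gfun_model()].
#' @param m scalar leader action.
#' @param search_grid starting grid for the multi-start search; default 41
#'   uniform points on the evolving type's trait bounds.
#' @param u_fixed trait values for frozen types (default `model$u_ref`).
#' @param dedup_tol tolerance within which candidate roots are merged.
#' @return An object of class `ess_solutions`: a list of
#'   `eco_evo_equilibrium` entries (fields `m`, `u_star`, `x_star`,
#'   `evolving`, `second_derivative`, `classification`, `is_ess`,
#'   `is_convergence_stable`, `invasion`), sorted by trait value.  A
#'   zero-length result carries the attribute
#'   `note = "no singular strategy found on grid"`.
#' @export
ess_solve <- function(model, m, search_grid = NULL, u_fixed = NULL,
                      dedup_tol = 1e-5) {
  ev <- evolving_index(model)
  lb <- model$trait_bounds[ev, 1]; ub <- model$trait_bounds[ev, 2]
  grid <- search_grid %||% seq(lb, ub, length.out = 41)
  u_fixed <- rep_len(as.numeric(u_fixed %||% model$u_ref), model$n_types)
  gfun <- resident_gradient_fun(model, m, u_fixed)
  fvals <- vapply(grid, gfun, numeric(1))
  finite <- is.finite(fvals)
  if (!any(finite)) {
    out <- structure(list(), class = "ess_solutions", m = m,
                     note = "no singular strategy found on grid")
    return(out)
  }
  roots <- numeric(0)
  if (all(abs(fvals[finite]) < 1e-12)) {
    # trait-neutral model: every trait is singular; report one representative
    roots <- u_fixed[ev]
  } else {
    # refine next to exact zeros: just above a pitchfork the new roots sit in
    # the grid cells adjoining the persisting zero and leave no sign change
    # between the original grid values
    zk <- which(finite & abs(fvals) < 1e-12)
    if (length(zk)) {
      extra <- unlist(lapply(zk, function(k) {
        c(if (k > 1) seq(grid[k - 1], grid[k], length.out = 11)[2:10],
          if (k < length(grid)) seq(grid[k], grid[k + 1],
                                    length.out = 11)[2:10])
      }))
      extra <- setdiff(unique(extra), grid)
      if (length(extra)) {
        fe <- vapply(extra, gfun, numeric(1))
        ord <- order(c(grid, extra))
        fvals <- c(fvals, fe)[ord]
        grid <- c(grid, extra)[ord]
        finite <- is.finite(fvals)
      }
    }
    roots <- grid[finite & abs(fvals) < 1e-12]
    for (k in seq_len(length(grid) - 1)) {
      f1 <- fvals[k]; f2 <- fvals[k + 1]
      if (is.finite(f1) && is.finite(f2) && f1 * f2 < 0) {
        r <- uniroot(gfun, c(grid[k], grid[k + 1]), f.lower = f1,
                     f.upper = f2, tol = 1e-12)$root
        roots <- c(roots, r)
      }
    }
    # boundary-pinned candidates: selection pushes against a closed bound
    if (is.finite(fvals[match(TRUE, finite)])) {
      il <- which(finite)[1]; iu <- rev(which(finite))[1]
      if (grid[il] == lb && fvals[il] < 0) roots <- c(roots, lb)
      if (grid[iu] == ub && fvals[iu] > 0) roots <- c(roots, ub)
    }
  }
  roots <- sort(roots)
  if (length(roots) > 1)
    roots <- roots[c(TRUE, diff(roots) > dedup_tol)]
  sols <- list()
  for (r in roots) {
    eq <- classify_singular(model, m, r, u_fixed)
    if (!is.null(eq)) sols[[length(sols) + 1L]] <- eq
  }
  if (length(sols) == 0L)
    return(structure(list(), class = "ess_solutions", m = m,
                     note = "no singular strategy found on grid"))
  sols <- sols[order(vapply(sols, function(s) s$u_star[s$evolving],
                            numeric(1)))]
  structure(sols, class = "ess_solutions", m = m)
}

classify_singular <- function(model, m, u_ev, u_fixed) {
  ev <- evolving_index(model)
  uv <- u_fixed; uv[ev] <- u_ev
  x <- ecological_equilibrium(model, uv, m)
  if (x[ev] <= 0) return(NULL)
  st <- eco_evo_state(x, uv)
  sd <- fitness_curvature(model, ev, st, m)
  lb <- model$trait_bounds[ev, 1]; ub <- model$trait_bounds[ev, 2]
  boundary <- (u_ev <= lb + 1e-12) || (u_ev >= ub - 1e-12)
  eq <- structure(list(m = m, u_star = uv, x_star = as.numeric(x),
                       evolving = ev, second_derivative = sd,
                       classification = NA_character_, is_ess = NA,
                       is_convergence_stable = NA, invasion = NULL),
                  class = "eco_evo_equilibrium")
  inv <- invasion_test(model, eq)
  eq$invasion <- inv
  if (boundary) {
    eq$classification <- if (inv$pass) "max" else "min"
    eq$is_ess <- inv$pass
  } else {
    eq$classification <- if (sd <= 1e-8) "max" else "min"
    eq$is_ess <- inv$pass && sd <= 1e-8
  }
  eq$is_convergence_stable <- convergence_stability(model, eq)
  eq
}

#' @export
print.eco_evo_equilibrium <- function(x, ...) {
  cat(sprintf(paste0("<eco_evo_equilibrium> m = %g: u* = %s, x* = %s\n",
                     "  %s; ESS: %s; convergence stable: %s; d2G/dv2 = %.4g\n"),
              x$m, paste(signif(x$u_star, 6), collapse = ", "),
              paste(signif(x$x_star, 6), collapse = ", "),
              x$classification, x$is_ess, x$is_convergence_stable,
              x$second_derivative))
  invisible(x)
}

#' @export
print.ess_solutions <- function(x, ...) {
  cat("<ess_solutions> m =", attr(x, "m"), "-", length(x),
      "singular strateg", if (length(x) == 1) "y" else "ies", "\n")
  if (!is.null(attr(x, "note"))) cat("  note:", attr(x, "note"), "\n")
  for (s in x) print(s)
  invisible(x)
}

#' Grid invasion test of a candidate ESS
#'
#' Checks that no rare mutant trait on a dense grid has positive fitness
#' against the candidate resident at its ecological equilibrium, i.e.
#' `G(v, u*, x*, m) <= tol` for all grid `v`.
#'
#' @param model a [gfun_model()].
#' @param equilibrium an `eco_evo_equilibrium` (from [ess_solve()]) with
#'   positive population for the evolving type.
#' @param v_grid mutant trait grid; default 401 uniform points on the
#'   evolving type's trait bounds.
#' @param tol invasion tolerance.
#' @return List with `pass` (logical), `worst_v` and `worst_fitness` (the
#'   argmax of mutant fitness over the grid).
#' @export
invasion_test <- function(model, equilibrium, v_grid = NULL, tol = 1e-9) {
  ev <- equilibrium$evolving
  if (equilibrium$x_star[ev] <= 0)
    stop("invasion test requires a positive population for the focal type")
  v_grid <- v_grid %||% seq(model$trait_bounds[ev, 1],
                            model$trait_bounds[ev, 2], length.out = 401)
  st <- eco_evo_state(equilibrium$x_star, equilibrium$u_star)
  g <- mutant_fitness(model, v_grid, ev, st, equilibrium$m)
  k <- which.max(g)
  list(pass = g[k] <= tol, worst_v = v_grid[k], worst_fitness = g[k])
}

#' Convergence stability of a singular strategy
#'
#' Tests whether monomorphic trait dynamics started near the singular
#' strategy evolve back towards it, by the sign of the selection gradient
#' along the resident-equilibrium manifold on either side (`u* +- h`, with
#' one-sided evaluation at a trait bound).
#'
#' @param model a [gfun_model()].
#' @param equilibrium an `eco_evo_equilibrium`.
#' @param h trait perturbation used for the sign test.
#' @return Logical.
#' @export
convergence_stability <- function(model, equilibrium, h = 1e-4) {
  ev <- equilibrium$evolving
  u0 <- equilibrium$u_star[ev]
  lb <- model$trait_bounds[ev, 1]; ub <- model$trait_bounds[ev, 2]
  gfun <- resident_gradient_fun(model, equilibrium$m, equilibrium$u_star)
  up <- if (u0 + h <= ub) gfun(u0 + h) else NA_real_
  dn <- if (u0 - h >= lb) gfun(u0 - h) else NA_real_
  okp <- is.na(up) || up < 0
  okd <- is.na(dn) || dn > 0
  isTRUE(okp && okd)
}

#' Trace ESS branches over a grid of leader actions
#'
#' Runs [ess_solve()] at each action in `m_grid`, assembles branches by
#' nearest-neighbour continuation, and locates bifurcation points by
#' bisection on the sign of the mutant-fitness curvature along a branch
#' whose classification flips (absolute tolerance `bisect_tol` in `m`).  A
#' sign change at which the number of singular strategies increases by two
#' is labelled a pitchfork.
#'
#' @param model a [gfun_model()].
#' @param m_grid increasing vector of leader actions.
#' @param u_fixed trait values for frozen types (default `model$u_ref`).
#' @param jump_bound maximum trait jump allowed when continuing a branch
#'   between consecutive grid actions; larger jumps split the branch with a
#'   warning.  Default: 10% of the trait range.
#' @param bisect_tol absolute tolerance in `m` for bifurcation bisection.
#' @return Object of class `ess_branch_diagram`: a list with `branches`
#'   (data frame: `m`, `branch_id`, `u_star`, `x_star` (total population),
#'   `classification`, `is_ess`, `is_convergence_stable`, plus `x_1..x_n`)
#'   and `bifurcations` (data frame: `m_c`, `kind`).
#' @export
ess_branch_diagram <- function(model, m_grid, u_fixed = NULL,
                               jump_bound = NULL, bisect_tol = 1e-6) {
  stopifnot(!is.unsorted(m_grid))
  ev <- evolving_index(model)
  tb <- model$trait_bounds[ev, ]
  jump_bound <- jump_bound %||% (0.1 * (tb[2] - tb[1]))
  u_fixed <- rep_len(as.numeric(u_fixed %||% model$u_ref), model$n_types)
  sols_by_m <- lapply(m_grid, function(m)
    ess_solve(model, m, u_fixed = u_fixed))
  branches <- list()   # each: list(id, last_u, rows = list())
  next_id <- c(pos = 0L, neg = 0L, zero = 0L)
  make_id <- function(u) {
    key <- if (abs(u) < 1e-8) "zero" else if (u > 0) "pos" else "neg"
    next_id[key] <<- next_id[key] + 1L
    base <- c(pos = "u+", neg = "u-", zero = "u0")[key]
    if (next_id[key] == 1L) base else paste0(base, ".", next_id[key])
  }
  for (k in seq_along(m_grid)) {
    sols <- sols_by_m[[k]]
    if (length(sols) == 0L) { for (b in seq_along(branches))
      branches[[b]]$open <- FALSE; next }
    us <- vapply(sols, function(s) s$u_star[s$evolving], numeric(1))
    taken_b <- logical(length(branches)); taken_s <- logical(length(sols))
    open <- vapply(branches, function(b) isTRUE(b$open), logical(1))
    if (any(open)) {
      d <- outer(vapply(branches, function(b) b$last_u, numeric(1)), us,
                 function(a, b) abs(a - b))
      d[!open, ] <- Inf
      ord <- order(d)
      for (idx in ord) {
        if (!is.finite(d[idx])) break
        bi <- (idx - 1L) %% nrow(d) + 1L; si <- (idx - 1L) %/% nrow(d) + 1L
        if (taken_b[bi] || taken_s[si]) next
        if (d[idx] > jump_bound) break
        taken_b[bi] <- TRUE; taken_s[si] <- TRUE
        branches[[bi]]$last_u <- us[si]
        branches[[bi]]$rows[[length(branches[[bi]]$rows) + 1L]] <-
          list(k = k, sol = sols[[si]])
      }
    }
    for (b in which(open & !taken_b)) branches[[b]]$open <- FALSE
    for (si in which(!taken_s)) {
      if (length(branches) > 0 && any(open))
        if (min(abs(vapply(branches[open], function(b) b$last_u,
                           numeric(1)) - us[si])) > jump_bound && k > 1)
          warning("branch jump larger than continuation bound at m = ",
                  m_grid[k], "; starting a new branch")
      branches[[length(branches) + 1L]] <-
        list(id = make_id(us[si]), last_u = us[si], open = TRUE,
             rows = list(list(k = k, sol = sols[[si]])))
    }
  }
  n <- model$n_types
  rows <- do.call(rbind, lapply(branches, function(b) {
    do.call(rbind, lapply(b$rows, function(r) {
      s <- r$sol
      df <- data.frame(m = m_grid[r$k], branch_id = b$id,
                       u_star = s$u_star[s$evolving],
                       x_star = sum(s$x_star),
                       classification = s$classification,
                       is_ess = s$is_ess,
                       is_convergence_stable = s$is_convergence_stable,
                       second_derivative = s$second_derivative,
                       stringsAsFactors = FALSE)
      for (i in seq_len(n)) df[[paste0("x_", i)]] <- s$x_star[i]
      df
    }))
  }))
  rows <- rows[order(rows$m, rows$branch_id), , drop = FALSE]
  rownames(rows) <- NULL
  bifs <- locate_bifurcations(model, m_grid, u_fixed, rows, sols_by_m,
                              bisect_tol)
  structure(list(branches = rows, bifurcations = bifs, m_grid = m_grid,
                 model = model$name),
            class = "ess_branch_diagram")
}

locate_bifurcations <- function(model, m_grid, u_fixed, rows, sols_by_m,
                                bisect_tol) {
  ev <- evolving_index(model)
  out <- data.frame(m_c = numeric(0), kind = character(0),
                    stringsAsFactors = FALSE)
  counts <- vapply(sols_by_m, length, integer(1))
  for (id in unique(rows$branch_id)) {
    br <- rows[rows$branch_id == id, , drop = FALSE]
    if (nrow(br) < 2) next
    flips <- which(diff(sign(br$second_derivative)) != 0 &
                     abs(br$second_derivative[-1]) > 0)
    for (fk in flips) {
      m1 <- br$m[fk]; m2 <- br$m[fk + 1]
      u_hint <- br$u_star[fk]
      sfun <- function(m) singular_curvature(model, m, u_hint, u_fixed)
      s1 <- sfun(m1); s2 <- sfun(m2)
      if (!is.finite(s1) || !is.finite(s2) || s1 * s2 > 0) next
      while (m2 - m1 > bisect_tol) {
        mm <- (m1 + m2) / 2
        sm <- sfun(mm)
        if (!is.finite(sm)) break
        if (sm * s1 <= 0) { m2 <- mm; s2 <- sm } else { m1 <- mm; s1 <- sm }
      }
      m_c <- (m1 + m2) / 2
      k1 <- findInterval(m_c, m_grid)
      kind <- if (k1 >= 1 && k1 < length(m_grid) &&
                  abs(counts[min(k1 + 1, length(counts))] - counts[k1]) == 2)
        "pitchfork" else "curvature-sign-change"
      out <- rbind(out, data.frame(m_c = m_c, kind = kind,
                                   stringsAsFactors = FALSE))
    }
  }
  unique(out)
}

# curvature of mutant fitness at the singular strategy continued from u_hint
singular_curvature <- function(model, m, u_hint, u_fixed) {
  ev <- evolving_index(model)
  gfun <- resident_gradient_fun(model, m, u_fixed)
  u <- track_singular(model, gfun, u_hint)
  if (!is.finite(u)) return(NA_real_)
  uv <- u_fixed; uv[ev] <- u
  x <- ecological_equilibrium(model, uv, m)
  if (x[ev] <= 0) return(NA_real_)
  fitness_curvature(model, ev, eco_evo_state(x, uv), m)
}

# locally continue a root of the selection gradient from a hint
track_singular <- function(model, gfun, u_hint, radius = NULL) {
  ev <- evolving_index(model)
  lb <- model$trait_bounds[ev, 1]; ub <- model$trait_bounds[ev, 2]
  radius <- radius %||% (0.02 * (ub - lb))
  f0 <- gfun(u_hint)
  if (is.finite(f0) && abs(f0) < 1e-13) return(u_hint)
  for (r in radius * 2^(0:4)) {
    a <- max(lb, u_hint - r); b <- min(ub, u_hint + r)
    fa <- gfun(a); fb <- gfun(b)
    if (is.finite(fa) && is.finite(fb) && fa * fb < 0)
      return(uniroot(gfun, c(a, b), f.lower = fa, f.upper = fb,
                     tol = 1e-12)$root)
    if (a == lb && b == ub) break
  }
  # pinned at a bound?
  fl <- gfun(lb); fu <- gfun(ub)
  if (is.finite(fl) && fl < 0) return(lb)
  if (is.finite(fu) && fu > 0) return(ub)
  NA_real_
}

#' @export
print.ess_branch_diagram <- function(x, ...) {
  cat("<ess_branch_diagram> model:", x$model, "\n")
  cat("  m in [", min(x$m_grid), ",", max(x$m_grid), "],",
      length(x$m_grid), "grid actions;",
      length(unique(x$branches$branch_id)), "branches\n")
  if (nrow(x$bifurcations))
    for (i in seq_len(nrow(x$bifurcations)))
      cat(sprintf("  bifurcation: %s at m_c = %.6f\n",
                  x$bifurcations$kind[i], x$bifurcations$m_c[i]))
  else cat("  no bifurcations detected\n")
  invisible(x)
}

#' Write an ESS branch diagram as CSV files
#'
#' @param diagram an `ess_branch_diagram`.
#' @param branches_path,bifurcations_path output CSV paths.
#' @return The two paths, invisibly.
#' @export
write_branch_csv <- function(diagram, branches_path, bifurcations_path) {
  write.csv(diagram$branches, branches_path, row.names = FALSE)
  write.csv(diagram$bifurcations, bifurcations_path, row.names = FALSE)
  invisible(c(branches_path, bifurcations_path))
}
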