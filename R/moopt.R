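#' Scalarization weight grid
#'
#' The default grid of weight pairs for the weighting method: `eta_1` from 1
#' to 0 in steps of 0.01 (101 pairs), with `eta_2 = 1 - eta_1`.
#'
#' @param n_points number of grid points.
#' @return an `n_points` x 2 matrix with columns `eta1`, `eta2`.
#' @export
default_weight_grid <- function(n_points = 101L) {
  e1 <- seq(1, 0, length.out = n_points)
  cbind(eta1 = e1, eta2 = 1 - e1)
}

#' Evaluation budget per single-objective minimization
#'
#' Splits an overall black-box evaluation budget equally over a number of
#' scalarized minimizations (integer division), as used by the
#' derivative-free baseline protocol.
#'
#' @param total overall number of function evaluations.
#' @param n_runs number of single-objective minimizations.
#' @return integer per-run budget.
#' @examples
#' per_run_budget(10000, 11)  # 909
#' @export
per_run_budget <- function(total, n_runs) {
  if (!is_count(total) || !is_count(n_runs) || n_runs < 1)
    stopf("total and n_runs must be positive integers")
  as.integer(total %/% n_runs)
}

# ---- internal helpers -------------------------------------------------------

# full decision-vector layout for a constraint set
vec_layout <- function(cs) {
  n <- cs$n
  r_free <- any(cs$l_r != cs$u_r)
  k <- length(cs$l_z)
  list(n = n, k = k, r_free = r_free,
       ix = seq_len(n), iy = n + seq_len(n),
       ir = if (r_free) 2L * n + seq_len(n) else integer(),
       iz = (if (r_free) 3L else 2L) * n + seq_len(k),
       lower = c(cs$l_x, cs$l_y, if (r_free) cs$l_r, cs$l_z),
       upper = c(cs$u_x, cs$u_y, if (r_free) cs$u_r, cs$u_z))
}

# feasibility of a raw encoded vector (used by optimizers; mirrors
# check_feasibility but avoids object construction in inner loops)
feasible_vec <- function(v, cs, lay = vec_layout(cs)) {
  if (any(v < lay$lower - 1e-9) || any(v > lay$upper + 1e-9)) return(FALSE)
  x <- v[lay$ix]; y <- v[lay$iy]
  if (any(y - x < cs$h - 1e-9)) return(FALSE)
  sum(y - x) >= cs$g - 1e-9
}

vec_to_setting <- function(v, cs, lay = vec_layout(cs)) {
  miu_setting(x = round(v[lay$ix]), y = round(v[lay$iy]),
              z = unname(v[lay$iz]),
              r = if (lay$r_free) round(v[lay$ir]) else cs$l_r)
}

scalarized_parts <- function(cs, eta, weights, lay) {
  gamma <- rep_len(weights$gamma %||% 1, cs$n)
  delta <- rep_len(weights$delta %||% 1, cs$n)
  eta3 <- if (length(eta) >= 3) eta[3] else 0
  lin <- numeric(length(lay$lower))
  lin[lay$ix] <- -eta[2] * gamma
  lin[lay$iy] <- eta[2] * gamma
  if (lay$r_free) lin[lay$ir] <- eta3 * delta
  const <- if (!lay$r_free && eta3 > 0) eta3 * sum(delta * cs$l_r) else 0
  list(gamma = gamma, delta = delta, lin = lin, const = const)
}

#' Solve one scalarized subproblem on the surrogate
#'
#' Minimizes `eta_1 * f1_surrogate + eta_2 * f2 (+ eta_3 * f3)` over the
#' continuous relaxation of the feasible set (box bounds, daily and weekly
#' minimum-hours constraints) with a gradient-based local method
#' (logarithmic-barrier [stats::constrOptim()] with BFGS, using the
#' backpropagated surrogate gradient and the analytic linear gradients),
#' started from a feasible setting.  The integer variables of the relaxed
#' optimum are then rounded to the nearest integers; if rounding breaks a
#' minimum-hours constraint, the open interval `(x_d, y_d)` is widened on
#' the days with the largest positive fractional residual until feasible.
#' A deterministic greedy integer polish (best-improvement single-hour
#' moves) follows.  The returned point is feasible, and its scalarized
#' value never exceeds the start's; otherwise the start itself is returned.
#'
#' @param m a surrogate ([train_mlp()] model or [fn_surrogate()]).
#' @param cs a [constraint_set()].
#' @param eta scalarization weights (length 2, or 3 with free rooms),
#'   nonnegative and summing to 1.
#' @param start a feasible [miu_setting()].
#' @param weights an [objective_weights()] for `gamma`/`delta`, or `NULL`
#'   for unit weights.
#' @param control list: `outer_eps` (barrier convergence tolerance, default
#'   1e-6), `maxit` (BFGS iterations per barrier step, default 500),
#'   `polish_iter` (max polish passes, default 200).
#' @return a candidate point: list with `setting`, `f1` (surrogate
#'   minutes), `f2` (hours), optional `f3`, `eta`, `value` (scalarized) and
#'   `f1_source = "surrogate"`.
#' @export
solve_scalarized <- function(m, cs, eta, start, weights = NULL,
                             control = list()) {
  if (any(eta < 0) || abs(sum(eta) - 1) > 1e-9)
    stopf("eta must be nonnegative and sum to 1")
  viol <- check_feasibility(start, cs)
  if (length(viol))
    stopf("infeasible start:\n  %s", paste(viol, collapse = "\n  "))
  lay <- vec_layout(cs)
  parts <- scalarized_parts(cs, eta, weights, lay)
  ctrl <- modifyList(list(outer_eps = 1e-6, maxit = 500L,
                          polish_iter = 200L), control)

  obj <- function(v) {
    f1 <- if (eta[1] > 0) predict_f1(m, v) else 0
    if (!is.finite(f1)) stopf("non-finite surrogate value")
    eta[1] * f1 + sum(parts$lin * v) + parts$const
  }
  gr <- function(v) {
    g <- parts$lin
    if (eta[1] > 0) g <- g + eta[1] * grad_f1(m, v)
    g
  }

  v0 <- c(start$x, start$y, if (lay$r_free) start$r, start$z)
  v_start <- v0
  d <- length(v0)
  free <- lay$upper > lay$lower
  eps <- 1e-3

  # strictly interior start for the barrier method
  v0[free] <- pmin(pmax(v0[free], lay$lower[free] + eps),
                   lay$upper[free] - eps)
  nudge_hours <- function(v, need_daily, need_total) {
    x <- v[lay$ix]; y <- v[lay$iy]
    for (dd in seq_len(cs$n)) {
      need <- need_daily[dd] - (y[dd] - x[dd])
      if (need > 0) {
        up <- min(need, lay$upper[lay$iy][dd] - eps - y[dd])
        if (up > 0) { y[dd] <- y[dd] + up; need <- need - up }
        if (need > 0) x[dd] <- max(x[dd] - need, lay$lower[lay$ix][dd] + eps)
      }
    }
    guard <- 0
    while (sum(y - x) < need_total && guard < 100) {
      slack_y <- lay$upper[lay$iy] - eps - y
      slack_x <- x - (lay$lower[lay$ix] + eps)
      if (max(slack_y) >= max(slack_x) && max(slack_y) > 0) {
        dd <- which.max(slack_y)
        y[dd] <- y[dd] + min(slack_y[dd], need_total - sum(y - x))
      } else if (max(slack_x) > 0) {
        dd <- which.max(slack_x)
        x[dd] <- x[dd] - min(slack_x[dd], need_total - sum(y - x))
      } else break
      guard <- guard + 1
    }
    v[lay$ix] <- x; v[lay$iy] <- y
    v
  }
  v0 <- nudge_hours(v0, cs$h + eps, cs$g + eps)

  # linear constraints ui %*% v - ci >= 0, reduced to the free coordinates
  ui <- rbind(diag(d), -diag(d))
  ci <- c(lay$lower, -lay$upper)
  for (dd in seq_len(cs$n)) {
    row <- numeric(d); row[lay$ix[dd]] <- -1; row[lay$iy[dd]] <- 1
    ui <- rbind(ui, row); ci <- c(ci, cs$h[dd])
  }
  row <- numeric(d); row[lay$ix] <- -1; row[lay$iy] <- 1
  ui <- rbind(ui, row); ci <- c(ci, cs$g)
  if (any(!free)) {
    ci <- ci - ui[, !free, drop = FALSE] %*% v0[!free]
    ui <- ui[, free, drop = FALSE]
    keep <- rowSums(abs(ui)) > 0
    ui <- ui[keep, , drop = FALSE]; ci <- ci[keep]
  }

  v_cont <- v0
  if (any(free)) {
    obj_free <- function(vf) obj(replace(v0, which(free), vf))
    gr_free <- function(vf) gr(replace(v0, which(free), vf))[free]
    opt <- stats::constrOptim(v0[free], f = obj_free, grad = gr_free,
                              ui = ui, ci = ci, method = "BFGS",
                              outer.eps = ctrl$outer_eps,
                              control = list(maxit = ctrl$maxit))
    v_cont[free] <- opt$par
  }

  # round integers, then repair the minimum-hours constraints
  v_int <- v_cont
  int_idx <- c(lay$ix, lay$iy, lay$ir)
  v_int[int_idx] <- round(v_cont[int_idx])
  v_int <- pmin(pmax(v_int, lay$lower), lay$upper)
  x <- v_int[lay$ix]; y <- v_int[lay$iy]
  y <- pmax(y, x)
  for (dd in seq_len(cs$n)) {
    while (y[dd] - x[dd] < cs$h[dd]) {
      if (y[dd] < cs$u_y[dd]) y[dd] <- y[dd] + 1
      else if (x[dd] > cs$l_x[dd]) x[dd] <- x[dd] - 1
      else stopf("cannot repair daily minimum hours on day %d", dd)
    }
  }
  frac_resid <- (v_cont[lay$iy] - v_cont[lay$ix]) - (y - x)
  while (sum(y - x) < cs$g) {
    can <- (y < cs$u_y) | (x > cs$l_x)
    if (!any(can)) stopf("cannot repair weekly minimum hours")
    dd <- which(can)[which.max(frac_resid[can])]
    if (y[dd] < cs$u_y[dd]) y[dd] <- y[dd] + 1 else x[dd] <- x[dd] - 1
    frac_resid[dd] <- frac_resid[dd] - 1
  }
  v_int[lay$ix] <- x; v_int[lay$iy] <- y

  # greedy best-improvement polish around the rounded relaxation optimum:
  # single-hour and two-hour moves per variable, paired day shifts (moving
  # a day's open window without changing its length), and diversion steps.
  # Deterministic; descends the surrogate's piecewise-linear wiggles that
  # the smooth relaxation cannot see.
  cur <- v_int
  cur_val <- obj(cur)
  neighbours <- function(v) {
    out <- list()
    for (i in int_idx) {
      for (step in c(-2, -1, 1, 2)) {
        cand <- v
        cand[i] <- cand[i] + step
        out[[length(out) + 1]] <- cand
      }
    }
    for (dd in seq_len(cs$n)) {        # slide the open window of one day
      for (step in c(-1, 1)) {
        cand <- v
        cand[lay$ix[dd]] <- cand[lay$ix[dd]] + step
        cand[lay$iy[dd]] <- cand[lay$iy[dd]] + step
        out[[length(out) + 1]] <- cand
      }
    }
    for (i in lay$iz) {
      for (step in c(-8, -2, 2, 8)) {
        cand <- v
        cand[i] <- min(max(cand[i] + step, lay$lower[i]), lay$upper[i])
        out[[length(out) + 1]] <- cand
      }
    }
    out
  }
  for (it in seq_len(ctrl$polish_iter)) {
    best_move <- NULL
    best_val <- cur_val
    for (cand in neighbours(cur)) {
      if (any(cand[lay$iy] < cand[lay$ix])) next
      if (!feasible_vec(cand, cs, lay)) next
      val <- obj(cand)
      if (val < best_val - 1e-9) {
        best_val <- val
        best_move <- cand
      }
    }
    if (is.null(best_move)) break
    cur <- best_move
    cur_val <- best_val
  }

  # never return a point worse than the (already integer) start
  start_val <- obj(v_start)
  if (cur_val > start_val + 1e-9) {
    cur <- v_start
    cur_val <- start_val
  }

  setting <- vec_to_setting(cur, cs, lay)
  stopifnot(length(check_feasibility(setting, cs)) == 0)
  f1 <- predict_f1(m, cur)
  out <- list(setting = setting, f1 = f1,
              f2 = f2_hours(setting, parts$gamma),
              eta = eta, value = cur_val, f1_source = "surrogate")
  if (lay$r_free || (length(eta) >= 3 && eta[3] > 0))
    out$f3 <- f3_rooms(setting, parts$delta)
  out
}

#' Generate candidate points with the weighting method
#'
#' Runs one [solve_scalarized()] per weight pair of the grid, all from the
#' same feasible start, and collapses candidates with identical settings.
#'
#' @param m a surrogate.
#' @param cs a [constraint_set()].
#' @param grid matrix of weight rows (default [default_weight_grid()]).
#' @param start feasible [miu_setting()]; defaults to the status-quo point.
#' @param weights an [objective_weights()] or `NULL`.
#' @param control passed to [solve_scalarized()].
#' @return list of candidate points.
#' @export
weighting_sweep <- function(m, cs, grid = default_weight_grid(),
                            start = as_is_setting(), weights = NULL,
                            control = list()) {
  if (!NROW(grid)) stopf("weight grid is empty")
  cands <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    eta <- as.numeric(grid[i, ])
    cands[[i]] <- tryCatch(
      solve_scalarized(m, cs, eta, start, weights, control),
      error = function(e)
        stopf("scalarized solve failed at eta = (%s): %s",
              paste(signif(eta, 4), collapse = ", "), conditionMessage(e)))
  }
  keys <- vapply(cands, function(cd)
    paste(encode_setting(cd$setting, include_r = !is.null(cd$setting$r)),
          collapse = ","), character(1))
  cands[!duplicated(keys)]
}

candidate_objectives <- function(points) {
  has_f3 <- !vapply(points, function(p) is.null(p$f3), logical(1))
  if (any(has_f3) && !all(has_f3))
    stopf("candidate points carry inconsistent objective sets")
  if (all(has_f3)) c("f1", "f2", "f3") else c("f1", "f2")
}

#' Filter candidates to the non-dominated front
#'
#' Exact non-domination filter under minimization of the active objective
#' set (`f1`, `f2` and, when present, `f3`): a point is removed iff some
#' other point is no worse in every objective and strictly better in at
#' least one.  Candidates with exactly equal objective vectors are
#' collapsed to one representative.  The front is returned sorted by `f2`
#' descending.
#'
#' @param points list of candidate points (from [weighting_sweep()] or
#'   built by hand with fields `f1`, `f2`).
#' @param provenance optional list stored on the front.
#' @return an object of class `pareto_front`.
#' @export
pareto_filter <- function(points, provenance = list()) {
  if (!length(points))
    return(structure(list(points = list(), objectives = c("f1", "f2"),
                          provenance = provenance), class = "pareto_front"))
  objs <- candidate_objectives(points)
  M <- do.call(rbind, lapply(points, function(p)
    vapply(objs, function(o) as.numeric(p[[o]]), numeric(1))))
  dup <- duplicated(M)
  M <- M[!dup, , drop = FALSE]
  pts <- points[!dup]

  keep <- if (ncol(M) == 2) {
    # sort by f1 ascending (ties: f2 ascending) and sweep the running
    # minimum of f2: a point survives iff it strictly improves it
    o <- order(M[, 1], M[, 2])
    k <- logical(nrow(M))
    best_f2 <- Inf
    for (i in o) {
      if (M[i, 2] < best_f2) {
        k[i] <- TRUE
        best_f2 <- M[i, 2]
      }
    }
    k
  } else {
    vapply(seq_len(nrow(M)), function(i) {
      !any(vapply(seq_len(nrow(M)), function(j) {
        j != i && all(M[j, ] <= M[i, ]) && any(M[j, ] < M[i, ])
      }, logical(1)))
    }, logical(1))
  }
  pts <- pts[keep]
  o <- order(-vapply(pts, function(p) p$f2, numeric(1)))
  structure(list(points = pts[o], objectives = objs,
                 provenance = provenance), class = "pareto_front")
}

#' Re-evaluate a front with the simulator
#'
#' Replaces each front member's surrogate `f1` with the sample-average DTDT
#' from a fresh simulation run of its setting (the analytic `f2`/`f3` are
#' untouched), flags the values as simulated, and re-filters for dominance.
#'
#' @param scn a validated [ed_scenario()].
#' @param front a [pareto_filter()] front.
#' @param params a [sim_params()].
#' @param weights an [objective_weights()] for `alpha`/`beta`, or `NULL`.
#' @return a refined `pareto_front`.
#' @export
refine_with_des <- function(scn, front, params = sim_params(),
                            weights = NULL) {
  pts <- front$points
  for (i in seq_along(pts)) {
    res <- simulate_ed(scn, pts[[i]]$setting, params)
    pts[[i]]$f1 <- f1_from_result(res, weights$alpha, weights$beta)
    pts[[i]]$f1_source <- "simulated"
  }
  out <- pareto_filter(pts, provenance = c(front$provenance,
                                           list(refined = TRUE)))
  out
}

#' @export
print.pareto_front <- function(x, ...) {
  cat(sprintf("Pareto front: %d point(s) on (%s)\n", length(x$points),
              paste(x$objectives, collapse = ", ")))
  if (length(x$points)) print(as.data.frame(x), digits = 6)
  invisible(x)
}

#' @export
as.data.frame.pareto_front <- function(x, ...) {
  rows <- lapply(x$points, function(p) {
    v <- encode_setting(p$setting, include_r = "f3" %in% x$objectives)
    c(as.list(v), list(f1 = p$f1, f2 = p$f2),
      if (!is.null(p$f3)) list(f3 = p$f3),
      list(eta1 = if (!is.null(p$eta)) p$eta[1] else NA_real_,
           f1_source = p$f1_source %||% NA_character_))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}

#' @export
#' @importFrom graphics plot points legend
plot.pareto_front <- function(x, ...) {
  df <- as.data.frame(x)
  plot(df$f2, df$f1, xlab = "f2: MIU open hours / week",
       ylab = "f1: overall expected DTDT (min)",
       main = "Waiting time vs operating hours", pch = 19, ...)
  invisible(x)
}

#' Export a Pareto front
#'
#' Writes the front as a CSV mirroring the decision-table layout
#' (`x1..xn, y1..yn, z.., f1, f2[, f3]`) plus a JSON file with the points
#' and provenance.
#'
#' @param front a `pareto_front`.
#' @param path CSV path (the JSON lands at `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_front <- function(front, path) {
  df <- as.data.frame(front)
  write.csv(df, path, row.names = FALSE)
  write_json_file(list(points = df, objectives = front$objectives,
                       provenance = front$provenance),
                  paste0(path, ".json"))
  invisible(path)
}

#' Derivative-free baseline minimizer
#'
#' A pattern-search baseline for the scalarized problem evaluated directly
#' on a black-box objective (e.g. the simulation-based sample average):
#' coordinate primitive directions with expanding/contracting step sizes
#' (integer steps for hours and rooms, continuous steps for the diversion
#' percentages) and a non-monotone acceptance rule (a trial point is
#' accepted if it improves on the worst of the last `memory` accepted
#' values).  Infeasible points are never evaluated.  The search stops when
#' the evaluation budget is exhausted or a full sweep at minimal step sizes
#' yields no acceptance, and returns the best point evaluated.
#'
#' @param objective function of an encoded setting vector returning a
#'   scalar to minimize.
#' @param cs a [constraint_set()].
#' @param start a feasible [miu_setting()].
#' @param budget maximum number of objective evaluations.
#' @param memory length of the non-monotone reference window.
#' @param z_step initial (and `z_min_step` minimal) step for the continuous
#'   diversion variables, in percentage points.
#' @param z_min_step minimal continuous step before termination.
#' @return an object of class `dfo_result`: `setting` (best found), `value`,
#'   `evaluations`, and the best encoded vector `par`.
#' @export
dfo_minimize <- function(objective, cs, start, budget, memory = 5L,
                         z_step = 8, z_min_step = 0.5) {
  if (!is_count(budget)) stopf("budget must be a nonnegative integer")
  viol <- check_feasibility(start, cs)
  if (length(viol))
    stopf("infeasible start:\n  %s", paste(viol, collapse = "\n  "))
  lay <- vec_layout(cs)
  v <- c(start$x, start$y, if (lay$r_free) start$r, start$z)
  if (budget == 0)
    return(structure(list(setting = start, value = NA_real_,
                          evaluations = 0L, par = v),
                     class = "dfo_result"))
  evals <- 0L
  f <- function(vv) {
    evals <<- evals + 1L
    objective(vv)
  }
  int_idx <- c(lay$ix, lay$iy, lay$ir)
  alpha <- ifelse(seq_along(v) %in% int_idx, 2, z_step)
  min_step <- ifelse(seq_along(v) %in% int_idx, 1, z_min_step)

  cur_val <- f(v)
  best_v <- v; best_val <- cur_val
  history <- cur_val

  repeat {
    improved_sweep <- FALSE
    for (i in seq_along(v)) {
      for (dir in c(1, -1)) {
        if (evals >= budget) break
        cand <- v
        cand[i] <- cand[i] + dir * alpha[i]
        if (i %in% int_idx) cand[i] <- round(cand[i])
        cand[i] <- min(max(cand[i], lay$lower[i]), lay$upper[i])
        if (cand[i] == v[i]) next
        if (!feasible_vec(cand, cs, lay)) next
        val <- f(cand)
        if (val < best_val) { best_val <- val; best_v <- cand }
        ref <- max(tail(history, memory))
        if (val < ref - 1e-12) {
          v <- cand
          cur_val <- val
          history <- c(history, val)
          alpha[i] <- if (i %in% int_idx) min(alpha[i] * 2, 16)
                      else min(alpha[i] * 2, 32)
          improved_sweep <- TRUE
        } else {
          alpha[i] <- max(alpha[i] / 2, min_step)
        }
      }
      if (evals >= budget) break
    }
    if (evals >= budget) break
    if (!improved_sweep && all(alpha <= min_step + 1e-12)) break
  }

  structure(list(setting = vec_to_setting(best_v, cs, lay),
                 value = best_val, evaluations = evals, par = best_v),
            class = "dfo_result")
}

#' @export
print.dfo_result <- function(x, ...) {
  cat(sprintf("derivative-free search: best value %.4f after %d evaluation(s)\n",
              x$value, x$evaluations))
  invisible(x)
}
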