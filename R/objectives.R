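#' Fast-track (MIU) resource setting
#'
#' The decision vector of the allocation problem: per-day opening hour `x`,
#' closing hour `y`, open-room count `r`, and the diversion percentages `z`
#' (share of eligible low-acuity patients sent to the fast track by the
#' triage nurse; first component = morning slot, second = afternoon slot).
#' A closed day is encoded as `y_d == x_d`.
#'
#' @param x integer vector of opening hours (0-24), one per day.
#' @param y integer vector of closing hours (0-24), `y >= x` componentwise.
#' @param z numeric vector of diversion percentages in `[0, 100]`, one per
#'   time slot.
#' @param r optional integer vector of open-room counts per day.
#' @return an object of class `miu_setting`.
#' @examples
#' as_is_setting()   # the status-quo schedule: 08-20 Mon-Sat, closed Sunday
#' @export
miu_setting <- function(x, y, z, r = NULL) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (!is_wholenumber(x) || !is_wholenumber(y))
    stopf("x and y must be integer-valued hours")
  if (any(x < 0 | x > 24 | y < 0 | y > 24))
    stopf("hours must lie in [0, 24]")
  if (any(y < x))
    stopf("closing hour y_d must not precede opening hour x_d (day %d)",
          which(y < x)[1])
  if (!is.numeric(z) || !length(z) || any(!is.finite(z)) ||
      any(z < 0 | z > 100))
    stopf("z must be percentages in [0, 100]")
  if (!is.null(r)) {
    if (length(r) != length(x)) stopf("r must have the same length as x")
    if (!is_wholenumber(r) || any(r < 0))
      stopf("r must be nonnegative integer room counts")
    r <- as.integer(round(r))
  }
  structure(list(x = as.integer(round(x)), y = as.integer(round(y)),
                 z = as.double(z), r = r),
            class = "miu_setting")
}

#' Status-quo setting of the case study
#'
#' The current operating schedule: open 08:00-20:00 Monday through Saturday,
#' closed on Sunday, 2 rooms, 45% morning and 5% afternoon diversion.
#' @return a [miu_setting()].
#' @export
as_is_setting <- function() {
  miu_setting(x = rep(8L, 7), y = c(rep(20L, 6), 8L), z = c(45, 5),
              r = rep(2L, 7))
}

#' @export
print.miu_setting <- function(x, ...) {
  days <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
  n <- length(x$x)
  lab <- if (n == 7) days else paste0("d", seq_len(n))
  sched <- ifelse(x$y > x$x, sprintf("%02d-%02d", x$x, x$y), "closed")
  cat("MIU setting:\n ", paste(sprintf("%s %s", lab, sched), collapse = "  "),
      "\n")
  if (!is.null(x$r))
    cat("  rooms:", paste(x$r, collapse = " "), "\n")
  cat("  diversion %:", paste(sprintf("%.4g", x$z), collapse = " / "),
      "(morning / afternoon)\n")
  invisible(x)
}

#' Feasibility check for a fast-track setting
#'
#' Evaluates every constraint of a [constraint_set()] against a setting and
#' returns the violations as data (one descriptor per broken rule, naming
#' the constraint and the day), so optimizers can build penalty or repair
#' logic on top.  An empty return value means the setting is feasible.
#'
#' The rules are: box bounds on `x`, `y`, `r` and `z`; the daily minimum
#' `y_d - x_d >= h_d`; and the period minimum `sum(y_d - x_d) >= g`.
#'
#' @param s a [miu_setting()].
#' @param cs a [constraint_set()] with matching number of days.
#' @return character vector of violations; empty if feasible.
#' @examples
#' check_feasibility(as_is_setting(), case_study_constraints())  # character(0)
#' @export
check_feasibility <- function(s, cs) {
  if (!inherits(s, "miu_setting")) stopf("s must be a miu_setting")
  if (!inherits(cs, "miu_constraints")) stopf("cs must be a miu_constraints")
  if (length(s$x) != cs$n)
    stopf("setting has %d days but constraints have %d", length(s$x), cs$n)
  v <- character()
  bad <- function(...) v <<- c(v, sprintf(...))
  for (d in seq_len(cs$n)) {
    if (s$x[d] < cs$l_x[d] || s$x[d] > cs$u_x[d])
      bad("box: x_%d = %d outside [%d, %d]", d, s$x[d], cs$l_x[d], cs$u_x[d])
    if (s$y[d] < cs$l_y[d] || s$y[d] > cs$u_y[d])
      bad("box: y_%d = %d outside [%d, %d]", d, s$y[d], cs$l_y[d], cs$u_y[d])
    if (!is.null(s$r) && (s$r[d] < cs$l_r[d] || s$r[d] > cs$u_r[d]))
      bad("box: r_%d = %d outside [%d, %d]", d, s$r[d], cs$l_r[d], cs$u_r[d])
    if (s$y[d] - s$x[d] < cs$h[d])
      bad("min-daily-hours: y_%d - x_%d = %d < h_%d = %d", d, d,
          s$y[d] - s$x[d], d, cs$h[d])
  }
  if (length(s$z) != length(cs$l_z))
    bad("box: setting has %d diversion slots, constraints have %d",
        length(s$z), length(cs$l_z))
  else for (k in seq_along(s$z)) {
    if (s$z[k] < cs$l_z[k] || s$z[k] > cs$u_z[k])
      bad("box: z_%d = %.4g outside [%.4g, %.4g]", k, s$z[k], cs$l_z[k],
          cs$u_z[k])
  }
  if (sum(s$y - s$x) < cs$g)
    bad("min-weekly-hours: sum(y - x) = %d < g = %d", sum(s$y - s$x), cs$g)
  v
}

#' Operating-hours objective
#'
#' The weighted count of fast-track working hours over the planning period,
#' `sum_d gamma_d * (y_d - x_d)` — the operating-cost proxy minimized against
#' waiting time.
#'
#' @param s a [miu_setting()].
#' @param gamma positive per-day weights (recycled); all 1 by default.
#' @return weighted hours (exact integer value when `gamma` is integer).
#' @examples
#' f2_hours(as_is_setting())   # 72
#' @export
f2_hours <- function(s, gamma = 1) {
  gamma <- rep_len(gamma, length(s$x))
  if (any(gamma <= 0)) stopf("gamma weights must be positive")
  sum(gamma * (s$y - s$x))
}

#' Open-rooms objective
#'
#' The weighted count of fast-track rooms open daily over the period,
#' `sum_d delta_d * r_d`.
#'
#' @param s a [miu_setting()] with non-`NULL` rooms `r`.
#' @param delta positive per-day weights (recycled); all 1 by default.
#' @return weighted room-days.
#' @export
f3_rooms <- function(s, delta = 1) {
  if (is.null(s$r)) stopf("setting has no room counts r")
  delta <- rep_len(delta, length(s$r))
  if (any(delta <= 0)) stopf("delta weights must be positive")
  sum(delta * s$r)
}

#' Objective weights
#'
#' The weighting coefficients of the waiting-time and cost objectives:
#' `alpha` per severity tag and `beta` per unit (waiting-time objective),
#' `gamma` per day (operating-hours objective), `delta` per day (open-rooms
#' objective), and the scalarization weights `eta` (nonnegative, summing
#' to 1).
#'
#' @param alpha named positive weights per tag.
#' @param beta named positive weights per unit.
#' @param gamma,delta positive per-day weights.
#' @param eta scalarization weight vector (length 2, or 3 when the rooms
#'   objective is active), or `NULL`.
#' @return an object of class `objective_weights`.
#' @export
objective_weights <- function(alpha = NULL, beta = NULL, gamma = 1,
                              delta = 1, eta = NULL) {
  for (w in list(alpha, beta, gamma, delta)) {
    if (!is.null(w) && (any(!is.finite(w)) || any(w <= 0)))
      stopf("alpha, beta, gamma and delta weights must be positive")
  }
  if (!is.null(eta)) {
    if (any(eta < 0) || abs(sum(eta) - 1) > 1e-12)
      stopf("eta must be nonnegative and sum to 1")
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma, delta = delta,
                 eta = eta), class = "objective_weights")
}

#' Overall expected waiting time from a simulation result
#'
#' The sample-average waiting-time objective: the double sum over severity
#' tags and eligible units of the weighted mean door-to-doctor time,
#' `sum_t alpha_t sum_u beta_u * mean_DTDT(t, u)`, where each cell mean is
#' the average over simulation replications of the per-replication mean (see
#' [mean_dtdt()]).
#'
#' @param res an `ed_sim_result` from [simulate_ed()].
#' @param alpha named positive weights per tag; default 1 for every tag.
#' @param beta named positive weights per unit; default 1 for every unit.
#' @return overall expected waiting time in minutes.
#' @export
f1_from_result <- function(res, alpha = NULL, beta = NULL) {
  cells <- res$cells  # data.frame: tag, unit
  tags <- unique(cells$tag)
  units <- unique(cells$unit)
  if (is.null(alpha)) alpha <- stats::setNames(rep(1, length(tags)), tags)
  if (is.null(beta)) beta <- stats::setNames(rep(1, length(units)), units)
  if (any(alpha <= 0) || any(beta <= 0))
    stopf("alpha and beta weights must be positive")
  total <- 0
  for (i in seq_len(nrow(cells))) {
    t <- cells$tag[i]; u <- cells$unit[i]
    a <- alpha[[t]] %||% 0
    b <- beta[[u]] %||% 0
    if (a * b == 0) next
    total <- total + a * b * mean_dtdt(res, t, u)
  }
  total
}

#' Encode and decode settings for the metamodel
#'
#' A setting maps to the flat feature vector `(x_1..x_n, y_1..y_n,
#' [r_1..r_n,] z_1..z_k)` used as metamodel input and dataset row.  The room
#' counts are included only when `include_r = TRUE`; when rooms are fixed by
#' the constraint set (`l_r == u_r`), they are omitted and `decode_setting`
#' restores them from the bounds.
#'
#' @param s a [miu_setting()].
#' @param include_r include the room counts in the encoding?
#' @param v numeric vector of length `2n + k` (or `3n + k` with rooms).
#' @param cs the governing [constraint_set()].
#' @return `encode_setting`: a named numeric vector; `decode_setting`: a
#'   [miu_setting()].
#' @examples
#' encode_setting(as_is_setting())
#' @export
encode_setting <- function(s, include_r = FALSE) {
  n <- length(s$x)
  v <- as.double(c(s$x, s$y, if (include_r) s$r, s$z))
  names(v) <- c(paste0("x", seq_len(n)), paste0("y", seq_len(n)),
                if (include_r) paste0("r", seq_len(n)),
                paste0("z", seq_along(s$z)))
  v
}

#' @rdname encode_setting
#' @export
decode_setting <- function(v, cs) {
  n <- cs$n
  k <- length(cs$l_z)
  r_free <- any(cs$l_r != cs$u_r)
  want <- 2L * n + k + if (r_free) n else 0L
  if (length(v) != want)
    stopf("feature vector has length %d, expected %d", length(v), want)
  x <- v[seq_len(n)]
  y <- v[n + seq_len(n)]
  if (r_free) {
    r <- v[2L * n + seq_len(n)]
    z <- v[3L * n + seq_len(k)]
  } else {
    r <- cs$l_r
    z <- v[2L * n + seq_len(k)]
  }
  miu_setting(x = x, y = y, z = unname(z), r = r)
}

encoded_names <- function(cs) {
  r_free <- any(cs$l_r != cs$u_r)
  c(paste0("x", seq_len(cs$n)), paste0("y", seq_len(cs$n)),
    if (r_free) paste0("r", seq_len(cs$n)),
    paste0("z", seq_along(cs$l_z)))
}
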