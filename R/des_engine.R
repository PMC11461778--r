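#' Simulation parameters
#'
#' Length, warm-up and replication settings of a simulation run.  The
#' defaults (38-day horizon, 1-week warm-up, 30 replications) are the
#' validated design of experiments for the case study; scaled-down values
#' are appropriate for dataset generation and testing.
#'
#' @param horizon_days simulated length in days.
#' @param warmup_days initial days discarded from statistics.
#' @param replications number of independent replications `N`.
#' @param base_seed integer; replication `i` derives its streams from
#'   `mix_seed(base_seed, i)`.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(horizon_days = 38, warmup_days = 7,
                       replications = 30, base_seed = 1L) {
  if (!is.numeric(horizon_days) || horizon_days <= 0)
    stopf("horizon_days must be positive")
  if (!is.numeric(warmup_days) || warmup_days < 0 ||
      warmup_days >= horizon_days)
    stopf("warmup_days must satisfy 0 <= warmup_days < horizon_days")
  if (!is_count(replications) || replications < 1)
    stopf("replications must be a positive integer")
  structure(list(horizon_days = as.double(horizon_days),
                 warmup_days = as.double(warmup_days),
                 replications = as.integer(replications),
                 base_seed = as.integer(base_seed)),
            class = "sim_params")
}

#' Sample arrival times from a piecewise-constant rate profile
#'
#' Draws one realization of a nonhomogeneous Poisson process whose rate is
#' piecewise constant on a repeating weekly grid of (day-of-week, hour)
#' cells.  Within each one-hour cell the count is Poisson with the cell rate
#' and the times are uniform, which is exact for a piecewise-constant
#' intensity.
#'
#' @param profile 7 x 24 matrix of rates (patients/hour), rows Monday..Sunday.
#' @param horizon_hours length of the sampling window in hours; the profile
#'   repeats weekly.  Day 1 of the simulation is a Monday.
#' @param seed optional integer seed; if `NULL` the current RNG state is
#'   used.
#' @return sorted numeric vector of arrival times in hours, strictly inside
#'   `[0, horizon_hours)`.
#' @export
sample_arrival_times <- function(profile, horizon_hours, seed = NULL) {
  if (!is.matrix(profile) || nrow(profile) != 7 || ncol(profile) != 24)
    stopf("profile must be a 7 x 24 matrix")
  if (any(profile < 0)) stopf("arrival rates must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  n_full <- floor(horizon_hours)
  frac <- horizon_hours - n_full
  k <- seq_len(n_full + (frac > 0)) - 1    # 0-based hour index
  day <- (k %/% 24) %% 7 + 1
  hr <- k %% 24
  rate <- profile[cbind(day, hr + 1)]
  width <- rep(1, length(k))
  if (frac > 0) width[length(k)] <- frac
  counts <- rpois(length(k), rate * width)
  if (!sum(counts)) return(numeric())
  starts <- rep(k, counts)
  w <- rep(width, counts)
  sort(starts + runif(sum(counts)) * w)
}

# weekly 7x24 capacity matrix -> step function (times in minutes from sim
# start, levels integer), compressed to runs; times start at 0
weekly_cap_steps <- function(mat, horizon_days) {
  n_hours <- ceiling(horizon_days * 24)
  k <- seq_len(n_hours) - 1
  lev <- mat[cbind((k %/% 24) %% 7 + 1, k %% 24 + 1)]
  keep <- c(TRUE, lev[-1] != lev[-length(lev)])
  list(time = k[keep] * 60, level = as.integer(lev[keep]))
}

# MIU capacity from the decision variables: r_d rooms on [x_d, y_d), else 0
miu_cap_steps <- function(setting, horizon_days) {
  n_days <- ceiling(horizon_days)
  times <- 0
  levels <- 0L
  for (dd in seq_len(n_days) - 1) {
    wd <- dd %% 7 + 1
    x <- setting$x[wd]; y <- setting$y[wd]; r <- setting$r[wd]
    if (y > x && r > 0) {
      times <- c(times, dd * 1440 + x * 60, dd * 1440 + y * 60)
      levels <- c(levels, as.integer(r), 0L)
    }
  }
  # merge coincident breakpoints (keep last) and drop repeated levels
  o <- order(times)
  times <- times[o]; levels <- levels[o]
  keep <- c(times[-length(times)] != times[-1], TRUE)
  times <- times[keep]; levels <- levels[keep]
  keep <- c(TRUE, levels[-1] != levels[-length(levels)])
  list(time = times[keep], level = levels[keep])
}

# is the MIU accepting patients at minute t (vectorized)?
miu_open_at <- function(setting, t_min) {
  dd <- floor(t_min / 1440)
  wd <- dd %% 7 + 1
  hod <- (t_min - dd * 1440) / 60
  hod >= setting$x[wd] & hod < setting$y[wd] & setting$r[wd] > 0
}

pick_from_mix <- function(u, mix) {
  nm <- names(mix)
  nm[findInterval(u, c(0, cumsum(mix)), rightmost.closed = TRUE,
                  all.inside = TRUE)]
}

#' Simulate ED patient flow for a fast-track setting
#'
#' Runs the discrete-event model for `replications` independent
#' replications.  In each replication patients arrive according to the
#' weekly-cyclic nonhomogeneous Poisson profile, queue FIFO for triage,
#' receive a severity tag, and are routed: whites go to the fast-track unit
#' when it is open and are retagged green otherwise; greens are diverted to
#' the fast track with probability `z_slot/100` (morning or afternoon slot)
#' when it is open, and otherwise join the shared units according to the
#' unit mix; yellows and reds go to their eligible units according to the
#' unit mix.  Each unit serves a non-preemptive priority queue (more severe
#' first, FIFO within tag) with a piecewise-constant room schedule; a room
#' is seized at the visit start (`t3`) and held for the visit duration.
#' When the fast track closes, patients already in service finish, and
#' queued patients are retagged green and rerouted to the shared units at
#' the closing time.  The door-to-doctor time of a patient is
#' `DTDT = t3 - t1`, with `t1` the triage start (arrival and triage start
#' are identified).
#'
#' Statistics are collected per (tag, unit) cell for patients arriving after
#' the warm-up period; patients still waiting at the horizon are censored
#' and counted separately.  Each replication draws from its own seed-derived
#' RNG streams, with sub-streams per stochastic element (arrivals, tags,
#' diversion, unit choice, triage times, visit times, rerouting), so
#' common-random-number comparisons across settings are aligned.
#'
#' @param scn a validated [ed_scenario()].
#' @param setting a [miu_setting()]; must carry room counts `r` when the
#'   scenario has a fast-track unit.
#' @param params a [sim_params()].
#' @param constraints optional [constraint_set()]; when supplied the setting
#'   is checked and an infeasible setting raises an error.
#' @param keep_log keep the per-patient event log of every replication?
#' @return an object of class `ed_sim_result` with per-cell per-replication
#'   mean DTDTs and patient counts, censoring counts, and the inputs as
#'   metadata.
#' @seealso [mean_dtdt()], [f1_from_result()]
#' @export
simulate_ed <- function(scn, setting, params = sim_params(),
                        constraints = NULL, keep_log = FALSE) {
  assert_valid_scenario(scn)
  if (!inherits(setting, "miu_setting")) stopf("setting must be a miu_setting")
  if (!is.null(constraints)) {
    viol <- check_feasibility(setting, constraints)
    if (length(viol))
      stopf("infeasible setting:\n  %s", paste(viol, collapse = "\n  "))
  }
  has_miu <- !is.null(scn$miu_unit)
  if (has_miu) {
    if (length(setting$x) != 7)
      stopf("weekly scenarios require a 7-day setting")
    if (is.null(setting$r)) stopf("setting must carry room counts r")
  }

  horizon_min <- params$horizon_days * 1440
  warmup_min <- params$warmup_days * 1440
  N <- params$replications

  # eligible (tag, unit) cells, in tag-major order
  cells <- do.call(rbind, lapply(scn$tags, function(t)
    data.frame(tag = t, unit = scn$eligible_units[[t]],
               stringsAsFactors = FALSE)))
  cell_key <- paste(cells$tag, cells$unit, sep = ".")
  rep_means <- matrix(NA_real_, N, length(cell_key),
                      dimnames = list(NULL, cell_key))
  rep_counts <- matrix(0L, N, length(cell_key),
                       dimnames = list(NULL, cell_key))
  censored <- integer(N)
  arrivals_eligible <- integer(N)
  logs <- if (keep_log) vector("list", N)

  cap_steps <- lapply(setdiff(scn$units, scn$miu_unit %||% ""),
                      function(u) weekly_cap_steps(scn$room_schedule[[u]],
                                                   params$horizon_days))
  names(cap_steps) <- setdiff(scn$units, scn$miu_unit %||% "")

  green_mix <- if (has_miu) scn$unit_mix[[scn$green_tag]]

  for (i in seq_len(N)) {
    rs <- mix_seed(params$base_seed, i)
    stream <- function(k) set.seed(mix_seed(rs, k))

    # 1: arrivals (hours -> minutes)
    stream(1)
    arr <- sample_arrival_times(scn$arrival_profile,
                                horizon_min / 60) * 60
    np <- length(arr)
    if (!np) {
      censored[i] <- 0L
      next
    }
    # 2-6: one draw per patient per stochastic element
    stream(2); u_tag <- runif(np)
    stream(3); u_div <- runif(np)
    stream(4); u_unit <- runif(np)
    stream(5); u_tri <- runif(np)
    stream(6); u_vis <- runif(np)

    tag <- scn$tags[findInterval(u_tag, c(0, cumsum(scn$tag_mix[scn$tags])),
                                 rightmost.closed = TRUE, all.inside = TRUE)]

    # triage: FIFO multi-server queue
    d_tri <- dist_quantile(scn$triage_time, u_tri)
    tri <- queue_sim_cpp(arr, integer(np), d_tri,
                         0, scn$triage_servers, horizon_min, FALSE)
    t1 <- tri$start
    t2 <- t1 + d_tri          # triage end = routing decision time

    # routing
    final_tag <- tag
    unit <- rep(NA_character_, np)
    routed <- !is.na(t2)
    if (has_miu) {
      open2 <- rep(FALSE, np)
      open2[routed] <- miu_open_at(setting, t2[routed])
      isW <- final_tag == scn$white_tag
      final_tag[isW & routed & !open2] <- scn$green_tag  # retag closed whites
      isG <- final_tag == scn$green_tag
      hod2 <- (t2 - floor(t2 / 1440) * 1440) / 60
      slot <- 1L + (hod2 >= scn$slot_boundary_hour)
      if (length(setting$z) == 1L) slot[] <- 1L
      z_at <- setting$z[slot] / 100
      to_miu <- routed & open2 & ((final_tag == scn$white_tag) |
                                  (isG & u_div < z_at))
      unit[to_miu] <- scn$miu_unit
      shared_g <- routed & isG & !to_miu
      unit[shared_g] <- pick_from_mix(u_unit[shared_g], green_mix)
    }
    other <- routed & is.na(unit)
    for (t in scn$tags) {
      sel <- other & final_tag == t
      if (!any(sel)) next
      mx <- scn$unit_mix[[t]]
      if (is.null(mx)) stopf("no unit mix for tag '%s'", t)
      unit[sel] <- pick_from_mix(u_unit[sel], mx)
    }

    # visit durations for the assigned (tag, unit)
    dur <- rep(NA_real_, np)
    for (t in unique(final_tag[routed])) {
      for (u in unique(unit[routed & final_tag == t])) {
        sel <- routed & final_tag == t & unit == u
        spec <- scn$visit_time[[t]][[u]]
        if (is.null(spec))
          stopf("no visit-time distribution for tag '%s' in unit '%s'", t, u)
        dur[sel] <- dist_quantile(spec, u_vis[sel])
      }
    }

    t3 <- rep(NA_real_, np)
    entry <- t2                      # unit-queue entry time

    # fast-track unit first: its closing rule feeds the shared units
    if (has_miu) {
      sel <- which(unit == scn$miu_unit & routed)
      if (length(sel)) {
        steps <- miu_cap_steps(setting, params$horizon_days)
        qs <- queue_sim_cpp(t2[sel], match(final_tag[sel], scn$tags),
                            dur[sel], steps$time, steps$level,
                            horizon_min, TRUE)
        t3[sel] <- qs$start
        ej <- sel[qs$status == 1L]
        if (length(ej)) {
          stream(7)
          u_re <- runif(length(ej))
          u_re2 <- runif(length(ej))
          final_tag[ej] <- scn$green_tag
          unit[ej] <- pick_from_mix(u_re, green_mix)
          entry[ej] <- qs$eject_time[qs$status == 1L]
          dur[ej] <- mapply(function(u, q)
            dist_quantile(scn$visit_time[[scn$green_tag]][[u]], q),
            unit[ej], u_re2)
        }
      }
    }

    for (u in names(cap_steps)) {
      sel <- which(unit == u & is.na(t3))
      if (!length(sel)) next
      qs <- queue_sim_cpp(entry[sel], match(final_tag[sel], scn$tags),
                          dur[sel], cap_steps[[u]]$time,
                          cap_steps[[u]]$level, horizon_min, FALSE)
      t3[sel] <- qs$start
    }

    # statistics (warm-up excluded; horizon-censored counted separately)
    eligible <- arr >= warmup_min
    counted <- eligible & !is.na(t3)
    dtdt <- t3 - t1
    key <- paste(final_tag, unit, sep = ".")
    for (j in seq_along(cell_key)) {
      sel <- counted & key == cell_key[j]
      m <- sum(sel)
      rep_counts[i, j] <- m
      if (m) rep_means[i, j] <- mean(dtdt[sel])
    }
    censored[i] <- sum(eligible & !counted)
    arrivals_eligible[i] <- sum(eligible)
    if (keep_log) {
      logs[[i]] <- data.frame(id = seq_len(np), tag = final_tag, unit = unit,
                              t1 = t1, t3 = t3, dtdt = dtdt, replication = i,
                              stringsAsFactors = FALSE)
    }
  }

  structure(list(cells = cells, rep_means = rep_means,
                 rep_counts = rep_counts, censored = censored,
                 arrivals_eligible = arrivals_eligible,
                 params = params, setting = setting,
                 scenario_hash = hash_object(scenario_to_list(scn)),
                 log = if (keep_log) do.call(rbind, logs)),
            class = "ed_sim_result")
}

#' Sample-average mean DTDT of a (tag, unit) cell
#'
#' The sample-average approximation of the expected door-to-doctor time for
#' one severity tag in one unit: the arithmetic mean, over the replications
#' in which the cell received patients, of the per-replication mean DTDT.
#'
#' @param res an `ed_sim_result`.
#' @param tag,unit cell identifiers.
#' @return mean DTDT in minutes.
#' @export
mean_dtdt <- function(res, tag, unit) {
  key <- paste(tag, unit, sep = ".")
  j <- match(key, colnames(res$rep_means))
  if (is.na(j))
    stopf("no cell for tag '%s' in unit '%s'", tag, unit)
  m <- res$rep_means[, j]
  ok <- !is.na(m)
  if (!any(ok))
    stopf("insufficient observations for tag '%s' in unit '%s'", tag, unit)
  mean(m[ok])
}

#' @export
print.ed_sim_result <- function(x, ...) {
  cat(sprintf("ED simulation result: %d replication(s), %.3g days (%.3g warm-up)\n",
              x$params$replications, x$params$horizon_days,
              x$params$warmup_days))
  cat(sprintf("  eligible arrivals/replication: %.1f; censored: %.2f\n",
              mean(x$arrivals_eligible), mean(x$censored)))
  invisible(x)
}

#' @export
summary.ed_sim_result <- function(object, ...) {
  cells <- object$cells
  cells$mean_dtdt_min <- vapply(seq_len(nrow(cells)), function(j) {
    m <- object$rep_means[, j]
    if (all(is.na(m))) NA_real_ else mean(m[!is.na(m)])
  }, numeric(1))
  cells$patients <- colSums(object$rep_counts)
  cells
}

#' Export the per-patient event log
#'
#' Writes the audit log of a result produced with `keep_log = TRUE` as a CSV
#' with columns `id, tag, unit, t1, t3, dtdt, replication` (times in minutes
#' from simulation start).
#'
#' @param res an `ed_sim_result` with a log.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_patient_log <- function(res, path) {
  if (is.null(res$log)) stopf("result carries no event log (keep_log = FALSE)")
  write.csv(res$log, path, row.names = FALSE)
  invisible(path)
}

#' Write a JSON summary of a simulation result
#'
#' @param res an `ed_sim_result`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_result_summary <- function(res, path) {
  s <- summary(res)
  write_json_file(list(
    cells = s,
    censored_per_replication = res$censored,
    params = unclass(res$params),
    setting = unclass(res$setting),
    scenario_hash = res$scenario_hash
  ), path)
  invisible(path)
}
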