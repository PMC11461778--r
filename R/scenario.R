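#' Construct an ED scenario
#'
#' An `ed_scenario` describes the simulated world: the ordered severity tags
#' (most severe first), the service units, which units each tag may be sent
#' to, the patient mix at triage, the weekly-cyclic arrival-rate profile, the
#' triage and visit/treatment time distributions, and the room schedules of
#' the always-open units.  The fast-track unit (`miu_unit`), when present, is
#' not scheduled here: its capacity is driven by the decision variables of a
#' [miu_setting()].
#'
#' Conventions: days are indexed 1..7 = Monday..Sunday, hours use the 24-h
#' clock, rates are patients/hour and durations are minutes.
#'
#' @param tags character vector of severity tags, most severe first.
#' @param units character vector of unit names.
#' @param eligible_units named list, tag -> character vector of units.
#' @param tag_mix named numeric, probability of each tag at triage (sums to 1).
#' @param unit_mix named list, tag -> named probabilities over that tag's
#'   eligible non-fast-track units (each sums to 1).  Tags whose only eligible
#'   unit is the fast-track unit may be omitted.
#' @param arrival_profile 7 x 24 numeric matrix of arrival rates
#'   (patients/hour), rows = days Monday..Sunday, columns = hours 0..23.
#' @param triage_servers number of triage nurses.
#' @param triage_time a [dist_spec()] for triage duration (minutes).
#' @param visit_time nested named list, tag -> unit -> [dist_spec()] for room
#'   occupancy during visit and treatment (minutes).
#' @param room_schedule named list, unit -> 7 x 24 integer matrix of room
#'   capacity, for every unit except `miu_unit`.
#' @param miu_unit name of the fast-track unit, or `NULL` if the scenario has
#'   none (e.g. single-queue validation reductions).
#' @param white_tag,green_tag the least and second-least severe tags; used by
#'   the retagging rule (whites become greens when the fast-track unit is
#'   closed) and the diversion rule.  Required when `miu_unit` is given.
#' @param slot_boundary_hour clock hour separating the morning diversion slot
#'   (first component of `z`) from the afternoon slot (second component).
#' @param meta optional list of documentation fields; if it contains
#'   `weekly_arrivals`, validation checks the profile against it.
#' @return an object of class `ed_scenario`.
#' @seealso [build_case_study_scenario()], [validate_scenario()]
#' @export
ed_scenario <- function(tags, units, eligible_units, tag_mix, unit_mix,
                        arrival_profile, triage_servers, triage_time,
                        visit_time, room_schedule, miu_unit = NULL,
                        white_tag = NULL, green_tag = NULL,
                        slot_boundary_hour = 13L, meta = list()) {
  scn <- structure(list(
    tags = as.character(tags),
    units = as.character(units),
    eligible_units = lapply(eligible_units, as.character),
    tag_mix = tag_mix,
    unit_mix = lapply(unit_mix, function(v) {
      storage.mode(v) <- "double"
      v
    }),
    arrival_profile = {
      m <- as.matrix(arrival_profile)
      dimnames(m) <- NULL
      storage.mode(m) <- "double"
      m
    },
    triage_servers = as.integer(triage_servers),
    triage_time = triage_time,
    visit_time = visit_time,
    room_schedule = lapply(room_schedule, function(m) {
      m <- as.matrix(m)
      dimnames(m) <- NULL
      storage.mode(m) <- "integer"
      m
    }),
    miu_unit = if (is.null(miu_unit)) NULL else as.character(miu_unit),
    white_tag = if (is.null(white_tag)) NULL else as.character(white_tag),
    green_tag = if (is.null(green_tag)) NULL else as.character(green_tag),
    slot_boundary_hour = as.integer(slot_boundary_hour),
    meta = meta
  ), class = "ed_scenario")
  storage.mode(scn$tag_mix) <- "double"
  scn
}

#' Validate an ED scenario
#'
#' Checks every structural invariant of the scenario and returns the
#' violations as data rather than raising, so callers can decide how to
#' react.  Each violation names the offending field (and, for the arrival
#' profile, the day/hour cell).
#'
#' @param s an [ed_scenario()].
#' @return character vector of violation descriptions; empty if valid.
#' @export
validate_scenario <- function(s) {
  v <- character()
  bad <- function(...) v <<- c(v, sprintf(...))
  if (!inherits(s, "ed_scenario")) return("not an ed_scenario object")
  if (!length(s$tags)) bad("tags: must be non-empty")
  if (!length(s$units)) bad("units: must be non-empty")
  if (anyDuplicated(s$tags)) bad("tags: duplicated tag names")
  if (anyDuplicated(s$units)) bad("units: duplicated unit names")

  # tag mix
  if (!identical(sort(names(s$tag_mix)), sort(s$tags))) {
    bad("tag_mix: names must match tags")
  } else {
    if (any(s$tag_mix < 0 | s$tag_mix > 1))
      bad("tag_mix: probabilities must lie in [0, 1]")
    if (abs(sum(s$tag_mix) - 1) > 1e-9)
      bad("tag_mix: probabilities sum to %.6f, not 1", sum(s$tag_mix))
  }

  # eligibility
  for (t in s$tags) {
    el <- s$eligible_units[[t]]
    if (is.null(el) || !length(el)) {
      bad("eligible_units: tag '%s' has no eligible units", t)
      next
    }
    if (!all(el %in% s$units))
      bad("eligible_units: tag '%s' references unknown units", t)
  }
  if (!is.null(s$miu_unit)) {
    if (!s$miu_unit %in% s$units) bad("miu_unit: '%s' not a unit", s$miu_unit)
    if (is.null(s$white_tag) || is.null(s$green_tag))
      bad("white_tag/green_tag: required when miu_unit is set")
    allowed <- utils::tail(s$tags, 2)  # two least severe tags only
    for (t in s$tags) {
      if (!is.null(s$eligible_units[[t]]) &&
          s$miu_unit %in% s$eligible_units[[t]] && !(t %in% allowed))
        bad("eligible_units: fast-track unit eligible for tag '%s' (only the two least severe tags may use it)", t)
    }
  }

  # unit mix: per-tag probabilities over eligible non-fast-track units
  for (t in s$tags) {
    el <- setdiff(s$eligible_units[[t]] %||% character(), s$miu_unit %||% "")
    um <- s$unit_mix[[t]]
    if (!length(el)) next
    if (is.null(um)) {
      bad("unit_mix: missing entry for tag '%s'", t)
      next
    }
    if (!identical(sort(names(um)), sort(el))) {
      bad("unit_mix: tag '%s' must cover exactly its eligible non-fast-track units", t)
      next
    }
    if (any(um < 0 | um > 1))
      bad("unit_mix: tag '%s' probabilities must lie in [0, 1]", t)
    if (abs(sum(um) - 1) > 1e-9)
      bad("unit_mix: tag '%s' probabilities sum to %.6f, not 1", t, sum(um))
  }

  # arrival profile
  ap <- s$arrival_profile
  if (!is.matrix(ap) || nrow(ap) != 7 || ncol(ap) != 24) {
    bad("arrival_profile: must be a 7 x 24 matrix (days x hours)")
  } else if (any(ap < 0)) {
    idx <- which(ap < 0, arr.ind = TRUE)[1, ]
    bad("arrival_profile: negative rate at day %d, hour %d",
        idx[1], idx[2] - 1L)
  }
  if (!is.null(s$meta$weekly_arrivals) && is.matrix(ap) &&
      all(dim(ap) == c(7, 24)) && all(ap >= 0)) {
    tot <- sum(ap)
    ref <- s$meta$weekly_arrivals
    if (abs(tot - ref) > 1e-3 * ref)
      bad("arrival_profile: implies %.2f weekly arrivals, documented total is %.2f",
          tot, ref)
  }

  # service time distributions
  msg <- validate_dist(s$triage_time)
  if (length(msg)) bad("triage_time: %s", paste(msg, collapse = "; "))
  if (!is_count(s$triage_servers) || s$triage_servers < 1)
    bad("triage_servers: must be a positive integer")
  for (t in names(s$visit_time)) {
    for (u in names(s$visit_time[[t]])) {
      msg <- validate_dist(s$visit_time[[t]][[u]])
      if (length(msg))
        bad("visit_time[%s][%s]: %s", t, u, paste(msg, collapse = "; "))
    }
  }
  # every eligible (tag, unit) cell needs a visit-time distribution
  for (t in s$tags) {
    for (u in s$eligible_units[[t]] %||% character()) {
      if (is.null(s$visit_time[[t]][[u]]))
        bad("visit_time: missing distribution for tag '%s' in unit '%s'", t, u)
    }
  }
  # retagged whites are served as greens, so green distributions must cover
  # the green tag's shared units even when whites only list the fast track
  if (!is.null(s$miu_unit) && !is.null(s$green_tag)) {
    for (u in setdiff(s$eligible_units[[s$green_tag]] %||% character(),
                      s$miu_unit)) {
      if (is.null(s$visit_time[[s$green_tag]][[u]]))
        bad("visit_time: missing distribution for tag '%s' in unit '%s'",
            s$green_tag, u)
    }
  }

  # room schedules for all scheduled (non-fast-track) units
  sched_units <- setdiff(s$units, s$miu_unit %||% "")
  for (u in sched_units) {
    m <- s$room_schedule[[u]]
    if (is.null(m)) {
      bad("room_schedule: missing schedule for unit '%s'", u)
      next
    }
    if (!is.matrix(m) || nrow(m) != 7 || ncol(m) != 24) {
      bad("room_schedule[%s]: must be a 7 x 24 matrix", u)
      next
    }
    if (any(m < 0) || !is_wholenumber(m))
      bad("room_schedule[%s]: capacities must be nonnegative integers", u)
  }

  if (!is.numeric(s$slot_boundary_hour) || s$slot_boundary_hour < 0 ||
      s$slot_boundary_hour > 24)
    bad("slot_boundary_hour: must lie in [0, 24]")
  v
}

assert_valid_scenario <- function(s) {
  v <- validate_scenario(s)
  if (length(v))
    stopf("invalid scenario:\n  %s", paste(v, collapse = "\n  "))
  invisible(s)
}

#' Weekly room-capacity matrix with a day/night split
#'
#' Convenience builder for the 7 x 24 capacity matrices of scheduled units.
#'
#' @param day,night integer room counts for the day and night blocks.
#' @param day_start,day_end clock hours delimiting the day block
#'   (`day_start <= hour < day_end`).
#' @return a 7 x 24 integer matrix.
#' @examples
#' room_matrix(3, 2)           # 3 rooms 08:00-20:00, 2 otherwise
#' room_matrix(2, 2)           # constant capacity
#' @export
room_matrix <- function(day, night = day, day_start = 8, day_end = 20) {
  hrs <- 0:23
  row <- ifelse(hrs >= day_start & hrs < day_end, day, night)
  matrix(as.integer(rep(row, each = 7)), nrow = 7)
}

# recursive override merge: every name must already exist in the base
merge_overrides <- function(base, ov, path = "") {
  for (nm in names(ov)) {
    here <- if (nzchar(path)) paste0(path, "$", nm) else nm
    if (!nm %in% names(base))
      stopf("unknown scenario field in overrides: '%s'", here)
    if (is.list(base[[nm]]) && is.list(ov[[nm]]) &&
        !inherits(base[[nm]], "dist_spec") && !is.null(names(ov[[nm]]))) {
      base[[nm]] <- merge_overrides(base[[nm]], ov[[nm]], here)
    } else {
      base[[nm]] <- ov[[nm]]
    }
  }
  base
}

#' Build the case-study ED scenario
#'
#' Returns a complete, validated scenario emulating a large urban ED central
#' area served by a Medical Unit (MU), a Surgical Unit (SU), dedicated
#' red-tag areas (MU_Red, SU_Red) and a fast-track Minor Injuries Unit (MIU):
#'
#' * four severity tags `R > Y > G > W`, with the triage mix and the per-tag
#'   unit mix computed from a one-month census of 3,428 patients
#'   (R 236, Y 2009, G 1136, W 47 after excluding the resuscitation area);
#' * MU with 3 rooms by day (08:00-20:00) and 2 by night, SU with 2/1,
#'   MU_Red with 1 and SU_Red with 2 rooms around the clock;
#' * a weekly-cyclic piecewise-constant arrival profile scaled to 4,200
#'   arrivals per 31 days (about 948 per week), peaking in late morning;
#' * lognormal visit times and exponential triage times chosen so that the
#'   shared day-time rooms run at roughly 80% utilization (congestion is what
#'   makes the waiting-time/operating-hours trade-off non-trivial);
#' * morning/afternoon diversion-slot boundary at 13:00.
#'
#' All defaults can be replaced through `overrides`, a named (possibly
#' nested) list whose names must match existing scenario fields; unknown
#' names raise an error.
#'
#' @param overrides named list of scenario fields to replace.
#' @return a validated [ed_scenario()].
#' @examples
#' scn <- build_case_study_scenario()
#' scn$room_schedule$MU[1, 9]  # 3 rooms at 08:00 on Mondays
#' scn2 <- build_case_study_scenario(list(triage_servers = 3L))
#' @export
build_case_study_scenario <- function(overrides = list()) {
  # one-month census counts (resuscitation area excluded): rows units,
  # columns tags; marginals drive tag_mix and unit_mix
  n_R <- c(MU_Red = 191, SU_Red = 45)
  n_Y <- c(MU = 1316, SU = 693)
  n_G <- c(MU = 248, SU = 628)    # greens not sent to the fast track
  n_G_miu <- 260
  n_W <- 47
  tot <- sum(n_R) + sum(n_Y) + sum(n_G) + n_G_miu + n_W  # 3428

  tag_mix <- c(R = sum(n_R), Y = sum(n_Y), G = sum(n_G) + n_G_miu,
               W = n_W) / tot

  # hour-of-day arrival shape (same on every day), normalized so the
  # expected number of arrivals is 4200 per 31 days
  shape <- c(rep(1.0, 7),    # 00-06: night
             rep(4.0, 5),    # 07-11: morning peak
             rep(3.3, 8),    # 12-19: afternoon
             rep(1.8, 4))    # 20-23: evening
  daily <- 4200 / 31
  rates <- shape * daily / sum(shape)
  arrival_profile <- matrix(rep(rates, each = 7), nrow = 7)

  ln <- function(mean) dist_spec("lognormal", mean = mean, sdlog = 0.5)

  base <- ed_scenario(
    tags = c("R", "Y", "G", "W"),
    units = c("MU", "SU", "MU_Red", "SU_Red", "MIU"),
    eligible_units = list(R = c("MU_Red", "SU_Red"), Y = c("MU", "SU"),
                          G = c("MU", "SU", "MIU"), W = "MIU"),
    tag_mix = tag_mix,
    unit_mix = list(R = n_R / sum(n_R), Y = n_Y / sum(n_Y),
                    G = n_G / sum(n_G)),
    arrival_profile = arrival_profile,
    triage_servers = 2L,
    triage_time = dist_spec("exponential", mean = 5),
    visit_time = list(
      R = list(MU_Red = ln(35), SU_Red = ln(35)),
      Y = list(MU = ln(38), SU = ln(35)),
      G = list(MU = ln(30), SU = ln(28), MIU = ln(22)),
      W = list(MIU = ln(18))
    ),
    room_schedule = list(
      MU = room_matrix(3, 2), SU = room_matrix(2, 1),
      MU_Red = room_matrix(1, 1), SU_Red = room_matrix(2, 2)
    ),
    miu_unit = "MIU", white_tag = "W", green_tag = "G",
    slot_boundary_hour = 13L,
    meta = list(label = "case-study ED fixture",
                monthly_arrivals = 4200, month_days = 31,
                weekly_arrivals = 4200 / 31 * 7)
  )
  if (length(overrides)) {
    scn <- merge_overrides(unclass(base), overrides)
    base <- do.call(ed_scenario, scn[setdiff(names(scn), character())])
  }
  assert_valid_scenario(base)
  base
}

#' @export
print.ed_scenario <- function(x, ...) {
  cat("ED scenario", if (!is.null(x$meta$label)) paste0("(", x$meta$label, ")"),
      "\n")
  cat("  tags (most severe first):", paste(x$tags, collapse = " > "), "\n")
  cat("  units:", paste(x$units, collapse = ", "),
      if (!is.null(x$miu_unit)) sprintf("(fast track: %s)", x$miu_unit), "\n")
  cat(sprintf("  expected arrivals/week: %.1f\n", sum(x$arrival_profile)))
  cat(sprintf("  triage: %d server(s), mean %.1f min\n", x$triage_servers,
              dist_mean(x$triage_time)))
  invisible(x)
}

#' Construct a constraint set for the fast-track schedule
#'
#' Bounds and minimum-hours rules governing a [miu_setting()]: box bounds on
#' the daily opening hour `x`, closing hour `y` and open-room count `r`, box
#' bounds on the diversion percentages `z`, a minimum daily number of open
#' hours `h_d`, and a minimum weekly total of open hours `g`.
#'
#' @param n number of days in the planning period.
#' @param l_x,u_x,l_y,u_y integer hour bounds (0-24), recycled to length `n`.
#' @param l_r,u_r integer room-count bounds, recycled to length `n`.
#' @param l_z,u_z numeric percentage bounds in `[0, 100]`, one per diversion
#'   slot variable.
#' @param h integer minimum daily open hours, recycled to length `n`.
#' @param g integer minimum total open hours over the period.
#' @return an object of class `miu_constraints`.
#' @seealso [case_study_constraints()], [check_feasibility()]
#' @export
constraint_set <- function(n, l_x, u_x, l_y, u_y, l_r = 0L, u_r = 0L,
                           l_z = 0, u_z = 100, h = 0L, g = 0L) {
  if (!is_count(n) || n < 1) stopf("n must be a positive integer")
  n <- as.integer(n)
  rec <- function(v, what) {
    if (!is_wholenumber(v)) stopf("%s must be integer-valued", what)
    as.integer(rep_len(v, n))
  }
  cs <- structure(list(
    n = n,
    l_x = rec(l_x, "l_x"), u_x = rec(u_x, "u_x"),
    l_y = rec(l_y, "l_y"), u_y = rec(u_y, "u_y"),
    l_r = rec(l_r, "l_r"), u_r = rec(u_r, "u_r"),
    l_z = as.double(l_z), u_z = as.double(u_z),
    h = rec(h, "h"),
    g = { if (!is_count(g)) stopf("g must be a nonnegative integer")
          as.integer(g) }
  ), class = "miu_constraints")
  if (length(cs$l_z) != length(cs$u_z))
    stopf("l_z and u_z must have equal length")
  if (any(cs$l_z < 0 | cs$u_z > 100 | cs$l_z > cs$u_z))
    stopf("z bounds must satisfy 0 <= l_z <= u_z <= 100")
  for (f in c("x", "y", "r")) {
    if (any(cs[[paste0("l_", f)]] > cs[[paste0("u_", f)]]))
      stopf("bounds must satisfy l_%s <= u_%s componentwise", f, f)
  }
  if (any(cs$l_x < 0) || any(cs$u_x > 24) || any(cs$l_y < 0) ||
      any(cs$u_y > 24))
    stopf("hour bounds must lie in [0, 24]")
  if (any(cs$h < 0)) stopf("h must be nonnegative")
  if (any(cs$h > cs$u_y - cs$l_x))
    stopf("h_d exceeds the attainable daily hours u_y - l_x")
  if (cs$g > sum(cs$u_y - cs$l_x))
    stopf("g exceeds the attainable weekly hours sum(u_y - l_x)")
  cs
}

#' Case-study constraint set
#'
#' The weekly planning constraints of the case study: opening and closing
#' hours free between 07:00 and 20:00 every day (`l = 7`, `u = 20`), rooms
#' fixed at 2, morning diversion bounded by 75% and afternoon diversion by
#' 35%, no daily minimum (`h_d = 0`, so the unit may close on some days), and
#' a weekly minimum of `g = 21` open hours.
#'
#' @return a [constraint_set()] with `n = 7`.
#' @examples
#' cs <- case_study_constraints()
#' cs$g          # 21
#' cs$u_z        # c(75, 35)
#' @export
case_study_constraints <- function() {
  constraint_set(n = 7, l_x = 7L, u_x = 20L, l_y = 7L, u_y = 20L,
                 l_r = 2L, u_r = 2L, l_z = c(0, 0), u_z = c(75, 35),
                 h = 0L, g = 21L)
}

#' @export
print.miu_constraints <- function(x, ...) {
  cat(sprintf("MIU constraints over %d days\n", x$n))
  cat(sprintf("  hours: x in [%s, %s], y in [%s, %s]\n",
              x$l_x[1], x$u_x[1], x$l_y[1], x$u_y[1]))
  cat(sprintf("  rooms: [%s, %s]%s\n", x$l_r[1], x$u_r[1],
              if (all(x$l_r == x$u_r)) " (fixed)" else ""))
  cat(sprintf("  diversion %%: [%s]..[%s]\n",
              paste(x$l_z, collapse = ","), paste(x$u_z, collapse = ",")))
  cat(sprintf("  min daily hours h: %s; min weekly hours g: %d\n",
              paste(unique(x$h), collapse = ","), x$g))
  invisible(x)
}

# ---- config-file serialization (JSON) --------------------------------------

scenario_to_list <- function(s) {
  list(
    type = "ed_scenario",
    tags = s$tags, units = s$units,
    eligible_units = s$eligible_units,
    tag_mix = as.list(s$tag_mix),
    unit_mix = lapply(s$unit_mix, as.list),
    arrival_profile = apply(s$arrival_profile, 1, identity, simplify = FALSE),
    triage_servers = s$triage_servers,
    triage_time = unclass(s$triage_time),
    visit_time = lapply(s$visit_time, function(tl) lapply(tl, unclass)),
    room_schedule = lapply(s$room_schedule, function(m)
      apply(m, 1, identity, simplify = FALSE)),
    miu_unit = s$miu_unit, white_tag = s$white_tag, green_tag = s$green_tag,
    slot_boundary_hour = s$slot_boundary_hour,
    meta = s$meta
  )
}

list_to_scenario <- function(l) {
  relist_dist <- function(d) do.call(dist_spec, d)
  rows_to_matrix <- function(rows, mode) {
    m <- do.call(rbind, lapply(rows, as.numeric))
    storage.mode(m) <- mode
    m
  }
  ed_scenario(
    tags = l$tags, units = l$units,
    eligible_units = l$eligible_units,
    tag_mix = unlist(l$tag_mix),
    unit_mix = lapply(l$unit_mix, unlist),
    arrival_profile = rows_to_matrix(l$arrival_profile, "double"),
    triage_servers = l$triage_servers,
    triage_time = relist_dist(l$triage_time),
    visit_time = lapply(l$visit_time, function(tl) lapply(tl, relist_dist)),
    room_schedule = lapply(l$room_schedule, rows_to_matrix, mode = "integer"),
    miu_unit = l$miu_unit, white_tag = l$white_tag, green_tag = l$green_tag,
    slot_boundary_hour = l$slot_boundary_hour,
    meta = l$meta
  )
}

#' Read and write scenario and constraint config files
#'
#' Scenarios and constraint sets serialize to JSON config files that
#' round-trip exactly: reading a written file reconstructs an object
#' identical to the original.  Times are 24-h clock hours, durations
#' minutes, rates patients/hour, days 1..7 = Monday..Sunday.
#'
#' @param s an [ed_scenario()]; `cs` a [constraint_set()].
#' @param path file path.
#' @return `read_scenario`/`read_constraints` return the reconstructed
#'   object; the writers return `path` invisibly.
#' @export
write_scenario <- function(s, path) {
  assert_valid_scenario(s)
  write_json_file(scenario_to_list(s), path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(l$type, "ed_scenario"))
    stopf("'%s' is not a scenario config file", path)
  l$eligible_units <- lapply(l$eligible_units, function(x)
    unlist(x, use.names = FALSE))
  l$tags <- unlist(l$tags)
  l$units <- unlist(l$units)
  l$meta <- lapply(l$meta, function(x) {
    x <- if (length(x) == 1) x[[1]] else unlist(x)
    if (is.numeric(x)) as.double(x) else x
  })
  s <- list_to_scenario(l)
  assert_valid_scenario(s)
  s
}

#' @rdname write_scenario
#' @export
write_constraints <- function(cs, path) {
  l <- c(list(type = "miu_constraints"), unclass(cs))
  write_json_file(l, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_constraints <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(l$type, "miu_constraints"))
    stopf("'%s' is not a constraints config file", path)
  constraint_set(n = l$n, l_x = l$l_x, u_x = l$u_x, l_y = l$l_y, u_y = l$u_y,
                 l_r = l$l_r, u_r = l$u_r, l_z = l$l_z, u_z = l$u_z,
                 h = l$h, g = l$g)
}
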