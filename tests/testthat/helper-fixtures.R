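# Shared fixtures: small scenarios and constraint sets built in code.

# single-queue reduction: one tag, one unit, constant Poisson arrivals,
# exponential service -- an M/M/c system whose mean queueing delay has the
# Erlang-C closed form (triage is a zero-delay pass-through)
mmc_scenario <- function(lambda_per_h, mean_service_min, c_rooms) {
  ed_scenario(
    tags = "G", units = "U",
    eligible_units = list(G = "U"),
    tag_mix = c(G = 1),
    unit_mix = list(G = c(U = 1)),
    arrival_profile = matrix(lambda_per_h, 7, 24),
    triage_servers = 1000L,
    triage_time = dist_spec("deterministic", value = 0),
    visit_time = list(G = list(U = dist_spec("exponential",
                                             mean = mean_service_min))),
    room_schedule = list(U = room_matrix(c_rooms, c_rooms)),
    miu_unit = NULL
  )
}

# one congested shared unit with three priority classes
priority_scenario <- function() {
  ed_scenario(
    tags = c("R", "Y", "G"), units = "U",
    eligible_units = list(R = "U", Y = "U", G = "U"),
    tag_mix = c(R = 0.2, Y = 0.4, G = 0.4),
    unit_mix = list(R = c(U = 1), Y = c(U = 1), G = c(U = 1)),
    arrival_profile = matrix(5, 7, 24),
    triage_servers = 1000L,
    triage_time = dist_spec("deterministic", value = 0),
    visit_time = list(R = list(U = dist_spec("exponential", mean = 20)),
                      Y = list(U = dist_spec("exponential", mean = 20)),
                      G = list(U = dist_spec("exponential", mean = 20))),
    room_schedule = list(U = room_matrix(2, 2)),
    miu_unit = NULL
  )
}

# reduced planning instance for exhaustive enumeration: 2 days, hours 7..10
tiny_constraints <- function(g = 4L, z_fixed = FALSE) {
  constraint_set(n = 2, l_x = 7L, u_x = 10L, l_y = 7L, u_y = 10L,
                 l_r = 1L, u_r = 1L,
                 l_z = if (z_fixed) c(50, 50) else c(0, 0),
                 u_z = if (z_fixed) c(50, 50) else c(100, 100),
                 h = 0L, g = g)
}

# every feasible (x1, y1, x2, y2) of a tiny_constraints instance
enumerate_tiny <- function(cs) {
  grid <- expand.grid(x1 = cs$l_x[1]:cs$u_x[1], y1 = cs$l_y[1]:cs$u_y[1],
                      x2 = cs$l_x[2]:cs$u_x[2], y2 = cs$l_y[2]:cs$u_y[2])
  ok <- with(grid, y1 >= x1 & y2 >= x2 &
               (y1 - x1) >= cs$h[1] & (y2 - x2) >= cs$h[2] &
               (y1 - x1) + (y2 - x2) >= cs$g)
  grid[ok, , drop = FALSE]
}

# independent rule-by-rule feasibility oracle (kept deliberately naive)
oracle_feasible <- function(s, cs) {
  ok <- TRUE
  for (d in seq_len(cs$n)) {
    ok <- ok && s$x[d] >= cs$l_x[d] && s$x[d] <= cs$u_x[d]
    ok <- ok && s$y[d] >= cs$l_y[d] && s$y[d] <= cs$u_y[d]
    if (!is.null(s$r))
      ok <- ok && s$r[d] >= cs$l_r[d] && s$r[d] <= cs$u_r[d]
    ok <- ok && (s$y[d] - s$x[d]) >= cs$h[d]
  }
  for (k in seq_along(s$z))
    ok <- ok && s$z[k] >= cs$l_z[k] && s$z[k] <= cs$u_z[k]
  ok && sum(s$y - s$x) >= cs$g
}

# the printed decision table of Pareto-optimal schedules used as input data
# (x1..x7, y1..y7 interleaved per day, z1, z2, f1, f2)
printed_front_rows <- function() {
  rows <- list(
    A = c(7,18, 9,20, 9,20, 7,19, 7,20, 10,20, 7,19, 65, 35, 701.23, 80),
    B = c(8,19, 10,20, 9,19, 7,18, 8,19, 10,20, 7,18, 70, 35, 702.52, 74),
    C = c(9,20, 10,20, 7,16, 7,18, 9,20, 9,17, 7,15, 65, 35, 705.23, 68),
    D = c(8,19, 10,20, 7,16, 7,18, 9,20, 8,16, 7,13, 60, 35, 708.98, 66),
    E = c(10,20, 11,20, 7,15, 10,18, 9,20, 9,14, 7,12, 60, 35, 711.09, 56),
    F = c(10,20, 10,19, 8,16, 10,18, 9,20, 9,13, 7,12, 60, 35, 714.55, 55),
    G = c(12,20, 9,17, 9,17, 10,15, 9,20, 10,14, 7,11, 65, 35, 719.00, 48),
    H = c(12,20, 9,16, 10,17, 10,15, 9,20, 10,14, 7,11, 65, 35, 722.95, 46),
    I = c(12,20, 9,16, 10,17, 11,14, 9,20, 10,14, 7,10, 65, 35, 733.92, 43),
    J = c(12,20, 8,14, 10,16, 11,13, 9,19, 9,13, 7,7, 65, 35, 736.74, 36),
    K = c(7,7, 10,13, 11,16, 11,14, 9,16, 12,15, 7,7, 60, 35, 766.11, 21))
  out <- lapply(rows, function(v) {
    x <- v[seq(1, 13, by = 2)]
    y <- v[seq(2, 14, by = 2)]
    list(setting = miu_setting(x, y, z = v[15:16], r = rep(2L, 7)),
         f1 = v[17], f2 = v[18])
  })
  names(out) <- names(rows)
  out
}

# reduced-scale simulation protocol used across tests
fast_params <- function(seed = 1L, reps = 3L, horizon = 6, warmup = 1) {
  sim_params(horizon_days = horizon, warmup_days = warmup,
             replications = reps, base_seed = seed)
}
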