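test_that("arrival sampler honours the piecewise-constant profile", {
  prof0 <- matrix(0, 7, 24)
  expect_length(sample_arrival_times(prof0, 100, seed = 1), 0)

  # constant rate: Poisson count concentration over a long window
  prof <- matrix(4, 7, 24)
  counts <- vapply(1:20, function(s)
    length(sample_arrival_times(prof, 1000, seed = s)), numeric(1))
  expect_true(all(abs(counts - 4000) < 3 * sqrt(4000)))

  # times live strictly inside the window and are sorted
  tt <- sample_arrival_times(prof, 10.5, seed = 3)
  expect_true(all(tt >= 0 & tt < 10.5))
  expect_identical(tt, sort(tt))

  neg <- prof; neg[2, 5] <- -1
  expect_error(sample_arrival_times(neg, 10), "nonnegative")
})

test_that("arrival sampler matches a thinning oracle on a two-step profile", {
  # profile: 3/h in hour 0, 7/h in hour 1 (same every day)
  prof <- matrix(0, 7, 24)
  prof[, 1] <- 3; prof[, 2] <- 7
  nrep <- 10000
  set.seed(99)
  mine <- t(vapply(seq_len(nrep), function(i) {
    tt <- sample_arrival_times(prof, 2)
    c(sum(tt < 1), sum(tt >= 1))
  }, numeric(2)))
  # independent thinning sampler: homogeneous process at the max rate,
  # accepted with probability rate(t)/max_rate
  thin <- t(vapply(seq_len(nrep), function(i) {
    n <- rpois(1, 7 * 2)
    t_raw <- sort(runif(n, 0, 2))
    rate <- ifelse(t_raw < 1, 3, 7)
    keep <- runif(n) < rate / 7
    tt <- t_raw[keep]
    c(sum(tt < 1), sum(tt >= 1))
  }, numeric(2)))
  for (j in 1:2) {
    br <- 0:max(mine[, j], thin[, j])
    tab1 <- tabulate(mine[, j] + 1, nbins = length(br))
    tab2 <- tabulate(thin[, j] + 1, nbins = length(br))
    keep <- (tab1 + tab2) >= 10          # pool sparse tails
    p <- suppressWarnings(stats::chisq.test(rbind(tab1[keep],
                                                  tab2[keep]))$p.value)
    expect_gt(p, 0.01)
  }
})

test_that("degenerate simulations behave as closed forms dictate", {
  # zero arrivals: empty result
  scn0 <- build_case_study_scenario(list(
    arrival_profile = matrix(0, 7, 24),
    meta = list(label = "empty", weekly_arrivals = NULL)))
  res0 <- simulate_ed(scn0, as_is_setting(), fast_params(seed = 1, reps = 2,
                                                         horizon = 2))
  expect_true(all(res0$rep_counts == 0))
  expect_true(all(is.na(res0$rep_means)))
  expect_error(mean_dtdt(res0, "G", "MU"), "insufficient observations")

  # single stream into an idle system with deterministic zero triage:
  # waiting time equals the queueing delay only, so a near-empty system
  # gives DTDT ~ 0
  mm <- mmc_scenario(0.05, 1, 5)
  res1 <- simulate_ed(mm, miu_setting(x = 8, y = 9, z = 1),
                      fast_params(seed = 2, reps = 2, horizon = 4,
                                  warmup = 0))
  expect_lt(mean_dtdt(res1, "G", "U"), 1e-6)
})

test_that("deterministic triage delay propagates into DTDT", {
  # deterministic triage of tau minutes, idle unit: t1 = arrival,
  # t3 = t1 + tau, so DTDT = tau exactly
  tau <- 7
  scn <- ed_scenario(
    tags = "G", units = "U", eligible_units = list(G = "U"),
    tag_mix = c(G = 1), unit_mix = list(G = c(U = 1)),
    arrival_profile = matrix(0.05, 7, 24),
    triage_servers = 50L,
    triage_time = dist_spec("deterministic", value = tau),
    visit_time = list(G = list(U = dist_spec("deterministic", value = 3))),
    room_schedule = list(U = room_matrix(50, 50)), miu_unit = NULL)
  res <- simulate_ed(scn, miu_setting(x = 8, y = 9, z = 1),
                     fast_params(seed = 4, reps = 2, horizon = 4, warmup = 0))
  expect_equal(mean_dtdt(res, "G", "U"), tau, tolerance = 1e-9)
})

test_that("simulation results are seed-deterministic and conservative", {
  scn <- build_case_study_scenario()
  p <- fast_params(seed = 31, reps = 3, horizon = 5, warmup = 1)
  r1 <- simulate_ed(scn, as_is_setting(), p)
  r2 <- simulate_ed(scn, as_is_setting(), p)
  expect_identical(r1$rep_means, r2$rep_means)
  expect_identical(r1$rep_counts, r2$rep_counts)
  expect_identical(r1$censored, r2$censored)
  # conservation: eligible arrivals = counted + censored, per replication
  expect_identical(r1$arrivals_eligible,
                   as.integer(rowSums(r1$rep_counts) + r1$censored))
  # a different seed changes the realization
  r3 <- simulate_ed(scn, as_is_setting(),
                    fast_params(seed = 32, reps = 3, horizon = 5, warmup = 1))
  expect_false(identical(r1$rep_means, r3$rep_means))
})

test_that("severity priority orders waiting times in a congested unit", {
  scn <- priority_scenario()   # rho ~ 0.83 on 2 rooms, tags R > Y > G
  res <- simulate_ed(scn, miu_setting(x = 8, y = 9, z = 1),
                     sim_params(horizon_days = 12, warmup_days = 2,
                                replications = 12, base_seed = 55))
  ms <- vapply(c("R", "Y", "G"), function(t)
    mean_dtdt(res, t, "U"), numeric(1))
  ses <- vapply(c("R", "Y", "G"), function(t) {
    v <- res$rep_means[, paste0(t, ".U")]
    sd(v) / sqrt(sum(!is.na(v)))
  }, numeric(1))
  expect_lt(ms["R"], ms["Y"] + 3 * (ses["R"] + ses["Y"]))
  expect_lt(ms["Y"], ms["G"] + 3 * (ses["Y"] + ses["G"]))
  # and the congestion is real: greens wait substantially longer than reds
  expect_gt(ms["G"], ms["R"])
})

test_that("sample-average variance shrinks like 1/N", {
  mm <- mmc_scenario(6, 15, 2)   # rho = 0.75, short horizon
  s <- miu_setting(x = 8, y = 9, z = 1)
  Ns <- c(5, 10, 20, 40)
  nrep <- 24
  vars <- vapply(Ns, function(N) {
    est <- vapply(seq_len(nrep), function(k) {
      res <- simulate_ed(mm, s, sim_params(horizon_days = 2,
                                           warmup_days = 0.5,
                                           replications = N,
                                           base_seed = 7000 + 100 * N + k))
      mean_dtdt(res, "G", "U")
    }, numeric(1))
    var(est)
  }, numeric(1))
  slope <- coef(lm(log(vars) ~ log(Ns)))[2]
  expect_gt(slope, -1.3)
  expect_lt(slope, -0.7)
})

test_that("raising morning diversion does not hurt shared-unit greens (CRN)", {
  scn <- build_case_study_scenario()
  p <- fast_params(seed = 77, reps = 6, horizon = 6, warmup = 1)
  lo <- simulate_ed(scn, miu_setting(rep(8L, 7), rep(20L, 7), c(30, 5),
                                     rep(2L, 7)), p)
  hi <- simulate_ed(scn, miu_setting(rep(8L, 7), rep(20L, 7), c(60, 5),
                                     rep(2L, 7)), p)
  m_lo <- mean_dtdt(lo, "G", "MU")
  m_hi <- mean_dtdt(hi, "G", "MU")
  se <- sd(lo$rep_means[, "G.MU"] - hi$rep_means[, "G.MU"]) /
    sqrt(p$replications)
  expect_lt(m_hi, m_lo + 3 * se)
})

test_that("per-replication cell means average into the SAA estimate", {
  mm <- mmc_scenario(4, 15, 2)
  res <- simulate_ed(mm, miu_setting(x = 8, y = 9, z = 1),
                     fast_params(seed = 9, reps = 5, horizon = 3,
                                 warmup = 0.5))
  m <- res$rep_means[, "G.U"]
  expect_equal(mean_dtdt(res, "G", "U"), mean(m[!is.na(m)]))
  expect_error(mean_dtdt(res, "Q", "U"), "no cell")
})

test_that("fast-track closing rule reroutes queued patients to shared units", {
  # MIU open 2 h/day with massive diversion: many greens queue at the MIU
  # and must be served eventually in MU/SU as greens, never stranded
  scn <- build_case_study_scenario()
  s <- miu_setting(x = rep(9L, 7), y = rep(12L, 7), z = c(75, 35),
                   r = rep(1L, 7))
  res <- simulate_ed(scn, s, fast_params(seed = 13, reps = 3, horizon = 5,
                                         warmup = 1))
  expect_identical(res$arrivals_eligible,
                   as.integer(rowSums(res$rep_counts) + res$censored))
  # greens were still served in the shared units
  expect_gt(sum(res$rep_counts[, "G.MU"]), 0)
  expect_gt(sum(res$rep_counts[, "G.SU"]), 0)
})

test_that("event log exports the audit columns", {
  mm <- mmc_scenario(2, 10, 2)
  res <- simulate_ed(mm, miu_setting(x = 8, y = 9, z = 1),
                     fast_params(seed = 21, reps = 2, horizon = 2,
                                 warmup = 0), keep_log = TRUE)
  f <- tempfile(fileext = ".csv")
  write_patient_log(res, f)
  log <- read.csv(f)
  expect_identical(names(log),
                   c("id", "tag", "unit", "t1", "t3", "dtdt", "replication"))
  expect_true(all(log$dtdt >= 0, na.rm = TRUE))
})
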