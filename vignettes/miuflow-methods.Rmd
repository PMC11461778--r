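---
title: "Methods: simulation-based optimization of ED fast-track resources"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation-based optimization of ED fast-track resources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the model behind **miuflow**, its assumptions, the
tunable parameters, the design decisions taken where the design was
genuinely open, and what the shipped synthetic scenario does and does not
demonstrate.

## The decision problem

An Emergency Department (ED) runs a fast track that diverts low-acuity
patients into a Minor Injuries Unit (MIU). The weekly plan fixes, per day
`d`: the MIU opening hour `x_d`, closing hour `y_d` (integers on the 24-h
clock; `y_d = x_d` closes the day), the open-room count `r_d`, and the
diversion percentages `z_1` (morning) and `z_2` (afternoon) — the share of
eligible patients the triage nurse sends to the MIU while it is open.

Objectives, both to be minimized:

* `f1 = Σ_t α_t Σ_{u ∈ U(t)} β_u E[DTDT^{tu}]`, the weighted overall
  expected door-to-doctor time (minutes): for every severity tag `t` and
  every unit `u` eligible for that tag, the expected DTDT of `t`-tagged
  patients served in `u`, estimated by discrete-event simulation;
* `f2 = Σ_d γ_d (y_d − x_d)`, weighted weekly MIU operating hours;
* optionally `f3 = Σ_d δ_d r_d`, weighted open room-days. In the shipped
  case study the MIU room count is fixed at 2, so `r` is dropped from the
  decision vector and `f3` is inactive.

Constraints: integer box bounds on `x`, `y`, `r`; real bounds on `z`
(percentages); per-day minimum open hours `y_d − x_d ≥ h_d`; weekly
minimum `Σ_d (y_d − x_d) ≥ g`. The case-study constraint set is
`l = 7, u = 20` for all hour variables, `u_z = (75, 35)`, `h_d = 0`
(days may close) and `g = 21`.

The expectation in `f1` is replaced by a sample average over `N`
independent simulation replications (sample average approximation). Each
replication uses its own seed-derived RNG stream with sub-streams per
stochastic element — arrivals, tag assignment, diversion decisions, unit
choice, triage times, visit times, rerouting — so that two settings
simulated with the same base seed share their randomness patient by
patient (common random numbers), which makes paired comparisons and the
monotonicity checks in the test suite meaningful.

## The patient-flow model

Patients arrive according to a nonhomogeneous Poisson process with a
piecewise-constant rate on a repeating weekly grid of one-hour
(day-of-week × hour) cells; within a cell, counts are Poisson and times
uniform, which is exact for a piecewise-constant intensity. Arrivals
queue FIFO for a fixed number of triage servers. `t1` is the triage
start; the model identifies arrival and triage start (`t0 = t1`), so DTDT
is computed as `t3 − t1` with `t3` the visit start. Length of stay is not
modeled.

Routing happens at triage end: white-tagged patients go to the MIU when
it is open and are retagged green otherwise; green-tagged patients are
diverted to the MIU with probability `z_slot/100` when it is open
(morning slot before `slot_boundary_hour`, default 13:00, afternoon slot
after) and otherwise join the shared units according to the per-tag unit
mix; yellow patients use the shared Medical/Surgical Units and red
patients their dedicated red-area rooms. Each unit is a non-preemptive
priority queue (more severe first, FIFO within tag) over a
piecewise-constant room schedule; a room is seized at `t3` and held for
the visit duration only — exams, observation and reassessment happen
after `t3`, cannot affect DTDT, and are therefore not modeled as
room-holding stages. Capacity step-downs (day to night) are
non-preemptive: rooms beyond the new level finish their patient and then
retire.

Closing rules, which the underlying sources leave unspecified, are
resolved as follows: at the closing hour the MIU stops new service
starts; patients already in a room finish; patients still queued are
retagged green and re-enter the shared units at the closing time, taking
their place at the tail of their priority class. Patients still waiting
anywhere at the simulation horizon are censored: excluded from the means
and reported in a separate count, so that per replication
`eligible arrivals = counted + censored` holds exactly. Statistics only
cover patients arriving after the warm-up period.

The default experimental design is a 38-day horizon, 7-day warm-up and
`N = 30` replications.

## The synthetic case-study scenario

No real ED data ships with the package. `build_case_study_scenario()`
constructs a synthetic world emulating the central area of a large urban
ED:

* tags `R > Y > G > W` with the triage mix derived from a one-month
  census of 3,428 patients (R 236, Y 2009, G 1136, W 47 after excluding
  the resuscitation area, which serves only the most critical reds and
  involves no waiting); per-tag unit mixes renormalize the census rows;
* units MU (3 rooms 08:00–20:00, 2 at night), SU (2/1), dedicated
  MU_Red (1) and SU_Red (2) around the clock, and the MIU (2 rooms,
  schedule driven by the decision variables);
* an arrival profile normalized to 4,200 arrivals per 31 days
  (≈ 948/week) with a late-morning peak, the same on every day of the
  week;
* exponential triage times (mean 5 min, 2 nurses) and lognormal visit
  times (log-scale sd 0.5) with means 35–38 min for the acute tags and
  18–28 min for the low-acuity ones. These were calibrated so the shared
  day-time rooms run at roughly 0.8 utilization with stable nights:
  enough congestion that MIU capacity genuinely matters (greens sharing
  the SU wait ≈ 2 h under the status-quo schedule), but no runaway
  queues. Without congestion the two objectives would not conflict and
  the Pareto front would be degenerate.

What the fixture deliberately does **not** emulate: day-of-week arrival
structure (every day repeats the same profile), empirically calibrated
service-time families, patient boarding/LWBS behavior, and any coupling
between units other than routing. Passing tests therefore demonstrate
the correctness and internal consistency of the machinery on a plausible
congested ED, not predictive validity for any real department. Absolute
`f1` values depend entirely on these synthetic choices.

The day-symmetry is a known, exact invariance of this fixture: rotating
the days of a schedule cyclically leaves the true response unchanged (up
to horizon-alignment effects that vanish with the warm-up). The
metamodeling pipeline exploits it twice, as described below. Both hooks
are opt-in and must not be used for scenarios with genuine day-of-week
structure.

## Metamodeling

`generate_dataset()` draws `p` feasible settings — uniform on the integer
box via per-day proposals, with whole-vector rejection until the weekly
minimum holds, which makes the accepted draw uniform on the feasible set
— and simulates each once with its own index-derived seed (so chunked or
parallel generation yields bit-identical datasets). The full-scale budget
of the case-study protocol is `p = 10,000` runs of 30 replications; the
package's scaled-down experiments use `p = 200` with the same per-run
protocol, which keeps the target noise around 5 minutes at the cost of
sparser coverage of the 16-dimensional design space.

`train_mlp()` fits a fully-connected ReLU multilayer perceptron by
mini-batch Adam on the mean squared error of standardized features and
target, with early stopping on held-out validation MAE (10% split,
seed-derived) and restoration of the best weights. Standardization is
applied because the raw inputs mix hour (7–20) and percentage (0–75)
scales. Training is deterministic given its seed. The full-scale
configuration — two hidden layers of 90 units, learning rate 1e-5, batch
4, patience 8, up to 574 epochs — is representable; the scaled-down
default used in the acceptance experiments is `hidden = c(32, 32)`,
batch 8, learning rate 1e-3, patience 30, up to 200 epochs, chosen for
the `p = 200` regime. `kfold_random_search()` implements the K-fold
(default `K = 5`) cross-validated random search protocol for
hyperparameter selection when a search space is preferred over fixed
values.

Two variance-reduction hooks for day-symmetric scenarios:

* `augment_days` in `mlp_hyperparams()` augments the *training split*
  with all cyclic day rotations of each design row (same target),
  teaching the network the invariance — an effective 7-fold enlargement
  of the training set. The validation split is never augmented, so early
  stopping stays honest.
* `symmetrize_surrogate()` wraps a trained model so that predictions and
  gradients are averaged over the 7 rotations of the input.

At `p = 200` these two hooks are what makes the downstream front
generation reliable: without them, occasional fitting artifacts in
sparsely sampled corners (few training points combine minimal weekly
hours with maximal diversion) can invert the learned hour response and
collapse the Pareto front to one or two points.

`predict_f1()` evaluates the surrogate; `grad_f1()` backpropagates
through the full standardize → network → de-standardize map, including
the scaler chain-rule terms. At a ReLU kink the right derivative is used;
the gradient is exact everywhere else, which the tests verify against
central finite differences away from kinks.

## Pareto front generation

The weighting method solves, for each weight pair on the default grid
`η_1 = 1.00, 0.99, …, 0.00` (101 pairs, all from the status-quo start),

    min  η1 · f1_surrogate(v) + η2 · f2(v)   s.t.  v feasible.

`solve_scalarized()` treats the integers as continuous, minimizes with a
logarithmic-barrier method (`stats::constrOptim`, BFGS inner iterations,
analytic gradients; barrier tolerance 1e-6) over the box and the two
linear minimum-hours constraints, then rounds the integer variables to
the nearest integers. If rounding breaks a minimum-hours constraint, the
open window `(x_d, y_d)` is widened on the days with the largest positive
fractional residual until feasible — a deterministic repair rule of this
package's own design. A greedy best-improvement integer polish follows
(±1/±2-hour moves per variable, paired moves sliding one day's window,
and coarse diversion steps), accepting only strict improvements. The
polish matters: the surrogate is piecewise linear, and the smooth
relaxation routinely stops one or two lattice steps away from the
scalarized optimum; without the polish, solves that stall above their
optimum produce candidates that a spuriously deep solve elsewhere then
dominates, shrinking the front. The returned point is always feasible and
never worse (in scalarized value) than the start; candidates with
identical settings are collapsed, and `pareto_filter()` applies an exact
non-domination filter (sort-and-sweep in the bi-objective case), so the
reported front is sorted by `f2` descending with strictly increasing
`f1`.

`refine_with_des()` optionally re-simulates every front member and
replaces its surrogate `f1` by the sample-average value, then re-filters
— dominance can change under refinement, and this package re-checks it.

`dfo_minimize()` provides the derivative-free baseline: coordinate
primitive directions with expanding/contracting steps (integer steps for
hours, continuous for percentages), a non-monotone acceptance rule
(improvement over the worst of the last 5 accepted values), never
evaluating infeasible points, and exact budget accounting. It is a
simplified pattern-search in the spirit of linesearch-based
derivative-free methods for mixed-integer problems, not a port of any
specific implementation; comparisons against the metamodel route are
qualitative (front coverage under the equal-budget split
`10,000 / 11 = 909` evaluations per weight pair).

## Numerical choices and degenerate inputs

* Coincident simulation events are ordered completions → capacity
  changes → arrivals, so a patient arriving exactly at an opening
  breakpoint is seated and one arriving exactly at closing is not.
* Zero-duration services and empty arrival streams are legal; a cell
  with no observations raises an explicit "insufficient observations"
  error when `f1` needs it.
* Degenerate box coordinates (`l = u`) are excluded from the continuous
  solve and fixed at their value.
* Seeds are mixed with a 32-bit multiplicative scheme (`mix_seed`), so
  every replication, design point and pipeline stage has an independent
  reproducible stream derived from one master seed.
* The rejection sampler aborts with an informative error after 10,000
  consecutive rejections.

## Scaled-down experimental protocol

The packaged experiments (test suite and acceptance script) run the
method end to end at reduced scale: `p = 200` design points with the
full per-run simulation protocol (38 days, 7-day warm-up, 30
replications), surrogate `hidden = c(32, 32)` with day-rotation
augmentation, and the full 101-pair weight sweep on the symmetrized
surrogate. Across independent dataset and training seeds this yields
fronts of roughly 7–29 distinct non-dominated schedules spanning weekly
hours from the feasible maximum region down to the minimum `g = 21`.
The single-unit M/M/2 reduction validates the queueing core against the
Erlang-C closed form to within Monte-Carlo error.

## Known limitations

* At `p = 200` the surrogate's absolute accuracy at the front's extremes
  is limited by design-space coverage; refined (re-simulated) `f1`
  values are more trustworthy than surrogate values there.
* The weighting method cannot reach non-convex parts of the true front.
* The DFO baseline at simulation cost is only practical at reduced
  budgets in the packaged experiments.
* All conclusions about "the ED" are conclusions about the synthetic
  fixture; applying the tool to a real department requires replacing the
  scenario with calibrated arrival profiles, mixes and service times.
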