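# miuflow

Simulation-based multiobjective optimization of Emergency Department (ED)
fast-track resources.

## The problem

Many EDs route low-acuity patients (triage tags *green* and *white*) through
a **fast track** into a dedicated **Minor Injuries Unit (MIU)**, keeping them
out of the queues of the shared Medical and Surgical Units. ED managers must
decide, for each day *d* of a weekly plan:

* the MIU opening and closing hours `x_d`, `y_d` (integers, a closed day is
  `y_d = x_d`),
* the number of open MIU rooms `r_d`,
* the percentages `z_1`, `z_2` of eligible patients the triage nurse diverts
  to the MIU in the morning and afternoon.

Two objectives conflict:

* `f1(x, y, r, z) = Σ_t α_t Σ_{u∈U(t)} β_u E[DTDT^{tu}]` — the overall
  expected **door-to-doctor time** (DTDT, minutes), summed over severity
  tags *t* and the units *u* eligible for each tag, estimated by a
  discrete-event simulation (DES) of the patient flow and the sample-average
  over *N* independent replications;
* `f2(x, y) = Σ_d γ_d (y_d − x_d)` — the weekly **MIU operating hours**
  (a cost proxy); optionally `f3(r) = Σ_d δ_d r_d` counts open rooms.

subject to box bounds, a daily minimum `y_d − x_d ≥ h_d` and a weekly
minimum `Σ_d (y_d − x_d) ≥ g`.

Because each evaluation of `f1` costs a full simulation run, the package
implements a **metamodeling approach**: simulate *p* randomly sampled
feasible settings, train a multilayer-perceptron (MLP) surrogate of `f1`
that exposes values *and* input gradients via backpropagation, and apply
the **weighting method** — minimizing `η_1 f1 + η_2 f2` over a grid of
weights with a gradient-based solver — to trace a Pareto front of
waiting-time/operating-hours trade-offs. A derivative-free pattern-search
baseline (`dfo_minimize`) evaluates the simulation directly under an equal
budget for comparison.

## Worked example

```r
library(miuflow)

scn <- build_case_study_scenario()
cs  <- case_study_constraints()

## status quo: open 08-20 Mon-Sat, closed Sunday, 45%/5% diversion
s0 <- as_is_setting()
f2_hours(s0)
#> [1] 72
res <- simulate_ed(scn, s0, sim_params(base_seed = 5))
summary(res)
#>   tag   unit mean_dtdt_min patients
#> 1   R MU_Red     11.486788     6976
#> 2   R SU_Red      5.036863     1753
#> 3   Y     MU     17.057664    48560
#> 4   Y     SU     23.701898    25301
#> 5   G     MU     43.484756    10295
#> 6   G     SU    114.035929    26158
#> 7   G    MIU      5.971917     5793
#> 8   W    MIU      5.837484     1083
f1_from_result(res)
#> [1] 226.6133
```

Greens sharing the congested Surgical Unit wait ~114 min on average while
fast-tracked patients are seen within minutes — the lever the optimizer
exploits. The full pipeline (reduced scale):

```r
ds <- generate_dataset(scn, cs, p = 200, sim_params(), seed = 11)
m  <- train_mlp(ds, mlp_hyperparams(hidden = c(32, 32), batch_size = 8,
                                    learning_rate = 1e-3, patience = 30,
                                    max_epochs = 200, augment_days = 7),
                seed = 12)
cands <- weighting_sweep(symmetrize_surrogate(m, 7), cs,
                         default_weight_grid(101))
front <- pareto_filter(cands)
front          # settings with f2 from ~60 down to 21 h and rising f1
plot(front)
refined <- refine_with_des(scn, front, sim_params())   # optional DES pass
```

Each front row is a feasible weekly MIU schedule; reading down the table,
operating hours `f2` decrease while the surrogate waiting time `f1`
increases — the trade-off curve the ED manager chooses from. File-driven
runs (JSON configs, manifests) are available through `run_pipeline()` and
`inst/scripts/miu_pipeline.R`.

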