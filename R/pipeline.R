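#' Read a pipeline run configuration
#'
#' A run configuration is a JSON document naming the scenario and
#' constraint config files and the knobs of each pipeline stage.  Relative
#' paths are resolved against the config file's directory.  Recognized
#' fields (all optional unless noted): `scenario` (path, required),
#' `constraints` (path, required), `out_dir` (required), `seed`, `p`
#' (dataset size), `sim` (list: `horizon_days`, `warmup_days`,
#' `replications`), `weights` (list: `alpha`, `beta`, `gamma`, `delta`),
#' `hyperparams` (list of [mlp_hyperparams()] arguments), `search` (list:
#' `space`, `K`, `n_candidates`; omitted = no hyperparameter search),
#' `weight_grid_points`, `refine` (logical: simulate the final front),
#' `dfo_budget_total`, `dfo_weight_pairs`.
#'
#' @param path JSON config path.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  for (f in c("scenario", "constraints", "out_dir")) {
    if (is.null(cfg[[f]])) stopf("run config is missing field '%s'", f)
  }
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p
                         else file.path(base, p)
  cfg$scenario <- resolve(cfg$scenario)
  cfg$constraints <- resolve(cfg$constraints)
  cfg$out_dir <- resolve(cfg$out_dir)
  for (f in c("scenario", "constraints")) {
    if (!file.exists(cfg[[f]])) stopf("config file '%s' does not exist",
                                      cfg[[f]])
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  structure(cfg, class = "run_config")
}

cfg_sim_params <- function(cfg, seed_offset = 0L) {
  s <- cfg$sim %||% list()
  sim_params(horizon_days = s$horizon_days %||% 38,
             warmup_days = s$warmup_days %||% 7,
             replications = s$replications %||% 30,
             base_seed = mix_seed(cfg$seed, seed_offset))
}

cfg_weights <- function(cfg) {
  w <- cfg$weights %||% list()
  objective_weights(alpha = if (!is.null(w$alpha)) unlist(w$alpha),
                    beta = if (!is.null(w$beta)) unlist(w$beta),
                    gamma = unlist(w$gamma %||% 1),
                    delta = unlist(w$delta %||% 1))
}

stage_manifest <- function(cfg, stage, inputs, outputs) {
  list(stage = stage,
       seed = cfg$seed,
       package_version = as.character(utils::packageVersion("miuflow")),
       inputs = lapply(inputs, function(p)
         list(path = basename(p), md5 = unname(tools::md5sum(p)))),
       outputs = lapply(outputs, basename))
}

#' Run one pipeline stage
#'
#' Executes one of the five stages of the end-to-end workflow and writes
#' its artifacts plus a manifest (`manifest-<stage>.json` with input
#' hashes, seed and package version) into the configured output directory,
#' so any stage can be re-run exactly from its manifest:
#'
#' * `"simulate"`: simulate the status-quo setting; writes
#'   `asis_result.json`.
#' * `"dataset"`: generate the metamodel dataset; writes `dataset.csv` (+
#'   provenance sidecar).
#' * `"train"`: optional K-fold random hyperparameter search, then train
#'   the surrogate on the dataset; writes `metamodel.json` and
#'   `training_report.csv`.
#' * `"optimize"`: weighting-method sweep on the surrogate, dominance
#'   filter, optional simulator refinement; writes `pareto_front.csv` (+
#'   JSON).
#' * `"compare-dfo"`: derivative-free baseline on the simulation-based
#'   objective under an equally split evaluation budget; writes
#'   `dfo_front.csv` (+ JSON).
#'
#' @param cfg a [read_run_config()] list (or an equivalent list).
#' @param stage one of `"simulate"`, `"dataset"`, `"train"`, `"optimize"`,
#'   `"compare-dfo"`.
#' @param verbose print progress messages?
#' @return named character vector of artifact paths, invisibly.
#' @export
run_pipeline <- function(cfg, stage = c("simulate", "dataset", "train",
                                        "optimize", "compare-dfo"),
                         verbose = FALSE) {
  stage <- match.arg(stage)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  scn <- read_scenario(cfg$scenario)
  cs <- read_constraints(cfg$constraints)
  weights <- cfg_weights(cfg)
  say <- function(...) if (verbose) message(sprintf(...))
  out <- function(name) file.path(cfg$out_dir, name)
  need <- function(path, producer) {
    if (!file.exists(path))
      stopf("missing upstream artifact '%s': run stage '%s' first",
            path, producer)
    path
  }

  artifacts <- switch(stage,
    "simulate" = {
      say("simulating status-quo setting")
      res <- simulate_ed(scn, as_is_setting(), cfg_sim_params(cfg, 1L),
                         constraints = cs)
      write_result_summary(res, out("asis_result.json"))
      c(result = out("asis_result.json"))
    },
    "dataset" = {
      p <- as.integer(cfg$p %||% 200L)
      say("generating dataset of %d design points", p)
      ds <- generate_dataset(scn, cs, p, cfg_sim_params(cfg, 2L),
                             seed = mix_seed(cfg$seed, 20L),
                             weights = weights)
      write_dataset(ds, out("dataset.csv"))
      c(dataset = out("dataset.csv"))
    },
    "train" = {
      dsp <- need(out("dataset.csv"), "dataset")
      ds <- read_dataset(dsp)
      hp_args <- cfg$hyperparams %||% list()
      if (!is.null(hp_args$hidden)) hp_args$hidden <- unlist(hp_args$hidden)
      hp <- do.call(mlp_hyperparams, hp_args)
      if (!is.null(cfg$search)) {
        say("hyperparameter search (%d candidates, K = %d)",
            cfg$search$n_candidates %||% 10L, cfg$search$K %||% 5L)
        space <- cfg$search$space
        sr <- kfold_random_search(ds, space, K = cfg$search$K %||% 5L,
                                  n_candidates = cfg$search$n_candidates %||% 10L,
                                  seed = mix_seed(cfg$seed, 30L))
        hp <- sr$best
      }
      say("training surrogate")
      m <- train_mlp(ds, hp, seed = mix_seed(cfg$seed, 31L))
      save_metamodel(m, out("metamodel.json"))
      write.csv(m$report, out("training_report.csv"), row.names = FALSE)
      c(metamodel = out("metamodel.json"),
        report = out("training_report.csv"))
    },
    "optimize" = {
      mp <- need(out("metamodel.json"), "train")
      m <- load_metamodel(mp)
      if (isTRUE(cfg$symmetrize_days)) m <- symmetrize_surrogate(m, cs$n)
      grid <- default_weight_grid(as.integer(cfg$weight_grid_points %||% 101L))
      say("weighting sweep over %d pairs", nrow(grid))
      cands <- weighting_sweep(m, cs, grid, start = as_is_setting(),
                               weights = weights)
      front <- pareto_filter(cands, provenance = list(
        weight_grid_points = nrow(grid), seed = cfg$seed,
        refined = FALSE))
      if (isTRUE(cfg$refine)) {
        say("refining %d front point(s) with the simulator",
            length(front$points))
        front <- refine_with_des(scn, front, cfg_sim_params(cfg, 3L),
                                 weights)
      }
      write_front(front, out("pareto_front.csv"))
      c(front = out("pareto_front.csv"))
    },
    "compare-dfo" = {
      total <- as.integer(cfg$dfo_budget_total %||% 10000L)
      npairs <- as.integer(cfg$dfo_weight_pairs %||% 11L)
      budget <- per_run_budget(total, npairs)
      grid <- default_weight_grid(npairs)
      sp <- cfg_sim_params(cfg, 4L)
      say("derivative-free baseline: %d pairs x %d evaluations",
          npairs, budget)
      gamma <- rep_len(weights$gamma %||% 1, cs$n)
      cands <- vector("list", npairs)
      for (i in seq_len(npairs)) {
        eta <- as.numeric(grid[i, ])
        objective <- function(v) {
          s <- decode_setting(v, cs)
          res <- simulate_ed(scn, s, sp)
          eta[1] * f1_from_result(res, weights$alpha, weights$beta) +
            eta[2] * f2_hours(s, gamma)
        }
        r <- dfo_minimize(objective, cs, as_is_setting(), budget)
        res <- simulate_ed(scn, r$setting, sp)
        cands[[i]] <- list(setting = r$setting,
                           f1 = f1_from_result(res, weights$alpha,
                                               weights$beta),
                           f2 = f2_hours(r$setting, gamma), eta = eta,
                           f1_source = "simulated")
      }
      front <- pareto_filter(cands, provenance = list(
        method = "dfo", budget_total = total, budget_per_run = budget,
        seed = cfg$seed))
      write_front(front, out("dfo_front.csv"))
      c(front = out("dfo_front.csv"))
    })

  manifest <- stage_manifest(cfg, stage,
                             inputs = c(cfg$scenario, cfg$constraints),
                             outputs = artifacts)
  write_json_file(manifest, out(paste0("manifest-", stage, ".json")))
  invisible(c(artifacts,
              manifest = out(paste0("manifest-", stage, ".json"))))
}
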