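#' Sample a feasible fast-track setting uniformly
#'
#' Draws `x_d` uniformly on its integer box, `y_d` uniformly on
#' `{max(x_d + h_d, l_y)..u_y}` (so the daily minimum holds by
#' construction), `r_d` uniformly on its box, and `z` uniformly on its box,
#' then rejects and redraws the whole vector until the weekly minimum-hours
#' constraint holds.  The proposal is uniform over its box; rejection makes
#' the accepted draw uniform over the feasible set of the proposal support.
#'
#' @param cs a [constraint_set()].
#' @param seed optional integer seed; if `NULL` the current RNG state is
#'   used.
#' @param max_tries rejection budget before an infeasibility error.
#' @return a feasible [miu_setting()]; the number of proposals drawn is
#'   attached as attribute `"attempts"`.
#' @export
sample_feasible_setting <- function(cs, seed = NULL, max_tries = 10000L) {
  if (!is.null(seed)) set.seed(seed)
  n <- cs$n
  for (attempt in seq_len(max_tries)) {
    x <- cs$l_x + floor(runif(n) * (cs$u_x - cs$l_x + 1L))
    x <- pmin(x, cs$u_x)
    ly <- pmax(x + cs$h, cs$l_y)
    if (any(ly > cs$u_y)) next   # daily minimum unattainable from this x
    y <- ly + floor(runif(n) * (cs$u_y - ly + 1L))
    y <- pmin(y, cs$u_y)
    r <- cs$l_r + floor(runif(n) * (cs$u_r - cs$l_r + 1L))
    r <- pmin(r, cs$u_r)
    z <- runif(length(cs$l_z), cs$l_z, cs$u_z)
    if (sum(y - x) >= cs$g) {
      s <- miu_setting(x = x, y = y, z = z, r = r)
      attr(s, "attempts") <- attempt
      return(s)
    }
  }
  stopf("could not draw a feasible setting in %d proposals", max_tries)
}

#' Generate a supervised dataset of simulated waiting times
#'
#' Builds the training set for the waiting-time metamodel: `p` independent
#' feasible settings sampled by [sample_feasible_setting()], each simulated
#' once (one run of `sim_params$replications` replications), with target
#' `w_j` the overall expected DTDT from [f1_from_result()].  Every design
#' point derives its own seed from `seed` and its index, so the dataset is
#' independent of any chunking of the generation (rows `j` can be produced
#' in parallel chunks and concatenated).
#'
#' @param scn a validated [ed_scenario()].
#' @param cs a [constraint_set()].
#' @param p number of design points.
#' @param params a [sim_params()]; its `base_seed` is ignored in favour of
#'   per-point derived seeds.
#' @param seed integer master seed.
#' @param weights an [objective_weights()] supplying `alpha`/`beta`, or
#'   `NULL` for unit weights.
#' @param j_range optional integer vector of design-point indices to
#'   generate (a chunk); defaults to `1:p`.
#' @return an object of class `miu_dataset` with fields `V` (p x m encoded
#'   design matrix), `w` (targets, minutes), `j` (design indices) and
#'   `provenance`.
#' @export
generate_dataset <- function(scn, cs, p, params = sim_params(), seed = 1L,
                             weights = NULL, j_range = NULL) {
  if (!is_count(p)) stopf("p must be a nonnegative integer")
  assert_valid_scenario(scn)
  j_range <- j_range %||% seq_len(p)
  if (length(j_range) && (any(j_range < 1) || any(j_range > p)))
    stopf("j_range must lie in 1..p")
  m <- length(encoded_names(cs))
  V <- matrix(numeric(), 0, m, dimnames = list(NULL, encoded_names(cs)))
  w <- numeric(0)
  alpha <- weights$alpha
  beta <- weights$beta
  rows <- vector("list", length(j_range))
  for (idx in seq_along(j_range)) {
    j <- j_range[idx]
    sj <- mix_seed(seed, j)
    s <- sample_feasible_setting(cs, seed = mix_seed(sj, 1))
    pj <- params
    pj$base_seed <- mix_seed(sj, 2)
    res <- tryCatch(simulate_ed(scn, s, pj),
                    error = function(e)
                      stopf("simulation failed at design point %d: %s", j,
                            conditionMessage(e)))
    wj <- tryCatch(f1_from_result(res, alpha, beta),
                   error = function(e)
                     stopf("objective failed at design point %d: %s", j,
                           conditionMessage(e)))
    rows[[idx]] <- list(v = encode_setting(s, include_r = any(cs$l_r != cs$u_r)),
                        w = wj)
  }
  if (length(rows)) {
    V <- do.call(rbind, lapply(rows, `[[`, "v"))
    colnames(V) <- encoded_names(cs)
    w <- vapply(rows, `[[`, numeric(1), "w")
  }
  structure(list(
    V = V, w = w, j = as.integer(j_range),
    provenance = list(scenario_hash = hash_object(scenario_to_list(scn)),
                      constraints = unclass(cs),
                      sim_params = unclass(params)[c("horizon_days",
                                                    "warmup_days",
                                                    "replications")],
                      seed = as.integer(seed), p = as.integer(p))
  ), class = "miu_dataset")
}

#' Concatenate dataset chunks
#'
#' Binds chunks produced by [generate_dataset()] with disjoint `j_range`s
#' into one dataset, ordered by design index.  Chunks must share provenance
#' (scenario, constraints, simulation parameters and master seed).
#'
#' @param ... `miu_dataset` chunks.
#' @return a `miu_dataset`.
#' @export
bind_datasets <- function(...) {
  parts <- list(...)
  if (!length(parts)) stopf("no datasets supplied")
  ref <- parts[[1]]$provenance
  for (pt in parts[-1]) {
    if (!identical(pt$provenance, ref))
      stopf("dataset chunks have differing provenance")
  }
  j <- unlist(lapply(parts, `[[`, "j"))
  if (anyDuplicated(j)) stopf("dataset chunks overlap in design indices")
  o <- order(j)
  V <- do.call(rbind, lapply(parts, `[[`, "V"))[o, , drop = FALSE]
  structure(list(V = V, w = unlist(lapply(parts, `[[`, "w"))[o],
                 j = j[o], provenance = ref), class = "miu_dataset")
}

#' @export
print.miu_dataset <- function(x, ...) {
  cat(sprintf("metamodel dataset: %d design point(s), %d feature(s)\n",
              nrow(x$V), ncol(x$V)))
  if (length(x$w))
    cat(sprintf("  target DTDT range: %.1f .. %.1f min\n", min(x$w),
                max(x$w)))
  invisible(x)
}

#' Persist and load metamodel datasets
#'
#' The dataset is written as a CSV (encoded feature columns plus
#' `w_dtdt_min`) with a JSON provenance sidecar (`<path>.json`); the loader
#' validates the schema against the sidecar.
#'
#' @param ds a `miu_dataset`.
#' @param path CSV path.
#' @return the loader returns a `miu_dataset`; the writer returns `path`
#'   invisibly.
#' @export
write_dataset <- function(ds, path) {
  df <- as.data.frame(ds$V)
  df$w_dtdt_min <- ds$w
  df$design_index <- ds$j
  write.csv(df, path, row.names = FALSE)
  write_json_file(ds$provenance, paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  side <- paste0(path, ".json")
  if (!file.exists(side)) stopf("missing provenance sidecar '%s'", side)
  prov <- jsonlite::read_json(side, simplifyVector = TRUE)
  feats <- setdiff(names(df), c("w_dtdt_min", "design_index"))
  if (!"w_dtdt_min" %in% names(df))
    stopf("'%s' is not a dataset file (no w_dtdt_min column)", path)
  V <- as.matrix(df[feats])
  structure(list(V = V, w = df$w_dtdt_min,
                 j = as.integer(df$design_index %||% seq_len(nrow(df))),
                 provenance = prov), class = "miu_dataset")
}
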