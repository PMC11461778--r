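#' Service-time distribution specification
#'
#' Lightweight spec for the nonnegative duration distributions used by the
#' simulator (triage and visit/treatment times, in minutes).  Draws are made
#' by quantile transform of a single uniform (or standard normal) variate per
#' patient, which keeps common-random-number comparisons across settings
#' aligned patient by patient.
#'
#' Supported families:
#' * `"deterministic"`: `value` (minutes);
#' * `"exponential"`: `mean` (minutes);
#' * `"lognormal"`: `mean` (minutes) and `sdlog` (log-scale sd); the
#'   log-scale location is derived as `log(mean) - sdlog^2/2`;
#' * `"uniform"`: `min`, `max` (minutes).
#'
#' @param family distribution family name.
#' @param ... family parameters (see above).
#' @return an object of class `dist_spec`.
#' @examples
#' dist_spec("lognormal", mean = 45, sdlog = 0.5)
#' dist_spec("exponential", mean = 5)
#' @export
dist_spec <- function(family = c("deterministic", "exponential",
                                 "lognormal", "uniform"), ...) {
  family <- match.arg(family)
  pars <- lapply(list(...), function(v)
    if (is.numeric(v)) as.double(v) else v)
  spec <- structure(c(list(family = family), pars), class = "dist_spec")
  msg <- validate_dist(spec)
  if (length(msg)) stopf("invalid dist_spec: %s", paste(msg, collapse = "; "))
  spec
}

# returns character vector of problems (empty if valid)
validate_dist <- function(spec) {
  if (!is.list(spec) || is.null(spec$family))
    return("not a distribution spec")
  f <- spec$family
  num1 <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  switch(f,
    deterministic = if (!num1(spec$value) || spec$value < 0)
      "deterministic value must be a nonnegative number" else character(),
    exponential = if (!num1(spec$mean) || spec$mean < 0)
      "exponential mean must be a nonnegative number" else character(),
    lognormal = {
      out <- character()
      if (!num1(spec$mean) || spec$mean <= 0)
        out <- c(out, "lognormal mean must be positive")
      if (!num1(spec$sdlog) || spec$sdlog <= 0)
        out <- c(out, "lognormal sdlog must be positive")
      out
    },
    uniform = if (!num1(spec$min) || !num1(spec$max) || spec$min < 0 ||
                  spec$max < spec$min)
      "uniform requires 0 <= min <= max" else character(),
    sprintf("unknown distribution family '%s'", f)
  )
}

#' Expected value of a duration spec
#' @param spec a [dist_spec()].
#' @return expected duration in minutes.
#' @export
dist_mean <- function(spec) {
  switch(spec$family,
    deterministic = spec$value,
    exponential = spec$mean,
    lognormal = spec$mean,
    uniform = (spec$min + spec$max) / 2,
    stopf("unknown distribution family '%s'", spec$family))
}

# quantile transform: u in (0,1) -> duration in minutes
dist_quantile <- function(spec, u) {
  switch(spec$family,
    deterministic = rep(spec$value, length(u)),
    exponential = if (spec$mean == 0) rep(0, length(u))
                  else qexp(u, rate = 1 / spec$mean),
    lognormal = qlnorm(u, meanlog = log(spec$mean) - spec$sdlog^2 / 2,
                       sdlog = spec$sdlog),
    uniform = qunif(u, spec$min, spec$max),
    stopf("unknown distribution family '%s'", spec$family))
}
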