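#' Specification of a simulated right-censored group
#'
#' Describes one group's event-time distribution, its independent censoring
#' mechanism and the sample size.  Supported event-time families:
#' \describe{
#'   \item{exponential}{\code{params = list(rate)}, survival
#'     \eqn{S(t) = e^{-\lambda t}}.}
#'   \item{weibull}{\code{params = list(shape, scale)},
#'     \eqn{S(t) = \exp(-(t/scale)^{shape})}.}
#'   \item{piecewise-exponential}{\code{params = list(rates, breaks)} with
#'     \code{length(breaks) == length(rates) - 1}: hazard \code{rates[j]} on
#'     the j-th interval of \code{c(0, breaks, Inf)}.}
#' }
#' Censoring is \code{"none"} (all events observed), a single number (an
#' administrative cutoff: everyone still at risk at that time is censored
#' there), or \code{list(family, params)} drawn from the same families,
#' independent of the event time.
#'
#' @param family event-time family name.
#' @param params family parameters, see Details.
#' @param censoring censoring mechanism (default \code{"none"}).
#' @param n sample size (\eqn{\ge 1}).
#' @param round_digits optionally round observed times to this many digits;
#'   continuous times have no ties, the knob creates ties on purpose to
#'   exercise tie conventions.
#' @return an object of class \code{simulation_spec}.
#' @export
simulation_spec <- function(family = c("exponential", "weibull",
                                       "piecewise-exponential"),
                            params, censoring = "none", n,
                            round_digits = NULL) {
  family <- match.arg(family)
  params <- validate_family_params(family, params)
  n <- as.integer(n)
  if (is.na(n) || n < 1L)
    stop("n must be a positive integer", call. = FALSE)
  censoring <- validate_censoring(censoring)
  structure(list(family = family, params = params, censoring = censoring,
                 n = n, round_digits = round_digits),
            class = "simulation_spec")
}

validate_family_params <- function(family, params) {
  params <- as.list(params)
  switch(family,
    "exponential" = {
      if (is.null(params$rate) && length(params) == 1L)
        names(params) <- "rate"
      if (!is.numeric(params$rate) || params$rate <= 0)
        stop("exponential family needs rate > 0", call. = FALSE)
      params[c("rate")]
    },
    "weibull" = {
      if (!is.numeric(params$shape) || params$shape <= 0 ||
          !is.numeric(params$scale) || params$scale <= 0)
        stop("weibull family needs shape > 0 and scale > 0", call. = FALSE)
      params[c("shape", "scale")]
    },
    "piecewise-exponential" = {
      rates <- params$rates
      breaks <- params$breaks %||% numeric(0)
      if (!is.numeric(rates) || any(rates <= 0))
        stop("piecewise-exponential needs positive rates", call. = FALSE)
      if (length(breaks) != length(rates) - 1L)
        stop("need length(breaks) == length(rates) - 1", call. = FALSE)
      if (is.unsorted(breaks, strictly = TRUE) || any(breaks <= 0))
        stop("breaks must be strictly increasing and positive", call. = FALSE)
      list(rates = rates, breaks = breaks)
    })
}

validate_censoring <- function(censoring) {
  if (identical(censoring, "none")) return("none")
  if (is.numeric(censoring) && length(censoring) == 1L) {
    if (censoring < 0) stop("administrative cutoff must be >= 0", call. = FALSE)
    return(list(family = "administrative", time = as.numeric(censoring)))
  }
  if (is.list(censoring) && !is.null(censoring$family)) {
    if (identical(censoring$family, "administrative")) {
      if (!is.numeric(censoring$time) || censoring$time < 0)
        stop("administrative cutoff must be >= 0", call. = FALSE)
      return(censoring)
    }
    censoring$params <- validate_family_params(censoring$family,
                                               censoring$params)
    return(censoring)
  }
  stop("censoring must be \"none\", a cutoff time, or list(family, params)",
       call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Draw event times from a family; piecewise-exponential by inverting the
# cumulative hazard at a unit-exponential draw.
draw_times <- function(family, params, n) {
  switch(family,
    "exponential" = rexp(n, rate = params$rate),
    "weibull" = rweibull(n, shape = params$shape, scale = params$scale),
    "piecewise-exponential" = {
      e <- rexp(n)  # target cumulative hazard
      cuts <- c(0, params$breaks)
      widths <- diff(c(cuts, Inf))
      Hcum <- c(0, cumsum(params$rates * widths)[-length(params$rates)])
      j <- findInterval(e, Hcum)
      cuts[j] + (e - Hcum[j]) / params$rates[j]
    })
}

#' Simulate a right-censored sample
#'
#' Observed time is the minimum of the event and censoring times; the event
#' indicator records whether the event came first.  All draws come from the
#' current R random stream (one shared stream per simulation run keeps
#' whole experiments reproducible from one \code{set.seed}); alternatively
#' pass \code{seed} to seed locally.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @param seed optional integer seed applied before drawing.
#' @return a \code{\link{censored_sample}}.
#' @examples
#' sp <- simulation_spec("exponential", list(rate = 1), censoring = "none",
#'                       n = 5)
#' simulate_censored_sample(sp, seed = 1)
#' @export
simulate_censored_sample <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!is.null(seed)) set.seed(seed)
  ev <- draw_times(spec$family, spec$params, spec$n)
  if (identical(spec$censoring, "none")) {
    time <- ev
    event <- rep(TRUE, spec$n)
  } else if (identical(spec$censoring$family, "administrative")) {
    cens <- rep(spec$censoring$time, spec$n)
    time <- pmin(ev, cens)
    event <- ev <= cens
  } else {
    cens <- draw_times(spec$censoring$family, spec$censoring$params, spec$n)
    time <- pmin(ev, cens)
    event <- ev <= cens
  }
  if (!is.null(spec$round_digits))
    time <- round(time, spec$round_digits)
  censored_sample(time, event)
}

#' Population quantile survival time
#'
#' The time \eqn{t} with \eqn{S(t) = p}, in closed form:
#' exponential \eqn{-\ln(p)/\lambda}; Weibull
#' \eqn{scale \cdot (-\ln p)^{1/shape}}; piecewise-exponential by inverting
#' the piecewise-linear cumulative hazard at \eqn{-\ln p}.
#'
#' @param family,params as in \code{\link{simulation_spec}}.
#' @param p probabilities strictly inside (0, 1).
#' @return numeric vector of times.
#' @examples
#' true_quantile("exponential", list(rate = 1), 0.5)  # log(2)
#' @export
true_quantile <- function(family, params, p) {
  family <- match.arg(family, c("exponential", "weibull",
                                "piecewise-exponential"))
  params <- validate_family_params(family, params)
  p <- as.numeric(p)
  if (anyNA(p) || any(p <= 0) || any(p >= 1))
    stop("p must lie strictly inside (0, 1)", call. = FALSE)
  h <- -log(p)  # target cumulative hazard
  switch(family,
    "exponential" = h / params$rate,
    "weibull" = params$scale * h^(1 / params$shape),
    "piecewise-exponential" = {
      cuts <- c(0, params$breaks)
      widths <- diff(c(cuts, Inf))
      Hcum <- c(0, cumsum(params$rates * widths)[-length(params$rates)])
      j <- findInterval(h, Hcum)
      cuts[j] + (h - Hcum[j]) / params$rates[j]
    })
}

#' Population quantile survival time difference
#'
#' \code{true_quantile(specA, p) - true_quantile(specB, p)}: the population
#' value that \code{\link{difference_curve}} estimates, used as the oracle
#' in consistency and coverage checks.
#'
#' @param specA,specB \code{simulation_spec} objects (their censoring parts
#'   are irrelevant here).
#' @param p probabilities strictly inside (0, 1).
#' @return numeric vector of time differences.
#' @export
true_difference <- function(specA, specB, p) {
  stopifnot(inherits(specA, "simulation_spec"),
            inherits(specB, "simulation_spec"))
  true_quantile(specA$family, specA$params, p) -
    true_quantile(specB$family, specB$params, p)
}
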