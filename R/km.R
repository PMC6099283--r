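#' Kaplan-Meier (product-limit) estimate of a survival curve
#'
#' Computes the product-limit estimator
#' \deqn{\hat S(t) = \prod_{t_i \le t} (1 - d_i / n_i)}
#' over the \eqn{K} distinct observed failure times \eqn{t_1 < \dots < t_K},
#' where \eqn{d_i} is the number of failures and \eqn{n_i} the size of the
#' risk set at \eqn{t_i}.  When an event and a censoring occur at the same
#' time, the censored observation is kept in the risk set for that event
#' (events precede censorings, the standard convention).
#'
#' The curve equals 1 on \eqn{[0, t_1)} and is treated as \emph{not defined}
#' for \eqn{t > t_K}: no level-extrapolation beyond the last observed
#' failure is performed.  A sample with no events at all yields a legal
#' \eqn{K = 0} curve that equals 1 at \eqn{t = 0} and is undefined for every
#' \eqn{t > 0}.
#'
#' @param sample a \code{\link{censored_sample}}.
#' @return an object of class \code{km_curve} with elements
#'   \code{time} (distinct failure times, increasing), \code{surv}
#'   (survival levels, strictly decreasing), \code{n_risk}, \code{n_event},
#'   \code{n} (sample size) and \code{censor_times}.
#' @seealso \code{\link{survival_at}}, \code{\link{quantile_at}},
#'   \code{\link{difference_curve}}
#' @examples
#' km_estimate(censored_sample(c(1, 2, 2, 3), c(FALSE, TRUE, TRUE, FALSE)))
#' @export
km_estimate <- function(sample) {
  sample <- as_censored_sample(sample)
  fit <- km_fit_int(sample$time, sample$event)
  structure(list(time = fit$time, surv = fit$surv,
                 n_risk = fit$n_risk, n_event = fit$n_event,
                 n = length(sample$time),
                 censor_times = sort(sample$time[!sample$event])),
            class = "km_curve")
}

# Lean internal fitter used in the bootstrap loop: risk set at a failure
# time t is #(time >= t), so same-time censorings stay at risk.
km_fit_int <- function(time, event) {
  n <- length(time)
  et <- time[event]
  if (length(et) == 0L)
    return(list(time = numeric(0), surv = numeric(0),
                n_risk = integer(0), n_event = integer(0)))
  st_all <- sort(time)
  st_ev <- sort(et)
  dt <- unique(st_ev)
  n_risk <- n - findInterval(dt, st_all, left.open = TRUE)
  n_event <- diff(c(0L, findInterval(dt, st_ev)))
  surv <- cumprod(1 - n_event / n_risk)
  list(time = dt, surv = surv, n_risk = n_risk, n_event = n_event)
}

#' @export
print.km_curve <- function(x, ...) {
  K <- length(x$time)
  cat(sprintf("Kaplan-Meier curve: n = %d, K = %d distinct failure times\n",
              x$n, K))
  if (K > 0L) {
    cat(sprintf("  domain [0, %g]; terminal level S(t_K) = %.6g\n",
                x$time[K], x$surv[K]))
    print(utils::head(data.frame(time = x$time, n_risk = x$n_risk,
                                 n_event = x$n_event, surv = x$surv), 10L))
    if (K > 10L) cat(sprintf("  ... %d more rows\n", K - 10L))
  } else {
    cat("  no events: S(0) = 1, undefined for t > 0\n")
  }
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Right-continuous step evaluation: 1 for \code{t} before the first failure
#' time, the current step level on \eqn{[t_1, t_K]}, and \code{NA} (the
#' undefined marker) for \code{t} beyond the last failure time.
#'
#' @param curve a \code{km_curve}.
#' @param t numeric vector of non-negative times.
#' @return numeric vector of survival probabilities; \code{NA} where the
#'   curve is undefined.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  t <- as.numeric(t)
  if (anyNA(t) || any(t < 0))
    stop("times must be non-negative and non-missing", call. = FALSE)
  K <- length(curve$time)
  out <- rep(1, length(t))
  if (K == 0L) {
    out[t > 0] <- NA_real_
    return(out)
  }
  idx <- findInterval(t, curve$time)
  pos <- idx > 0L
  out[pos] <- curve$surv[idx[pos]]
  out[t > curve$time[K]] <- NA_real_
  out
}

#' Quantile survival time of a Kaplan-Meier curve
#'
#' For \eqn{\hat S(t_K) \le p \le 1} the \eqn{p}th quantile survival time is
#' \deqn{\hat Q(p) = \min\{ t_j : \hat S(t_j) \le p \},}
#' the earliest observed failure time at which the curve has dropped to
#' \eqn{p} or below.  Note that \eqn{p} labels the survival axis, so this is
#' the conventional \eqn{(1-p)}th quantile of the event-time distribution.
#' Level comparisons use a small absolute tolerance (1e-12) so that a
#' \code{p} exactly equal to a stored level selects the earlier time, as the
#' minimum intends.
#'
#' @param curve a \code{km_curve} with at least one event (\eqn{K > 0}).
#' @param p numeric vector of probabilities in
#'   \eqn{[\hat S(t_K), 1]}; values outside this range are an error because
#'   the quantile is undefined there.
#' @return numeric vector of quantile survival times.
#' @examples
#' cv <- km_estimate(censored_sample(1:3, rep(TRUE, 3)))
#' quantile_at(cv, 0.5)  # 2
#' @export
quantile_at <- function(curve, p) {
  stopifnot(inherits(curve, "km_curve"))
  K <- length(curve$time)
  if (K == 0L)
    stop("quantile undefined: the curve has no observed failure times (K = 0)",
         call. = FALSE)
  p <- as.numeric(p)
  sK <- curve$surv[K]
  if (anyNA(p) || any(p < sK - .km_tol) || any(p > 1 + .km_tol))
    stop(sprintf("p must lie in [S(t_K), 1] = [%.6g, 1]", sK), call. = FALSE)
  quantile_int(curve$time, curve$surv, p)
}

# Vectorized Q(p) = min{ t_j : s_j <= p + tol } for strictly decreasing s.
quantile_int <- function(tt, ss, p) {
  K <- length(ss)
  m <- findInterval(p + .km_tol, rev(ss))  # how many levels are <= p
  tt[K - m + 1L]
}
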