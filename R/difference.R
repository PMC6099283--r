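#' Quantile survival time difference curve between two groups
#'
#' The estimator \eqn{\hat D(p) = \hat Q(p) - \hat Q'(p)} of the horizontal
#' gap between two Kaplan-Meier curves, defined for
#' \eqn{p^0 \le p \le 1} where
#' \eqn{p^0 = \max(\hat S(t_K), \hat S'(u_L))} is the smallest survival
#' probability at which both quantile estimates exist.  When \eqn{p^0 = 0}
#' (both curves reach zero) the value at \eqn{p = 0} is
#' \eqn{t_K - u_L}, the difference of the last failure times.
#'
#' \eqn{\hat D} is piecewise constant in \eqn{p}: its breakpoints are the
#' merged survival levels of the two curves, and the value on
#' \eqn{[\ell_i, \ell_{i-1})} (closed at the lower level, matching the
#' minimum in the quantile definition) is \eqn{\hat D(\ell_i)}.  The stored
#' step representation is eager, but \code{\link{evaluate_difference}}
#' recomputes from the source curves so breakpoint values are exact.
#'
#' @param curve1,curve2 \code{km_curve} objects with at least one event
#'   each; group 1 minus group 2.
#' @return an object of class \code{qdiff_curve} with elements
#'   \code{levels} (strictly decreasing breakpoints down to \code{p0}),
#'   \code{values} (\eqn{\hat D} on the interval starting at each
#'   breakpoint), \code{p0}, and the two source curves.
#' @examples
#' a <- km_estimate(censored_sample(c(2, 4), c(TRUE, TRUE)))
#' b <- km_estimate(censored_sample(c(1, 5), c(TRUE, TRUE)))
#' difference_curve(a, b)
#' @export
difference_curve <- function(curve1, curve2) {
  stopifnot(inherits(curve1, "km_curve"), inherits(curve2, "km_curve"))
  if (length(curve1$time) == 0L || length(curve2$time) == 0L)
    stop("both curves must have at least one observed failure time (K > 0)",
         call. = FALSE)
  stp <- diff_step_int(curve1$time, curve1$surv, curve2$time, curve2$surv)
  structure(list(levels = stp$levels, values = stp$values, p0 = stp$p0,
                 curve1 = curve1, curve2 = curve2),
            class = "qdiff_curve")
}

# Step representation of Q1(p) - Q2(p): breakpoints are the merged level
# sets restricted to [p0, 1); the terminal levels guarantee p0 is included.
diff_step_int <- function(t1, s1, t2, s2) {
  p0 <- max(s1[length(s1)], s2[length(s2)])
  lev <- sort(unique(c(s1, s2)), decreasing = TRUE)
  lev <- lev[lev >= p0 - .km_tol]
  vals <- quantile_int(t1, s1, lev) - quantile_int(t2, s2, lev)
  list(levels = lev, values = vals, p0 = p0)
}

# Evaluate a stored step representation; NA below p0 (undefined).
eval_step_int <- function(levels, values, p0, p) {
  K <- length(levels)
  m <- findInterval(p + .km_tol, rev(levels))
  i <- pmax(K - m + 1L, 1L)
  out <- ifelse(m >= 1L, values[i], NA_real_)
  out[p < p0 - .km_tol] <- NA_real_
  out
}

#' @export
print.qdiff_curve <- function(x, ...) {
  cat(sprintf("Quantile survival time difference curve on [%.6g, 1]\n", x$p0))
  cat(sprintf("  %d breakpoints; D(1) = %g", length(x$levels), x$values[1L]))
  if (x$p0 == 0)
    cat(sprintf("; D(0) = t_K - u_L = %g", x$values[length(x$values)]))
  cat("\n")
  invisible(x)
}

#' Evaluate a difference curve at given probabilities
#'
#' Recomputes \eqn{\hat Q(p) - \hat Q'(p)} from the stored source curves at
#' each \code{p} rather than looking up the cached step representation, so
#' values at breakpoints are exact.
#'
#' @param dcurve a \code{qdiff_curve}.
#' @param p numeric vector of probabilities in \eqn{[p^0, 1]}; values
#'   outside the domain are an error.
#' @return numeric vector of time differences.
#' @export
evaluate_difference <- function(dcurve, p) {
  stopifnot(inherits(dcurve, "qdiff_curve"))
  p <- as.numeric(p)
  if (anyNA(p) || any(p < dcurve$p0 - .km_tol) || any(p > 1 + .km_tol))
    stop(sprintf("p must lie in the curve domain [%.6g, 1]", dcurve$p0),
         call. = FALSE)
  quantile_at(dcurve$curve1, p) - quantile_at(dcurve$curve2, p)
}
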