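#' Efron's censored-data bootstrap resample
#'
#' Draws \code{n} pairs (time, event) independently with replacement from
#' the observed pairs of one group, preserving the sample size.  Uses the
#' current R random number stream; seed management is the caller's job
#' (see \code{\link{bootstrap_differences}}).
#'
#' @param sample a \code{\link{censored_sample}}.
#' @return a new \code{censored_sample} of the same size.
#' @export
resample_censored <- function(sample) {
  sample <- as_censored_sample(sample)
  idx <- sample.int(length(sample$time), replace = TRUE)
  censored_sample(sample$time[idx], sample$event[idx])
}

#' Bootstrap bundle of quantile difference curves
#'
#' Draws \code{B} bootstrap replicates: each replicate resamples the two
#' groups independently (within-group resampling with replacement, Efron's
#' classical bootstrap for censored data), fits both Kaplan-Meier curves,
#' and forms the replicated quantile difference curve
#' \eqn{\hat D^{*i}(p)} with its own lower domain bound \eqn{p^{*i}}
#' (defined in analogy to \eqn{p^0}).  Replicates in which either group has
#' no events carry an explicit no-events marker (\code{NA} in
#' \code{p_stars}, \code{NULL} curve): their difference curve is undefined
#' at every \eqn{p}.  Such replicates are excluded from the
#' \eqn{p^*}-based summaries but still contribute conservative sentinel
#' mass to the weighted band (see \code{\link{band_at}}).
#'
#' For the bundle figure a value of \code{B} between 40 and 200 is
#' reasonable; for a \eqn{100(1-\alpha)\%} confidence band the rule of
#' thumb is \eqn{B \ge 100/\alpha} (2000 for 95\%, 10000 for 99\%).
#'
#' @param sample1,sample2 \code{censored_sample} objects for the two groups.
#' @param B number of bootstrap replicates (\eqn{\ge 1}).
#' @param seed integer seed; \code{0} (the default) derives a fresh seed
#'   from the session's random stream and records it, so every run is
#'   reproducible from the metadata.
#' @return an object of class \code{qdiff_bootstrap}: \code{replicates}
#'   (list of per-replicate step representations or \code{NULL}),
#'   \code{p_stars}, \code{B}, \code{seed}, group sizes \code{n}/\code{m},
#'   the observed \code{qdiff_curve} in \code{observed}, and
#'   \code{n_no_events}.
#' @export
bootstrap_differences <- function(sample1, sample2, B, seed = 0L) {
  sample1 <- as_censored_sample(sample1)
  sample2 <- as_censored_sample(sample2)
  B <- as.integer(B)
  if (is.na(B) || B < 1L)
    stop("B must be a positive integer", call. = FALSE)
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0L)
    stop("seed must be a non-negative integer", call. = FALSE)
  if (seed == 0L)
    seed <- sample.int(.Machine$integer.max, 1L)
  set.seed(seed)

  k1 <- km_estimate(sample1)
  k2 <- km_estimate(sample2)
  observed <- difference_curve(k1, k2)

  t1 <- sample1$time; e1 <- sample1$event; n <- length(t1)
  t2 <- sample2$time; e2 <- sample2$event; m <- length(t2)
  replicates <- vector("list", B)
  p_stars <- rep(NA_real_, B)
  for (i in seq_len(B)) {
    i1 <- sample.int(n, replace = TRUE)
    i2 <- sample.int(m, replace = TRUE)
    f1 <- km_fit_int(t1[i1], e1[i1])
    f2 <- km_fit_int(t2[i2], e2[i2])
    if (length(f1$time) == 0L || length(f2$time) == 0L) next  # no-events marker
    stp <- diff_step_int(f1$time, f1$surv, f2$time, f2$surv)
    replicates[[i]] <- stp
    p_stars[i] <- stp$p0
  }
  structure(list(replicates = replicates, p_stars = p_stars, B = B,
                 seed = seed, n = n, m = m, observed = observed,
                 n_no_events = sum(is.na(p_stars))),
            class = "qdiff_bootstrap")
}

#' @export
print.qdiff_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap bundle: B = %d replicates (groups n = %d, m = %d), seed = %d\n",
              x$B, x$n, x$m, x$seed))
  ps <- x$p_stars[!is.na(x$p_stars)]
  if (length(ps))
    cat(sprintf("  p* range [%.4g, %.4g]; p*_max = %.4g\n",
                min(ps), max(ps), max(ps)))
  if (x$n_no_events > 0L)
    cat(sprintf("  %d replicate(s) with no events in a group (undefined everywhere)\n",
                x$n_no_events))
  invisible(x)
}

# First `k` replicates of a bundle, sharing the parent's RNG stream -- used
# when a bundle figure and a band from the same resampling pass are wanted.
bundle_head <- function(bundle, k) {
  stopifnot(inherits(bundle, "qdiff_bootstrap"), k >= 0L, k <= bundle$B)
  out <- bundle
  out$replicates <- bundle$replicates[seq_len(k)]
  out$p_stars <- bundle$p_stars[seq_len(k)]
  out$B <- as.integer(k)
  out$n_no_events <- sum(is.na(out$p_stars))
  out
}

#' Smallest probability at which every bootstrap replicate is defined
#'
#' \eqn{p^*_{\max} = \max(p^{*1}, \dots, p^{*B})}: below it at least one
#' replicated difference curve is undefined.  Replicates with the no-events
#' marker are excluded (they never become defined).
#'
#' @param bundle a \code{qdiff_bootstrap}.
#' @return a probability.
#' @export
p_star_max <- function(bundle) {
  stopifnot(inherits(bundle, "qdiff_bootstrap"))
  ps <- bundle$p_stars[!is.na(bundle$p_stars)]
  if (length(ps) == 0L)
    stop("no replicate with events in both groups", call. = FALSE)
  max(ps)
}

#' Upper-endpoint (1 - alpha) quantile of the replicate domain bounds
#'
#' The conservative band extension needs a specific \eqn{(1-\alpha)}
#' quantile of \eqn{p^{*1} \dots p^{*B}}: with order statistics
#' \eqn{x_{(1)} \le \dots \le x_{(B)}}, if \eqn{(1-\alpha) B} is an integer
#' \eqn{r} the usual empirical quantile is any value in
#' \eqn{[x_{(r)}, x_{(r+1)}]} and the \emph{upper} endpoint
#' \eqn{x_{(r+1)}} is taken (clipped to \eqn{x_{(B)}}); otherwise the
#' quantile is the unique \eqn{x_{(\lceil (1-\alpha) B \rceil)}}.
#'
#' @param p_stars numeric vector of per-replicate lower domain bounds;
#'   \code{NA} entries (no-events markers) are dropped.
#' @param alpha two-sided level as a fraction in (0, 1).
#' @return a probability.
#' @export
p_star_upper_quantile <- function(p_stars, alpha) {
  p_stars <- p_stars[!is.na(p_stars)]
  if (length(p_stars) == 0L)
    stop("empty p_stars", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be a fraction in (0, 1)", call. = FALSE)
  x <- sort(p_stars)
  B <- length(x)
  r <- (1 - alpha) * B
  if (abs(r - round(r)) < 1e-9) {
    x[min(round(r) + 1L, B)]
  } else {
    x[ceiling(r)]
  }
}

#' Weighted empirical quantile (left-continuous inverse CDF)
#'
#' The smallest value \eqn{v} such that the cumulative weight of all values
#' \eqn{\le v} reaches \eqn{q}.  With equal weights \eqn{1/B} this is the
#' \eqn{\lceil qB \rceil}th order statistic, so the unweighted and weighted
#' band regions use one and the same quantile rule.
#'
#' @param values numeric vector.
#' @param weights positive weights of the same length, summing to 1
#'   (within 1e-9).
#' @param q quantile level in (0, 1).
#' @return a single value from \code{values}.
#' @export
weighted_quantile <- function(values, weights, q) {
  if (length(values) != length(weights) || length(values) == 0L)
    stop("`values` and `weights` must be nonempty and of equal length",
         call. = FALSE)
  if (any(weights <= 0))
    stop("weights must be positive", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9)
    stop("weights must sum to 1 (within 1e-9)", call. = FALSE)
  if (!is.numeric(q) || any(q <= 0) || any(q >= 1))
    stop("q must lie in (0, 1)", call. = FALSE)
  o <- order(values)
  v <- values[o]
  cw <- cumsum(weights[o])
  vapply(q, function(qi) v[which(cw >= qi - 1e-12)[1L]], numeric(1))
}

# Shared per-p band computation.  `vals` are the replicate differences at p
# (NA = undefined there), B the bundle size.  Undefined replicates are
# replaced by two sentinel values -M and +M with half weight each, M one
# more than the largest absolute defined value (any larger M is
# equivalent); an endpoint landing on a sentinel is reported as NA.
band_quantiles_int <- function(vals, B, alpha, sentinel_inflate = 1) {
  def <- !is.na(vals)
  nd <- sum(def)
  if (nd == B) {
    w <- rep(1 / B, B)
    lo <- weighted_quantile(vals, w, alpha / 2)
    up <- weighted_quantile(vals, w, 1 - alpha / 2)
    return(c(lo, up))
  }
  M <- (if (nd > 0L) max(abs(vals[def])) + 1 else 1) * sentinel_inflate
  v <- c(vals[def], rep(c(-M, M), times = B - nd))
  w <- c(rep(1 / B, nd), rep(0.5 / B, 2L * (B - nd)))
  lo <- weighted_quantile(v, w, alpha / 2)
  up <- weighted_quantile(v, w, 1 - alpha / 2)
  if (lo == -M) lo <- NA_real_
  if (up == M) up <- NA_real_
  c(lo, up)
}

#' Pointwise bootstrap confidence limits at a single probability
#'
#' In the \emph{core} region \eqn{p \ge p^*_{\max}} every replicate (bar
#' no-events ones) is defined and the limits are the \eqn{\alpha/2} and
#' \eqn{1-\alpha/2} empirical quantiles of
#' \eqn{\hat D^{*1}(p), \dots, \hat D^{*B}(p)}.  In the \emph{extended}
#' region \eqn{p^*_{1-\alpha} \le p < p^*_{\max}} each undefined replicate
#' is conservatively replaced by the two sentinel values \eqn{-M} and
#' \eqn{+M} (weights \eqn{0.5/B} each, \eqn{M} larger than every defined
#' \eqn{|\hat D^{*i}(p)|}) and the same two weighted quantiles are taken;
#' an endpoint that lands on a sentinel is undefined (\code{NA}).
#'
#' @param bundle a \code{qdiff_bootstrap}.
#' @param p a single probability, at least \eqn{p^*_{1-\alpha}}.
#' @param alpha two-sided level as a fraction (0.05 for a 95\% band).
#' @param sentinel_inflate multiply the automatic \eqn{M} by this factor;
#'   results must not depend on it (testing hook for the arbitrariness of
#'   \eqn{M}).
#' @return list with \code{lower}, \code{upper}, \code{region}
#'   (\code{"core"} or \code{"extended"}), \code{p_star_max},
#'   \code{p_star_1_alpha} and \code{n_undefined} (replicates undefined at
#'   this \code{p}).
#' @export
band_at <- function(bundle, p, alpha, sentinel_inflate = 1) {
  stopifnot(inherits(bundle, "qdiff_bootstrap"), length(p) == 1L)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be a fraction in (0, 1)", call. = FALSE)
  psm <- p_star_max(bundle)
  p1a <- p_star_upper_quantile(bundle$p_stars, alpha)
  if (p < p1a - .km_tol)
    stop(sprintf("p = %.6g is below p*_{1-alpha} = %.6g: no band there",
                 p, p1a), call. = FALSE)
  vals <- vapply(bundle$replicates, function(r) {
    if (is.null(r)) NA_real_ else eval_step_int(r$levels, r$values, r$p0, p)
  }, numeric(1))
  qs <- band_quantiles_int(vals, bundle$B, alpha, sentinel_inflate)
  list(lower = qs[1L], upper = qs[2L],
       region = if (p >= psm - .km_tol) "core" else "extended",
       p_star_max = psm, p_star_1_alpha = p1a,
       n_undefined = sum(is.na(vals)))
}

#' Pointwise bootstrap confidence band for a difference curve
#'
#' Applies \code{\link{band_at}} over a probability grid, flags each grid
#' point as \code{core} (\eqn{p \ge p^*_{\max}}), \code{extended}
#' (\eqn{p^*_{1-\alpha} \le p < p^*_{\max}}, conservative weighted limits)
#' or \code{undefined} (below \eqn{p^*_{1-\alpha}}).  The band is
#' \emph{pointwise}: no familywise adjustment is made.
#'
#' The exact band is piecewise constant with breakpoints at the union of
#' all replicates' level sets, which can be very large.  The default grid
#' merges the observed curve's breakpoints, all replicate domain bounds
#' \eqn{p^{*i}} and a uniform grid of 1001 points on [0, 1] --- visually
#' indistinguishable from the exact band at bounded cost.  Pass
#' \code{grid = "exact"} for the full union, or any numeric vector.
#'
#' @param bundle a \code{qdiff_bootstrap}.
#' @param alpha two-sided level as a fraction (default 0.05).
#' @param grid \code{NULL} (default grid), \code{"exact"}, or a numeric
#'   vector of probabilities in [0, 1].
#' @return an object of class \code{qdiff_band}: descending \code{grid},
#'   \code{lower}, \code{upper} (NA where undefined), \code{region},
#'   \code{alpha}, \code{p_star_max}, \code{p_star_1_alpha}, \code{B}.
#' @export
confidence_band <- function(bundle, alpha = 0.05, grid = NULL) {
  stopifnot(inherits(bundle, "qdiff_bootstrap"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be a fraction in (0, 1)", call. = FALSE)
  ps_ok <- bundle$p_stars[!is.na(bundle$p_stars)]
  if (is.null(grid)) {
    grid <- c(bundle$observed$levels, 1, ps_ok, seq(0, 1, length.out = 1001L))
  } else if (identical(grid, "exact")) {
    grid <- c(1, ps_ok,
              unlist(lapply(bundle$replicates,
                            function(r) if (is.null(r)) NULL else r$levels)))
  } else {
    grid <- as.numeric(grid)
    if (anyNA(grid) || any(grid < 0) || any(grid > 1))
      stop("grid values must lie in [0, 1]", call. = FALSE)
  }
  grid <- sort(unique(grid), decreasing = TRUE)
  psm <- p_star_max(bundle)
  p1a <- p_star_upper_quantile(bundle$p_stars, alpha)

  # replicate values over the whole grid, one vectorized pass per replicate
  V <- vapply(bundle$replicates, function(r) {
    if (is.null(r)) rep(NA_real_, length(grid))
    else eval_step_int(r$levels, r$values, r$p0, grid)
  }, numeric(length(grid)))
  V <- matrix(V, nrow = length(grid))

  lower <- upper <- rep(NA_real_, length(grid))
  region <- rep("undefined", length(grid))
  live <- grid >= p1a - .km_tol
  region[live & grid < psm - .km_tol] <- "extended"
  region[grid >= psm - .km_tol] <- "core"
  for (g in which(live)) {
    qs <- band_quantiles_int(V[g, ], bundle$B, alpha)
    lower[g] <- qs[1L]
    upper[g] <- qs[2L]
  }
  structure(list(grid = grid, lower = lower, upper = upper, region = region,
                 alpha = alpha, p_star_max = psm, p_star_1_alpha = p1a,
                 B = bundle$B),
            class = "qdiff_band")
}

#' @export
print.qdiff_band <- function(x, ...) {
  cat(sprintf("Pointwise %g%% bootstrap confidence band (B = %d)\n",
              100 * (1 - x$alpha), x$B))
  cat(sprintf("  core region: p >= p*_max = %.4g; extended down to p*_{1-alpha} = %.4g\n",
              x$p_star_max, x$p_star_1_alpha))
  cat(sprintf("  grid: %d points, %d core / %d extended / %d undefined\n",
              length(x$grid), sum(x$region == "core"),
              sum(x$region == "extended"), sum(x$region == "undefined")))
  invisible(x)
}
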