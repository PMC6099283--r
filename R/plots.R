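# Coordinates for a step function of p that holds values[i] on the
# interval [levels[i], previous level), closed at the lower level;
# `top` is the upper end of the first interval (1 for a full curve).
step_coords <- function(levels, values, top = 1) {
  K <- length(levels)
  upper <- c(top, levels[-K])
  list(x = rep(values, each = 2L),
       y = as.vector(rbind(upper, levels)))
}

#' Plot two Kaplan-Meier curves
#'
#' The standard product-limit plot for the two groups, drawn only over each
#' curve's domain \eqn{[0, t_K]} (the estimate is undefined beyond the last
#' failure time).  Censoring times are marked with tick marks by default.
#'
#' @param curve1,curve2 \code{km_curve} objects.
#' @param labels character vector of two group labels.
#' @param timeunit axis unit string.
#' @param censor_ticks mark censoring times on the curves?
#' @param main plot title.
#' @return invisibly, NULL.
#' @export
plot_km <- function(curve1, curve2, labels = c("group 1", "group 2"),
                    timeunit = "years", censor_ticks = TRUE,
                    main = "Kaplan-Meier curves") {
  cols <- c("#0072B2", "#D55E00")
  tmax <- max(curve1$time, curve2$time, curve1$censor_times,
              curve2$censor_times, 0)
  plot(NA, xlim = c(0, tmax), ylim = c(0, 1),
       xlab = sprintf("Time (%s)", timeunit),
       ylab = "Survival probability", main = main)
  for (g in 1:2) {
    cv <- list(curve1, curve2)[[g]]
    K <- length(cv$time)
    if (K > 0L) {
      # right-continuous steps: level holds on [t_i, t_{i+1})
      x <- c(0, rep(cv$time, each = 2L))
      y <- c(1, 1, rep(cv$surv[-K], each = 2L), cv$surv[K])
      lines(x, y, col = cols[g], lwd = 2)
      if (censor_ticks && length(cv$censor_times)) {
        ct <- cv$censor_times[cv$censor_times <= cv$time[K]]
        if (length(ct))
          graphics::points(ct, survival_at(cv, ct), pch = 3, cex = 0.7,
                           col = cols[g])
      }
    } else {
      graphics::points(0, 1, col = cols[g], pch = 16)
    }
  }
  legend("bottomleft", legend = labels, col = cols, lwd = 2, bty = "n")
  invisible(NULL)
}

#' Plot a quantile survival time difference curve
#'
#' Draws the difference curve in the customary orientation: survival
#' probability on the \emph{vertical} axis (to match the Kaplan-Meier
#' plot), quantile time difference on the horizontal axis.  The point
#' estimate is a green solid step line; an optional bootstrap bundle is
#' drawn underneath in light grey; an optional confidence band is drawn as
#' a green transparent area (\code{band_style = "area"}) or as two black
#' solid lines (\code{band_style = "lines"}, used when the band and the
#' bundle are combined).  Undefined band stretches leave gaps --- sentinel
#' values are never drawn.  A dashed vertical reference line marks a
#' difference of zero.
#'
#' @param dcurve a \code{qdiff_curve} (the point estimate; required).
#' @param bundle optional \code{qdiff_bootstrap} whose replicates are drawn
#'   as grey step lines.
#' @param band optional \code{qdiff_band}.
#' @param band_style \code{"area"} or \code{"lines"}.
#' @param labels character vector of two group labels (for the axis text).
#' @param timeunit axis unit string.
#' @param main plot title.
#' @return invisibly, NULL.
#' @export
plot_difference <- function(dcurve, bundle = NULL, band = NULL,
                            band_style = c("area", "lines"),
                            labels = c("group 1", "group 2"),
                            timeunit = "years",
                            main = "Quantile survival time difference") {
  stopifnot(inherits(dcurve, "qdiff_curve"))
  band_style <- match.arg(band_style)
  xs <- dcurve$values
  if (!is.null(bundle))
    xs <- c(xs, unlist(lapply(bundle$replicates,
                              function(r) if (is.null(r)) NULL else r$values)))
  if (!is.null(band)) xs <- c(xs, band$lower, band$upper)
  xr <- range(xs, 0, na.rm = TRUE)
  plot(NA, xlim = xr, ylim = c(0, 1),
       xlab = sprintf("Quantile time difference, %s - %s (%s)",
                      labels[1L], labels[2L], timeunit),
       ylab = "Survival probability", main = main)
  abline(v = 0, lty = 2, col = "grey40")

  if (!is.null(bundle)) {
    for (r in bundle$replicates) {
      if (is.null(r)) next
      sc <- step_coords(r$levels, r$values)
      lines(sc$x, sc$y, col = "grey80", lwd = 0.6)
    }
  }
  if (!is.null(band)) {
    stopifnot(inherits(band, "qdiff_band"))
    # contiguous runs where both endpoints are defined
    ok <- !is.na(band$lower) & !is.na(band$upper)
    runs <- split(which(ok), cumsum(!ok)[ok])
    for (idx in runs) {
      if (length(idx) < 1L) next
      lo <- step_coords(band$grid[idx], band$lower[idx],
                        top = band$grid[idx[1L]])
      up <- step_coords(band$grid[idx], band$upper[idx],
                        top = band$grid[idx[1L]])
      if (band_style == "area") {
        polygon(c(lo$x, rev(up$x)), c(lo$y, rev(up$y)),
                col = adjustcolor("#009E40", alpha.f = 0.25), border = NA)
      } else {
        lines(lo$x, lo$y, col = "black", lwd = 1.4)
        lines(up$x, up$y, col = "black", lwd = 1.4)
      }
    }
  }
  sc <- step_coords(dcurve$levels, dcurve$values)
  lines(sc$x, sc$y, col = "#009E40", lwd = 2.4)
  invisible(NULL)
}
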