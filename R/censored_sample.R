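#' Construct a right-censored survival sample
#'
#' Bundles observed times and event indicators for one group of patients.
#' An event indicator of \code{TRUE} marks an observed failure, \code{FALSE}
#' marks a right-censored observation (the true event time is only known to
#' exceed the recorded time).
#'
#' @param time numeric vector of non-negative, finite observation times.
#' @param event logical vector of the same length; \code{TRUE} = failure,
#'   \code{FALSE} = censored.  Numeric 0/1 is accepted and coerced.
#' @return an object of class \code{censored_sample} with elements
#'   \code{time} and \code{event}.
#' @examples
#' censored_sample(c(1, 2, 2, 3), c(FALSE, TRUE, TRUE, FALSE))
#' @export
censored_sample <- function(time, event) {
  time <- as.numeric(time)
  event <- as.logical(event)
  if (length(time) != length(event) || length(time) < 1L)
    stop("`time` and `event` must have the same length >= 1", call. = FALSE)
  if (anyNA(time) || anyNA(event))
    stop("missing values are not allowed in `time` or `event`", call. = FALSE)
  if (any(!is.finite(time)))
    stop("all times must be finite", call. = FALSE)
  if (any(time < 0))
    stop("all times must be non-negative", call. = FALSE)
  structure(list(time = time, event = event), class = "censored_sample")
}

#' @export
print.censored_sample <- function(x, ...) {
  cat(sprintf("Right-censored sample: n = %d (%d events, %d censored)\n",
              length(x$time), sum(x$event), sum(!x$event)))
  invisible(x)
}

#' @export
length.censored_sample <- function(x) length(x$time)

as_censored_sample <- function(x) {
  if (inherits(x, "censored_sample")) return(x)
  stop("expected a `censored_sample` object", call. = FALSE)
}
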