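#' Column mapping for a two-group survival table
#'
#' Names the time, status and group columns of a delimited input table and
#' says how the status and group codes are to be read.  Group codes are
#' compared after trimming and conversion to character, so numeric and text
#' codes both work.
#'
#' @param time_col,status_col,group_col column names.
#' @param censval status value(s) meaning "censored"; anything else is an
#'   event.  Default \code{"0"}.
#' @param gvalue1,gvalue2 the two group codes to compare (group 1 minus
#'   group 2); must differ.
#' @param grouplbl,gvallbl1,gvallbl2 optional display labels.
#' @param timeunit display unit for the time axis, default \code{"years"}.
#' @return an object of class \code{column_spec}.
#' @export
column_spec <- function(time_col, status_col, group_col,
                        censval = "0", gvalue1, gvalue2,
                        grouplbl = NULL, gvallbl1 = NULL, gvallbl2 = NULL,
                        timeunit = "years") {
  censval <- trimws(as.character(censval))
  if (length(censval) == 0L)
    stop("censval must name at least one censoring code", call. = FALSE)
  gvalue1 <- trimws(as.character(gvalue1))
  gvalue2 <- trimws(as.character(gvalue2))
  if (identical(gvalue1, gvalue2))
    stop("gvalue1 and gvalue2 must differ", call. = FALSE)
  structure(list(time_col = time_col, status_col = status_col,
                 group_col = group_col, censval = censval,
                 gvalue1 = gvalue1, gvalue2 = gvalue2,
                 grouplbl = grouplbl %||% group_col,
                 gvallbl1 = gvallbl1 %||% gvalue1,
                 gvallbl2 = gvallbl2 %||% gvalue2,
                 timeunit = timeunit),
            class = "column_spec")
}

#' Read a two-group right-censored survival table
#'
#' Reads a delimited file (tab-separated for \code{.tsv}/\code{.tab}/
#' \code{.txt}, comma-separated otherwise), splits it into the two groups
#' named in \code{spec}, and converts the status codes: values listed in
#' \code{spec$censval} are censored, every other value is an event.  Rows
#' with a missing time, status or group, and rows belonging to other
#' groups, are dropped with a message and counted in the result.
#'
#' @param path path to the delimited file (header row mandatory).
#' @param spec a \code{\link{column_spec}}.
#' @return list with \code{sample1}, \code{sample2}
#'   (\code{\link{censored_sample}} objects), \code{dropped} (named counts
#'   \code{missing} and \code{other_group}) and the \code{spec}.
#' @export
read_survival_table <- function(path, spec) {
  stopifnot(inherits(spec, "column_spec"))
  if (!file.exists(path))
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  reader <- if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE))
    read.delim else read.csv
  df <- reader(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c(spec$time_col, spec$status_col, spec$group_col))
    if (!col %in% names(df))
      stop(sprintf("column \"%s\" not found in %s", col, path), call. = FALSE)

  time <- suppressWarnings(as.numeric(df[[spec$time_col]]))
  status <- trimws(as.character(df[[spec$status_col]]))
  group <- trimws(as.character(df[[spec$group_col]]))
  miss <- is.na(time) | is.na(status) | status == "" |
    is.na(group) | group == ""
  n_missing <- sum(miss)
  time <- time[!miss]; status <- status[!miss]; group <- group[!miss]
  if (any(time < 0))
    stop("negative survival times in input", call. = FALSE)

  in1 <- group == spec$gvalue1
  in2 <- group == spec$gvalue2
  n_other <- sum(!in1 & !in2)
  if (n_missing > 0L)
    message(sprintf("dropped %d row(s) with missing time/status/group",
                    n_missing))
  if (n_other > 0L)
    message(sprintf("dropped %d row(s) outside groups \"%s\"/\"%s\"",
                    n_other, spec$gvalue1, spec$gvalue2))
  if (!any(in1))
    stop(sprintf("no rows with group value \"%s\"", spec$gvalue1),
         call. = FALSE)
  if (!any(in2))
    stop(sprintf("no rows with group value \"%s\"", spec$gvalue2),
         call. = FALSE)
  event <- !(status %in% spec$censval)
  list(sample1 = censored_sample(time[in1], event[in1]),
       sample2 = censored_sample(time[in2], event[in2]),
       dropped = c(missing = n_missing, other_group = n_other),
       spec = spec)
}

#' Write all analysis artifacts as tidy delimited tables
#'
#' Writes up to four CSV files into \code{out_dir}: \code{km_curves.csv}
#' (group, time, survival, n_at_risk, n_events), \code{difference_curve.csv}
#' (p_level, difference), \code{band.csv} (p, lower, upper, region) and
#' \code{bundle.csv} (replicate_id, p_level, difference).  Undefined band
#' endpoints are written as empty fields; sentinel values never reach the
#' output.  All tables round-trip through \code{read.csv} at full float
#' precision.
#'
#' @param curves list of two \code{km_curve} objects (group 1, group 2).
#' @param dcurve a \code{qdiff_curve}, or NULL to skip.
#' @param bundle a \code{qdiff_bootstrap}, or NULL to skip.
#' @param band a \code{qdiff_band}, or NULL to skip.
#' @param out_dir output directory, created if needed.
#' @return invisibly, the named character vector of files written.
#' @export
write_outputs <- function(curves, dcurve = NULL, bundle = NULL, band = NULL,
                          out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory %s", out_dir),
         call. = FALSE)
  files <- character(0)
  wr <- function(df, name) {
    f <- file.path(out_dir, name)
    write.csv(format_full(df), f, row.names = FALSE, na = "", quote = FALSE)
    files[[name]] <<- f
  }
  if (!is.null(curves)) {
    stopifnot(length(curves) == 2L)
    tab <- do.call(rbind, lapply(1:2, function(g) {
      cv <- curves[[g]]
      data.frame(group = g, time = cv$time, survival = cv$surv,
                 n_at_risk = cv$n_risk, n_events = cv$n_event)
    }))
    wr(tab, "km_curves.csv")
  }
  if (!is.null(dcurve))
    wr(data.frame(p_level = dcurve$levels, difference = dcurve$values),
       "difference_curve.csv")
  if (!is.null(band))
    wr(data.frame(p = band$grid, lower = band$lower, upper = band$upper,
                  region = band$region),
       "band.csv")
  if (!is.null(bundle)) {
    tab <- do.call(rbind, lapply(seq_len(bundle$B), function(i) {
      r <- bundle$replicates[[i]]
      if (is.null(r)) return(NULL)
      data.frame(replicate_id = i, p_level = r$levels, difference = r$values)
    }))
    wr(tab, "bundle.csv")
  }
  invisible(unlist(files))
}

# full-precision serialization: numbers via format(..., digits = 17)
format_full <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]]))
      df[[j]] <- ifelse(is.na(df[[j]]), NA,
                        format(df[[j]], digits = 17, trim = TRUE,
                               scientific = FALSE))
  df
}
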