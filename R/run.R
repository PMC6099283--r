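#' Configuration for a full quantile-difference analysis run
#'
#' Mirrors the parameter surface of the original macro: \code{alpha} is
#' given in \emph{percent} (\code{alpha = 5} requests a 95\% pointwise
#' band) and converted to a fraction once, here at the boundary;
#' \code{boot} is the number of bootstrap replicates used for the band
#' (minimum 100); \code{bundle} is the number of replicates shown in the
#' bundle figures (the first \code{bundle} replicates of the single
#' \code{boot}-sized resampling pass, so one RNG stream produces
#' consistent figures); \code{seedval = 0} draws a fresh seed and records
#' it in the run metadata.
#'
#' @param data path to the delimited input table.
#' @param time_col,status_col,group_col,censval,gvalue1,gvalue2,grouplbl,gvallbl1,gvallbl2,timeunit
#'   passed to \code{\link{column_spec}}.
#' @param alpha pointwise two-sided confidence level, in percent
#'   (default 5).
#' @param boot bootstrap replicates for the band (default 2000, min 100).
#' @param bundle replicates shown in bundle figures (default 200; 0 skips
#'   the bundle figure).
#' @param seedval integer bootstrap seed; 0 = derive from entropy.
#' @param out_dir output directory.
#' @param grid \code{"default"} or \code{"exact"} band evaluation grid.
#' @param plots which figures to produce: any of \code{"km"},
#'   \code{"bundle"}, \code{"band"}, \code{"combined"}, or \code{"all"}.
#' @param censor_ticks mark censoring times on the KM plot?
#' @return an object of class \code{run_config}.
#' @export
run_config <- function(data, time_col = "time", status_col = "status",
                       group_col = "group", censval = "0",
                       gvalue1, gvalue2, grouplbl = NULL,
                       gvallbl1 = NULL, gvallbl2 = NULL,
                       timeunit = "years",
                       alpha = 5, boot = 2000L, bundle = 200L,
                       seedval = 0L, out_dir, grid = c("default", "exact"),
                       plots = "all", censor_ticks = TRUE) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 100)
    stop("alpha is a percent and must lie in (0, 100)", call. = FALSE)
  boot <- as.integer(boot)
  if (is.na(boot) || boot < 100L)
    stop("boot must be at least 100", call. = FALSE)
  bundle <- as.integer(bundle)
  if (is.na(bundle) || bundle < 0L || bundle > boot)
    stop("bundle must satisfy 0 <= bundle <= boot", call. = FALSE)
  seedval <- as.integer(seedval)
  if (is.na(seedval) || seedval < 0L)
    stop("seedval must be a non-negative integer", call. = FALSE)
  grid <- match.arg(grid)
  known <- c("km", "bundle", "band", "combined")
  plots <- if ("all" %in% plots) known else match.arg(plots, known,
                                                      several.ok = TRUE)
  spec <- column_spec(time_col, status_col, group_col, censval,
                      gvalue1, gvalue2, grouplbl, gvallbl1, gvallbl2,
                      timeunit)
  structure(list(data = data, spec = spec, alpha = alpha, boot = boot,
                 bundle = bundle, seedval = seedval, out_dir = out_dir,
                 grid = grid, plots = plots, censor_ticks = censor_ticks),
            class = "run_config")
}

#' Run the complete quantile-difference analysis
#'
#' End-to-end driver: reads the two-group table, fits both Kaplan-Meier
#' curves and the difference curve, runs one \code{boot}-sized bootstrap
#' pass, derives the pointwise confidence band and the bundle (the first
#' \code{bundle} replicates), writes all tidy output tables, a
#' \code{run_metadata.json} record (seed actually used, \eqn{p^*_{\max}},
#' \eqn{p^*_{1-\alpha}}, dropped-row and no-event-replicate counts) and
#' the requested figures (PDF always; PNG when the device is available).
#'
#' @param config a \code{\link{run_config}}.
#' @return invisibly, a list with the fitted objects and the paths of all
#'   files written.
#' @export
run_kmdiff <- function(config) {
  stopifnot(inherits(config, "run_config"))
  spec <- config$spec
  inp <- read_survival_table(config$data, spec)
  k1 <- km_estimate(inp$sample1)
  k2 <- km_estimate(inp$sample2)
  if (length(k1$time) == 0L || length(k2$time) == 0L)
    stop("a group has no events: the difference curve is undefined",
         call. = FALSE)

  alpha <- config$alpha / 100  # percent -> fraction, once
  boot <- bootstrap_differences(inp$sample1, inp$sample2,
                                B = config$boot, seed = config$seedval)
  dcurve <- boot$observed
  band <- confidence_band(boot, alpha = alpha,
                          grid = if (config$grid == "exact") "exact"
                                 else NULL)
  bnd <- if (config$bundle > 0L) bundle_head(boot, config$bundle) else NULL

  out_dir <- config$out_dir
  files <- write_outputs(list(k1, k2), dcurve, bnd, band, out_dir)
  labels <- c(spec$gvallbl1, spec$gvallbl2)

  meta <- list(seed = boot$seed, boot = boot$B, bundle = config$bundle,
               alpha_percent = config$alpha,
               p_star_max = band$p_star_max,
               p_star_1_alpha = band$p_star_1_alpha,
               p0 = dcurve$p0,
               n = boot$n, m = boot$m,
               dropped_rows = as.list(inp$dropped),
               n_no_event_replicates = boot$n_no_events)
  meta_path <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  files <- c(files, run_metadata.json = meta_path)

  draw <- list()
  if ("km" %in% config$plots)
    draw$km <- function() plot_km(k1, k2, labels, spec$timeunit,
                                  config$censor_ticks)
  if ("bundle" %in% config$plots && !is.null(bnd))
    draw$diff_bundle <- function()
      plot_difference(dcurve, bundle = bnd, labels = labels,
                      timeunit = spec$timeunit)
  if ("band" %in% config$plots)
    draw$diff_band <- function()
      plot_difference(dcurve, band = band, band_style = "area",
                      labels = labels, timeunit = spec$timeunit)
  if ("combined" %in% config$plots)
    draw$diff_combined <- function()
      plot_difference(dcurve, bundle = bnd, band = band,
                      band_style = "lines", labels = labels,
                      timeunit = spec$timeunit)
  for (nm in names(draw))
    files <- c(files, export_figure(draw[[nm]], file.path(out_dir, nm)))

  invisible(list(curves = list(k1, k2), dcurve = dcurve, bundle = bnd,
                 band = band, files = files, meta = meta))
}

# Write a figure as PDF (always available) and PNG (when capable).
export_figure <- function(draw_fn, stem) {
  out <- character(0)
  pdf_path <- paste0(stem, ".pdf")
  pdf(pdf_path, width = 7, height = 5.5)
  draw_fn()
  dev.off()
  out[basename(pdf_path)] <- pdf_path
  if (isTRUE(unname(capabilities("png")))) {
    png_path <- paste0(stem, ".png")
    ok <- tryCatch({
      png(png_path, width = 1400, height = 1100, res = 200)
      draw_fn()
      dev.off()
      TRUE
    }, error = function(e) {
      try(dev.off(), silent = TRUE)
      FALSE
    })
    if (ok) out[basename(png_path)] <- png_path
  }
  out
}

#' Command-line entry point
#'
#' Thin wrapper so \code{Rscript -e 'kmdiff::kmdiff_cli()' --args ...} or
#' the installed script \code{system.file("cli", "kmdiff.R", package =
#' "kmdiff")} can drive \code{\link{run_kmdiff}}.  Exits with status 0 on
#' success; errors are printed and give a nonzero status when run
#' non-interactively.
#'
#' @param args character vector of command-line arguments.
#' @return invisibly, the \code{run_kmdiff} result.
#' @export
kmdiff_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  ol <- list(
    optparse::make_option("--data", type = "character",
                          help = "input CSV/TSV survival table (required)"),
    optparse::make_option("--time", type = "character", default = "time"),
    optparse::make_option("--timeunit", type = "character",
                          default = "years"),
    optparse::make_option("--status", type = "character",
                          default = "status"),
    optparse::make_option("--censval", type = "character", default = "0",
                          help = "comma-separated censoring codes"),
    optparse::make_option("--group", type = "character", default = "group"),
    optparse::make_option("--gvalue1", type = "character",
                          help = "first group code (required)"),
    optparse::make_option("--gvalue2", type = "character",
                          help = "second group code (required)"),
    optparse::make_option("--grouplbl", type = "character", default = NULL),
    optparse::make_option("--gvallbl1", type = "character", default = NULL),
    optparse::make_option("--gvallbl2", type = "character", default = NULL),
    optparse::make_option("--alpha", type = "double", default = 5,
                          help = "confidence level in percent [default %default]"),
    optparse::make_option("--boot", type = "integer", default = 2000L),
    optparse::make_option("--bundle", type = "integer", default = 200L),
    optparse::make_option("--seedval", type = "integer", default = 0L),
    optparse::make_option("--out-dir", type = "character", dest = "out_dir",
                          default = "kmdiff_out"),
    optparse::make_option("--grid", type = "character", default = "default"),
    optparse::make_option("--plots", type = "character", default = "all",
                          help = "comma list of km,bundle,band,combined or all"))
  opt <- optparse::parse_args(optparse::OptionParser(option_list = ol),
                              args = args)
  run <- function() {
    for (req in c("data", "gvalue1", "gvalue2"))
      if (is.null(opt[[req]]))
        stop(sprintf("--%s is required", req), call. = FALSE)
    cfg <- run_config(data = opt$data, time_col = opt$time,
                      status_col = opt$status, group_col = opt$group,
                      censval = strsplit(opt$censval, ",")[[1]],
                      gvalue1 = opt$gvalue1, gvalue2 = opt$gvalue2,
                      grouplbl = opt$grouplbl, gvallbl1 = opt$gvallbl1,
                      gvallbl2 = opt$gvallbl2, timeunit = opt$timeunit,
                      alpha = opt$alpha, boot = opt$boot,
                      bundle = opt$bundle, seedval = opt$seedval,
                      out_dir = opt$out_dir, grid = opt$grid,
                      plots = strsplit(opt$plots, ",")[[1]])
    run_kmdiff(cfg)
  }
  if (interactive()) return(invisible(run()))
  res <- tryCatch(run(), error = function(e) {
    message("kmdiff error: ", conditionMessage(e))
    quit(save = "no", status = 1L)
  })
  invisible(res)
}
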