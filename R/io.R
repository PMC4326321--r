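#' Read a single-band raster (ESRI ASCII grid)
#'
#' Reads an ESRI ASCII grid (`.asc`) into a matrix plus [grid_meta]; the
#' `nodata_value` mask becomes `NA`. GeoTIFF is not supported; `.tif` paths
#' raise an explicit error. Grids whose cell size looks like degrees
#' (cellsize < 1 with small origin magnitudes) are rejected: the engine
#' requires a projected metric system.
#'
#' @param path Path to the `.asc` file.
#' @param type `"classified"` to return a [classified_grid], `"slope"` for a
#'   [slope_grid], `"matrix"` for the raw list (`values`, `meta`).
#' @return Depends on `type`.
#' @export
read_raster <- function(path, type = c("matrix", "classified", "slope")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("raster file not found: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    stop("GeoTIFF input is not supported; supply an ESRI ASCII grid (.asc)")
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1L
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (!key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
                    "yllcenter", "cellsize", "nodata_value")) break
    hdr[[key]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  for (k in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[k]])) stop("malformed ASCII grid header: missing ", k)
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop(sprintf("ASCII grid body has %d values; header promises %d",
                 length(vals), hdr$ncols * hdr$nrows))
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - hdr$cellsize / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - hdr$cellsize / 2
  if (hdr$cellsize < 1 && abs(xll) <= 360 && abs(yll) <= 90) {
    stop("raster appears to be in geographic (degree) units; reproject to metres first")
  }
  meta <- grid_meta(hdr$nrows, hdr$ncols, cell_size = hdr$cellsize,
                    origin_x = xll, origin_y = yll + hdr$nrows * hdr$cellsize)
  switch(type,
         matrix = list(values = m, meta = meta),
         classified = classified_grid(m, meta),
         slope = slope_grid(m, meta))
}

#' Write a matrix grid as an ESRI ASCII grid
#'
#' @param x A [classified_grid], [slope_grid], or plain matrix.
#' @param path Output `.asc` path.
#' @param meta Required [grid_meta] when `x` is a plain matrix.
#' @param nodata Nodata sentinel written for `NA` cells (default -9999).
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path, meta = NULL, nodata = -9999) {
  if (inherits(x, "classified_grid")) { m <- x$codes; meta <- x$meta }
  else if (inherits(x, "slope_grid")) { m <- x$slope_deg; meta <- x$meta }
  else { m <- as.matrix(x); if (is.null(meta)) stop("meta is required for a plain matrix") }
  m[is.na(m)] <- nodata
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", meta$n_cols),
    sprintf("nrows %d", meta$n_rows),
    sprintf("xllcorner %.10g", meta$origin_x),
    sprintf("yllcorner %.10g", meta$origin_y - meta$n_rows * meta$cell_size),
    sprintf("cellsize %.10g", meta$cell_size),
    sprintf("nodata_value %.10g", nodata)
  ), con)
  utils::write.table(format(m, trim = TRUE, digits = 10), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Analysis configuration
#'
#' Collects every tunable of the pipeline in one round-trippable list:
#' class speeds (km/h), cell size (m), the slope coefficient (or the grid it
#' is calibrated over), the log-shift margin (h), the per-step selection
#' level, the CI normal quantile, seeds and file paths.
#'
#' @param speeds Named speeds, km/h (see [speed_table()]).
#' @param cell_size Cell size in metres.
#' @param slope_k Fixed slope coefficient; ignored when `k_grid` is given.
#' @param k_grid Candidate coefficients for calibration (`NULL` = no
#'   calibration; use `slope_k` directly).
#' @param offset_margin_hours Margin of the log-shift rule (default 0.1 h).
#' @param fixed_offset_hours Optional fixed log-shift constant (hours)
#'   overriding the data-driven rule; `NULL` (default) uses the rule.
#' @param lrt_alpha Per-step inclusion level (default 0.05).
#' @param ci_z Normal quantile for CIs (default 1.96).
#' @param seed Global seed recorded and used by pipeline stages.
#' @param paths Named list of file paths (landcover, slope, facility,
#'   villages, survey, refs, out_dir) as needed by [run_pipeline()].
#' @return Object of class `analysis_config` (a plain list).
#' @export
analysis_config <- function(speeds = as.list(unclass(speed_table())),
                            cell_size = 100, slope_k = 0, k_grid = NULL,
                            offset_margin_hours = 0.1, fixed_offset_hours = NULL,
                            lrt_alpha = 0.05,
                            ci_z = 1.96, seed = 1L, paths = list()) {
  structure(list(speeds = speeds, cell_size = cell_size, slope_k = slope_k,
                 k_grid = k_grid, offset_margin_hours = offset_margin_hours,
                 fixed_offset_hours = fixed_offset_hours,
                 lrt_alpha = lrt_alpha, ci_z = ci_z, seed = as.integer(seed),
                 paths = paths),
            class = "analysis_config")
}

#' Read / write an analysis configuration (YAML)
#'
#' @param path YAML file path.
#' @return For `read_config`, an [analysis_config()]; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- analysis_config()
  for (k in names(raw)) cfg[[k]] <- raw[[k]]
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @rdname read_config
#' @param config An [analysis_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Travel times and straight-line distances for a set of points
#'
#' @param friction A [friction_surface].
#' @param facility The origin [point_location].
#' @param points Data frame with columns `label`, `x`, `y`.
#' @return Data frame `label`, `x`, `y`, `minutes`, `km`.
#' @export
travel_time_table <- function(friction, facility, points) {
  cg <- accumulate_cost(friction, facility)
  points <- as.data.frame(points)
  minutes <- vapply(seq_len(nrow(points)), function(i) {
    travel_time_at(cg, point_location(points$x[i], points$y[i], points$label[i]))
  }, numeric(1))
  km <- vapply(seq_len(nrow(points)), function(i) {
    euclidean_distance(facility, point_location(points$x[i], points$y[i]))
  }, numeric(1))
  data.frame(label = points$label, x = points$x, y = points$y,
             minutes = minutes, km = km)
}

#' Full delay analysis of a survey against modelled times
#'
#' Joins the survey to per-village modelled times and distances, computes
#' delays, applies the exclusion rules, builds the SES quartile from the
#' `ses_item_*` columns (when present), produces the descriptive summaries
#' with Kruskal-Wallis tests for each candidate factor, and fits the
#' forward-selection log-delay regression.
#'
#' @param survey Data frame: one row per woman with `id`, `village_label`,
#'   `reported_hours` and the candidate covariate columns (plus optional
#'   `ses_item_*` 0/1 columns).
#' @param times Data frame from [travel_time_table()] (per-village `label`,
#'   `minutes`, `km`).
#' @param candidates Candidate covariates in tie-break order; default: all
#'   variables of [default_covariate_distributions()] present in the survey,
#'   plus `ses_quartile` when asset items are present.
#' @param lrt_alpha,ci_z,offset_margin_hours,fixed_offset Passed to
#'   [delay_lm()] (`fixed_offset` as its `offset` argument).
#' @return List: `records` (with delays and exclusion reasons), `exclusions`
#'   (tally), `descriptives` (list of [describe_by_factor()] results per
#'   factor x outcome), `fit` (the `delay_lm`), `table3` (long-format
#'   descriptive table), `table4` (adjusted-ratio table).
#' @export
analyze_survey <- function(survey, times, candidates = NULL,
                           lrt_alpha = 0.05, ci_z = 1.96,
                           offset_margin_hours = 0.1, fixed_offset = NULL) {
  survey <- as.data.frame(survey); times <- as.data.frame(times)
  m <- match(survey$village_label, times$label)
  survey$modelled_hours <- times$minutes[m] / 60
  survey$distance_km <- if ("km" %in% names(times)) times$km[m] else NA_real_
  dl <- compute_delay(survey$reported_hours, survey$modelled_hours)
  survey$delay_hours <- dl$delay_hours

  # pin the documented reference levels (self-referral, PPH, "not difficult",
  # the 3-4 reliance band) regardless of how the CSV ordered the categories
  refs <- c(referrals = "none", complication = "pph",
            transport_difficulty = "not", rely_network = "3-4")
  for (v in names(refs)) {
    if (v %in% names(survey) && refs[[v]] %in% unique(as.character(survey[[v]]))) {
      survey[[v]] <- stats::relevel(factor(survey[[v]]), ref = refs[[v]])
    }
  }

  item_cols <- grep("^ses_item_", names(survey), value = TRUE)
  if (length(item_cols)) {
    ses <- ses_index(survey[, item_cols, drop = FALSE])
    survey$ses_quartile <- ses$quartile
  }
  if (is.null(candidates)) {
    candidates <- intersect(names(default_covariate_distributions()), names(survey))
    # wealth enters the candidate list with the other social-class variables
    if ("ses_quartile" %in% names(survey)) {
      candidates <- append(candidates, "ses_quartile",
                           after = match("referrals", candidates, nomatch = 0L))
    }
  }
  excl <- apply_exclusions(survey, exposure_cols = candidates)
  inc <- excl$included

  outcomes <- c(distance = "distance_km", modelled = "modelled_hours",
                reported = "reported_hours", delay = "delay_hours")
  descriptives <- list()
  t3 <- list()
  for (v in candidates) {
    for (on in names(outcomes)) {
      gs <- tryCatch(describe_by_factor(inc, v, outcomes[[on]]),
                     error = function(e) NULL)
      if (is.null(gs)) next
      descriptives[[paste(v, on, sep = ".")]] <- gs
      t3[[length(t3) + 1L]] <- data.frame(
        factor = v, outcome = on, gs$summary,
        kw_H = gs$kw_H, kw_p = gs$kw_p)
    }
  }
  fit <- fit_log_delay_model(inc, candidates, alpha = lrt_alpha, conf_z = ci_z,
                             margin_hours = offset_margin_hours,
                             offset = fixed_offset)
  list(records = survey, exclusions = excl$tally, descriptives = descriptives,
       fit = fit, table3 = do.call(rbind, t3), table4 = fit$ratios)
}

#' Run the full pipeline from a configuration
#'
#' Executes the stages in order — build friction, calibrate the slope
#' coefficient (when `k_grid` is configured and reference times are given),
#' accumulate travel times and extract them at the village points, then the
#' delay analysis — writing `times.csv`, `table3.csv`, `table4.csv`,
#' `exclusions.json`, `calib.json` (when calibrated) and `pipeline.log` to
#' the output directory. A stage failure halts the run with the stage name.
#'
#' @param config An [analysis_config()] whose `paths` name the inputs
#'   (`landcover`, `slope`, `facility` as `c(x, y)`, `villages`, `survey`,
#'   optionally `refs`) and `out_dir`.
#' @return Invisibly, a list with the calibration (or `NULL`), the times
#'   table and the analysis results.
#' @export
run_pipeline <- function(config) {
  p <- config$paths
  out <- p$out_dir
  if (is.null(out)) stop("config$paths$out_dir is required")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out, "pipeline.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf, append = TRUE)
  cat(sprintf("pipeline run %s\nR %s, traveldelay %s, seed %d\n",
              format(Sys.time()), getRversion(),
              as.character(utils::packageVersion("traveldelay")), config$seed),
      file = logf)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  for (need in c("landcover", "slope", "facility", "villages", "survey")) {
    if (is.null(p[[need]])) stop("config$paths$", need, " is required")
  }
  for (f in c("landcover", "slope", "villages", "survey")) {
    if (!file.exists(p[[f]])) stop("input file not found: ", p[[f]])
  }
  set.seed(config$seed)

  classes <- stage("read-landcover", read_raster(p$landcover, "classified"))
  slope <- stage("read-slope", read_raster(p$slope, "slope"))
  if (!same_grid(classes$meta, slope$meta)) {
    stop("pipeline stage 'assemble' failed: land-cover and slope grids do not align")
  }
  speeds <- do.call(speed_table, config$speeds)
  friction0 <- stage("build-friction", build_friction(classes, speeds))
  facility <- point_location(p$facility[1], p$facility[2], "facility")

  calib <- NULL
  k <- config$slope_k
  if (!is.null(config$k_grid) && !is.null(p$refs)) {
    refs <- stage("read-refs", utils::read.csv(p$refs))
    calib <- stage("calibrate",
                   calibrate_slope_factor(friction0, slope, facility, refs,
                                          config$k_grid))
    k <- calib$k_star
    jsonlite::write_json(list(k_star = calib$k_star,
                              objective = calib$objective_value,
                              table = calib$table),
                         file.path(out, "calib.json"), auto_unbox = TRUE, digits = NA)
    logline("calibrated slope k = %g", k)
  }
  friction <- stage("slope-modifier", apply_slope_modifier(friction0, slope, k))

  villages <- stage("read-villages", utils::read.csv(p$villages))
  times <- stage("travel-time", travel_time_table(friction, facility, villages))
  utils::write.csv(times, file.path(out, "times.csv"), row.names = FALSE)
  logline("travel times written for %d villages", nrow(times))

  survey <- stage("read-survey", utils::read.csv(p$survey, stringsAsFactors = TRUE))
  res <- stage("analyze",
               analyze_survey(survey, times,
                              lrt_alpha = config$lrt_alpha, ci_z = config$ci_z,
                              offset_margin_hours = config$offset_margin_hours,
                              fixed_offset = config$fixed_offset_hours))
  utils::write.csv(res$table3, file.path(out, "table3.csv"), row.names = FALSE)
  utils::write.csv(res$table4, file.path(out, "table4.csv"), row.names = FALSE)
  jsonlite::write_json(as.list(res$exclusions), file.path(out, "exclusions.json"),
                       auto_unbox = TRUE)
  logline("analysis complete: n = %d included, %d candidates, %d selected",
          res$fit$n, length(res$fit$candidates), length(res$fit$selected))
  invisible(list(calibration = calib, times = times, analysis = res))
}
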