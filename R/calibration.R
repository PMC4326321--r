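#' Calibrate the slope friction coefficient against reference drive times
#'
#' Reference times to named destinations (as reported by drivers who know the
#' routes) are intervals `[lo, hi]` in minutes; a single value is `lo = hi`.
#' For each candidate `k` in `k_grid` the friction surface is re-penalised
#' with [apply_slope_modifier()], travel times are re-accumulated, and each
#' destination's modelled time is scored against its reference interval:
#' zero if the model falls inside the interval, otherwise the distance to the
#' nearer endpoint divided by the interval midpoint (relative error, so long
#' routes do not dominate). The objective is the sum over destinations; the
#' calibrated `k_star` is the arg-min, ties broken toward the smallest `k`
#' (the least-modified model).
#'
#' @param friction0 A [friction_surface] built without slope penalty (k = 0).
#' @param slope A [slope_grid].
#' @param origin The facility [point_location].
#' @param refs A data frame with columns `label`, `x`, `y`, `ref_lo_min`,
#'   `ref_hi_min` (minutes, `0 < lo <= hi`).
#' @param k_grid Numeric vector of candidate slope coefficients; must contain
#'   0 so the uncalibrated model is always scored.
#' @param unreachable_penalty Objective contribution for a destination that
#'   cannot be reached at some `k` (default 10, i.e. 1000% relative error).
#' @return An object of class `slope_calibration`: `k_star`,
#'   `objective_value`, `objectives` (per `k`), and `table` — one row per
#'   destination with the reference interval, the initial (k = 0) and final
#'   (k = `k_star`) modelled minutes.
#' @export
calibrate_slope_factor <- function(friction0, slope, origin, refs, k_grid,
                                   unreachable_penalty = 10) {
  stopifnot(inherits(friction0, "friction_surface"), inherits(slope, "slope_grid"))
  refs <- as.data.frame(refs)
  need <- c("label", "x", "y", "ref_lo_min", "ref_hi_min")
  if (!all(need %in% names(refs))) {
    stop("refs must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(refs) == 0L) stop("refs must contain at least one reference destination")
  if (any(refs$ref_lo_min <= 0) || any(refs$ref_hi_min < refs$ref_lo_min)) {
    stop("reference intervals must satisfy 0 < lo <= hi")
  }
  k_grid <- sort(unique(as.numeric(k_grid)))
  if (length(k_grid) == 0L || any(k_grid < 0)) stop("k_grid must be nonempty and nonnegative")
  if (!0 %in% k_grid) stop("k_grid must include 0 (the uncalibrated model)")

  mid <- (refs$ref_lo_min + refs$ref_hi_min) / 2
  modelled <- matrix(NA_real_, nrow(refs), length(k_grid),
                     dimnames = list(refs$label, paste0("k=", k_grid)))
  objectives <- numeric(length(k_grid))
  for (ki in seq_along(k_grid)) {
    fr <- apply_slope_modifier(friction0, slope, k_grid[ki])
    cg <- accumulate_cost(fr, origin)
    m <- vapply(seq_len(nrow(refs)), function(d) {
      tryCatch(travel_time_at(cg, point_location(refs$x[d], refs$y[d], refs$label[d])),
               error = function(e) NA_real_)
    }, numeric(1))
    modelled[, ki] <- m
    err <- ifelse(is.na(m), unreachable_penalty,
                  ifelse(m >= refs$ref_lo_min & m <= refs$ref_hi_min, 0,
                         pmin(abs(m - refs$ref_lo_min), abs(m - refs$ref_hi_min)) / mid))
    if (anyNA(m)) {
      warning(sprintf("unreachable destination(s) at k = %g: %s",
                      k_grid[ki], paste(refs$label[is.na(m)], collapse = ", ")))
    }
    objectives[ki] <- sum(err)
  }
  best <- which.min(objectives)  # first minimum = smallest k after sorting
  tab <- data.frame(
    destination   = refs$label,
    ref_lo_min    = refs$ref_lo_min,
    ref_hi_min    = refs$ref_hi_min,
    initial_model = modelled[, which(k_grid == 0)],
    final_model   = modelled[, best],
    row.names     = NULL
  )
  structure(list(k_star = k_grid[best], objective_value = objectives[best],
                 k_grid = k_grid, objectives = objectives, table = tab),
            class = "slope_calibration")
}

#' Validation table for a slope calibration
#'
#' One row per reference destination with the reference interval and the
#' modelled minutes before (k = 0) and after (k = `k_star`) calibration.
#'
#' @param result A `slope_calibration` from [calibrate_slope_factor()].
#' @param path Optional file path; if given the table is also written as CSV.
#' @return The validation data frame, invisibly if written to `path`.
#' @export
validation_report <- function(result, path = NULL) {
  stopifnot(inherits(result, "slope_calibration"))
  tab <- result$table
  tab$reference <- ifelse(tab$ref_lo_min == tab$ref_hi_min,
                          formatC(tab$ref_lo_min, format = "fg"),
                          paste0(tab$ref_lo_min, "-", tab$ref_hi_min))
  tab <- tab[, c("destination", "reference", "initial_model", "final_model")]
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' @export
print.slope_calibration <- function(x, ...) {
  cat(sprintf("<slope_calibration> k* = %g (objective %.4g over %d destinations)\n",
              x$k_star, x$objective_value, nrow(x$table)))
  print(validation_report(x), row.names = FALSE)
  invisible(x)
}

#' @export
plot.slope_calibration <- function(x, ...) {
  graphics::plot(x$k_grid, x$objectives, type = "b", xlab = "slope coefficient k",
                 ylab = "calibration objective", ...)
  graphics::abline(v = x$k_star, lty = 2)
  invisible(x)
}
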