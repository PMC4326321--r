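#' Best-case travel speed table
#'
#' Best-case speeds by surface class, in km/h: vehicle speeds on the road
#' network (80 primary, 55 secondary, 40 tracks), walking (1.75 km/h) on
#' foot-only terrain, and a near-zero sentinel speed for open water, which is
#' treated as essentially impassable but kept finite so accumulated costs stay
#' well-defined.
#'
#' @param primary_road,secondary_road,track,foot_only,water Speeds in km/h.
#' @return Named numeric vector of class `speed_table`.
#' @export
speed_table <- function(primary_road = 80, secondary_road = 55, track = 40,
                        foot_only = 1.75, water = 0.001) {
  s <- c(primary_road = primary_road, secondary_road = secondary_road,
         track = track, foot_only = foot_only, water = water)
  if (any(s <= 0)) stop("all speeds must be > 0")
  if (s[["water"]] > min(s)) stop("water speed must not exceed any other class speed")
  structure(s, class = "speed_table")
}

# km/h -> traversal cost in seconds per metre
kmh_to_spm <- function(speed_kmh) 3.6 / speed_kmh

#' Build a friction surface from a classified grid
#'
#' Converts each cell's class speed into a traversal cost in seconds per
#' metre (`3.6 / speed_kmh`). Nodata cells are untraversable (`NA` cost).
#' The slope coefficient of the returned surface is 0; see
#' [apply_slope_modifier()].
#'
#' @param classes A [classified_grid].
#' @param speeds A [speed_table].
#' @return An object of class `friction_surface` with fields `meta`,
#'   `cost` (s/m matrix, `NA` = untraversable) and `slope_factor_k`.
#' @export
build_friction <- function(classes, speeds = speed_table()) {
  stopifnot(inherits(classes, "classified_grid"))
  if (!inherits(speeds, "speed_table")) speeds <- do.call(speed_table, as.list(speeds))
  codes <- classes$codes
  present <- unique(codes[!is.na(codes)])
  known <- surface_classes[names(speeds)]
  missing <- setdiff(present, known)
  if (length(missing)) stop("no speed defined for class code(s): ", paste(missing, collapse = ", "))
  cost_by_code <- rep(NA_real_, max(surface_classes))
  cost_by_code[surface_classes[names(speeds)]] <- kmh_to_spm(unname(speeds))
  cost <- matrix(NA_real_, nrow(codes), ncol(codes))
  ok <- !is.na(codes)
  cost[ok] <- cost_by_code[codes[ok]]
  water <- !is.na(codes) & codes == surface_classes[["water"]]
  structure(list(meta = classes$meta, cost = cost, slope_factor_k = 0),
            water_mask = water,
            water_sentinel = kmh_to_spm(speeds[["water"]]),
            class = "friction_surface")
}

#' Apply a slope penalty to a friction surface
#'
#' Multiplies every cell's traversal cost by `1 + k * tan(slope)`, so flat
#' cells are unchanged and steep cells become proportionally slower. The same
#' penalty applies to all travel modes; water cells remain at the impassable
#' sentinel cost. Always applied to the surface's unpenalised (k = 0) cost,
#' so re-applying with a new `k` replaces rather than compounds the penalty.
#'
#' @param friction A [friction_surface] (with `slope_factor_k = 0`, as
#'   produced by [build_friction()], or a previously penalised surface, whose
#'   base cost is recovered from its stored slope grid).
#' @param slope A [slope_grid] of the same shape.
#' @param k Nonnegative slope coefficient (dimensionless; cost multiplier is
#'   `1 + k * tan(slope)`).
#' @return The penalised `friction_surface`, with `slope_factor_k = k`.
#' @export
apply_slope_modifier <- function(friction, slope, k) {
  stopifnot(inherits(friction, "friction_surface"), inherits(slope, "slope_grid"))
  if (!is.numeric(k) || length(k) != 1 || k < 0) stop("k must be a single nonnegative number")
  if (!same_grid(friction$meta, slope$meta)) stop("friction and slope grids do not align")
  if (any(slope$slope_deg >= 90, na.rm = TRUE)) stop("slope angles >= 90 degrees are not allowed")
  base <- friction_base_cost(friction)
  mult <- 1 + k * tan(slope$slope_deg * pi / 180)
  out <- friction
  out$cost <- base * mult
  # water keeps its sentinel cost: the cell is impassable regardless of slope
  sent <- attr(friction, "water_sentinel")
  if (!is.null(sent)) out$cost[friction_water_mask(friction)] <- sent
  out$slope_factor_k <- k
  attr(out, "base_cost") <- base
  out
}

# Unpenalised cost of a friction surface (cost as built from class speeds).
friction_base_cost <- function(friction) {
  b <- attr(friction, "base_cost")
  if (is.null(b)) friction$cost else b
}

friction_water_mask <- function(friction) {
  m <- attr(friction, "water_mask")
  if (is.null(m)) matrix(FALSE, nrow(friction$cost), ncol(friction$cost)) else m
}

#' @export
print.friction_surface <- function(x, ...) {
  rng <- range(x$cost, na.rm = TRUE)
  cat(sprintf("<friction_surface> %d x %d cells (%g m), cost %.4g-%.4g s/m, slope k = %g\n",
              x$meta$n_rows, x$meta$n_cols, x$meta$cell_size, rng[1], rng[2],
              x$slope_factor_k))
  invisible(x)
}

#' @export
plot.friction_surface <- function(x, main = "Friction (s/m, log scale)", ...) {
  z <- log10(t(x$cost)[, rev(seq_len(nrow(x$cost))), drop = FALSE])
  graphics::image(z, main = main, axes = FALSE, useRaster = TRUE, ...)
  invisible(x)
}
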