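#' Specification of a synthetic landscape
#'
#' Describes a landscape the travel-time engine can be exercised on: a
#' foot-only background crossed by road corridors, one or more mountain
#' zones with smoothed random elevation (slope derived by finite
#' differences), and water bodies. The default plan is a 20 x 20 km grid at
#' 100 m resolution with the facility on a west-east primary road, a
#' secondary road branching north, a track descending into a mountainous
#' south-east quadrant, and a river crossed by the primary road (the
#' crossing cell keeps the road class: a bridge).
#'
#' @param meta A [grid_meta] (default 200 x 200 cells of 100 m).
#' @param facility A [point_location] for the facility; must lie on a road.
#' @param road_plan List of polylines (`class`, `coords`) as for
#'   [rasterize_network()].
#' @param mountain_zones List of zones, each a list with `poly` (n x 2
#'   vertex matrix), `n_bumps`, `amp_m` (peak height range, metres) and
#'   `width_m` (bump SD range, metres).
#' @param water_bodies List of polygons (n x 2 vertex matrices).
#' @param n_villages Number of villages to place (default 12, placed in
#'   near/far and on-road/off-road strata).
#' @param rng_seed Seed for all randomness in [simulate_landscape()].
#' @return Object of class `landscape_spec`.
#' @export
landscape_spec <- function(meta = grid_meta(200, 200, 100),
                           facility = point_location(2050, 9950, "facility"),
                           road_plan = default_road_plan(),
                           mountain_zones = default_mountain_zones(),
                           water_bodies = default_water_bodies(),
                           n_villages = 12, rng_seed = 1L) {
  stopifnot(inherits(meta, "grid_meta"), inherits(facility, "point_location"))
  structure(list(meta = meta, facility = facility, road_plan = road_plan,
                 mountain_zones = mountain_zones, water_bodies = water_bodies,
                 n_villages = as.integer(n_villages), rng_seed = as.integer(rng_seed)),
            class = "landscape_spec")
}

#' @rdname landscape_spec
#' @export
default_road_plan <- function() {
  list(
    list(class = "primary_road",
         coords = rbind(c(150, 9950), c(19850, 9950))),
    list(class = "secondary_road",
         coords = rbind(c(10050, 9950), c(10050, 19000))),
    list(class = "track",
         coords = rbind(c(15050, 9950), c(17000, 6000), c(19000, 3000)))
  )
}

#' @rdname landscape_spec
#' @export
default_mountain_zones <- function() {
  list(list(poly = rbind(c(13000, 1000), c(20000, 1000), c(20000, 9000), c(13000, 9000)),
            n_bumps = 10, amp_m = c(300, 900), width_m = c(600, 1500)))
}

#' @rdname landscape_spec
#' @export
default_water_bodies <- function() {
  # a north-south river crossed by the primary road
  list(rbind(c(6000, 0), c(6400, 0), c(6400, 20000), c(6000, 20000)))
}

#' Generate a synthetic landscape
#'
#' Builds the classified surface (foot-only background, water bodies, then
#' roads burnt in with the fastest-class rule so road-river crossings are
#' bridges), derives a slope grid from smoothed random mountain elevation,
#' and places villages on traversable cells in near/far and on/off-road
#' strata (villages falling on water are rejected and resampled).
#' Deterministic under `spec$rng_seed`.
#'
#' @param spec A [landscape_spec()].
#' @return List: `classes` ([classified_grid]), `slope` ([slope_grid]),
#'   `facility` ([point_location]), `villages` (data frame label, x, y).
#' @export
simulate_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  meta <- spec$meta
  set.seed(spec$rng_seed)

  codes <- matrix(surface_classes[["foot_only"]], meta$n_rows, meta$n_cols)
  for (poly in spec$water_bodies) {
    codes[cells_in_polygon(meta, as.matrix(poly))] <- surface_classes[["water"]]
  }
  classes <- classified_grid(codes, meta)
  classes <- rasterize_network(classes, spec$road_plan)

  elev <- matrix(0, meta$n_rows, meta$n_cols)
  cx <- cell_centre_x(meta, seq_len(meta$n_cols))
  cy <- cell_centre_y(meta, seq_len(meta$n_rows))
  CX <- matrix(cx, meta$n_rows, meta$n_cols, byrow = TRUE)
  CY <- matrix(cy, meta$n_rows, meta$n_cols)
  for (zone in spec$mountain_zones) {
    inz <- cells_in_polygon(meta, as.matrix(zone$poly))
    if (!any(inz)) next
    zx <- range(zone$poly[, 1]); zy <- range(zone$poly[, 2])
    for (b in seq_len(zone$n_bumps)) {
      bx <- stats::runif(1, zx[1], zx[2]); by <- stats::runif(1, zy[1], zy[2])
      amp <- stats::runif(1, zone$amp_m[1], zone$amp_m[2])
      wd <- stats::runif(1, zone$width_m[1], zone$width_m[2])
      bump <- amp * exp(-((CX - bx)^2 + (CY - by)^2) / (2 * wd^2))
      bump[!inz] <- 0  # confine relief to the zone
      elev <- elev + bump
    }
  }
  slope <- slope_from_elevation(elev, meta)

  villages <- place_villages(classes, spec$facility, spec$n_villages)
  list(classes = classes, slope = slope, facility = spec$facility,
       villages = villages)
}

# Slope (degrees) from an elevation matrix by central finite differences.
slope_from_elevation <- function(elev, meta) {
  nr <- nrow(elev); nc <- ncol(elev); h <- meta$cell_size
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  if (nc >= 3) gx[, 2:(nc - 1)] <- (elev[, 3:nc] - elev[, 1:(nc - 2)]) / (2 * h)
  if (nr >= 3) gy[2:(nr - 1), ] <- (elev[3:nr, ] - elev[1:(nr - 2), ]) / (2 * h)
  deg <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  slope_grid(pmin(deg, 89.9), meta)
}

# Stratified village placement: on-road near/far, off-road, and mountain-zone
# cells, rejecting water. Labels v01, v02, ...
place_villages <- function(classes, facility, n_villages) {
  meta <- classes$meta
  codes <- classes$codes
  road <- which(codes %in% surface_classes[c("primary_road", "secondary_road", "track")])
  land <- which(codes == surface_classes[["foot_only"]])
  if (!length(road)) stop("landscape has no road cells to place villages on")
  ij <- function(idx) cbind(row = (idx - 1L) %% meta$n_rows + 1L,
                            col = (idx - 1L) %/% meta$n_rows + 1L)
  coord <- function(idx) {
    rc <- ij(idx)
    cbind(x = cell_centre_x(meta, rc[, "col"]), y = cell_centre_y(meta, rc[, "row"]))
  }
  dist_fac <- function(idx) {
    xy <- coord(idx)
    sqrt((xy[, "x"] - facility$x)^2 + (xy[, "y"] - facility$y)^2)
  }
  dr <- dist_fac(road)
  near_road <- road[dr <= stats::quantile(dr, 0.4) & dr > 2 * meta$cell_size]
  far_road <- road[dr > stats::quantile(dr, 0.6)]
  n_on <- ceiling(n_villages / 2)
  n_off <- n_villages - n_on
  pick <- c(sample(near_road, ceiling(n_on / 2)),
            sample(far_road, floor(n_on / 2)),
            sample(land, n_off))
  pick <- pick[seq_len(n_villages)]
  xy <- coord(pick)
  data.frame(label = sprintf("v%02d", seq_len(n_villages)),
             x = xy[, "x"], y = xy[, "y"])
}
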