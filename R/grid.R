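#' Surface class codes
#'
#' Integer codes used in classified grids. Travel speed decreases with the
#' code: primary roads are fastest, open water is effectively impassable.
#' `NA` marks nodata (untraversable, outside the study area).
#'
#' @format Named integer vector with elements `primary_road`, `secondary_road`,
#'   `track`, `foot_only`, `water`.
#' @export
surface_classes <- c(
  primary_road   = 1L,
  secondary_road = 2L,
  track          = 3L,
  foot_only      = 4L,
  water          = 5L
)

#' Grid metadata
#'
#' Describes a north-up raster on a projected metric coordinate system:
#' row 1 is the top row, cell centres sit at
#' `(origin_x + (col - 0.5) * cell_size, origin_y - (row - 0.5) * cell_size)`
#' where `(origin_x, origin_y)` is the grid's upper-left corner.
#'
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param cell_size Cell edge length in metres (default 100, the model's
#'   working resolution).
#' @param origin_x,origin_y Projected coordinates (metres) of the upper-left
#'   corner.
#' @param crs_note Free-text note about the projection.
#' @return An object of class `grid_meta`.
#' @export
grid_meta <- function(n_rows, n_cols, cell_size = 100,
                      origin_x = 0, origin_y = n_rows * cell_size,
                      crs_note = "") {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop("grid must have at least one row and one column")
  if (!is.numeric(cell_size) || cell_size <= 0) stop("cell_size must be > 0")
  structure(
    list(n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
         origin_x = origin_x, origin_y = origin_y, crs_note = crs_note),
    class = "grid_meta"
  )
}

#' @export
print.grid_meta <- function(x, ...) {
  cat(sprintf("<grid_meta> %d x %d cells, %g m resolution, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y))
  invisible(x)
}

same_grid <- function(a, b) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(c(a$origin_x, a$origin_y), c(b$origin_x, b$origin_y)))
}

# Cell-centre coordinates; i, j are 1-based row/column indices.
cell_centre_x <- function(meta, j) meta$origin_x + (j - 0.5) * meta$cell_size
cell_centre_y <- function(meta, i) meta$origin_y - (i - 0.5) * meta$cell_size

# Nearest cell (row, col) to a projected point; errors outside the extent.
point_to_cell <- function(meta, x, y, what = "point") {
  jf <- (x - meta$origin_x) / meta$cell_size
  if_ <- (meta$origin_y - y) / meta$cell_size
  if (jf < 0 || jf > meta$n_cols || if_ < 0 || if_ > meta$n_rows) {
    stop(sprintf("%s (%g, %g) lies outside the grid extent", what, x, y))
  }
  c(row = min(meta$n_rows, max(1L, as.integer(floor(if_)) + 1L)),
    col = min(meta$n_cols, max(1L, as.integer(floor(jf)) + 1L)))
}

#' Point location on the projected grid
#'
#' @param x,y Projected coordinates in metres.
#' @param label Optional free-text label.
#' @return An object of class `point_location`.
#' @export
point_location <- function(x, y, label = "") {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == 1, length(y) == 1)
  structure(list(x = x, y = y, label = as.character(label)),
            class = "point_location")
}

#' @export
print.point_location <- function(x, ...) {
  cat(sprintf("<point> %s(%g, %g)\n",
              if (nzchar(x$label)) paste0(x$label, " ") else "", x$x, x$y))
  invisible(x)
}

#' Classified surface grid
#'
#' @param codes Integer matrix of [surface_classes] codes; `NA` marks nodata.
#' @param meta A [grid_meta] matching `dim(codes)`.
#' @return An object of class `classified_grid`.
#' @export
classified_grid <- function(codes, meta) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (!inherits(meta, "grid_meta")) stop("meta must be a grid_meta")
  if (nrow(codes) != meta$n_rows || ncol(codes) != meta$n_cols) {
    stop("codes matrix does not match the grid dimensions in meta")
  }
  bad <- setdiff(unique(codes[!is.na(codes)]), surface_classes)
  if (length(bad)) stop("unknown surface class code(s): ", paste(bad, collapse = ", "))
  structure(list(meta = meta, codes = codes), class = "classified_grid")
}

#' Slope grid (degrees)
#'
#' @param slope_deg Numeric matrix of slope angles in degrees, `0 <= slope < 90`.
#' @param meta A [grid_meta] matching `dim(slope_deg)`.
#' @return An object of class `slope_grid`.
#' @export
slope_grid <- function(slope_deg, meta) {
  slope_deg <- as.matrix(slope_deg)
  if (!inherits(meta, "grid_meta")) stop("meta must be a grid_meta")
  if (nrow(slope_deg) != meta$n_rows || ncol(slope_deg) != meta$n_cols) {
    stop("slope matrix does not match the grid dimensions in meta")
  }
  rng <- range(slope_deg, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] >= 90) stop("slope angles must satisfy 0 <= slope < 90 degrees")
  structure(list(meta = meta, slope_deg = slope_deg), class = "slope_grid")
}

#' Burn road polylines into a classified grid
#'
#' Every cell whose centre lies within half a cell size of a polyline receives
#' that polyline's road class. Where classes overlap (a crossing, or a road
#' over water) the fastest class wins: a road crossing a river is a bridge.
#' All other cells are left unchanged.
#'
#' @param grid A [classified_grid] to burn into.
#' @param lines List of polylines; each is a list with elements `class`
#'   (a name from [surface_classes], one of the road classes) and `coords`
#'   (two-column matrix of projected x, y vertices).
#' @return The updated [classified_grid].
#' @export
rasterize_network <- function(grid, lines) {
  stopifnot(inherits(grid, "classified_grid"))
  if (length(lines) == 0L) return(grid)
  meta <- grid$meta
  xmin <- meta$origin_x; xmax <- meta$origin_x + meta$n_cols * meta$cell_size
  ymax <- meta$origin_y; ymin <- meta$origin_y - meta$n_rows * meta$cell_size

  cx <- cell_centre_x(meta, seq_len(meta$n_cols))
  cy <- cell_centre_y(meta, seq_len(meta$n_rows))
  # full centre coordinate matrices (row-major layout matches codes)
  CX <- matrix(cx, meta$n_rows, meta$n_cols, byrow = TRUE)
  CY <- matrix(cy, meta$n_rows, meta$n_cols)
  codes <- grid$codes
  half <- meta$cell_size / 2

  road_codes <- surface_classes[c("primary_road", "secondary_road", "track")]
  for (ln in lines) {
    cls <- ln$class
    if (!cls %in% names(road_codes)) {
      stop("polyline class must be a road class, got: ", cls)
    }
    v <- as.matrix(ln$coords)
    if (ncol(v) != 2L || nrow(v) < 2L) stop("polyline coords must be an n x 2 matrix with n >= 2")
    out <- v[, 1] < xmin | v[, 1] > xmax | v[, 2] < ymin | v[, 2] > ymax
    if (any(out)) {
      k <- which(out)[1]
      stop(sprintf("polyline vertex %d at (%g, %g) lies outside the grid extent",
                   k, v[k, 1], v[k, 2]))
    }
    code <- surface_classes[[cls]]
    hit <- matrix(FALSE, meta$n_rows, meta$n_cols)
    for (s in seq_len(nrow(v) - 1L)) {
      d <- dist_point_segment(CX, CY, v[s, 1], v[s, 2], v[s + 1, 1], v[s + 1, 2])
      hit <- hit | (d <= half)
    }
    # fastest class wins: smaller code = faster
    codes[hit] <- pmin(codes[hit], code, na.rm = TRUE)
  }
  classified_grid(codes, meta)
}

# Vectorised distance from points (px, py) to the segment (ax,ay)-(bx,by).
dist_point_segment <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- ((px - ax) * dx + (py - ay) * dy) / len2
  t <- pmin(1, pmax(0, t))
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

# Even-odd rule point-in-polygon test for cell centres; poly is an n x 2
# matrix of vertices (closed implicitly). Returns a logical matrix.
cells_in_polygon <- function(meta, poly) {
  cx <- cell_centre_x(meta, seq_len(meta$n_cols))
  cy <- cell_centre_y(meta, seq_len(meta$n_rows))
  CX <- matrix(cx, meta$n_rows, meta$n_cols, byrow = TRUE)
  CY <- matrix(cy, meta$n_rows, meta$n_cols)
  inside <- matrix(FALSE, meta$n_rows, meta$n_cols)
  n <- nrow(poly)
  jp <- n
  for (k in seq_len(n)) {
    xi <- poly[k, 1]; yi <- poly[k, 2]
    xj <- poly[jp, 1]; yj <- poly[jp, 2]
    crosses <- ((yi > CY) != (yj > CY)) &
      (CX < (xj - xi) * (CY - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    jp <- k
  }
  inside
}
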