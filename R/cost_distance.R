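#' Accumulated least-cost travel time from an origin
#'
#' Computes, for every cell, the minimum travel time from the origin over
#' 8-connected cell-centre paths. The cost of a step between adjacent cells is
#' the inter-centre distance (`cell_size`, or `cell_size * sqrt(2)` for a
#' diagonal step) multiplied by the arithmetic mean of the two cells'
#' frictions (s/m). Shortest paths are found with Dijkstra's label-setting
#' algorithm on the lattice graph; results are returned in minutes.
#'
#' Untraversable (nodata) cells and cells not connected to the origin carry
#' `NA` minutes and are flagged in the `reached` matrix.
#'
#' @param friction A [friction_surface].
#' @param origin A [point_location] inside the grid extent, on a traversable
#'   cell.
#' @return An object of class `cost_grid` with fields `meta`, `minutes`
#'   (matrix, `NA` = not reached), `reached` (logical matrix) and `origin`.
#' @export
accumulate_cost <- function(friction, origin) {
  stopifnot(inherits(friction, "friction_surface"), inherits(origin, "point_location"))
  meta <- friction$meta
  f <- friction$cost
  rc <- point_to_cell(meta, origin$x, origin$y, what = "origin")
  if (is.na(f[rc["row"], rc["col"]])) {
    stop(sprintf("origin %s falls on an untraversable (nodata) cell", origin$label))
  }
  nr <- meta$n_rows; nc <- meta$n_cols
  id <- function(i, j) (j - 1L) * nr + i  # column-major vertex index

  # Build undirected lattice edges once: E (right), S (down), SE, SW.
  edges_from <- integer(0); edges_to <- integer(0); w <- numeric(0)
  ii <- matrix(seq_len(nr), nr, nc)
  jj <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  step <- function(di, dj) {
    keep <- ii + di >= 1L & ii + di <= nr & jj + dj >= 1L & jj + dj <= nc
    a <- id(ii[keep], jj[keep])
    b <- id(ii[keep] + di, jj[keep] + dj)
    dist <- meta$cell_size * sqrt(di * di + dj * dj)
    wt <- dist * (f[a] + f[b]) / 2
    ok <- !is.na(wt)
    list(a = a[ok], b = b[ok], w = wt[ok])
  }
  for (d in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    e <- step(d[1], d[2])
    edges_from <- c(edges_from, e$a); edges_to <- c(edges_to, e$b); w <- c(w, e$w)
  }

  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(rbind(edges_from, edges_to)))
  seconds <- as.vector(igraph::distances(
    g, v = id(rc["row"], rc["col"]), weights = w, algorithm = "dijkstra"))
  minutes <- matrix(seconds / 60, nr, nc)
  reached <- is.finite(minutes)
  minutes[!reached] <- NA_real_
  structure(list(meta = meta, minutes = minutes, reached = reached,
                 traversable = !is.na(f),
                 origin = origin, origin_cell = rc),
            class = "cost_grid")
}

#' Extract the travel time at a point
#'
#' Snaps the point to the nearest cell centre (no interpolation: travel time
#' is not smooth across barriers) and returns that cell's accumulated time.
#'
#' @param grid A [cost_grid] from [accumulate_cost()].
#' @param point A [point_location] inside the grid extent.
#' @return Travel time in minutes.
#' @export
travel_time_at <- function(grid, point) {
  stopifnot(inherits(grid, "cost_grid"), inherits(point, "point_location"))
  rc <- point_to_cell(grid$meta, point$x, point$y,
                      what = if (nzchar(point$label)) point$label else "point")
  m <- grid$minutes[rc["row"], rc["col"]]
  if (is.na(m)) {
    why <- if (!grid$traversable[rc["row"], rc["col"]]) {
      "untraversable (nodata)"
    } else {
      "traversable but not reached from the origin"
    }
    stop(sprintf("point %s snaps to cell (%d, %d) which is %s",
                 point$label, rc["row"], rc["col"], why))
  }
  unname(m)
}

#' Straight-line (Euclidean) distance between two projected points
#'
#' @param a,b [point_location]s in the same projected metric system.
#' @return Distance in kilometres.
#' @export
euclidean_distance <- function(a, b) {
  stopifnot(inherits(a, "point_location"), inherits(b, "point_location"))
  sqrt((a$x - b$x)^2 + (a$y - b$y)^2) / 1000
}

#' @export
print.cost_grid <- function(x, ...) {
  cat(sprintf("<cost_grid> %d x %d cells from origin %s(%g, %g); %d/%d cells reached, max %.1f min\n",
              x$meta$n_rows, x$meta$n_cols,
              if (nzchar(x$origin$label)) paste0(x$origin$label, " ") else "",
              x$origin$x, x$origin$y,
              sum(x$reached), length(x$reached),
              max(x$minutes, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.cost_grid <- function(x, main = "Accumulated travel time (min)", ...) {
  z <- t(x$minutes)[, rev(seq_len(nrow(x$minutes))), drop = FALSE]
  graphics::image(z, main = main, axes = FALSE, useRaster = TRUE, ...)
  invisible(x)
}
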