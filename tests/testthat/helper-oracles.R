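# Independent oracles, deliberately implemented differently from the package:
# the cost-distance oracle is a Bellman-Ford label-correcting relaxation (the
# package uses Dijkstra via igraph), plus an exhaustive simple-path
# enumerator for very small grids; the Kruskal-Wallis oracle evaluates the
# mean-rank formula with the tie correction explicitly.

# Minimum accumulated seconds from origin over 8-connected paths, edge cost
# = distance x mean endpoint friction, by iterated relaxation to fixpoint.
oracle_accumulate_seconds <- function(f, cell_size, origin_rc) {
  nr <- nrow(f); nc <- ncol(f)
  d <- matrix(Inf, nr, nc)
  d[origin_rc[1], origin_rc[2]] <- 0
  moves <- expand.grid(di = -1:1, dj = -1:1)
  moves <- moves[!(moves$di == 0 & moves$dj == 0), ]
  repeat {
    changed <- FALSE
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (!is.finite(d[i, j]) || is.na(f[i, j])) next
      for (m in seq_len(nrow(moves))) {
        ii <- i + moves$di[m]; jj <- j + moves$dj[m]
        if (ii < 1 || ii > nr || jj < 1 || jj > nc || is.na(f[ii, jj])) next
        step <- cell_size * sqrt(moves$di[m]^2 + moves$dj[m]^2) * (f[i, j] + f[ii, jj]) / 2
        if (d[i, j] + step < d[ii, jj] - 1e-12) {
          d[ii, jj] <- d[i, j] + step
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  d
}

# Exhaustive enumeration of all simple 8-connected paths origin -> target.
oracle_enumerate_seconds <- function(f, cell_size, origin_rc, target_rc) {
  nr <- nrow(f); nc <- ncol(f)
  best <- Inf
  visited <- matrix(FALSE, nr, nc)
  recurse <- function(i, j, acc) {
    if (i == target_rc[1] && j == target_rc[2]) {
      best <<- min(best, acc)
      return()
    }
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      if (visited[ii, jj] || is.na(f[ii, jj])) next
      step <- cell_size * sqrt(di^2 + dj^2) * (f[i, j] + f[ii, jj]) / 2
      if (acc + step >= best) next  # cannot improve (costs are positive)
      visited[ii, jj] <<- TRUE
      recurse(ii, jj, acc + step)
      visited[ii, jj] <<- FALSE
    }
  }
  visited[origin_rc[1], origin_rc[2]] <- TRUE
  recurse(origin_rc[1], origin_rc[2], 0)
  best
}

# Kruskal-Wallis H with tie correction, from the rank formula written out.
oracle_kruskal_H <- function(y, g) {
  g <- factor(g)
  r <- rank(y)
  N <- length(y)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  H <- 12 / (N * (N + 1)) * sum(n * (rbar - (N + 1) / 2)^2)
  ties <- table(y)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# A small random friction grid with values spanning road-to-walking costs.
random_friction <- function(nr, nc, cell_size = 100) {
  f <- matrix(exp(stats::runif(nr * nc, log(0.045), log(2.06))), nr, nc)
  structure(list(meta = grid_meta(nr, nc, cell_size), cost = f, slope_factor_k = 0),
            class = "friction_surface")
}
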