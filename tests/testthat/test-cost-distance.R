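test_that("origin cell costs zero and uniform corridors follow the closed form", {
  g1 <- uniform_grid(1, 1, "track")
  cg <- accumulate_cost(build_friction(g1), centre_of(g1$meta, 1, 1))
  expect_equal(cg$minutes[1, 1], 0)

  # 1 x N primary corridor: a cell i cells from the origin costs i x 100 m x 0.045 s/m
  g <- uniform_grid(1, 11, "primary_road")
  cg <- accumulate_cost(build_friction(g), centre_of(g$meta, 1, 1, "origin"))
  expect_equal(cg$minutes[1, ] * 60, 4.5 * (0:10))
  expect_equal(travel_time_at(cg, centre_of(g$meta, 1, 11)), 0.75)  # 45 s at 10 cells
})

test_that("2D uniform grids follow the chebyshev-with-diagonals geodesic", {
  g <- uniform_grid(6, 9, "foot_only")
  f <- 3.6 / 1.75
  cg <- accumulate_cost(build_friction(g), centre_of(g$meta, 2, 3))
  for (i in c(1, 4, 6)) for (j in c(1, 5, 9)) {
    di <- abs(i - 2); dj <- abs(j - 3)
    path_len <- (sqrt(2) * min(di, dj) + abs(di - dj)) * 100
    expect_equal(cg$minutes[i, j], f * path_len / 60, tolerance = 1e-10)
  }
})

test_that("accumulated cost matches the path-enumeration oracle on a 3x3 grid with a costly centre", {
  f <- matrix(0.09, 3, 3)
  f[2, 2] <- 50  # high-cost centre: optimal paths must detour
  fr <- structure(list(meta = grid_meta(3, 3, 100), cost = f, slope_factor_k = 0),
                  class = "friction_surface")
  cg <- accumulate_cost(fr, centre_of(fr$meta, 1, 1))
  for (i in 1:3) for (j in 1:3) {
    expect_equal(cg$minutes[i, j] * 60,
                 oracle_enumerate_seconds(f, 100, c(1, 1), c(i, j)),
                 tolerance = 1e-9)
  }
})

test_that("accumulated cost equals brute-force shortest paths on random grids", {
  set.seed(42)
  for (rep in 1:25) {
    nr <- sample(4:5, 1); nc <- sample(4:5, 1)
    fr <- random_friction(nr, nc)
    oi <- sample(nr, 1); oj <- sample(nc, 1)
    cg <- accumulate_cost(fr, centre_of(fr$meta, oi, oj))
    expect_equal(cg$minutes * 60,
                 oracle_accumulate_seconds(fr$cost, 100, c(oi, oj)),
                 tolerance = 1e-9)
  }
})

test_that("times are symmetric in origin and destination", {
  set.seed(7)
  fr <- random_friction(5, 5)
  a <- c(1, 1); b <- c(4, 5)
  t_ab <- travel_time_at(accumulate_cost(fr, centre_of(fr$meta, a[1], a[2])),
                         centre_of(fr$meta, b[1], b[2]))
  t_ba <- travel_time_at(accumulate_cost(fr, centre_of(fr$meta, b[1], b[2])),
                         centre_of(fr$meta, a[1], a[2]))
  expect_equal(t_ab, t_ba, tolerance = 1e-12)
})

test_that("raising one cell's friction never shortens any travel time", {
  set.seed(11)
  fr <- random_friction(5, 4)
  cg0 <- accumulate_cost(fr, centre_of(fr$meta, 1, 1))
  for (rep in 1:5) {
    fr2 <- fr
    fr2$cost[sample(5, 1), sample(4, 1)] <- 10
    cg2 <- accumulate_cost(fr2, centre_of(fr$meta, 1, 1))
    expect_true(all(cg2$minutes - cg0$minutes >= -1e-12))
  }
})

test_that("point extraction snaps to the nearest centre and flags bad cells", {
  g <- uniform_grid(1, 10, "primary_road")
  cg <- accumulate_cost(build_friction(g), centre_of(g$meta, 1, 1))
  expect_equal(travel_time_at(cg, centre_of(g$meta, 1, 1)), 0)
  # 49 m from centre of cell 2, 51 m from centre of cell 1 -> cell 2
  expect_equal(travel_time_at(cg, point_location(150 + 1, 50)) * 60, 4.5)
  expect_error(travel_time_at(cg, point_location(-50, 50)), "outside")

  codes <- matrix(surface_classes[["primary_road"]], 1, 3)
  codes[1, 2] <- NA  # break the corridor
  fr <- build_friction(classified_grid(codes, grid_meta(1, 3)))
  cg <- accumulate_cost(fr, centre_of(fr$meta, 1, 1))
  expect_error(travel_time_at(cg, centre_of(fr$meta, 1, 2)), "untraversable")
  expect_error(travel_time_at(cg, centre_of(fr$meta, 1, 3)), "not reached")
  expect_error(accumulate_cost(fr, centre_of(fr$meta, 1, 2)), "nodata")
  expect_error(accumulate_cost(fr, point_location(1e6, 1e6)), "outside")
})

test_that("euclidean distances come out in km", {
  expect_equal(euclidean_distance(point_location(0, 0), point_location(0, 0)), 0)
  expect_equal(euclidean_distance(point_location(0, 0), point_location(3000, 4000)), 5)
  expect_equal(euclidean_distance(point_location(268000, 0), point_location(0, 0)), 268)
})
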