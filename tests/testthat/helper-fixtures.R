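# Small fixtures built in code.

# Uniform classified grid of one surface class.
uniform_grid <- function(nr, nc, class = "foot_only", cell_size = 100) {
  classified_grid(matrix(surface_classes[[class]], nr, nc),
                  grid_meta(nr, nc, cell_size))
}

# The centre coordinates of cell (i, j) for a grid's meta.
centre_of <- function(meta, i, j, label = "") {
  point_location(meta$origin_x + (j - 0.5) * meta$cell_size,
                 meta$origin_y - (i - 0.5) * meta$cell_size, label)
}

# A 3-row corridor landscape: a track along the middle row with a steep
# mountain section, used for slope-calibration tests. Returns friction at
# k = 0, the slope grid, the origin and a set of destination points.
mountain_corridor <- function(n_cols = 40, steep_cols = 15:30, slope_deg = 30) {
  cls <- uniform_grid(3, n_cols, "foot_only")
  codes <- cls$codes
  codes[2, ] <- surface_classes[["track"]]
  cls <- classified_grid(codes, cls$meta)
  sl <- matrix(0, 3, n_cols)
  sl[, steep_cols] <- slope_deg
  list(friction0 = build_friction(cls),
       slope = slope_grid(sl, cls$meta),
       origin = centre_of(cls$meta, 2, 1, "facility"),
       dest = centre_of(cls$meta, 2, n_cols, "far_end"),
       meta = cls$meta)
}

# A small cohort with a single active binary covariate (ratio `ratio`) and
# one pure-noise covariate, delays all positive when sigma is small.
toy_cohort <- function(n, ratio = 2, sigma = 0.2, alpha = log(2), seed = 1) {
  set.seed(seed)
  x <- factor(sample(c("ref", "exposed"), n, TRUE), levels = c("ref", "exposed"))
  z <- factor(sample(letters[1:3], n, TRUE))
  delay <- exp(alpha + log(ratio) * (x == "exposed") + rnorm(n, 0, sigma)) - 0.1
  data.frame(delay_hours = delay, exposure = x, noise = z)
}
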