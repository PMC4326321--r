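test_that("landscape generation is deterministic and respects its spec", {
  spec <- landscape_spec(rng_seed = 4)
  a <- simulate_landscape(spec)
  b <- simulate_landscape(spec)
  expect_identical(a$classes$codes, b$classes$codes)
  expect_identical(a$slope$slope_deg, b$slope$slope_deg)
  expect_identical(a$villages, b$villages)

  # no mountain zones -> slope identically zero
  flat <- simulate_landscape(landscape_spec(mountain_zones = list(), rng_seed = 1))
  expect_true(all(flat$slope$slope_deg == 0))

  # villages land on traversable (non-water) cells
  for (i in seq_len(nrow(a$villages))) {
    rc <- traveldelay:::point_to_cell(a$classes$meta, a$villages$x[i], a$villages$y[i])
    expect_false(a$classes$codes[rc["row"], rc["col"]] == surface_classes[["water"]])
  }
  # the river is water except where roads bridge it
  col_river <- 62  # x ~ 6150 m lies inside the default river strip
  river_col <- a$classes$codes[, col_river]
  expect_true(any(river_col == surface_classes[["water"]]))
  expect_true(any(river_col == surface_classes[["primary_road"]]))
})

test_that("an 80 km primary corridor gives a 60 minute modelled time", {
  g <- uniform_grid(1, 801, "foot_only")  # 80.1 km corridor, 100 m cells
  g <- rasterize_network(g, list(list(class = "primary_road",
                                      coords = rbind(c(0, 50), c(80100, 50)))))
  cg <- accumulate_cost(build_friction(g), centre_of(g$meta, 1, 1))
  expect_equal(travel_time_at(cg, centre_of(g$meta, 1, 801)), 60, tolerance = 1e-9)
})

test_that("cohort generation is deterministic and follows its closed form", {
  spec0 <- cohort_spec(n = 200, rng_seed = 9)
  mh <- c(v1 = 0.5, v2 = 2)
  s1 <- simulate_cohort(spec0, mh)
  s2 <- simulate_cohort(spec0, mh)
  expect_identical(s1, s2)
  expect_equal(s1$survey$reported_hours - s1$truth$modelled_hours,
               s1$truth$delay_hours, tolerance = 1e-12)

  # sigma = 0, everyone at reference, alpha = log(2.1), c0 = 0.1 -> delay 2.0
  dists <- lapply(default_covariate_distributions(), function(p) {
    q <- p; q[] <- 0; q[1] <- 1; q
  })
  spec <- cohort_spec(n = 50, covariate_distributions = dists,
                      alpha = log(2.1), sigma = 0, c0 = 0.1, rng_seed = 1)
  sim <- simulate_cohort(spec, mh)
  expect_equal(sim$truth$delay_hours, rep(2.0, 50), tolerance = 1e-12)

  # one-referral indicator on: (delay + 0.1) is exactly 4.9x the reference
  dists2 <- dists
  dists2$referrals <- c(none = 0, one = 1, two_plus = 0)
  sim2 <- simulate_cohort(cohort_spec(n = 50, covariate_distributions = dists2,
                                      alpha = log(2.1), sigma = 0, rng_seed = 1), mh)
  expect_equal((sim2$truth$delay_hours + 0.1) / (sim$truth$delay_hours + 0.1),
               rep(4.9, 50), tolerance = 1e-12)
})

test_that("cohort specs validate their probabilities and effects", {
  bad <- default_covariate_distributions()
  bad$season <- c(summer = 0.5, fall = 0.4)  # does not sum to 1
  expect_error(cohort_spec(covariate_distributions = bad), "sum to 1")
  expect_error(cohort_spec(effect_ratios = list(nonsense = c(a = 2))), "unknown variable")
  expect_error(cohort_spec(effect_ratios = list(referrals = c(zzz = 2))), "unknown level")
  expect_error(cohort_spec(effect_ratios = list(referrals = c(one = -1))), "> 0")
  expect_error(simulate_cohort(cohort_spec(n = 10), c(1, 2)), "named")
})

test_that("generator calibration hits its marginal targets and is reproducible", {
  cal <- calibrate_generator_defaults(n_mc = 50000, seed = 31)
  expect_equal(cal$achieved_median, 2.0, tolerance = 0.05)
  expect_equal(cal$achieved_share, 0.20, tolerance = 0.005)
  expect_true(cal$attained)
  cal2 <- calibrate_generator_defaults(n_mc = 50000, seed = 31)
  expect_identical(cal, cal2)

  # the documented cohort_spec defaults are the calibrated values
  spec <- cohort_spec()
  cal_big <- calibrate_generator_defaults()
  expect_equal(spec$alpha, cal_big$alpha, tolerance = 1e-6)
  expect_equal(spec$sigma, cal_big$sigma, tolerance = 1e-6)

  # a zero non-positive-share target collapses sigma toward the bound
  expect_warning(
    cal0 <- calibrate_generator_defaults(target_share_nonpositive = 0,
                                         n_mc = 20000, seed = 2),
    "bound")
  expect_false(cal0$attained)
})

test_that("delays can go negative but never below -c0, and large c0 triggers exclusions", {
  sim <- simulate_cohort(cohort_spec(n = 5000, rng_seed = 3), c(v = 1))
  d <- sim$truth$delay_hours
  expect_gt(mean(d <= 0), 0.1)   # a sizeable no-delay share
  expect_true(all(d > -0.1))     # support bounded by the generator offset
  # with a larger generator offset the implausible tail (delay <= -1) exists
  sim2 <- simulate_cohort(cohort_spec(n = 5000, c0 = 1.5, rng_seed = 3), c(v = 1))
  rec <- data.frame(delay_hours = sim2$truth$delay_hours)
  out <- apply_exclusions(rec)
  expect_gt(out$tally[["implausible_reported"]], 0)
})

test_that("null effect ratios lead to selections at the per-step alpha level", {
  n_any <- 0
  first_step_p <- c()
  for (s in 1:10) {
    spec <- cohort_spec(n = 300, effect_ratios = list(), sigma = 1,
                        alpha = 0.7, rng_seed = 700 + s)
    sim <- simulate_cohort(spec, c(v = 1))
    fit <- fit_log_delay_model(sim$truth,
                               c("referrals", "transport_difficulty",
                                 "complication", "rely_network"),
                               offset = 0.1)
    n_any <- n_any + (length(fit$selected) > 0)
    first_step_p <- c(first_step_p, fit$lrt_trace[[1]]$p)
  }
  # 4 candidates at 0.05: P(any selected) ~ 1 - 0.95^4 ~ 19%
  expect_lte(n_any, 7)
  # per-candidate first-step rejections near the nominal level
  expect_lt(mean(first_step_p < 0.05), 0.25)
})
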