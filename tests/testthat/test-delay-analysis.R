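test_that("delay is reported minus modelled, with missingness flagged", {
  d <- compute_delay(c(3.6, 2, 0.5, NA), c(1, 2, 2, 1))
  expect_equal(d$delay_hours, c(2.6, 0, -1.5, NA))
  expect_equal(d$delay_missing, c(FALSE, FALSE, FALSE, TRUE))
  expect_error(compute_delay(-1, 1), "nonnegative")
})

test_that("exclusion boundary at -1 h is inclusive and reasons partition the cohort", {
  rec <- data.frame(delay_hours = c(2, -1.0, -0.99, NA, 0.5),
                    expo = c("a", "a", "b", "a", NA))
  out <- apply_exclusions(rec, exposure_cols = "expo")
  expect_equal(unname(out$tally),
               c(1L, 1L, 1L, 2L))  # no_coords, implausible, missing_exposure, none
  expect_equal(sum(out$tally), nrow(rec))
  expect_equal(out$excluded$exclusion_reason[out$excluded$delay_hours %in% -1],
               "implausible_reported")
  expect_true(-0.99 %in% out$included$delay_hours)  # boundary complement kept
  # each excluded record carries exactly one reason
  expect_true(all(out$excluded$exclusion_reason != "none"))
})

test_that("SES weights are inverse ownership proportions and quartiles balance", {
  # 4 households; item A owned by 2 (w = 2), item B owned by 1 (w = 4)
  flags <- cbind(A = c(1, 1, 0, 0), B = c(1, 0, 0, 0))
  idx <- ses_index(flags)
  expect_equal(unname(idx$item_weights), c(2, 4))
  expect_equal(idx$household_scores[1], 6)  # owns both

  # 8 distinct scores -> exactly 2 per quartile
  set.seed(1)
  f8 <- cbind(a = c(0, 0, 0, 0, 1, 1, 1, 1), b = c(0, 0, 1, 1, 0, 1, 1, 1),
              c = c(0, 1, 0, 1, 1, 0, 1, 1))
  idx8 <- ses_index(f8)
  if (length(unique(idx8$household_scores)) == 8) {
    expect_equal(unname(table(idx8$quartile)), rep(2L, 4))
  }

  # all households identical -> one tied group, never split across quartiles
  same <- cbind(a = rep(1, 6))
  expect_equal(length(unique(ses_index(same)$quartile)), 1L)

  # an item nobody owns is dropped with a warning
  expect_warning(ses_index(cbind(a = c(1, 0), b = c(0, 0))), "no household")
})

test_that("SES quartiles are invariant to rescaling all weights", {
  set.seed(3)
  flags <- matrix(rbinom(200, 1, 0.4), 50, 4)
  colnames(flags) <- letters[1:4]
  idx <- ses_index(flags)
  # doubling every weight doubles scores but cannot change quartiles
  s2 <- 2 * idx$household_scores
  qs <- stats::quantile(s2, c(0.25, 0.5, 0.75))
  q2 <- cut(s2, c(-Inf, qs, Inf), labels = levels(idx$quartile),
            include.lowest = TRUE, ordered_result = TRUE)
  expect_equal(as.integer(q2), as.integer(idx$quartile))
})

test_that("group summaries reproduce the Kruskal-Wallis rank statistic", {
  d <- data.frame(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 4, 5, 6))
  gs <- describe_by_factor(d, "g", "y")
  expect_equal(gs$kw_H, 3.857, tolerance = 5e-4)
  expect_equal(gs$kw_df, 1)
  expect_equal(gs$summary$median, c(2, 5))
  expect_equal(gs$summary$q1, c(1.5, 4.5))
  expect_equal(gs$summary$q3, c(2.5, 5.5))

  # identical groups -> H = 0; all-identical values -> H = 0, p = 1
  d2 <- data.frame(g = rep(c("a", "b"), each = 4), y = rep(1:4, 2))
  expect_equal(describe_by_factor(d2, "g", "y")$kw_H, 0)
  d3 <- data.frame(g = rep(c("a", "b"), 5), y = rep(7, 10))
  gs3 <- describe_by_factor(d3, "g", "y")
  expect_equal(gs3$kw_H, 0)
  expect_equal(gs3$kw_p, 1)
})

test_that("tied data match a brute-force rank computation", {
  set.seed(9)
  for (rep in 1:20) {
    y <- sample(1:6, 24, replace = TRUE)  # heavy ties
    g <- sample(c("a", "b", "c"), 24, replace = TRUE)
    if (length(unique(g)) < 2 || length(unique(y)) == 1) next
    gs <- describe_by_factor(data.frame(g = g, y = y), "g", "y")
    expect_equal(gs$kw_H, oracle_kruskal_H(y, g), tolerance = 1e-10)
  }
})

test_that("the log-shift rule follows min-shift plus margin, or a fixed constant", {
  tr <- log_transform_delay(c(0.5, 2, 10))
  expect_equal(tr$offset_c, 0.1)
  expect_equal(tr$y, log(c(0.5, 2, 10) + 0.1))

  tr2 <- log_transform_delay(c(-2, 0, 3))
  expect_equal(tr2$offset_c, 2.1)
  expect_equal(min(tr2$y), log(0.1))  # smallest delay maps to log(margin)

  tr3 <- log_transform_delay(c(0.5, 2), offset = 0.25)
  expect_equal(tr3$offset_c, 0.25)
  expect_error(log_transform_delay(c(-1, 2), offset = 0.5), "positive")
  expect_error(log_transform_delay(numeric(0)), "no delays")
  expect_error(log_transform_delay(c(1, Inf)), "finite")
})

test_that("ratios back-transform with symmetric log-scale intervals", {
  expect_equal(unname(back_transform_ratios(0, 0)[1, ]), c(1, 1, 1))
  expect_equal(unname(back_transform_ratios(log(2), 0)[1, ]), c(2, 2, 2))
  bt <- back_transform_ratios(0.5, 0.2)
  expect_equal(unname(bt[1, "ratio"]), exp(0.5))
  expect_equal(unname(bt[1, "ci_lo"] * bt[1, "ci_hi"]), exp(1), tolerance = 1e-12)
  expect_error(back_transform_ratios(1, -0.1), "nonnegative")
})
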