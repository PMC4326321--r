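test_that("a strong binary effect is selected and its ratio recovered", {
  d <- toy_cohort(5000, ratio = 2, sigma = 0.2)
  fit <- delay_lm(delay_hours ~ exposure + noise, data = d)
  expect_true("exposure" %in% fit$selected)
  r <- fit$ratios
  est <- r$ratio[r$term == "exposure" & r$level == "exposed"]
  expect_gt(est, 1.9)
  expect_lt(est, 2.1)
  # reference level carries ratio exactly 1
  expect_equal(r$ratio[r$reference], rep(1, sum(r$reference)))
  # CI brackets the estimate
  expect_true(all(r$ci_lo <= r$ratio & r$ratio <= r$ci_hi))
})

test_that("noise-free generation is recovered exactly", {
  d <- toy_cohort(400, ratio = 4.9, sigma = 0)
  # an exact fit makes summary.lm grumble; the point estimates are still exact
  fit <- suppressWarnings(delay_lm(delay_hours ~ exposure, data = d))
  r <- fit$ratios
  expect_equal(r$ratio[r$level == "exposed"], 4.9, tolerance = 1e-9)
  expect_equal(fit$offset_c, 0.1)  # delays all positive under the rule
})

test_that("pure-noise candidates usually yield the intercept-only model", {
  picks <- vapply(1:20, function(s) {
    set.seed(s + 100)
    d <- data.frame(delay_hours = exp(rnorm(1000, 0.5, 1)) - 0.1,
                    a = factor(sample(letters[1:2], 1000, TRUE)),
                    b = factor(sample(letters[1:3], 1000, TRUE)),
                    c = factor(sample(letters[1:4], 1000, TRUE)))
    fit <- delay_lm(delay_hours ~ a + b + c, data = d)
    length(fit$selected)
  }, numeric(1))
  # three candidates at the 0.05 per-step level: expect roughly
  # 1 - 0.95^3 ~ 14% of replicates to admit any variable
  expect_gte(sum(picks == 0), 10)
})

test_that("each selection step increases the log-likelihood and obeys the trace", {
  d <- toy_cohort(2000, ratio = 3, sigma = 0.5, seed = 5)
  fit <- delay_lm(delay_hours ~ exposure + noise, data = d)
  for (tr in fit$lrt_trace) {
    expect_true(all(tr$statistic >= 0, na.rm = TRUE))  # LR never negative
    expect_true(all(tr$df >= 1, na.rm = TRUE))
  }
  # selected terms were each significant at their inclusion step
  for (s in seq_along(fit$selected)) {
    tr <- fit$lrt_trace[[s]]
    expect_lt(tr$p[tr$term == fit$selected[s]], fit$alpha)
  }
})

test_that("tie-break and reference handling follow the declared order", {
  # two copies of the same covariate: the first in the formula wins the tie
  d <- toy_cohort(800, ratio = 3, sigma = 0.3, seed = 11)
  d$exposure2 <- d$exposure
  expect_warning(fit <- delay_lm(delay_hours ~ exposure + exposure2, data = d),
                 "degenerate")
  expect_equal(fit$selected[1], "exposure")
  # the duplicate is collinear and gets skipped
  expect_length(fit$selected, 1)
})

test_that("degenerate inputs error or warn rather than mislead", {
  d <- toy_cohort(50, sigma = 0.3)
  expect_error(delay_lm(delay_hours ~ exposure, data = d[0, ]), "complete cases|no delays")
  d$onelevel <- factor("x")
  fit <- suppressWarnings(delay_lm(delay_hours ~ onelevel, data = d))
  expect_length(fit$selected, 0)
})

test_that("the F-test variant agrees with the chi-square LRT on strong effects", {
  d <- toy_cohort(1000, ratio = 2.5, sigma = 0.4, seed = 3)
  f1 <- delay_lm(delay_hours ~ exposure + noise, data = d, test = "lrt")
  f2 <- delay_lm(delay_hours ~ exposure + noise, data = d, test = "f")
  expect_equal(f1$selected, f2$selected)
  expect_equal(f1$ratios$ratio, f2$ratios$ratio, tolerance = 1e-10)
})

test_that("methods behave like a classic modelling object", {
  d <- toy_cohort(500, ratio = 2, sigma = 0.3, seed = 2)
  fit <- delay_lm(delay_hours ~ exposure + noise, data = d)
  expect_s3_class(fit, "delay_lm")
  expect_output(print(fit), "selected")
  expect_output(print(summary(fit)), "Log-scale fit")
  expect_named(coef(fit))
  ci <- confint(fit)
  expect_true(all(ci[, 1] < ci[, 2]))
  p <- predict(fit)
  expect_length(p, fit$n)
  # prediction inverts the link: exp(eta) - c
  expect_equal(p, exp(predict(fit, type = "log")) - fit$offset_c)
  expect_length(residuals(fit), fit$n)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(fit$n, 2))
  expect_true(all(sims > -fit$offset_c))
})

test_that("generating ratios fall inside the fitted 95% CI at the nominal rate", {
  cover <- matrix(NA, 30, 2)
  for (s in 1:30) {
    d <- toy_cohort(2000, ratio = 2, sigma = 1.5, alpha = 0, seed = s + 500)
    fit <- delay_lm(delay_hours ~ exposure + noise, data = d, offset = 0.1)
    r <- fit$ratios
    row <- r[r$term == "exposure" & r$level == "exposed", ]
    if (nrow(row) == 1) cover[s, ] <- c(row$ci_lo <= 2, 2 <= row$ci_hi)
  }
  hit <- rowSums(cover) == 2
  expect_gte(mean(hit, na.rm = TRUE), 0.9)
})
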