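#' Forward-selection log-linear model for travel delays
#'
#' Fits a linear regression of `log(delay + c)` on categorical risk factors,
#' building the model by forward selection: at each step every remaining
#' candidate term is added to the current model, the likelihood-ratio
#' chi-square against the current model is computed (normal-theory
#' likelihood, df = number of added indicator columns), and the candidate
#' with the smallest p-value is added if `p < alpha`; ties are broken by the
#' order the terms appear in the formula. Selection stops when no candidate
#' qualifies. Coefficients are reported back-transformed as adjusted
#' ratios — multiplicative effects on `delay + c` relative to each factor's
#' reference level — with normal-approximation confidence intervals.
#'
#' Only complete cases over the outcome and all candidate terms are used
#' (complete-case analysis; no imputation).
#'
#' @param formula Model formula, `delay_hours ~ factor1 + factor2 + ...`.
#'   The left-hand side is the delay in hours; right-hand-side terms are the
#'   candidate risk factors, in tie-break order.
#' @param data Data frame holding the outcome and candidates.
#' @param alpha Per-step inclusion level for the likelihood-ratio test
#'   (default 0.05).
#' @param conf_z Normal quantile for the ratio confidence intervals
#'   (default 1.96, a 95% interval).
#' @param margin_hours Margin for the log-shift rule of
#'   [log_transform_delay()] (default 0.1 h).
#' @param offset Optional fixed log-shift constant in hours, overriding the
#'   data-driven rule (see [log_transform_delay()]).
#' @param test `"lrt"` (default) for the normal-theory likelihood-ratio
#'   chi-square, or `"f"` for the exact nested-model F-test.
#' @return An object of class `delay_lm`; see [summary.delay_lm()].
#'   Components include `selected` (terms in inclusion order), `fit` (the
#'   underlying `lm` on the log scale), `ratios` (adjusted-ratio table),
#'   `offset_c`, and `lrt_trace` (per-step candidate p-values).
#' @seealso [back_transform_ratios()], [log_transform_delay()]
#' @export
delay_lm <- function(formula, data, alpha = 0.05, conf_z = 1.96,
                     margin_hours = 0.1, offset = NULL, test = c("lrt", "f")) {
  test <- match.arg(test)
  data <- as.data.frame(data)
  outcome <- all.vars(formula[[2]])
  if (length(outcome) != 1L || !outcome %in% names(data)) {
    stop("the formula's left-hand side must be a single column of data")
  }
  candidates <- attr(stats::terms(formula, data = data), "term.labels")
  if (length(candidates) == 0L) stop("no candidate terms in the formula")
  keep <- stats::complete.cases(data[, c(outcome, candidates), drop = FALSE])
  d <- data[keep, , drop = FALSE]
  if (nrow(d) < 3L) stop("too few complete cases to fit a model (n = ", nrow(d), ")")
  for (v in candidates) if (!is.numeric(d[[v]])) d[[v]] <- droplevels(factor(d[[v]]))

  tr <- log_transform_delay(d[[outcome]], margin_hours = margin_hours, offset = offset)
  d$.y <- tr$y

  selected <- character(0)
  remaining <- candidates
  current <- stats::lm(.y ~ 1, data = d)
  trace <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    ll0 <- stats::logLik(current)
    cand_p <- rep(NA_real_, length(remaining))
    names(cand_p) <- remaining
    cand_stat <- cand_df <- cand_p
    for (ci in seq_along(remaining)) {
      v <- d[[remaining[ci]]]
      if (is.factor(v) && nlevels(v) < 2L) next  # constant: degenerate
      fml <- stats::reformulate(c(selected, remaining[ci]), response = ".y")
      fit1 <- tryCatch(stats::lm(fml, data = d), error = function(e) NULL)
      if (is.null(fit1)) next
      df1 <- length(stats::coef(fit1)) - sum(is.na(stats::coef(fit1)))
      ddf <- df1 - (length(stats::coef(current)) - sum(is.na(stats::coef(current))))
      if (ddf < 1L || nrow(d) <= df1) next  # collinear/degenerate: skip
      if (test == "lrt") {
        stat <- as.numeric(2 * (stats::logLik(fit1) - ll0))
        stat <- max(stat, 0)
        p <- stats::pchisq(stat, df = ddf, lower.tail = FALSE)
      } else {
        a <- stats::anova(current, fit1)
        stat <- a$F[2]; p <- a$`Pr(>F)`[2]
      }
      cand_stat[ci] <- stat; cand_df[ci] <- ddf; cand_p[ci] <- p
    }
    if (all(is.na(cand_p))) {
      if (length(remaining)) warning("remaining candidate(s) skipped as degenerate: ",
                                     paste(remaining, collapse = ", "))
      break
    }
    trace[[step]] <- data.frame(term = remaining, statistic = unname(cand_stat),
                                df = unname(cand_df), p = unname(cand_p),
                                row.names = NULL)
    best <- which(cand_p == min(cand_p, na.rm = TRUE))[1]  # ties: formula order
    if (is.na(cand_p[best]) || cand_p[best] >= alpha) break
    selected <- c(selected, remaining[best])
    remaining <- remaining[-best]
    current <- stats::lm(stats::reformulate(selected, response = ".y"), data = d)
    if (length(remaining) == 0L) break
  }

  ratios <- ratio_table(current, d, selected, conf_z)
  structure(list(call = match.call(), formula = formula, selected = selected,
                 candidates = candidates, fit = current, ratios = ratios,
                 offset_c = tr$offset_c, alpha = alpha, conf_z = conf_z,
                 test = test, n = nrow(d), n_dropped = sum(!keep),
                 lrt_trace = trace, data = d),
            class = "delay_lm")
}

# Adjusted-ratio table including reference rows (ratio exactly 1).
ratio_table <- function(fit, d, selected, conf_z) {
  if (length(selected) == 0L) {
    return(data.frame(term = character(0), level = character(0),
                      reference = logical(0), beta = numeric(0), se = numeric(0),
                      ratio = numeric(0), ci_lo = numeric(0), ci_hi = numeric(0),
                      p = numeric(0)))
  }
  sm <- stats::coef(summary(fit))
  rows <- list()
  for (v in selected) {
    x <- d[[v]]
    if (is.numeric(x)) {
      nm <- v
      b <- sm[nm, "Estimate"]; se <- sm[nm, "Std. Error"]; p <- sm[nm, "Pr(>|t|)"]
      bt <- back_transform_ratios(b, se, conf_z)
      rows[[length(rows) + 1L]] <- data.frame(
        term = v, level = v, reference = FALSE, beta = b, se = se,
        ratio = bt[, "ratio"], ci_lo = bt[, "ci_lo"], ci_hi = bt[, "ci_hi"], p = p)
    } else {
      levs <- levels(x)
      rows[[length(rows) + 1L]] <- data.frame(
        term = v, level = levs[1], reference = TRUE, beta = 0, se = 0,
        ratio = 1, ci_lo = 1, ci_hi = 1, p = NA_real_)
      for (lv in levs[-1]) {
        nm <- paste0(v, lv)
        if (!nm %in% rownames(sm)) next  # dropped as collinear
        b <- sm[nm, "Estimate"]; se <- sm[nm, "Std. Error"]; p <- sm[nm, "Pr(>|t|)"]
        bt <- back_transform_ratios(b, se, conf_z)
        rows[[length(rows) + 1L]] <- data.frame(
          term = v, level = lv, reference = FALSE, beta = b, se = se,
          ratio = bt[, "ratio"], ci_lo = bt[, "ci_lo"], ci_hi = bt[, "ci_hi"], p = p)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.delay_lm <- function(x, digits = 3, ...) {
  cat("Forward-selection log-linear delay model\n")
  cat(sprintf("  n = %d complete cases (%d dropped), offset c = %.3g h\n",
              x$n, x$n_dropped, x$offset_c))
  if (length(x$selected) == 0L) {
    cat("  no candidate passed the inclusion test; intercept-only model\n")
  } else {
    cat("  selected (in order):", paste(x$selected, collapse = ", "), "\n\n")
    tab <- x$ratios
    tab$ratio <- round(tab$ratio, digits)
    tab$ci <- ifelse(tab$reference, "reference",
                     sprintf("[%s, %s]", format(round(tab$ci_lo, digits)),
                             format(round(tab$ci_hi, digits))))
    print(tab[, c("term", "level", "ratio", "ci")], row.names = FALSE)
  }
  invisible(x)
}

#' Summary of a fitted delay model
#'
#' @param object A `delay_lm` fit.
#' @param ... Unused.
#' @return Object of class `summary.delay_lm`: the adjusted-ratio table, the
#'   selection trace, the offset, and the underlying `lm` summary.
#' @export
summary.delay_lm <- function(object, ...) {
  structure(list(model = object, lm_summary = summary(object$fit)),
            class = "summary.delay_lm")
}

#' @export
print.summary.delay_lm <- function(x, ...) {
  print(x$model)
  cat(sprintf("\nLog-scale fit: residual SD %.3f on %d df, R-squared %.3f\n",
              x$lm_summary$sigma, x$lm_summary$df[2], x$lm_summary$r.squared))
  if (length(x$model$lrt_trace)) {
    cat("\nSelection trace (per-step candidate p-values):\n")
    for (s in seq_along(x$model$lrt_trace)) {
      tr <- x$model$lrt_trace[[s]]
      best <- tr$term[which.min(tr$p)]
      cat(sprintf("  step %d: best %s (p = %.3g)\n", s, best, min(tr$p, na.rm = TRUE)))
    }
  }
  invisible(x)
}

#' @export
coef.delay_lm <- function(object, ...) stats::coef(object$fit)

#' Confidence intervals for adjusted ratios
#'
#' @param object A `delay_lm` fit.
#' @param parm Ignored (all selected terms are returned).
#' @param level Confidence level (default 0.95).
#' @param ... Unused.
#' @return Matrix of ratio-scale lower/upper bounds, one row per non-reference
#'   coefficient.
#' @export
confint.delay_lm <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  tab <- object$ratios[!object$ratios$reference, , drop = FALSE]
  bt <- back_transform_ratios(tab$beta, tab$se, z)
  out <- bt[, c("ci_lo", "ci_hi"), drop = FALSE]
  rownames(out) <- paste0(tab$term, ":", tab$level)
  colnames(out) <- sprintf("%g %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  out
}

#' Predict delays from a fitted delay model
#'
#' @param object A `delay_lm` fit.
#' @param newdata Data frame of covariates; defaults to the fitting data.
#' @param type `"delay"` (default) for the median predicted delay in hours
#'   (`exp(X beta) - c`), or `"log"` for the linear predictor on the
#'   log(delay + c) scale.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.delay_lm <- function(object, newdata = NULL, type = c("delay", "log"), ...) {
  type <- match.arg(type)
  eta <- if (is.null(newdata)) stats::predict(object$fit)
         else stats::predict(object$fit, newdata = as.data.frame(newdata))
  if (type == "log") eta else exp(eta) - object$offset_c
}

#' @export
residuals.delay_lm <- function(object, ...) stats::residuals(object$fit)

#' Simulate delays from a fitted delay model
#'
#' Draws new log-normal delays from the fitted model: the linear predictor
#' plus normal noise at the estimated residual SD, back-transformed by
#' subtracting the offset.
#'
#' @param object A `delay_lm` fit.
#' @param nsim Number of simulated replicates.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns of simulated delays (hours).
#' @export
simulate.delay_lm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  eta <- stats::predict(object$fit)
  sd <- summary(object$fit)$sigma
  out <- replicate(nsim, exp(eta + stats::rnorm(length(eta), 0, sd)) - object$offset_c)
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}

#' @export
plot.delay_lm <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  r <- stats::residuals(x$fit)
  graphics::plot(stats::fitted(x$fit), r, xlab = "fitted log(delay + c)",
                 ylab = "residual", main = "Residuals vs fitted", ...)
  graphics::abline(h = 0, lty = 2)
  stats::qqnorm(r, main = "Normal Q-Q of residuals")
  stats::qqline(r)
  invisible(x)
}

#' Forward-selection delay regression (pipeline form)
#'
#' Convenience wrapper around [delay_lm()] taking a character vector of
#' candidate columns (in tie-break order) instead of a formula.
#'
#' @param records Data frame with a `delay_hours` column and the candidates.
#' @param candidates Character vector of candidate column names.
#' @param ... Passed to [delay_lm()].
#' @return A `delay_lm` fit.
#' @export
fit_log_delay_model <- function(records, candidates, ...) {
  delay_lm(stats::reformulate(candidates, response = "delay_hours"),
           data = records, ...)
}
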