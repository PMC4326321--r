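#' Default covariate distributions for the synthetic cohort
#'
#' Category probabilities for every survey risk factor, in the order the
#' variables enter the candidate list (which is also the forward-selection
#' tie-break order). Within each variable the first level is the regression
#' reference level (self-referral, PPH, "not difficult" transport, the "3-4"
#' reliance band). Probabilities follow the published cohort margins where a
#' descriptive table prints them, and are uniform-ish otherwise.
#'
#' @return Named list of named probability vectors.
#' @export
default_covariate_distributions <- function() {
  norm <- function(x) x / sum(x)
  list(
    referrals = norm(c(none = 0.397, one = 0.431, two_plus = 0.172)),
    occupation = norm(c(labourer = 0.378, farming = 0.338, business = 0.167,
                        professional = 0.065, other = 0.052)),
    husband_education = norm(c(no = 0.615, yes = 0.385)),
    community_participation = norm(c(no = 0.669, yes = 0.331)),
    borrow_network = norm(c(`0` = 0.058, `1-2` = 0.347, `3-4` = 0.344, `5+` = 0.248)),
    rely_network = norm(c(`3-4` = 0.056, `0` = 0.518, `1-2` = 0.336, `5+` = 0.091)),
    household_type = norm(c(nuclear = 0.549, extended = 0.451)),
    birth_family_near = norm(c(yes = 0.777, no = 0.223)),
    season = norm(c(summer = 0.219, fall = 0.254, winter = 0.259, spring = 0.269)),
    urban_rural = norm(c(rural = 0.749, urban = 0.251)),
    complication = norm(c(pph = 0.119, haem_early = 0.149, severe_preeclampsia = 0.127,
                          aph = 0.136, eclampsia = 0.231, impending_rupture = 0.094,
                          uterine_rupture = 0.074, severe_infection = 0.060,
                          other = 0.010)),
    anc_visits = norm(c(none = 0.328, `1-3` = 0.429, `4+` = 0.243)),
    parity = norm(c(nullipara = 0.292, `1-2` = 0.209, `3-5` = 0.257, `6+` = 0.241)),
    ambulance = norm(c(no = 0.847, yes = 0.153)),
    community_vehicle = norm(c(yes = 0.889, no = 0.111)),
    transport_difficulty = norm(c(not = 0.536, moderately = 0.315, very = 0.150))
  )
}

#' Default multiplicative effects for the synthetic cohort
#'
#' True adjusted ratios used as generating truth: one referral 4.9 and two or
#' more referrals 19.5 (vs self-referral), transport "very difficult" 2.1
#' (vs not difficult), severe infection 2.6 (vs PPH) and a 5+ reliance
#' network 2.0 (vs the 3-4 band). All other levels have ratio 1.
#'
#' @return Named list: per variable, a named vector of per-level ratios.
#' @export
default_effect_ratios <- function() {
  list(
    referrals = c(one = 4.9, two_plus = 19.5),
    transport_difficulty = c(very = 2.1),
    complication = c(severe_infection = 2.6),
    rely_network = c(`5+` = 2.0)
  )
}

# Household asset items and ownership probabilities driving the SES index.
default_ses_items <- function() {
  c(radio = 0.70, land = 0.55, bicycle = 0.45, tv = 0.35,
    motorcycle = 0.25, car = 0.08)
}

#' Specification of a synthetic survey cohort
#'
#' The generative model mirrors the analysis model: each woman's delay
#' satisfies `log(delay + c0) = alpha + sum(log(ratio) * indicator) + eps`
#' with `eps ~ N(0, sigma^2)`, covariates drawn independently, and
#' `reported = modelled + delay`. The default `alpha` and `sigma` are the
#' values returned by [calibrate_generator_defaults()], chosen so the
#' marginal delay distribution has a median of about 2.0 hours with about
#' 20% of delays non-positive.
#'
#' @param n Cohort size (default 5000).
#' @param covariate_distributions See [default_covariate_distributions()].
#' @param effect_ratios See [default_effect_ratios()]; all ratios > 0.
#' @param alpha Intercept on the log(delay + c0) scale.
#' @param sigma Noise SD on the log scale (> 0 unless exactly noise-free).
#' @param c0 Generator offset in hours (default 0.1, matching the analysis
#'   module's minimal-shift rule when all delays are positive).
#' @param ses_items Named vector of asset-ownership probabilities.
#' @param rng_seed Seed for all randomness in [simulate_cohort()].
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 5000,
                        covariate_distributions = default_covariate_distributions(),
                        effect_ratios = default_effect_ratios(),
                        alpha = -0.671161, sigma = 3.422883, c0 = 0.1,
                        ses_items = default_ses_items(),
                        rng_seed = 1L) {
  stopifnot(n >= 1, sigma >= 0, c0 > 0)
  for (v in names(covariate_distributions)) {
    p <- covariate_distributions[[v]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) stop("probabilities for ", v, " must be nonnegative and sum to 1")
  }
  for (v in names(effect_ratios)) {
    if (!v %in% names(covariate_distributions)) stop("effect on unknown variable: ", v)
    if (any(effect_ratios[[v]] <= 0)) stop("effect ratios must be > 0")
    bad <- setdiff(names(effect_ratios[[v]]), names(covariate_distributions[[v]]))
    if (length(bad)) stop("effect on unknown level of ", v, ": ", paste(bad, collapse = ", "))
  }
  structure(list(n = as.integer(n), covariate_distributions = covariate_distributions,
                 effect_ratios = effect_ratios, alpha = alpha, sigma = sigma,
                 c0 = c0, ses_items = ses_items, rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> n = %d, alpha = %.3f, sigma = %.3f, c0 = %g h, seed = %d\n",
              x$n, x$alpha, x$sigma, x$c0, x$rng_seed))
  cat("  active effects:",
      paste(unlist(lapply(names(x$effect_ratios), function(v)
        paste0(v, ":", names(x$effect_ratios[[v]]), "=", x$effect_ratios[[v]]))),
        collapse = ", "), "\n")
  invisible(x)
}

# Covariate score: sum of log effect ratios for a drawn covariate data frame.
effect_score <- function(spec, covariates) {
  s <- numeric(nrow(covariates))
  for (v in names(spec$effect_ratios)) {
    r <- spec$effect_ratios[[v]]
    for (lv in names(r)) s <- s + log(r[[lv]]) * (covariates[[v]] == lv)
  }
  s
}

draw_covariates <- function(spec, n) {
  out <- lapply(names(spec$covariate_distributions), function(v) {
    p <- spec$covariate_distributions[[v]]
    factor(sample(names(p), n, replace = TRUE, prob = p), levels = names(p))
  })
  names(out) <- names(spec$covariate_distributions)
  as.data.frame(out)
}

#' Simulate a survey cohort with known generating truth
#'
#' Draws covariates, log-normal noise and asset-ownership flags under the
#' cohort specification; assigns each woman a village (uniformly) with its
#' modelled best-case travel time; and constructs
#' `reported = modelled + delay` with
#' `delay = exp(alpha + score + eps) - c0`. Reported times are floored at
#' one minute (a respondent never reports a non-positive travel time), so
#' for villages modelled at under `c0` hours the survey-derived delay can
#' differ slightly from the generative one. Deterministic under
#' `spec$rng_seed`.
#'
#' @param spec A [cohort_spec()].
#' @param modelled_hours Named numeric vector: modelled best-case travel time
#'   in hours per village label.
#' @return List with `survey` (one row per woman: id, village_label,
#'   reported_hours, covariates and `ses_item_*` flags — what an interview
#'   would yield) and `truth` (the generating covariates, modelled time, true
#'   delay, score, and the spec's alpha/sigma/c0).
#' @export
simulate_cohort <- function(spec, modelled_hours) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(names(modelled_hours)) || any(!nzchar(names(modelled_hours)))) {
    stop("modelled_hours must be a named vector (village labels)")
  }
  if (any(modelled_hours < 0, na.rm = TRUE)) stop("modelled times must be nonnegative")
  n <- spec$n
  set.seed(spec$rng_seed)
  village <- sample(names(modelled_hours), n, replace = TRUE)
  covs <- draw_covariates(spec, n)
  eps <- stats::rnorm(n, 0, spec$sigma)
  score <- effect_score(spec, covs)
  delay <- exp(spec$alpha + score + eps) - spec$c0
  modelled <- unname(modelled_hours[village])
  # a respondent never reports less than a minute of travel
  reported <- pmax(modelled + delay, 1 / 60)
  items <- vapply(spec$ses_items, function(p) stats::rbinom(n, 1L, p),
                  integer(n))
  colnames(items) <- paste0("ses_item_", names(spec$ses_items))
  survey <- data.frame(id = seq_len(n), village_label = village,
                       reported_hours = reported, covs, items,
                       stringsAsFactors = FALSE)
  truth <- data.frame(id = seq_len(n), village_label = village,
                      modelled_hours = modelled, delay_hours = delay,
                      score = score, covs)
  truth$alpha <- spec$alpha; truth$sigma <- spec$sigma; truth$c0 <- spec$c0
  list(survey = survey, truth = truth)
}

#' Calibrate the generator's intercept and noise SD
#'
#' Finds `(alpha, sigma)` such that the marginal delay distribution implied
#' by the covariate distributions and effect ratios matches a target median
#' and a target share of non-positive delays. Uses a seeded Monte-Carlo
#' sample of the covariate score and noise: for a given `sigma`, `alpha` is
#' pinned by the median condition in closed form, and the share of
#' non-positive delays is monotone increasing in `sigma`, so the share
#' condition is solved by root finding. If the target share is unattainable
#' (e.g. 0 with `c0 > 0`), the nearest attainable value is reported with a
#' warning.
#'
#' @param spec A [cohort_spec()]; its `alpha`/`sigma` are ignored.
#' @param target_median_hours Target marginal median delay (default 2.0 h).
#' @param target_share_nonpositive Target P(delay <= 0) (default 0.20).
#' @param n_mc Monte-Carlo sample size (default 200000).
#' @param seed RNG seed for the Monte-Carlo draw.
#' @return List: `alpha`, `sigma`, `achieved_median`, `achieved_share`,
#'   `attained` (FALSE when the nearest-attainable fallback was used).
#' @export
calibrate_generator_defaults <- function(spec = cohort_spec(),
                                         target_median_hours = 2.0,
                                         target_share_nonpositive = 0.20,
                                         n_mc = 200000, seed = 20070201) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  covs <- draw_covariates(spec, n_mc)
  s <- effect_score(spec, covs)
  e <- stats::rnorm(n_mc)
  lt <- log(target_median_hours + spec$c0)
  eval_sigma <- function(sigma) {
    z <- s + sigma * e
    alpha <- lt - stats::median(z)
    share <- mean(exp(alpha + z) - spec$c0 <= 0)
    list(alpha = alpha, share = share)
  }
  lo <- 1e-6; hi <- 12
  sh_lo <- eval_sigma(lo)$share; sh_hi <- eval_sigma(hi)$share
  attained <- TRUE
  if (target_share_nonpositive <= sh_lo) {
    warning(sprintf(paste0("target non-positive share %.3g is at or below the ",
                           "noise-free bound %.3g; sigma collapses to the bound"),
                    target_share_nonpositive, sh_lo))
    sigma <- lo; attained <- FALSE
  } else if (target_share_nonpositive >= sh_hi) {
    warning("target non-positive share unattainable; returning nearest attainable value")
    sigma <- hi; attained <- FALSE
  } else {
    sigma <- stats::uniroot(function(sg) eval_sigma(sg)$share - target_share_nonpositive,
                            c(lo, hi), tol = 1e-4)$root
  }
  at <- eval_sigma(sigma)
  z <- s + sigma * e
  list(alpha = at$alpha, sigma = sigma,
       achieved_median = stats::median(exp(at$alpha + z) - spec$c0),
       achieved_share = at$share, attained = attained)
}
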