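# Direct synthetic draws for the single-link models (no cohort machinery),
# so each fit is tested against a truth it must recover.
copay_draws <- function(n, sdlog = 0.10, seed = 1) {
  noise_sd <- sdlog
  withr::with_seed(seed, {
    dat <- tibble::tibble(
      med_class = sample(c("ARB", "IS"), n, replace = TRUE,
                         prob = c(0.73, 0.27)),
      tier = sample(c("preferred", "nonpreferred"), n, replace = TRUE,
                    prob = c(0.65, 0.35))
    )
    dat <- dplyr::left_join(dat, default_copay_model(noise_sd),
                            by = c("med_class", "tier"))
    dat$monthly_copayment <- if (noise_sd == 0) dat$center else
      exp(rnorm(n, log(dat$center), noise_sd))
    dat
  })
}

test_that("tier:copayment model recovers the class-by-tier cell structure", {
  # zero dispersion: cell estimates exactly equal the configured centers
  dat <- copay_draws(400, sdlog = 0)
  for (lam in c(0.25, 1)) {
    fit <- fit_tier_copay(dat, lambda = lam)
    td <- tidy(fit)
    expect_equal(td$preferred, c(10.60, 14.86), tolerance = 1e-9)
    expect_equal(td$nonpreferred, c(11.81, 16.42), tolerance = 1e-9)
    expect_equal(td$tier_difference, c(1.21, 1.56), tolerance = 1e-9)
  }
  # permutation invariance
  fit1 <- fit_tier_copay(dat)
  fit2 <- fit_tier_copay(dat[sample(nrow(dat)), ])
  expect_equal(tidy(fit1), tidy(fit2), tolerance = 1e-12)
  # modest dispersion: differences recovered near the published dollars
  dat <- copay_draws(20000, sdlog = 0.10, seed = 2)
  td <- tidy(fit_tier_copay(dat))
  expect_equal(td$tier_difference[td$med_class == "ARB"], 1.21,
               tolerance = 0.10 / 1.21)
  expect_equal(td$tier_difference[td$med_class == "IS"], 1.56,
               tolerance = 0.12 / 1.56)
  # single-tier data falls back to a class-only model with a warning
  expect_warning(fit_tier_copay(dat[dat$tier == "preferred", ]),
                 "one formulary tier")
})

test_that("box-cox selection recovers the generating exponent", {
  set.seed(31)
  n <- 4000
  copay <- exp(rnorm(n, log(12), 0.6))
  for (lam in c(0, 0.25, 1)) {
    x <- if (lam == 0) log(copay) else copay^lam
    pdc <- 0.9 - 0.05 * x + rnorm(n, 0, 0.02)
    sel <- boxcox_select(copay, pdc)
    expect_equal(as.numeric(sel), lam)
    # ranking is invariant to rescaling the copayments
    expect_equal(as.numeric(boxcox_select(copay * 7, pdc)), lam)
  }
  # exactly linear data select the identity with zero residual error
  pdc_lin <- 1 - 0.001 * copay
  expect_equal(as.numeric(boxcox_select(copay, pdc_lin)), 1)
  expect_error(boxcox_select(c(0, 1, 2), pdc_lin[1:3]), "positive")
  expect_error(boxcox_select(copay, pdc_lin, lambda_grid = numeric(0)),
               "non-empty")
  # without a response, the profile likelihood normalizes a skewed variable
  expect_equal(as.numeric(boxcox_select(copay)), 0)
})

test_that("adherence mixed model recovers coefficients exactly in the noiseless limit", {
  am <- default_adherence_model()
  am$pcp_sd <- 0
  am$resid_sd <- 0
  cfg <- small_config(seed = 41, adherence_model = am,
                      copay_model = default_copay_model(sdlog = 0.10))
  links <- fit_all_links(cfg)
  td <- tidy(links$ca)
  est <- function(term) td$estimate[td$term == term]
  # realization rounds PDC to whole days, so recovery is exact to ~1/360
  expect_equal(est("copay_bc"), -0.08, tolerance = 0.02)
  expect_equal(est("med_classIS"), -0.49, tolerance = 0.01 / 0.49)
  expect_equal(est("income45-75k"), 0.06, tolerance = 0.05)
  expect_equal(est("income>=75k"), 0.08, tolerance = 0.05)
  expect_equal(est("freq_gt_dailyTRUE"), -0.04, tolerance = 0.06)
  expect_equal(est("(Intercept)"), 0.894, tolerance = 0.05)
})

test_that("adherence model drops the random effect for a single prescriber", {
  dat <- tibble::tibble(
    pdc = runif(40, 0.3, 1), monthly_copayment = runif(40, 8, 20),
    med_class = rep(c("ARB", "IS"), 20),
    income = rep(c("<45k", "45-75k"), 20),
    doses_per_day = 1, pcp_id = "P1"
  )
  expect_warning(fit <- fit_copay_adherence(dat), "random intercept")
  expect_false(fit$has_re)
  expect_s3_class(tidy(fit), "tbl_df")
})

test_that("fds:tier model recovers interaction and class odds ratios", {
  cfg <- sim_config(seed = 51, n_pcps = c(non = 400L, low = 100L, high = 50L),
                    patients_per_pcp = 12L)
  links <- fit_all_links(cfg)
  td <- tidy(links$fds)
  row <- td[td$term == "grouphigh:periodboth_fds", ]
  # truth 1.9 lies in the 95% CI and the point estimate is in its vicinity
  expect_gt(1.9, row$conf.low)
  expect_lt(1.9, row$conf.high)
  expect_lt(abs(log(row$estimate) - log(1.9)), 0.5)
  cls <- td[td$term == "med_classIS", ]
  expect_gt(4.1, cls$conf.low)
  expect_lt(4.1, cls$conf.high)
})

test_that("fitted odds ratios and cell probabilities are internally consistent", {
  cfg <- small_config(seed = 52)
  links <- fit_all_links(cfg)
  est <- coef(links$fds$gee)
  base_odds <- exp(est[["(Intercept)"]])
  odds <- base_odds * exp(est[["grouphigh"]]) *
    exp(est[["periodboth_fds"]]) * exp(est[["grouphigh:periodboth_fds"]])
  expect_equal(predict_cell_probability(links$fds, "high", "both_fds"),
               odds / (1 + odds), tolerance = 1e-12)
  expect_equal(predict_cell_probability(links$fds, "non", "pre"),
               base_odds / (1 + base_odds), tolerance = 1e-12)
})

test_that("an empty exposure cell drops its term with a named warning", {
  cfg <- small_config(seed = 53)
  sim <- simulate_study(cfg)
  coh <- build_cohort(sim$claims, sim$pcps, seed = 55)
  ic <- coh$index_claims
  ic <- ic[!(ic$group == "high" & ic$period == "both_fds"), ]
  expect_warning(fit <- fit_fds_tier(ic), "high, both_fds")
  expect_false("grouphigh:periodboth_fds" %in% tidy(fit)$term)
})

test_that("backward selection eliminates noise and respects protection", {
  dat <- gee_fixture()
  set.seed(61)
  dat$noise <- rnorm(nrow(dat))
  fit <- gee_logit(y ~ x1 + x2 + noise, data = dat, id = id)
  red <- backward_select(fit, protected = "x1")
  kept <- attr(terms(red$formula), "term.labels")
  expect_false("noise" %in% kept)
  expect_true("x1" %in% kept)
  elim <- attr(red, "elimination")
  expect_true("noise" %in% elim$term)
  expect_true(all(elim$criterion_after <= elim$criterion_before + 1e-8))

  # alpha = 1 with the criterion check off strips every unprotected term
  red_all <- backward_select(fit, alpha = 1, protected = "x1",
                             use_criterion = FALSE)
  expect_equal(attr(terms(red_all$formula), "term.labels"), "x1")

  # nothing removable when every term is significant
  set.seed(62)
  n <- 600
  x1 <- rnorm(n); x2 <- rnorm(n)
  strong <- tibble::tibble(
    id = rep(1:60, each = 10), x1 = x1, x2 = x2,
    y = rbinom(n, 1, plogis(1.5 * x1 - 1.5 * x2))
  )
  fit_s <- gee_logit(y ~ x1 + x2, data = strong, id = id)
  red_s <- backward_select(fit_s)
  expect_setequal(attr(terms(red_s$formula), "term.labels"), c("x1", "x2"))
})

test_that("backward selection on the mixed model removes an irrelevant covariate", {
  cfg <- small_config(seed = 63)
  links <- fit_all_links(cfg)
  adher <- links$adher
  set.seed(64)
  adher$noise <- rnorm(nrow(adher))
  fit <- fit_copay_adherence(adher, extra_covariates = "noise")
  red <- backward_select(fit)
  kept <- attr(terms(lme4::nobars(stats::formula(red$model))), "term.labels")
  expect_false("noise" %in% kept)
  expect_true("copay_bc" %in% kept)
  expect_true("med_class" %in% kept)
})

test_that("unadjusted group-by-period table handles degenerate inputs", {
  ic <- tibble::tibble(
    group = "high", period = "both_fds", tier = "preferred"
  )
  out <- summarize_unadjusted(ic)
  cell <- out[out$group == "high" & out$period == "both_fds", ]
  expect_equal(cell$pct_preferred, 100)
  empty <- out[out$group == "non" & out$period == "pre", ]
  expect_true(is.na(empty$pct_preferred))
  # all-preferred input: every non-empty cell is 100
  ic2 <- tibble::tibble(
    group = rep(c("non", "low", "high"), each = 3),
    period = rep(c("pre", "noninterruptive_only", "both_fds"), 3),
    tier = "preferred"
  )
  out2 <- summarize_unadjusted(ic2)
  expect_true(all(out2$pct_preferred == 100))
})
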