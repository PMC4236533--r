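test_that("rosters honour group sizes, usage thresholds and determinism", {
  cfg <- sim_config(seed = 3, n_pcps = c(non = 1570L, low = 187L, high = 74L),
                    patients_per_pcp = 1L)
  ros <- simulate_rosters(cfg)
  expect_equal(as.integer(table(ros$pcps$group)), c(1570L, 187L, 74L))
  expect_true(all(ros$pcps$usage_rate[ros$pcps$group == "non"] == 0))
  expect_true(all(ros$pcps$usage_rate[ros$pcps$group == "low"] < 0.30))
  expect_true(all(ros$pcps$usage_rate[ros$pcps$group == "high"] >= 0.30))
  # adopters carry real activation dates, non-adopters only a latent trend date
  expect_true(all(!is.na(ros$pcps$activation_date[ros$pcps$group != "non"])))
  expect_true(all(is.na(ros$pcps$activation_date[ros$pcps$group == "non"])))
  expect_true(all(!is.na(ros$pcps$sim_trend_date[ros$pcps$group == "non"])))
  # every patient links to exactly one prescriber; income strata present
  expect_true(all(ros$patients$pcp_id %in% ros$pcps$pcp_id))
  expect_setequal(levels(ros$patients$income), c("<45k", "45-75k", ">=75k"))

  ros2 <- simulate_rosters(cfg)
  expect_identical(ros, ros2)
})

test_that("high-user usage rates have the configured mean", {
  cfg <- sim_config(seed = 11,
                    n_pcps = c(non = 1L, low = 1L, high = 10000L),
                    patients_per_pcp = 1L)
  ros <- simulate_rosters(cfg)
  rates <- ros$pcps$usage_rate[ros$pcps$group == "high"]
  expect_equal(mean(rates), 0.61, tolerance = 0.02 / 0.61)
})

test_that("claims generation is deterministic and respects the tier cells", {
  cfg <- small_config(seed = 5,
                      tier_probabilities = tier_cells_uniform(0.78))
  sim1 <- simulate_study(cfg)
  sim2 <- simulate_study(cfg)
  expect_identical(sim1$claims, sim2$claims)

  idx <- sim1$claims[sim1$claims$sim_index, ]
  expect_gt(nrow(idx), 2000)
  # every cell is 0.78, so the pooled preferred share converges there
  expect_equal(mean(idx$tier == "preferred"), 0.78, tolerance = 0.02 / 0.78)
})

test_that("zero copay dispersion degenerates to the exact centers", {
  cfg <- small_config(seed = 6, copay_model = default_copay_model(sdlog = 0))
  sim <- simulate_study(cfg)
  idx <- sim$claims[sim$claims$sim_index, ]
  arb_pref <- idx[idx$med_class == "ARB" & idx$tier == "preferred", ]
  expect_true(all(arb_pref$copayment == 10.60))
  is_non <- idx[idx$med_class == "IS" & idx$tier == "nonpreferred", ]
  expect_true(all(is_non$copayment == 16.42))
})

test_that("raising copayments lowers realized adherence", {
  cfg_lo <- small_config(seed = 9)
  shifted <- default_copay_model()
  shifted$center <- shifted$center + 10
  cfg_hi <- small_config(seed = 9, copay_model = shifted)
  pdc_of <- function(cfg) {
    sim <- simulate_study(cfg)
    idx <- sim$claims[sim$claims$sim_index, ]
    mean(idx$sim_target_pdc)
  }
  expect_lt(pdc_of(cfg_hi), pdc_of(cfg_lo))
})

test_that("simulated refills realize the target PDC to the day", {
  cfg <- small_config(seed = 12)
  sim <- simulate_study(cfg)
  coh <- build_cohort(sim$claims, sim$pcps, seed = 14)
  pdc <- compute_pdc(coh$index_claims, sim$claims,
                     extract_end = cfg$study_end)
  expect_true(all(pdc$pdc >= 0 & pdc$pdc <= 1))
  m <- dplyr::inner_join(
    coh$index_claims[coh$index_claims$eligible_for_adherence,
                     c("claim_id", "sim_target_pdc")],
    pdc[, c("claim_id", "covered_days")], by = "claim_id"
  )
  want <- pmin(pmax(round(m$sim_target_pdc * 180), 30L), 180L)
  expect_equal(m$covered_days, want)
})

test_that("claims before a prescriber's activation are never FDS-exposed", {
  cfg <- small_config(seed = 13)
  sim <- simulate_study(cfg)
  dat <- dplyr::left_join(
    sim$claims[sim$claims$sim_index, ],
    sim$pcps[, c("pcp_id", "activation_date", "sim_trend_date")],
    by = "pcp_id"
  )
  eff <- dplyr::coalesce(dat$activation_date, dat$sim_trend_date)
  pre_activation <- dat$fill_date < eff
  expect_true(all(dat$sim_period[pre_activation] == "pre"))
  expect_true(all(dat$sim_period[!pre_activation] != "pre"))
})

test_that("true_parameters keys match the fitted estimate names", {
  tp <- true_parameters(small_config(seed = 1))
  expect_setequal(tp$fds_tier$term, c(
    "med_classIS", "grouplow", "grouphigh", "periodnoninterruptive_only",
    "periodboth_fds", "grouplow:periodnoninterruptive_only",
    "grouphigh:periodnoninterruptive_only", "grouplow:periodboth_fds",
    "grouphigh:periodboth_fds"
  ))
  expect_equal(
    tp$copay_adherence$estimate[tp$copay_adherence$term == "copay_bc"], -0.08
  )
  expect_equal(
    tp$copay_adherence$estimate[tp$copay_adherence$term == "med_classIS"],
    -0.49
  )
  expect_equal(tp$boxcox_lambda, 0.25)
  expect_equal(tp$tier_copay$tier_difference, c(1.21, 1.56))
})
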