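claims_tbl <- function(patient, class, day, supply = 30L,
                       origin = as.Date("2004-01-01")) {
  tibble::tibble(
    claim_id = sprintf("c%03d", seq_along(day)),
    patient_id = patient, med_class = class, fill_date = origin + day,
    days_supplied = as.integer(supply), copayment = 10, doses_per_day = 1
  )
}

test_that("minimum days-supplied filter keeps exactly the stated boundary", {
  cl <- claims_tbl("p1", "ARB", c(0, 10, 20), supply = c(14L, 15L, 30L))
  kept <- filter_min_days(cl)
  expect_equal(kept$claim_id, c("c002", "c003"))
  expect_identical(filter_min_days(cl[0, ]), cl[0, ])
})

test_that("index identification implements the same-class 180-day washout", {
  # same-class fill 100 days later is blocked
  cl <- claims_tbl(c("p1", "p1"), "ARB", c(0, 100))
  expect_equal(identify_index_claims(cl)$claim_id, "c001")
  # a gap beyond the washout yields two index claims
  cl <- claims_tbl(c("p1", "p1"), "ARB", c(0, 200))
  expect_equal(identify_index_claims(cl)$claim_id, c("c001", "c002"))
  # cross-class claims never block
  cl <- claims_tbl("p1", c("IS", "ARB"), c(0, 30))
  expect_equal(identify_index_claims(cl)$claim_id, c("c001", "c002"))
})

test_that("index identification matches brute force, is order-invariant and idempotent", {
  brute <- function(cl, washout = 180L) {
    keep <- vapply(seq_len(nrow(cl)), function(i) {
      !any(cl$patient_id == cl$patient_id[i] &
             cl$med_class == cl$med_class[i] &
             cl$fill_date >= cl$fill_date[i] - washout &
             cl$fill_date < cl$fill_date[i])
    }, logical(1))
    sort(cl$claim_id[keep])
  }
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(3:25, 1)
    cl <- claims_tbl(
      patient = sample(paste0("p", 1:4), n, replace = TRUE),
      class = sample(c("ARB", "IS"), n, replace = TRUE),
      day = sample(0:700, n)
    )
    got <- identify_index_claims(cl)
    expect_equal(sort(got$claim_id), brute(cl))
    # row-order invariance
    perm <- cl[sample(n), ]
    expect_equal(sort(identify_index_claims(perm)$claim_id), brute(cl))
    # idempotence
    expect_equal(identify_index_claims(got), got)
  }
})

test_that("adherence eligibility flips at the 2006 cutoff and drops nothing", {
  cl <- claims_tbl(c("p1", "p2", "p3"), "ARB", c(0, 729, 730))
  # origin 2004-01-01 + 730 = 2005-12-31; +731 = 2006-01-01
  cl$fill_date <- as.Date(c("2005-12-31", "2006-01-01", "2004-05-05"))
  out <- flag_adherence_eligibility(cl)
  expect_equal(nrow(out), 3)
  expect_equal(out$eligible_for_adherence, c(TRUE, FALSE, TRUE))
})

test_that("synthetic dates resample the adopter distribution", {
  pcps <- tibble::tibble(
    pcp_id = paste0("P", 1:3),
    activation_date = as.Date(c("2005-05-01", NA, NA))
  )
  out <- assign_synthetic_dates(pcps, seed = 1)
  # degenerate multiset: every non-adopter gets the single adopter date
  expect_true(all(out$effective_activation == as.Date("2005-05-01")))
  expect_identical(out$activation_date, pcps$activation_date)

  # empirical proportions from a 2-date multiset stay within 3 SE of 1/2
  d1 <- as.Date("2005-03-01"); d2 <- as.Date("2005-10-01")
  pcps <- tibble::tibble(
    pcp_id = paste0("P", 1:10002),
    activation_date = c(d1, d2, rep(as.Date(NA), 10000))
  )
  out <- assign_synthetic_dates(pcps, seed = 2)
  prop <- mean(out$synthetic_activation_date[-(1:2)] == d1)
  expect_lt(abs(prop - 0.5), 3 * sqrt(0.25 / 10000))
  # determinism
  out2 <- assign_synthetic_dates(pcps, seed = 2)
  expect_identical(out, out2)

  expect_error(
    assign_synthetic_dates(
      tibble::tibble(pcp_id = "P1", activation_date = as.Date(NA)), seed = 1
    ),
    "No adopters"
  )
})

test_that("period labels partition all orderings of fill, activation and go-live", {
  golive <- as.Date("2005-09-16")
  expect_equal(as.character(classify_period(as.Date("2005-08-01"),
                                            as.Date("2005-07-01"), golive)),
               "noninterruptive_only")
  expect_equal(as.character(classify_period(as.Date("2005-09-16"),
                                            as.Date("2005-07-01"), golive)),
               "both_fds")
  expect_equal(as.character(classify_period(as.Date("2005-09-20"),
                                            as.Date("2005-10-01"), golive)),
               "pre")
  # enumerate a date grid around the go-live: exactly one label, matching
  # the declarative definition
  days <- as.Date("2005-09-16") + seq(-400, 400, by = 25)
  grid <- expand.grid(fill = days, act = days)
  lab <- classify_period(grid$fill, grid$act, golive)
  expect_false(anyNA(lab))
  want <- ifelse(grid$fill < grid$act, "pre",
                 ifelse(grid$fill < golive, "noninterruptive_only",
                        "both_fds"))
  expect_equal(as.character(lab), want)
})

test_that("monthly copayment standardization is exact", {
  expect_equal(monthly_copayment(30, 90), 10)
  expect_equal(monthly_copayment(10.60, 30), 10.60)
  expect_equal(monthly_copayment(0, 45), 0)
  expect_error(monthly_copayment(10, 0), "positive")
})

test_that("the exclusion cascade is order-correct and the flag switches it", {
  # a 10-day trial fill 100 days before a full fill: removed upstream, it
  # cannot block the later claim from being index
  cl <- claims_tbl(c("p1", "p1"), "ARB", c(0, 100), supply = c(10L, 30L))
  pcps <- tibble::tibble(pcp_id = "P1", group = "non",
                         usage_rate = 0, activation_date = as.Date(NA))
  cl$pcp_id <- "P1"
  pcps_a <- tibble::tibble(pcp_id = "P1", group = "high", usage_rate = 0.6,
                           activation_date = as.Date("2005-06-01"))
  out1 <- build_cohort(cl, pcps_a, seed = 1)
  expect_equal(out1$index_claims$claim_id, "c002")
  out2 <- build_cohort(cl, pcps_a, seed = 1, min_days_first = FALSE)
  expect_equal(nrow(out2$index_claims), 0)
  # manifest counts never increase along the cascade
  expect_true(all(diff(out1$exclusions$n) <= 0))
})

test_that("cohort labels are consistent with the effective activation date", {
  cfg <- small_config(seed = 21)
  sim <- simulate_study(cfg)
  coh <- build_cohort(sim$claims, sim$pcps, seed = 23)
  ic <- coh$index_claims
  relab <- classify_period(ic$fill_date, ic$effective_activation,
                           cfg$interruptive_start)
  expect_equal(as.character(ic$period), as.character(relab))
  # adopters keep their real dates
  adopters <- coh$pcps[!is.na(coh$pcps$activation_date), ]
  expect_equal(adopters$effective_activation, adopters$activation_date)
  # synthetic dates are resampled adopter dates
  non <- coh$pcps[is.na(coh$pcps$activation_date), ]
  expect_true(all(non$effective_activation %in% adopters$activation_date))
  # monthly copayment column matches the convention
  expect_equal(ic$monthly_copayment,
               ic$copayment * 30 / ic$days_supplied)
})
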