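sample_weighted <- function(x, n, prob) {
  x[sample.int(length(x), n, replace = TRUE, prob = prob)]
}

#' Generate prescriber and patient rosters
#'
#' Draws the prescriber roster (usage group, e-prescribing usage rate,
#' activation date for adopters, a latent trend date for non-adopters) and
#' the patient roster (age, sex, income stratum, attributed prescriber).
#' Non-users have usage rate 0; low users draw below the 0.30 threshold;
#' high users draw from a rescaled Beta with mean 0.61 above it. Adopters'
#' activation dates are sampled with replacement from the configured
#' empirical distribution. `sim_trend_date` is generator ground truth (the
#' date that drives the secular trend of a non-adopter's tier mix); the
#' analysis stage never reads it and instead assigns its own synthetic
#' dates with [assign_synthetic_dates()].
#'
#' @param config A [sim_config()] object.
#' @param seed Seed for this stage; defaults to `config$seed`.
#' @return A list with tibbles `pcps` and `patients`.
#' @export
simulate_rosters <- function(config, seed = config$seed) {
  config <- validate_sim_config(config)
  withr::with_seed(seed, {
    n <- config$n_pcps[GROUPS]
    pcps <- tibble(
      pcp_id = sprintf("P%04d", seq_len(sum(n))),
      group = factor(rep(GROUPS, times = n), levels = GROUPS)
    )
    usage <- numeric(nrow(pcps))
    lo <- pcps$group == "low"
    hi <- pcps$group == "high"
    usage[lo] <- runif(sum(lo), config$usage_low_range[1],
                       config$usage_low_range[2])
    usage[hi] <- 0.30 + 0.70 * rbeta(sum(hi), config$usage_high_shape[1],
                                     config$usage_high_shape[2])
    pcps$usage_rate <- usage
    adopter <- pcps$group != "non"
    act <- rep(as.Date(NA), nrow(pcps))
    act[adopter] <- sample(config$activation_dates, sum(adopter),
                           replace = TRUE)
    pcps$activation_date <- act
    trend <- rep(as.Date(NA), nrow(pcps))
    trend[!adopter] <- sample(config$activation_dates, sum(!adopter),
                              replace = TRUE)
    pcps$sim_trend_date <- trend
    pcps$specialty <- sample_weighted(
      c("Family practice", "Internal medicine", "Non-surgical", "Pediatrics"),
      nrow(pcps), prob = c(0.32, 0.53, 0.002, 0.148)
    )
    pcps$practice_size <- sample_weighted(
      c("1", "2-5", "6-10", "11-25", ">25"),
      nrow(pcps), prob = c(0.48, 0.40, 0.10, 0.013, 0.007)
    )

    n_pat <- nrow(pcps) * config$patients_per_pcp
    patients <- tibble(
      patient_id = sprintf("PT%06d", seq_len(n_pat)),
      pcp_id = rep(pcps$pcp_id, each = config$patients_per_pcp),
      age = pmin(pmax(round(rnorm(n_pat, config$age_mean, config$age_sd)), 0),
                 100),
      sex = if_else(runif(n_pat) < config$p_female, "F", "M"),
      income = factor(
        sample_weighted(INCOMES, n_pat, prob = config$income_probs),
        levels = INCOMES
      )
    )
    list(pcps = pcps, patients = patients)
  })
}

# Period of a fill date relative to an effective activation date and the
# interruptive go-live (both boundaries inclusive on the exposed side).
period_of <- function(fill_date, activation_date, interruptive_start) {
  out <- rep("pre", length(fill_date))
  post <- fill_date >= activation_date
  out[post] <- "noninterruptive_only"
  out[post & fill_date >= interruptive_start] <- "both_fds"
  factor(out, levels = PERIODS)
}

# Refill schedule realizing `covered` days of supply inside a
# `window`-day window with 30-day fills: contiguous fills from day 0, with
# the final fill placed so that exactly the residual days fall in-window.
refill_offsets <- function(covered, window = 180L, supply = 30L) {
  n <- ceiling(covered / supply)
  if (n <= 1) return(integer(0))
  r <- covered - supply * (n - 1)
  c(supply * seq_len(n - 2), window - r)
}

#' Generate a synthetic claims stream
#'
#' For each rostered patient, draws one new-start episode (two with
#' probability `p_both_classes`, one per class): an index fill date uniform
#' in the study window, a medication class, a formulary tier from the
#' configured (group, period, class) probability cell, a log-normal monthly
#' copayment around the class-by-tier center, a dosing frequency, and a
#' target 180-day PDC from the linear adherence model (prescriber random
#' intercept plus residual, clipped to [0, 1]). Refills are emitted as
#' 30-day supplies whose gaps realize the target PDC to the day; the
#' copayment on every claim is the monthly copayment scaled by days
#' supplied / 30. Refills dated beyond the study window are censored.
#'
#' @param config A [sim_config()] object.
#' @param rosters Result of [simulate_rosters()].
#' @param seed Seed for this stage; defaults to `config$seed + 1`.
#' @return A claims tibble, one row per dispensing, with ground-truth
#'   columns `sim_index`, `sim_period` and `sim_target_pdc` alongside the
#'   observable fields.
#' @export
simulate_claims <- function(config, rosters, seed = config$seed + 1L) {
  config <- validate_sim_config(config)
  pcps <- rosters$pcps
  patients <- rosters$patients
  withr::with_seed(seed, {
    pcp_re <- setNames(rnorm(nrow(pcps), 0, config$adherence_model$pcp_sd),
                       pcps$pcp_id)

    eps <- patients %>%
      select("patient_id", "pcp_id", "income") %>%
      mutate(
        first_class = if_else(runif(n()) < config$class_mix, "ARB", "IS"),
        second = runif(n()) < config$p_both_classes
      )
    eps <- bind_rows(
      eps %>% mutate(med_class = .data$first_class),
      eps %>% filter(.data$second) %>%
        mutate(med_class = if_else(.data$first_class == "ARB", "IS", "ARB"))
    ) %>%
      select(-"first_class", -"second") %>%
      arrange(.data$patient_id, .data$med_class)

    n_ep <- nrow(eps)
    window_days <- as.integer(config$study_end - config$study_start)
    eps <- eps %>%
      left_join(pcps %>% select("pcp_id", "group", "activation_date",
                                "sim_trend_date"),
                by = "pcp_id") %>%
      mutate(
        fill_date = config$study_start +
          sample.int(window_days + 1L, n_ep, replace = TRUE) - 1L,
        effective_date = coalesce(.data$activation_date, .data$sim_trend_date),
        sim_period = period_of(.data$fill_date, .data$effective_date,
                               config$interruptive_start)
      ) %>%
      mutate(.group = as.character(.data$group),
             .period = as.character(.data$sim_period)) %>%
      left_join(
        config$tier_probabilities %>%
          mutate(.group = as.character(.data$group),
                 .period = as.character(.data$period)) %>%
          select(".group", ".period", "med_class", "p_preferred"),
        by = c(".group", ".period", "med_class")
      ) %>%
      select(-".group", -".period")

    eps$tier <- factor(
      if_else(runif(n_ep) < eps$p_preferred, "preferred", "nonpreferred"),
      levels = TIERS
    )

    eps <- eps %>%
      left_join(config$copay_model, by = c("med_class", "tier")) %>%
      mutate(
        monthly_copay = if_else(
          .data$sdlog == 0, .data$center,
          exp(rnorm(n_ep, log(.data$center), .data$sdlog))
        ),
        doses_per_day = if_else(runif(n_ep) < config$p_freq_gt_daily, 2, 1)
      )

    am <- config$adherence_model
    mu <- am$intercept +
      am$copay_slope * eps$monthly_copay^am$copay_lambda +
      am$is_offset * (eps$med_class == "IS") +
      am$income_mid * (eps$income == "45-75k") +
      am$income_high * (eps$income == ">=75k") +
      am$freq_gt_daily * (eps$doses_per_day > 1)
    mu <- pmin(pmax(mu, 0), 1)
    target <- mu + unname(pcp_re[eps$pcp_id]) +
      if (am$resid_sd > 0) rnorm(n_ep, 0, am$resid_sd) else 0
    eps$sim_target_pdc <- pmin(pmax(target, 0), 1)

    covered <- pmin(pmax(round(eps$sim_target_pdc * 180), 30L), 180L)
    offsets <- lapply(covered, refill_offsets)
    n_fills <- vapply(offsets, length, integer(1)) + 1L
    idx <- rep(seq_len(n_ep), n_fills)

    claims <- eps[idx, c("patient_id", "pcp_id", "med_class", "tier",
                         "fill_date", "monthly_copay", "doses_per_day",
                         "sim_period", "sim_target_pdc")]
    claims$fill_date <- claims$fill_date +
      unlist(lapply(offsets, function(o) c(0L, o)))
    claims$sim_index <- !duplicated(idx)
    claims <- claims %>%
      filter(.data$fill_date <= config$study_end) %>%
      mutate(
        days_supplied = 30L,
        copayment = round(.data$monthly_copay * .data$days_supplied / 30, 4)
      ) %>%
      arrange(.data$patient_id, .data$med_class, .data$fill_date) %>%
      mutate(claim_id = sprintf("C%07d", row_number())) %>%
      select("claim_id", "patient_id", "pcp_id", "med_class", "tier",
             "fill_date", "days_supplied", "copayment", "doses_per_day",
             "sim_index", "sim_period", "sim_target_pdc")
    as_tibble(claims)
  })
}

#' Simulate rosters and claims in one call
#'
#' @inheritParams simulate_rosters
#' @return A list with `pcps`, `patients` and `claims` tibbles.
#' @export
simulate_study <- function(config, seed = config$seed) {
  rosters <- simulate_rosters(config, seed = seed)
  claims <- simulate_claims(config, rosters, seed = seed + 1L)
  c(rosters, list(claims = claims))
}

#' Generator ground truth, keyed like fitted-model output
#'
#' Inverts the configured tier-probability cells into the odds ratios of the
#' difference-in-differences logistic model (class effect, group and period
#' main effects, group x period interactions, all on the ARB logit scale
#' with the non-user pre-FDS cell as reference), and echoes the true
#' tier-to-copayment cell centers and the adherence-model coefficients.
#' Terms are named exactly as the corresponding fitted models name them, so
#' recovery tests can join truth to estimates.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `model_estimates` with elements `fds_tier`,
#'   `tier_copay`, `boxcox_lambda` and `copay_adherence`.
#' @export
true_parameters <- function(config) {
  config <- validate_sim_config(config)
  cells <- config$tier_probabilities
  l <- function(g, t, c = "ARB") {
    qlogis(cells$p_preferred[cells$group == g & cells$period == t &
                               cells$med_class == c])
  }
  class_lor <- mean(qlogis(cells$p_preferred[cells$med_class == "IS"]) -
                      qlogis(cells$p_preferred[cells$med_class == "ARB"]))
  fds <- tibble(
    term = c("med_classIS", "grouplow", "grouphigh",
             "periodnoninterruptive_only", "periodboth_fds",
             "grouplow:periodnoninterruptive_only",
             "grouphigh:periodnoninterruptive_only",
             "grouplow:periodboth_fds", "grouphigh:periodboth_fds"),
    odds_ratio = exp(c(
      class_lor,
      l("low", "pre") - l("non", "pre"),
      l("high", "pre") - l("non", "pre"),
      l("non", "noninterruptive_only") - l("non", "pre"),
      l("non", "both_fds") - l("non", "pre"),
      (l("low", "noninterruptive_only") - l("low", "pre")) -
        (l("non", "noninterruptive_only") - l("non", "pre")),
      (l("high", "noninterruptive_only") - l("high", "pre")) -
        (l("non", "noninterruptive_only") - l("non", "pre")),
      (l("low", "both_fds") - l("low", "pre")) -
        (l("non", "both_fds") - l("non", "pre")),
      (l("high", "both_fds") - l("high", "pre")) -
        (l("non", "both_fds") - l("non", "pre"))
    ))
  )
  cm <- config$copay_model
  cc <- function(cl, ti) cm$center[cm$med_class == cl & cm$tier == ti]
  tier_copay <- tibble(
    med_class = CLASSES,
    preferred = c(cc("ARB", "preferred"), cc("IS", "preferred")),
    nonpreferred = c(cc("ARB", "nonpreferred"), cc("IS", "nonpreferred"))
  ) %>%
    mutate(tier_difference = .data$nonpreferred - .data$preferred)
  am <- config$adherence_model
  adher <- tibble(
    term = c("(Intercept)", "copay_bc", "med_classIS", "income45-75k",
             "income>=75k", "freq_gt_dailyTRUE"),
    estimate = c(am$intercept, am$copay_slope, am$is_offset, am$income_mid,
                 am$income_high, am$freq_gt_daily)
  )
  structure(
    list(fds_tier = fds, tier_copay = tier_copay,
         boxcox_lambda = am$copay_lambda, copay_adherence = adher,
         pcp_sd = am$pcp_sd, resid_sd = am$resid_sd),
    class = "model_estimates"
  )
}
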