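#' Drop short (trial-start) dispensings
#'
#' Removes claims with fewer than `min_days` days supplied. Short supplies
#' are typically trial starts or data errors; removing them upstream of
#' index identification also stops them from blocking a later claim's
#' new-user status (set `before_index = FALSE` in [build_cohort()] to keep
#' them as washout blockers instead).
#'
#' @param claims Claims tibble with a `days_supplied` column.
#' @param min_days Minimum days supplied to retain (default 15).
#' @return The claims that meet the minimum, input order preserved.
#' @export
filter_min_days <- function(claims, min_days = 15L) {
  filter(claims, .data$days_supplied >= min_days)
}

#' Identify index (new-user) claims
#'
#' A claim is an index claim when the same patient has no same-class claim
#' in the `washout_days` days before it (exclusive of the fill date itself).
#' Claims of the other medication class never block. The retained set does
#' not depend on the row order of the input; output keeps input order.
#'
#' @param claims Claims tibble (`patient_id`, `med_class`, `fill_date`, ...).
#' @param washout_days Lookback window in days (default 180; the six-month
#'   washout is taken as 180 days to match the adherence window).
#' @return The subset of `claims` that are index claims.
#' @export
identify_index_claims <- function(claims, washout_days = 180L) {
  if (nrow(claims) == 0) return(claims)
  ord <- claims %>%
    mutate(.row = row_number()) %>%
    arrange(.data$patient_id, .data$med_class, .data$fill_date, .data$.row) %>%
    group_by(.data$patient_id, .data$med_class) %>%
    mutate(.is_index = is_index_within(as.integer(.data$fill_date),
                                       washout_days)) %>%
    ungroup() %>%
    arrange(.data$.row)
  claims[ord$.is_index, , drop = FALSE]
}

# For sorted fill dates of one patient x class, a fill is blocked iff some
# prior same-class fill lies in [fill - washout, fill); the nearest prior
# fill is the only one that can matter, so the test reduces to the gap to
# the previous fill exceeding the washout. Any prior claim blocks, index or
# not (the washout looks at dispensing history, not at the index set).
is_index_within <- function(days, washout) {
  if (length(days) <= 1) return(rep(TRUE, length(days)))
  c(TRUE, diff(days) > washout)
}

#' Flag index claims usable in adherence analyses
#'
#' Index claims filled on or after `cutoff` (default 2006-01-01) lack a full
#' 180 days of follow-up in the extract and are flagged ineligible; no rows
#' are dropped, because tier analyses use all index claims.
#'
#' @param index_claims Index-claim tibble with `fill_date`.
#' @param cutoff First ineligible fill date.
#' @return The input with an `eligible_for_adherence` logical column.
#' @export
flag_adherence_eligibility <- function(index_claims,
                                       cutoff = as.Date("2006-01-01")) {
  mutate(index_claims,
         eligible_for_adherence = .data$fill_date < as.Date(cutoff))
}

#' Assign synthetic activation dates to non-adopters
#'
#' Each prescriber without an activation date receives a synthetic one drawn
#' i.i.d. with replacement from the multiset of adopters' actual activation
#' dates, so control prescribers can be split into the same exposure periods
#' and secular trends cancel in the difference-in-differences contrast.
#'
#' @param pcps Prescriber tibble with an `activation_date` column (NA for
#'   non-adopters).
#' @param seed Integer seed for the draw.
#' @return The input with `synthetic_activation_date` and
#'   `effective_activation` (actual where present, synthetic otherwise).
#' @export
assign_synthetic_dates <- function(pcps, seed) {
  adopter_dates <- pcps$activation_date[!is.na(pcps$activation_date)]
  if (length(adopter_dates) == 0) {
    abort(paste("No adopters with activation dates: the empirical",
                "distribution of synthetic dates is undefined."))
  }
  needs <- is.na(pcps$activation_date)
  synth <- rep(as.Date(NA), nrow(pcps))
  withr::with_seed(seed, {
    synth[needs] <- sample(adopter_dates, sum(needs), replace = TRUE)
  })
  pcps %>%
    mutate(synthetic_activation_date = synth,
           effective_activation = coalesce(.data$activation_date, synth))
}

#' Classify a fill into an FDS exposure period
#'
#' Vectorized over fills: `pre` before the (effective) activation date,
#' `noninterruptive_only` from activation up to the interruptive go-live,
#' `both_fds` on or after both. Boundaries are inclusive on the exposed side
#' (a fill on the activation date is post-activation; a fill on the go-live
#' date is in the combined period). The three labels partition all dates.
#'
#' @param fill_date,effective_activation Date vectors (recycled).
#' @param interruptive_start Go-live date of interruptive alerts.
#' @return Factor with levels `pre`, `noninterruptive_only`, `both_fds`.
#' @export
classify_period <- function(fill_date, effective_activation,
                            interruptive_start = as.Date("2005-09-16")) {
  period_of(as.Date(fill_date), as.Date(effective_activation),
            as.Date(interruptive_start))
}

#' Standardize a dispensing's copayment to a 30-day month
#'
#' @param copayment Dollar amount paid on the claim.
#' @param days_supplied Days of medication supplied (must be >= 1).
#' @return `copayment * 30 / days_supplied`.
#' @export
monthly_copayment <- function(copayment, days_supplied) {
  if (any(days_supplied <= 0)) {
    abort("days_supplied must be positive to standardize a copayment.")
  }
  copayment * 30 / days_supplied
}

#' Build the analysis cohort from raw claims
#'
#' Applies the exclusion cascade in its stated order — minimum days-supplied
#' filter, 180-day same-class washout index identification, adherence
#' eligibility flag — then assigns synthetic activation dates to
#' non-adopters, labels every index claim with its exposure period and
#' prescriber usage group, and standardizes copayments to a 30-day month.
#'
#' @param claims Raw claims tibble.
#' @param pcps Prescriber roster with `group` and `activation_date`.
#' @param seed Seed for the synthetic-date draw.
#' @param min_days,washout_days,adherence_cutoff,interruptive_start Cascade
#'   parameters (defaults: 15 days, 180 days, 2006-01-01, 2005-09-16).
#' @param min_days_first If `FALSE`, sub-minimum claims still block the
#'   washout (they are removed only from the candidate index set).
#' @return A list with `index_claims` (the labelled cohort), `pcps` (with
#'   effective activation dates) and `exclusions` (a tibble of row counts
#'   surviving each cascade step).
#' @export
build_cohort <- function(claims, pcps, seed,
                         min_days = 15L, washout_days = 180L,
                         adherence_cutoff = as.Date("2006-01-01"),
                         interruptive_start = as.Date("2005-09-16"),
                         min_days_first = TRUE) {
  if (!"claim_id" %in% names(claims)) {
    claims <- mutate(claims, claim_id = sprintf("C%07d", row_number()))
  }
  n_raw <- nrow(claims)
  if (min_days_first) {
    kept <- filter_min_days(claims, min_days)
    n_min <- nrow(kept)
    index <- identify_index_claims(kept, washout_days)
  } else {
    index_all <- identify_index_claims(claims, washout_days)
    kept <- filter_min_days(claims, min_days)
    n_min <- nrow(kept)
    index <- dplyr::semi_join(kept, index_all, by = "claim_id")
  }
  n_index <- nrow(index)
  pcps <- assign_synthetic_dates(pcps, seed)
  index <- index %>%
    left_join(pcps %>% select("pcp_id", "group", "usage_rate",
                              "effective_activation"),
              by = "pcp_id") %>%
    mutate(
      period = classify_period(.data$fill_date, .data$effective_activation,
                               interruptive_start),
      monthly_copayment = monthly_copayment(.data$copayment,
                                            .data$days_supplied)
    ) %>%
    flag_adherence_eligibility(adherence_cutoff)
  exclusions <- tibble(
    step = c("raw_claims", paste0("days_supplied_ge_", min_days),
             "index_claims", "adherence_eligible"),
    n = c(n_raw, n_min, n_index, sum(index$eligible_for_adherence))
  )
  list(index_claims = index, pcps = pcps, exclusions = exclusions)
}
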