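# Canonical factor levels used throughout the package.
GROUPS <- c("non", "low", "high")
PERIODS <- c("pre", "noninterruptive_only", "both_fds")
CLASSES <- c("ARB", "IS")
TIERS <- c("preferred", "nonpreferred")
INCOMES <- c("<45k", "45-75k", ">=75k")

#' Default e-prescribing activation date distribution
#'
#' An empirical multiset of 297 activation dates spread over calendar 2005,
#' built by piecewise-linear interpolation of a quantile function through the
#' observed adoption-date quartiles of the adopter cohort (first quartile
#' 2005-06-02, median 2005-08-04, third quartile 2005-09-29). Software
#' activation rolled out throughout 2005, so the support runs from early
#' January to late December.
#'
#' @param n Number of dates to return (default 297, the adopter count).
#' @return A `Date` vector of length `n`, sorted.
#' @export
default_activation_dates <- function(n = 297L) {
  knots_p <- c(0, 0.25, 0.5, 0.75, 1)
  knots_d <- as.numeric(as.Date(c(
    "2005-01-03", "2005-06-02", "2005-08-04", "2005-09-29", "2005-12-30"
  )))
  p <- seq(0, 1, length.out = n)
  as.Date(round(stats::approx(knots_p, knots_d, xout = p)$y),
          origin = "1970-01-01")
}

# Solve the ARB-scale intercept b such that the ARB/IS mixture probability
# w * expit(b) + (1 - w) * expit(b + log(class_or)) equals `target`.
solve_mixture_logit <- function(target, class_or, arb_share) {
  f <- function(b) {
    arb_share * plogis(b) + (1 - arb_share) * plogis(b + log(class_or)) - target
  }
  uniroot(f, interval = c(-15, 15), tol = 1e-12)$root
}

# Pooled preferred-tier percentages by user group x exposure period
# (unadjusted claims-level rates used for calibration).
table2_pooled <- function() {
  matrix(c(0.63, 0.69, 0.70,
           0.59, 0.60, 0.61,
           0.57, 0.61, 0.78),
         nrow = 3, byrow = TRUE,
         dimnames = list(GROUPS, PERIODS))
}

cells_from_logits <- function(logit_arb, class_or) {
  grid <- tidyr::expand_grid(group = GROUPS, period = PERIODS,
                             med_class = CLASSES)
  grid$p_preferred <- purrr::pmap_dbl(grid, function(group, period, med_class) {
    l <- logit_arb[group, period] + if (med_class == "IS") log(class_or) else 0
    plogis(l)
  })
  grid
}

#' Default preferred-tier probability cells
#'
#' Builds the (group x period x class) preferred-tier probability table used
#' as generator ground truth. The construction is additive on the logit
#' scale: the intercept reproduces the pooled non-user pre-FDS rate (63%);
#' group and period main effects reproduce the remaining pooled margins of
#' the unadjusted group-by-period table; the four difference-in-differences
#' interaction odds ratios are set explicitly (defaults are the published
#' adjusted estimates, 0.9/0.8/0.9/1.9, so the high-user x interruptive-period
#' truth is exactly 1.9); inhaled steroids sit `class_or` (default 4.1) above
#' ARBs in odds within every cell.
#'
#' @param interaction_or Named numeric of the four group x period interaction
#'   odds ratios, names `low:noninterruptive_only`, `low:both_fds`,
#'   `high:noninterruptive_only`, `high:both_fds`.
#' @param class_or Odds ratio of preferred tier for IS relative to ARB.
#' @param arb_share Probability that a new start is an ARB (used to anchor
#'   the intercept so the pooled non-user pre-FDS cell is 63%).
#' @return A tibble with columns `group`, `period`, `med_class`,
#'   `p_preferred` (18 rows).
#' @export
tier_cells_default <- function(interaction_or = c("low:noninterruptive_only" = 0.9,
                                                  "low:both_fds" = 0.8,
                                                  "high:noninterruptive_only" = 0.9,
                                                  "high:both_fds" = 1.9),
                               class_or = 4.1, arb_share = 0.73) {
  p2 <- table2_pooled()
  b0 <- solve_mixture_logit(p2["non", "pre"], class_or, arb_share)
  g <- c(non = 0,
         low = qlogis(p2["low", "pre"]) - qlogis(p2["non", "pre"]),
         high = qlogis(p2["high", "pre"]) - qlogis(p2["non", "pre"]))
  t <- c(pre = 0,
         noninterruptive_only = qlogis(p2["non", "noninterruptive_only"]) -
           qlogis(p2["non", "pre"]),
         both_fds = qlogis(p2["non", "both_fds"]) - qlogis(p2["non", "pre"]))
  logit_arb <- matrix(0, 3, 3, dimnames = list(GROUPS, PERIODS))
  for (gg in GROUPS) for (tt in PERIODS) {
    int <- 0
    key <- paste(gg, tt, sep = ":")
    if (key %in% names(interaction_or)) int <- log(interaction_or[[key]])
    logit_arb[gg, tt] <- b0 + g[[gg]] + t[[tt]] + int
  }
  cells_from_logits(logit_arb, class_or)
}

#' Preferred-tier cells that reproduce the pooled unadjusted table exactly
#'
#' For every (group, period) cell, solves for class-specific probabilities
#' such that the ARB/IS mixture equals the pooled unadjusted preferred-tier
#' percentage for that cell (non-users 63/69/70, low users 59/60/61, high
#' users 57/61/78) while keeping a constant IS-vs-ARB class odds ratio.
#' Use this calibration when the target of a simulation is the unadjusted
#' cell table itself rather than the adjusted interaction odds ratios.
#'
#' @inheritParams tier_cells_default
#' @return A tibble with columns `group`, `period`, `med_class`, `p_preferred`.
#' @export
tier_cells_table2 <- function(class_or = 4.1, arb_share = 0.73) {
  p2 <- table2_pooled()
  logit_arb <- matrix(0, 3, 3, dimnames = list(GROUPS, PERIODS))
  for (gg in GROUPS) for (tt in PERIODS) {
    logit_arb[gg, tt] <- solve_mixture_logit(p2[gg, tt], class_or, arb_share)
  }
  cells_from_logits(logit_arb, class_or)
}

#' Flat preferred-tier cells (null configuration)
#'
#' Every (group, period, class) cell gets the same preferred-tier
#' probability, so all difference-in-differences interaction odds ratios are
#' 1 by construction. Useful for type-I-error simulations.
#'
#' @param p Preferred-tier probability applied to every cell.
#' @return A tibble with columns `group`, `period`, `med_class`, `p_preferred`.
#' @export
tier_cells_uniform <- function(p = 0.65) {
  tidyr::expand_grid(group = GROUPS, period = PERIODS, med_class = CLASSES) %>%
    mutate(p_preferred = p)
}

default_copay_model <- function(sdlog = 0.10) {
  tibble(
    med_class = rep(CLASSES, each = 2),
    tier = rep(TIERS, 2),
    center = c(10.60, 11.81, 14.86, 16.42),
    sdlog = sdlog
  )
}

default_adherence_model <- function() {
  list(
    intercept = 0.894,       # anchors ARB PDC at ~74.6% at the non-preferred copay
    copay_slope = -0.08,     # absolute PDC per unit monthly copay^lambda
    copay_lambda = 0.25,
    is_offset = -0.49,       # inhaled steroid class
    income_mid = 0.06,       # $45k-$75k vs <$45k
    income_high = 0.08,      # >=$75k vs <$45k
    freq_gt_daily = -0.04,   # dosing more than once daily
    pcp_sd = 0.05,           # prescriber random intercept SD
    # residual SD kept small enough that the latent linear PDC model stays
    # inside [0, 1] for ~99% of draws; larger noise would clip at the unit
    # bounds and the generated world would no longer follow the linear law
    resid_sd = 0.06
  )
}

#' Simulation configuration
#'
#' Assembles and validates the configuration of the synthetic pharmacy-claims
#' generator. Defaults describe the studied world: 1570/187/74 prescribers in
#' the non-user / low-user (<30% e-prescribing) / high-user (>30%) groups, a
#' three-year claims window, rolling activation during 2005 with interruptive
#' alerts switched on 2005-09-16, two brand-only medication classes (ARB and
#' inhaled steroid), class-by-tier monthly copayment medians of
#' $10.60/$11.81 (ARB preferred/non-preferred) and $14.86/$16.42 (IS), and a
#' linear adherence model on the quarter-power copayment scale (slope -0.08)
#' with class (-0.49), income (+0.06/+0.08) and dosing-frequency (-0.04)
#' offsets and a prescriber random intercept.
#'
#' @param seed Integer seed; every stochastic draw of the generator derives
#'   from it.
#' @param n_pcps Named integer vector `c(non=, low=, high=)` of prescriber
#'   counts per usage group.
#' @param patients_per_pcp New-user patients attributed to each prescriber.
#' @param study_start,study_end Claims extract window (dates).
#' @param interruptive_start Go-live date of interruptive alerts; fills on or
#'   after this date by an activated prescriber are in the combined-FDS period.
#' @param activation_dates Date vector: the empirical multiset of adopter
#'   activation dates sampled by the generator (must lie in calendar 2005).
#' @param class_mix Probability a new start is an ARB (vs inhaled steroid).
#' @param p_both_classes Probability a patient starts a second, other-class
#'   episode (keeps claims/patients slightly above 1).
#' @param tier_probabilities Tibble (`group`, `period`, `med_class`,
#'   `p_preferred`): preferred-tier probability per cell. See
#'   [tier_cells_default()], [tier_cells_table2()], [tier_cells_uniform()].
#' @param copay_model Tibble (`med_class`, `tier`, `center`, `sdlog`): the
#'   monthly copayment is log-normal with median `center` (multiplicative
#'   noise reproduces the right skew typical of cost data); `sdlog = 0`
#'   degenerates to the exact center.
#' @param adherence_model Named list of coefficients of the linear PDC model
#'   (see [default_adherence_model()]).
#' @param income_probs Marginal probabilities of the three income strata.
#' @param p_freq_gt_daily Probability an index medication is dosed more than
#'   once daily.
#' @param usage_low_range Uniform support of low-user usage rates (below 0.30).
#' @param usage_high_shape Beta shape parameters for high-user usage rates,
#'   rescaled to (0.30, 1); defaults give mean 0.61.
#' @param age_mean,age_sd,p_female Patient demographics.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed,
                       n_pcps = c(non = 1570L, low = 187L, high = 74L),
                       patients_per_pcp = 8L,
                       study_start = as.Date("2003-06-03"),
                       study_end = as.Date("2006-07-21"),
                       interruptive_start = as.Date("2005-09-16"),
                       activation_dates = default_activation_dates(),
                       class_mix = 0.73,
                       p_both_classes = 0.019,
                       tier_probabilities = tier_cells_default(),
                       copay_model = default_copay_model(),
                       adherence_model = default_adherence_model(),
                       income_probs = c(`<45k` = 0.18, `45-75k` = 0.58,
                                        `>=75k` = 0.24),
                       p_freq_gt_daily = 0.12,
                       usage_low_range = c(0.005, 0.295),
                       usage_high_shape = c(2, 2 * (1 - 31 / 70) / (31 / 70)),
                       age_mean = 46, age_sd = 19, p_female = 0.52) {
  if (missing(seed)) abort("`seed` is mandatory in the simulation config.")
  cfg <- list(
    seed = as.integer(seed), n_pcps = n_pcps,
    patients_per_pcp = as.integer(patients_per_pcp),
    study_start = as.Date(study_start), study_end = as.Date(study_end),
    interruptive_start = as.Date(interruptive_start),
    activation_dates = as.Date(activation_dates),
    class_mix = class_mix, p_both_classes = p_both_classes,
    tier_probabilities = as_tibble(tier_probabilities),
    copay_model = as_tibble(copay_model),
    adherence_model = adherence_model,
    income_probs = income_probs, p_freq_gt_daily = p_freq_gt_daily,
    usage_low_range = usage_low_range, usage_high_shape = usage_high_shape,
    age_mean = age_mean, age_sd = age_sd, p_female = p_female
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!all(GROUPS %in% names(cfg$n_pcps))) {
    abort("`n_pcps` must be named with groups 'non', 'low', 'high'.")
  }
  if (any(cfg$n_pcps < 0)) abort("Prescriber group counts must be >= 0.")
  if (sum(cfg$n_pcps) == 0) {
    abort("Rejecting configuration: zero prescribers in every group.")
  }
  probs <- c(cfg$class_mix, cfg$p_both_classes,
             cfg$tier_probabilities$p_preferred, cfg$income_probs,
             cfg$p_freq_gt_daily, cfg$p_female)
  if (any(probs < 0 | probs > 1)) abort("All probabilities must lie in [0, 1].")
  if (abs(sum(cfg$income_probs) - 1) > 1e-8) {
    abort("`income_probs` must sum to 1.")
  }
  if (length(cfg$activation_dates) == 0) {
    abort("`activation_dates` must be non-empty.")
  }
  if (any(format(cfg$activation_dates, "%Y") != "2005")) {
    abort("All activation dates must fall within calendar 2005.")
  }
  if (any(cfg$copay_model$sdlog < 0)) abort("Copay dispersion must be >= 0.")
  if (cfg$adherence_model$pcp_sd < 0 || cfg$adherence_model$resid_sd < 0) {
    abort("Adherence model SDs must be >= 0.")
  }
  needed <- tidyr::expand_grid(group = GROUPS, period = PERIODS,
                               med_class = CLASSES)
  missing_cells <- dplyr::anti_join(
    needed, cfg$tier_probabilities, by = c("group", "period", "med_class")
  )
  if (nrow(missing_cells) > 0) {
    cell <- missing_cells[1, ]
    abort(sprintf(
      "tier_probabilities is missing the (%s, %s, %s) cell.",
      cell$group, cell$period, cell$med_class
    ))
  }
  if (cfg$study_end <= cfg$study_start) abort("Empty study window.")
  cfg
}

#' Read a simulation configuration from a YAML file
#'
#' Scalar fields override the defaults of [sim_config()]; `seed` must be
#' present in the file unless supplied through the `seed` argument. Dates are
#' ISO-8601 strings. The tier-probability table can be given either as
#' `tier_calibration: default|table2|uniform` (with optional
#' `uniform_p`) or as an inline list of `{group, period, med_class,
#' p_preferred}` records under `tier_probabilities`.
#'
#' @param path Path to the YAML file.
#' @param seed Optional seed overriding the file.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  seed <- seed %||% raw$seed
  if (is.null(seed)) abort("A seed is mandatory (in the file or as a flag).")
  args <- list(seed = seed)
  if (!is.null(raw$n_pcps)) args$n_pcps <- unlist(raw$n_pcps)
  for (f in c("patients_per_pcp", "class_mix", "p_both_classes",
              "p_freq_gt_daily")) {
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  }
  for (f in c("study_start", "study_end", "interruptive_start")) {
    if (!is.null(raw[[f]])) args[[f]] <- as.Date(raw[[f]])
  }
  if (!is.null(raw$activation_dates)) {
    args$activation_dates <- as.Date(unlist(raw$activation_dates))
  }
  if (!is.null(raw$tier_probabilities)) {
    args$tier_probabilities <- dplyr::bind_rows(raw$tier_probabilities)
  } else if (!is.null(raw$tier_calibration)) {
    args$tier_probabilities <- switch(
      raw$tier_calibration,
      default = tier_cells_default(),
      table2 = tier_cells_table2(),
      uniform = tier_cells_uniform(raw$uniform_p %||% 0.65),
      abort(sprintf("Unknown tier_calibration '%s'.", raw$tier_calibration))
    )
  }
  if (!is.null(raw$copay_model)) {
    args$copay_model <- dplyr::bind_rows(raw$copay_model)
  }
  if (!is.null(raw$copay_sdlog)) {
    args$copay_model <- default_copay_model(sdlog = raw$copay_sdlog)
  }
  if (!is.null(raw$adherence_model)) {
    args$adherence_model <- modifyList(default_adherence_model(),
                                       raw$adherence_model)
  }
  do.call(sim_config, args)
}
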