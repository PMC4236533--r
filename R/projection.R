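#' Expected monthly copayment change from a preferred-tier shift
#'
#' A shift of `delta_p` of prescriptions from the non-preferred to the
#' preferred tier changes the expected monthly copayment by
#' `c_non - [delta_p * c_pref + (1 - delta_p) * c_non]`, i.e.
#' `delta_p * (c_non - c_pref)` dollars saved per month.
#'
#' @param delta_p Absolute increase in the probability of a preferred-tier
#'   prescription, in `[0, 1]`.
#' @param copay_preferred,copay_nonpreferred Monthly copayments (dollars).
#' @return Expected reduction in monthly copayment, rounded to cents.
#' @export
expected_copay_change <- function(delta_p, copay_preferred,
                                  copay_nonpreferred) {
  if (any(delta_p < 0 | delta_p > 1)) {
    abort("`delta_p` must lie in [0, 1].")
  }
  round(copay_nonpreferred -
          (delta_p * copay_preferred + (1 - delta_p) * copay_nonpreferred),
        2)
}

#' PDC change implied by a copayment change
#'
#' Applies the fitted adherence slope on the transformed copayment scale:
#' `slope * (new^lambda - base^lambda)`. With the negative quarter-power
#' slope, a falling copayment yields a positive PDC change.
#'
#' @param copay_slope Absolute PDC change per unit of transformed copayment
#'   (default -0.08 per unit monthly copay to the 1/4 power).
#' @param base_copay,new_copay Monthly copayments (dollars, positive).
#' @param lambda Transform exponent (default 0.25).
#' @return Absolute change in PDC (proportion scale).
#' @export
pdc_change_from_copay <- function(copay_slope, base_copay, new_copay,
                                  lambda = 0.25) {
  if (any(base_copay <= 0 | new_copay <= 0)) {
    abort("Copayments must be positive.")
  }
  copay_slope * (new_copay^lambda - base_copay^lambda)
}

#' PDC change from a cost-sharing elasticity benchmark
#'
#' A proportional-response projection: with an elasticity of `elasticity`
#' (use decrease per unit relative cost-sharing increase; the benchmark
#' midrange is 0.4, i.e. a 4% use decrease per 10% cost increase), a signed
#' relative copayment change of `relative_copay_change` moves adherence by
#' `base_pdc * elasticity * (-relative_copay_change)`.
#'
#' @param base_pdc Baseline PDC in `[0, 1]` (0.60 in the benchmark
#'   projection).
#' @param elasticity Non-negative elasticity magnitude.
#' @param relative_copay_change Signed fractional change in copayment
#'   (negative = cheaper).
#' @return Absolute change in PDC.
#' @export
elasticity_projection <- function(base_pdc, elasticity,
                                  relative_copay_change) {
  if (any(base_pdc < 0 | base_pdc > 1)) abort("`base_pdc` must be in [0, 1].")
  if (any(elasticity < 0)) abort("`elasticity` must be >= 0.")
  base_pdc * elasticity * (-relative_copay_change)
}

#' Absolute probability shift implied by an odds ratio
#'
#' Converts a baseline probability to odds, applies the odds ratio, and
#' back-transforms; returns the new minus the baseline probability.
#'
#' @param odds_ratio Positive odds ratio.
#' @param baseline_probability Baseline probability strictly inside (0, 1).
#' @return Absolute increase in probability.
#' @export
net_probability_shift <- function(odds_ratio, baseline_probability) {
  if (any(odds_ratio <= 0)) abort("`odds_ratio` must be positive.")
  if (any(baseline_probability <= 0 | baseline_probability >= 1)) {
    abort("`baseline_probability` must be strictly inside (0, 1).")
  }
  odds <- baseline_probability / (1 - baseline_probability) * odds_ratio
  odds / (1 + odds) - baseline_probability
}

#' Chain the three model links into copayment and adherence projections
#'
#' Composes the FDS-to-tier odds ratio, the tier-to-copayment cell
#' estimates, and the copayment-to-adherence slope into (a) the expected
#' monthly copayment reduction per class, (b) the implied PDC gain
#' evaluated at the class's expected baseline copayment
#' (`delta_p * c_pref + (1 - delta_p) * c_non` after the shift), and (c) an
#' external-benchmark variant substituting survey copayments and a
#' cost-sharing elasticity for the study's own weak tier-to-copayment and
#' copayment-to-adherence links.
#'
#' @param odds_ratio Interaction odds ratio of the FDS:tier model.
#' @param baseline_probability Baseline preferred-tier probability the odds
#'   ratio acts on (per class, named numeric or scalar).
#' @param tier_copay Tibble with `med_class`, `preferred`, `nonpreferred`
#'   (as produced by `tidy()` on a [fit_tier_copay()] fit or by
#'   [true_parameters()]).
#' @param copay_slope Adherence slope per unit transformed copayment.
#' @param lambda Copayment transform exponent.
#' @param benchmark_copays Numeric of length 2, external survey copayments
#'   `c(preferred, nonpreferred)` (defaults $29/$52).
#' @param elasticity,base_pdc Benchmark elasticity and baseline PDC.
#' @return A `projection_result` tibble, one row per class plus one
#'   benchmark row, with the assumption columns echoed.
#' @export
project_effects <- function(odds_ratio, baseline_probability, tier_copay,
                            copay_slope = -0.08, lambda = 0.25,
                            benchmark_copays = c(preferred = 29,
                                                 nonpreferred = 52),
                            elasticity = 0.4, base_pdc = 0.60) {
  if (length(baseline_probability) == 1) {
    baseline_probability <- setNames(
      rep(baseline_probability, nrow(tier_copay)), tier_copay$med_class)
  }
  rows <- purrr::pmap(tier_copay, function(med_class, preferred,
                                           nonpreferred, ...) {
    dp <- net_probability_shift(odds_ratio,
                                baseline_probability[[med_class]])
    dc <- expected_copay_change(dp, preferred, nonpreferred)
    base <- dp * preferred + (1 - dp) * nonpreferred
    tibble(
      scope = med_class, delta_p = dp,
      copay_preferred = preferred, copay_nonpreferred = nonpreferred,
      expected_copay_change = dc,
      pdc_change = pdc_change_from_copay(copay_slope, base, base - dc,
                                         lambda)
    )
  })
  dp_bench <- net_probability_shift(
    odds_ratio, baseline_probability[[1]])
  dc_bench <- expected_copay_change(dp_bench, benchmark_copays[["preferred"]],
                                    benchmark_copays[["nonpreferred"]])
  bench <- tibble(
    scope = "external_benchmark", delta_p = dp_bench,
    copay_preferred = benchmark_copays[["preferred"]],
    copay_nonpreferred = benchmark_copays[["nonpreferred"]],
    expected_copay_change = dc_bench,
    pdc_change = elasticity_projection(base_pdc, elasticity, -dp_bench)
  )
  out <- bind_rows(bind_rows(rows), bench) %>%
    mutate(odds_ratio = odds_ratio, copay_slope = copay_slope,
           lambda = lambda, elasticity = elasticity, base_pdc = base_pdc)
  class(out) <- c("projection_result", class(out))
  out
}
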