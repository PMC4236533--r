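default_constants <- function() {
  list(survey_copay_preferred = 29, survey_copay_nonpreferred = 52,
       elasticity = 0.4, base_pdc = 0.60)
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
}

#' Run the full analysis pipeline on a synthetic study
#'
#' End-to-end orchestration: simulate rosters and claims, build the
#' new-user cohort (exclusion cascade, synthetic control dates, period and
#' group labels), compute 180-day PDC, fit the three statistical links,
#' chain them into projections, and write paper-style tables plus machine-
#' readable estimates and a run manifest to `out_dir`. Re-running with the
#' same configuration reproduces every numeric output. All computation
#' happens in the module functions; this layer only sequences and writes.
#'
#' @param config A [sim_config()] object or the path to a YAML config file.
#' @param out_dir Output directory (created if missing). `NULL` skips all
#'   file output and just returns the results.
#' @param constants External benchmark constants (see
#'   `default_constants()`): survey copayments and cost-sharing elasticity.
#' @param lambda Copayment Box-Cox exponent used by the tier:copayment and
#'   copayment:adherence models. Default 0.25 (the published quarter-power
#'   transform); `"select"` chooses it on the run's own data with
#'   [boxcox_select()], adjusting for class, income and dosing frequency.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the simulated tables, cohort, PDC
#'   records, fitted models, `estimates`, `projections` and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         constants = default_constants(), lambda = 0.25,
                         quiet = FALSE) {
  t0 <- Sys.time()
  if (is.character(config)) config <- read_sim_config(config)
  config <- validate_sim_config(config)
  say <- function(fmt, ...) {
    if (!quiet) message(sprintf(paste0("[%5.1fs] ", fmt),
                                as.numeric(Sys.time() - t0, units = "secs"),
                                ...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  say("simulate: %d PCPs x %d patients", sum(config$n_pcps),
      config$patients_per_pcp)
  sim <- stage("simulate", simulate_study(config))
  say("simulated %d claims for %d patients", nrow(sim$claims),
      nrow(sim$patients))

  cohort <- stage("cohort", build_cohort(
    sim$claims, sim$pcps, seed = config$seed + 2L,
    interruptive_start = config$interruptive_start
  ))
  say("cohort: %d index claims (%d adherence-eligible)",
      nrow(cohort$index_claims),
      sum(cohort$index_claims$eligible_for_adherence))

  pdc <- stage("pdc", compute_pdc(cohort$index_claims, sim$claims,
                                  extract_end = config$study_end))
  adher_data <- cohort$index_claims %>%
    dplyr::inner_join(pdc %>% select("claim_id", "pdc", "covered_days"),
                      by = "claim_id") %>%
    left_join(sim$patients %>% select("patient_id", "income"),
              by = "patient_id")
  say("pdc: %d records, mean PDC %.3f", nrow(pdc), mean(pdc$pdc))

  table2 <- stage("table2", summarize_unadjusted(cohort$index_claims))
  fds_fit <- stage("fds_tier", fit_fds_tier(cohort$index_claims))
  say("fds:tier GEE converged in %d iterations (alpha %.3f)",
      fds_fit$gee$iterations, fds_fit$gee$alpha)
  tc_fit <- stage("tier_copay", fit_tier_copay(
    cohort$index_claims,
    lambda = if (identical(lambda, "select")) 0.25 else lambda
  ))
  if (identical(lambda, "select")) {
    lambda <- stage("boxcox", as.numeric(boxcox_select(
      adher_data$monthly_copayment, adher_data$pdc,
      covariates = adher_data[, c("med_class", "income", "doses_per_day")]
    )))
    say("box-cox selected lambda %.2f", lambda)
  }
  ca_fit <- stage("copay_adherence", fit_copay_adherence(adher_data,
                                                         lambda = lambda))

  fds_tidy <- tidy(fds_fit)
  interaction_or <- fds_tidy$estimate[
    fds_tidy$term == "grouphigh:periodboth_fds"]
  baseline <- table2 %>%
    filter(.data$group == "high",
           .data$period == "noninterruptive_only") %>%
    pull(.data$pct_preferred) / 100
  slope <- tidy(ca_fit)$estimate[tidy(ca_fit)$term == "copay_bc"]
  if (length(interaction_or) == 1 && length(baseline) == 1 &&
      is.finite(baseline) && baseline > 0 && baseline < 1) {
    projections <- stage("projection", project_effects(
      odds_ratio = interaction_or, baseline_probability = baseline,
      tier_copay = tidy(tc_fit), copay_slope = slope, lambda = lambda,
      benchmark_copays = c(preferred = constants$survey_copay_preferred,
                           nonpreferred = constants$survey_copay_nonpreferred),
      elasticity = constants$elasticity,
      base_pdc = constants$base_pdc
    ))
  } else {
    say(paste("projection skipped: the high-user x combined-FDS cell is",
              "absent or degenerate in this cohort"))
    projections <- tibble(note = paste(
      "not computed: high-user x combined-FDS exposure cell absent",
      "or degenerate"))
  }

  estimates <- list(
    fds_tier = fds_tidy, fds_tier_glance = glance(fds_fit),
    tier_copay = tidy(tc_fit), boxcox_lambda = lambda,
    copay_adherence = tidy(ca_fit),
    copay_adherence_glance = glance(ca_fit)
  )
  manifest <- list(
    package_version = as.character(utils::packageVersion("fdslink")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config_hash = rlang::hash(config),
    timestamp = format(Sys.time(), tz = "UTC"),
    exclusions = cohort$exclusions,
    n_pcps = nrow(sim$pcps), n_patients = nrow(sim$patients)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    readr::write_csv(sim$claims, p("claims.csv"))
    readr::write_csv(sim$pcps, p("pcps.csv"))
    readr::write_csv(sim$patients, p("patients.csv"))
    readr::write_csv(cohort$index_claims, p("cohort.csv"))
    readr::write_csv(pdc, p("pdc.csv"))
    readr::write_csv(table2, p("table2.csv"))
    readr::write_csv(tidy(fds_fit), p("table3.csv"))
    readr::write_csv(tidy(ca_fit), p("table4.csv"))
    write_json_out(estimates, p("estimates.json"))
    write_json_out(projections, p("projections.json"))
    write_json_out(manifest, p("manifest.json"))
    say("wrote outputs to %s", out_dir)
  }
  invisible(list(
    config = config, sim = sim, cohort = cohort, pdc = pdc,
    adherence_data = adher_data, table2 = table2, fds_tier = fds_fit,
    tier_copay = tc_fit, copay_adherence = ca_fit,
    boxcox_lambda = lambda, estimates = estimates,
    projections = projections, manifest = manifest
  ))
}
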