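# Small-world configuration used across tests: enough prescribers per group
# for the clustered fits, small enough to keep the suite fast.
small_config <- function(seed = 1, ...) {
  sim_config(seed = seed,
             n_pcps = c(non = 150L, low = 40L, high = 20L),
             patients_per_pcp = 10L, ...)
}

# Literal day-by-day PDC oracle: simulate a pill stock (shift) or mark each
# fill's own calendar span (truncate) over the window, then count marked
# days. Independent of the interval arithmetic in the package.
pdc_oracle <- function(d, s, window = 180L, overlap = "shift") {
  cover <- rep(FALSE, window)
  if (overlap == "shift") {
    stock <- 0
    t <- min(c(d, 0L))
    horizon <- max(d) + sum(s) + window
    while (t < horizon) {
      if (any(d == t)) stock <- stock + sum(s[d == t])
      if (stock > 0) {
        if (t >= 0 && t < window) cover[t + 1] <- TRUE
        stock <- stock - 1
      }
      t <- t + 1
    }
  } else {
    for (k in seq_along(d)) {
      for (t in d[k]:(d[k] + s[k] - 1)) {
        if (t >= 0 && t < window) cover[t + 1] <- TRUE
      }
    }
  }
  sum(cover)
}

pdc_tables <- function(d, s, index_day = 0L) {
  origin <- as.Date("2005-01-01")
  list(
    idx = tibble::tibble(claim_id = "i1", patient_id = "p1",
                         med_class = "ARB", fill_date = origin + index_day),
    claims = tibble::tibble(patient_id = "p1", med_class = "ARB",
                            fill_date = origin + d, days_supplied = s)
  )
}

# Clustered binary fixture whose exchangeable-GEE solution was computed
# independently (statsmodels GEE on the identical CSV); the expected
# numbers frozen in test-gee.R come from that run.
gee_fixture <- function() {
  set.seed(123)
  n_cl <- 60
  m <- 8
  dat <- tibble::tibble(
    id = rep(sprintf("c%02d", 1:n_cl), each = m),
    x1 = rnorm(n_cl * m),
    x2 = rbinom(n_cl * m, 1, 0.4),
    u = rep(rnorm(n_cl, 0, 0.8), each = m)
  )
  dat$y <- rbinom(nrow(dat), 1, plogis(-0.3 + 0.7 * dat$x1 - 0.5 * dat$x2 +
                                         dat$u))
  dat
}

# One simulated study -> the three fitted links, returned with CIs, for
# recovery and coverage checks.
fit_all_links <- function(cfg) {
  sim <- simulate_study(cfg)
  coh <- build_cohort(sim$claims, sim$pcps, seed = cfg$seed + 2L,
                      interruptive_start = cfg$interruptive_start)
  pdc <- compute_pdc(coh$index_claims, sim$claims,
                     extract_end = cfg$study_end)
  adher <- dplyr::inner_join(coh$index_claims,
                             pdc[, c("claim_id", "pdc")], by = "claim_id")
  adher <- dplyr::left_join(adher, sim$patients[, c("patient_id", "income")],
                            by = "patient_id")
  list(
    sim = sim, cohort = coh,
    fds = fit_fds_tier(coh$index_claims),
    tc = fit_tier_copay(coh$index_claims),
    ca = fit_copay_adherence(adher, lambda = 0.25),
    adher = adher
  )
}
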