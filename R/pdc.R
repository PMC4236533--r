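# Covered days inside [0, window) for fills at integer day offsets `d`
# (relative to the index fill) with supplies `supply`, under either overlap
# convention. Fills must be sorted by day. "shift" queues overlapping
# supply to start when the previous supply runs out (stockpiling);
# "truncate" discards overlap (each fill covers its own calendar span).
covered_days_engine <- function(d, supply, window, overlap) {
  covered <- 0L
  if (overlap == "shift") {
    e <- -.Machine$integer.max
    for (k in seq_along(d)) {
      s <- max(d[k], e)
      e <- s + supply[k]
      covered <- covered + max(0L, min(e, window) - max(s, 0L))
    }
  } else {
    e <- -.Machine$integer.max
    for (k in seq_along(d)) {
      s <- max(d[k], e)           # start of the *new* coverage this fill adds
      e2 <- d[k] + supply[k]
      covered <- covered + max(0L, min(e2, window) - max(s, 0L))
      e <- max(e, e2)
    }
  }
  covered
}

# Grouped cumulative sum / cumulative max over runs of equal consecutive
# group ids (rows must be sorted by group). The cummax uses an offset large
# enough to dominate the value range, so it stays exact in doubles.
grouped_cumsum <- function(x, gid) {
  cs <- cumsum(x)
  first <- !duplicated(gid)
  base <- cs[first] - x[first]
  cs - rep(base, times = rle(gid)$lengths)
}

grouped_cummax <- function(x, gid_seq) {
  big <- 1e9
  cummax(x + gid_seq * big) - gid_seq * big
}

# Vectorized covered-days for groups holding exactly one index claim each:
# the sequential recursions reduce to grouped cumsum/cummax identities
#   shift:    e_k = max_j<=k (d_j - C_{j-1}) + C_k,  start_k = e_k - s_k
#   truncate: start_k = max(d_k, max_j<k e2_j),      e2_k = d_k + s_k
covered_days_vectorized <- function(d, supply, gid_seq, window, overlap) {
  if (overlap == "shift") {
    C <- grouped_cumsum(supply, gid_seq)
    e <- grouped_cummax(d - (C - supply), gid_seq) + C
    contrib <- pmax(0, pmin(e, window) - pmax(e - supply, 0))
  } else {
    e2 <- d + supply
    first <- !duplicated(gid_seq)
    prev <- c(-.Machine$integer.max, grouped_cummax(e2, gid_seq)[-length(e2)])
    prev[first] <- -.Machine$integer.max
    contrib <- pmax(0, pmin(e2, window) - pmax(pmax(d, prev), 0))
  }
  drop(rowsum(contrib, gid_seq))
}

#' Proportion of days covered over a fixed follow-up window
#'
#' For every adherence-eligible index claim, computes the fraction of the
#' `window_days` days starting at the index fill date (day 0 counts as
#' covered day 1) on which any medication of the index class was available
#' to the patient, pooling fills across tiers and products within the
#' class. Each fill contributes its days supplied from its fill date; under
#' the default stockpiling convention (`overlap = "shift"`), supply
#' dispensed while a previous supply is still active is queued to start
#' when that supply runs out, while `overlap = "truncate"` discards the
#' overlap. Coverage beyond the window end is truncated. Fills dated before
#' the index claim also contribute any supply that (possibly after
#' shifting) reaches into the window.
#'
#' @param index_claims Index-claim tibble (needs `claim_id`, `patient_id`,
#'   `med_class`, `fill_date`; rows with `eligible_for_adherence == FALSE`
#'   are skipped when the column is present and `eligible_only = TRUE`).
#' @param claims All claims of the same patients (any tier), used as the
#'   supply stream; needs `patient_id`, `med_class`, `fill_date`,
#'   `days_supplied`.
#' @param window_days Follow-up window length in days (default 180).
#' @param overlap `"shift"` (stockpiling, default) or `"truncate"`.
#' @param extract_end Optional last date observable in the claims extract;
#'   windows running past it are still computed but flagged
#'   `right_censored`.
#' @param eligible_only Drop adherence-ineligible index claims first.
#' @return A tibble with one row per computed index claim: `claim_id`,
#'   `covered_days`, `pdc` (= covered / window), `window_start`,
#'   `window_end`, `right_censored`.
#' @export
compute_pdc <- function(index_claims, claims, window_days = 180L,
                        overlap = c("shift", "truncate"),
                        extract_end = NULL, eligible_only = TRUE) {
  overlap <- match.arg(overlap)
  window_days <- as.integer(window_days)
  idx <- index_claims
  if (eligible_only && "eligible_for_adherence" %in% names(idx)) {
    idx <- filter(idx, .data$eligible_for_adherence)
  }
  if (nrow(idx) == 0) {
    return(tibble(claim_id = character(), covered_days = integer(),
                  pdc = numeric(), window_start = as.Date(character()),
                  window_end = as.Date(character()),
                  right_censored = logical()))
  }
  supply <- claims %>%
    select("patient_id", "med_class", "fill_date", "days_supplied") %>%
    arrange(.data$patient_id, .data$med_class, .data$fill_date)
  skey <- paste(supply$patient_id, supply$med_class, sep = "\r")
  sday <- as.integer(supply$fill_date)
  ikey <- paste(idx$patient_id, idx$med_class, sep = "\r")
  iday <- as.integer(idx$fill_date)
  covered <- integer(nrow(idx))

  # Fast path: patient-class groups holding exactly one index claim.
  n_index_in_key <- table(ikey)
  single <- ikey %in% names(n_index_in_key)[n_index_in_key == 1]
  if (any(single)) {
    pos <- match(skey, ikey[single])
    use <- !is.na(pos)
    gid <- pos[use]
    o <- order(gid)                     # rows sorted by key, then date
    gid <- gid[o]
    d <- (sday[use][o] - iday[single][gid])
    s <- supply$days_supplied[use][o]
    cov_g <- covered_days_vectorized(d, s, gid, window_days, overlap)
    cov_all <- integer(sum(single))
    cov_all[as.integer(names(cov_g))] <- as.integer(round(cov_g))
    covered[single] <- cov_all
  }

  # Sequential engine for the remaining (multi-index) groups.
  rest <- which(!single)
  if (length(rest) > 0) {
    supply_split <- split(seq_len(nrow(supply)), skey)
    for (i in rest) {
      rows <- supply_split[[ikey[i]]]
      if (is.null(rows)) next
      covered[i] <- covered_days_engine(sday[rows] - iday[i],
                                        supply$days_supplied[rows],
                                        window_days, overlap)
    }
  }

  out <- tibble(
    claim_id = idx$claim_id,
    covered_days = covered,
    pdc = covered / window_days,
    window_start = idx$fill_date,
    window_end = idx$fill_date + window_days,
    right_censored = if (is.null(extract_end)) FALSE else
      idx$fill_date + window_days - 1L > as.Date(extract_end)
  )
  if (any(out$right_censored)) {
    warn(sprintf(
      "%d PDC window(s) extend past the extract end and are right-censored.",
      sum(out$right_censored)
    ))
  }
  out
}
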