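box_cox <- function(x, lambda) {
  if (lambda == 0) log(x) else x^lambda
}

#' Fit the FDS-to-tier difference-in-differences model
#'
#' Clustered logistic regression of preferred-tier status on medication
#' class, prescriber usage group, exposure period, and the four
#' group-by-period interactions, estimated by GEE with an exchangeable
#' working correlation within prescriber and robust standard errors. The
#' effect of interest is the high-user x combined-FDS interaction: how much
#' more the odds of a preferred-tier choice rose among heavy e-prescribers
#' once interruptive alerts were live, net of the secular trend among
#' non-adopters.
#'
#' @param index_claims Labelled cohort from [build_cohort()] (needs `tier`,
#'   `med_class`, `group`, `period`, `pcp_id`).
#' @param include_pediatric Add a pediatric-prescriber indicator (needs a
#'   `specialty` column); off by default, matching the primary model.
#' @param corstr Working correlation for the GEE.
#' @return A `fds_tier_fit` object wrapping the `gee_logit` fit.
#' @export
fit_fds_tier <- function(index_claims, include_pediatric = FALSE,
                         corstr = "exchangeable") {
  dat <- index_claims %>%
    mutate(
      preferred = as.integer(.data$tier == "preferred"),
      med_class = factor(.data$med_class, levels = CLASSES),
      group = factor(.data$group, levels = GROUPS),
      period = factor(.data$period, levels = PERIODS)
    )
  cells <- dat %>% count(.data$group, .data$period, .drop = FALSE)
  empty <- filter(cells, .data$n == 0)
  if (nrow(empty) > 0) {
    warn(paste0(
      "No claims in group x period cell(s): ",
      paste(sprintf("(%s, %s)", empty$group, empty$period), collapse = ", "),
      "; the corresponding terms are dropped from the fit."
    ))
    dat <- dat %>%
      mutate(group = droplevels(.data$group),
             period = droplevels(.data$period))
  }
  rhs <- "med_class + group + period + group:period"
  if (include_pediatric) {
    dat <- mutate(dat, pediatric = .data$specialty == "Pediatrics")
    rhs <- paste(rhs, "+ pediatric")
  }
  fml <- as.formula(paste("preferred ~", rhs))
  fit <- gee_logit(fml, data = as.data.frame(dat), id = pcp_id,
                   corstr = corstr)
  structure(list(gee = fit, dropped_cells = empty,
                 include_pediatric = include_pediatric),
            class = "fds_tier_fit")
}

#' @method tidy fds_tier_fit
#' @export
tidy.fds_tier_fit <- function(x, exponentiate = TRUE, conf.level = 0.95,
                              ...) {
  tidy(x$gee, exponentiate = exponentiate, conf.level = conf.level)
}

#' @method glance fds_tier_fit
#' @export
glance.fds_tier_fit <- function(x, ...) glance(x$gee)

#' @export
print.fds_tier_fit <- function(x, ...) {
  cat("FDS:tier difference-in-differences model (clustered logistic GEE)\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Model-implied preferred-tier probability for a cell
#'
#' Applies the fitted odds ratios multiplicatively on the odds scale and
#' back-transforms, which is algebraically identical to evaluating the
#' linear predictor; exposed so the odds-ratio/probability consistency of
#' the fit can be checked and so cell probabilities can be reported.
#'
#' @param fit A `fds_tier_fit`.
#' @param group,period,med_class Cell coordinates.
#' @return Model-implied probability of a preferred-tier claim.
#' @export
predict_cell_probability <- function(fit, group, period,
                                     med_class = "ARB") {
  est <- coef(fit$gee)
  lp <- est[["(Intercept)"]]
  add <- function(nm) if (nm %in% names(est)) est[[nm]] else 0
  if (med_class == "IS") lp <- lp + add("med_classIS")
  if (group != "non") lp <- lp + add(paste0("group", group))
  if (period != "pre") lp <- lp + add(paste0("period", period))
  if (group != "non" && period != "pre") {
    lp <- lp + add(paste0("group", group, ":period", period))
  }
  plogis(lp)
}

#' Select a Box-Cox exponent for the copayment variable
#'
#' Searches a grid of exponents for the power transform of the (positive)
#' monthly copayment. With a `response` supplied, the criterion is the root
#' mean square error of the linear regression of the response on the
#' transformed copayment, mirroring transform-then-regress selection; the
#' grid exponent with the smallest RMSE wins (first on ties, so the
#' default coarse grid prefers the simpler exponent). Without a response,
#' the classical Box-Cox profile log-likelihood of the transformed variable
#' (with its Jacobian) is maximized. `lambda = 0` denotes the log
#' transform. Ranking under either criterion is invariant to rescaling the
#' copayments by a positive constant.
#'
#' @param copay Positive monthly copayments.
#' @param response Optional outcome (e.g. PDC) for the regression criterion.
#' @param lambda_grid Exponents to search (default 0, 1/4, 1/2, 1).
#' @param covariates Optional data frame of adjustment covariates included
#'   in the selection regression (e.g. medication class), so the transform
#'   is judged on the within-stratum copayment-response relationship.
#' @return The selected exponent, with the search profile attached as
#'   attribute `"profile"`.
#' @export
boxcox_select <- function(copay, response = NULL,
                          lambda_grid = c(0, 0.25, 0.5, 1),
                          covariates = NULL) {
  if (length(lambda_grid) == 0) abort("`lambda_grid` must be non-empty.")
  if (any(copay <= 0)) {
    abort(paste("Copayments must be strictly positive for a Box-Cox",
                "transform; add a small shift constant to zero copays."))
  }
  if (!is.null(response)) {
    score <- vapply(lambda_grid, function(l) {
      dat <- data.frame(.y = response, .x = box_cox(copay, l))
      if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
      sqrt(mean(resid(lm(.y ~ ., data = dat))^2))
    }, numeric(1))
    best <- lambda_grid[which.min(score)]
    profile <- tibble(lambda = lambda_grid, rmse = score)
  } else {
    n <- length(copay)
    score <- vapply(lambda_grid, function(l) {
      y <- if (l == 0) log(copay) else (copay^l - 1) / l
      -n / 2 * log(mean((y - mean(y))^2)) + (l - 1) * sum(log(copay))
    }, numeric(1))
    best <- lambda_grid[which.max(score)]
    profile <- tibble(lambda = lambda_grid, loglik = score)
  }
  structure(best, profile = profile)
}

#' Fit the tier-to-copayment model
#'
#' Linear regression of the Box-Cox transformed monthly copayment on
#' formulary tier, medication class and their interaction (the insurer is
#' assumed to set copayments from tier and class alone; the interaction
#' makes every class-by-tier cell exactly representable). Cell estimates
#' are back-transformed to dollars, which for a right-skewed copayment
#' distribution approximates the cell median; `lambda = 1` gives the
#' untransformed model whose cells are means.
#'
#' @param index_claims Cohort tibble with `monthly_copayment`, `tier`,
#'   `med_class`.
#' @param lambda Box-Cox exponent applied to the copayment (default 0.25).
#' @return A `tier_copay_fit` with the `lm` fit, per-cell dollar estimates
#'   and per-class tier differences.
#' @export
fit_tier_copay <- function(index_claims, lambda = 0.25) {
  dat <- index_claims %>%
    mutate(tier = factor(.data$tier, levels = TIERS),
           med_class = factor(.data$med_class, levels = CLASSES),
           copay_bc = box_cox(.data$monthly_copayment, lambda))
  single_tier <- dplyr::n_distinct(dat$tier) < 2
  if (single_tier) {
    warn("Only one formulary tier present; fitting a class-only model.")
    fit <- lm(copay_bc ~ med_class, data = dat)
  } else {
    fit <- lm(copay_bc ~ tier * med_class, data = dat)
  }
  grid <- tidyr::expand_grid(
    tier = factor(TIERS, levels = TIERS),
    med_class = factor(CLASSES, levels = CLASSES)
  )
  pred <- unname(predict(fit, newdata = grid))
  grid$copay_dollars <- if (lambda == 0) exp(pred) else pred^(1 / lambda)
  cells <- tidyr::pivot_wider(grid, names_from = "tier",
                              values_from = "copay_dollars") %>%
    mutate(tier_difference = .data$nonpreferred - .data$preferred)
  structure(list(lm = fit, lambda = lambda, cells = cells,
                 single_tier = single_tier),
            class = "tier_copay_fit")
}

#' @method tidy tier_copay_fit
#' @export
tidy.tier_copay_fit <- function(x, ...) {
  x$cells %>% mutate(med_class = as.character(.data$med_class))
}

#' @method glance tier_copay_fit
#' @export
glance.tier_copay_fit <- function(x, ...) {
  s <- summary(x$lm)
  tibble(lambda = x$lambda, r.squared = s$r.squared, sigma = s$sigma,
         n = length(resid(x$lm)))
}

#' @export
print.tier_copay_fit <- function(x, ...) {
  cat(sprintf("Tier:copayment model on copay^%s scale\n",
              format(x$lambda)))
  print(tidy(x))
  invisible(x)
}

#' Fit the copayment-to-adherence mixed model
#'
#' Linear mixed model of the absolute PDC on the Box-Cox transformed
#' monthly copayment, medication class, income stratum and
#' more-than-daily dosing, with a prescriber random intercept (REML).
#' Coefficients are absolute changes in PDC: the copayment coefficient is
#' the PDC change per unit increase of the monthly copayment to the
#' `lambda` power. Wald z statistics on the fixed effects are reported;
#' with fewer than two prescribers the random effect is dropped and a
#' plain linear model fitted, with a warning.
#'
#' @param pdc_data Tibble with `pdc`, `monthly_copayment`, `med_class`,
#'   `income`, `doses_per_day`, `pcp_id`.
#' @param lambda Box-Cox exponent for the copayment (default 0.25,
#'   typically the output of [boxcox_select()]).
#' @param extra_covariates Names of additional columns of `pdc_data` to
#'   include as fixed effects (candidates for [backward_select()]).
#' @return A `copay_adherence_fit`.
#' @export
fit_copay_adherence <- function(pdc_data, lambda = 0.25,
                                extra_covariates = NULL) {
  dat <- pdc_data %>%
    mutate(copay_bc = box_cox(.data$monthly_copayment, lambda),
           med_class = factor(.data$med_class, levels = CLASSES),
           income = factor(.data$income, levels = INCOMES),
           freq_gt_daily = .data$doses_per_day > 1)
  dat <- as.data.frame(dat)
  has_re <- dplyr::n_distinct(dat$pcp_id) >= 2
  rhs <- paste(c("copay_bc", "med_class", "income", "freq_gt_daily",
                 extra_covariates), collapse = " + ")
  if (has_re) {
    fml <- as.formula(paste("pdc ~", rhs, "+ (1 | pcp_id)"))
    fit <- lme4::lmer(fml, data = dat, REML = TRUE)
  } else {
    warn("Fewer than two prescribers; dropping the random intercept.")
    fit <- lm(as.formula(paste("pdc ~", rhs)), data = dat)
  }
  structure(list(model = fit, lambda = lambda, has_re = has_re,
                 n = nrow(dat)),
            class = "copay_adherence_fit")
}

#' @method tidy copay_adherence_fit
#' @export
tidy.copay_adherence_fit <- function(x, conf.level = 0.95, ...) {
  if (x$has_re) {
    est <- lme4::fixef(x$model)
    se <- sqrt(diag(as.matrix(vcov(x$model))))
  } else {
    est <- coef(x$model)
    se <- sqrt(diag(vcov(x$model)))
  }
  z <- est / se
  q <- qnorm(1 - (1 - conf.level) / 2)
  tibble(term = names(est), estimate = unname(est),
         std.error = unname(se), statistic = unname(z),
         p.value = unname(2 * pnorm(-abs(z))),
         conf.low = unname(est - q * se), conf.high = unname(est + q * se))
}

#' @method glance copay_adherence_fit
#' @export
glance.copay_adherence_fit <- function(x, ...) {
  if (x$has_re) {
    vc <- as.data.frame(lme4::VarCorr(x$model))
    ml <- stats::update(x$model, REML = FALSE)
    tibble(n = x$n, lambda = x$lambda,
           pcp_sd = vc$sdcor[vc$grp == "pcp_id"],
           resid_sd = vc$sdcor[vc$grp == "Residual"],
           aic_ml = AIC(ml))
  } else {
    tibble(n = x$n, lambda = x$lambda, pcp_sd = NA_real_,
           resid_sd = summary(x$model)$sigma, aic_ml = AIC(x$model))
  }
}

#' @export
print.copay_adherence_fit <- function(x, ...) {
  cat(sprintf(
    "Copayment:adherence linear mixed model (PDC on copay^%s)\n",
    format(x$lambda)))
  print(tidy(x), n = Inf)
  invisible(x)
}

# ---- backward selection ----------------------------------------------------

term_pvalues_gee <- function(fit) {
  tl <- attr(terms(fit$formula), "term.labels")
  X <- model.matrix(fit$formula, fit$data)
  asg <- attr(X, "assign")
  vapply(seq_along(tl), function(i) {
    wald_term_p(coef(fit), fit$vcov_robust, colnames(X)[asg == i])
  }, numeric(1)) |> setNames(tl)
}

term_pvalues_lmer <- function(model) {
  fml <- stats::formula(model)
  fixed <- lme4::nobars(fml)
  tl <- attr(terms(fixed), "term.labels")
  X <- lme4::getME(model, "X")
  asg <- attr(model.matrix(fixed, stats::model.frame(model)), "assign")
  est <- lme4::fixef(model)
  V <- as.matrix(vcov(model))
  dimnames(V) <- list(names(est), names(est))
  vapply(seq_along(tl), function(i) {
    wald_term_p(est, V, colnames(X)[asg == i])
  }, numeric(1)) |> setNames(tl)
}

drop_term <- function(formula, term) {
  update(formula, as.formula(paste(". ~ . -", term)))
}

#' Backward elimination under a p-value threshold and a fit criterion
#'
#' Starting from a full fitted model, repeatedly considers the removable
#' term with the largest joint-Wald p-value above `alpha` and removes it if
#' the fit criterion — QIC for the clustered logistic GEE, ML-based AIC for
#' the linear mixed model — does not worsen; when the worst term's removal
#' worsens the criterion, the next-least-significant candidate is tried.
#' Interaction terms always protect their main effects, and `protected`
#' terms are never candidates. The procedure is deterministic given the
#' data.
#'
#' @param fit A `fds_tier_fit`, `gee_logit` or `copay_adherence_fit`.
#' @param alpha Retention threshold (default 0.05): terms with p <= alpha
#'   are kept.
#' @param protected Character vector of term labels never removed (defaults:
#'   the exposure terms `group`, `period`, `group:period` for the tier
#'   model; `copay_bc` for the adherence model).
#' @param use_criterion If `FALSE`, the QIC/AIC guard is skipped and
#'   removal is by p-value alone.
#' @return A refitted object of the same class as `fit`, with an
#'   `"elimination"` attribute recording each removal (term, p-value,
#'   criterion before/after).
#' @export
backward_select <- function(fit, alpha = 0.05, protected = NULL,
                            use_criterion = TRUE) {
  UseMethod("backward_select")
}

#' @export
backward_select.fds_tier_fit <- function(fit, alpha = 0.05,
                                         protected = c("group", "period",
                                                       "group:period"),
                                         use_criterion = TRUE) {
  inner <- backward_select(fit$gee, alpha = alpha, protected = protected,
                           use_criterion = use_criterion)
  out <- fit
  out$gee <- inner
  attr(out, "elimination") <- attr(inner, "elimination")
  out
}

#' @export
backward_select.gee_logit <- function(fit, alpha = 0.05, protected = NULL,
                                      use_criterion = TRUE) {
  log <- list()
  repeat {
    tl <- attr(terms(fit$formula), "term.labels")
    in_higher <- vapply(tl, function(t) {
      any(vapply(setdiff(tl, t), function(h) {
        all(strsplit(t, ":")[[1]] %in% strsplit(h, ":")[[1]])
      }, logical(1)))
    }, logical(1))
    removable <- setdiff(tl[!in_higher], protected)
    if (length(removable) == 0) break
    p <- term_pvalues_gee(fit)[removable]
    over <- if (alpha >= 1) !is.na(p) else !is.na(p) & p > alpha
    cand <- names(sort(p[over], decreasing = TRUE))
    if (length(cand) == 0) break
    removed <- FALSE
    for (term in cand) {
      new_fit <- gee_logit(drop_term(fit$formula, term), data = fit$data,
                           id = fit$id_var, corstr = fit$corstr)
      if (!use_criterion || new_fit$qic <= fit$qic + 1e-8) {
        log[[length(log) + 1]] <- tibble(
          term = term, p.value = unname(p[term]),
          criterion_before = fit$qic, criterion_after = new_fit$qic
        )
        fit <- new_fit
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }
  attr(fit, "elimination") <- bind_rows(log)
  fit
}

#' @export
backward_select.copay_adherence_fit <- function(fit, alpha = 0.05,
                                                protected = "copay_bc",
                                                use_criterion = TRUE) {
  if (!fit$has_re) {
    abort("Backward selection is implemented for the mixed-model fit.")
  }
  model <- fit$model
  crit <- AIC(stats::update(model, REML = FALSE))
  log <- list()
  repeat {
    fixed <- lme4::nobars(stats::formula(model))
    tl <- attr(terms(fixed), "term.labels")
    in_higher <- vapply(tl, function(t) {
      any(vapply(setdiff(tl, t), function(h) {
        all(strsplit(t, ":")[[1]] %in% strsplit(h, ":")[[1]])
      }, logical(1)))
    }, logical(1))
    removable <- setdiff(tl[!in_higher], protected)
    if (length(removable) == 0) break
    p <- term_pvalues_lmer(model)[removable]
    over <- if (alpha >= 1) !is.na(p) else !is.na(p) & p > alpha
    cand <- names(sort(p[over], decreasing = TRUE))
    if (length(cand) == 0) break
    removed <- FALSE
    for (term in cand) {
      new_model <- stats::update(model, drop_term(stats::formula(model),
                                                  term))
      new_crit <- AIC(stats::update(new_model, REML = FALSE))
      if (!use_criterion || new_crit <= crit + 1e-8) {
        log[[length(log) + 1]] <- tibble(
          term = term, p.value = unname(p[term]),
          criterion_before = crit, criterion_after = new_crit
        )
        model <- new_model
        crit <- new_crit
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }
  out <- fit
  out$model <- model
  attr(out, "elimination") <- bind_rows(log)
  out
}

#' Unadjusted preferred-tier percentages by user group and period
#'
#' The descriptive group-by-period table: percent of index claims on the
#' preferred tier in each of the nine cells, with an `all` margin over
#' groups and over periods. Empty cells report `NA`, not zero.
#'
#' @param index_claims Labelled cohort tibble (`group`, `period`, `tier`).
#' @return A tibble with `group`, `period`, `n`, `n_preferred`,
#'   `pct_preferred` (0-100 scale).
#' @export
summarize_unadjusted <- function(index_claims) {
  dat <- index_claims %>%
    mutate(group = factor(.data$group, levels = GROUPS),
           period = factor(.data$period, levels = PERIODS),
           preferred = .data$tier == "preferred")
  cells <- dat %>%
    group_by(.data$group, .data$period, .drop = FALSE) %>%
    summarise(n = n(), n_preferred = sum(.data$preferred), .groups = "drop")
  margin_g <- dat %>%
    group_by(.data$period, .drop = FALSE) %>%
    summarise(n = n(), n_preferred = sum(.data$preferred), .groups = "drop") %>%
    mutate(group = factor("all", levels = c(GROUPS, "all")))
  margin_p <- dat %>%
    group_by(.data$group, .drop = FALSE) %>%
    summarise(n = n(), n_preferred = sum(.data$preferred), .groups = "drop") %>%
    mutate(period = factor("all", levels = c(PERIODS, "all")))
  bind_rows(
    cells %>% mutate(group = factor(.data$group, levels = c(GROUPS, "all")),
                     period = factor(.data$period,
                                     levels = c(PERIODS, "all"))),
    margin_g %>% mutate(period = factor(.data$period,
                                        levels = c(PERIODS, "all"))),
    margin_p %>% mutate(group = factor(.data$group,
                                       levels = c(GROUPS, "all")))
  ) %>%
    mutate(pct_preferred = if_else(.data$n > 0,
                                   100 * .data$n_preferred / .data$n,
                                   NA_real_)) %>%
    arrange(.data$group, .data$period)
}
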