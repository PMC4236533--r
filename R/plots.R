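#' Preferred-tier trend by user group over calendar time
#'
#' Plots the unadjusted percent of index claims on the preferred tier per
#' calendar quarter, one line per prescriber usage group, with the
#' interruptive go-live marked — the descriptive picture behind the
#' difference-in-differences design.
#'
#' @param index_claims Labelled cohort tibble.
#' @param interruptive_start Go-live date drawn as a vertical reference.
#' @return A ggplot object.
#' @export
plot_tier_trend <- function(index_claims,
                            interruptive_start = as.Date("2005-09-16")) {
  dat <- index_claims %>%
    mutate(
      quarter = as.Date(cut(.data$fill_date, "quarter")),
      group = factor(.data$group, levels = GROUPS)
    ) %>%
    group_by(.data$group, .data$quarter) %>%
    summarise(pct_preferred = 100 * mean(.data$tier == "preferred"),
              n = n(), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$quarter,
                                    y = .data$pct_preferred,
                                    colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.6) +
    ggplot2::geom_vline(xintercept = as.numeric(interruptive_start),
                        linetype = "dashed") +
    ggplot2::scale_size_area(max_size = 3, guide = "none") +
    ggplot2::labs(x = NULL, y = "Preferred tier (%)",
                  colour = "Usage group",
                  title = "Unadjusted preferred-tier prescribing over time",
                  subtitle = "Dashed line: interruptive FDS go-live") +
    ggplot2::theme_minimal()
}

#' Forest plot of the FDS:tier odds ratios
#'
#' @param object A `fds_tier_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fds_tier_fit
#' @export
autoplot.fds_tier_fit <- function(object, ...) {
  dat <- tidy(object) %>%
    filter(.data$term != "(Intercept)") %>%
    mutate(term = factor(.data$term, levels = rev(.data$term)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (log scale, 95% CI)", y = NULL,
                  title = "FDS:tier difference-in-differences model") +
    ggplot2::theme_minimal()
}

#' Adherence against transformed copayment
#'
#' Scatter of PDC against the transformed monthly copayment with the
#' fitted marginal slope overlaid.
#'
#' @param object A `copay_adherence_fit`.
#' @param data The adherence analysis data used for the fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot copay_adherence_fit
#' @export
autoplot.copay_adherence_fit <- function(object, data, ...) {
  lambda <- object$lambda
  td <- tidy(object)
  dat <- data %>%
    mutate(copay_bc = box_cox(.data$monthly_copayment, lambda))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$copay_bc, y = .data$pdc)) +
    ggplot2::geom_point(alpha = 0.1, size = 0.5) +
    ggplot2::geom_abline(
      intercept = td$estimate[td$term == "(Intercept)"],
      slope = td$estimate[td$term == "copay_bc"], colour = "red"
    ) +
    ggplot2::facet_wrap(~med_class) +
    ggplot2::labs(
      x = sprintf("Monthly copayment^%s", format(lambda)),
      y = "180-day PDC",
      title = "Copayment:adherence relationship"
    ) +
    ggplot2::theme_minimal()
}
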