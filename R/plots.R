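# ggplot2 helpers for the standard result views: exposure and disparity
# trajectories, exposure distributions, avoided deaths, and per-capita rates.

group_labels <- c(
  black_nh = "Black non-Hispanic", white_nh = "White non-Hispanic",
  hispanic = "Hispanic", other = "Other", total = "Total"
)

#' Plot exposure or disparity trajectories by group and scenario
#'
#' @param comparison An `aq_comparison` (or its long exposure tibble).
#' @param metric `"pw_exposure"` or `"disparity"`.
#' @return A ggplot.
#' @export
plot_exposure_trends <- function(comparison, metric = "pw_exposure") {
  df <- if (inherits(comparison, "aq_comparison")) comparison$exposure else comparison
  df <- df |> filter(.data$metric == .env$metric, .data$group != "total")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$period, y = .data$value, colour = .data$scenario
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~group, labeller = ggplot2::labeller(group = group_labels)) +
    ggplot2::labs(
      x = NULL,
      y = if (metric == "disparity") {
        expression(Disparity ~ (mu * g / m^3))
      } else {
        expression(PM[2.5] - equivalent ~ exposure ~ (mu * g / m^3))
      },
      colour = "Scenario"
    ) +
    ggplot2::theme_minimal()
}

#' Plot population-weighted exposure distributions for one period
#'
#' Median with 10th/90th-percentile error bars and the interquartile range,
#' by group and scenario.
#'
#' @param comparison An `aq_comparison`.
#' @param period Period to display (default 2050).
#' @return A ggplot.
#' @export
plot_exposure_distribution <- function(comparison, period = 2050) {
  df <- comparison$exposure |>
    filter(.data$period == .env$period, startsWith(.data$metric, "q")) |>
    tidyr::pivot_wider(names_from = "metric", values_from = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario, colour = .data$scenario)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$q10, ymax = .data$q90),
      width = 0.3
    ) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
      linewidth = 1.5
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$q50), size = 2) +
    ggplot2::facet_wrap(~group, labeller = ggplot2::labeller(group = group_labels)) +
    ggplot2::labs(
      x = NULL, y = expression(Exposure ~ (mu * g / m^3)),
      title = sprintf("Population-weighted exposure distributions, %d", period)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 45, hjust = 1),
      legend.position = "none"
    )
}

#' Plot cumulative avoided deaths by scenario
#'
#' Ranges across the health-estimate variants, relative to current policy.
#'
#' @param comparison An `aq_comparison`.
#' @return A ggplot.
#' @export
plot_avoided_deaths <- function(comparison) {
  df <- comparison$avoided |>
    summarise(
      lo = min(.data$avoided), hi = max(.data$avoided),
      mid = stats::median(.data$avoided), .by = "scenario"
    )
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$scenario, .data$mid)
  )) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mid), size = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Cumulative avoided deaths vs current policy, 2020-2050"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-capita deaths by race and scenario
#'
#' @param comparison An `aq_comparison`.
#' @param variant Variant to display (default `"B"`).
#' @return A ggplot.
#' @export
plot_per_capita_deaths <- function(comparison, variant = "B") {
  df <- comparison$per_capita |> filter(.data$variant == .env$variant)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$group, y = .data$per_100k, fill = .data$scenario
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_x_discrete(labels = group_labels) +
    ggplot2::labs(
      x = NULL, y = "Deaths per 100,000",
      fill = "Scenario"
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.aq_comparison <- function(object,
                                   type = c("exposure", "disparity", "distribution", "avoided", "per_capita"),
                                   ...) {
  type <- match.arg(type)
  switch(type,
    exposure = plot_exposure_trends(object, "pw_exposure"),
    disparity = plot_exposure_trends(object, "disparity"),
    distribution = plot_exposure_distribution(object, ...),
    avoided = plot_avoided_deaths(object),
    per_capita = plot_per_capita_deaths(object, ...)
  )
}
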