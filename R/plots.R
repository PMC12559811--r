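#' Plot survivorship and fecundity schedules
#'
#' Draws the age-specific survivorship curve l_x and per-capita fecundity
#' m_x for each cohort in a schedules table ([life_schedules()]), faceted by
#' quantity.
#'
#' @param object An `rl_schedules` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.rl_schedules <- function(object, ...) {
  long <- object |>
    select(all_of(c("cohort_id", "day", "l_x", "m_x"))) |>
    tidyr::pivot_longer(c("l_x", "m_x"), names_to = "quantity", values_to = "value")
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$day, y = .data$value, group = .data$cohort_id)
  ) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(
      x = "Age (days since hatch)", y = NULL,
      title = "Age-specific survivorship and fecundity"
    )
}

#' Plot percent-change contrasts
#'
#' Bar chart of the percent changes from [run_contrasts()]: treatments
#' against their generation control, and F5 against F1, faceted by metric
#' and contrast family.
#'
#' @param object An `rl_contrasts` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.rl_contrasts <- function(object, ...) {
  d <- object |>
    mutate(
      treatment = factor(.data$treatment, levels = uvb_treatments()),
      panel = ifelse(.data$family == "vs_control",
        paste(.data$generation, "vs control"), "F5 vs F1"
      )
    )
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = .data$treatment, y = .data$percent_change, fill = .data$treatment)
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_grid(metric ~ panel, scales = "free_y") +
    ggplot2::labs(
      x = "UVB treatment", y = "Change (%)",
      title = "Maternal UVB exposure contrasts"
    ) +
    ggplot2::guides(fill = "none")
}
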