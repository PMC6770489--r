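stratum_label <- function(gender, age_class, menstrual_status) {
  suffix <- dplyr::case_when(
    menstrual_status == "premenopausal" ~ " (pre-M)",
    menstrual_status == "postmenopausal" ~ " (post-M)",
    TRUE ~ ""
  )
  paste0(substr(gender, 1, 1), " ", age_class, suffix)
}

#' Plot a burden result
#'
#' Bar chart of mean DALY per 100,000 per stratum with 95% uncertainty
#' intervals.
#'
#' @param object An `iron_burden` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot iron_burden
autoplot.iron_burden <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::mutate(
      stratum = stratum_label(
        .data$gender, .data$age_class, .data$menstrual_status
      )
    )
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = stats::reorder(.data$stratum, .data$daly_per_100k_mean),
      y = .data$daly_per_100k_mean, fill = .data$gender
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$daly_per_100k_lo, ymax = .data$daly_per_100k_hi
      ),
      width = 0.3
    ) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "DALY per 100,000 per year",
      title = "Iron-deficiency anaemia burden by stratum"
    )
}

#' Plot a scenario dose-response curve
#'
#' Mean DALY per 100,000 against ground-beef dose, one line per stratum,
#' with 95% uncertainty ribbons.
#'
#' @param object An `iron_scenario` tibble from [scenario_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot iron_scenario
autoplot.iron_scenario <- function(object, ...) {
  d <- object |>
    dplyr::mutate(
      stratum = stratum_label(
        .data$gender, .data$age_class, .data$menstrual_status
      )
    )
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = .data$dose_g_day, y = .data$daly_per_100k_mean,
      colour = .data$stratum, fill = .data$stratum
    )
  ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$daly_per_100k_lo, ymax = .data$daly_per_100k_hi
      ),
      alpha = 0.15, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Cooked ground beef (g/day)", y = "DALY per 100,000 per year",
      title = "Burden under red-meat consumption scenarios"
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
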