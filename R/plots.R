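#' Plot the score distribution of a scored cohort
#'
#' Bar chart of total scores filled by score category.
#'
#' @param object A `tcrad_scored` cohort.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tcrad_scored <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$total_score, fill = .data$category)) +
    geom_bar() +
    scale_x_continuous(breaks = 0:14) +
    labs(x = "Total score (points)", y = "Participants",
         fill = "Category",
         title = "Traditional diet score distribution") +
    theme_minimal()
}

#' Plot score-category proportions by stratum
#'
#' Stacked bars of the low/moderate/high percentages from
#' [category_proportions()].
#'
#' @param proportions Output of [category_proportions()].
#' @return A ggplot.
#' @export
plot_category_proportions <- function(proportions) {
  long <- proportions |>
    tidyr::pivot_longer(dplyr::starts_with("pct_"), names_to = "category",
                        values_to = "pct", names_prefix = "pct_") |>
    dplyr::mutate(category = factor(.data$category,
                                    levels = c("low", "moderate", "high")))
  ggplot(long, aes(x = .data$level, y = .data$pct, fill = .data$category)) +
    geom_col() +
    labs(x = NULL, y = "% of stratum", fill = "Score category",
         title = "Score categories by stratum") +
    theme_minimal()
}

#' Plot score-nutrient correlations
#'
#' Lollipop chart of Spearman rho per nutrient from
#' [correlate_score_nutrients()].
#'
#' @param correlations Output of [correlate_score_nutrients()].
#' @return A ggplot.
#' @export
plot_score_correlations <- function(correlations) {
  df <- dplyr::arrange(correlations, .data$rho) |>
    dplyr::mutate(nutrient = factor(.data$nutrient, levels = .data$nutrient))
  ggplot(df, aes(x = .data$rho, y = .data$nutrient)) +
    geom_segment(aes(x = 0, xend = .data$rho, yend = .data$nutrient),
                 color = "grey60") +
    geom_point(aes(color = .data$rho > 0), size = 2, show.legend = FALSE) +
    geom_vline(xintercept = 0, linetype = 2) +
    labs(x = "Spearman rho vs. total score", y = NULL,
         title = "Score-nutrient rank correlations") +
    theme_minimal()
}
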