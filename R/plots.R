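# ggplot2 figures for the main result shapes.

#' Mean standardized association by age bin and kin category
#'
#' Point-and-error-bar figure of mean z-standardized association (+/- 1
#' s.e.) per six-month infant-age bin, split by kin category — the shape
#' of the headline association figures.
#'
#' @param table an analysis table from [build_within_period_dataset()] or
#'   [build_between_period_dataset()].
#' @return a ggplot object.
#' @export
plot_association_bins <- function(table) {
  means <- kb_bin_means(table)
  pd <- ggplot2::position_dodge(width = 0.4)
  ggplot2::ggplot(means, ggplot2::aes(x = .data$age_bin, y = .data$mean_z,
                                      colour = .data$kin,
                                      group = .data$kin)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_z - .data$se,
                                        ymax = .data$mean_z + .data$se),
                           width = 0.2, position = pd) +
    ggplot2::geom_point(size = 2, position = pd) +
    ggplot2::labs(x = "infant age bin (six-month)",
                  y = "standardized association (mean ± s.e.)",
                  colour = "kin category") +
    ggplot2::theme_minimal()
}

#' Observed minus expected interaction proportions by kin category
#'
#' Mean (+/- 1 s.e.) per-infant observed-minus-expected proportion of
#' interaction strength for each kin category.
#'
#' @param summaries output of [interaction_summaries()].
#' @param period infancy period to plot (default `"LATE"`).
#' @param categories kin categories to include.
#' @return a ggplot object.
#' @export
plot_interaction_differences <- function(summaries, period = "LATE",
                                         categories = c("FATHER", "NON_KIN")) {
  d <- summaries$observed |>
    filter(.data$period == !!period, .data$kin %in% categories) |>
    mutate(diff_obs = .data$observed_prop - .data$expected_prop) |>
    group_by(.data$kin) |>
    summarise(mean_diff = mean(.data$diff_obs),
              se = sd(.data$diff_obs) / sqrt(dplyr::n()),
              .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$kin, y = .data$mean_diff)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_col(fill = "grey75", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_diff - .data$se,
                                        ymax = .data$mean_diff + .data$se),
                           width = 0.15) +
    ggplot2::labs(x = "kin category",
                  y = "observed − expected proportion (mean ± s.e.)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods
#'
#' `autoplot()` on a `"kb_assoc_fit"` draws the per-bin association means
#' of its analysis table; on a `"kb_elo"` it draws rating trajectories.
#'
#' @param object fitted object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.kb_assoc_fit <- function(object, ...) {
  plot_association_bins(object$data)
}

#' @rdname autoplot.kb_assoc_fit
#' @export
autoplot.kb_elo <- function(object, ...) {
  h <- object$history |>
    tidyr::pivot_longer(c("rating_winner", "rating_loser"),
                        values_to = "rating") |>
    mutate(male_id = ifelse(.data$name == "rating_winner",
                            .data$winner_id, .data$loser_id))
  ggplot2::ggplot(h, ggplot2::aes(x = .data$date, y = .data$rating,
                                  colour = .data$male_id)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = NULL, y = "Elo rating", colour = "male") +
    ggplot2::theme_minimal()
}
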