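#' Bar chart of averaged stimulus importances
#'
#' Per-face mean random-forest importance, coloured by the presented
#' emotion (the weighted model's view of which stimuli carry diagnostic
#' signal).
#'
#' @param importances data frame from [average_importances()].
#' @return A ggplot object.
#' @export
plot_importances <- function(importances) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_importances requires ggplot2")
  }
  ggplot2::ggplot(importances,
                  ggplot2::aes(x = factor(.data$face), y = .data$mean_importance,
                               fill = .data$emotion)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Face number", y = "Mean importance", fill = "Emotion") +
    ggplot2::theme_minimal()
}

#' Grouped bars of per-emotion feature means with significance stars
#'
#' @param tab result of [emotion_feature_table()].
#' @param feature feature to display (e.g. `"fix_eyes"`).
#' @return A ggplot object.
#' @export
plot_feature_comparison <- function(tab, feature = "fix_eyes") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_feature_comparison requires ggplot2")
  }
  s <- tab$summary[tab$summary$feature == feature, ]
  cmp <- tab$comparisons[tab$comparisons$feature == feature, ]
  ggplot2::ggplot(s, ggplot2::aes(x = .data$emotion, y = .data$mean,
                                  fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           position = ggplot2::position_dodge(width = 0.9),
                           width = 0.25) +
    ggplot2::geom_text(data = cmp,
                       ggplot2::aes(x = .data$emotion, y = Inf,
                                    label = .data$stars),
                       vjust = 1.2, inherit.aes = FALSE) +
    ggplot2::labs(x = NULL, y = feature, fill = NULL) +
    ggplot2::theme_minimal()
}
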