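#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Correlation heatmap
#'
#' Symptom (and benefit) correlation heatmap with a diverging palette:
#' red = negative, blue = positive correlation, intensity tracking the
#' effect size.
#'
#' @param object An `epro_corr` from [pearson_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot epro_corr
#' @export
autoplot.epro_corr <- function(object, ...) {
  df <- tidy(object)
  df$var1 <- factor(df$var1, levels = object$labels)
  df$var2 <- factor(df$var2, levels = rev(object$labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$var1, y = .data$var2,
                                   fill = .data$r)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0,
                                  limits = c(-1, 1), na.value = "grey70",
                                  name = "Pearson r") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Weekly compliance plot
#'
#' @param compliance Tibble from [compute_compliance()].
#' @return A ggplot of mean answered questionnaires per active patient per
#'   week.
#' @export
plot_compliance <- function(compliance) {
  ggplot2::ggplot(compliance, ggplot2::aes(x = .data$week, y = .data$mean)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", color = "grey60") +
    ggplot2::labs(x = "Week of follow-up",
                  y = "Questionnaires per active patient") +
    ggplot2::theme_minimal()
}

#' Benefit-stratified symptom trajectory plot
#'
#' Mean grade of one symptom per 2-week bin, for all evaluable patients and
#' the benefit (CR/PR/SD) and PD arms.
#'
#' @param cohort An [epro_cohort()].
#' @param symptom Symptom id.
#' @param window Week window (default first 12 weeks).
#' @param bin_width Bin width in weeks.
#' @return A ggplot.
#' @export
plot_symptom_trajectory <- function(cohort, symptom, window = c(1, 12),
                                    bin_width = 2L) {
  df <- dplyr::bind_rows(
    purrr::map(c(all = "all", benefit = "benefit", PD = "PD"), function(g) {
      binned_average_grade(cohort, symptom, group = g, window = window,
                           bin_width = bin_width)
    }),
    .id = "group"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$week_from, y = .data$mean_grade,
                                   color = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Week (bin start)", y = paste("Mean", symptom, "grade"),
                  color = NULL) +
    ggplot2::theme_minimal()
}
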