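#' @importFrom ggplot2 ggplot aes geom_col geom_errorbar geom_histogram
#'   geom_vline geom_rug facet_wrap labs position_dodge theme_minimal
#'   autoplot after_stat
NULL

#' Plot population-level mutation load
#'
#' Bar chart of mean individual load (mean over member genomes, error bars
#' at one SD) per population, faceted by functional class and split into
#' masked and realised components.
#'
#' @param pop_load Tibble from [population_load()].
#' @return A ggplot object.
#' @export
plot_population_load <- function(pop_load) {
  long <- pop_load |>
    tidyr::pivot_longer(
      cols = c("l_mask_mean", "l_realised_mean"),
      names_to = "component", values_to = "mean"
    ) |>
    mutate(
      sd = if_else(.data$component == "l_mask_mean", .data$l_mask_sd,
                   .data$l_realised_sd),
      component = if_else(.data$component == "l_mask_mean",
                          "masked", "realised")
    )
  ggplot(long, aes(x = .data$population, y = .data$mean, fill = .data$component)) +
    geom_col(position = position_dodge(width = 0.9)) +
    geom_errorbar(aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
                  position = position_dodge(width = 0.9), width = 0.25,
                  na.rm = TRUE) +
    facet_wrap(~class, scales = "free_y") +
    labs(x = NULL, y = "mean individual load (loci)", fill = NULL) +
    theme_minimal()
}

#' Plot the net impact of donor populations
#'
#' Figure-4-style summary: per donor population and class, the mean number
#' of novel variants added and of exposed deleterious variants masked at
#' probability 1, averaged over recipient populations (error bars at one
#' SD).
#'
#' @param net Output of [net_impact_summary()] (or its `by_class` tibble).
#' @return A ggplot object.
#' @export
plot_net_impact <- function(net) {
  by_class <- if (is.list(net) && !is.data.frame(net)) net$by_class else net
  long <- by_class |>
    tidyr::pivot_longer(cols = c("m_add_mean", "masked_p1_mean"),
                        names_to = "metric", values_to = "mean") |>
    mutate(
      sd = if_else(.data$metric == "m_add_mean", .data$m_add_sd,
                   .data$masked_p1_sd),
      metric = if_else(.data$metric == "m_add_mean", "added (M_add)",
                       "masked (p = 1)")
    )
  ggplot(long, aes(x = .data$class, y = .data$mean, fill = .data$metric)) +
    geom_col(position = position_dodge(width = 0.9)) +
    geom_errorbar(aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
                  position = position_dodge(width = 0.9), width = 0.25,
                  na.rm = TRUE) +
    facet_wrap(~donor_pop) +
    labs(x = NULL, y = "mean variants per donor genome", fill = NULL) +
    theme_minimal()
}

#' Plot an F_ST outlier screen
#'
#' Figure-5-style view: histogram of the neutral (gene-desert) F_ST
#' distribution, the percentile cutoff as a dashed line, and the test-set
#' F_ST values as a rug.
#'
#' @param screen An `outlier_screen` from [fst_outlier_screen()].
#' @param bins Histogram bin count (default 50).
#' @return A ggplot object.
#' @export
plot_fst_screen <- function(screen, bins = 50) {
  stopifnot(inherits(screen, "outlier_screen"))
  if (is.null(screen$neutral)) {
    abort("screen carries no neutral distribution; use fst_outlier_screen()")
  }
  ggplot(screen$neutral, aes(x = .data$fst)) +
    geom_histogram(aes(y = after_stat(density)), bins = bins,
                   fill = "grey80", colour = "grey50") +
    geom_vline(xintercept = screen$cutoff, linetype = "dashed",
               colour = "red") +
    geom_rug(data = screen$loci, aes(x = .data$fst, colour = .data$outlier),
             sides = "b", inherit.aes = FALSE) +
    labs(x = expression(F[ST]), y = "neutral density",
         colour = "outlier",
         title = sprintf("%d / %d test loci above the %0.4f cutoff",
                         screen$n_outliers, screen$n_test, screen$cutoff)) +
    theme_minimal()
}

#' @rdname plot_fst_screen
#' @param object,... Passed through to [plot_fst_screen()].
#' @export
autoplot.outlier_screen <- function(object, ...) plot_fst_screen(object, ...)
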