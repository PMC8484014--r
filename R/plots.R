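#' Volcano plot of DMR calls
#'
#' Methylation difference against `-log10(q)` for every tested window,
#' with DMRs highlighted and the effect-size cutoffs drawn.
#'
#' @param object A `dmr_calls` result from [call_dmrs()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dmr_calls
#' @export
autoplot.dmr_calls <- function(object, ...) {
  cutoff <- attr(object, "min_delta")
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$delta, y = -log10(pmax(.data$q, 1e-300)),
    colour = .data$is_dmr
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-cutoff, cutoff),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey65",
                                            `TRUE` = "firebrick"),
                                 name = "DMR") +
    ggplot2::labs(
      x = sprintf("Methylation difference (%s - %s)",
                  attr(object, "focal"), attr(object, "reference")),
      y = expression(-log[10] ~ q),
      title = sprintf("%s DMRs: %s vs %s", attr(object, "context"),
                      attr(object, "focal"), attr(object, "reference"))
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of DMR counts per comparison
#'
#' @param dmr_counts A tibble of [glance()]d DMR calls, e.g.
#'   `tidy(run)` from [run_cohort_analysis()].
#' @return A ggplot.
#' @export
plot_dmr_counts <- function(dmr_counts) {
  long <- dmr_counts %>%
    select("generation", "comparison", "context", "n_hyper", "n_hypo") %>%
    tidyr::pivot_longer(c("n_hyper", "n_hypo"), names_to = "direction",
                        values_to = "n") %>%
    mutate(direction = sub("^n_", "", .data$direction))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$generation, y = .data$n,
                                     fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(context ~ comparison) +
    ggplot2::labs(x = NULL, y = "DMR windows", fill = "Direction") +
    ggplot2::theme_minimal()
}

#' Bar chart of trajectory class counts
#'
#' @param trajectory A tibble from [classify_trajectory()].
#' @return A ggplot.
#' @export
plot_trajectory_classes <- function(trajectory) {
  counts <- count(trajectory, .data$class)
  ggplot2::ggplot(counts, ggplot2::aes(x = stats::reorder(.data$class,
                                                          -.data$n),
                                       y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Trajectory class", y = "Windows") +
    ggplot2::theme_minimal()
}

#' Expression ratios of DMR-linked genes by DMR direction
#'
#' Boxplot of per-gene log2 expression ratios split by the direction of
#' the linked DMR, the visual check of the negative
#' methylation-expression coupling.
#'
#' @param linked_ratios A tibble with columns `direction` and
#'   `log2_ratio` (e.g. joined from [genes_near_dmrs()] and
#'   [expression_ratio()]).
#' @return A ggplot.
#' @export
plot_expression_by_dmr <- function(linked_ratios) {
  ggplot2::ggplot(linked_ratios, ggplot2::aes(x = .data$direction,
                                              y = .data$log2_ratio,
                                              fill = .data$direction)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Linked DMR direction",
                  y = expression(log[2] ~ "TPM ratio")) +
    ggplot2::theme_minimal()
}

#' Histogram of LTR insertion times
#'
#' @param ages A tibble from [ltr_age()].
#' @param binwidth Bin width in million years.
#' @return A ggplot.
#' @export
plot_ltr_ages <- function(ages, binwidth = 0.25) {
  ggplot2::ggplot(ages, ggplot2::aes(x = .data$t_years / 1e6)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "darkseagreen4",
                            colour = "white") +
    ggplot2::labs(x = "Insertion time (million years)", y = "Elements") +
    ggplot2::theme_minimal()
}
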