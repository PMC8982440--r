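#' Plot a windowed genome track
#'
#' Line plot of window values along each chromosome, one facet per
#' chromosome; masked windows are dropped.
#'
#' @param track Window-track tibble (`chrom`, `start`, `end`, `value`).
#' @param ylab Y-axis label.
#' @return A ggplot object.
#' @export
plot_window_track <- function(track, ylab = "value") {
  track |>
    filter(!is.na(.data$value)) |>
    mutate(mid = (.data$start + .data$end) / 2e6) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$mid, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot cumulative clade-specificity profiles
#'
#' @param profile Output of [cumulative_specificity_profile()].
#' @return A ggplot object with one line per specificity label.
#' @export
plot_cumulative_specificity <- function(profile) {
  profile |>
    select(-"label") |>
    tidyr::pivot_longer(dplyr::starts_with("cum_"),
                        names_to = "specificity", values_to = "count") |>
    mutate(specificity = sub("^cum_", "", .data$specificity)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$gene_rank, y = .data$count,
                                 colour = .data$specificity)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "gene rank along chromosome",
                  y = "cumulative genes", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-chromosome conservation ratios
#'
#' @param profile Output of [conservation_profile()].
#' @return A ggplot object (one point per target species and chromosome).
#' @export
plot_conservation_profile <- function(profile) {
  profile |>
    filter(.data$chrom != "(unplaced)") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$chrom, y = .data$ratio,
                                 colour = .data$target_species,
                                 group = .data$target_species)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "conservation ratio", colour = "target") +
    ggplot2::theme_minimal()
}

#' Boxplot of protein pI by regulation block
#'
#' @param block_pi A [compare_block_pi()] result.
#' @return A ggplot object.
#' @export
plot_block_pi <- function(block_pi) {
  pi_tab <- attr(block_pi, "pi_values")
  if (is.null(pi_tab)) abort("no pi_values attached to this comparison")
  ggplot2::ggplot(pi_tab, ggplot2::aes(x = factor(.data$block),
                                       y = .data$pi)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = "block", y = "isoelectric point (pI)") +
    ggplot2::theme_minimal()
}

#' @describeIn run_sandbox_pipeline Bar chart of rank-1 indicator counts per
#'   chromosome.
#' @param object A `sandbox_report`.
#' @param ... Unused.
#' @method autoplot sandbox_report
#' @export
autoplot.sandbox_report <- function(object, ...) {
  ggplot2::ggplot(object$top_counts,
                  ggplot2::aes(x = .data$chrom, y = .data$n_top)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "indicators ranked first") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
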