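## ggplot2 visualisations for the main result types.

#' Heatmap of the threshold-sensitivity grid
#'
#' @param object An `hvcpg_grid` from [threshold_grid()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.hvcpg_grid <- function(object, ...) {
  df <- tidy.hvcpg_grid(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$j), y = factor(.data$i),
                                   fill = .data$n_hvcpgs)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_hvcpgs), size = 2.5) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "minimum % of covering datasets (j)",
                  y = "top variance percentage (i)",
                  fill = "hvCpGs") +
    ggplot2::theme_minimal()
}

#' Correlation-decay profile plot
#'
#' @param object A `decay_profile` from [correlation_decay_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.decay_profile <- function(object, ...) {
  df <- as_tibble(object)
  df$mid <- (df$bin_start + df$bin_end) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$mean_rho)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.6) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "inter-CpG distance (bp)",
                  y = "mean pairwise Spearman correlation",
                  size = "pairs") +
    ggplot2::theme_minimal()
}

#' Coverage-fraction plot of an hvCpG call
#'
#' Shows, for the array background, the number of covering datasets against
#' the fraction flagged hypervariable, with called hvCpGs highlighted.
#'
#' @param object An `hvcpg_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.hvcpg_result <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_covered, y = .data$fraction,
                                   colour = .data$is_hvcpg)) +
    ggplot2::geom_jitter(width = 0.2, height = 0.005, alpha = 0.4, size = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "datasets covering the CpG",
                  y = "fraction of covering datasets flagged",
                  colour = "hvCpG") +
    ggplot2::theme_minimal()
}

#' Power distribution plot
#'
#' @param object A `siv_power` result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.siv_power <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$power)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "detection power", y = "CpGs") +
    ggplot2::theme_minimal()
}

#' Forest plot of enrichment results
#'
#' @param results Tibble of enrichment rows (e.g. from
#'   [set_overlap_report()] or [proximity_enrichment()]).
#' @param label Column naming each row (default `set` if present, else
#'   `distance_bp`).
#' @return A ggplot.
#' @export
plot_enrichment <- function(results, label = NULL) {
  label <- label %||% if ("set" %in% names(results)) "set" else "distance_bp"
  df <- mutate(as_tibble(results), .label = factor(.data[[label]]))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_or, y = .data$.label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
  if (all(c("ci_low", "ci_high") %in% names(df)) && !all(is.na(df$ci_low))) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2)
  }
  p
}
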