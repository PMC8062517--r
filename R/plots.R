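# ggplot2 views of the package's result types.

#' Ranked log10 abundance plot of an OTU table
#'
#' @param table A `connsim_otu_table`.
#' @return A ggplot: log10 summed read abundance against abundance rank.
#' @export
plot_rank_abundance <- function(table) {
  reps <- otu_replicates(table)
  tot <- rowSums(as.matrix(table[, reps, drop = FALSE]))
  df <- tibble(rank = rank(-tot, ties.method = "first"), reads = tot) %>%
    filter(.data$reads > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = log10(.data$reads))) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::labs(x = "OTU rank", y = "log10 reads (summed over replicates)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.connsim_sim <- function(object, ...) {
  tr <- object$trajectory %>%
    tidyr::pivot_longer(c("substrate", "total_biomass"),
                        names_to = "series", values_to = "value")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time_h, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = NULL,
                  title = sprintf("%s-environment growth (stop step %d)",
                                  object$environment, object$stop_step)) +
    ggplot2::theme_minimal()
}

#' Heatmap of a paired-growth grid
#'
#' @param grid Tibble with `bin_i`, `bin_j`, `count` (see
#'   [pair_grid_and_ratios()]).
#' @param bin_width Bin width in log10 units (for axis labels).
#' @return A ggplot tile map of pair counts over log10 size bins.
#' @export
plot_pair_grid <- function(grid, bin_width = 0.5) {
  ggplot2::ggplot(grid, ggplot2::aes(x = (.data$bin_i - 0.5) * bin_width,
                                     y = (.data$bin_j - 0.5) * bin_width,
                                     fill = log10(.data$count + 1))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log10(count+1)") +
    ggplot2::labs(x = "log10 size, partner 1", y = "log10 size, partner 2") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @export
autoplot.connsim_pca <- function(object, ...) {
  sc <- object$scores
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   label = .data$dataset)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", object$explained_var[1]),
      y = sprintf("PC2 (%.1f%%)", object$explained_var[2])
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.connsim_deviation <- function(object, ...) {
  ggplot2::ggplot(object$by_bin, ggplot2::aes(x = .data$log10_mid)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$env_lo, ymax = .data$env_hi),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed), colour = "firebrick") +
    ggplot2::labs(x = "|log10 paired size ratio|", y = "probability mass",
                  title = "observed profile vs 5th-95th simulated envelope") +
    ggplot2::theme_minimal()
}

#' Boxplots of alpha diversity by condition
#'
#' @param diversity Tibble from [diversity_trajectory()] or
#'   `run_experiment()$diversity`.
#' @param measure Measure column to plot (default `"shannon"`).
#' @return A ggplot.
#' @export
plot_diversity <- function(diversity, measure = "shannon") {
  assert_that(measure %in% names(diversity), "unknown measure column")
  ggplot2::ggplot(diversity,
                  ggplot2::aes(x = .data$condition, y = .data[[measure]])) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = measure) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
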