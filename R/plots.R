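#' Chromosome copy-number plot
#'
#' The standard per-chromosome CN panel: gray dots are per-bin copy
#' number, the blue line is the running mean copy number along the
#' chromosome, red marks flag masked (repetitive/excluded) regions and
#' the black box marks the centromere. The y axis is fixed at \[0, 4\]
#' copies.
#'
#' @param object A `cn_profile`.
#' @param chroms Optional subset of chromosomes (default: all, faceted).
#' @param mean_window Window (bins) of the running mean line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cn_profile
#' @export
autoplot.cn_profile <- function(object, chroms = NULL, mean_window = 15, ...) {
  df <- as_tibble(object[c("chrom", "start", "end", "cn", "masked")])
  if (!is.null(chroms)) df <- df[df$chrom %in% chroms, ]
  df$mb <- (df$start + df$end) / 2 / 1e6
  df$chrom <- factor(df$chrom, levels = unique(df$chrom))

  running_mean <- function(x, k) {
    if (length(x) < k) return(rep(mean(x, na.rm = TRUE), length(x)))
    as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  }
  df <- df |>
    group_by(.data$chrom) |>
    mutate(cn_mean = running_mean(.data$cn, mean_window)) |>
    ungroup()

  cen <- attr(object, "centromeres")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mb)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cn), colour = "gray60",
                        size = 0.6, na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$cn_mean), colour = "blue",
                       na.rm = TRUE) +
    ggplot2::geom_point(
      data = df[df$masked, ],
      ggplot2::aes(y = 0.05), colour = "red", shape = 15, size = 0.8
    ) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::coord_cartesian(ylim = c(0, 4)) +
    ggplot2::labs(x = "position (Mb)", y = "copy number") +
    ggplot2::theme_minimal()
  if (!is.null(cen)) {
    cen_df <- as_tibble(cen)
    if (!is.null(chroms)) cen_df <- cen_df[cen_df$chrom %in% chroms, ]
    cen_df <- cen_df[cen_df$chrom %in% levels(df$chrom), ]
    cen_df$chrom <- factor(cen_df$chrom, levels = levels(df$chrom))
    p <- p + ggplot2::geom_rect(
      data = cen_df,
      ggplot2::aes(xmin = .data$cen_start / 1e6, xmax = .data$cen_end / 1e6,
                   ymin = 0, ymax = 0.15),
      fill = "black", inherit.aes = FALSE
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the CN profile of a sample result
#' @param result A `sample_result`.
#' @param ... Passed to [autoplot.cn_profile()].
#' @return A ggplot object.
#' @export
plot_sample <- function(result, ...) {
  autoplot(result$profile, ...)
}
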