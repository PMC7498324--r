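#' Stacked-bar plot of per-position tail composition
#'
#' Mirrors the standard display for nucleotidyltransferase tail profiling:
#' one stacked bar of base frequencies per 3'-anchored tail position (last
#' added nucleotide rightmost), with positional coverage overlaid as dots.
#'
#' @param composition A [positional_composition()] result.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_composition <- function(composition, title = NULL) {
  stopifnot(inherits(composition, "composition_result"))
  pos <- composition$reported_positions
  if (length(pos) == 0L) {
    stop_racetails("no reported positions to plot",
                   "racetails_empty_result_error")
  }
  df <- data.frame(
    position = factor(rep(-pos, each = 4L), levels = sort(-pos)),
    base = factor(rep(RNA_BASES, times = length(pos)), levels = RNA_BASES),
    frequency = as.vector(composition$per_position)
  )
  cov <- data.frame(
    position = factor(sort(-pos), levels = sort(-pos)),
    coverage = unname(composition$coverage[as.character(rev(sort(pos)))])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$frequency,
                                   fill = .data$base)) +
    ggplot2::geom_col() +
    ggplot2::geom_point(data = cov,
                        ggplot2::aes(x = .data$position, y = .data$coverage),
                        inherit.aes = FALSE) +
    ggplot2::scale_fill_manual(values = c(A = "#66c2a5", C = "#fc8d62",
                                          G = "#8da0cb", U = "#e78ac3")) +
    ggplot2::labs(x = "tail position (3'-anchored, last base rightmost)",
                  y = "frequency / coverage", fill = "base", title = title) +
    ggplot2::theme_minimal()
}

#' Plot a competition fit with confidence bands
#'
#' Data points for one experiment, the fitted displacement curve and the
#' pointwise delta-method confidence band, on a log concentration axis.
#'
#' @param fit A [fit_competition_global()] result.
#' @param data The measurements that were fitted.
#' @param experiment Experiment id to display (default: first).
#' @param n_grid Number of curve points (default 200).
#' @return A ggplot object.
#' @export
plot_competition_fit <- function(fit, data, experiment = NULL, n_grid = 200L) {
  stopifnot(inherits(fit, "competition_fit"))
  if (is.null(experiment)) experiment <- fit$experiments[1L]
  sub <- data[data$experiment_id == experiment, ]
  cpos <- sub$concentration_nM[sub$concentration_nM > 0]
  grid <- exp(seq(log(min(cpos)), log(max(cpos)), length.out = n_grid))
  bd <- fit$band(grid, experiment = experiment)
  ggplot2::ggplot(sub, ggplot2::aes(x = .data$concentration_nM,
                                    y = .data$anisotropy)) +
    ggplot2::geom_ribbon(data = bd,
                         ggplot2::aes(x = .data$concentration_nM,
                                      ymin = .data$lower, ymax = .data$upper),
                         inherit.aes = FALSE, alpha = 0.2) +
    ggplot2::geom_line(data = bd,
                       ggplot2::aes(x = .data$concentration_nM, y = .data$fit),
                       inherit.aes = FALSE, colour = "red") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "[competitor] (nM)", y = "anisotropy",
                  title = sprintf("IC50 = %.0f +/- %.0f nM",
                                  fit$ic50, fit$se_ic50)) +
    ggplot2::theme_minimal()
}
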