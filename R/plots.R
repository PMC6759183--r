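# ggplot2 display methods for the main result types.

#' @describeIn credible_envelopes Plot a fitted growth curve with model and
#'   predictive envelopes, plus the line's observations when available in
#'   `data`.
#' @param object A `credible_envelope`.
#' @param data Optional observation tibble (`time_dd`, `height_cm`) to
#'   overlay.
#' @param ... Unused.
#' @exportS3Method
autoplot.credible_envelope <- function(object, data = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_dd)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$pred_lo,
                                      ymax = .data$pred_hi),
                         fill = "darkgreen", alpha = 0.2) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$model_lo,
                                      ymax = .data$model_hi),
                         fill = "gold", alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::labs(x = "Thermal time (DD)", y = "Height (cm)",
                  title = attr(object, "line"),
                  subtitle = sprintf("%.0f%% credible envelopes",
                                     100 * attr(object, "level")))
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(data = data,
                                 ggplot2::aes(x = .data$time_dd,
                                              y = .data$height_cm),
                                 inherit.aes = FALSE, size = 1)
  }
  p
}

#' Plot a LOD curve
#'
#' Genome scan faceted by chromosome, with an optional threshold line.
#'
#' @param object A `lod_curve`.
#' @param threshold Optional genome-wide LOD threshold to draw.
#' @param ... Unused.
#' @exportS3Method
autoplot.lod_curve <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$pos_cM, y = .data$lod)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "Position (cM)", y = "LOD",
                  title = sprintf("%s scan (n = %d)",
                                  attr(object, "scan_type"),
                                  attr(object, "n")))
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                                 colour = "red")
  }
  p
}

#' Plot module-trait associations
#'
#' Tile map of eigengene-trait correlations, starred where the
#' Holm-adjusted p-value clears the significance level.
#'
#' @param object Output of [module_trait_tests()].
#' @param ... Unused.
#' @export
plot_module_trait <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$trait, y = .data$module,
                                       fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$significant, "*", "")),
                       size = 6) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r")
}
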