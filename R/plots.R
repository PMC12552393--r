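#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_abline geom_errorbar
#'   geom_jitter labs theme_minimal position_dodge
#' @export
ggplot2::autoplot

#' Ordination scatter plot
#'
#' Plots the first two principal-coordinate axes, optionally coloured and
#' shaped by sample metadata (tissue and sex by default).
#'
#' @param object An `epirad_mds` object.
#' @param meta Optional sample metadata joined by `sample_id`.
#' @param colour,shape Metadata column names for aesthetics.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.epirad_mds <- function(object, meta = NULL, colour = "sex",
                                shape = "tissue", ...) {
  pts <- object$points
  if (object$k < 2) abort("need at least 2 axes to plot")
  if (!is.null(meta)) {
    info <- dplyr::distinct(meta, .data$sample_id, .data$sex,
                            .data$age_group, .data$tissue)
    pts <- dplyr::left_join(pts, info, by = "sample_id")
  }
  mapping <- if (!is.null(meta)) {
    aes(.data$axis1, .data$axis2, colour = .data[[colour]],
        shape = .data[[shape]])
  } else {
    aes(.data$axis1, .data$axis2)
  }
  ggplot(pts, mapping) +
    geom_point(size = 2.5, alpha = 0.85) +
    labs(
      x = sprintf("Axis 1 (%.1f%%)", object$percent_variance[1]),
      y = sprintf("Axis 2 (%.1f%%)", object$percent_variance[2])
    ) +
    theme_minimal()
}

#' Residual Q-Q plot
#'
#' @param object An `epirad_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.epirad_fit <- function(object, ...) {
  qq <- qq_normality_check(object)
  ggplot(qq, aes(.data$theoretical, .data$sample)) +
    geom_point() +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    labs(x = "Normal quantiles", y = "Standardized residuals") +
    theme_minimal()
}

#' Model-estimated group means with raw values
#'
#' Shows per-sample values jittered within groups and overlays the
#' model-estimated means with their 95% confidence intervals.
#'
#' @param data Data frame of raw per-individual values.
#' @param means Output of [estimated_means()].
#' @param x Grouping variable on the x axis (e.g. `"age_group"`).
#' @param y Response column in `data`.
#' @param colour Optional second grouping (e.g. `"sex"`).
#' @return A ggplot object.
#' @export
plot_estimated_means <- function(data, means, x, y, colour = NULL) {
  pd <- position_dodge(width = 0.4)
  mapping <- if (is.null(colour)) {
    aes(.data[[x]], .data[[y]])
  } else {
    aes(.data[[x]], .data[[y]], colour = .data[[colour]])
  }
  p <- ggplot(data, mapping) +
    geom_jitter(width = 0.08, alpha = 0.5, size = 1.5)
  mean_mapping <- if (is.null(colour)) {
    aes(.data[[x]], .data$estimate)
  } else {
    aes(.data[[x]], .data$estimate, colour = .data[[colour]])
  }
  p +
    geom_point(data = means, mapping = mean_mapping, size = 3, shape = 1,
               stroke = 1.2, position = pd) +
    geom_errorbar(
      data = means,
      mapping = if (is.null(colour)) {
        aes(.data[[x]], .data$estimate, ymin = .data$conf_low,
            ymax = .data$conf_high)
      } else {
        aes(.data[[x]], .data$estimate, ymin = .data$conf_low,
            ymax = .data$conf_high, colour = .data[[colour]])
      },
      width = 0.15, position = pd
    ) +
    theme_minimal()
}
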