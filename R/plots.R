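# ggplot2 methods for the package's result types.

#' Heat map of a consumption/release atlas
#'
#' Tile map of log2 control-normalized ratios, ordered by correlation-
#' distance clustering when possible (falling back to input order when a
#' profile has zero variance).
#'
#' @param object A [adjusted_ratio()] atlas.
#' @param cluster Reorder rows/columns by [cluster_atlas()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot consumption_atlas
#' @export
autoplot.consumption_atlas <- function(object, cluster = TRUE, ...) {
  dat <- as_tibble(object)
  if ("cell_line" %in% names(dat) && length(unique(dat$cell_line)) > 1) {
    dat$metabolite <- paste(dat$cell_line, dat$metabolite, sep = ":")
  }
  if (cluster) {
    ord <- tryCatch(cluster_atlas(object), error = function(e) NULL)
    if (!is.null(ord)) {
      dat$gene <- factor(dat$gene, levels = ord$row_order)
      dat$metabolite <- factor(dat$metabolite, levels = ord$col_order)
    }
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$metabolite, y = .data$gene,
                                    fill = .data$log2_ratio)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                                  name = "log2 ratio\nto control") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       hjust = 1))
}

#' Standard-curve diagnostic plot
#'
#' @param object A [fit_standard_curve()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot standard_curve
#' @export
autoplot.standard_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$conc, y = .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "#2166ac") +
    ggplot2::labs(
      x = "concentration",
      y = "signal",
      subtitle = sprintf("slope = %.4g, intercept = %.4g, R² = %.4f",
                         object$slope, object$intercept, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Bar plot of an isotopologue distribution
#'
#' @param mid Named numeric MID vector (e.g. from [correct_mid()]).
#' @return A ggplot object.
#' @export
plot_mid <- function(mid) {
  dat <- tibble(
    mass_shift = factor(names(mid) %||% paste0("M+", seq_along(mid) - 1L),
                        levels = names(mid) %||% paste0("M+", seq_along(mid) - 1L)),
    fraction = as.numeric(mid)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mass_shift, y = .data$fraction)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = NULL, y = "fraction") +
    ggplot2::theme_minimal()
}
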