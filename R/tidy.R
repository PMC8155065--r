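# broom-style accessors and ggplot2 plotting for result objects.

#' @export
tidy.ic_score_result <- function(x, ...) {
  tibble(
    score_pct = 100 * x$score,
    category2 = as.character(categorize(x$score, scheme_2cat())),
    category4 = as.character(categorize(x$score, scheme_4cat())),
    dilation_iterations = x$dilation_iterations,
    ic_pixels_after_dilation = x$ic_pixels_after_dilation,
    total_pixels = x$total_pixels
  )
}

#' @export
glance.ic_score_result <- function(x, ...) tidy(x)

#' @export
tidy.concordance_result <- function(x, ...) as_tibble(unclass(x))

#' @export
glance.concordance_result <- function(x, ...) tidy(x)

#' @export
tidy.acceptance_result <- function(x, ...) x$overall

#' @export
glance.acceptance_result <- function(x, ...) x$overall

patch_to_plot_df <- function(patch) {
  d <- dim(patch)
  px <- patch$pixels
  tibble(
    col = rep(seq_len(d[2]), each = d[1]),
    row = rep(seq_len(d[1]), times = d[2]),
    fill = grDevices::rgb(as.vector(px[, , 1]), as.vector(px[, , 2]),
                          as.vector(px[, , 3]), maxColorValue = 255)
  )
}

#' Plot an RGB patch
#'
#' @param object an `rgb_patch`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.rgb_patch <- function(object, ...) {
  df <- patch_to_plot_df(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(fill = df$fill) +
    ggplot2::scale_y_reverse(expand = c(0, 0)) +
    ggplot2::scale_x_continuous(expand = c(0, 0)) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Plot a scoring result as an IC-mask overlay
#'
#' Renders the dilated IC mask over the source patch when the result was
#' produced by [score_patch()] (which retains the component masks).
#'
#' @param object an `ic_score_result`.
#' @param patch the scored `rgb_patch`.
#' @param color overlay RGB triple.
#' @param alpha overlay blend weight.
#' @param ... unused.
#' @return A ggplot object titled with the percent score.
#' @export
plot_ic_overlay <- function(object, patch, color = c(255L, 64L, 64L),
                            alpha = 0.5, ...) {
  stopifnot(inherits(object, "ic_score_result"))
  over <- render_overlay(patch, object$component_masks$ic_dilated,
                         color = color, alpha = alpha)
  autoplot(over) +
    ggplot2::ggtitle(sprintf("IC score = %.1f%%", 100 * object$score))
}

#' Plot a concordance report
#'
#' Estimates with 95% confidence bars, faceted by statistic.
#'
#' @param report tibble from [concordance_report()].
#' @return A ggplot object.
#' @export
plot_concordance <- function(report) {
  ggplot2::ggplot(report,
                  ggplot2::aes(x = .data$round, y = .data$estimate)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high),
                           width = 0.2, na.rm = TRUE) +
    ggplot2::facet_wrap(~statistic) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "estimate (95% CI)", x = NULL) +
    ggplot2::theme_minimal()
}
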