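# ggplot2 presentation layer.  The tables behind each figure come from
# heatmap_table() / polar_summary(); the figures themselves carry no
# additional computation.

#' Heatmap of a community profile
#'
#' @param object A `community_profile`.
#' @param mode `"abundance"` (default when available) or `"occurrence"`.
#' @param ... Unused.
#' @return A ggplot object (functions x samples tile heatmap).
#' @export
autoplot.community_profile <- function(object, mode = NULL, ...) {
  mode <- mode %||% if (object$has_abundance) "abundance" else "occurrence"
  value_col <- if (mode == "abundance") "relative_abundance" else "occurrence"
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$sample, y = .data$function_name,
    fill = .data[[value_col]])) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::scale_fill_gradient(low = "white", high = "#08519c",
                                 limits = c(0, 1), name = mode) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Polar plot of the major metabolic functions
#'
#' Shows, for each displayed function (those reaching `min_display` in
#' at least one sample), its per-sample value as radial bars.
#'
#' @inheritParams polar_summary
#' @return A ggplot object with polar coordinates.
#' @export
plot_function_polar <- function(profile, min_display = 0.10,
                                samples = NULL, mode = NULL) {
  wide <- polar_summary(profile, min_display = min_display,
                        samples = samples, mode = mode)
  long <- tidyr::pivot_longer(wide, -"function_name",
                              names_to = "sample", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$function_name, y = .data$value, fill = .data$sample)) +
    ggplot2::geom_col(position = "dodge", width = 0.8) +
    ggplot2::coord_polar() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of function occurrence or abundance
#'
#' Convenience wrapper around [autoplot.community_profile()].
#'
#' @inheritParams autoplot.community_profile
#' @param profile A `community_profile`.
#' @return A ggplot object.
#' @export
plot_function_heatmap <- function(profile, mode = NULL) {
  autoplot(profile, mode = mode)
}
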