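# ggplot2 views of the main result types. These are QC plots, not
# cartography: exclusion bars, accumulation curves, temporal increments,
# and a richness-by-area scatter with the fitted Poisson curve.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot filter accounting
#'
#' Horizontal bars of per-stage exclusions and the retained remainder, as
#' shares of the initial record count.
#'
#' @param object A `filter_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.filter_report <- function(object, ...) {
  df <- filter_accounting(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pct_of_initial,
                                   y = stats::reorder(.data$stage, .data$pct_of_initial))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "% of initial records", y = NULL,
                  title = "Record retention through the three filters") +
    ggplot2::theme_minimal()
}

#' Plot a species accumulation curve
#'
#' @param object Tibble from [accumulation_curve()]; permutation curves show
#'   a 95% ribbon.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_accumulation <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$richness))
  if (all(c("lower", "upper") %in% names(object))) {
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                               ymax = .data$upper),
                                  fill = "grey80")
  }
  p + ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::labs(x = "Sampling units examined", y = "Expected species",
                  title = "Species accumulation") +
    ggplot2::theme_minimal()
}

#' Plot the temporal increment of records and species
#'
#' @param object Tibble from [temporal_summary()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_temporal <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$decade)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$n_species), fill = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$n_records), colour = "darkorange") +
    ggplot2::labs(x = "Decade", y = "Species (bars) / records (line)",
                  title = "Temporal increment of the database") +
    ggplot2::theme_minimal()
}

#' Plot richness against basin area with the fitted model
#'
#' @param object A `richness_area_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.richness_area_fit <- function(object, ...) {
  df <- object$fit$data
  df$fitted <- stats::fitted(object$fit)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$y)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::labs(
      x = if (object$covariate == "log_area") "log area (km²)" else "area (km²)",
      y = "Species richness",
      title = "Richness–area relationship (Poisson GLM)") +
    ggplot2::theme_minimal()
}
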