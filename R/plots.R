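#' Plot abundance and biomass size spectra
#'
#' Log2 abundance and biomass per size class, one panel per fjord, stations
#' overplotted. The bimodal shape (meiofauna mode, macrofauna mode, trough
#' between them) is the feature to look for.
#'
#' @param object A `size_spectrum` tibble.
#' @param response `"abundance"`, `"biomass"` or `"both"` (default).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.size_spectrum <- function(object, response = c("both", "abundance",
                                                        "biomass"), ...) {
  response <- match.arg(response)
  df <- tibble::as_tibble(as.data.frame(object))
  long <- tidyr::pivot_longer(
    dplyr::select(df, "fjord_id", "station_id", "class_index",
                  "abundance", "biomass_ug"),
    c("abundance", "biomass_ug"),
    names_to = "response", values_to = "value"
  )
  if (response != "both") {
    keep <- if (response == "abundance") "abundance" else "biomass_ug"
    long <- dplyr::filter(long, .data$response == keep)
  }
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$class_index, y = log2(.data$value),
    group = .data$station_id
  )) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$response),
      cols = ggplot2::vars(.data$fjord_id),
      scales = "free_y"
    ) +
    ggplot2::labs(
      x = "log2 size class (ug DM)",
      y = "log2 value per 0.1 m^2"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an NBSS fit
#'
#' Normalized biomass points on log2 axes with the fitted regression line.
#'
#' @param object An `nbss_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nbss_fit <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class_index, y = .data$log_nb)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linewidth = 0.4) +
    ggplot2::labs(
      x = "log2 size class (ug DM)",
      y = paste0("log", object$log_base, " normalized biomass"),
      title = sprintf("NBSS: slope %.3f +/- %.3f, R2 %.2f",
                      object$slope, object$slope_se, object$r2)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an NBSS group comparison
#'
#' Station points and per-group common-slope lines from [compare_slopes()].
#'
#' @param object An `nbss_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nbss_comparison <- function(object, ...) {
  d <- object$data
  lines <- dplyr::mutate(object$intercepts, slope = object$common_slope)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class_index, y = .data$log_nb,
                                  colour = .data$.group)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   colour = .data$group),
      linewidth = 0.4
    ) +
    ggplot2::labs(
      x = "log2 size class (ug DM)",
      y = paste0("log", object$log_base, " normalized biomass"),
      colour = object$group
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
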