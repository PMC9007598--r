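#' Plot methods for surfaces and isobole results
#'
#' `autoplot()` methods render a confidence-level response surface as a
#' heatmap with overlaid confidence-level isoboles, and an adaptive isobole
#' run as its evaluated nodes coloured by iteration with the final isobole
#' on top.
#'
#' @param object A `confidence_surface` or `fastisoboles_result`.
#' @param levels Confidence levels for overlaid isoboles.
#' @param ... Unused.
#' @return A ggplot object.
#' @name isocomb-plots
NULL

#' @rdname isocomb-plots
#' @export
autoplot.confidence_surface <- function(object, levels = c(0.5, 0.95), ...) {
  long <- tidy_surface(object)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$amt1, y = .data$amt2)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$confidence)) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "dose, drug 1", y = "dose, drug 2",
                  fill = "confidence",
                  title = sprintf("Confidence of reaching %.0f%% success (%d populations)",
                                  100 * object$target_rate, object$n_pop))
  for (lev in levels) {
    ci <- confidence_isobole(object, lev)
    comps <- attr(ci, "components")
    if (!is.null(comps)) {
      df <- dplyr::bind_rows(purrr::imap(comps, function(cp, i)
        dplyr::mutate(cp, piece = i, level = lev)))
      p <- p + ggplot2::geom_path(
        data = df,
        ggplot2::aes(group = .data$piece, linetype = factor(.data$level)),
        colour = "black")
    }
  }
  p + ggplot2::labs(linetype = "isobole level")
}

#' @rdname isocomb-plots
#' @export
autoplot.fastisoboles_result <- function(object, ...) {
  p <- ggplot2::ggplot(object$cache,
                       ggplot2::aes(x = .data$amt1, y = .data$amt2)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$iteration_first_evaluated)),
                        size = 0.8) +
    ggplot2::labs(x = "dose, drug 1", y = "dose, drug 2", colour = "iteration",
                  title = sprintf("fastIsoboles: %d evaluations, target %.0f%%",
                                  object$n_evaluations, 100 * object$target_rate))
  if (nrow(object$isobole) > 0) {
    df <- tidy(object)
    p <- p + ggplot2::geom_path(data = df,
                                ggplot2::aes(group = .data$piece),
                                colour = "black", linewidth = 0.8)
  }
  p
}

#' Overlay an ensemble of effective isoboles
#'
#' @param results List of `fastisoboles_result`s (one per population).
#' @return A ggplot object.
#' @export
plot_isobole_ensemble <- function(results) {
  df <- dplyr::bind_rows(purrr::imap(results, function(r, i) {
    if (nrow(r$isobole) == 0) return(NULL)
    dplyr::mutate(r$isobole, population_id = i)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data$population_id)) +
    ggplot2::geom_path(alpha = 0.25) +
    ggplot2::labs(x = "dose, drug 1", y = "dose, drug 2",
                  title = "Effective isoboles across population realizations")
}
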