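#' Plot a predicted expression profile
#'
#' @param object a `"model_output"` from [predict_locus()].
#' @param target optional observed profile to overlay.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.model_output <- function(object, target = NULL, ...) {
  d <- object$prediction
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$rate)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "percent embryo length", y = "transcription rate")
  if (!is.null(target)) {
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(position = d$position, rate = target),
      colour = "grey30", linetype = 2)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heat map of window contributions to expression
#'
#' Shows `R[m, m+alpha] * T[m, m+alpha]` — how much each window,
#' centred on `m + alpha/2`, contributes to total expression at each axis
#' position.
#'
#' @param output a `"model_output"` from [predict_locus()] (competition
#'   mode).
#' @param alpha window size used (for centring the x-axis); taken from the
#'   contribution matrix when `NULL`.
#' @return A ggplot object.
#' @export
plot_contribution_map <- function(output, alpha = NULL) {
  cm <- output$contribution
  ws <- output$window_start
  if (is.null(ws) || length(ws) != nrow(cm)) ws <- seq_len(nrow(cm))
  alpha <- alpha %||% (nrow(cm) - length(output$prediction$position) + 1)
  d <- tibble::tibble(
    centre = rep(ws + alpha / 2, times = ncol(cm)),
    position = rep(output$prediction$position, each = nrow(cm)),
    contribution = as.vector(cm)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$centre, y = .data$position,
                                  fill = .data$contribution)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "window centre (bp)", y = "percent embryo length",
                  fill = "R x T")
}

#' Cumulative plot of per-factor border contributions
#'
#' @param bc tibble from [border_contributions()].
#' @return A ggplot object.
#' @export
plot_border_contributions <- function(bc) {
  ggplot2::ggplot(bc, ggplot2::aes(x = .data$position,
                                   y = .data$contribution,
                                   fill = .data$tf)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::labs(x = "percent embryo length",
                  y = "contribution to change in rate", fill = "factor")
}

#' Annealing trace plot
#'
#' @param object a `"fit_result"` from [anneal()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.fit_result <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$move)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$value), colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$best), colour = "firebrick") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "move", y = "SSE")
}
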