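#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col labs
#'   theme_minimal
#' @export
ggplot2::autoplot

#' Plot methods
#'
#' `autoplot()` methods for the package's result types: spike rasters
#' ([spike_raster_table()]), binned rate traces ([rate_trace()], optionally
#' overlaid with a cosine fit), and similarity curves ([similarity_index()]).
#'
#' @param object A `cb_raster`, `cb_ratetrace` or `cb_sicurve`.
#' @param fit Optional `cb_cosfit` drawn over a rate trace.
#' @param ... Unused.
#' @return A ggplot object.
#' @name cb-plots
NULL

#' @rdname cb-plots
#' @export
autoplot.cb_raster <- function(object, ...) {
  ggplot(object, aes(x = .data$t_ms, y = .data$row)) +
    geom_point(shape = ".", alpha = 0.7) +
    labs(x = "time (ms)", y = "neuron") +
    theme_minimal()
}

#' @rdname cb-plots
#' @export
autoplot.cb_ratetrace <- function(object, fit = NULL, ...) {
  p <- ggplot(object, aes(x = .data$t_mid, y = .data$rate_hz)) +
    geom_point() +
    labs(x = "time (ms)", y = "firing rate (spikes/s)") +
    theme_minimal()
  if (!is.null(fit)) {
    tt <- seq(min(object$t_mid), max(object$t_mid), length.out = 400)
    curve <- tibble(
      t_mid = tt,
      rate_hz = fit$a + fit$b * cos(2 * pi * fit$freq_hz * tt / 1000 + fit$phi)
    )
    p <- p + geom_line(data = curve, aes(x = .data$t_mid, y = .data$rate_hz))
  }
  p
}

#' @rdname cb-plots
#' @export
autoplot.cb_sicurve <- function(object, ...) {
  ggplot(object, aes(x = .data$delta_ms, y = .data$si)) +
    geom_line() + geom_point() +
    labs(x = expression(Delta * t ~ "(ms)"), y = "similarity index") +
    theme_minimal()
}
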