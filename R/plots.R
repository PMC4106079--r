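# ggplot2 displays for traces, equilibrium curves and stability maps.

#' Plot a simulation trace
#'
#' `what = "V"` draws the potential-time curve; `what = "gates"` the
#' three gating variables against time.
#'
#' @param object An [hh_simulate()] trace.
#' @param what `"V"` or `"gates"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hh_trace <- function(object, what = c("V", "gates"), ...) {
  what <- match.arg(what)
  if (what == "V") {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$V)) +
      ggplot2::geom_line(colour = "#2c3e77") +
      ggplot2::labs(x = "time (ms)", y = "V (mV)")
  } else {
    long <- tidyr_pivot_gates(object)
    ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                       colour = .data$gate)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (ms)", y = "gate opening", colour = NULL)
  }
}

# minimal long-format helper (keeps tidyr out of Imports)
tidyr_pivot_gates <- function(trace) {
  dplyr::bind_rows(lapply(c("m", "h", "n"), function(g) {
    tibble::tibble(time = trace$time, gate = g, value = trace[[g]])
  }))
}

#' Plot a one-parameter equilibrium curve
#'
#' Equilibrium potential against the swept conductance, coloured by
#' the Routh-Hurwitz verdict.
#'
#' @param curve A tibble from [equilibrium_curve()].
#' @return A ggplot object.
#' @export
plot_equilibrium_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$param_value,
                                      y = .data$V_star,
                                      colour = .data$stable)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = paste0(curve$param_name[1], " (mS/cm^2)"),
                  y = "V* (mV)", colour = "stable")
}

#' Plot a stability map
#'
#' Raster of the stable region over the (g_Na, g_K) plane with the
#' refined boundary points overlaid; optionally the fitted upper
#' boundary line.
#'
#' @param object An [stability_map()] result.
#' @param fit Optional [fit_upper_boundary()] result to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hh_stability_map <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object$grid,
                       ggplot2::aes(x = .data$g_Na, y = .data$g_K)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$stable)) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#f8c8dc",
                                          `FALSE` = "white"),
                               na.value = "grey70") +
    ggplot2::geom_point(data = object$boundary, size = 0.3,
                        ggplot2::aes(shape = .data$branch)) +
    ggplot2::labs(x = "g_Na (mS/cm^2)", y = "g_K (mS/cm^2)",
                  fill = "stable", shape = "boundary")
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_abline(slope = fit$slope,
                                  intercept = fit$intercept,
                                  colour = "#2c3e77")
  }
  p
}
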