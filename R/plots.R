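#' Plot population rate traces of a simulation
#'
#' Population-mean firing rates over time, one facet per population, with
#' stimulus phases shaded.
#'
#' @param object An `npe_sim` simulated with `record_every > 0`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.npe_sim <- function(object, ...) {
  if (is.null(object$traces))
    stop("simulation was run with record_every = 0; no traces to plot",
         call. = FALSE)
  ph <- object$phases
  ph$end <- cumsum(ph$duration)
  ph$start <- ph$end - ph$duration
  shade <- ph[ph$kind != "baseline", ]
  ggplot2::ggplot(object$traces,
                  ggplot2::aes(x = .data$time / 1000, y = .data$rate)) +
    ggplot2::geom_rect(
      data = shade, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start / 1000, xmax = .data$end / 1000,
                   ymin = -Inf, ymax = Inf, fill = .data$kind),
      alpha = 0.15) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~population, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "population rate (1/s)",
                  fill = "phase") +
    ggplot2::theme_minimal()
}

#' Response heatmap sorted by mismatch amplitude
#'
#' The standard display of PC prediction-error structure: one row per PC,
#' columns feedback / mismatch / playback, rows sorted by mismatch
#' response, values normalized to \[-1, 1\].
#'
#' @param classified A tibble from [classify_pcs()].
#' @return A ggplot object.
#' @export
plot_response_heatmap <- function(classified) {
  long <- classified |>
    dplyr::mutate(order = rank(-.data$mm, ties.method = "first")) |>
    tidyr::pivot_longer(c("fb", "mm", "pb"), names_to = "phase",
                        values_to = "drr") |>
    dplyr::group_by(.data$unit) |>
    dplyr::mutate(drr = {
      peak <- max(abs(.data$drr), na.rm = TRUE)
      if (is.finite(peak) && peak > 0) .data$drr / peak else .data$drr * 0
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(phase = factor(.data$phase, c("fb", "mm", "pb"),
                                 c("FB", "MM", "PB")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$phase, y = .data$order,
                                     fill = .data$drr)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "PC (sorted by MM response)",
                  fill = "norm.\ndR/R") +
    ggplot2::theme_minimal()
}

#' Plot somatic excitation/inhibition current traces
#'
#' PC-population mean somatic excitatory and inhibitory currents (pA) over
#' time, the display used to illustrate stimulus-by-stimulus E/I balance.
#'
#' @param sim An `npe_sim` simulated with `record_every > 0`.
#' @param gain Rate-to-current gain; defaults to the network value.
#' @return A ggplot object.
#' @export
plot_currents <- function(sim, gain = NULL) {
  if (is.null(sim$current_traces))
    stop("simulation was run with record_every = 0; no traces to plot",
         call. = FALSE)
  g <- gain %||% sim$network$pc$gain
  long <- sim$current_traces |>
    dplyr::mutate(net = .data$exc - .data$inh) |>
    tidyr::pivot_longer(c("exc", "inh", "net"), names_to = "component",
                        values_to = "current") |>
    dplyr::mutate(current = .data$current / g)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time / 1000,
                                     y = .data$current,
                                     colour = .data$component)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::scale_colour_manual(values = c(exc = "#fb6a4a",
                                            inh = "#6baed6",
                                            net = "grey30")) +
    ggplot2::labs(x = "time (s)", y = "somatic current (pA)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
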