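#' @importFrom ggplot2 autoplot
NULL

#' Raster plot of a spike record
#'
#' Spike times per neuron, coloured by population, with the stimulus onset
#' marked.
#'
#' @param object A `spike_record`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spike_record <- function(object, ...) {
  df <- tidy.spike_record(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$neuron_id,
                                   colour = .data$pop)) +
    ggplot2::geom_point(shape = ".", alpha = 0.6) +
    ggplot2::geom_vline(xintercept = object$onset_ms, linetype = "dashed") +
    ggplot2::labs(x = "time (ms)", y = "neuron", colour = "population") +
    ggplot2::theme_minimal()
}

#' Peristimulus time histogram plot
#'
#' Individual trial traces (thin) with the across-trial average (thick).
#'
#' @param object A [psth()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psth <- function(object, ...) {
  ggplot2::ggplot() +
    ggplot2::geom_step(data = object$trace,
                       ggplot2::aes(x = .data$bin_start_ms, y = .data$rate_Hz,
                                    group = .data$trial),
                       colour = "grey40", alpha = 0.3) +
    ggplot2::geom_step(data = object$average,
                       ggplot2::aes(x = .data$bin_start_ms, y = .data$rate_Hz),
                       colour = "red", linewidth = 1) +
    ggplot2::labs(x = "time (ms)", y = paste0(object$population, " rate (Hz)")) +
    ggplot2::theme_minimal()
}

#' Heat-map slice of a transfer-function grid
#'
#' Shows one population's output rate over the E and P axes at a fixed
#' S-axis node.
#'
#' @param object A `tf_grid`.
#' @param population Population to display.
#' @param s_index Index into the S axis for the displayed slice.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tf_grid <- function(object, population = object$excitatory,
                             s_index = 1, ...) {
  df <- as_tibble.tf_grid(object) |>
    dplyr::filter(.data$dlambda_S == object$ax_S[s_index])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dlambda_E, y = .data$dlambda_P,
                                   fill = .data[[paste0("rate_", population)]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = paste0(population, " rate (Hz)")) +
    ggplot2::labs(x = "dlambda_E (Hz)", y = "dlambda_P (Hz)",
                  title = paste0("dlambda_S = ", object$ax_S[s_index], " Hz")) +
    ggplot2::theme_minimal()
}

#' Heat map of a variability sweep
#'
#' Excitatory output variance over the two swept factors; masked
#' (rejected / out-of-hull) cells are blank.
#'
#' @param object A `variability_map` from [sweep_factor_variability()] or
#'   [sweep_mean_variability()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.variability_map <- function(object, ...) {
  if (all(c("f1", "f2") %in% names(object))) {
    axes <- attr(object, "axes")
    p <- ggplot2::ggplot(object,
                         ggplot2::aes(x = .data$f1, y = .data$f2,
                                      fill = .data$var_E)) +
      ggplot2::labs(x = axes[1], y = axes[2])
  } else {
    p <- ggplot2::ggplot(object,
                         ggplot2::aes(x = .data$dlambda_E, y = .data$dlambda_P,
                                      fill = .data$var_E)) +
      ggplot2::labs(x = "dlambda_E (Hz)", y = "dlambda_P (Hz)")
  }
  p + ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "var E (Hz²)", na.value = "white") +
    ggplot2::theme_minimal()
}
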