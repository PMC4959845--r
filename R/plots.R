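#' Raster plot of a simulation
#'
#' @param object A `sim_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sim_result
#' @export
autoplot.sim_result <- function(object, ...) {
  ggplot2::ggplot(object$spikes,
                  ggplot2::aes(x = .data$time, y = .data$neuron,
                               colour = .data$population)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "time (s)", y = "neuron",
                  title = sprintf("%s network spike raster", object$variant)) +
    ggplot2::theme_minimal()
}

#' Power-spectrum plot
#'
#' @param object A `spectral_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spectral_summary
#' @export
autoplot.spectral_summary <- function(object, ...) {
  pk <- attr(object, "peak_frequency")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$frequency, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = pk, linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "frequency (Hz)", y = "power",
                  subtitle = sprintf("peak at %.1f Hz", pk)) +
    ggplot2::theme_minimal()
}

#' Target and reconstruction overlay
#'
#' @param result A `sim_result` with a stimulus attached.
#' @return A ggplot object.
#' @export
plot_reconstruction <- function(result) {
  ro <- result$readout
  df <- tibble(time = ro$time, target = result$stimulus$x)
  long <- tidyr::pivot_longer(dplyr::bind_cols(df, ro[-1]),
                              -"time", names_to = "trace")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$trace)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "value") +
    ggplot2::theme_minimal()
}

#' Sweep metric plot
#'
#' Plots a metric column of a [run_sweep()] table against the swept value,
#' averaging over seeds.
#'
#' @param sweep_table Output of [run_sweep()].
#' @param metric Name of the metric column (default `"error"`).
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep_table, metric = "error") {
  avg <- sweep_table %>%
    group_by(.data$value) %>%
    summarise(m = mean(.data[[metric]], na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$value, y = .data$m)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "swept value", y = metric) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
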