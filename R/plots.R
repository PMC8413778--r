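#' Plot a difference wave at one electrode
#'
#' Standard, deviant and difference (MMN) traces against time.
#'
#' @param object A `difference_wave`.
#' @param electrode Electrode label, default `"Fz"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.difference_wave <- function(object, electrode = "Fz", ...) {
  td <- tidy(object)
  td <- td[td$channel == electrode, ]
  long <- tidyr::pivot_longer(td, c("standard_uv", "deviant_uv", "diff_uv"),
                              names_to = "trace", values_to = "uv")
  long$trace <- factor(long$trace, levels = c("standard_uv", "deviant_uv", "diff_uv"),
                       labels = c("standard", "deviant", "difference (MMN)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_ms, y = .data$uv,
                                     colour = .data$trace)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_line() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "time (ms)", y = "amplitude (uV, negative up)",
                  colour = NULL,
                  title = sprintf("%s MMN at %s", object$kind, electrode)) +
    ggplot2::theme_minimal()
}

#' Plot a scalp map
#'
#' A simple planar electrode plot: position from the montage, fill from the
#' map value. Not an interpolated topography — just the electrode values.
#'
#' @param map Topomap tibble (`electrode`, `value`).
#' @param montage Montage supplying electrode positions.
#' @return A ggplot object.
#' @export
plot_topomap <- function(map, montage = montage_1020_32()) {
  df <- dplyr::inner_join(map, montage, by = c(electrode = "name"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(fill = .data$value), shape = 21, size = 7) +
    ggplot2::geom_text(ggplot2::aes(label = .data$electrode), size = 2.4,
                       nudge_y = 0.09) +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "uV") +
    ggplot2::theme_void()
}

#' Gender-by-condition interaction plot of the measures
#'
#' Cell means with SEM error bars, one line per gender.
#'
#' @param measures Measures tibble from [run_study()] or [measure_mmn()].
#' @param dv `"peak_latency_ms"` or `"mean_amplitude_uv"`.
#' @return A ggplot object.
#' @export
plot_interaction <- function(measures, dv = "peak_latency_ms") {
  cs <- measures |>
    dplyr::group_by(.data$gender, .data$condition) |>
    dplyr::summarise(m = mean(.data[[dv]]),
                     sem = sd(.data[[dv]]) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(cs, ggplot2::aes(x = .data$condition, y = .data$m,
                                   colour = .data$gender, group = .data$gender)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$m - .data$sem,
                                          ymax = .data$m + .data$sem)) +
    ggplot2::labs(x = "oddball condition", y = dv, colour = NULL) +
    ggplot2::theme_minimal()
}
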