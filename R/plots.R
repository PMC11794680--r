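#' Bland-Altman plot for one agreement cell
#'
#' Differences (device minus criterion) against pair means, with the bias
#' and the 1.96-SD limits of agreement drawn as horizontal lines.
#'
#' @param device,criterion Paired numeric vectors.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(device, criterion, title = NULL) {
  ba <- bland_altman(device, criterion)
  df <- tibble::tibble(mean_value = (device + criterion) / 2,
                       difference = device - criterion)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_value,
                                   y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = ba$bias, linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of device and criterion",
                  y = "Device - criterion", title = title) +
    ggplot2::theme_minimal()
}

#' Overlay a device IBI trace on the criterion
#'
#' The standard visual check after synchronization: both beat-to-beat traces
#' on a common clock.
#'
#' @param device,criterion IBI series tibbles (device already lag-aligned).
#' @return A ggplot object.
#' @export
plot_ibi_comparison <- function(device, criterion) {
  df <- dplyr::bind_rows(
    dplyr::mutate(criterion, stream = "criterion"),
    dplyr::mutate(device, stream = device$device_id[1] %||% "device")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$onset_ms / 1000,
                                   y = .data$ibi_ms,
                                   colour = .data$stream)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "IBI (ms)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn agreement_stats MAAPE bar chart per device and condition,
#'   faceted by feature.
#' @param object An `hrv_agreement` object.
#' @param ... Unused.
#' @method autoplot hrv_agreement
#' @export
autoplot.hrv_agreement <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$maape,
                                   fill = .data$device_id)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$maape_ci_low, ymax = .data$maape_ci_high),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$feature), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "MAAPE (%)", fill = "Device") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @describeIn run_pipeline Signal-quality stacked bars per device.
#' @param object An `hrv_validation` object.
#' @param ... Unused.
#' @method autoplot hrv_validation
#' @export
autoplot.hrv_validation <- function(object, ...) {
  df <- object$quality_labels |>
    dplyr::count(.data$device_id, .data$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$device_id, y = .data$n,
                                   fill = .data$label)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_y_continuous(labels = function(v) 100 * v) +
    ggplot2::labs(x = NULL, y = "Segments (%)", fill = "Quality") +
    ggplot2::theme_minimal()
}
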