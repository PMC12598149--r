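#' Plot fluorescence traces of a synthetic dataset
#'
#' Stacked per-ROI traces with ground-truth burst windows shaded.
#'
#' @param object A `calci_dataset`.
#' @param rois Optional character vector of ROI ids (default: first 6).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.calci_dataset <- function(object, rois = NULL, ...) {
  ids <- rois %||% head(unique(object$traces$roi_id), 6)
  tr <- dplyr::filter(object$traces, .data$roi_id %in% ids)
  bu <- dplyr::filter(object$ground_truth$bursts, .data$roi_id %in% ids)
  p <- ggplot2::ggplot(tr, ggplot2::aes(.data$time_s, .data$F)) +
    ggplot2::geom_line(linewidth = 0.25) +
    ggplot2::facet_wrap(~roi_id, ncol = 1, strip.position = "right") +
    ggplot2::labs(x = "time (s)", y = expression(Delta * "F/F"),
                  title = paste("condition:", object$condition))
  if (nrow(bu)) {
    p <- p + ggplot2::geom_rect(
      data = bu,
      ggplot2::aes(xmin = .data$burst_start_s, xmax = .data$burst_end_s,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.15)
  }
  p
}

#' Plot one processed ROI: fluorescence, denoised fit and deconvolved events
#'
#' @param processed A `calci_processed` object.
#' @param roi ROI id (default: first).
#' @param events Optional `calci_transients` tibble; detected peaks are
#'   marked.
#' @return A ggplot object.
#' @export
plot_trace <- function(processed, roi = NULL, events = NULL) {
  roi <- roi %||% processed$traces$roi_id[1]
  d <- dplyr::filter(processed$traces, .data$roi_id == roi)
  long <- tidyr::pivot_longer(
    dplyr::select(d, "time_s", "fluor", "denoised", "deconv"),
    c("fluor", "denoised", "deconv"),
    names_to = "signal", values_to = "value") |>
    dplyr::mutate(signal = factor(.data$signal,
                                  c("fluor", "denoised", "deconv")))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line(linewidth = 0.25) +
    ggplot2::facet_wrap(~signal, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, title = roi)
  if (!is.null(events)) {
    ev <- dplyr::filter(events, .data$roi_id == roi)
    if (nrow(ev)) {
      p <- p + ggplot2::geom_vline(
        data = dplyr::mutate(ev, signal = factor("fluor",
                                                 c("fluor", "denoised",
                                                   "deconv"))),
        ggplot2::aes(xintercept = .data$peak_time_s),
        color = "firebrick", alpha = 0.5, linewidth = 0.2)
    }
  }
  p
}

#' Plot an interval mixture over the interval histogram
#'
#' Weighted component densities and, when defined, the burst threshold at
#' their intersection.
#'
#' @param object An `interval_mixture`.
#' @param intervals Optional interval vector to show as a histogram.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.interval_mixture <- function(object, intervals = NULL, ...) {
  xmax <- max(object$mu_s + 6 * object$sigma_s, 3 / object$rate_per_s,
              intervals %||% 0)
  grid <- tibble::tibble(x = seq(1e-3, xmax, length.out = 512)) |>
    dplyr::mutate(
      gaussian = object$w_g * dnorm(.data$x, object$mu_s, object$sigma_s),
      exponential = object$w_e * dexp(.data$x, object$rate_per_s)) |>
    tidyr::pivot_longer(c("gaussian", "exponential"),
                        names_to = "component", values_to = "density")
  p <- ggplot2::ggplot()
  if (!is.null(intervals)) {
    p <- p + ggplot2::geom_histogram(
      data = tibble::tibble(x = intervals),
      ggplot2::aes(.data$x, ggplot2::after_stat(density)),
      bins = 60, fill = "grey85", color = "grey70")
  }
  p <- p + ggplot2::geom_line(
    data = grid,
    ggplot2::aes(.data$x, .data$density, color = .data$component))
  thr <- tryCatch(mixture_intersection(object), error = function(e) NULL)
  if (!is.null(thr)) {
    p <- p + ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
      ggplot2::annotate("text", x = thr, y = Inf, vjust = 1.5, hjust = -0.1,
                        label = sprintf("threshold %.1f s", thr))
  }
  p + ggplot2::labs(x = "interpeak interval (s)", y = "density")
}

#' Plot per-ROI activity metrics
#'
#' @param object An `activity_metrics` object.
#' @param ... Unused.
#' @return A ggplot object (jittered per-ROI points per metric).
#' @export
autoplot.activity_metrics <- function(object, ...) {
  long <- object$per_roi |>
    dplyr::select("roi_id", "n_transients", "n_bursts",
                  "mean_burst_duration_s", "fraction_active",
                  "intraburst_period_s") |>
    tidyr::pivot_longer(-"roi_id", names_to = "metric") |>
    dplyr::filter(is.finite(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(x = "", y = .data$value)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar",
                          width = 0.4, linewidth = 0.3, color = "firebrick") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Plot a sigmoid fit with its data
#'
#' @param object A `sigmoid_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sigmoid_fit <- function(object, ...) {
  grid <- seq(min(object$x), max(object$x), length.out = 256)
  ggplot2::ggplot() +
    ggplot2::geom_point(data = tibble::tibble(x = object$x, y = object$y),
                        ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_line(
      data = tibble::tibble(x = grid, y = predict(object, grid)),
      ggplot2::aes(.data$x, .data$y), color = "steelblue") +
    ggplot2::labs(
      x = "x", y = "y",
      subtitle = sprintf("%s fit, R² = %.3f", object$form,
                         object$r_squared))
}
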