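# Presentation-layer plots. All statistics are computed by the module
# functions; these only draw.

#' Plot an octagon stimulus
#'
#' @param object An `octagon`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.octagon <- function(object, ...) {
  v <- tibble::as_tibble(object$vertices)
  v <- dplyr::bind_rows(v, v[1, ])
  ggplot2::ggplot(v, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_polygon(fill = "black") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s octagon (rotation %g deg)",
                                  object$condition, object$rotation_deg),
                  x = "deg", y = "deg") +
    ggplot2::theme_minimal()
}

#' Plot grand-average ROI waveforms by condition
#'
#' @param erps A `subject_erps`.
#' @param roi An `roi_spec`; its electrodes define the trace and its window
#'   is shaded.
#' @return A ggplot with one line per condition and the S - A difference.
#' @export
plot_erp <- function(erps, roi = canonical_roi()) {
  ri <- roi_indices(erps, roi)
  long <- purrr::map_dfr(seq_along(erps$conditions), function(cj) {
    g <- apply(erps$data[ri$ch, , , cj, drop = FALSE], 2, mean)
    tibble::tibble(condition = erps$conditions[cj],
                   time_ms = erps$times_ms, amplitude_uv = g)
  })
  diffw <- tidyr::pivot_wider(long, names_from = "condition",
                              values_from = "amplitude_uv")
  diffw <- dplyr::mutate(diffw,
                         condition = "difference (S - A)",
                         amplitude_uv = .data$symmetric - .data$asymmetric)
  long <- dplyr::bind_rows(long, diffw[, names(long)])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_ms, y = .data$amplitude_uv,
                                     color = .data$condition)) +
    ggplot2::annotate("rect", xmin = roi$window_ms[1], xmax = roi$window_ms[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.12) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "amplitude (uV)",
                  title = sprintf("ROI grand averages (%s)", roi$origin)) +
    ggplot2::theme_minimal()
}

#' Plot the spatiotemporal mask of a cluster test
#'
#' Channel-by-time raster of cluster membership for significant clusters.
#'
#' @param object A `cluster_test`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cluster_test <- function(object, ...) {
  n_ch <- nrow(object$tmap$t)
  sig <- which(object$clusters$significant)
  cells <- purrr::map_dfr(sig, function(k) {
    cl <- object$cluster_details[[k]]
    tibble::tibble(
      channel = object$tmap$channels[(cl$cells - 1) %% n_ch + 1],
      time_ms = object$tmap$times_ms[(cl$cells - 1) %/% n_ch + 1],
      sign = ifelse(cl$mass < 0, "negative", "positive"))
  })
  if (nrow(cells) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", 0, 0, label = "no significant cluster") +
             ggplot2::theme_void())
  }
  cells$channel <- factor(cells$channel, levels = object$tmap$channels)
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$time_ms, y = .data$channel,
                                      fill = .data$sign)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "time (ms)", y = NULL,
                  title = "significant spatiotemporal clusters") +
    ggplot2::theme_minimal()
}

#' Plot a reliability curve
#'
#' Reliability vs per-condition epoch count with Clopper-Pearson intervals.
#'
#' @param object An `spn_reliability`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spn_reliability <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$m, y = .data$reliability)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                           width = 0.5) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$alpha, linetype = 2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "epochs per condition (m)",
                  y = sprintf("P(one-tailed p < %.2f)", object$alpha),
                  title = "fixed-cohort subsampling reliability") +
    ggplot2::theme_minimal()
}
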