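#' Plot an omega PEV trace against its surrogate bands
#'
#' @param object An `encoding_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.encoding_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$wpev), linewidth = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$pointwise_band),
                       linetype = "dashed", colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$global_band,
                        colour = "firebrick") +
    ggplot2::labs(
      x = "time from event (s)", y = expression(omega * "PEV"),
      title = sprintf("unit %s%s", object$unit_id,
                      if (object$encoder) " (encoder)" else "")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a (z-scored) spectrogram
#'
#' @param object A `spectrogram`.
#' @param ... Unused.
#' @return A ggplot tile plot (time x frequency).
#' @export
autoplot.spectrogram <- function(object, ...) {
  df <- tidyr::expand_grid(
    time = object$window_centers, freq = object$freqs
  )
  df$power <- as.vector(t(object$power))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$freq,
                                   fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(
      name = if (object$normalized) "z" else "power"
    ) +
    ggplot2::labs(x = "time from event (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot orthonormalized population trajectories by block
#'
#' Projects each trial's trajectory onto the top two orthonormalized
#' dimensions, colour-coded by block.
#'
#' @param trajset A `trajectory_set` with `blocks`.
#' @param dims Two dimensions to display.
#' @return A ggplot.
#' @export
plot_trajectories <- function(trajset, dims = c(1, 2)) {
  n_tr <- dim(trajset$latents)[3]
  df <- dplyr::bind_rows(lapply(seq_len(n_tr), function(tr) {
    tibble::tibble(
      trial = tr,
      block = factor(trajset$blocks[tr] %||% 1),
      bin = seq_len(dim(trajset$latents)[2]),
      d1 = trajset$latents[dims[1], , tr],
      d2 = trajset$latents[dims[2], , tr]
    )
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$d1, .data$d2, group = .data$trial,
                                   colour = .data$block)) +
    ggplot2::geom_path(alpha = 0.5) +
    ggplot2::labs(x = sprintf("dim %d", dims[1]),
                  y = sprintf("dim %d", dims[2])) +
    ggplot2::theme_minimal()
}

#' Plot a time-lagged PLV profile
#'
#' @param lag_result Output of [lagged_plv_profile()].
#' @return A ggplot with the peak lag marked.
#' @export
plot_lag_profile <- function(lag_result) {
  ggplot2::ggplot(lag_result$profile,
                  ggplot2::aes(.data$lag_ms, .data$plv)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = lag_result$peak_lag_ms,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "spike-time lag (ms)", y = "PLV") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
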