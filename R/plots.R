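#' Plot a rupture-force density
#'
#' Density against force (`time * loading_rate`), with the most-probable
#' rupture force marked.
#'
#' @param object A [rupture_density()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rupture_density <- function(object, ...) {
  dat <- object$data
  dat$force <- dat$time * object$loading_rate
  dat$density_per_pN <- dat$density / object$loading_rate
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$force, y = .data$density_per_pN)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$mode_force, linetype = "dashed") +
    ggplot2::labs(
      x = "Force (pN)", y = expression(Probability~density~(pN^-1)),
      title = sprintf("Rupture density, %s model, %.3g pN/s",
                      object$variant, object$loading_rate)) +
    ggplot2::theme_classic()
}

#' Plot a Freedman-Diaconis histogram with its KDE overlay
#'
#' @param object An [fd_histogram()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fd_histogram <- function(object, ...) {
  dens <- object$density
  dens$count <- dens$density * object$n * object$bin_width
  ggplot2::ggplot() +
    ggplot2::geom_col(data = object$bins,
                      ggplot2::aes(x = .data$mid, y = .data$count),
                      width = object$bin_width, fill = "grey80",
                      colour = "grey30") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(x = .data$force, y = .data$count)) +
    ggplot2::labs(x = "Rupture force (pN)", y = "Count") +
    ggplot2::theme_classic()
}

#' Dynamic force spectrum: mode forces vs loading rate
#'
#' Most-probable rupture forces with bandwidth error bars on a log loading-
#' rate axis, optionally overlaid with model curves (a named list of
#' functions `l_r -> mode force`, e.g. from [bell_evans_mode_force()] or
#' [predict_mode_force()]).
#'
#' @param points A mode-point tibble (see [rupture_modes()]).
#' @param models Optional named list of vectorized prediction functions.
#' @param n_curve Points per model curve.
#' @return A ggplot object.
#' @export
plot_force_spectrum <- function(points, models = NULL, n_curve = 60) {
  p <- ggplot2::ggplot(points,
                       ggplot2::aes(x = .data$mean_loading_rate,
                                    y = .data$mode_force)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mode_force - .data$error,
                                        ymax = .data$mode_force + .data$error),
                           width = 0.05) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$condition), size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(Loading~rate~(pN~s^-1)),
                  y = "Most-probable rupture force (pN)") +
    ggplot2::theme_classic()
  if (!is.null(models)) {
    lr <- exp(seq(log(min(points$mean_loading_rate)),
                  log(max(points$mean_loading_rate)), length.out = n_curve))
    curves <- purrr::imap_dfr(models, function(fn, nm)
      tibble::tibble(model = nm, mean_loading_rate = lr, mode_force = fn(lr)))
    p <- p + ggplot2::geom_line(
      data = curves, ggplot2::aes(linetype = .data$model), colour = "black")
  }
  p
}

#' Plot a BLI sensorgram
#'
#' @param s A sensorgram tibble (`time`, `signal`, `phase`).
#' @return A ggplot object.
#' @export
plot_sensorgram <- function(s) {
  check_sensorgram(s)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$time, y = .data$signal,
                                  colour = .data$phase)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Signal (nm)") +
    ggplot2::theme_classic()
}

#' Plot mean tip-link lifetime over the stimulus grid
#'
#' Mean lifetime with SEM error bars against frequency, one line per
#' deflection amplitude.
#'
#' @param grid Output of [tip_link_lifetime_grid()].
#' @return A ggplot object.
#' @export
plot_lifetime_grid <- function(grid) {
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$frequency,
                                     y = .data$mean_lifetime,
                                     colour = factor(.data$amplitude))) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_lifetime - .data$sem,
      ymax = .data$mean_lifetime + .data$sem)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Stimulus frequency (Hz)", y = "Mean lifetime (s)",
                  colour = "Amplitude (nm)") +
    ggplot2::theme_classic()
}
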