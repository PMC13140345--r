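#' Plot the tilt-angle / loading relationship
#'
#' Axial loading (percent bodyweight) as a function of head-up-tilt angle,
#' with optional reference markers (e.g. Moon at 9.5 deg, Mars at 22.3 deg).
#'
#' @param theta_max_deg Upper end of the angle axis (default 90).
#' @param markers Optional named numeric vector of angles to highlight,
#'   e.g. `c(Moon = 9.5, Mars = 22.3)`.
#' @return A ggplot object.
#' @export
plot_loading_curve <- function(theta_max_deg = 90,
                               markers = c(Moon = 9.5, Mars = 22.3)) {
  grid <- tibble::tibble(theta_deg = seq(0, theta_max_deg, length.out = 200))
  grid$loading_pct <- axial_loading_pct(grid$theta_deg)
  p <- ggplot2::ggplot(grid, ggplot2::aes(.data$theta_deg, .data$loading_pct)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Head-up tilt angle (deg)",
                  y = "Axial loading (% bodyweight)")
  if (length(markers) > 0) {
    pts <- tibble::tibble(label = names(markers), theta_deg = unname(markers),
                          loading_pct = axial_loading_pct(unname(markers)))
    p <- p +
      ggplot2::geom_point(data = pts, size = 2) +
      ggplot2::geom_text(data = pts, ggplot2::aes(label = .data$label),
                         nudge_y = 4, nudge_x = -2)
  }
  p
}

#' Plot a pendulum-effect error curve
#'
#' Additional axial acceleration above the simulated gravity level, per rope
#' group and for the mass-weighted whole body, against axial displacement.
#'
#' @param object A `pendulum_curve` from [pendulum_error_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pendulum_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$s_axial_m, .data$additional_accel_ms2,
                               colour = .data$rope)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Axial displacement (m)",
      y = expression("Additional axial acceleration" ~ (m ~ s^-2)),
      colour = "Rope",
      subtitle = sprintf("theta = %.1f deg, ankle rope %.1f m",
                         attr(object, "theta_deg"), attr(object, "l_ankle_m")))
}

#' Bland-Altman plot
#'
#' Pairwise means against differences, with the bias (dashed) and limits of
#' agreement (solid) and their confidence bands.
#'
#' @param object A `bland_altman` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bland_altman <- function(object, ...) {
  est <- tidy(object)
  ggplot2::ggplot(object$pairs, ggplot2::aes(.data$mean, .data$diff)) +
    ggplot2::geom_rect(
      data = est, inherit.aes = FALSE,
      ggplot2::aes(xmin = -Inf, xmax = Inf,
                   ymin = .data$conf.low, ymax = .data$conf.high),
      alpha = 0.15) +
    ggplot2::geom_hline(data = est[est$term == "bias", ],
                        ggplot2::aes(yintercept = .data$estimate),
                        linetype = "dashed") +
    ggplot2::geom_hline(data = est[est$term != "bias", ],
                        ggplot2::aes(yintercept = .data$estimate)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Mean of paired measurements",
                  y = "Difference between measurements")
}
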