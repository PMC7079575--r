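#' Plot joint-angle curves over the gait cycle
#'
#' @param angles Tibble with `cycle_pct` (or `time`), `joint`,
#'   `angle_deg`, and optionally a `series` column distinguishing
#'   model vs reference curves.
#' @param stance_fraction Shades the stance portion of the cycle.
#' @return A ggplot object.
#' @export
plot_joint_angles <- function(angles, stance_fraction = 0.6) {
  xcol <- if ("cycle_pct" %in% names(angles)) "cycle_pct" else "time"
  p <- ggplot2::ggplot(angles,
                       ggplot2::aes(x = .data[[xcol]], y = .data$angle_deg))
  if (xcol == "cycle_pct") {
    p <- p + ggplot2::annotate("rect", xmin = stance_fraction * 100,
                               xmax = 100, ymin = -Inf, ymax = Inf,
                               alpha = 0.08)
  }
  if ("series" %in% names(angles)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(color = .data$series,
                                             linetype = .data$series))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p +
    ggplot2::facet_wrap(~joint, scales = "free_y") +
    ggplot2::labs(x = if (xcol == "cycle_pct") "Gait cycle (%)" else "Time (s)",
                  y = "Joint angle (deg)") +
    ggplot2::theme_minimal()
}

#' Plot ground reaction forces normalized by body weight
#'
#' @param grf GRF tibble (`time`, `fx`, `fy`, `fz`).
#' @param body_mass_kg Body mass for BW normalization.
#' @return A ggplot object.
#' @export
plot_grf <- function(grf, body_mass_kg) {
  bw <- body_mass_kg * 9.81
  long <- grf %>%
    select("time", "fx", "fy", "fz") %>%
    tidyr::pivot_longer(-"time", names_to = "channel",
                        values_to = "force_n") %>%
    mutate(channel = dplyr::recode(.data$channel, fx = "cranial-caudal",
                                   fy = "vertical", fz = "mediolateral"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time,
                                     y = .data$force_n / bw,
                                     color = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Force (BW)", color = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn inverse_kinematics Per-frame RMS marker error plot.
#' @method autoplot ik_fit
#' @export
autoplot.ik_fit <- function(object, ...) {
  ggplot2::ggplot(object$frames,
                  ggplot2::aes(x = .data$time, y = .data$rms_mm)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "RMS marker error (mm)") +
    ggplot2::theme_minimal()
}

#' @describeIn static_optimization Activation time-series plot, one
#'   line per muscle, highlighting the most active muscles.
#' @param n_label Number of top muscles to color individually.
#' @method autoplot activation_solution
#' @export
autoplot.activation_solution <- function(object, n_label = 6, ...) {
  states <- object$states
  top <- states %>%
    group_by(.data$muscle) %>%
    summarise(peak = max(.data$activation), .groups = "drop") %>%
    arrange(dplyr::desc(.data$peak)) %>%
    head(n_label) %>%
    pull(.data$muscle)
  states$highlight <- ifelse(states$muscle %in% top, states$muscle, "other")
  ggplot2::ggplot(states,
                  ggplot2::aes(x = .data$time, y = .data$activation,
                               group = .data$muscle,
                               color = .data$highlight)) +
    ggplot2::geom_line() +
    ggplot2::scale_color_brewer(palette = "Dark2", name = NULL) +
    ggplot2::labs(x = "Time (s)", y = "Activation") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
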