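#' Plot a fraction-responding curve
#'
#' Fraction of cells with `R_2 > 0.5 * R_1` against the inter-pulse interval,
#' one curve per cell-specific noise level.
#'
#' @param df A [run_fraction_responding()] (or
#'   [fraction_responding_surrogate()]) result.
#' @param tau Optional relaxation time to mark, minutes.
#' @return A ggplot object.
#' @export
plot_fraction_responding <- function(df, tau = NULL) {
  has_sigma <- "sigma" %in% names(df)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$T_min, y = .data$fraction,
    colour = if (has_sigma) factor(.data$sigma) else NULL,
    group = if (has_sigma) factor(.data$sigma) else 1
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "inter-pulse interval T (min)",
      y = expression("fraction of cells with " * R[2] > 0.5 * R[1]),
      colour = expression(sigma)
    ) +
    ggplot2::ylim(0, 1)
  if (!is.null(tau)) {
    p <- p + ggplot2::geom_vline(xintercept = tau, linetype = "dashed")
  }
  p
}

#' Scatter plot of two-pulse responses
#'
#' `R_1` versus `R_2` coloured by input sequence, the picture behind the
#' joint two-dimensional MI of the two-pulse experiment.
#'
#' @param data A channel dataset with columns `R_1`, `R_2`.
#' @return A ggplot object.
#' @export
plot_two_pulse_scatter <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(
    x = .data$R_1, y = .data$R_2, colour = .data$sequence
  )) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(
      x = expression(R[1] ~ "(molecule" %.% "s)"),
      y = expression(R[2] ~ "(molecule" %.% "s)"),
      colour = "sequence"
    )
}

#' Plot bitrate against pulse frequency
#'
#' @param df A [run_bitrate_scan()] result.
#' @return A ggplot object.
#' @export
plot_bitrate_scan <- function(df) {
  df$noise <- sprintf("sigma==%g~mu[0]==%g", df$sigma, df$mu0)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$phi_per_h, y = .data$bitrate_bit_per_h,
    colour = .data$scheme, shape = .data$scheme
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~noise, labeller = ggplot2::label_parsed) +
    ggplot2::labs(
      x = expression(Phi == 1 / T ~ (h^-1)),
      y = expression("bitrate (bit" ~ h^-1 * ")"),
      colour = "input scheme", shape = "input scheme"
    )
}

#' Plot an ERK trajectory
#'
#' @param traj A [simulate_mapk()] trajectory.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(traj) {
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$time_s / 60, y = .data$ERKpp)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = expression(ERK[pp] ~ "(molecules/cell)"))
}

#' @describeIn maximize_mi MI trace of the optimizer, one line per restart.
#' @param object A `capacity_estimate`.
#' @export
autoplot.capacity_estimate <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(
    x = .data$iter, y = .data$mi, colour = factor(.data$restart)
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "MI (bits)", colour = "restart")
}
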