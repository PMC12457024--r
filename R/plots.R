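# ggplot2 views of a coupled solve.

#' Plot pressure, velocity and concentration profiles of a coupled solve
#'
#' Four panels across the choroid (shaded choriocapillaris) and sclera:
#' pressure (mmHg), superficial fluid velocity, SA concentration (mM) and
#' atRA:SA concentration (nM). Positive velocities point outward, from the
#' RPE towards the orbit.
#'
#' @param object an `atra_model` from [solve_steady_state()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.atra_model <- function(object, ...) {
  prof <- tidy(object)
  p <- object$params
  long <- tidyr::pivot_longer(
    dplyr::transmute(prof,
      x_um = .data$x * 1e6, layer = .data$layer,
      `pressure (mmHg)` = .data$p_mmHg,
      `fluid velocity (m/s)` = .data$u,
      `SA (mM)` = .data$c2_mM,
      `atRA:SA (nM)` = .data$c3_nM
    ),
    cols = -c("x_um", "layer"), names_to = "panel", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x_um, y = .data$value)) +
    ggplot2::annotate("rect",
      xmin = 0, xmax = p$alpha * p$L_C * 1e6,
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "red"
    ) +
    ggplot2::geom_vline(xintercept = p$L_C * 1e6, linetype = 2) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(
      x = "distance from RPE (µm)", y = NULL,
      title = sprintf("%s / %s steady state", p$species, p$condition)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.atra_model
#' @param model an `atra_model`.
#' @export
plot_profiles <- function(model, ...) autoplot.atra_model(model, ...)
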