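# ggplot2 views of simulations and fits.

#' Plot a perfusion trace or simulation
#'
#' @param trace A trace/simulation tibble (`time_s`, `perfusion`, `phase`).
#' @return A ggplot object.
#' @export
plot_rh_trace <- function(trace) {
  ggplot2::ggplot(trace,
                  ggplot2::aes(x = .data$time_s, y = .data$perfusion,
                               colour = .data$phase)) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "time since cuff inflation (s)",
                  y = "perfusion (mL/100mL/min)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the ischemic state trajectories of a simulation
#'
#' Oxygen tensions, metabolite concentrations, regulatory influences and
#' muscle activation as functions of time.
#'
#' @param sim An [rh_simulate()] result containing state columns.
#' @return A ggplot object (faceted).
#' @export
plot_rh_states <- function(sim) {
  long <- tidyr::pivot_longer(
    sim[, c("time_s", "PO2c", "PO2t", "C_atp", "C_ado", "A", "z")],
    cols = -"time_s", names_to = "state", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~state, scales = "free_y") +
    ggplot2::labs(x = "time since cuff inflation (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_rh_fit
#' @export
autoplot.rh_fit <- function(object, ...) plot_rh_fit(object, ...)

#' Plot a fit against its data
#'
#' Measured samples and the fitted model curve, one panel per cuff duration.
#'
#' @param object An `rh_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_rh_fit <- function(object, ...) {
  res <- object$residuals
  res$duration <- factor(paste0(res$t_cuff / 60, "-min cuff"))
  ggplot2::ggplot(res, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$data), size = 0.8,
                        alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$model), colour = "#d1495b") +
    ggplot2::facet_wrap(~duration) +
    ggplot2::labs(x = "time since cuff inflation (s)",
                  y = "perfusion (mL/100mL/min)",
                  subtitle = sprintf("reduced chi-square %.2f",
                                     object$chi2_red)) +
    ggplot2::theme_minimal()
}
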