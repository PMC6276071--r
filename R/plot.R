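#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line labs
#'   scale_x_log10 geom_hline theme_minimal
#' @export
ggplot2::autoplot

#' Plot a flux saturation curve
#'
#' Points on a log concentration axis, optionally overlaid with a fitted
#' Michaelis-Menten hyperbola.
#'
#' @param object A `flux_curve`.
#' @param fit Optional [saturation_fit][fit_michaelis_menten()] to overlay.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.flux_curve <- function(object, fit = NULL, ...) {
  p <- ggplot(as_tibble(object), aes(x = .data$concentration, y = .data$flux)) +
    geom_point() +
    scale_x_log10() +
    labs(x = "cis/ambient concentration (mmol/L)",
         y = expression(flux ~ (C[T] ~ s^{-1})),
         title = attr(object, "protocol")) +
    theme_minimal()
  if (!is.null(fit) && isTRUE(fit$converged)) {
    g <- exp(seq(log(min(object$concentration)), log(max(object$concentration)),
                 length.out = 200))
    p <- p + geom_line(data = tibble(concentration = g,
                                     flux = fit$Vmax * g / (fit$Km + g)))
  }
  p
}

#' Plot a counterflow time course
#'
#' The inside/outside labelled-concentration ratio over time; excursions
#' above the dashed unity line are the countercurrent overshoot.
#'
#' @param object A `counterflow_course` from [run_counterflow()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.counterflow_course <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$time, y = .data$ratio)) +
    geom_line() +
    geom_hline(yintercept = 1, linetype = "dashed") +
    labs(x = "time (s)", y = "labelled concentration ratio (in/out)",
         title = "counterflow") +
    theme_minimal()
}

#' Plot a mass-action time course
#'
#' @param object A `time_course` from [integrate_time_course()].
#' @param variable `"occupancy"`, `"concentration"`, or both.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.time_course <- function(object, variable = c("occupancy", "concentration"),
                                 ...) {
  df <- as_tibble(object)
  df <- df[df$variable %in% variable, ]
  df$series <- ifelse(is.na(df$species) | df$variable == "occupancy",
                      df$id, paste0(df$id, ":", df$species))
  ggplot(df, aes(x = .data$time, y = .data$value, colour = .data$series)) +
    geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    labs(x = "time (s)", y = NULL, colour = NULL) +
    theme_minimal()
}
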