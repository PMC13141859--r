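#' @importFrom ggplot2 ggplot aes autoplot
NULL

#' Plot stacked sensorgrams
#'
#' Response versus time, one curve per cycle, coloured by analyte
#' concentration.
#'
#' @param data stacked sensorgram tibble (`time`, `response`,
#'   `concentration`, optionally `cycle`).
#' @return a ggplot.
#' @export
plot_sensorgrams <- function(data) {
  data <- as_tibble(data)
  if (is.null(data[["cycle"]])) {
    data$cycle <- match(data$concentration, unique(data$concentration))
  }
  ggplot(data, aes(x = .data$time, y = .data$response,
                   group = .data$cycle,
                   colour = factor(signif(.data$concentration * 1e9, 3)))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "response (RU)",
                  colour = "concentration (nM)") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_sensorgrams autoplot method for a single simulated
#'   sensorgram.
#' @param object a `sensorgram`.
#' @param ... unused.
#' @export
#' @method autoplot sensorgram
autoplot.sensorgram <- function(object, ...) plot_sensorgrams(object)

#' Plot a global kinetic fit
#'
#' Observed points overlaid with the fitted 1:1 model curves.
#'
#' @param object a `kinetic_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
#' @method autoplot kinetic_fit
autoplot.kinetic_fit <- function(object, ...) {
  d <- object$data
  d <- d[order(d$cycle, d$time), ]
  d$fitted <- object$fitted
  ggplot(d, aes(x = .data$time, group = .data$cycle,
                colour = factor(signif(.data$concentration * 1e9, 3)))) +
    ggplot2::geom_point(aes(y = .data$response), size = 0.3, alpha = 0.4) +
    ggplot2::geom_line(aes(y = .data$fitted)) +
    ggplot2::labs(x = "time (s)", y = "response (RU)",
                  colour = "concentration (nM)") +
    ggplot2::theme_minimal()
}

#' Plot a viability screen
#'
#' Heavy-atom clash count per grid angle; viable angles highlighted,
#' with the heavy-clash tolerance drawn as a reference line.
#'
#' @param object a `ternary_screen`.
#' @param ... unused.
#' @return a ggplot.
#' @export
#' @method autoplot ternary_screen
autoplot.ternary_screen <- function(object, ...) {
  params <- attr(object, "params")
  ggplot(as_tibble(object),
         aes(x = .data$angle, y = .data$heavy_pairs,
             fill = .data$viable)) +
    ggplot2::geom_col(width = 0.8 * (params$step_deg %||% 10)) +
    ggplot2::geom_hline(yintercept = params$max_heavy %||% 20,
                        linetype = "dashed") +
    ggplot2::labs(x = "linker dihedral (deg)",
                  y = "heavy-atom clash pairs", fill = "viable") +
    ggplot2::theme_minimal()
}

#' Plot per-frame median RMSD of a representative-frame selection
#'
#' @param object a `representative_frame`.
#' @param ... unused.
#' @return a ggplot.
#' @export
#' @method autoplot representative_frame
autoplot.representative_frame <- function(object, ...) {
  ggplot(object$summary, aes(x = .data$time_ns, y = .data$median_rmsd)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = object$summary[object$index, ],
                        colour = "red", size = 2) +
    ggplot2::labs(x = "time (ns)", y = "median RMSD to other frames (A)") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
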