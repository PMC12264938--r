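#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a free-energy estimate
#'
#' @param x A [free_energy_estimate()].
#' @param ... Unused.
#' @return One-row tibble with `estimate`, `std.error`, `method`,
#'   `n.samples`, `flag`.
#' @export
tidy.free_energy_estimate <- function(x, ...) {
  tibble::tibble(estimate = x$value, std.error = x$uncertainty,
                 method = x$method, n.samples = x$n_samples,
                 flag = x$flag %||% NA_character_)
}

#' @rdname tidy.free_energy_estimate
#' @export
glance.free_energy_estimate <- function(x, ...) tidy(x, ...)

#' Tidy a cycle result
#'
#' @param x A `cycle_result` from [combine_cycle()].
#' @param ... Unused.
#' @return Four-row tibble (three legs plus the combined value) with
#'   `term`, `estimate`, `std.error`, `method`.
#' @export
tidy.cycle_result <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$osp_add_xray), term = "osp_add_xray"),
    dplyr::mutate(tidy(x$msld_core), term = "msld_core"),
    dplyr::mutate(tidy(x$osp_remove_flip), term = "osp_remove_flip"),
    dplyr::mutate(tidy(x$combined), term = "combined")
  ) |>
    dplyr::select("term", "estimate", "std.error", "method", "n.samples")
}

#' @rdname tidy.cycle_result
#' @return `glance()`: one-row tibble with the combined value and its
#'   uncertainty.
#' @export
glance.cycle_result <- function(x, ...) {
  tibble::tibble(ddG = x$combined$value,
                 std.error = x$combined$uncertainty,
                 method = x$combined$method)
}

#' Plot a lambda trace
#'
#' Time series of both pose couplings; endpoint-dominance thresholds are
#' drawn as dashed lines.
#'
#' @param object A `lambda_trace` tibble.
#' @param threshold Dominance threshold drawn on the plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lambda_trace <- function(object, threshold = 0.99, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            cols = c("lambda_xray", "lambda_flip"),
                            names_to = "pose", values_to = "lambda")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ps, y = .data$lambda,
                                   colour = .data$pose)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = c(threshold, 1 - threshold),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "time (ps)", y = expression(lambda), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a cycle result
#'
#' Bar chart of the three cycle legs and the combined relative pose free
#' energy, with one-sigma error bars.
#'
#' @param object A `cycle_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cycle_result <- function(object, ...) {
  df <- tidy(object)
  df$term <- factor(df$term, levels = c("osp_add_xray", "msld_core",
                                        "osp_remove_flip", "combined"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$estimate - .data$std.error,
                                        ymax = .data$estimate + .data$std.error),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "free energy (kcal/mol)") +
    ggplot2::theme_minimal()
}

#' Plot a bias profile
#'
#' The stored free-energy-landscape estimate of a tabulated bias model as a
#' function of the xray-pose coupling.
#'
#' @param object A [bias_model()] with a tabulated profile.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bias_model <- function(object, ...) {
  if (is.null(object$table)) stop("only tabulated bias models can be plotted")
  df <- tibble::tibble(lambda = object$table$mid, b = object$table$value)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lambda, y = .data$b)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(lambda["xray"]),
                  y = "landscape estimate b (kcal/mol)") +
    ggplot2::theme_minimal()
}
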