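#' Plot a PDE solution
#'
#' Tip and stalk density profiles over space, coloured by output time.
#'
#' @param object A `pde_solution` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pde_solution <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("N", "E"), names_to = "field",
                              values_to = "density")
  long$field <- factor(long$field, c("N", "E"),
                       c("tip density N", "stalk density E"))
  ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$density,
                                     colour = .data$t, group = .data$t)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~field, scales = "free_y") +
    ggplot2::labs(x = "x", y = "density", colour = "t") +
    ggplot2::theme_minimal()
}

#' Plot a leading-order solution in the laboratory frame
#'
#' @param object A `leading_order_solution` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.leading_order_solution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$X, .data$u0,
                                       colour = .data$tau, group = .data$tau)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "X", y = expression(u[0]), colour = expression(tau)) +
    ggplot2::theme_minimal()
}

#' Plot a self-similar profile
#'
#' @param object A `similarity_profile` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.similarity_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$z, .data$U)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z", y = expression(tilde(U)[0])) +
    ggplot2::theme_minimal()
}

#' Plot normalized difference curves from a comparison report
#'
#' @param comparison A tibble from [compare_solutions()].
#' @return A ggplot object.
#' @export
plot_comparison <- function(comparison) {
  ggplot2::ggplot(comparison, ggplot2::aes(.data$t, .data$max_rel_diff,
                                           colour = .data$field)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "t", y = "max relative difference", colour = "field") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
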