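#' Plot methods
#'
#' `autoplot()` methods give quick-look ggplot2 figures for the package's
#' result types: slab density profiles, binodal fits with their critical
#' point, genetic-algorithm progressions and pair correlation functions.
#'
#' @param object Result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name idpevolve-autoplot
NULL

#' @rdname idpevolve-autoplot
#' @export
autoplot.density_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$density)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$density - .data$se,
                                          ymax = .data$density + .data$se),
                             size = 0.3) +
    ggplot2::labs(x = "z (Å)", y = expression(rho ~ (g ~ cm^-3))) +
    ggplot2::theme_minimal()
}

#' @rdname idpevolve-autoplot
#' @export
autoplot.binodal_fit <- function(object, ...) {
  pred <- predict(object)
  pts <- tidyr::pivot_longer(object$points, c("rho_v", "rho_l"),
                             names_to = "branch", values_to = "rho")
  curve <- tidyr::pivot_longer(pred, c("rho_v", "rho_l"),
                               names_to = "branch", values_to = "rho")
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$rho, y = .data$temperature)) +
    ggplot2::geom_point(ggplot2::aes(alpha = .data$included)) +
    ggplot2::geom_path(data = curve, ggplot2::aes(group = .data$branch),
                       linetype = "dotted") +
    ggplot2::annotate("point", x = object$rho_c, y = object$tc, shape = 4,
                      size = 3) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.3),
                                guide = "none") +
    ggplot2::labs(x = expression(rho ~ (g ~ cm^-3)), y = "T (K)") +
    ggplot2::theme_minimal()
}

#' @rdname idpevolve-autoplot
#' @export
autoplot.ga_history <- function(object, ...) {
  s <- tidyr::pivot_longer(object$summary,
                           c("mean_fitness", "max_fitness", "diversity"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(s, ggplot2::aes(x = .data$round, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "round", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname idpevolve-autoplot
#' @export
autoplot.rdf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$g)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (Å)", y = "g(r)") +
    ggplot2::theme_minimal()
}
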