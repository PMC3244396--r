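# broom-style tidiers and ggplot2 autoplot methods for fitted objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a latent class fit
#'
#' One row per class x item with the endorsement probability, its
#' approximate standard error on the logit scale, and the class mixing
#' proportion.
#'
#' @param x An `lca_fit`.
#' @param ... Unused.
#' @return Tibble: `class`, `item`, `estimate`, `se_logit`, `pi`.
#' @export
tidy.lca_fit <- function(x, ...) {
  J <- length(x$item_names)
  tibble::tibble(class = rep(seq_len(x$K), each = J),
                 item = rep(x$item_names, x$K),
                 estimate = as.vector(t(x$model$rho)),
                 se_logit = as.vector(t(x$se_logit_rho)),
                 pi = rep(x$model$pi, each = J))
}

#' One-row summary of a latent class fit
#'
#' @param x An `lca_fit`.
#' @param ... Unused.
#' @return Tibble: `K`, `n`, `loglik`, `n_params`, `bic`, `entropy`,
#'   `converged`, `n_starts_used`.
#' @export
glance.lca_fit <- function(x, ...) {
  tibble::tibble(K = x$K, n = x$n, loglik = x$loglik, n_params = x$n_params,
                 bic = x$bic, entropy = x$entropy, converged = x$converged,
                 n_starts_used = x$n_starts_used)
}

#' Tidy a model-selection table
#'
#' @param x An `lca_selection`.
#' @param ... Unused.
#' @return The per-K tibble with a `chosen` flag.
#' @export
tidy.lca_selection <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x), chosen = .data$K == attr(x, "chosen_K"))
}

#' Tidy a pseudo-class Wald test
#'
#' @param x A `wald_result`.
#' @param ... Unused.
#' @return One-row tibble with statistic, df and p-value.
#' @export
tidy.wald_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 n_draws = x$n_draws)
}

#' Class-profile plot for a latent class fit
#'
#' Endorsement probability of each indicator by latent class — the
#' standard profile view of a latent class solution.
#'
#' @param object An `lca_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lca_fit <- function(object, ...) {
  td <- tidy(object)
  td$item <- factor(td$item, levels = object$item_names)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$item, y = .data$estimate,
                                   colour = factor(.data$class),
                                   group = factor(.data$class))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "endorsement probability",
                  colour = "latent class") +
    ggplot2::theme_minimal()
}

#' BIC-by-K plot for a model-selection table
#'
#' @param object An `lca_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lca_selection <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$K, y = .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chosen), size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red"), guide = "none") +
    ggplot2::labs(y = "BIC") +
    ggplot2::theme_minimal()
}

#' Manhattan plot of association results
#'
#' @param object An `assoc_result` from [run_association()].
#' @param model Which genetic model to show (default: all, faceted).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.assoc_result <- function(object, model = NULL, ...) {
  d <- tibble::as_tibble(object)
  d <- d[d$testable, ]
  if (!is.null(model)) d <- d[d$model %in% model, ]
  d$chromosome <- factor(d$chromosome, levels = as.character(1:22))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$position,
                                       y = -log10(.data$p),
                                       colour = .data$chromosome)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(model ~ chromosome, scales = "free_x",
                        space = "free_x", switch = "x") +
    ggplot2::labs(x = "chromosome", y = expression(-log[10](p))) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing.x = ggplot2::unit(0.1, "lines"))
  p
}

#' Q-Q plot of association p-values
#'
#' @param result An `assoc_result`.
#' @param model Genetic model to plot (default: first tested model).
#' @return A ggplot object, annotated with the genomic inflation factor.
#' @export
plot_qq <- function(result, model = NULL) {
  stopifnot(inherits(result, "assoc_result"))
  qq <- attr(result, "qq")
  lam <- attr(result, "lambda")
  model <- model %||% names(qq)[1]
  d <- qq[[model]]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(expected ~ -log[10](p)),
                  y = expression(observed ~ -log[10](p)),
                  subtitle = sprintf("%s model, lambda = %.3f",
                                     model, lam[[model]])) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
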