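#' Plot the mixture-prior posterior of the causal effect
#'
#' Density of the causal-effect draws after importance resampling, with the
#' ROPE shaded; the proportion of mass inside the shaded band is what the
#' ternary decision rule acts on.
#'
#' @param object An `mr_weighted_draws` from [mixture_resample()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mr_weighted_draws
#' @export
autoplot.mr_weighted_draws <- function(object, ...) {
  T <- object$prior$rope_T
  df <- tibble::tibble(beta = object$resampled_beta)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta)) +
    ggplot2::annotate("rect", xmin = -T, xmax = T, ymin = -Inf, ymax = Inf,
                      alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_density() +
    ggplot2::geom_vline(xintercept = c(-T, T), linetype = 2) +
    ggplot2::labs(x = expression(beta),
                  y = "posterior density (mixture prior)",
                  title = "Causal-effect posterior with ROPE") +
    ggplot2::theme_minimal()
}

#' Trace plot of causal-effect draws
#'
#' @param object An `mr_fit`.
#' @param parameter Parameter to trace (default `"beta"`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mr_fit
#' @export
autoplot.mr_fit <- function(object, parameter = "beta", ...) {
  df <- object$draws[c(".chain", ".iteration", parameter)]
  names(df)[3L] <- "value"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$.iteration, y = .data$value,
                                   colour = factor(.data$.chain))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "iteration (post warmup)", y = parameter,
                  colour = "chain") +
    ggplot2::theme_minimal()
}

#' Expected-loss surface plot
#'
#' Displays the per-scenario expected loss of each method over the (T, a)
#' values drawn during the experiment: the frequentist surface is flat in
#' (T, a) by construction, the Bayesian one varies with the ROPE half-width
#' and the uncertain-outcome cost.
#'
#' @param object An `mr_experiment` from [run_experiment()].
#' @param bins Bins per axis for the (T, a) surface.
#' @param ... Unused.
#' @return A ggplot (faceted by scenario factors).
#' @method autoplot mr_experiment
#' @export
autoplot.mr_experiment <- function(object, bins = 4, ...) {
  surf <- loss_surface(object, bins = bins)
  ggplot2::ggplot(surf, ggplot2::aes(x = .data$T_mid, y = .data$a_mid,
                                     fill = .data$expected_loss)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$missing_rate, .data$beta_true),
      cols = ggplot2::vars(.data$alpha_strength, .data$method),
      labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(name = "expected loss") +
    ggplot2::labs(x = "ROPE half-width T", y = "uncertain cost a") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
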