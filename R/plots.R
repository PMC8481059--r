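# autoplot() methods: diagnostic displays for fits, GOF reports and
# bootstrap replicate clouds.

#' Diagnostic plots
#'
#' `autoplot()` methods for the package's result objects:
#'
#' * `ss_fit` — empirical CDFs of both samples overlaid with the fitted
#'   EIW CDFs at the estimated parameters;
#' * `eiw_gof` — P-P plot of the fitted probabilities against the plotting
#'   positions i/(n+1), with the identity line;
#' * `ss_boot` — histogram of the bootstrap replicates of R with the point
#'   estimate and the interval endpoints at the requested level.
#'
#' @param object A fitted object.
#' @param level For `ss_boot`: which confidence level's endpoints to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-eiwss
NULL

#' @rdname autoplot-eiwss
#' @param data For `ss_fit`: the data the model was fitted to (the fit
#'   object does not retain it).
#' @export
autoplot.ss_fit <- function(object, data, ...) {
  v <- ss_vectors(data)
  series <- dplyr::bind_rows(
    dplyr::mutate(eiw_cdf_series(v$x, object$theta1, object$beta), role = "strength"),
    dplyr::mutate(eiw_cdf_series(v$y, object$theta2, object$beta), role = "stress")
  )
  ggplot2::ggplot(series, ggplot2::aes(.data$x, .data$value)) +
    ggplot2::geom_step(
      data = ~ dplyr::filter(.x, .data$curve == "empirical"), colour = "grey40"
    ) +
    ggplot2::geom_line(
      data = ~ dplyr::filter(.x, .data$curve == "fitted"), colour = "firebrick"
    ) +
    ggplot2::facet_wrap(~role, scales = "free_x") +
    ggplot2::labs(
      x = "Observed value", y = "CDF",
      title = sprintf("Fitted EIW CDFs (%s), R = %.4f",
                      toupper(object$method), object$r_hat)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-eiwss
#' @export
autoplot.eiw_gof <- function(object, ...) {
  ggplot2::ggplot(object$pp_points, ggplot2::aes(.data$empirical, .data$fitted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Empirical probability i/(n+1)", y = "Fitted EIW probability",
      title = sprintf("P-P plot, D = %.4f (p = %.3f)", object$statistic, object$p.value)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-eiwss
#' @export
autoplot.ss_boot <- function(object, level = 0.95, ...) {
  iv <- dplyr::filter(object$intervals, abs(.data$level - !!level) < 1e-9)
  df <- tibble::tibble(r = object$replicates)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$r)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$r_hat, colour = "black", linewidth = 0.8) +
    ggplot2::labs(
      x = "Bootstrap replicate of R", y = "Count",
      title = sprintf("Parametric bootstrap (%s), B = %d", toupper(object$method), object$B),
      subtitle = sprintf("Point estimate R = %.4f; %d%% interval endpoints dashed",
                         object$r_hat, round(100 * level))
    ) +
    ggplot2::theme_minimal()
  if (nrow(iv) > 0) {
    p <- p + ggplot2::geom_vline(
      xintercept = c(iv$lower, iv$upper), linetype = 2,
      colour = rep(c("steelblue", "firebrick")[seq_len(nrow(iv))], 2)
    )
  }
  p
}
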