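# Goodness of fit: one-sample Kolmogorov-Smirnov statistic against a fitted
# EIW law, plus the data series behind CDF-overlay and P-P displays.

#' Kolmogorov-Smirnov test of an EIW fit
#'
#' Computes the one-sample KS statistic
#' \eqn{D = \max_i \max(i/n - F(x_{(i)}),\; F(x_{(i)}) - (i-1)/n)}
#' of a sample against EIW(`theta`, `beta`).  No correction is applied for
#' parameters estimated from the same sample.  The default p-value rule
#' (`"auto"`) is the usual one: the exact finite-n distribution when
#' n < 100 and the sample has no ties, otherwise the asymptotic Kolmogorov
#' distribution evaluated at \eqn{\sqrt{n} D}; either method can also be
#' forced.
#'
#' @param x Positive sample.
#' @param theta,beta Parameters of the fitted law (typically from
#'   [fit_eiw()]).
#' @param p_method `"auto"` (default), `"asymptotic"` or `"exact"`.
#' @return An object of class `eiw_gof` with elements `statistic`,
#'   `p.value`, `n`, `theta`, `beta` and the [pp_series()] tibble
#'   `pp_points`.  Supports [tidy()], [glance()] and [ggplot2::autoplot()].
#' @examples
#' x <- dplyr::filter(eiw_dataset("jute"), role == "strength")$value
#' f <- fit_eiw(x)
#' eiw_ks_test(x, f$theta, f$beta)
#' @export
eiw_ks_test <- function(x, theta, beta,
                        p_method = c("auto", "asymptotic", "exact")) {
  p_method <- match.arg(p_method)
  check_positive_sample(x, "x")
  s <- sort(x)
  n <- length(s)
  FF <- peiw(s, theta, beta)
  D <- max(pmax(seq_len(n) / n - FF, FF - (seq_len(n) - 1) / n))
  if (p_method == "auto") {
    p_method <- if (n < 100 && !anyDuplicated(s)) "exact" else "asymptotic"
  }
  p <- switch(
    p_method,
    asymptotic = kolmogorov_sf(sqrt(n) * D),
    exact = suppressWarnings(
      stats::ks.test(s, function(q) peiw(q, theta, beta), exact = TRUE)$p.value
    )
  )
  structure(
    list(
      statistic = D, p.value = min(max(p, 0), 1), n = n,
      theta = theta, beta = beta, p_method = p_method,
      pp_points = pp_series(x, theta, beta)
    ),
    class = "eiw_gof"
  )
}

# survival function of the Kolmogorov distribution,
# Q(t) = 2 * sum_{j>=1} (-1)^{j-1} exp(-2 j^2 t^2)
kolmogorov_sf <- function(t) {
  if (t < 1e-8) return(1)
  j <- 1:100
  min(1, max(0, 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * t^2))))
}

#' Probability-probability series for an EIW fit
#'
#' Pairs the plotting positions i/(n+1) with the fitted CDF at the order
#' statistics — the coordinates of a P-P plot.
#'
#' @inheritParams eiw_ks_test
#' @return A tibble with columns `empirical` (i/(n+1)) and `fitted`
#'   (F at the i-th order statistic, nondecreasing).
#' @export
pp_series <- function(x, theta, beta) {
  check_positive_sample(x, "x")
  s <- sort(x)
  n <- length(s)
  tibble::tibble(
    empirical = seq_len(n) / (n + 1),
    fitted = peiw(s, theta, beta)
  )
}

#' Empirical and fitted CDF series for overlay displays
#'
#' Returns the empirical CDF step coordinates of the sample together with
#' the fitted EIW CDF evaluated on a regular grid spanning the data range —
#' the series behind a fitted-vs-empirical CDF overlay.
#'
#' @inheritParams eiw_ks_test
#' @param grid_n Number of grid points for the fitted curve.
#' @return A tibble with columns `x`, `value` and `curve`
#'   (`"empirical"` or `"fitted"`).
#' @export
eiw_cdf_series <- function(x, theta, beta, grid_n = 200) {
  check_positive_sample(x, "x")
  s <- sort(x)
  grid <- seq(min(s) * 0.9, max(s) * 1.1, length.out = grid_n)
  dplyr::bind_rows(
    tibble::tibble(x = s, value = seq_along(s) / length(s), curve = "empirical"),
    tibble::tibble(x = grid, value = peiw(grid, theta, beta), curve = "fitted")
  )
}

#' @export
print.eiw_gof <- function(x, ...) {
  cat(sprintf(
    "One-sample KS test against EIW(theta = %.4f, beta = %.4f)\n",
    x$theta, x$beta
  ))
  cat(sprintf("D = %.4f, p-value = %.4f (%s), n = %d\n",
              x$statistic, x$p.value, x$p_method, x$n))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.eiw_gof <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p.value, n = x$n,
                 theta = x$theta, beta = x$beta)
}

#' @rdname tidiers
#' @export
glance.eiw_gof <- function(x, ...) tidy(x)
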