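# Parametric bootstrap intervals for R.  Replicate samples are drawn from
# the fitted EIW laws (never resampled from the data), refit with the same
# estimator, and the replicate R values are summarised by percentile
# (Boot-P) or bias-corrected percentile (Boot-BCP) intervals.

# rank rule: order statistic at ceiling(B * p), clamped into [1, B]; the
# tiny slack keeps exact multiples (e.g. B * 0.05 for B = 20) from being
# pushed up a rank by floating-point noise
boot_rank <- function(B, p) min(max(ceiling(B * p - 1e-9), 1L), B)

#' Percentile bootstrap interval
#'
#' Endpoints are the replicate order statistics at ranks
#' `ceiling(B * gamma/2)` and `ceiling(B * (1 - gamma/2))`.
#'
#' @param replicates Numeric vector of bootstrap estimates.
#' @param level Confidence level `1 - gamma`, e.g. 0.95.
#' @param rule `"rank"` (order-statistic rule, default) or `"interpolate"`
#'   (type-7 interpolating quantile), the latter kept for sensitivity checks.
#' @return Named vector `c(lower, upper)`.
#' @export
boot_p_interval <- function(replicates, level = 0.95,
                            rule = c("rank", "interpolate")) {
  rule <- match.arg(rule)
  stopifnot(length(replicates) > 0, level > 0, level < 1)
  gamma <- 1 - level
  s <- sort(replicates)
  B <- length(s)
  if (rule == "rank") {
    c(lower = s[boot_rank(B, gamma / 2)], upper = s[boot_rank(B, 1 - gamma / 2)])
  } else {
    q <- stats::quantile(s, c(gamma / 2, 1 - gamma / 2), names = FALSE)
    c(lower = q[1], upper = q[2])
  }
}

#' Bias-corrected percentile bootstrap interval
#'
#' Shifts the percentile ranks by the bias-correction constant
#' \eqn{z_0 = \Phi^{-1}(\hat p)}, where \eqn{\hat p} is the fraction of
#' replicates below the original-data estimate (ties counted with weight
#' 1/2, and the fraction clamped to `[1/(2B), 1 - 1/(2B)]` so `z0` stays
#' finite when all replicates fall on one side).  Endpoints are the
#' replicate order statistics at ranks `ceiling(B * delta)` with
#' \eqn{\delta_1 = \Phi(2 z_0 + z_{\gamma/2})},
#' \eqn{\delta_2 = \Phi(2 z_0 + z_{1-\gamma/2})}.  With `z0 = 0` the
#' interval coincides with [boot_p_interval()].
#'
#' @inheritParams boot_p_interval
#' @param r_hat Original-data point estimate.
#' @return Named vector `c(lower, upper, z0)`.
#' @export
boot_bcp_interval <- function(replicates, r_hat, level = 0.95,
                              rule = c("rank", "interpolate")) {
  rule <- match.arg(rule)
  stopifnot(length(replicates) > 0, level > 0, level < 1)
  gamma <- 1 - level
  s <- sort(replicates)
  B <- length(s)
  prop <- (sum(s < r_hat) + 0.5 * sum(s == r_hat)) / B
  prop <- min(max(prop, 1 / (2 * B)), 1 - 1 / (2 * B))
  z0 <- stats::qnorm(prop)
  d1 <- stats::pnorm(2 * z0 + stats::qnorm(gamma / 2))
  d2 <- stats::pnorm(2 * z0 + stats::qnorm(1 - gamma / 2))
  if (rule == "rank") {
    c(lower = s[boot_rank(B, d1)], upper = s[boot_rank(B, d2)], z0 = z0)
  } else {
    q <- stats::quantile(s, c(d1, d2), names = FALSE)
    c(lower = q[1], upper = q[2], z0 = z0)
  }
}

#' Parametric bootstrap replicates of the reliability estimate
#'
#' Fits the chosen estimator to `data`, then repeatedly draws size-n and
#' size-k samples from the fitted EIW(theta1, beta) and EIW(theta2, beta)
#' laws, refits with the same method, and records the replicate reliability
#' estimates.  A replicate whose refit fails is redrawn (at most 10 times)
#' so the returned vector always holds `B` values.
#'
#' @inheritParams fit_ss
#' @param B Number of bootstrap replicates (at least 50).
#' @param seed Integer master seed; per-replicate sub-seeds are derived from
#'   it by a counter scheme so runs are reproducible.
#' @param restarts Restarts per refit (passed to [fit_ss()]; the default is
#'   lower than for a one-off fit since refits start from their own MLE).
#' @return Numeric vector of `B` replicate estimates, with attributes
#'   `r_hat` (original estimate) and `n_redrawn`.
#' @export
bootstrap_replicates <- function(data, method = "mle", B = 1000, seed = 1,
                                 restarts = 1) {
  stopifnot(B >= 50)
  fit <- fit_ss(data, method, se = FALSE)
  n <- fit$n
  k <- fit$k
  reps <- numeric(B)
  redrawn <- 0L
  for (b in seq_len(B)) {
    val <- NA_real_
    for (attempt in 0:10) {
      sub <- (seed + b + attempt * (B + 11L)) %% .Machine$integer.max
      val <- tryCatch({
        d <- with_preserved_seed(sub, list(x = reiw(n, fit$theta1, fit$beta),
                                           y = reiw(k, fit$theta2, fit$beta)))
        fit_ss_xy(d$x, d$y, method, restarts = restarts, se = FALSE)$r_hat
      }, error = function(e) NA_real_)
      if (!is.na(val)) break
      redrawn <- redrawn + 1L
    }
    if (is.na(val)) {
      rlang::abort(sprintf("Bootstrap replicate %d failed after 10 redraws.", b),
                   class = "eiwss_convergence_error")
    }
    reps[b] <- val
  }
  structure(reps, r_hat = fit$r_hat, n_redrawn = redrawn)
}

#' Bootstrap confidence intervals for the stress-strength reliability
#'
#' Runs the parametric bootstrap ([bootstrap_replicates()]) and summarises
#' the replicates into percentile (`boot_p`) and bias-corrected percentile
#' (`boot_bcp`) confidence intervals at one or more levels.
#'
#' @inheritParams bootstrap_replicates
#' @param conf_levels Confidence levels, e.g. `c(0.90, 0.95, 0.99)`.
#' @param rule Quantile rule, see [boot_p_interval()].
#' @return An object of class `ss_boot`: a list with the original `fit`,
#'   `r_hat`, the sorted `replicates`, `B`, and an `intervals` tibble with
#'   columns `level`, `kind`, `lower`, `upper`, `length`, `z0`.
#'   Supports [tidy()], [glance()] and [ggplot2::autoplot()].
#' @examples
#' \donttest{
#' b <- ss_bootstrap(eiw_dataset("carbon"), "mle", B = 200, seed = 42)
#' tidy(b)
#' }
#' @export
ss_bootstrap <- function(data, method = "mle", B = 1000,
                         conf_levels = c(0.90, 0.95, 0.99), seed = 1,
                         rule = c("rank", "interpolate"), restarts = 1) {
  rule <- match.arg(rule)
  fit <- fit_ss(data, method, se = FALSE)
  reps <- bootstrap_replicates(data, method, B = B, seed = seed,
                               restarts = restarts)
  r_hat <- attr(reps, "r_hat")
  sorted <- sort(as.numeric(reps))
  intervals <- purrr::map_dfr(sort(conf_levels), function(lv) {
    bp <- boot_p_interval(sorted, lv, rule)
    bc <- boot_bcp_interval(sorted, r_hat, lv, rule)
    tibble::tibble(
      level = lv,
      kind = c("boot_p", "boot_bcp"),
      lower = c(bp[["lower"]], bc[["lower"]]),
      upper = c(bp[["upper"]], bc[["upper"]]),
      z0 = c(NA_real_, bc[["z0"]])
    )
  })
  intervals$length <- intervals$upper - intervals$lower
  structure(
    list(
      fit = fit, r_hat = r_hat, replicates = sorted, B = B,
      method = method, seed = seed, n_redrawn = attr(reps, "n_redrawn"),
      intervals = intervals
    ),
    class = "ss_boot"
  )
}

#' @export
print.ss_boot <- function(x, ...) {
  cat(sprintf(
    "Parametric bootstrap for R (%s), B = %d, R-hat = %.4f\n",
    toupper(x$method), x$B, x$r_hat
  ))
  print(as.data.frame(x$intervals), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.ss_boot <- function(x, ...) x$intervals

#' @rdname tidiers
#' @export
glance.ss_boot <- function(x, ...) {
  tibble::tibble(
    method = x$method, r_hat = x$r_hat, B = x$B,
    boot_mean = mean(x$replicates), boot_sd = stats::sd(x$replicates),
    n_redrawn = x$n_redrawn
  )
}
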