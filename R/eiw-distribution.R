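# Distribution primitives for the exponentiated inverted Weibull (EIW) law,
# F(x) = exp(-theta * x^-beta) on x > 0.  theta > 0 is the exponentiation
# ("scale-type") parameter, beta > 0 the shape.  Everything is evaluated in
# log space first so that extreme x neither underflow nor overflow.

check_eiw_params <- function(theta, beta) {
  if (!is.numeric(theta) || anyNA(theta) || any(theta <= 0)) {
    rlang::abort("`theta` must be a positive, finite numeric.")
  }
  if (!is.numeric(beta) || anyNA(beta) || any(beta <= 0)) {
    rlang::abort("`beta` must be a positive, finite numeric.")
  }
  invisible(NULL)
}

check_positive_sample <- function(x, arg = "x") {
  if (!is.numeric(x) || length(x) == 0 || anyNA(x) ||
      any(!is.finite(x)) || any(x <= 0)) {
    rlang::abort(sprintf(
      "`%s` must contain strictly positive finite values only.", arg
    ))
  }
  invisible(NULL)
}

#' The exponentiated inverted Weibull distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the exponentiated inverted Weibull (EIW) distribution with
#' exponentiation parameter `theta` and shape `beta`.  The distribution
#' function is \eqn{F(x) = \exp(-\theta x^{-\beta})} on \eqn{x > 0}; with
#' `theta = 1` it reduces to the standard inverted Weibull law, and the
#' transform \eqn{X^{-\beta}} is exponential with rate `theta`.
#'
#' The support is strictly positive: evaluating the density or distribution
#' function at non-positive `x` is an error, not 0, because the model never
#' assigns mass there and a non-positive observation always signals an input
#' problem in the intended reliability applications.
#'
#' @param x,q Vector of strictly positive quantiles.
#' @param p Vector of probabilities in (0, 1).
#' @param n Number of draws.
#' @param theta Positive exponentiation parameter \eqn{\theta}.
#' @param beta Positive shape parameter \eqn{\beta}.
#' @param log,log.p Logical; if `TRUE`, probabilities/densities are returned
#'   on the log scale.
#' @param lower.tail Logical; if `TRUE` (default) probabilities are
#'   \eqn{P(X \le x)}.
#'
#' @return `deiw` gives the density, `peiw` the distribution function,
#'   `qeiw` the quantile function and `reiw` random draws.
#'
#' @examples
#' deiw(1, theta = 1, beta = 1)        # exp(-1)
#' peiw(1, theta = 1, beta = 1)        # exp(-1)
#' qeiw(0.5, theta = 1, beta = 1)      # 1 / log(2)
#' set.seed(1)
#' reiw(5, theta = 2, beta = 1.3)
#' @name eiw
NULL

#' @rdname eiw
#' @export
deiw <- function(x, theta, beta, log = FALSE) {
  check_eiw_params(theta, beta)
  check_positive_sample(x, "x")
  logf <- log(theta) + log(beta) - (beta + 1) * log(x) - theta * x^(-beta)
  if (log) logf else exp(logf)
}

#' @rdname eiw
#' @export
peiw <- function(q, theta, beta, lower.tail = TRUE, log.p = FALSE) {
  check_eiw_params(theta, beta)
  check_positive_sample(q, "q")
  logF <- -theta * q^(-beta)
  if (lower.tail) {
    if (log.p) logF else exp(logF)
  } else {
    # upper tail via log1p for accuracy when F is close to 1
    lp <- log1p(-exp(logF))
    if (log.p) lp else exp(lp)
  }
}

#' @rdname eiw
#' @export
qeiw <- function(p, theta, beta, lower.tail = TRUE, log.p = FALSE) {
  check_eiw_params(theta, beta)
  if (log.p) p <- exp(p)
  if (!lower.tail) p <- 1 - p
  if (!is.numeric(p) || anyNA(p) || any(p <= 0) || any(p >= 1)) {
    rlang::abort("`p` must lie strictly inside (0, 1).")
  }
  # exact inverse of F(x) = exp(-theta x^-beta)
  (-log(p) / theta)^(-1 / beta)
}

#' @rdname eiw
#' @export
reiw <- function(n, theta, beta) {
  check_eiw_params(theta, beta)
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1) {
    rlang::abort("`n` must be a positive integer.")
  }
  qeiw(stats::runif(n), theta = theta, beta = beta)
}

#' Stress-strength reliability of two EIW laws with a common shape
#'
#' For independent strength \eqn{X \sim \mathrm{EIW}(\theta_1, \beta)} and
#' stress \eqn{Y \sim \mathrm{EIW}(\theta_2, \beta)} the probability that the
#' component survives is \eqn{R = P(Y < X) = \theta_1 / (\theta_1 + \theta_2)},
#' free of the shared shape \eqn{\beta}.  This is the probabilistic index
#' (two-sample AUC) of the two laws.
#'
#' @param theta1,theta2 Positive exponentiation parameters of the strength
#'   and stress distributions.
#' @return A value in (0, 1); vectorised over its arguments.
#' @examples
#' ss_reliability(3, 0.1)
#' @export
ss_reliability <- function(theta1, theta2) {
  check_eiw_params(theta1, 1)
  check_eiw_params(theta2, 1)
  theta1 / (theta1 + theta2)
}
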