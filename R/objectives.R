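# The estimation criteria.  Each method is *defined* by its objective
# function over (theta1, theta2, beta); printed gradient systems in the
# source literature for these criteria are treated as bookkeeping, not as
# definitions.  All objectives are evaluated on the sorted samples.

SS_METHODS <- c("mle", "mpse", "msade", "msalde", "lse", "wlse", "cme", "ade")

# smallest spacing admitted inside log/ratio criteria; ties or near-ties
# otherwise send log-spacings to -Inf
SPACING_FLOOR <- 1e-10
CDF_CLAMP <- 1e-12

#' Spacings of the fitted EIW distribution at the order statistics
#'
#' Increments of the fitted CDF between consecutive order statistics, with
#' the boundary conventions \eqn{F(x_{(0)}) = 0} and \eqn{F(x_{(n+1)}) = 1},
#' so the n + 1 spacings of an n-point sample always sum to one.
#'
#' @param x Positive sample (sorted internally).
#' @param theta,beta EIW parameters.
#' @return Numeric vector of length `length(x) + 1`.
#' @export
eiw_spacings <- function(x, theta, beta) {
  check_positive_sample(x, "x")
  diff(c(0, peiw(sort(x), theta, beta), 1))
}

# One-sample pieces ---------------------------------------------------------

# mean log spacing (the quantity MPS maximises), floored against ties
mean_log_spacing <- function(s, theta, beta) {
  d <- pmax(diff(c(0, exp(-theta * s^(-beta)), 1)), SPACING_FLOOR)
  mean(log(d))
}

abs_spacing_dist <- function(s, theta, beta) {
  n <- length(s)
  d <- diff(c(0, exp(-theta * s^(-beta)), 1))
  sum(abs(d - 1 / (n + 1)))
}

abs_log_spacing_dist <- function(s, theta, beta) {
  n <- length(s)
  d <- pmax(diff(c(0, exp(-theta * s^(-beta)), 1)), SPACING_FLOOR)
  sum(abs(log(d) - log(1 / (n + 1))))
}

ls_dist <- function(s, theta, beta, weights = NULL, positions) {
  FF <- exp(-theta * s^(-beta))
  if (is.null(weights)) sum((FF - positions)^2) else sum(weights * (FF - positions)^2)
}

# standard one-sample Anderson-Darling statistic at fixed parameters
ad_stat <- function(s, theta, beta) {
  n <- length(s)
  FF <- pmin(pmax(exp(-theta * s^(-beta)), CDF_CLAMP), 1 - CDF_CLAMP)
  -n - mean((2 * seq_len(n) - 1) * (log(FF) + log(1 - rev(FF))))
}

# Joint criteria ------------------------------------------------------------

#' Joint estimation objective for a stress-strength data set
#'
#' Returns the two-sample objective function a given method optimises, as a
#' closure over the (sorted) data: a function of `(theta1, theta2, beta)`
#' returning the criterion value.  Minimising this function (for every
#' method; the maximum-product-of-spacings criterion is returned negated)
#' yields the method's estimates.  Exposed mainly so the optimisation
#' surfaces can be inspected and checked independently of the optimiser.
#'
#' @param data A data frame with `value`/`role` columns (see [ss_data()]).
#' @param method One of `"mle"`, `"mpse"`, `"msade"`, `"msalde"`, `"lse"`,
#'   `"wlse"`, `"cme"`, `"ade"`.
#' @param cme_positions Plotting-position convention for the Cramér-von Mises
#'   criterion: `"standard"` pairs the i-th order statistic with
#'   (2i - 1)/(2n) (the Cramér-von Mises convention, default);
#'   `"as_printed"` uses the reversed (2(n - i) + 1)/(2n) pairing that
#'   appears in some accounts of the criterion and is kept only for
#'   sensitivity checks (it pairs the smallest observation with the largest
#'   probability and drives the fit degenerate).
#' @return A function `f(theta1, theta2, beta)`.
#' @examples
#' d <- ss_data(c(1, 2, 3, 4), c(0.5, 1.5, 2.5, 3.5))
#' f <- ss_objective(d, "lse")
#' f(1, 1, 1)
#' @export
ss_objective <- function(data, method = SS_METHODS,
                         cme_positions = c("standard", "as_printed")) {
  v <- ss_vectors(data)
  ss_objective_xy(v$x, v$y, method, cme_positions)
}

# vector-based core, used directly by the bootstrap and simulation loops
ss_objective_xy <- function(x, y, method = SS_METHODS,
                            cme_positions = c("standard", "as_printed")) {
  method <- match.arg(method)
  cme_positions <- match.arg(cme_positions)
  sx <- sort(x)
  sy <- sort(y)
  n <- length(sx)
  k <- length(sy)

  switch(
    method,
    mle = function(theta1, theta2, beta) {
      -( (n + k) * log(beta) + n * log(theta1) + k * log(theta2) -
           (beta + 1) * (sum(log(sx)) + sum(log(sy))) -
           theta1 * sum(sx^(-beta)) - theta2 * sum(sy^(-beta)) )
    },
    mpse = function(theta1, theta2, beta) {
      -(mean_log_spacing(sx, theta1, beta) + mean_log_spacing(sy, theta2, beta))
    },
    msade = function(theta1, theta2, beta) {
      abs_spacing_dist(sx, theta1, beta) + abs_spacing_dist(sy, theta2, beta)
    },
    msalde = function(theta1, theta2, beta) {
      abs_log_spacing_dist(sx, theta1, beta) + abs_log_spacing_dist(sy, theta2, beta)
    },
    lse = function(theta1, theta2, beta) {
      ls_dist(sx, theta1, beta, positions = seq_len(n) / (n + 1)) +
        ls_dist(sy, theta2, beta, positions = seq_len(k) / (k + 1))
    },
    wlse = function(theta1, theta2, beta) {
      i <- seq_len(n); j <- seq_len(k)
      w1 <- (n + 1)^2 * (n + 2) / (i * (n - i + 1))
      w2 <- (k + 1)^2 * (k + 2) / (j * (k - j + 1))
      ls_dist(sx, theta1, beta, w1, i / (n + 1)) +
        ls_dist(sy, theta2, beta, w2, j / (k + 1))
    },
    cme = function(theta1, theta2, beta) {
      i <- seq_len(n); j <- seq_len(k)
      p1 <- if (cme_positions == "standard") (2 * i - 1) / (2 * n) else (2 * (n - i) + 1) / (2 * n)
      p2 <- if (cme_positions == "standard") (2 * j - 1) / (2 * k) else (2 * (k - j) + 1) / (2 * k)
      1 / (12 * n) + 1 / (12 * k) +
        ls_dist(sx, theta1, beta, positions = p1) +
        ls_dist(sy, theta2, beta, positions = p2)
    },
    ade = function(theta1, theta2, beta) {
      ad_stat(sx, theta1, beta) + ad_stat(sy, theta2, beta)
    }
  )
}
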