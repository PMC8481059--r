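# Point estimation.  The joint model: strength X ~ EIW(theta1, beta),
# stress Y ~ EIW(theta2, beta) with a shared shape.  The MLE is computed
# exactly by profiling: at fixed beta the likelihood is maximised by
# theta1 = n / sum(x^-beta), theta2 = k / sum(y^-beta), leaving a 1-D root
# finding problem in beta.  The seven distance criteria are optimised
# numerically over (log theta1, log theta2, log beta) with jittered restarts
# around the MLE.

# weighted mean of log(s) with weights x^-beta, via log-sum-exp so large beta
# cannot underflow the weights
wmean_log <- function(s, beta) {
  a <- -beta * log(s)
  a <- a - max(a)
  w <- exp(a)
  sum(w * log(s)) / sum(w)
}

# d/dbeta of the profile log-likelihood (joint when y given, one-sample
# otherwise); vectorised root target
profile_score <- function(beta, x, y = NULL) {
  n <- length(x)
  out <- n / beta - sum(log(x)) + n * wmean_log(x, beta)
  if (!is.null(y)) {
    k <- length(y)
    out <- out + k / beta - sum(log(y)) + k * wmean_log(y, beta)
  }
  out
}

# Bracket [lo, hi] is expanded geometrically until the score changes sign.
solve_profile_beta <- function(x, y = NULL, lower = 1e-3, upper = 1e3,
                               tol = 1e-10, max_expand = 6) {
  f_lo <- profile_score(lower, x, y)
  f_hi <- profile_score(upper, x, y)
  expand <- 0
  while (f_lo * f_hi > 0 && expand < max_expand) {
    lower <- lower / 10
    upper <- upper * 10
    f_lo <- profile_score(lower, x, y)
    f_hi <- profile_score(upper, x, y)
    expand <- expand + 1
  }
  if (!is.finite(f_lo) || !is.finite(f_hi) || f_lo * f_hi > 0) {
    rlang::abort(c(
      "Could not bracket a root of the profile score.",
      sprintf("Search interval [%g, %g]; score endpoints %g, %g.",
              lower, upper, f_lo, f_hi)
    ), class = "eiwss_convergence_error")
  }
  stats::uniroot(profile_score, c(lower, upper), x = x, y = y, tol = tol)$root
}

new_ss_fit <- function(method, theta1, theta2, beta, objective, converged,
                       restarts_used, n, k, se = NULL) {
  structure(
    list(
      method = method,
      theta1 = theta1, theta2 = theta2, beta = beta,
      r_hat = ss_reliability(theta1, theta2),
      se = se,
      objective = objective,
      converged = converged,
      restarts_used = restarts_used,
      n = n, k = k
    ),
    class = "ss_fit"
  )
}

#' Fit the joint stress-strength EIW model
#'
#' Estimates `(theta1, theta2, beta)` of the common-shape EIW stress-strength
#' model and the reliability `R = theta1 / (theta1 + theta2)` by one of eight
#' methods:
#'
#' * `"mle"` — maximum likelihood, computed exactly via the profile
#'   likelihood (1-D root finding in `beta`);
#' * `"mpse"` — maximum product of spacings (mean log spacing of both
#'   samples, Cheng-Amin);
#' * `"msade"`, `"msalde"` — minimum spacing absolute / absolute-log
#'   distance from the uniform spacing 1/(n+1);
#' * `"lse"`, `"wlse"` — (weighted) least squares of the fitted CDF against
#'   plotting positions i/(n+1);
#' * `"cme"` — Cramér-von Mises minimum distance;
#' * `"ade"` — Anderson-Darling minimum distance.
#'
#' The seven distance criteria are optimised over
#' `(log theta1, log theta2, log beta)` starting from the MLE, with
#' `restarts` additional multiplicatively jittered starts; smooth criteria
#' get a quasi-Newton polish, the non-smooth spacing-distance criteria use
#' Nelder-Mead polytope search throughout.  The best objective value wins.
#'
#' @param data A data frame with `value`/`role` columns (see [ss_data()],
#'   [eiw_dataset()]).
#' @param method Estimation method tag (see above).
#' @param restarts Number of jittered restarts around the MLE start.
#' @param cme_positions Passed to [ss_objective()]; Cramér-von Mises
#'   plotting-position convention.
#' @param se Logical: compute standard errors?  For the MLE these come from
#'   the inverse observed information; for other methods standard errors are
#'   not defined by the criterion itself and are available separately as a
#'   bootstrap standard deviation via [ss_bootstrap()].
#' @return An object of class `ss_fit`: a list with the estimates, `r_hat`,
#'   the criterion value, convergence diagnostics and (for the MLE) standard
#'   errors.  Supports [tidy()], [glance()] and `print()`.
#' @examples
#' fit_ss(eiw_dataset("carbon"), "mle")
#' @export
fit_ss <- function(data, method = SS_METHODS, restarts = 4,
                   cme_positions = c("standard", "as_printed"),
                   se = identical(match.arg(method), "mle")) {
  v <- ss_vectors(data)
  fit_ss_xy(v$x, v$y, method = method, restarts = restarts,
            cme_positions = cme_positions, se = se)
}

# vector-based core of fit_ss; hot path for bootstrap and simulation
fit_ss_xy <- function(x, y, method = SS_METHODS, restarts = 4,
                      cme_positions = c("standard", "as_printed"),
                      se = identical(match.arg(method), "mle")) {
  method <- match.arg(method)
  cme_positions <- match.arg(cme_positions)
  n <- length(x)
  k <- length(y)

  beta_mle <- solve_profile_beta(x, y)
  th1_mle <- n / sum(x^(-beta_mle))
  th2_mle <- k / sum(y^(-beta_mle))

  if (method == "mle") {
    obj <- ss_objective_xy(x, y, "mle")
    grad_ok <- abs(profile_score(beta_mle, x, y)) < 1e-6
    fit <- new_ss_fit(
      "mle", th1_mle, th2_mle, beta_mle,
      objective = obj(th1_mle, th2_mle, beta_mle),
      converged = grad_ok, restarts_used = 0L, n = n, k = k
    )
    if (se) fit$se <- mle_standard_errors_xy(x, y, fit)
    return(fit)
  }

  f <- ss_objective_xy(x, y, method, cme_positions)
  fpar <- function(p) {
    val <- f(exp(p[1]), exp(p[2]), exp(p[3]))
    if (!is.finite(val)) .Machine$double.xmax else val
  }
  start <- log(c(th1_mle, th2_mle, beta_mle))
  smooth <- method %in% c("mpse", "lse", "wlse", "cme", "ade")

  # deterministic multiplicative jitter around the MLE start
  jitters <- if (restarts > 0) {
    with_preserved_seed(7103, matrix(stats::rnorm(3 * restarts, 0, 0.5),
                                     nrow = restarts))
  } else {
    matrix(numeric(0), nrow = 0, ncol = 3)
  }

  best <- NULL
  for (r in 0:restarts) {
    p0 <- if (r == 0) start else start + jitters[r, ]
    o <- stats::optim(p0, fpar, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
    o <- stats::optim(o$par, fpar, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
    if (smooth) {
      ob <- tryCatch(
        stats::optim(o$par, fpar, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-12)),
        error = function(e) NULL
      )
      if (!is.null(ob) && is.finite(ob$value) && ob$value < o$value) o <- ob
    }
    if (is.null(best) || o$value < best$value) {
      best <- o
      best$restart <- r
    }
  }
  if (!is.finite(best$value) || best$value >= .Machine$double.xmax) {
    rlang::abort(c(
      sprintf("Optimisation of the %s criterion failed.", toupper(method)),
      sprintf("Best objective %g after %d restarts.", best$value, restarts)
    ), class = "eiwss_convergence_error")
  }
  est <- exp(best$par)
  new_ss_fit(
    method, est[1], est[2], est[3],
    objective = best$value,
    converged = TRUE,
    restarts_used = as.integer(restarts),
    n = n, k = k
  )
}

#' Fit all (or several) estimation methods at once
#'
#' Applies [fit_ss()] for each requested method and stacks the results into
#' a tidy table, one row per method — the shape of the case-study comparison
#' tables.
#'
#' @inheritParams fit_ss
#' @param methods Character vector of method tags.
#' @return A tibble with columns `method`, `theta1`, `theta2`, `beta`,
#'   `r_hat`, `objective`, `converged`.
#' @examples
#' fit_ss_all(eiw_dataset("jute"), methods = c("mle", "lse"))
#' @export
fit_ss_all <- function(data, methods = SS_METHODS, restarts = 4,
                       cme_positions = c("standard", "as_printed")) {
  cme_positions <- match.arg(cme_positions)
  methods <- match.arg(methods, SS_METHODS, several.ok = TRUE)
  purrr::map_dfr(methods, function(m) {
    fit <- fit_ss(data, m, restarts = restarts, cme_positions = cme_positions,
                  se = FALSE)
    tibble::tibble(
      method = m, theta1 = fit$theta1, theta2 = fit$theta2, beta = fit$beta,
      r_hat = fit$r_hat, objective = fit$objective, converged = fit$converged
    )
  })
}

#' Single-sample EIW maximum-likelihood fit
#'
#' Fits EIW(`theta`, `beta`) to one sample by maximum likelihood using the
#' same profile structure as the joint fit (`theta = n / sum(x^-beta)` at
#' the root of the one-sample profile score), with standard errors from the
#' inverse observed information.
#'
#' @param x Positive sample of length at least 2.
#' @return An object of class `eiw_fit` with elements `theta`, `beta`, `se`
#'   (named), `loglik` and `n`.  Supports [tidy()] and [glance()].
#' @examples
#' x <- dplyr::filter(eiw_dataset("carbon"), role == "strength")$value
#' fit_eiw(x)
#' @export
fit_eiw <- function(x) {
  check_positive_sample(x, "x")
  if (length(x) < 2) rlang::abort("`x` needs at least two observations.")
  n <- length(x)
  beta <- solve_profile_beta(x)
  theta <- n / sum(x^(-beta))
  ll <- n * log(theta * beta) - (beta + 1) * sum(log(x)) - theta * sum(x^(-beta))
  nll <- function(p) {
    -(n * log(p[1] * p[2]) - (p[2] + 1) * sum(log(x)) - p[1] * sum(x^(-p[2])))
  }
  info <- central_hessian(nll, c(theta, beta))
  se <- information_se(info, c("theta", "beta"))
  structure(
    list(theta = theta, beta = beta, se = se, loglik = ll, n = n),
    class = "eiw_fit"
  )
}

# Symmetric central-difference Hessian with steps scaled to the parameter
# magnitude.
central_hessian <- function(fn, par, rel_step = 1e-4) {
  p <- length(par)
  h <- pmax(abs(par), 1e-4) * rel_step
  H <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    for (j in i:p) {
      ei <- ej <- numeric(p)
      ei[i] <- h[i]
      ej[j] <- h[j]
      if (i == j) {
        H[i, i] <- (fn(par + ei) - 2 * fn(par) + fn(par - ei)) / h[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (fn(par + ei + ej) - fn(par + ei - ej) -
             fn(par - ei + ej) + fn(par - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

information_se <- function(info, names) {
  se <- rep(NA_real_, length(names))
  names(se) <- names
  ev <- tryCatch(eigen(info, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) NA_real_)
  if (anyNA(ev) || any(ev <= 0)) {
    rlang::warn("Observed information is not positive definite; standard errors undefined.")
    return(se)
  }
  se[] <- sqrt(diag(solve(info)))
  se
}

#' Observed-information standard errors for a joint MLE fit
#'
#' Square roots of the diagonal of the inverse observed information (the
#' negative Hessian of the joint log-likelihood, by central differences with
#' magnitude-scaled steps) at the maximum-likelihood estimates.
#'
#' @param data The data the fit was produced from.
#' @param fit An `ss_fit` with `method == "mle"`.
#' @return Named numeric vector `c(theta1, theta2, beta)` of standard
#'   errors; `NA` with a warning if the observed information is not positive
#'   definite.
#' @export
mle_standard_errors <- function(data, fit) {
  v <- ss_vectors(data)
  mle_standard_errors_xy(v$x, v$y, fit)
}

mle_standard_errors_xy <- function(x, y, fit) {
  stopifnot(inherits(fit, "ss_fit"))
  if (fit$method != "mle") {
    rlang::abort("Information-based standard errors are defined for the MLE only.")
  }
  obj <- ss_objective_xy(x, y, "mle")  # negative log-likelihood
  nll <- function(p) obj(p[1], p[2], p[3])
  info <- central_hessian(nll, c(fit$theta1, fit$theta2, fit$beta))
  information_se(info, c("theta1", "theta2", "beta"))
}

# Methods -------------------------------------------------------------------

#' @export
print.ss_fit <- function(x, ...) {
  cat(sprintf(
    "Stress-strength EIW fit (%s), n = %d, k = %d\n",
    toupper(x$method), x$n, x$k
  ))
  est <- c(theta1 = x$theta1, theta2 = x$theta2, beta = x$beta, R = x$r_hat)
  print(signif(est, 6))
  if (!is.null(x$se) && !anyNA(x$se)) {
    cat("SE:", paste(sprintf("%s=%.4g", names(x$se), x$se), collapse = ", "), "\n")
  }
  cat(sprintf("criterion value %.6g; converged: %s\n", x$objective, x$converged))
  invisible(x)
}

#' Tidiers for fitted stress-strength and single-sample EIW models
#'
#' `tidy()` returns one row per parameter (`theta1`, `theta2`, `beta`, and
#' the derived reliability `R` for joint fits) with standard errors where
#' defined; `glance()` returns a one-row model summary.
#'
#' @param x An `ss_fit` or `eiw_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.ss_fit <- function(x, ...) {
  se <- x$se %||% c(theta1 = NA_real_, theta2 = NA_real_, beta = NA_real_)
  tibble::tibble(
    term = c("theta1", "theta2", "beta", "R"),
    estimate = c(x$theta1, x$theta2, x$beta, x$r_hat),
    std.error = c(unname(se[c("theta1", "theta2", "beta")]), NA_real_)
  )
}

#' @rdname tidiers
#' @export
glance.ss_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method, r_hat = x$r_hat, objective = x$objective,
    converged = x$converged, restarts = x$restarts_used, n = x$n, k = x$k
  )
}

#' @rdname tidiers
#' @export
tidy.eiw_fit <- function(x, ...) {
  tibble::tibble(
    term = c("theta", "beta"),
    estimate = c(x$theta, x$beta),
    std.error = unname(x$se[c("theta", "beta")])
  )
}

#' @rdname tidiers
#' @export
glance.eiw_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n = x$n)
}

#' @export
print.eiw_fit <- function(x, ...) {
  cat(sprintf("EIW maximum-likelihood fit, n = %d\n", x$n))
  print(signif(c(theta = x$theta, beta = x$beta), 6))
  cat("SE:", paste(sprintf("%s=%.4g", names(x$se), x$se), collapse = ", "), "\n")
  invisible(x)
}
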