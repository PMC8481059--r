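# Monte Carlo evaluation harness: draw two-sample EIW data over a grid of
# truth triples and sample sizes, apply the requested estimators to the same
# generated data streams, and summarise mean/MSE per parameter and mean
# bootstrap interval lengths.

#' Configure a Monte Carlo study of the stress-strength estimators
#'
#' The defaults mirror the reference simulation design: truth triples
#' covering the three cases (theta1 varied against theta2 = 0.1 at
#' beta = 0.5; theta2 varied against theta1 = 3 at beta = 0.9; theta2 varied
#' against theta1 = 0.5 at beta = 0.5), the sample-size grid
#' (n, k) = (30, 40), (35, 45), (50, 60), (70, 80), 10000 replicates and all
#' eight methods.
#'
#' @param cases Data frame with columns `theta1`, `theta2`, `beta` (one row
#'   per truth triple).
#' @param sizes Data frame with columns `n` and `k` (the stress-sample size;
#'   a column named `m` is accepted as an alias for `k`).
#' @param reps Number of Monte Carlo replicates per cell.
#' @param methods Estimator tags to evaluate.
#' @param boot `NULL` (no interval study) or a list with elements `B`
#'   (bootstrap size, default 500), `levels` (subset of 0.90/0.95/0.99) and
#'   `kinds` (subset of `"boot_p"`, `"boot_bcp"`).
#' @param seed Master seed; every replicate derives its own sub-seed from it
#'   by a counter scheme, so results are reproducible and every method sees
#'   identical data.
#' @param restarts Restarts per distance-criterion fit inside the study.
#' @return An object of class `ss_sim_config`.
#' @export
ss_sim_config <- function(cases = default_sim_cases(),
                          sizes = default_sim_sizes(),
                          reps = 10000,
                          methods = SS_METHODS,
                          boot = NULL,
                          seed = 1,
                          restarts = 1) {
  cases <- tibble::as_tibble(cases)
  if (!all(c("theta1", "theta2", "beta") %in% names(cases)) || nrow(cases) == 0) {
    rlang::abort("`cases` needs columns theta1, theta2, beta and at least one row.")
  }
  if (any(as.matrix(cases[, c("theta1", "theta2", "beta")]) <= 0)) {
    rlang::abort("All truth parameters must be positive.")
  }
  sizes <- tibble::as_tibble(sizes)
  if ("m" %in% names(sizes) && !("k" %in% names(sizes))) {
    sizes <- dplyr::rename(sizes, k = "m")
  }
  if (!all(c("n", "k") %in% names(sizes)) || nrow(sizes) == 0) {
    rlang::abort("`sizes` needs columns n and k (or m) and at least one row.")
  }
  if (any(sizes$n < 2) || any(sizes$k < 2)) {
    rlang::abort("Sample sizes must be at least 2.")
  }
  if (length(methods) == 0) rlang::abort("`methods` must not be empty.")
  methods <- match.arg(methods, SS_METHODS, several.ok = TRUE)
  if (!is.numeric(reps) || reps < 1) rlang::abort("`reps` must be at least 1.")
  if (!is.null(boot)) {
    boot <- utils::modifyList(
      list(B = 500, levels = c(0.90, 0.95, 0.99), kinds = c("boot_p", "boot_bcp")),
      boot
    )
    if (!all(boot$levels %in% c(0.90, 0.95, 0.99)) ||
        !all(boot$kinds %in% c("boot_p", "boot_bcp"))) {
      rlang::abort("Invalid bootstrap levels or interval kinds.")
    }
  }
  structure(
    list(cases = cases, sizes = sizes, reps = as.integer(reps),
         methods = methods, boot = boot, seed = as.integer(seed),
         restarts = restarts),
    class = "ss_sim_config"
  )
}

#' @rdname ss_sim_config
#' @export
default_sim_cases <- function() {
  tibble::tibble(
    case = c("case1a", "case1b", "case2a", "case2b", "case3a", "case3b"),
    theta1 = c(0.1, 3, 3, 3, 0.5, 0.5),
    theta2 = c(0.1, 0.1, 0.4, 2, 0.4, 1.5),
    beta = c(0.5, 0.5, 0.9, 0.9, 0.5, 0.5)
  )
}

#' @rdname ss_sim_config
#' @export
default_sim_sizes <- function() {
  tibble::tibble(n = c(30, 35, 50, 70), k = c(40, 45, 60, 80))
}

sim_sub_seed <- function(seed, ci, sj, rep) {
  (as.double(seed) + (ci * 101 + sj) * 1e6 + rep) %% 2147483629
}

#' Run a configured Monte Carlo study
#'
#' For every (case, size) cell and replicate, draws the two samples by
#' inverse-transform sampling, fits every requested method to the same data,
#' and accumulates the mean and mean squared error of each parameter
#' estimate and of the reliability.  Replicates whose fit fails are excluded
#' from that method's summaries and counted.  If the configuration requests
#' a bootstrap block, mean interval lengths per level and kind are collected
#' as well (a nested bootstrap; expect a much longer run).
#'
#' @param config An [ss_sim_config()].
#' @return An object of class `ss_sim_result`: a list with
#'   * `point`: tibble with one row per (case, n, k, method, parameter)
#'     holding `truth`, `mean`, `mse`, `n_fail`, `n_used`;
#'   * `ci`: tibble of mean interval lengths (or `NULL`);
#'   * `config`: the configuration.
#' @examples
#' cfg <- ss_sim_config(
#'   cases = tibble::tibble(theta1 = 0.5, theta2 = 0.4, beta = 0.5),
#'   sizes = tibble::tibble(n = 30, k = 40),
#'   reps = 25, methods = "mle", seed = 9
#' )
#' run_ss_study(cfg)$point
#' @export
run_ss_study <- function(config) {
  stopifnot(inherits(config, "ss_sim_config"))
  cases <- config$cases
  if (!("case" %in% names(cases))) {
    cases$case <- paste0("case", seq_len(nrow(cases)))
  }
  point_rows <- list()
  ci_rows <- list()
  for (ci in seq_len(nrow(cases))) {
    truth <- c(theta1 = cases$theta1[ci], theta2 = cases$theta2[ci],
               beta = cases$beta[ci])
    truth["r"] <- ss_reliability(truth[["theta1"]], truth[["theta2"]])
    for (sj in seq_len(nrow(config$sizes))) {
      n <- config$sizes$n[sj]
      k <- config$sizes$k[sj]
      est <- array(
        NA_real_, dim = c(config$reps, length(config$methods), 4),
        dimnames = list(NULL, config$methods, c("theta1", "theta2", "beta", "r"))
      )
      lens <- if (!is.null(config$boot)) list() else NULL
      for (rep in seq_len(config$reps)) {
        sub <- sim_sub_seed(config$seed, ci, sj, rep)
        d <- with_preserved_seed(sub, list(
          x = reiw(n, truth[["theta1"]], truth[["beta"]]),
          y = reiw(k, truth[["theta2"]], truth[["beta"]])
        ))
        for (m in config$methods) {
          fit <- tryCatch(
            fit_ss_xy(d$x, d$y, m, restarts = config$restarts, se = FALSE),
            error = function(e) NULL
          )
          if (!is.null(fit)) {
            est[rep, m, ] <- c(fit$theta1, fit$theta2, fit$beta, fit$r_hat)
            if (!is.null(config$boot)) {
              b <- ss_bootstrap(
                ss_data(d$x, d$y), m, B = config$boot$B,
                conf_levels = config$boot$levels,
                seed = sub + 17, restarts = config$restarts
              )
              iv <- dplyr::filter(b$intervals, .data$kind %in% config$boot$kinds)
              iv$method <- m
              iv$rep <- rep
              lens[[length(lens) + 1L]] <- iv
            }
          }
        }
      }
      for (m in config$methods) {
        vals <- est[, m, , drop = FALSE]
        ok <- !is.na(vals[, 1, 1])
        for (p in c("theta1", "theta2", "beta", "r")) {
          v <- est[ok, m, p]
          tv <- truth[[p]]
          point_rows[[length(point_rows) + 1L]] <- tibble::tibble(
            case = cases$case[ci], n = n, k = k, method = m,
            parameter = p, truth = tv,
            mean = mean(v), mse = mean((v - tv)^2),
            n_used = sum(ok), n_fail = sum(!ok)
          )
        }
      }
      if (!is.null(config$boot) && length(lens) > 0) {
        ci_rows[[length(ci_rows) + 1L]] <- dplyr::bind_rows(lens) |>
          dplyr::group_by(.data$method, .data$level, .data$kind) |>
          dplyr::summarise(mean_length = mean(.data$length), .groups = "drop") |>
          dplyr::mutate(case = cases$case[ci], n = n, k = k, .before = 1)
      }
    }
  }
  structure(
    list(
      point = dplyr::bind_rows(point_rows),
      ci = if (length(ci_rows) > 0) dplyr::bind_rows(ci_rows) else NULL,
      config = config
    ),
    class = "ss_sim_result"
  )
}

#' Lay a study result out as a comparison table
#'
#' `sim_point_table()` arranges the point summaries as two statistic rows
#' (Mean, MSE) per (case, method), with one column per parameter and sample
#' size; `sim_ci_table()` arranges mean interval lengths with one `L` column
#' per (level, kind).  Both mirror the usual side-by-side layout of
#' estimator-comparison tables.
#'
#' @param result An `ss_sim_result`.
#' @return A tibble.
#' @export
sim_point_table <- function(result) {
  stopifnot(inherits(result, "ss_sim_result"))
  pt <- result$point
  one_size <- dplyr::n_distinct(paste(pt$n, pt$k)) == 1
  pt |>
    tidyr::pivot_longer(c("mean", "mse"), names_to = "statistic") |>
    dplyr::mutate(
      statistic = ifelse(.data$statistic == "mean", "Mean", "MSE"),
      col = if (one_size) .data$parameter else
        paste0(.data$parameter, "_n", .data$n, "_k", .data$k)
    ) |>
    dplyr::select("case", "method", "statistic", "col", "value") |>
    tidyr::pivot_wider(names_from = "col", values_from = "value") |>
    dplyr::arrange(.data$case, .data$method, dplyr::desc(.data$statistic))
}

#' @rdname sim_point_table
#' @export
sim_ci_table <- function(result) {
  stopifnot(inherits(result, "ss_sim_result"))
  if (is.null(result$ci)) {
    rlang::abort("The study was run without a bootstrap block.")
  }
  result$ci |>
    dplyr::mutate(col = sprintf("L%.0f_%s", 100 * .data$level, .data$kind)) |>
    dplyr::select("case", "n", "k", "method", "col", "mean_length") |>
    tidyr::pivot_wider(names_from = "col", values_from = "mean_length") |>
    dplyr::arrange(.data$case, .data$n, .data$method)
}

#' @export
print.ss_sim_result <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo study: %d case(s) x %d size(s) x %d method(s), %d reps\n",
    nrow(x$config$cases), nrow(x$config$sizes), length(x$config$methods),
    x$config$reps
  ))
  print(sim_point_table(x), n = 20)
  invisible(x)
}
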