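# Two-sample containers: a stress-strength data set is a long tibble with a
# `value` column and a `role` column ("strength" or "stress").

SS_ROLES <- c("strength", "stress")

#' Assemble a stress-strength data set
#'
#' Combines a strength sample and a stress sample into the long tibble format
#' used by every fitting function in the package: one row per observation,
#' with columns `value` (positive real) and `role` (`"strength"` or
#' `"stress"`).  Both samples must hold at least two strictly positive,
#' finite values.
#'
#' @param x Numeric vector of strength observations (size n).
#' @param y Numeric vector of stress observations (size k).
#' @return A tibble of class `ss_data` with columns `value` and `role`.
#' @examples
#' ss_data(c(1.2, 3.4, 2.2), c(0.8, 1.1, 0.7))
#' @export
ss_data <- function(x, y) {
  check_positive_sample(x, "x")
  check_positive_sample(y, "y")
  if (length(x) < 2 || length(y) < 2) {
    rlang::abort("Both samples need at least two observations.")
  }
  out <- tibble::tibble(
    value = c(as.numeric(x), as.numeric(y)),
    role = factor(rep(SS_ROLES, c(length(x), length(y))), levels = SS_ROLES)
  )
  class(out) <- c("ss_data", class(out))
  out
}

# Extract the two samples back out of any data frame with value/role columns.
ss_vectors <- function(data) {
  if (!is.data.frame(data) || !all(c("value", "role") %in% names(data))) {
    rlang::abort(
      "`data` must be a data frame with columns `value` and `role` (see `ss_data()`)."
    )
  }
  role <- as.character(data$role)
  bad <- setdiff(unique(role), SS_ROLES)
  if (length(bad) > 0) {
    rlang::abort(sprintf("Unknown role(s): %s.", paste(bad, collapse = ", ")))
  }
  x <- data$value[role == "strength"]
  y <- data$value[role == "stress"]
  check_positive_sample(x, "strength sample")
  check_positive_sample(y, "stress sample")
  if (length(x) < 2 || length(y) < 2) {
    rlang::abort("Both samples need at least two observations.")
  }
  list(x = as.numeric(x), y = as.numeric(y))
}

#' Read strength and stress samples from plain-text files
#'
#' Each file holds one sample: either one positive decimal per line or a
#' single-column CSV with an optional header line.
#'
#' @param strength_file,stress_file Paths to the two sample files.
#' @return An [ss_data()] tibble.
#' @export
read_ss_samples <- function(strength_file, stress_file) {
  ss_data(read_sample_file(strength_file), read_sample_file(stress_file))
}

read_sample_file <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Input file does not exist: %s", path))
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  # strip a single header line if the first entry is not numeric
  vals <- suppressWarnings(as.numeric(lines))
  if (length(vals) > 0 && is.na(vals[1]) && length(lines) > 1) {
    lines <- lines[-1]
    vals <- suppressWarnings(as.numeric(lines))
  }
  bad <- which(is.na(vals))
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "Non-numeric value in %s at line %d: '%s'", path, bad[1], lines[bad[1]]
    ))
  }
  if (any(vals <= 0)) {
    rlang::abort(sprintf(
      "Non-positive value in %s at line %d.", path, which(vals <= 0)[1]
    ))
  }
  vals
}

#' Case-study breaking-strength data sets
#'
#' Returns one of the two bundled breaking-strength data sets used in the
#' case studies, as an [ss_data()] tibble.
#'
#' * `"jute"`: breaking strengths of jute fiber at two gauge lengths
#'   (Xia et al. 2009); the 10 mm sample (n = 30) is the strength `x`, the
#'   20 mm sample (n = 30) the stress `y`.
#' * `"carbon"`: tensile strength (GPa) of single carbon fibers
#'   (Bader and Priest 1982); Data Set I (n = 63) is the strength `x`,
#'   Data Set II (m = 69) the stress `y`.  The source text labels both sets
#'   "10 mm" in one place and calls the second "length of 20 mm" in another;
#'   the sets are therefore identified here by their listing order and sample
#'   size, which are unambiguous.
#'
#' @param name `"jute"` or `"carbon"`.
#' @return An `ss_data` tibble with attributes `dataset` (the name) and
#'   `provenance` (a citation string).  A fresh copy is returned on every
#'   call.
#' @examples
#' jute <- eiw_dataset("jute")
#' dplyr::count(jute, role)
#' @export
eiw_dataset <- function(name = c("jute", "carbon")) {
  name <- match.arg(name)
  dir <- system.file("extdata", package = "eiwss", mustWork = TRUE)
  out <- read_ss_samples(
    file.path(dir, paste0(name, "_x.txt")),
    file.path(dir, paste0(name, "_y.txt"))
  )
  attr(out, "dataset") <- name
  attr(out, "provenance") <- switch(
    name,
    jute = paste(
      "Breaking strengths of jute fiber at 10 mm (strength) and 20 mm",
      "(stress) gauge lengths; Xia, Mi and Zhou (2009), J. Compos. Mater."
    ),
    carbon = paste(
      "GPa strength of single carbon fibers, Data Set I (n = 63, strength)",
      "and Data Set II (m = 69, stress); Bader and Priest (1982).",
      "Gauge-length labels for the two sets are contradictory in the source",
      "text; sets are keyed by listing order."
    )
  )
  out
}

#' Simulate a synthetic stress-strength data set
#'
#' Draws a strength sample of size `n` from EIW(`theta1`, `beta`) and a
#' stress sample of size `k` from EIW(`theta2`, `beta`) by inverse-transform
#' sampling, for use in recovery tests and worked examples.
#'
#' @param theta1,theta2 Positive exponentiation parameters of the two laws.
#' @param beta Common positive shape parameter.
#' @param n,k Sample sizes (each at least 2).
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @return An [ss_data()] tibble carrying the generating truth in its
#'   `truth` attribute (a named vector with `theta1`, `theta2`, `beta`, `r`).
#' @examples
#' d <- ss_simulate_data(0.5, 0.4, 0.5, n = 30, k = 40, seed = 7)
#' attr(d, "truth")
#' @export
ss_simulate_data <- function(theta1, theta2, beta, n, k, seed = NULL) {
  check_eiw_params(theta1, beta)
  check_eiw_params(theta2, beta)
  draw <- function() {
    ss_data(reiw(n, theta1, beta), reiw(k, theta2, beta))
  }
  out <- if (is.null(seed)) draw() else with_preserved_seed(seed, draw())
  attr(out, "truth") <- c(
    theta1 = theta1, theta2 = theta2, beta = beta,
    r = ss_reliability(theta1, theta2)
  )
  out
}

# Run `expr` under `set.seed(seed)` and restore the caller's RNG state.
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
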