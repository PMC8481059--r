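# The seven distance criteria are defined by their objectives; the
# optimiser is checked against an exhaustive log-space grid search on a
# tiny fixed sample, and against structural invariants (swap antisymmetry,
# scale equivariance, reduction relations) on the case-study data.

distance_methods <- c("mpse", "msade", "msalde", "lse", "wlse", "cme", "ade")

test_that("optimiser matches the exhaustive grid oracle on toy data", {
  for (m in distance_methods) {
    f <- ss_objective(toy_data, m)
    fit <- fit_ss(toy_data, m, se = FALSE)
    oracle <- grid_search_oracle(f, center = c(fit$theta1, fit$theta2, fit$beta),
                                 half_width = log(8), len = 25)
    # the optimiser must dominate every grid point...
    expect_lte(fit$objective, oracle$value + 1e-9)
    # ...and sit within one grid cell of the grid argmin
    expect_lt(max(abs(log(c(fit$theta1, fit$theta2, fit$beta)) -
                        log(oracle$par))), oracle$spacing + 1e-9)
  }
})

test_that("every method satisfies R in (0,1) and the exact ratio identity", {
  tab <- fit_ss_all(jute)
  expect_equal(nrow(tab), 8)
  expect_true(all(tab$r_hat > 0 & tab$r_hat < 1))
  expect_equal(tab$r_hat, tab$theta1 / (tab$theta1 + tab$theta2))
  expect_true(all(tab$converged))
})

test_that("swapping the sample roles maps R to 1 - R for all methods", {
  d <- ss_simulate_data(1.2, 0.6, 0.8, 18, 14, seed = 41)
  swapped <- ss_data(sample_of(d, "stress"), sample_of(d, "strength"))
  for (m in c("mle", distance_methods)) {
    r1 <- fit_ss(d, m, se = FALSE)$r_hat
    r2 <- fit_ss(swapped, m, se = FALSE)$r_hat
    expect_equal(r1, 1 - r2, tolerance = 1e-4)
  }
})

test_that("identical samples in both roles give R = 1/2 for all methods", {
  x <- c(0.7, 1.3, 2.0, 2.9, 4.1)
  d <- ss_data(x, x)
  for (m in distance_methods) {
    fit <- fit_ss(d, m, se = FALSE)
    expect_equal(fit$r_hat, 0.5, tolerance = 1e-5)
  }
})

test_that("MPSE is scale-equivariant within optimiser tolerance", {
  base <- fit_ss(jute, "mpse", se = FALSE)
  scaled <- ss_data(sample_of(jute, "strength") * 5,
                    sample_of(jute, "stress") * 5)
  fs <- fit_ss(scaled, "mpse", se = FALSE)
  expect_equal(fs$beta, base$beta, tolerance = 1e-3)
  expect_equal(fs$r_hat, base$r_hat, tolerance = 1e-3)
  expect_equal(fs$theta1 / base$theta1, 5^base$beta, tolerance = 1e-2)
})

test_that("distance optima dominate the MLE point on their own criterion", {
  mle <- fit_ss(jute, "mle", se = FALSE)
  for (m in distance_methods) {
    f <- ss_objective(jute, m)
    fit <- fit_ss(jute, m, se = FALSE)
    expect_lte(fit$objective, f(mle$theta1, mle$theta2, mle$beta) + 1e-10)
  }
})

test_that("weighted least squares reduces to least squares at unit weights", {
  sx <- sort(sample_of(toy_data, "strength"))
  n <- length(sx)
  pos <- seq_len(n) / (n + 1)
  w_unit <- eiwss:::ls_dist(sx, 1.4, 0.9, weights = rep(1, n), positions = pos)
  unweighted <- eiwss:::ls_dist(sx, 1.4, 0.9, positions = pos)
  expect_identical(w_unit, unweighted)
  # the WLS weights are positive and symmetric in i <-> n - i + 1
  i <- seq_len(7)
  w <- (7 + 1)^2 * (7 + 2) / (i * (7 - i + 1))
  expect_true(all(w > 0))
  expect_equal(w, rev(w))
})

test_that("spacing floor keeps tied observations finite in log criteria", {
  d <- ss_data(c(1, 1, 1, 2, 3), c(0.5, 1.4, 2.2, 2.9))
  f <- ss_objective(d, "mpse")
  expect_true(is.finite(f(1, 1, 1)))
  fit <- fit_ss(d, "mpse", se = FALSE)
  expect_true(is.finite(fit$objective))
  expect_true(fit$r_hat > 0 && fit$r_hat < 1)
})

test_that("the reversed plotting-position variant is available but distinct", {
  f_std <- ss_objective(jute, "cme", cme_positions = "standard")
  f_rev <- ss_objective(jute, "cme", cme_positions = "as_printed")
  expect_false(isTRUE(all.equal(f_std(400, 300, 1.1), f_rev(400, 300, 1.1))))
  # the standard convention contains the Cramer-von Mises constant term
  expect_gte(f_std(400, 300, 1.1), 1 / (12 * 30) + 1 / (12 * 30))
})
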