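# The joint MLE is computed by profiling theta1, theta2 out of the
# likelihood and root-finding the 1-D profile score in beta, so it can be
# checked hard against an independent optimiser and against closed-form
# structure.

test_that("joint MLE solves the score equations and beats naive optimisation", {
  fit <- fit_ss(carbon, "mle")
  v <- list(x = sample_of(carbon, "strength"), y = sample_of(carbon, "stress"))
  n <- length(v$x); k <- length(v$y)

  # stationarity of the full 3-D gradient at the solution
  expect_equal(n / fit$theta1, sum(v$x^(-fit$beta)), tolerance = 1e-8)
  expect_equal(k / fit$theta2, sum(v$y^(-fit$beta)), tolerance = 1e-8)
  score_beta <- (n + k) / fit$beta - sum(log(v$x)) - sum(log(v$y)) +
    fit$theta1 * sum(v$x^(-fit$beta) * log(v$x)) +
    fit$theta2 * sum(v$y^(-fit$beta) * log(v$y))
  expect_lt(abs(score_beta), 1e-6)
  expect_true(fit$converged)
  expect_equal(fit$r_hat, fit$theta1 / (fit$theta1 + fit$theta2))

  # independent oracle: direct Nelder-Mead maximisation of the 3-parameter
  # log-likelihood must not find a higher likelihood
  nll <- ss_objective(carbon, "mle")
  alt <- optim(log(c(100, 30, 4)),
               function(p) nll(exp(p[1]), exp(p[2]), exp(p[3])),
               control = list(maxit = 5000, reltol = 1e-12))
  expect_lte(nll(fit$theta1, fit$theta2, fit$beta), alt$value + 1e-6)
})

test_that("joint MLE reproduces the carbon-fiber case study", {
  fit <- fit_ss(carbon, "mle")
  expect_equal(fit$theta1, 103.9460, tolerance = 5e-4)
  expect_equal(fit$theta2, 30.6687, tolerance = 5e-4)
  expect_equal(fit$beta, 4.5745, tolerance = 1e-4)
  expect_equal(fit$r_hat, 0.7722, tolerance = 1e-3)
  # published standard errors from the observed information
  expect_equal(unname(fit$se), c(30.2423, 6.3435, 0.2792), tolerance = 1e-3)
})

test_that("jute joint MLE matches the frozen exact optimum", {
  # frozen values computed independently by profile root-finding at
  # tolerance 1e-12 (see also the likelihood-dominance check above)
  fit <- fit_ss(jute, "mle")
  expect_equal(fit$beta, 1.133205, tolerance = 1e-5)
  expect_equal(fit$theta1, 386.0612, tolerance = 1e-5)
  expect_equal(fit$theta2, 285.0976, tolerance = 1e-5)
  expect_equal(fit$r_hat, 0.575216, tolerance = 1e-5)
})

test_that("identical samples in both roles give R = 1/2 exactly", {
  x <- sample_of(jute, "strength")
  d <- ss_data(x, x)
  fit <- fit_ss(d, "mle")
  expect_equal(fit$theta1, fit$theta2, tolerance = 1e-10)
  expect_equal(fit$r_hat, 0.5, tolerance = 1e-10)
})

test_that("MLE is scale-equivariant: beta and R invariant, theta ~ c^beta", {
  fit <- fit_ss(jute, "mle")
  for (c0 in c(0.01, 7)) {
    scaled <- ss_data(sample_of(jute, "strength") * c0,
                      sample_of(jute, "stress") * c0)
    fs <- fit_ss(scaled, "mle", se = FALSE)
    expect_equal(fs$beta, fit$beta, tolerance = 1e-6)
    expect_equal(fs$r_hat, fit$r_hat, tolerance = 1e-6)
    expect_equal(fs$theta1, fit$theta1 * c0^fit$beta, tolerance = 1e-4)
  }
})

test_that("single-sample MLE: stationarity, equivariance and case studies", {
  x <- sample_of(jute, "strength")
  fit <- fit_eiw(x)
  n <- length(x)
  expect_equal(n / fit$theta, sum(x^(-fit$beta)), tolerance = 1e-8)

  # frozen exact optimum for jute X; the carbon samples reproduce the
  # published pairs (the stress sample matches the cell printed first)
  expect_equal(fit$theta, 491.6752, tolerance = 1e-4)
  expect_equal(fit$beta, 1.18336, tolerance = 1e-4)
  cy <- fit_eiw(sample_of(carbon, "stress"))
  expect_equal(cy$theta, 23.2675, tolerance = 5e-4)
  expect_equal(cy$beta, 4.1271, tolerance = 5e-4)
  cx <- fit_eiw(sample_of(carbon, "strength"))
  expect_equal(cx$theta, 230.4763, tolerance = 5e-4)
  expect_equal(cx$beta, 5.4338, tolerance = 5e-4)

  # x -> cx multiplies theta by c^beta and leaves beta unchanged
  sc <- fit_eiw(x * 3)
  expect_equal(sc$beta, fit$beta, tolerance = 1e-8)
  expect_equal(sc$theta, fit$theta * 3^fit$beta, tolerance = 1e-5)

  expect_error(fit_eiw(c(1)), "two observations")
})

test_that("observed-information standard errors behave asymptotically", {
  fit <- fit_ss(jute, "mle", se = FALSE)
  nll <- ss_objective(jute, "mle")
  H <- eiwss:::central_hessian(function(p) nll(p[1], p[2], p[3]),
                               c(fit$theta1, fit$theta2, fit$beta))
  expect_lt(max(abs(H - t(H))), 1e-8 * max(abs(H)))

  # SEs shrink like 1/sqrt(n) across a 10-fold size increase
  d1 <- ss_simulate_data(0.5, 0.4, 0.5, 500, 500, seed = 5)
  d2 <- ss_simulate_data(0.5, 0.4, 0.5, 5000, 5000, seed = 6)
  se1 <- fit_ss(d1, "mle")$se
  se2 <- fit_ss(d2, "mle")$se
  ratio <- se1[["beta"]] / se2[["beta"]]
  expect_gt(ratio, sqrt(10) * 0.7)
  expect_lt(ratio, sqrt(10) * 1.4)

  # jute X single-sample SEs have the published order of magnitude
  sej <- fit_eiw(sample_of(jute, "strength"))$se
  expect_gt(sej[["theta"]], 100)
  expect_lt(sej[["theta"]], 1000)
  expect_gt(sej[["beta"]], 0.05)
  expect_lt(sej[["beta"]], 0.5)

  expect_error(mle_standard_errors(jute, fit_ss(jute, "lse", se = FALSE)),
               "MLE only")
})

test_that("tidiers return the documented shapes", {
  fit <- fit_ss(carbon, "mle")
  td <- tidy(fit)
  expect_equal(td$term, c("theta1", "theta2", "beta", "R"))
  expect_equal(td$estimate[4], fit$r_hat)
  expect_equal(nrow(glance(fit)), 1)
  tf <- tidy(fit_eiw(sample_of(jute, "stress")))
  expect_equal(tf$term, c("theta", "beta"))
  expect_true(all(tf$std.error > 0))
})
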