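one_cell_config <- function(reps, methods = "mle", seed = 3, boot = NULL) {
  ss_sim_config(
    cases = tibble::tibble(theta1 = 0.5, theta2 = 0.4, beta = 0.5),
    sizes = tibble::tibble(n = 12, k = 15),
    reps = reps, methods = methods, seed = seed, boot = boot
  )
}

test_that("configuration validates its fields and maps m to k", {
  cfg <- ss_sim_config(sizes = tibble::tibble(n = 30, m = 40), reps = 5,
                       methods = "mle")
  expect_equal(cfg$sizes$k, 40)
  expect_error(ss_sim_config(cases = tibble::tibble(theta1 = -1, theta2 = 1, beta = 1)),
               "positive")
  expect_error(ss_sim_config(reps = 0), "at least 1")
  expect_error(ss_sim_config(methods = character(0)), "empty")
  expect_error(ss_sim_config(methods = "nope"))
  expect_error(ss_sim_config(boot = list(levels = 0.5)), "levels")
  # defaults carry the published design grid
  expect_equal(default_sim_sizes()$n, c(30, 35, 50, 70))
  expect_equal(default_sim_sizes()$k, c(40, 45, 60, 80))
  expect_equal(nrow(default_sim_cases()), 6)
})

test_that("a 1-rep study reproduces a direct fit on the same stream", {
  cfg <- one_cell_config(reps = 1, seed = 555)
  res <- run_ss_study(cfg)
  # regenerate the single replicate's data with the study's sub-seed scheme
  sub <- eiwss:::sim_sub_seed(555, 1, 1, 1)
  d <- eiwss:::with_preserved_seed(sub, ss_data(reiw(12, 0.5, 0.5),
                                                reiw(15, 0.4, 0.5)))
  direct <- fit_ss(d, "mle", se = FALSE)
  pt <- res$point
  expect_equal(pt$mean[pt$parameter == "r"], direct$r_hat)
  expect_equal(pt$mean[pt$parameter == "beta"], direct$beta)
  expect_equal(pt$mse[pt$parameter == "r"], (direct$r_hat - 5 / 9)^2)
})

test_that("study summaries are deterministic, complete and coherent", {
  res1 <- run_ss_study(one_cell_config(reps = 40, methods = c("mle", "lse")))
  res2 <- run_ss_study(one_cell_config(reps = 40, methods = c("mle", "lse")))
  expect_equal(res1$point, res2$point)
  pt <- res1$point
  expect_equal(nrow(pt), 2 * 4)
  expect_true(all(pt$n_used + pt$n_fail == 40))
  # bias^2 <= MSE up to float tolerance
  expect_true(all(pt$mse >= (pt$mean - pt$truth)^2 - 1e-12))
})

test_that("equal thetas give mean R near 1/2 and bootstrap lengths appear", {
  cfg <- ss_sim_config(
    cases = tibble::tibble(theta1 = 0.3, theta2 = 0.3, beta = 0.8),
    sizes = tibble::tibble(n = 20, k = 20),
    reps = 300, methods = "mle", seed = 12
  )
  res <- run_ss_study(cfg)
  r_row <- res$point[res$point$parameter == "r", ]
  mc_se <- sqrt(r_row$mse / r_row$n_used)
  expect_lt(abs(r_row$mean - 0.5), 3 * mc_se)

  with_boot <- ss_sim_config(
    cases = tibble::tibble(theta1 = 0.5, theta2 = 0.4, beta = 0.5),
    sizes = tibble::tibble(n = 10, k = 10),
    reps = 3, methods = "mle", seed = 2,
    boot = list(B = 60, levels = c(0.90, 0.95))
  )
  res_b <- run_ss_study(with_boot)
  expect_false(is.null(res_b$ci))
  expect_true(all(res_b$ci$mean_length > 0))
  # percentile lengths grow with the level on average
  ci <- sim_ci_table(res_b)
  expect_true(all(ci$L95_boot_p >= ci$L90_boot_p))
})

test_that("tables lay out as statistic rows by parameter columns", {
  res <- run_ss_study(one_cell_config(reps = 5))
  tab <- sim_point_table(res)
  expect_equal(nrow(tab), 2)                      # Mean and MSE rows
  expect_setequal(tab$statistic, c("Mean", "MSE"))
  expect_true(all(c("theta1", "theta2", "beta", "r") %in% names(tab)))

  # TSV round trip at 6 significant digits
  f <- withr::local_tempfile(fileext = ".tsv")
  out <- as.data.frame(lapply(tab, function(c) if (is.numeric(c)) signif(c, 6) else c))
  utils::write.table(out, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- utils::read.delim(f, check.names = FALSE)
  expect_equal(back$r, signif(tab$r, 6))
  expect_equal(back$beta, signif(tab$beta, 6))

  expect_error(sim_ci_table(res), "without a bootstrap")
})
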