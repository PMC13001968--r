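test_that("the SSE objective is exact arithmetic over both traits", {
  truth <- ecto_reference_truth()
  tr <- ecto_simulate(truth$params, truth$init, truth$wave_times)
  obs <- ecto_observed(truth$wave_times, tr$N, tr$P)
  expect_equal(sse_objective(truth$params, truth$init, obs), 0,
               tolerance = 1e-12)
  shifted <- ecto_observed(truth$wave_times, tr$N + 0.1, tr$P - 0.2)
  expect_equal(sse_objective(truth$params, truth$init, shifted),
               6 * 0.1^2 + 6 * 0.2^2, tolerance = 1e-9)
  expect_error(ecto_observed(truth$wave_times, tr$N[-1], tr$P), "length")
})

test_that("pathological parameters return the finite penalty, not an error", {
  obs <- ecto_observed(c(0, 10, 50), c(0.5, 0.5, 0.5), c(1, 1, 1))
  bad <- ecto_params(mu = 0, beta = -1, c1 = 10, G = 0.01)
  val <- sse_objective(bad, ecto_init(N0 = 0.5, P0 = 1, E0 = 0), obs)
  expect_identical(val, 1e6)
})

test_that("a noiseless fit started at the truth stays at the truth", {
  truth <- ecto_reference_truth()
  obs <- generate_trajectory_data(truth$params, truth$init, truth$wave_times,
                                  noise_sd = 0, seed = 11)
  spec <- recovery_spec()
  tru <- c(alpha = 0.098, beta = 0.2, gamma = 0.15)
  f <- ecto_fit_single(obs, spec, start = tru)
  expect_lte(f$sse, 1e-8)
  expect_equal(coef(f), tru, tolerance = 1e-4)
  # perturbed 5% start recovers the optimum
  f2 <- ecto_fit_single(obs, spec, start = tru * 1.05)
  expect_lte(f2$sse, 1e-6)
  expect_error(ecto_fit_single(obs, spec, start = c(alpha = -1, beta = 0.2,
                                                    gamma = 0.15)),
               "bounds")
})

test_that("fixed parameters pass through untouched and masks are honored", {
  truth <- ecto_reference_truth()
  obs <- generate_trajectory_data(truth$params, truth$init, truth$wave_times,
                                  noise_sd = 0.01, seed = 21)
  spec <- ecto_spec(free = c("alpha", "beta"),
                    fixed = c(mu = 0.123456789, gamma = 0.15, c1 = 0.5,
                              c2 = 0.2, c3 = 1.0, K = 0.54321, G = 1,
                              E0 = 0.05))
  f <- ecto_fit(obs, spec, n_starts = 2, seed = 3)
  expect_identical(coef(f, all = TRUE)[["mu"]], 0.123456789)
  expect_identical(coef(f, all = TRUE)[["K"]], 0.54321)
  expect_setequal(names(coef(f)), c("alpha", "beta"))
  # N0/P0 pinned to the first observed values under the data policy
  expect_identical(f$init$N0, obs$n_obs[1])
  expect_identical(f$init$P0, obs$p_obs[1])
})

test_that("multistart is reproducible and improves monotonically", {
  truth <- ecto_reference_truth()
  obs <- generate_trajectory_data(truth$params, truth$init, truth$wave_times,
                                  noise_sd = 0.01, seed = 31)
  spec <- recovery_spec()
  f1 <- ecto_fit(obs, spec, n_starts = 3, seed = 99)
  f2 <- ecto_fit(obs, spec, n_starts = 3, seed = 99)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$sse, f2$sse)
  expect_identical(f1$sse_starts, f2$sse_starts)
  # extending the same seed stream can only improve the best SSE
  sse_by_n <- vapply(c(1, 2, 4), function(n) {
    ecto_fit(obs, spec, n_starts = n, seed = 99)$sse
  }, numeric(1))
  expect_true(all(diff(sse_by_n) <= 1e-12))
  # start-distribution bookkeeping
  expect_equal(unname(f1$start_stats["min"]), min(f1$sse_starts))
  expect_lte(f1$start_stats["min"], f1$start_stats["mean"])
  expect_lte(f1$start_stats["mean"], f1$start_stats["max"])
})

test_that("fit methods expose coefficients, predictions and residuals", {
  obs <- entropy_to_observed(dental_entropy(), "supp", "time")
  f <- ecto_fit(obs, ecto_spec_reduced(), n_starts = 3, seed = 7)
  expect_s3_class(f, "ecto_fit")
  expect_equal(f$sse, sum(residuals(f)$n_resid^2) + sum(residuals(f)$p_resid^2),
               tolerance = 1e-9)
  pr <- predict(f, times = seq(0, 3, by = 0.5))
  expect_s3_class(pr, "ecto_trajectory")
  expect_equal(nrow(pr), 7L)
  expect_equal(fitted(f)$n_fit, pr$N[pr$time %in% 0:3], tolerance = 1e-8)
  expect_output(print(f), "ECTO model fit")
  expect_output(print(summary(f)), "Multistart SSE")
  sims <- simulate(f, nsim = 3, seed = 5)
  expect_length(sims, 3L)
  expect_s3_class(sims[[1]], "ecto_observed")
  # all-fixed specification: pure evaluation, no optimizer
  spec0 <- ecto_spec(fixed = c(mu = 0.1, alpha = 0.2))
  f0 <- ecto_fit(obs, spec0)
  expect_length(coef(f0), 0L)
  expect_true(f0$converged)
})
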