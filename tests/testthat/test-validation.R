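test_that("fit metrics match hand-computed residual sums", {
  m <- fit_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(m[c("rmse", "r_squared", "pearson_r")]), c(0, 1, 1))
  m2 <- fit_metrics(c(0, 1), c(1, 0))
  expect_equal(unname(m2["rmse"]), 1)
  expect_equal(unname(m2["pearson_r"]), -1)
  # hand-computed: SSE 0.10, SStot 5, cov 4.7 / (sqrt(5) * sqrt(4.5))
  obs <- c(1, 2, 3, 4); pred <- c(1.1, 1.9, 3.2, 3.8)
  m3 <- fit_metrics(obs, pred)
  expect_equal(unname(m3["rmse"]), sqrt(0.10 / 4), tolerance = 1e-12)
  expect_equal(unname(m3["r_squared"]), 1 - 0.10 / 5, tolerance = 1e-12)
  expect_equal(unname(m3["pearson_r"]), 4.7 / sqrt(5 * 4.5), tolerance = 1e-12)
  r <- 4.7 / sqrt(5 * 4.5)
  tstat <- r * sqrt(2) / sqrt(1 - r^2)
  expect_equal(unname(m3["pearson_p"]), 2 * stats::pt(-abs(tstat), df = 2),
               tolerance = 1e-9)
  expect_error(fit_metrics(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(fit_metrics(1:3, 1:4), "length")
})

test_that("DTW handles warps, is symmetric, and matches exhaustive search", {
  expect_equal(dtw_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(dtw_distance(c(1, 2, 3), c(1, 2, 2, 3)), 0)
  expect_equal(dtw_distance(c(0, 0), c(1, 1)), 2)
  expect_error(dtw_distance(numeric(0), 1), "non-empty")
  set.seed(13)
  for (i in 1:15) {
    a <- round(runif(sample(1:6, 1), -2, 2), 2)
    b <- round(runif(sample(1:6, 1), -2, 2), 2)
    d <- dtw_distance(a, b)
    expect_equal(d, dtw_oracle(a, b), tolerance = 1e-12)
    expect_equal(d, dtw_distance(b, a), tolerance = 1e-12)
    expect_gte(d, 0)
  }
  # zero iff identical after collapsing consecutive duplicates
  expect_equal(dtw_distance(c(1, 1, 2, 2, 3), c(1, 2, 3, 3)), 0)
  expect_gt(dtw_distance(c(1, 2, 3), c(1, 3, 2)), 0)
})

test_that("leave-one-wave-out recovers exact predictions for an exact model", {
  truth <- ecto_reference_truth()
  obs <- generate_trajectory_data(truth$params, truth$init, truth$wave_times,
                                  noise_sd = 0, seed = 4)
  spec0 <- ecto_spec(fixed = c(mu = 0.1, alpha = 0.098, beta = 0.2,
                               gamma = 0.15, c1 = 0.5, c2 = 0.2, c3 = 1.0,
                               K = 0.5, G = 1, E0 = 0.05))
  loo <- loo_validate(obs, spec0, n_starts = 2, seed = 8)
  expect_equal(nrow(loo$folds), 6L)
  expect_lt(max(loo$rmse), 1e-6)
  expect_output(print(loo), "Aggregate LOO RMSE")
  # four waves give four folds
  obs4 <- ecto_observed(obs$wave_time[1:4], obs$n_obs[1:4], obs$p_obs[1:4])
  loo4 <- loo_validate(obs4, spec0, n_starts = 2, seed = 8)
  expect_equal(nrow(loo4$folds), 4L)
  expect_error(loo_validate(obs4[1:2, ], spec0), "at least 3")
})

test_that("sensitivity scan reports two rows per free parameter", {
  obs <- entropy_to_observed(dental_entropy(), "supp", "time")
  f <- ecto_fit(obs, ecto_spec_reduced(), n_starts = 4, seed = 12)
  sc <- sensitivity_scan(f)
  expect_s3_class(sc, "ecto_sensitivity")
  expect_equal(nrow(sc), 2L * length(coef(f)))
  expect_setequal(unique(sc$direction), c("-10%", "+10%"))
  expect_equal(sc$pct_change,
               100 * (sc$total_rmse - attr(sc, "baseline_rmse")) /
                 attr(sc, "baseline_rmse"))
  # perturbing a structurally sensitive parameter changes the RMSE
  expect_gt(max(abs(sc$pct_change[sc$parameter == "alpha"])), 0)
})

test_that("a dead parameter shows exactly zero sensitivity", {
  truth <- ecto_reference_truth()
  obs <- generate_trajectory_data(truth$params, truth$init, truth$wave_times,
                                  noise_sd = 0.01, seed = 17)
  # E0 = 0 and gamma = 0 make the stress channel identically zero, so c3
  # multiplies a dead signal
  spec <- ecto_spec(free = c("alpha", "c3"),
                    fixed = c(mu = 0.1, beta = 0.2, gamma = 0, c1 = 0.5,
                              c2 = 0.2, K = 0.5, G = 1, E0 = 0),
                    lower = c(E0 = 0))
  f <- ecto_fit(obs, spec, n_starts = 3, seed = 17)
  sc <- sensitivity_scan(f)
  expect_equal(sc$pct_change[sc$parameter == "c3"], c(0, 0), tolerance = 1e-10)
  # refit-others mode keeps the report structure
  sc2 <- sensitivity_scan(f, mode = "perturb_refit_others")
  expect_equal(nrow(sc2), 4L)
})
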