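test_that("selection pressure and metabolic cost evaluate term by term", {
  p0 <- ecto_params()
  expect_equal(selection_pressure(2, 3, p0), 0)
  # beta enters squared: sign cannot flip the damping
  pneg <- ecto_params(alpha = 1, beta = -0.5)
  expect_equal(selection_pressure(0, 1, pneg), 0.25)
  p3 <- set3_params()
  expect_equal(selection_pressure(1, 1, p3), 0.098 + 0.17117^2,
               tolerance = 1e-12)

  expect_equal(metabolic_cost(c(N = 4, P = 7, E_stress = 2), p0), 0)
  pm <- ecto_params(c1 = 2.0, c2 = 0.21)
  expect_equal(metabolic_cost(c(N = 1, P = 0.5, E_stress = 9), pm), 1.21)
  # forcing at phase zero is inert
  pf <- ecto_params(c1 = 1, c3 = 1, A = 1, omega = 2, forcing = TRUE)
  st <- c(N = 0.5, P = 0.5, E_stress = 0.2)
  expect_equal(metabolic_cost(st, pf, t = 5, t0 = 5),
               metabolic_cost(st, ecto_params(c1 = 1, c3 = 1), t = 5))
})

test_that("the RHS matches hand-evaluated derivatives", {
  p0 <- ecto_params(mu = 0.3, alpha = 0.2, beta = 0.4, gamma = 0.1,
                    c1 = 1, c2 = 1, c3 = 1)
  expect_equal(unname(ecto_rhs(0, c(N = 0, P = 0, E_stress = 0), p0)),
               c(0, 0, 0))
  plin <- ecto_params(mu = 0.1)
  expect_equal(unname(ecto_rhs(0, c(N = 2, P = 3, E_stress = 1), plin)),
               c(0.2, 0.3, 0))
  # reference parameterization, term-by-term oracle
  p3 <- set3_params()
  st <- c(N = 0.9, P = 0.93, E_stress = 0.01)
  s <- 0.098 * 0.9 + 0.17117^2 * 0.93
  emet <- 2.0 * 0.93 + 0.21 * 0.9
  want <- c(1e-5 * 0.9 - s * 0.9,
            1e-5 * 0.93 - 0.17117 * 0.93 * emet / 1,
            0.03 * 0.01 * 0.9 / (0.9 + 0.5))
  expect_equal(unname(ecto_rhs(0, st, p3)), want, tolerance = 1e-12)
  expect_error(ecto_rhs(1, c(N = NaN, P = 0, E_stress = 0), p3), "t = 1")
})

test_that("simulation agrees with closed-form special cases", {
  # exponential growth: mu only
  pe <- ecto_params(mu = 0.2)
  tr <- ecto_simulate(pe, ecto_init(N0 = 0.5, P0 = 0.3, E0 = 0), c(0, 4))
  expect_equal(tr$N[2], 0.5 * exp(0.8), tolerance = 1e-7)
  expect_equal(tr$P[2], 0.3 * exp(0.8), tolerance = 1e-7)
  # hyperbolic decay: alpha only
  ph <- ecto_params(alpha = 0.5)
  trh <- ecto_simulate(ph, ecto_init(N0 = 1, P0 = 0, E0 = 0), c(0, 2))
  expect_equal(trh$N[2], 0.5, tolerance = 1e-7)
  # exponential stress growth under constant N
  ps <- ecto_params(gamma = 0.03, K = 0.5)
  trs <- ecto_simulate(ps, ecto_init(N0 = 0.5, P0 = 0, E0 = 0.01), c(0, 10))
  expect_equal(trs$E_stress[2], 0.01 * exp(0.03 * 0.5 / (0.5 + 0.5) * 10),
               tolerance = 1e-7)
})

test_that("trajectories start at the initial condition and honor granularity", {
  p3 <- set3_params()
  init <- set3_init()
  one <- ecto_simulate(p3, init, times = 0)
  expect_equal(nrow(one), 1L)
  expect_equal(unlist(one[1, c("N", "P", "E_stress")]),
               c(N = 0.9, P = 0.93, E_stress = 0.01))
  coarse <- ecto_simulate(p3, init, times = c(0, 5, 10))
  fine <- ecto_simulate(p3, init, times = seq(0, 10, by = 0.5))
  expect_equal(coarse$N, fine$N[fine$time %in% c(0, 5, 10)], tolerance = 1e-6)
  expect_equal(coarse$P, fine$P[fine$time %in% c(0, 5, 10)], tolerance = 1e-6)
  # evaluation may start after t0; the integration still begins at t0
  late <- ecto_simulate(p3, init, times = c(5, 10))
  expect_equal(late$N, coarse$N[2:3], tolerance = 1e-8)
})

test_that("nonnegative parameters and states keep every component nonnegative", {
  set.seed(7)
  for (i in 1:15) {
    p <- ecto_params(mu = runif(1, 0, 0.3), alpha = runif(1, 0, 0.5),
                     beta = runif(1, 0, 0.5), gamma = runif(1, 0, 0.3),
                     c1 = runif(1, 0, 1), c2 = runif(1, 0, 1),
                     c3 = runif(1, 0, 1), K = runif(1, 0.1, 2))
    init <- ecto_init(N0 = runif(1, 0, 1), P0 = runif(1, 0, 1),
                      E0 = runif(1, 0, 0.2))
    tr <- ecto_simulate(p, init, seq(0, 20, by = 2))
    expect_true(all(tr$N >= -1e-10 & tr$P >= -1e-10 & tr$E_stress >= -1e-10))
    # stress is nondecreasing whenever gamma >= 0 and N >= 0
    expect_true(all(diff(tr$E_stress) >= -1e-10))
  }
})

test_that("the uncoupled variant equals the coupled system with couplings off", {
  pc <- ecto_params(mu = 0.05, alpha = 0.1, beta = 0, gamma = 0.1,
                    c1 = 0.5, c2 = 0, c3 = 0, K = 0.5)
  pu <- ecto_params(mu = 0.05, alpha = 0.1, beta = 0.7, gamma = 0.1,
                    c1 = 0.5, c2 = 0.3, c3 = 2, K = 0.5, coupled = FALSE)
  init <- ecto_init(N0 = 0.8, P0 = 0.6, E0 = 0.05)
  tt <- seq(0, 20, by = 4)
  trc <- ecto_simulate(pc, init, tt)
  tru <- ecto_simulate(pu, init, tt)
  expect_equal(trc$N, tru$N, tolerance = 1e-8)
  expect_equal(trc$P, tru$P, tolerance = 1e-8)
  # uncoupled P is pure exponential persistence
  expect_equal(tru$P, 0.6 * exp(0.05 * tt), tolerance = 1e-6)
})

test_that("state blow-up raises a structured simulation error", {
  bad <- ecto_params(mu = 0, beta = -1, c1 = 10, G = 0.01)
  expect_error(ecto_simulate(bad, ecto_init(N0 = 0.5, P0 = 1, E0 = 0),
                             c(0, 50)),
               class = "ecto_simulation_error")
  expect_error(ecto_simulate(set3_params(), set3_init(), c(1, 0.5)),
               "increasing")
})
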