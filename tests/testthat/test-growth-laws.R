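test_that("stationary points and basic rates of the empirical laws", {
  expect_equal(growth_rate(growth_law("logistic",
    list(a = 0.1, K = 2, V0 = 0.1)), 2), 0)
  expect_equal(growth_rate(growth_law("gompertz",
    list(a = 0.1, K = 2, V0 = 0.1)), 2), 0)
  expect_equal(growth_rate(growth_law("linear", list(a = 0.31, V0 = 0.1)),
                           c(0.5, 5)), c(0.31, 0.31))
  expect_equal(growth_rate(growth_law("surface", list(a = 0.2, V0 = 0.1)), 8),
               0.2 * 4)
  # proliferative rim: full volume when the tumor is thinner than the rim
  rim <- growth_law("rim", list(a = 0.1, d = 1, V0 = 0.1))
  expect_equal(growth_rate(rim, 0.1), 0.1 * 0.1)
  expect_error(growth_law("banana", list(a = 1)), "unknown law")
  expect_error(growth_law("logistic", list(a = 1)), "needs parameters")
})

test_that("exponential-linear law hugs its piecewise envelope", {
  lam0 <- 0.08; lam1 <- 0.31
  law <- growth_law("exponential_linear",
                    list(lambda0 = lam0, lambda1 = lam1, psi = 20, V0 = 0.1))
  V <- exp(seq(log(0.05), log(50), length.out = 120))
  g <- growth_rate(law, V)
  envelope <- pmin(lam0 * V, lam1)
  expect_true(all(abs(g - envelope) / envelope < 0.05))
  # stable far into the linear phase (no overflow at psi = 20)
  expect_equal(growth_rate(law, 1e8), lam1, tolerance = 1e-6)
})

test_that("closed-form trajectories for exponential and linear laws", {
  exp_law <- growth_law("exponential", list(a = 0.08, V0 = 0.29))
  sim <- simulate_law(exp_law, t_grid = c(0, 5))
  expect_equal(sim$V[2], 0.29 * exp(0.4), tolerance = 1e-7)

  lin_law <- growth_law("linear", list(a = 0.31, V0 = 0.29))
  sim <- simulate_law(lin_law, t_grid = c(0, 10))
  expect_equal(sim$V[2], 0.29 + 3.1, tolerance = 1e-8)

  # EL with an enormous linear rate never leaves the exponential phase
  el <- growth_law("exponential_linear",
                   list(lambda0 = 0.08, lambda1 = 1e4, V0 = 0.29))
  sim <- simulate_law(el, t_grid = c(0, 5))
  expect_equal(sim$V[2], 0.29 * exp(0.4), tolerance = 1e-3)
})

test_that("all laws grow without drug; only logistic/Gompertz saturate", {
  laws <- list(
    growth_law("linear", list(a = 0.31, V0 = 0.3)),
    growth_law("exponential", list(a = 0.08, V0 = 0.3)),
    growth_law("logistic", list(a = 0.2, K = 3, V0 = 0.3)),
    growth_law("gompertz", list(a = 0.2, K = 3, V0 = 0.3)),
    growth_law("exponential_linear",
               list(lambda0 = 0.08, lambda1 = 0.31, V0 = 0.3)),
    growth_law("surface", list(a = 0.2, V0 = 0.3)),
    growth_law("rim", list(a = 0.3, d = 0.2, V0 = 0.3)))
  tg <- seq(0, 150, by = 5)
  Vends <- vapply(laws, function(l) {
    sim <- simulate_law(l, t_grid = tg)
    expect_true(all(diff(sim$V) > -1e-9))  # non-decreasing (saturating laws
    expect_gt(sim$V[4], sim$V[1])          # flatten at K); growing early on
    utils::tail(sim$V, 1)
  }, numeric(1))
  names(Vends) <- vapply(laws, `[[`, "", "name")
  # bounded laws converge to K = 3; the rest pass any bound given time
  expect_lt(Vends[["logistic"]], 3 + 1e-6)
  expect_lt(Vends[["gompertz"]], 3 + 1e-6)
  expect_true(all(Vends[setdiff(names(Vends),
                                c("logistic", "gompertz"))] > 10))
})

test_that("kill term couples to total volume for the empirical laws", {
  law <- growth_law("exponential", list(a = 0.08, V0 = 0.29, k_drug = 0.01))
  sch <- dose_schedule(1, 50)
  sim <- simulate_law(law, sch, seq(0, 3, by = 0.5))
  # cumulative kill over a dose: log V drops by k*D/k_elim relative to control
  expect_equal(utils::tail(sim$V, 1),
               0.29 * exp(0.08 * 3 - 0.01 * 50 / sch$k_elim *
                            (1 - exp(-sch$k_elim * 2))),
               tolerance = 1e-6)
})
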