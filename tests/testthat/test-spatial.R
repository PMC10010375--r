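test_that("shell profile satisfies its boundary conditions and limits", {
  R <- 0.6; Rn <- 0.3; cb <- 1
  for (rho in c(0.5, 2, 5, 20, 200)) {
    # outer Dirichlet condition
    expect_equal(shell_profile(R, R, Rn, rho, cb), cb, tolerance = 1e-10)
    # zero flux at the necrotic boundary (one-sided difference)
    h <- 1e-7
    dc <- (shell_profile(Rn + h, R, Rn, rho, cb) -
             shell_profile(Rn, R, Rn, rho, cb)) / h
    expect_lt(abs(dc), 1e-4 * cb / (R - Rn) + rho * h)
    # bounds and monotone increase toward the surface
    rr <- seq(Rn, R, length.out = 50)
    cc <- shell_profile(rr, R, Rn, rho, cb)
    expect_true(all(cc >= 0 & cc <= cb + 1e-12))
    expect_true(all(diff(cc) >= -1e-12))
  }
  # uniform limit
  rr <- seq(Rn, R, length.out = 9)
  expect_equal(shell_profile(rr, R, Rn, 0, 2.5), rep(2.5, 9))
  expect_error(shell_profile(0.1, R, Rn, 1, 1), "lie in")
})

test_that("closed-form profile matches the finite-difference BVP oracle", {
  R <- 0.6; Rn <- 0.3; cb <- 1
  r_eval <- seq(Rn, R, length.out = 11)
  for (rho in c(1, 5)) {
    got <- shell_profile(r_eval, R, Rn, rho, cb)
    ref <- fd_shell_profile(r_eval, R, Rn, rho, cb)
    expect_lt(max(abs(got - ref)), 1e-6)
  }
  # no-core geometry as well
  got <- shell_profile(seq(0.01, 0.5, length.out = 9), 0.5, 0, 3, 1)
  ref <- fd_shell_profile(seq(0.01, 0.5, length.out = 9), 0.5, 1e-9, 3, 1)
  expect_equal(got, ref, tolerance = 1e-4)
})

test_that("penetration ratio is 1 at rho = 0 and strictly decreasing", {
  expect_equal(penetration_ratio(0.6, 0.3, 0), 1)
  rhos <- seq(0, 25, length.out = 50)
  pr <- penetration_ratio(0.6, 0.3, rhos)
  expect_true(all(diff(pr) < 0))
  expect_true(all(pr > 0 & pr <= 1))
  # surface kill: essentially nothing reaches the core at large rho
  expect_lt(penetration_ratio(0.6, 0.3, 100), 1e-10)
})

test_that("shell-integrated kill matches its exact and quadrature limits", {
  R <- 0.6; Rn <- 0.3; cb <- 1.7; k <- 5.7e-3
  G <- 1 - (Rn / R)^3
  # uniform drug recovers k * c_b * G exactly
  expect_identical(effective_kill(R, Rn, 0, cb, k), k * cb * G)
  expect_identical(effective_kill(R, Rn, 5, 0, k), 0)
  # high-resolution Simpson oracle on the closed-form profile
  for (rho in c(2, 5, 15)) {
    n <- 40001
    rr <- seq(Rn, R, length.out = n)
    f <- shell_profile(rr, R, Rn, rho, cb) * rr^2
    h <- rr[2] - rr[1]
    simpson <- h / 3 * (f[1] + f[n] + 4 * sum(f[seq(2, n - 1, 2)]) +
                          2 * sum(f[seq(3, n - 2, 2)]))
    expect_equal(effective_kill(R, Rn, rho, cb, k), k * 3 * simpson / R^3,
                 tolerance = 1e-7)
  }
})

test_that("spatial trajectory reduces to the non-spatial model at rho = 0", {
  p <- cdx_dl_params()
  sch <- protocol1_schedule()
  tg <- seq(0, 30, by = 2)
  base <- simulate_dl(p, sch, tg)
  sp0 <- simulate_spatial(p, sch, tg, spatial_drug_params(0))
  expect_equal(sp0$V, base$V, tolerance = 1e-6)
  expect_equal(sp0$G, base$G, tolerance = 1e-6)
})

test_that("reduced penetration weakens the drug effect monotonically", {
  p <- cdx_dl_params()
  sch <- protocol1_schedule()
  tg <- seq(0, 30, by = 2)
  Vend <- vapply(c(0, 2, 5, 10), function(rho)
    utils::tail(simulate_spatial(p, sch, tg, spatial_drug_params(rho))$V, 1),
    numeric(1))
  expect_true(all(diff(Vend) > 0))
  # finer sweep: final volume non-decreasing in rho
  Vend2 <- vapply(seq(0, 12, length.out = 20), function(rho)
    utils::tail(simulate_spatial(p, sch, tg, spatial_drug_params(rho))$V, 1),
    numeric(1))
  expect_true(all(diff(Vend2) >= -1e-8))
})
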