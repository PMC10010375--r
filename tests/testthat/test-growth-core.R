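test_that("critical volume is the sphere volume of the critical radius", {
  expect_equal(critical_volume(0.41), 4 * pi / 3 * 0.41^3)
  expect_equal(critical_volume(0.41), 0.2887, tolerance = 1e-3)
  for (r in c(0.1, 0.41, 1.0))
    expect_equal(radius_from_volume(critical_volume(r)), r, tolerance = 1e-12)
  expect_error(critical_volume(0), "positive")
  expect_error(critical_volume(-1), "positive")
})

test_that("necrotic radius solves the diffusion constraint", {
  # onset: constraint reduces to R^2 = R_c^2, core has zero radius
  expect_equal(solve_necrotic_radius(0.41, 0.41), 0)
  # analytic, Brent and the independent sign-scan oracle agree
  for (R in c(0.5, 0.82, 1.5, 4)) {
    rn_a <- solve_necrotic_radius(R, 0.41)
    rn_b <- solve_necrotic_radius(R, 0.41, method = "brent")
    rn_o <- scan_necrotic_radius(R, 0.41)
    expect_equal(rn_a, rn_o, tolerance = 1e-8)
    expect_equal(rn_b, rn_o, tolerance = 1e-8)
    # residual of the constraint itself
    expect_lt(abs(R^2 - 3 * rn_a^2 + 2 * rn_a^3 / R - 0.41^2), 1e-9)
  }
  # large-tumor limit: rim thickness R - R_n -> R_c / sqrt(3)
  R <- 100 * 0.41
  expect_equal(R - solve_necrotic_radius(R, 0.41), 0.41 / sqrt(3),
               tolerance = 2e-3)
  expect_error(solve_necrotic_radius(0.3, 0.41), "proliferating")
})

test_that("growth fraction: branches, continuity, monotonicity, oracle", {
  Rc <- 0.41
  Vc <- critical_volume(Rc)
  # fully proliferating branch
  expect_identical(growth_fraction(0.1, Rc), 1)
  expect_identical(growth_fraction(Vc, Rc), 1)
  # continuity at onset
  expect_lt(1 - growth_fraction(Vc * (1 + 1e-6), Rc), 1e-3)
  # strictly decreasing beyond onset
  V <- seq(Vc * 1.01, 8, length.out = 60)
  expect_true(all(diff(growth_fraction(V, Rc)) < 0))
  # cross-check against the constraint-scan oracle at V = 1
  R1 <- radius_from_volume(1.0)
  rn <- scan_necrotic_radius(R1, Rc)
  expect_equal(growth_fraction(1.0, Rc), 1 - (rn / R1)^3, tolerance = 1e-8)
  expect_error(growth_fraction(-1, Rc), "positive")
})

test_that("necrotic area fraction of a central section", {
  expect_equal(necrotic_area_fraction(1), 0)
  # core at 80% of the radius: G = 1 - 0.8^3 = 0.488, area fraction 0.64
  expect_equal(necrotic_area_fraction(1 - 0.8^3), 0.64, tolerance = 1e-12)
  G <- seq(0.05, 1, length.out = 40)
  expect_true(all(diff(necrotic_area_fraction(G)) < 0))
  expect_error(necrotic_area_fraction(0), "\\(0, 1\\]")
  expect_error(necrotic_area_fraction(1.2), "\\(0, 1\\]")
})

test_that("right-hand side: exponential limit, shrinkage, constraint rate", {
  p <- cdx_dl_params()
  # fully proliferating, no drug: pure exponential growth
  d <- dl_rhs(list(V = 0.1, R_n = 0), p, conc = 0)
  expect_equal(d$dV, p$lambda_net * 0.1)
  expect_equal(d$G, 1)
  expect_equal(d$dR_n, 0)
  # strong constant drug beats growth: volume shrinks
  c_hi <- 2 * p$lambda_net / p$k_drug
  expect_lt(dl_rhs(list(V = 0.1, R_n = 0), p, conc = c_hi)$dV, 0)
  # limited phase: dR_n/dt from the differentiated constraint matches a
  # finite difference of the algebraic solve along the volume direction
  V <- 1.4
  R <- radius_from_volume(V)
  Rn <- solve_necrotic_radius(R, p$R_c)
  d <- dl_rhs(list(V = V, R_n = Rn), p, conc = 0)
  h <- 1e-6
  Rn2 <- solve_necrotic_radius(radius_from_volume(V + h * d$dV), p$R_c)
  expect_equal(d$dR_n, (Rn2 - Rn) / h, tolerance = 1e-4)
})

test_that("untreated simulation matches the closed-form exponential phase", {
  # horizon inside the fully proliferating phase (V stays below V_c)
  p <- cdx_dl_params()
  tg <- seq(0, 1, by = 0.25)
  sim <- simulate_dl(p, t_grid = tg)
  expect_equal(sim$V, 0.25 * exp(0.12 * tg), tolerance = 1e-7)
  # never-necrotic limit (huge critical radius): exponential to 1e-6 over
  # the full horizon
  p2 <- dl_params(0.12, 0.05, 5.7e-3, R_c = 100, V0 = 0.25)
  tg2 <- seq(0, 30, by = 2)
  sim2 <- simulate_dl(p2, t_grid = tg2)
  expect_equal(sim2$V, 0.25 * exp(0.12 * tg2), tolerance = 1e-6)
  expect_true(all(sim2$G == 1))
})

test_that("differentiated-constraint and algebraic integrations agree", {
  set.seed(42)
  sch <- protocol1_schedule()
  tg <- seq(0, 30, by = 2)
  for (i in 1:20) {
    p <- dl_params(lambda_net = runif(1, 0.05, 0.25),
                   lambda_nec = runif(1, 0.01, 0.12),
                   k_drug = runif(1, 1e-3, 1e-2),
                   R_c = runif(1, 0.25, 0.6),
                   V0 = runif(1, 0.1, 0.6))
    a <- simulate_dl(p, sch, tg, method = "algebraic")
    b <- simulate_dl(p, sch, tg, method = "ode")
    expect_equal(a$V, b$V, tolerance = 1e-5)
    expect_equal(a$G, b$G, tolerance = 1e-5)
  }
})

test_that("compiled RK4 core agrees with the deSolve reference", {
  p <- cdx_dl_params()
  sch <- protocol1_schedule()
  tg <- seq(0, 30, by = 1)
  ref <- simulate_dl(p, sch, tg)
  fast <- dlgrowth:::.predict_volumes(
    "dl", c(lambda_net = p$lambda_net, lambda_nec = p$lambda_nec,
            k_drug = p$k_drug, R_c = p$R_c, V0 = p$V0),
    tg, sch$times, sch$amounts, sch$k_elim)
  expect_equal(fast, ref$V, tolerance = 1e-6)
})

test_that("trajectory invariants hold along a dosed trajectory", {
  p <- cdx_dl_params()
  sch <- protocol1_schedule(100)   # strong dosing to force a rebound
  tg <- seq(0, 30, by = 0.25)
  sim <- simulate_dl(p, sch, tg)
  # state consistency at every output time
  expect_equal(sim$V, 4 * pi / 3 * sim$R^3, tolerance = 1e-9)
  expect_equal(sim$G, 1 - (sim$R_n / sim$R)^3, tolerance = 1e-9)
  expect_true(all(sim$G > 0 & sim$G <= 1))
  expect_true(all(sim$R_n >= 0 & sim$R_n < sim$R))
  # G continuous through the onset crossing: no jumps on a fine grid
  expect_lt(max(abs(diff(sim$G))), 0.05)
  # growth-fraction rebound: when treatment shrinks the tumor, G recovers
  i_dose <- which(tg == 15)
  i_post <- which(tg == 18)
  expect_lt(sim$V[i_post], sim$V[i_dose])     # shrinking after the dose
  expect_gt(sim$G[i_post], sim$G[i_dose])     # growing fraction rebounds
})

test_that("larger tumors have smaller growth fractions", {
  # monotone response across a family of initial volumes (same parameters)
  G_end <- vapply(c(0.3, 0.6, 1.2, 2.4), function(v0) {
    p <- dl_params(0.12, 0.05, 5.7e-3, 0.41, v0)
    utils::tail(simulate_dl(p, t_grid = c(0, 5, 10))$G, 1)
  }, numeric(1))
  expect_true(all(diff(G_end) < 0))
})
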