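test_that("individual fit recovers noise-free generating parameters", {
  th <- c(lambda_net = 0.12, lambda_nec = 0.05, k_drug = 5.7e-3,
          R_c = 0.41, V0 = 0.25)
  tt <- c(0, 2, 5, 7, 9, 12, 14, 16, 19, 21, 23, 26, 28, 30)
  ke <- decay_rate_from_half_life(0.5)
  V <- dlgrowth:::.predict_volumes("dl", th, tt, c(1, 8, 15), rep(50, 3), ke)
  est <- fit_individual(list(times = tt, y = V, dose_t = c(1, 8, 15),
                             dose_a = rep(50, 3)), "dl", k_elim = ke)
  expect_true(all(abs(est - th) / th < 0.01))
})

test_that("individual fit flattens on a constant series", {
  tt <- seq(0, 21, by = 3)
  sub <- list(times = tt, y = rep(0.2, length(tt)),
              dose_t = numeric(0), dose_a = numeric(0))
  est <- fit_individual(sub, "el")
  f <- dlgrowth:::.predict_volumes("el", est, tt, numeric(0), numeric(0),
                                   decay_rate_from_half_life(0.5))
  expect_lt(max(abs(f - 0.2) / 0.2), 0.02)
  expect_lt(est[["lambda0"]], 0.01)
})

test_that("individual fit enforces its data requirements", {
  expect_error(fit_individual(list(times = c(0, 1, 2), y = c(1, 1, 1),
                                   dose_t = numeric(0),
                                   dose_a = numeric(0)), "dl"),
               "at least 4")
  expect_error(fit_individual(list(times = 0:3, y = rep(1, 4),
                                   dose_t = numeric(0),
                                   dose_a = numeric(0)), "dl"),
               "fewer observations than parameters")
})

test_that("SAEM recovers a degenerate cohort exactly", {
  # no heterogeneity, (almost) no noise: fixed effects to < 0.5%, iiv -> 0
  fe <- c(lambda_net = 0.12, lambda_nec = 0.05, k_drug = 5.7e-3,
          R_c = 0.41, V0 = 0.25)
  pop <- population_model(fe, numeric(0),
                          residual = list(type = "proportional", sd = 1e-4))
  coh <- generate_cohort(small_design(6), pop, "dl", seed = 3)
  fit <- fit_population(coh, "dl",
                        saem_control(n_burn = 100, n_smooth = 60,
                                     n_chains = 1),
                        seed = 2)
  expect_true(all(abs(fit$population$fixed_effects - fe) / fe < 0.005))
  expect_true(all(fit$population$iiv_sd / fe < 0.05))
  expect_lt(fit$sigma, 0.01)
})

test_that("SAEM is deterministic given a seed", {
  coh <- generate_cohort(small_design(4), dl_population_default(), "dl",
                         seed = 8)
  ctl <- saem_control(n_burn = 20, n_smooth = 10, n_chains = 1)
  f1 <- fit_population(coh, "dl", ctl, seed = 42)
  f2 <- fit_population(coh, "dl", ctl, seed = 42)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$population$fixed_effects, f2$population$fixed_effects)
  f3 <- fit_population(coh, "dl", ctl, seed = 43)
  expect_false(identical(f1$trace, f3$trace))
})

test_that("importance-sampling likelihood matches dense quadrature", {
  # one random effect only (initial volume): the marginal likelihood is a
  # one-dimensional integral that a dense trapezoid rule computes exactly,
  # an independent oracle for the importance sampler
  fe <- c(lambda_net = 0.1, lambda_nec = 0.03, k_drug = 4e-3,
          R_c = 0.4, V0 = 0.3)
  pop <- population_model(fe, c(V0 = 0.06),
                          residual = list(type = "proportional", sd = 0.08))
  coh <- generate_cohort(small_design(5), pop, "dl", seed = 12)
  fit <- fit_population(coh, "dl",
                        saem_control(n_burn = 80, n_smooth = 40,
                                     n_chains = 1), seed = 2,
                        init = pop, estimated = "V0")
  ic <- information_criteria(fit, coh, n_is = 500, seed = 9)
  mu <- log(fit$population$fixed_effects)
  om <- fit$omega[["V0"]]
  subs <- dlgrowth:::.cohort_subjects(coh)
  ll_quad <- sum(vapply(subs, function(s) {
    phi <- seq(mu[["V0"]] - 6 * om, mu[["V0"]] + 6 * om, length.out = 601)
    integrand <- vapply(phi, function(ph) {
      th <- fit$population$fixed_effects
      th["V0"] <- exp(ph)
      f <- dlgrowth:::.predict_volumes("dl", th, s$times, s$dose_t,
                                       s$dose_a, coh$k_elim, hmax = 0.05)
      exp(sum(stats::dnorm(s$y, f, fit$sigma * f, log = TRUE))) *
        stats::dnorm(ph, mu[["V0"]], om)
    }, numeric(1))
    log(sum(integrand) * (phi[2] - phi[1]))
  }, numeric(1)))
  expect_lt(abs(ic$loglik - ll_quad), 0.1)
  expect_true(is.finite(ic$aic))
})

test_that("nested-model likelihood ordering and perfect-fit rmse", {
  # a cohort generated from the EL model with the drug term disabled: the
  # fit that also estimates k_drug (larger model) cannot have lower
  # log-likelihood than the fit with k_drug fixed at its tiny init
  obs <- c(0, 3, 6, 9, 12, 15, 18, 21)
  des <- cohort_design(list(list(n = 6, dose_days = c(1, 8, 15),
                                 dose_amount = 50, obs_days = obs)))
  pop <- population_model(c(lambda0 = 0.1, lambda1 = 0.4, k_drug = 1e-8,
                            V0 = 0.3),
                          c(lambda0 = 0.01, V0 = 0.03),
                          residual = list(type = "proportional", sd = 0.08))
  coh <- generate_cohort(des, pop, "el", seed = 21)
  ctl <- saem_control(n_burn = 60, n_smooth = 30, n_chains = 1)
  fit_full <- fit_population(coh, "el", ctl, seed = 5)
  fit_restr <- fit_population(coh, "el", ctl, seed = 5,
                              init = c(lambda0 = 0.1, lambda1 = 0.4,
                                       k_drug = 1e-8, V0 = 0.3),
                              estimated = c("lambda0", "lambda1", "V0"))
  ll_full <- information_criteria(fit_full, coh, n_is = 200, seed = 3)$loglik
  ll_restr <- information_criteria(fit_restr, coh, n_is = 200,
                                   seed = 3)$loglik
  expect_gt(ll_full, ll_restr - 2)   # nesting up to Monte-Carlo error
  # rmse of an essentially perfect fit on noise-free data
  pop0 <- population_model(c(lambda0 = 0.1, lambda1 = 0.4, k_drug = 1e-8,
                             V0 = 0.3), numeric(0),
                           residual = list(type = "proportional", sd = 1e-6))
  coh0 <- generate_cohort(des, pop0, "el", seed = 22)
  fit0 <- fit_population(coh0, "el", ctl, seed = 5)
  ic0 <- information_criteria(fit0, coh0, n_is = 100, seed = 3)
  expect_lt(ic0$rmse, 1e-3)
})

test_that("repeated-run protocol selects by marginal likelihood", {
  coh <- generate_cohort(small_design(5), dl_population_default(), "dl",
                         seed = 31)
  fit <- fit_population_runs(coh, "dl",
                             saem_control(n_burn = 30, n_smooth = 15,
                                          n_chains = 1),
                             n_runs = 2, seed = 3, n_is = 80)
  expect_length(fit$runs_loglik, 2)
  expect_true(all(is.finite(fit$runs_loglik)))
  expect_s3_class(fit, "dl_fit")
})
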