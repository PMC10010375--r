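# Shared fixtures: the CDX-calibrated parameter sets and small designs used
# across the suite. Everything is built in code; no data files.

cdx_dl_params <- function() {
  dl_params(lambda_net = 0.12, lambda_nec = 0.05, k_drug = 5.7e-3,
            R_c = 0.41, V0 = 0.25)
}

cdx_el_params <- function() {
  el_params(lambda0 = 0.08, lambda1 = 0.31, k_drug = 1.2e-3, V0 = 0.29)
}

protocol1_schedule <- function(amount = 50) {
  dose_schedule(c(1, 8, 15), amount)
}

# Small single-arm design for fast fitting tests.
small_design <- function(n = 8, dosed = TRUE) {
  cohort_design(list(list(
    n = n,
    dose_days = if (dosed) c(1, 8, 15) else numeric(0),
    dose_amount = 50,
    obs_days = c(0, 2, 5, 7, 9, 12, 14, 16, 19, 21, 23, 26, 28, 30))))
}

# Independent oracle: dense sign-scan root of the diffusion constraint
# R^2 - 3 Rn^2 + 2 Rn^3 / R = R_c^2 on [0, R), refined by bisection on the
# bracketing grid cell. Deliberately avoids solve_necrotic_radius().
scan_necrotic_radius <- function(R, R_c, n_grid = 20000) {
  f <- function(rn) R^2 - 3 * rn^2 + 2 * rn^3 / R - R_c^2
  g <- seq(0, R * (1 - 1e-9), length.out = n_grid)
  v <- f(g)
  i <- which(v[-1] <= 0 & v[-n_grid] > 0)[1]
  if (is.na(i)) return(0)
  lo <- g[i]; hi <- g[i + 1]
  for (it in 1:80) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
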