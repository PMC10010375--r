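#' Sphere geometry helpers
#'
#' `critical_volume()` converts the critical radius at which necrosis first
#' appears into the corresponding critical volume; `radius_from_volume()` and
#' `volume_from_radius()` are the sphere round-trip pair used throughout.
#'
#' @param R_c Critical radius (cm), strictly positive.
#' @return Volume in cm^3.
#' @examples
#' critical_volume(0.41)            # ~0.2887 cm^3
#' radius_from_volume(critical_volume(0.41))
#' @export
critical_volume <- function(R_c) {
  if (any(!is.finite(R_c)) || any(R_c <= 0))
    stop("critical_volume: R_c must be positive and finite", call. = FALSE)
  4 * pi / 3 * R_c^3
}

#' @rdname critical_volume
#' @param V Volume (cm^3).
#' @export
radius_from_volume <- function(V) {
  if (any(!is.finite(V)) || any(V < 0))
    stop("radius_from_volume: V must be non-negative and finite", call. = FALSE)
  (3 * V / (4 * pi))^(1 / 3)
}

#' @rdname critical_volume
#' @param R Radius (cm).
#' @export
volume_from_radius <- function(R) 4 * pi / 3 * R^3

# Root x = R_n/R of 2x^3 - 3x^2 + (1 - s) = 0 on [0, 1), s = (R_c/R)^2 in (0, 1].
# Exact trigonometric root of the depressed cubic; the branch is the one with
# x(1) = 0 and x(0) = 1. Vectorized in s.
.necrotic_ratio <- function(s) {
  s <- pmin(pmax(s, 0), 1)
  x <- 0.5 + cos((2 * pi - acos(2 * s - 1)) / 3)
  pmin(pmax(x, 0), 1)
}

#' Necrotic radius from the nutrient-diffusion constraint
#'
#' In the diffusion-limited phase (outer radius `R >= R_c`) the necrotic
#' radius `R_n` is the unique root in `[0, R)` of the steady-state spherical
#' diffusion balance `R^2 - 3 R_n^2 + 2 R_n^3 / R = R_c^2` (uniform nutrient
#' consumption in the live shell, no flux into the core). The constraint is
#' scale-invariant: with `x = R_n/R` and `s = (R_c/R)^2` it is the cubic
#' `2x^3 - 3x^2 + (1 - s) = 0`, which the default method solves exactly in
#' trigonometric form. `method = "brent"` solves the original constraint by
#' bracketed root finding instead; the two agree to the stated tolerance.
#'
#' @param R Outer tumor radius (cm); must satisfy `R >= R_c`.
#' @param R_c Critical radius (cm).
#' @param method `"analytic"` (exact cubic root, default) or `"brent"`
#'   (bracketed `uniroot` on the constraint).
#' @param tol Absolute tolerance (cm) for the `"brent"` method.
#' @return The necrotic radius `R_n` in cm, in `[0, R)`.
#' @examples
#' solve_necrotic_radius(0.82, 0.41)
#' solve_necrotic_radius(0.41, 0.41)  # onset: 0
#' @export
solve_necrotic_radius <- function(R, R_c, method = c("analytic", "brent"),
                                  tol = 1e-10) {
  method <- match.arg(method)
  if (any(!is.finite(R)) || any(R <= 0) || !is.finite(R_c) || R_c <= 0)
    stop("solve_necrotic_radius: R and R_c must be positive", call. = FALSE)
  if (any(R < R_c * (1 - 1e-12)))
    stop("solve_necrotic_radius: R < R_c is the fully proliferating phase; ",
         "no necrotic core exists (use G = 1)", call. = FALSE)
  if (method == "analytic") {
    s <- (R_c / R)^2
    return(.necrotic_ratio(s) * R)
  }
  vapply(R, function(Ri) {
    f <- function(rn) Ri^2 - 3 * rn^2 + 2 * rn^3 / Ri - R_c^2
    if (f(0) <= tol) return(0)
    up <- Ri * (1 - 1e-14)
    if (f(0) * f(up) > 0)
      stop("solve_necrotic_radius: no sign change in bracket", call. = FALSE)
    stats::uniroot(f, c(0, up), tol = tol)$root
  }, numeric(1))
}

#' Growing fraction of a spherical tumor
#'
#' Returns the proliferating volume fraction `G` implied by the
#' nutrient-diffusion constraint: `G = 1` for volumes at or below the critical
#' volume (fully proliferating tumor, exponential growth), and
#' `G = 1 - (R_n/R)^3` in the diffusion-limited phase, with `R_n` from
#' [solve_necrotic_radius()]. `G` is continuous (and continuously
#' differentiable) through the onset and strictly decreasing in volume beyond
#' it.
#'
#' @param V Tumor volume (cm^3), strictly positive; vectorized.
#' @param R_c Critical radius (cm).
#' @return Growth fraction in `(0, 1]`.
#' @examples
#' growth_fraction(0.1, 0.41)   # below critical volume: 1
#' growth_fraction(1.0, 0.41)
#' @export
growth_fraction <- function(V, R_c) {
  if (any(!is.finite(V)) || any(V <= 0))
    stop("growth_fraction: V must be positive and finite", call. = FALSE)
  if (!is.finite(R_c) || R_c <= 0)
    stop("growth_fraction: R_c must be positive and finite", call. = FALSE)
  Vc <- critical_volume(R_c)
  s <- pmin((Vc / V)^(2 / 3), 1)
  1 - .necrotic_ratio(s)^3
}

#' Necrotic area fraction of a central cross-section
#'
#' Maps the volumetric growth fraction `G` to the necrotic area fraction seen
#' on a central (equatorial) histological section of a spherical tumor:
#' the core of radius `R_n` occupies `(R_n/R)^2 = (1 - G)^{2/3}` of the
#' section area. This is how model-predicted growth fractions are compared
#' with Ki-67 endpoint histology.
#'
#' @param G Growth fraction in `(0, 1]`; vectorized.
#' @return Necrotic area fraction in `[0, 1)`.
#' @examples
#' necrotic_area_fraction(1)      # no core
#' necrotic_area_fraction(0.488)  # core at 80% of the radius: 0.64
#' @export
necrotic_area_fraction <- function(G) {
  if (any(!is.finite(G)) || any(G <= 0) || any(G > 1))
    stop("necrotic_area_fraction: G must lie in (0, 1]", call. = FALSE)
  (1 - G)^(2 / 3)
}

#' Right-hand side of the diffusion-limited growth law
#'
#' Evaluates the instantaneous derivatives of the coupled volume /
#' necrotic-radius system at a given state and drug concentration:
#' `dV/dt = lambda_net*G*V - lambda_nec*(1-G)*V - k_drug*c*G*V`, with only
#' the growing fraction proliferating and the drug acting only on living
#' cells. In the diffusion-limited phase `dR_n/dt` follows from
#' differentiating the constraint along the trajectory,
#' `dR_n/dt = dR/dt * (R_n^2 + R_n R + R^2) / (3 R R_n)`; in the fully
#' proliferating phase `G = 1` and `dR_n/dt = 0`. Mostly useful for testing
#' and for building custom integrators; [simulate_dl()] is the user-facing
#' solver.
#'
#' @param state Named list or vector with `V` (cm^3) and `R_n` (cm).
#' @param params A [dl_params()] object.
#' @param conc Drug concentration (mg/kg).
#' @return A list with `dV`, `dR_n` (per day) and the current `G`.
#' @export
dl_rhs <- function(state, params, conc = 0) {
  stopifnot(inherits(params, "dl_params"))
  V <- state[["V"]]
  Rn <- state[["R_n"]]
  R <- radius_from_volume(V)
  G <- if (Rn > 0) 1 - (Rn / R)^3 else 1
  dV <- params$lambda_net * G * V - params$lambda_nec * (1 - G) * V -
    params$k_drug * conc * G * V
  if (Rn > 0) {
    dR <- dV / (4 * pi * R^2)
    dRn <- dR * (Rn^2 + Rn * R + R^2) / (3 * R * Rn)
  } else {
    dRn <- 0
  }
  list(dV = dV, dR_n = dRn, G = G)
}

# --- trajectory simulation ---------------------------------------------------

# Breakpoints where the RHS is discontinuous in t (dose boluses); integration
# restarts at each so the solver never steps across a concentration jump.
.segment_times <- function(t_grid, dose_times) {
  tt <- sort(unique(c(t_grid, dose_times[dose_times > min(t_grid) &
                                           dose_times < max(t_grid)])))
  tt
}

#' Simulate the diffusion-limited growth law
#'
#' Integrates tumor volume under the diffusion-limited model, optionally under
#' a dosing schedule (exponential plasma kinetics, bolus doses as
#' concentration jumps). Two integration routes are provided and agree to
#' solver tolerance:
#'
#' * `"algebraic"` (default): integrate volume only, re-solving the
#'   growth-fraction constraint exactly at every right-hand-side evaluation.
#' * `"ode"`: the differentiated-constraint route — integrate the coupled
#'   system of volume and (squared) necrotic radius, with event detection for
#'   crossings of the critical volume in both directions, so that a tumor
#'   shrinking under treatment switches back to the fully proliferating
#'   branch (and its growing fraction rebounds).
#'
#' The squared necrotic radius is used as the ODE state because its
#' derivative, `dz/dt = 2 R' (R_n^2 + R_n R + R^2)/(3R)` with `z = R_n^2`,
#' stays finite at necrosis onset where `dR_n/dt` itself is singular.
#'
#' @param params A [dl_params()] object.
#' @param schedule A [dose_schedule()] or `NULL` for untreated growth.
#' @param t_grid Increasing vector of output times (days), starting at 0.
#' @param method `"algebraic"` or `"ode"` (see Details).
#' @param rtol,atol Integrator tolerances.
#' @return A data.frame of class `dl_trajectory` with columns `time`, `V`,
#'   `R`, `R_n`, `G` and `conc`.
#' @examples
#' p <- dl_params(0.12, 0.05, 5.7e-3, 0.41, 0.25)
#' sim <- simulate_dl(p, t_grid = seq(0, 30, by = 1))
#' head(sim)
#' @export
simulate_dl <- function(params, schedule = NULL, t_grid,
                        method = c("algebraic", "ode"),
                        rtol = 1e-9, atol = 1e-11) {
  method <- match.arg(method)
  stopifnot(inherits(params, "dl_params"))
  .check_grid(t_grid)
  sch <- .as_schedule(schedule)
  Vc <- critical_volume(params$R_c)

  if (method == "algebraic") {
    make_rhs <- function(conc_fun) {
      function(t, y, p) {
        V <- y[1]
        G <- growth_fraction(max(V, 1e-300), params$R_c)
        dV <- params$lambda_net * G * V - params$lambda_nec * (1 - G) * V -
          params$k_drug * conc_fun(t) * G * V
        list(dV)
      }
    }
    V <- .integrate_segments(make_rhs, y0 = c(V = params$V0), t_grid, sch,
                             rtol, atol)[, "V"]
    R <- radius_from_volume(V)
    G <- growth_fraction(V, params$R_c)
    Rn <- (1 - G)^(1 / 3) * R
  } else {
    V <- .simulate_dl_ode(params, sch, t_grid, rtol, atol)
    R <- radius_from_volume(V)
    G <- growth_fraction(V, params$R_c)
    Rn <- (1 - G)^(1 / 3) * R
  }
  out <- data.frame(time = t_grid, V = V, R = R, R_n = Rn, G = G,
                    conc = pk_concentration(t_grid, sch))
  class(out) <- c("dl_trajectory", "data.frame")
  out
}

.check_grid <- function(t_grid) {
  if (length(t_grid) < 2L || any(diff(t_grid) <= 0) || t_grid[1] != 0)
    stop("t_grid must be increasing and start at 0", call. = FALSE)
}

# deSolve integration over segments split at dose times; `make_rhs` receives
# the segment's exact concentration function (see .conc_segment).
.integrate_segments <- function(make_rhs, y0, t_grid, sch, rtol, atol) {
  brks <- sch$times[sch$times > t_grid[1] & sch$times < max(t_grid)]
  cuts <- sort(unique(c(t_grid[1], brks, max(t_grid))))
  out <- matrix(NA_real_, length(t_grid), length(y0),
                dimnames = list(NULL, names(y0)))
  out[1, ] <- y0
  y <- y0
  for (k in seq_len(length(cuts) - 1L)) {
    a <- cuts[k]; b <- cuts[k + 1L]
    inner <- t_grid[t_grid > a & t_grid <= b]
    tt <- sort(unique(c(a, inner, b)))
    rhs <- make_rhs(.conc_segment(sch, a))
    sol <- deSolve::lsoda(y, tt, rhs, parms = NULL, rtol = rtol, atol = atol,
                          tcrit = b)
    if (attr(sol, "istate")[1] < 0)
      stop("integration failed at t = ", utils::tail(sol[, 1], 1), call. = FALSE)
    keep <- tt %in% inner
    out[match(tt[keep], t_grid), ] <- sol[keep, -1, drop = FALSE]
    y <- sol[nrow(sol), -1]
    names(y) <- names(y0)
  }
  out
}

# Differentiated-constraint integration: states (V, z = R_n^2), phase flag,
# lsodar root-finding on V - Vc for switches in both directions.
.simulate_dl_ode <- function(params, sch, t_grid, rtol, atol) {
  Vc <- critical_volume(params$R_c)

  make_free <- function(conc_fun) function(t, y, p) {
    V <- y[1]
    dV <- (params$lambda_net - params$k_drug * conc_fun(t)) * V
    list(c(dV, 0))
  }
  make_lim <- function(conc_fun) function(t, y, p) {
    V <- y[1]; z <- max(y[2], 0)
    R <- radius_from_volume(V)
    Rn <- sqrt(z)
    G <- max(1 - (Rn / R)^3, 0)
    dV <- params$lambda_net * G * V - params$lambda_nec * (1 - G) * V -
      params$k_drug * conc_fun(t) * G * V
    dR <- dV / (4 * pi * R^2)
    dz <- 2 * dR * (Rn^2 + Rn * R + R^2) / (3 * R)
    list(c(dV, dz))
  }
  root_V <- function(t, y, p) y[1] - Vc

  Vfull <- numeric(length(t_grid))
  Vfull[1] <- params$V0
  dose_brks <- sch$times[sch$times > 0 & sch$times < max(t_grid)]
  cuts <- sort(unique(c(0, dose_brks, max(t_grid))))
  y <- c(params$V0, if (params$V0 > Vc)
    solve_necrotic_radius(radius_from_volume(params$V0), params$R_c)^2 else 0)
  phase <- if (params$V0 > Vc) 2L else 1L
  t_now <- 0
  for (k in seq_len(length(cuts) - 1L)) {
    a <- cuts[k]; b <- cuts[k + 1L]
    conc_fun <- .conc_segment(sch, a)
    while (t_now < b - 1e-12) {
      inner <- t_grid[t_grid > t_now & t_grid <= b]
      tt <- sort(unique(c(t_now, inner, b)))
      rhs <- if (phase == 1L) make_free(conc_fun) else make_lim(conc_fun)
      sol <- deSolve::lsodar(y, tt, rhs, parms = NULL, rtol = rtol,
                             atol = atol, rootfunc = root_V, tcrit = b)
      if (attr(sol, "istate")[1] < 0)
        stop("integration failed at t = ", utils::tail(sol[, 1], 1),
             call. = FALSE)
      got <- sol[, 1]
      fill <- got %in% inner
      Vfull[match(got[fill], t_grid)] <- sol[fill, 2]
      t_end <- got[length(got)]
      y <- sol[nrow(sol), 2:3]
      if (t_end <= t_now + 1e-12)
        stop("phase-switch event loop stalled at t = ", t_end, call. = FALSE)
      t_now <- t_end
      if (t_end < b - 1e-12) {
        # crossed the critical volume: switch phase and restart
        if (phase == 1L) {
          phase <- 2L
          y[2] <- 0           # necrosis onset: core starts at zero radius
          y[1] <- Vc * (1 + 1e-12)
        } else {
          phase <- 1L
          y[2] <- 0
          y[1] <- Vc * (1 - 1e-12)
        }
      }
    }
  }
  Vfull
}

#' @export
print.dl_trajectory <- function(x, ...) {
  cat(sprintf("Diffusion-limited trajectory: %d time points, t in [%g, %g] days\n",
              nrow(x), min(x$time), max(x$time)))
  cat(sprintf("  V: %.4g -> %.4g cm^3;  G: %.3f -> %.3f\n",
              x$V[1], x$V[nrow(x)], x$G[1], x$G[nrow(x)]))
  NextMethod()
}
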