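#' Population model: fixed effects, inter-individual variability, error model
#'
#' The unit of population simulation and SAEM fitting. Individual parameters
#' are log-normally distributed around the fixed effects (the population
#' medians, standard in pharmacometrics for strictly positive parameters):
#' `theta_i = theta_pop * exp(eta_i)`, `eta_i ~ N(0, omega^2)`. For
#' comparability with how inter-individual variability is usually tabulated,
#' `iiv_sd` is given as the SD of the parameter on its *natural* scale; the
#' log-scale `omega` is solved from
#' `sd/median = exp(omega^2/2) * sqrt(exp(omega^2) - 1)`
#' (see [iiv_to_omega()]).
#'
#' @param fixed_effects Named vector/list of positive population medians.
#' @param iiv_sd Named vector of non-negative natural-scale SDs; names must
#'   be a subset of `fixed_effects`; missing entries mean no variability.
#' @param residual Error model: `list(type, sd)` with type
#'   `"proportional"` (sd is a CV; default 0.1) or `"additive"` (sd in cm^3).
#' @return A `population_model` object.
#' @examples
#' pop <- population_model(c(a = 0.1, V0 = 0.25), c(a = 0.02))
#' sample_individual_params(pop, n = 3, seed = 1)
#' @export
population_model <- function(fixed_effects,
                             iiv_sd = numeric(0),
                             residual = list(type = "proportional", sd = 0.1)) {
  fe <- unlist(fixed_effects)
  if (is.null(names(fe)) || any(!nzchar(names(fe))))
    stop("population_model: fixed_effects must be named", call. = FALSE)
  if (any(!is.finite(fe)) || any(fe <= 0))
    stop("population_model: fixed effects must be positive", call. = FALSE)
  iiv <- unlist(iiv_sd)
  if (length(iiv) && (is.null(names(iiv)) || !all(names(iiv) %in% names(fe))))
    stop("population_model: iiv_sd names must be a subset of fixed_effects",
         call. = FALSE)
  if (any(iiv < 0)) stop("population_model: iiv_sd must be >= 0", call. = FALSE)
  if (!residual$type %in% c("proportional", "additive"))
    stop("population_model: residual$type must be proportional or additive",
         call. = FALSE)
  if (!is.finite(residual$sd) || residual$sd <= 0)
    stop("population_model: residual$sd must be positive", call. = FALSE)
  full_iiv <- stats::setNames(rep(0, length(fe)), names(fe))
  full_iiv[names(iiv)] <- iiv
  structure(list(fixed_effects = fe, iiv_sd = full_iiv, residual = residual),
            class = "population_model")
}

#' Convert between natural-scale iiv SD and log-normal omega
#'
#' For a log-normal parameter with median `m` and log-scale SD `omega`, the
#' natural-scale SD is `m * exp(omega^2/2) * sqrt(exp(omega^2) - 1)`.
#' `iiv_to_omega()` inverts this relation.
#'
#' @param median Population median (fixed effect), positive.
#' @param sd Natural-scale SD, non-negative.
#' @return `iiv_to_omega()`: omega (log-scale SD); `omega_to_iiv()`: the
#'   natural-scale SD.
#' @export
iiv_to_omega <- function(median, sd) {
  cv2 <- (sd / median)^2
  tt <- (1 + sqrt(1 + 4 * cv2)) / 2
  sqrt(log(tt))
}

#' @rdname iiv_to_omega
#' @param omega Log-scale SD, non-negative.
#' @export
omega_to_iiv <- function(median, omega) {
  median * exp(omega^2 / 2) * sqrt(expm1(omega^2))
}

#' Draw individual parameter sets from a population model
#'
#' Each parameter is drawn log-normally around its fixed effect with the
#' omega implied by its natural-scale iiv SD; parameters with zero iiv are
#' returned exactly. Deterministic given `seed`.
#'
#' @param pop A [population_model()].
#' @param n Number of individuals.
#' @param seed Optional integer seed.
#' @return A matrix (`n` rows) of positive parameter draws, columns named as
#'   the fixed effects.
#' @export
sample_individual_params <- function(pop, n = 1, seed = NULL) {
  stopifnot(inherits(pop, "population_model"))
  if (!is.null(seed)) set.seed(seed)
  fe <- pop$fixed_effects
  om <- iiv_to_omega(fe, pop$iiv_sd)
  eta <- matrix(stats::rnorm(n * length(fe)), n, length(fe))
  out <- sweep(sweep(eta, 2, om, `*`), 2, log(fe), `+`)
  out <- exp(out)
  colnames(out) <- names(fe)
  out
}

#' Default CDX-calibrated population models
#'
#' Ready-made [population_model()] objects for the diffusion-limited and
#' exponential-linear laws, with fixed effects and inter-individual SDs
#' calibrated to irinotecan-treated colorectal cell-derived-xenograft
#' studies, and 10% proportional caliper measurement error. These are the
#' defaults of the synthetic-cohort generator.
#'
#' @param residual_cv Proportional residual SD (CV); default 0.1.
#' @return A `population_model`.
#' @export
dl_population_default <- function(residual_cv = 0.1) {
  population_model(
    fixed_effects = c(lambda_net = 0.12, lambda_nec = 0.05,
                      k_drug = 5.7e-3, R_c = 0.41, V0 = 0.25),
    iiv_sd = c(lambda_net = 0.02, lambda_nec = 0.03,
               k_drug = 2.4e-4, R_c = 0.07, V0 = 0.11),
    residual = list(type = "proportional", sd = residual_cv))
}

#' @rdname dl_population_default
#' @export
el_population_default <- function(residual_cv = 0.1) {
  population_model(
    fixed_effects = c(lambda0 = 0.08, lambda1 = 0.31,
                      k_drug = 1.2e-3, V0 = 0.29),
    iiv_sd = c(lambda0 = 0.25, lambda1 = 0.06,
               k_drug = 4e-4, V0 = 0.13),
    residual = list(type = "proportional", sd = residual_cv))
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population model (log-normal random effects):\n")
  om <- iiv_to_omega(x$fixed_effects, x$iiv_sd)
  df <- data.frame(median = x$fixed_effects, iiv_sd = x$iiv_sd,
                   omega = om)
  print(df, digits = 4)
  cat(sprintf("Residual: %s, sd %.4g\n", x$residual$type, x$residual$sd))
  invisible(x)
}
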