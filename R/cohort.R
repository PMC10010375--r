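#' Cohort designs for synthetic xenograft studies
#'
#' A design is a list of arms, each with a number of subjects, a dosing
#' protocol (days and mg/kg) and nominal measurement days. The bundled
#' `"az_cdx"` preset, [design_az_cdx()], emulates a three-protocol
#' cell-derived-xenograft efficacy study: weekly 50 mg/kg irinotecan doses on
#' days 1, 8, 15 (protocol 1), days 1, 8, 15, 22 (protocol 2) or days
#' 4, 11, 18, 25 (protocol 3), with arm sizes in proportion 68:18:9 and
#' caliper measurements every 2-3 days over ~30 days.
#'
#' @param arms List of arms; each arm a list with `n` (subjects), `dose_days`
#'   (numeric, possibly empty), `dose_amount` (mg/kg) and `obs_days`.
#' @param k_elim Drug elimination rate (day^-1); default the 12-h irinotecan
#'   half-life.
#' @return A `cohort_design` object.
#' @export
cohort_design <- function(arms, k_elim = decay_rate_from_half_life(0.5)) {
  for (arm in arms) {
    if (is.null(arm$n) || arm$n < 1)
      stop("cohort_design: each arm needs n >= 1", call. = FALSE)
    if (is.null(arm$obs_days) || any(diff(arm$obs_days) <= 0))
      stop("cohort_design: obs_days must be strictly increasing", call. = FALSE)
  }
  structure(list(arms = arms, k_elim = k_elim), class = "cohort_design")
}

#' @rdname cohort_design
#' @param n_total Total number of subjects; split across the three protocols
#'   in proportion 68:18:9 (the default 95 gives exactly 68/18/9).
#' @param dose_amount Dose size in mg/kg (default 50).
#' @export
design_az_cdx <- function(n_total = 95, dose_amount = 50) {
  obs <- c(0, 2, 5, 7, 9, 12, 14, 16, 19, 21, 23, 26, 28, 30)
  if (n_total < 3) stop("design_az_cdx: need at least 3 subjects", call. = FALSE)
  # largest-remainder apportionment, with every arm kept non-empty
  props <- c(68, 18, 9) / 95
  share <- props * n_total
  n <- floor(share)
  rem <- n_total - sum(n)
  if (rem > 0) {
    extra <- order(share - n, decreasing = TRUE)[seq_len(rem)]
    n[extra] <- n[extra] + 1L
  }
  while (any(n < 1)) {
    n[which.max(n)] <- n[which.max(n)] - 1L
    n[which.min(n)] <- n[which.min(n)] + 1L
  }
  protos <- list(c(1, 8, 15), c(1, 8, 15, 22), c(4, 11, 18, 25))
  arms <- lapply(1:3, function(i)
    list(n = n[i], dose_days = protos[[i]], dose_amount = dose_amount,
         obs_days = obs))
  cohort_design(arms)
}

# Per-subject seed stream: deterministic in (master seed, arm, position in
# arm), so changing one arm's size does not perturb other subjects' draws.
.subject_seed <- function(seed, arm, j) {
  s <- as.numeric(seed) %% 2147483629
  as.integer((s * 48271 + arm * 7919 + j * 1009) %% 2147483629)
}

#' Generate a synthetic longitudinal cohort
#'
#' For each subject: draw individual parameters from the population model,
#' simulate the chosen growth law under the subject's arm protocol, and apply
#' measurement error at the nominal observation days (proportional by
#' default, emulating caliper noise on the volume). If a draw produces a
#' non-positive measurement it is redrawn (counted in the `redraws`
#' attribute).
#'
#' @param design A [cohort_design()].
#' @param pop A [population_model()] whose fixed-effect names match the model
#'   (`dl`: lambda_net, lambda_nec, k_drug, R_c, V0; `el`: lambda0, lambda1,
#'   k_drug, V0). Defaults to the CDX-calibrated population for the model.
#' @param model `"dl"` (diffusion-limited) or `"el"` (exponential-linear).
#' @param seed Master integer seed.
#' @return A `cohort` object: list with data.frames `observations`
#'   (`subject_id`, `time_days`, `volume_cm3`) and `doses` (`subject_id`,
#'   `time_days`, `dose_mg_per_kg`), plus `k_elim`. The generating individual
#'   parameters are kept in `attr(, "truth")`.
#' @examples
#' coh <- generate_cohort(design_az_cdx(12), seed = 1)
#' head(coh$observations)
#' @export
generate_cohort <- function(design, pop = NULL, model = c("dl", "el"),
                            seed = 1) {
  model <- match.arg(model)
  stopifnot(inherits(design, "cohort_design"))
  if (is.null(pop))
    pop <- if (model == "dl") dl_population_default() else el_population_default()
  stopifnot(inherits(pop, "population_model"))
  .check_pop_names(pop, model)

  obs_list <- list(); dose_list <- list(); truth <- list()
  redraws <- 0L
  idx <- 0L
  for (a in seq_along(design$arms)) {
    arm <- design$arms[[a]]
    for (j in seq_len(arm$n)) {
      idx <- idx + 1L
      sid <- sprintf("S%03d", idx)
      set.seed(.subject_seed(seed, a, j))
      theta <- sample_individual_params(pop, 1)[1, ]
      tt <- arm$obs_days
      sim_t <- if (tt[1] == 0) tt else c(0, tt)
      Vt <- .predict_volumes(model, theta, sim_t, arm$dose_days,
                             rep(arm$dose_amount, length(arm$dose_days)),
                             design$k_elim)
      V <- Vt[match(tt, sim_t)]
      for (tries in 1:100) {
        y <- if (pop$residual$type == "proportional")
          V * (1 + pop$residual$sd * stats::rnorm(length(V)))
        else V + pop$residual$sd * stats::rnorm(length(V))
        if (all(y > 0)) break
        redraws <- redraws + 1L
      }
      y[y <= 0] <- 1e-4
      obs_list[[idx]] <- data.frame(subject_id = sid, time_days = tt,
                                    volume_cm3 = y)
      if (length(arm$dose_days))
        dose_list[[idx]] <- data.frame(subject_id = sid,
                                       time_days = arm$dose_days,
                                       dose_mg_per_kg = arm$dose_amount)
      truth[[idx]] <- theta
    }
  }
  out <- structure(list(
    observations = do.call(rbind, obs_list),
    doses = if (length(dose_list)) do.call(rbind, dose_list) else
      data.frame(subject_id = character(0), time_days = numeric(0),
                 dose_mg_per_kg = numeric(0)),
    k_elim = design$k_elim), class = "cohort")
  attr(out, "truth") <- do.call(rbind, truth)
  attr(out, "redraws") <- redraws
  rownames(out$observations) <- NULL
  out
}

.check_pop_names <- function(pop, model) {
  need <- if (model == "dl")
    c("lambda_net", "lambda_nec", "k_drug", "R_c", "V0")
  else c("lambda0", "lambda1", "k_drug", "V0")
  if (!all(need %in% names(pop$fixed_effects)))
    stop("population model for '", model, "' needs parameters ",
         paste(need, collapse = ", "), call. = FALSE)
  invisible(need)
}

# Fast model prediction at observation times via the compiled RK4 core.
.predict_volumes <- function(model, theta, t_out, dose_t, dose_a, k_elim,
                             hmax = 0.02) {
  # wild optimizer/MCMC proposals: report non-finite predictions, don't error
  if (any(!is.finite(unlist(theta))) || any(unlist(theta) <= 0))
    return(rep(NaN, length(t_out)))
  if (model == "dl") {
    pars <- c(theta[["lambda_net"]], theta[["lambda_nec"]], theta[["k_drug"]],
              critical_volume(theta[["R_c"]]))
    code <- 0L
  } else {
    psi <- if ("psi" %in% names(theta)) theta[["psi"]] else 20
    pars <- c(theta[["lambda0"]], theta[["lambda1"]], theta[["k_drug"]], psi)
    code <- 1L
  }
  .sim_growth_cpp(code, pars, theta[["V0"]], as.numeric(dose_t),
                  as.numeric(dose_a), k_elim, as.numeric(t_out), hmax)[, "V"]
}

#' @export
print.cohort <- function(x, ...) {
  ns <- length(unique(x$observations$subject_id))
  cat(sprintf("Cohort: %d subjects, %d observations, %d dose events (k_elim %.3g /day)\n",
              ns, nrow(x$observations), nrow(x$doses), x$k_elim))
  invisible(x)
}

# Split a cohort into per-subject records used by the fitting routines.
.cohort_subjects <- function(cohort) {
  ids <- unique(cohort$observations$subject_id)
  lapply(ids, function(id) {
    o <- cohort$observations[cohort$observations$subject_id == id, ]
    d <- cohort$doses[cohort$doses$subject_id == id, ]
    list(id = id, times = o$time_days, y = o$volume_cm3,
         dose_t = d$time_days, dose_a = d$dose_mg_per_kg)
  })
}
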