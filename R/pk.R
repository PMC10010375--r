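#' Exponential plasma kinetics and dose schedules
#'
#' Bolus doses are idealized as instantaneous jumps in plasma concentration
#' (carried in mg/kg, i.e. amount per body weight, so that the kill term
#' `k_drug * c` has units day^-1). Between doses the concentration decays as a
#' single exponential with rate `k_elim`; the concentration at time `t` is the
#' superposition of all past doses and is right-continuous at dose times.
#' The default elimination rate corresponds to the 12-hour plasma half-life
#' of irinotecan (CPT-11), `ln(2)/0.5` per day.
#'
#' @param times Dose times (days), non-negative.
#' @param amounts Dose amounts (mg/kg), non-negative; recycled if length 1.
#' @param k_elim Elimination rate (day^-1).
#' @return A `dose_schedule` object.
#' @examples
#' sch <- dose_schedule(c(1, 8, 15), 50)
#' pk_concentration(c(1, 1.5, 2), sch)
#' @export
dose_schedule <- function(times = numeric(0), amounts = numeric(0),
                          k_elim = decay_rate_from_half_life(0.5)) {
  if (length(amounts) == 1L) amounts <- rep(amounts, length(times))
  if (length(times) != length(amounts))
    stop("dose_schedule: times and amounts must have equal length", call. = FALSE)
  if (any(times < 0) || any(amounts < 0))
    stop("dose_schedule: times and amounts must be non-negative", call. = FALSE)
  if (!is.finite(k_elim) || k_elim <= 0)
    stop("dose_schedule: k_elim must be positive", call. = FALSE)
  o <- order(times)
  structure(list(times = as.numeric(times[o]), amounts = as.numeric(amounts[o]),
                 k_elim = k_elim),
            class = "dose_schedule")
}

.as_schedule <- function(schedule) {
  if (is.null(schedule)) return(dose_schedule())
  stopifnot(inherits(schedule, "dose_schedule"))
  schedule
}

#' @rdname dose_schedule
#' @param t_half Half-life in days.
#' @export
decay_rate_from_half_life <- function(t_half) {
  if (any(!is.finite(t_half)) || any(t_half <= 0))
    stop("decay_rate_from_half_life: t_half must be positive", call. = FALSE)
  log(2) / t_half
}

#' @rdname dose_schedule
#' @param k_elim Elimination rate (day^-1).
#' @export
half_life_from_decay_rate <- function(k_elim) {
  if (any(!is.finite(k_elim)) || any(k_elim <= 0))
    stop("half_life_from_decay_rate: k_elim must be positive", call. = FALSE)
  log(2) / k_elim
}

#' Plasma concentration under a dose schedule
#'
#' Superposition of exponentially decaying boluses:
#' `c(t) = sum_i amount_i * exp(-k_elim (t - time_i))` over doses with
#' `time_i <= t`; zero before the first dose.
#'
#' @param t Times (days); vectorized.
#' @param schedule A [dose_schedule()].
#' @return Concentrations (mg/kg).
#' @export
pk_concentration <- function(t, schedule) {
  sch <- .as_schedule(schedule)
  if (length(sch$times) == 0L) return(rep(0, length(t)))
  vapply(t, function(ti) {
    past <- sch$times <= ti
    sum(sch$amounts[past] * exp(-sch$k_elim * (ti - sch$times[past])))
  }, numeric(1))
}

# Exact within-segment concentration: on a dose-free interval starting at `a`
# (inclusive of any bolus given exactly at `a`), c(t) = c(a) exp(-k (t - a)).
# Integrators use this so the solver never sees a concentration jump.
.conc_segment <- function(sch, a) {
  Ca <- pk_concentration(a, sch)
  k <- sch$k_elim
  function(t) Ca * exp(-k * (t - a))
}

#' @export
print.dose_schedule <- function(x, ...) {
  cat(sprintf("Dose schedule: %d dose(s), k_elim %.4g /day (t1/2 %.3g days)\n",
              length(x$times), x$k_elim, log(2) / x$k_elim))
  if (length(x$times))
    cat("  days:", paste(x$times, collapse = ", "),
        " amounts (mg/kg):", paste(x$amounts, collapse = ", "), "\n")
  invisible(x)
}
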