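#' Read and write longitudinal cohort CSV files
#'
#' The interchange format is a pair of plain CSV files: a volume table with
#' header `subject_id,time_days,volume_cm3` and an optional dose table with
#' header `subject_id,time_days,dose_mg_per_kg`. Validation is strict:
#' volumes must be positive, times sorted within subject, and every dose
#' record must name a subject present in the volume table; violations are
#' reported with the offending file line (header = line 1).
#'
#' @param volumes_path Path to the volume CSV.
#' @param doses_path Optional path to the dose CSV.
#' @param k_elim Elimination rate to attach (day^-1); default the 12-h
#'   irinotecan half-life.
#' @return A `cohort` object.
#' @export
read_cohort <- function(volumes_path, doses_path = NULL,
                        k_elim = decay_rate_from_half_life(0.5)) {
  obs <- utils::read.csv(volumes_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "time_days", "volume_cm3")
  if (!all(need %in% names(obs)))
    stop("read_cohort: ", volumes_path, " must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(obs$volume_cm3) | obs$volume_cm3 <= 0)
  if (length(bad))
    stop("read_cohort: non-positive volume at line ", bad[1] + 1L, " of ",
         volumes_path, call. = FALSE)
  for (id in unique(obs$subject_id)) {
    rows <- which(obs$subject_id == id)
    tt <- obs$time_days[rows]
    if (any(diff(tt) <= 0))
      stop("read_cohort: times not strictly increasing for subject '", id,
           "' at line ", rows[which(diff(tt) <= 0)[1] + 1L] + 1L, " of ",
           volumes_path, call. = FALSE)
  }
  doses <- data.frame(subject_id = character(0), time_days = numeric(0),
                      dose_mg_per_kg = numeric(0))
  if (!is.null(doses_path)) {
    doses <- utils::read.csv(doses_path, stringsAsFactors = FALSE)
    needd <- c("subject_id", "time_days", "dose_mg_per_kg")
    if (!all(needd %in% names(doses)))
      stop("read_cohort: ", doses_path, " must have columns ",
           paste(needd, collapse = ", "), call. = FALSE)
    bad <- which(!(doses$subject_id %in% obs$subject_id))
    if (length(bad))
      stop("read_cohort: dose for unknown subject '",
           doses$subject_id[bad[1]], "' at line ", bad[1] + 1L, " of ",
           doses_path, call. = FALSE)
    bad <- which(!is.finite(doses$dose_mg_per_kg) | doses$dose_mg_per_kg < 0)
    if (length(bad))
      stop("read_cohort: negative dose at line ", bad[1] + 1L, " of ",
           doses_path, call. = FALSE)
  }
  structure(list(observations = obs[, need], doses = doses, k_elim = k_elim),
            class = "cohort")
}

#' @rdname read_cohort
#' @param cohort A `cohort` object.
#' @export
write_cohort <- function(cohort, volumes_path, doses_path = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  utils::write.csv(cohort$observations, volumes_path, row.names = FALSE)
  if (!is.null(doses_path))
    utils::write.csv(cohort$doses, doses_path, row.names = FALSE)
  invisible(cohort)
}

#' Write a fit report table
#'
#' One row per population parameter: estimate, natural-scale iiv SD, and the
#' fit-wide rmse and AIC on the first row, in the layout conventional for
#' mixed-effects tumor-growth reports.
#'
#' @param fit A `dl_fit`.
#' @param ic Output of [information_criteria()] (optional).
#' @param path Output CSV path.
#' @export
write_fit_report <- function(fit, ic = NULL, path) {
  stopifnot(inherits(fit, "dl_fit"))
  fe <- fit$population$fixed_effects
  df <- data.frame(parameter = names(fe), value = unname(fe),
                   iiv = unname(fit$population$iiv_sd),
                   rmse = NA_real_, aic = NA_real_)
  if (!is.null(ic)) { df$rmse[1] <- ic$rmse; df$aic[1] <- ic$aic }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
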