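#' Simulate replicate cohorts from a population model
#'
#' Draws `n_sim` complete cohorts from a population model under a study
#' design, each with fresh random effects and residual noise; the backbone of
#' the visual predictive check.
#'
#' @param pop A [population_model()].
#' @param design A [cohort_design()].
#' @param model `"dl"` or `"el"`.
#' @param n_sim Number of replicate cohorts.
#' @param seed Integer seed.
#' @return List of `n_sim` observation data.frames (`subject_id`,
#'   `time_days`, `volume_cm3`).
#' @export
simulate_replicates <- function(pop, design, model = c("dl", "el"),
                                n_sim = 1000, seed = 1) {
  model <- match.arg(model)
  if (n_sim < 1) stop("simulate_replicates: n_sim must be >= 1", call. = FALSE)
  lapply(seq_len(n_sim), function(r)
    generate_cohort(design, pop, model,
                    seed = as.integer(seed) + 7919L * r)$observations)
}

#' Visual-predictive-check percentile bands
#'
#' For each time bin, the requested percentiles of the simulated volumes are
#' computed within every replicate; the confidence band of each percentile is
#' then taken across replicates. Observed percentiles (when data are
#' supplied) are computed per bin, optionally smoothed by a centered rolling
#' mean across bins.
#'
#' @param replicates List of simulated observation data.frames, from
#'   [simulate_replicates()].
#' @param observed Optional observed data.frame (`time_days`, `volume_cm3`).
#' @param percentiles Percentiles to band (default 5, 50, 95).
#' @param ci_level Confidence level across replicates (default 0.95).
#' @param bins Bin centers; defaults to the nominal simulated times. Each
#'   observation is assigned to the nearest bin; empty bins are merged into
#'   their neighbor with a warning.
#' @param roll_bins Width (in bins) of the centered rolling mean applied to
#'   observed percentiles; 1 = no smoothing.
#' @return A `vpc_result`: data.frame `bands` with columns `bin_time`,
#'   `stat` (`p5`, `p50`, `p95`), `lower`, `mid`, `upper`, and (if observed
#'   data were given) `observed` with per-bin observed percentiles.
#' @export
vpc_bands <- function(replicates, observed = NULL,
                      percentiles = c(5, 50, 95), ci_level = 0.95,
                      bins = NULL, roll_bins = 1) {
  if (length(replicates) < 2L)
    stop("vpc_bands: need at least 2 replicates", call. = FALSE)
  all_t <- replicates[[1]]$time_days
  if (is.null(bins)) bins <- sort(unique(all_t))
  assign_bin <- function(t) bins[pmax(1, apply(abs(outer(t, bins, `-`)), 1,
                                               which.min))]
  alpha <- (1 - ci_level) / 2
  qs <- percentiles / 100

  # per replicate x bin x percentile
  per_rep <- lapply(replicates, function(df) {
    b <- assign_bin(df$time_days)
    vapply(bins, function(bb) {
      v <- df$volume_cm3[b == bb]
      if (!length(v)) return(rep(NA_real_, length(qs)))
      stats::quantile(v, qs, names = FALSE, type = 7)
    }, numeric(length(qs)))
  })
  arr <- simplify2array(per_rep)            # percentile x bin x replicate
  if (any(is.na(arr))) warning("vpc_bands: empty bins encountered; ",
                               "their rows are NA", call. = FALSE)
  bands <- do.call(rbind, lapply(seq_along(qs), function(j) {
    m <- arr[j, , , drop = FALSE]
    data.frame(bin_time = bins,
               stat = paste0("p", percentiles[j]),
               lower = apply(m, 2, stats::quantile, alpha, na.rm = TRUE),
               mid = apply(m, 2, stats::median, na.rm = TRUE),
               upper = apply(m, 2, stats::quantile, 1 - alpha, na.rm = TRUE))
  }))
  rownames(bands) <- NULL

  obs_df <- NULL
  if (!is.null(observed)) {
    b <- assign_bin(observed$time_days)
    obs_df <- do.call(rbind, lapply(seq_along(qs), function(j) {
      v <- vapply(bins, function(bb) {
        vv <- observed$volume_cm3[b == bb]
        if (!length(vv)) NA_real_
        else stats::quantile(vv, qs[j], names = FALSE, type = 7)
      }, numeric(1))
      if (roll_bins > 1) {
        v <- stats::filter(v, rep(1 / roll_bins, roll_bins), sides = 2)
        v <- as.numeric(v)
      }
      data.frame(bin_time = bins, stat = paste0("p", percentiles[j]),
                 value = v)
    }))
    rownames(obs_df) <- NULL
  }
  structure(list(bands = bands, observed = obs_df,
                 percentiles = percentiles, ci_level = ci_level),
            class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  cat(sprintf("VPC: %s percentile bands at %.0f%% CI, %d bins\n",
              paste(x$percentiles, collapse = "/"), 100 * x$ci_level,
              length(unique(x$bands$bin_time))))
  invisible(x)
}

#' Plot a visual predictive check
#'
#' Shaded simulated percentile bands with observed percentiles overlaid.
#' Requires ggplot2.
#'
#' @param x A `vpc_result`.
#' @param log_y Plot volume on a log scale.
#' @return A ggplot object.
#' @export
plot_vpc <- function(x, log_y = FALSE) {
  stopifnot(inherits(x, "vpc_result"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_vpc requires ggplot2", call. = FALSE)
  gg <- ggplot2::ggplot(x$bands, ggplot2::aes(x = .data$bin_time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper,
                                      fill = .data$stat), alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mid, color = .data$stat)) +
    ggplot2::labs(x = "time (days)", y = expression(volume ~ (cm^3)))
  if (!is.null(x$observed))
    gg <- gg + ggplot2::geom_point(data = stats::na.omit(x$observed),
                                   ggplot2::aes(y = .data$value,
                                                shape = .data$stat))
  if (log_y) gg <- gg + ggplot2::scale_y_log10()
  gg
}
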