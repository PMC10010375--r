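#' Empirical comparator growth laws
#'
#' Constructs one of the classical empirical tumor growth laws used in
#' preclinical modelling, as a rate function `g(V)` in the volume rate
#' equation `dV/dt = g(V) - k_drug * c(t) * V` (for these laws the kill acts
#' on total volume, since they carry no growing fraction):
#'
#' * `linear`: `g = a` (cm^3/day)
#' * `exponential`: `g = a V`
#' * `logistic`: `g = a V (1 - V/K)`
#' * `gompertz`: `g = a V log(K/V)`
#' * `exponential_linear`: smooth interpolation
#'   `g = lambda0 V / (1 + (lambda0 V / lambda1)^psi)^(1/psi)` between an
#'   exponential phase (rate `lambda0`, day^-1) and a linear phase (slope
#'   `lambda1`, cm^3/day), with large fixed `psi` (default 20) giving a fast
#'   transition
#' * `surface`: `g = a V^(2/3)` (growth proportional to surface area)
#' * `rim`: `g = a * (V - max(0, (R - d))^3 * 4*pi/3)` — proliferation
#'   confined to an outer rim of fixed thickness `d` (cm), with
#'   `R = (3V/4pi)^(1/3)`
#'
#' @param name One of `"linear"`, `"exponential"`, `"logistic"`,
#'   `"gompertz"`, `"exponential_linear"`, `"surface"`, `"rim"`.
#' @param params Named list of positive parameters for the law (see above),
#'   including `V0` (initial volume, cm^3) and optionally `k_drug`
#'   (kg mg^-1 day^-1, default 0).
#' @return A `growth_law` object with elements `name`, `params`, and the
#'   rate function `g`.
#' @examples
#' law <- growth_law("gompertz", list(a = 0.1, K = 5, V0 = 0.2))
#' growth_rate(law, c(0.5, 5))
#' @export
growth_law <- function(name, params) {
  known <- c("linear", "exponential", "logistic", "gompertz",
             "exponential_linear", "surface", "rim")
  if (!is.character(name) || length(name) != 1L || !(name %in% known))
    stop("growth_law: unknown law '", name, "'; expected one of ",
         paste(known, collapse = ", "), call. = FALSE)
  req <- switch(name,
    linear = "a", exponential = "a", logistic = c("a", "K"),
    gompertz = c("a", "K"), exponential_linear = c("lambda0", "lambda1"),
    surface = "a", rim = c("a", "d"))
  if (!all(req %in% names(params)))
    stop("growth_law: '", name, "' needs parameters ",
         paste(req, collapse = ", "), call. = FALSE)
  if (name == "exponential_linear" && is.null(params$psi)) params$psi <- 20
  if (is.null(params$k_drug)) params$k_drug <- 0
  for (nm in setdiff(names(params), "k_drug"))
    if (!is.finite(params[[nm]]) || params[[nm]] <= 0)
      stop("growth_law: parameter '", nm, "' must be positive", call. = FALSE)
  g <- switch(name,
    linear = function(V, p) rep(p$a, length(V)),
    exponential = function(V, p) p$a * V,
    logistic = function(V, p) p$a * V * (1 - V / p$K),
    gompertz = function(V, p) p$a * V * log(p$K / V),
    exponential_linear = function(V, p) {
      # stable for large (lambda0 V / lambda1)^psi
      lr <- p$psi * (log(p$lambda0) + log(V) - log(p$lambda1))
      denom <- ifelse(lr > 700, exp(lr / p$psi), (1 + exp(lr))^(1 / p$psi))
      p$lambda0 * V / denom
    },
    surface = function(V, p) p$a * V^(2 / 3),
    rim = function(V, p) {
      R <- (3 * V / (4 * pi))^(1 / 3)
      core <- pmax(R - p$d, 0)^3 * 4 * pi / 3
      p$a * (V - core)
    })
  structure(list(name = name, params = params, g = g), class = "growth_law")
}

#' @rdname growth_law
#' @param law A `growth_law` object.
#' @param V Volumes (cm^3), positive; vectorized.
#' @return `growth_rate()`: growth rates `g(V)` in cm^3/day.
#' @export
growth_rate <- function(law, V) {
  stopifnot(inherits(law, "growth_law"))
  if (any(!is.finite(V)) || any(V <= 0))
    stop("growth_rate: V must be positive and finite", call. = FALSE)
  law$g(V, law$params)
}

#' Simulate an empirical growth law under a dosing schedule
#'
#' Integrates `dV/dt = g(V) - k_drug * c(t) * V` with bolus doses handled as
#' concentration jumps (integration restarts at each dose time).
#'
#' @param law A [growth_law()] object; `law$params$V0` is the initial volume
#'   and `law$params$k_drug` the drug potency.
#' @inheritParams simulate_dl
#' @return A data.frame with columns `time`, `V` and `conc`.
#' @examples
#' law <- growth_law("exponential", list(a = 0.08, V0 = 0.29))
#' simulate_law(law, t_grid = c(0, 5))
#' @export
simulate_law <- function(law, schedule = NULL, t_grid,
                         rtol = 1e-9, atol = 1e-11) {
  stopifnot(inherits(law, "growth_law"))
  .check_grid(t_grid)
  if (is.null(law$params$V0))
    stop("simulate_law: law$params$V0 is required", call. = FALSE)
  sch <- .as_schedule(schedule)
  make_rhs <- function(conc_fun) {
    function(t, y, p) {
      V <- max(y[1], 1e-300)
      list(law$g(V, law$params) - law$params$k_drug * conc_fun(t) * V)
    }
  }
  V <- .integrate_segments(make_rhs, y0 = c(V = law$params$V0), t_grid, sch,
                           rtol, atol)[, "V"]
  data.frame(time = t_grid, V = V, conc = pk_concentration(t_grid, sch))
}
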