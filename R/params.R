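#' Diffusion-limited model parameters
#'
#' Bundles the five parameters of the diffusion-limited growth law: tumor
#' volume grows at net rate `lambda_net` in the proliferating fraction, is
#' lost at rate `lambda_nec` from the necrotic fraction, and is killed at
#' rate `k_drug * c(t)` in the proliferating fraction, where `c(t)` is the
#' plasma drug concentration in mg/kg. Necrosis first appears when the tumor
#' radius exceeds the critical radius `R_c`.
#'
#' @param lambda_net Net proliferation rate in the growing fraction (day^-1).
#' @param lambda_nec Breakdown/removal rate in the necrotic core (day^-1).
#' @param k_drug Drug potency (kg mg^-1 day^-1).
#' @param R_c Critical radius at which necrosis first appears (cm).
#' @param V0 Initial tumor volume (cm^3).
#'
#' @return An object of class `dl_params`.
#' @examples
#' p <- dl_params(lambda_net = 0.12, lambda_nec = 0.05,
#'                k_drug = 5.7e-3, R_c = 0.41, V0 = 0.25)
#' critical_volume(p$R_c)
#' @export
dl_params <- function(lambda_net, lambda_nec, k_drug, R_c, V0) {
  x <- list(lambda_net = lambda_net, lambda_nec = lambda_nec,
            k_drug = k_drug, R_c = R_c, V0 = V0)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("dl_params: '", nm, "' must be a single positive finite number",
           call. = FALSE)
  }
  structure(x, class = "dl_params")
}

#' Exponential-linear model parameters
#'
#' The exponential-linear growth law interpolates smoothly between an
#' exponential phase with rate `lambda0` and a linear phase with slope
#' `lambda1`; the transition sharpness `psi` is conventionally held fixed at
#' a large value (20) so the model is effectively three-parameter plus the
#' drug potency.
#'
#' @param lambda0 Exponential-phase growth rate (day^-1).
#' @param lambda1 Linear-phase growth rate (cm^3 day^-1).
#' @param k_drug Drug potency (kg mg^-1 day^-1).
#' @param V0 Initial tumor volume (cm^3).
#' @param psi Transition sharpness (dimensionless, fixed by default).
#'
#' @return An object of class `el_params`.
#' @export
el_params <- function(lambda0, lambda1, k_drug, V0, psi = 20) {
  x <- list(lambda0 = lambda0, lambda1 = lambda1, k_drug = k_drug,
            V0 = V0, psi = psi)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("el_params: '", nm, "' must be a single positive finite number",
           call. = FALSE)
  }
  structure(x, class = "el_params")
}

#' @export
print.dl_params <- function(x, ...) {
  cat("Diffusion-limited growth parameters:\n")
  cat(sprintf("  lambda_net %.4g /day   lambda_nec %.4g /day\n",
              x$lambda_net, x$lambda_nec))
  cat(sprintf("  k_drug %.4g kg/mg/day   R_c %.4g cm (V_c %.4g cm^3)   V0 %.4g cm^3\n",
              x$k_drug, x$R_c, critical_volume(x$R_c), x$V0))
  invisible(x)
}

#' @export
print.el_params <- function(x, ...) {
  cat("Exponential-linear growth parameters:\n")
  cat(sprintf("  lambda0 %.4g /day   lambda1 %.4g cm^3/day   psi %.3g (fixed)\n",
              x$lambda0, x$lambda1, x$psi))
  cat(sprintf("  k_drug %.4g kg/mg/day   V0 %.4g cm^3\n", x$k_drug, x$V0))
  invisible(x)
}
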