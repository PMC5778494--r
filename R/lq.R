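#' LQ linear coefficient from the MKM quality variable
#'
#' `alpha = alpha0 + beta * zstar`: the MKM predicts the linear coefficient
#' of the linear-quadratic survival model from the saturation-corrected
#' dose-mean specific energy per event, with `beta` independent of radiation
#' quality.
#'
#' @param params an [mkm_params()] set (or preset name).
#' @param zstar z*_1D in Gy; non-negative (vectorized).
#' @return alpha in Gy^-1.
#' @export
alpha_from_zstar <- function(params, zstar) {
  params <- as_mkm_params(params)
  if (any(!is.finite(zstar)) || any(zstar < 0))
    stop_mkm("invalid_parameter", "zstar must be non-negative")
  params$alpha0 + params$beta * zstar
}

#' Dose producing a given surviving fraction (inverse LQ model)
#'
#' Solves `exp(-alpha*D - beta*D^2) = S` for the positive dose. The root is
#' evaluated in the cancellation-free form
#' `D = -2 log(S) / (alpha + sqrt(alpha^2 - 4*beta*log(S)))`,
#' which degrades gracefully to the pure-linear limit `-log(S)/alpha` as
#' `beta -> 0` (the branch switches below beta = 1e-12).
#'
#' @param alpha linear coefficient, Gy^-1 (> 0).
#' @param beta quadratic coefficient, Gy^-2 (>= 0).
#' @param survival target surviving fraction in (0, 1); vectorized over
#'   `alpha`, `beta`, `survival`.
#' @return Dose in Gy.
#' @export
dose_for_survival <- function(alpha, beta, survival) {
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop_mkm("invalid_parameter", "alpha must be positive")
  if (any(!is.finite(beta)) || any(beta < 0))
    stop_mkm("invalid_parameter", "beta must be non-negative")
  if (any(!is.finite(survival)) || any(survival <= 0) || any(survival >= 1))
    stop_mkm("invalid_parameter", "survival must lie strictly in (0, 1)")
  lnS <- log(survival)
  n <- max(length(alpha), length(beta), length(lnS))
  alpha <- rep_len(alpha, n); beta <- rep_len(beta, n); lnS <- rep_len(lnS, n)
  ifelse(beta < 1e-12,
         -lnS / alpha,
         -2 * lnS / (alpha + sqrt(alpha^2 - 4 * beta * lnS)))
}

#' Surviving fraction at a given dose (forward LQ model)
#'
#' `S = exp(-alpha*D - beta*D^2)`; equals 1 at zero dose and is strictly
#' decreasing in dose.
#'
#' @inheritParams dose_for_survival
#' @param dose absorbed dose, Gy (>= 0); vectorized.
#' @return Surviving fraction in (0, 1].
#' @export
survival_for_dose <- function(alpha, beta, dose) {
  if (any(!is.finite(dose)) || any(dose < 0))
    stop_mkm("invalid_parameter", "dose must be non-negative")
  exp(-alpha * dose - beta * dose^2)
}

#' RBE at a survival endpoint
#'
#' The relative biological effectiveness of a test field with LQ
#' coefficients `(alpha, beta)` against a reference radiation, at the
#' surviving fraction `survival` (default 10%):
#' `RBE = D_ref(S) / D_test(S)`. RBE exceeds 1 exactly when the test field
#' needs less dose than the reference for the same effect.
#'
#' @inheritParams dose_for_survival
#' @param reference a [reference_radiation()] (or preset name `"X200KVP"`).
#' @param survival endpoint surviving fraction, default 0.1.
#' @return Dimensionless RBE.
#' @export
rbe_at_endpoint <- function(alpha, beta, reference = reference_radiation(),
                            survival = 0.1) {
  reference <- as_reference(reference)
  check_survival_fraction(survival)
  dose_for_survival(reference$alpha_x, reference$beta_x, survival) /
    dose_for_survival(alpha, beta, survival)
}
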