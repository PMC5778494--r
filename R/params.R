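#' MKM parameter set
#'
#' The microdosimetric kinetic model predicts the linear LQ coefficient from
#' radiation quality as `alpha = alpha0 + beta * z*_1D`, with `beta` treated
#' as independent of radiation quality. A parameter set bundles the LQ
#' intercept `alpha0`, the shared `beta`, the sensitive-domain radius `rd`,
#' the saturation parameter `y0` and the domain density `rho`.
#'
#' Two immutable presets fitted to human salivary gland (HSG) cell survival
#' are provided via [mkm_preset()]:
#' \describe{
#'   \item{SET_A}{alpha0 = 0.155 Gy^-1, beta = 0.0615 Gy^-2, rd = 0.282 um,
#'     y0 = 93.4 keV/um — the survival-analysis set.}
#'   \item{SET_B}{alpha0 = 0.13 Gy^-1, beta = 0.05 Gy^-2, rd = 0.42 um,
#'     y0 = 150 keV/um — the RBE-weighted-dose set (default downstream).}
#' }
#'
#' @param alpha0 LQ linear coefficient in the limit of vanishing LET, Gy^-1.
#' @param beta LQ quadratic coefficient, Gy^-2.
#' @param rd domain radius, um.
#' @param y0 saturation parameter, keV/um.
#' @param rho domain density, g/cm^3.
#' @return An object of class `"mkm_params"`.
#' @examples
#' mkm_preset("SET_B")
#' @export
mkm_params <- function(alpha0, beta, rd, y0, rho = 1.0) {
  vals <- c(alpha0 = alpha0, beta = beta, rd = rd, y0 = y0, rho = rho)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_mkm("invalid_parameter", "all MKM parameters must be positive and finite")
  structure(as.list(vals), class = "mkm_params")
}

.mkm_presets <- list(
  SET_A = list(alpha0 = 0.155, beta = 0.0615, rd = 0.282, y0 = 93.4, rho = 1.0),
  SET_B = list(alpha0 = 0.13,  beta = 0.05,   rd = 0.42,  y0 = 150,  rho = 1.0))

#' @rdname mkm_params
#' @param name preset name, `"SET_A"` or `"SET_B"`.
#' @export
mkm_preset <- function(name = c("SET_B", "SET_A")) {
  name <- match.arg(toupper(name), c("SET_B", "SET_A"))
  p <- .mkm_presets[[name]]
  out <- mkm_params(p$alpha0, p$beta, p$rd, p$y0, p$rho)
  attr(out, "preset") <- name
  out
}

as_mkm_params <- function(x) {
  if (inherits(x, "mkm_params")) return(x)
  if (is.character(x) && length(x) == 1L) return(mkm_preset(x))
  stop_mkm("type_error", "expected an 'mkm_params' object or preset name")
}

#' @export
print.mkm_params <- function(x, ...) {
  preset <- attr(x, "preset")
  cat("MKM parameter set", if (!is.null(preset)) paste0("(", preset, ")"), "\n")
  cat(sprintf("  alpha0 = %g Gy^-1, beta = %g Gy^-2\n", x$alpha0, x$beta))
  cat(sprintf("  domain: rd = %g um, rho = %g g/cm^3; y0 = %g keV/um\n",
              x$rd, x$rho, x$y0))
  invisible(x)
}

#' Reference radiation
#'
#' LQ coefficients of the reference field used in the RBE ratio. The default
#' is 200 kVp X-rays with alpha = 0.19 Gy^-1 and beta = 0.05 Gy^-2
#' (preset name `"X200KVP"`).
#'
#' @param alpha_x linear coefficient, Gy^-1 (> 0).
#' @param beta_x quadratic coefficient, Gy^-2 (>= 0).
#' @param label free-text description.
#' @return An object of class `"reference_radiation"`.
#' @export
reference_radiation <- function(alpha_x = 0.19, beta_x = 0.05,
                                label = "200 kVp X-rays") {
  if (!is.finite(alpha_x) || alpha_x <= 0)
    stop_mkm("invalid_parameter", "alpha_x must be positive")
  if (!is.finite(beta_x) || beta_x < 0)
    stop_mkm("invalid_parameter", "beta_x must be non-negative")
  structure(list(alpha_x = alpha_x, beta_x = beta_x, label = label),
            class = "reference_radiation")
}

#' @rdname reference_radiation
#' @param name preset name; `"X200KVP"` is the only built-in.
#' @export
reference_preset <- function(name = "X200KVP") {
  if (toupper(name) != "X200KVP")
    stop_mkm("unknown_preset", sprintf("unknown reference preset '%s'", name))
  reference_radiation()
}

as_reference <- function(x) {
  if (inherits(x, "reference_radiation")) return(x)
  if (is.character(x) && length(x) == 1L) return(reference_preset(x))
  stop_mkm("type_error", "expected a 'reference_radiation' object or preset name")
}

#' @export
print.reference_radiation <- function(x, ...) {
  cat(sprintf("Reference radiation: %s (alpha = %g Gy^-1, beta = %g Gy^-2)\n",
              x$label, x$alpha_x, x$beta_x))
  invisible(x)
}

check_survival_fraction <- function(survival) {
  if (!is.numeric(survival) || length(survival) != 1L ||
      !is.finite(survival) || survival <= 0 || survival >= 1)
    stop_mkm("invalid_parameter", "survival fraction must lie strictly in (0, 1)")
  survival
}
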