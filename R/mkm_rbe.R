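#' Fit an MKM RBE-weighted depth-dose profile
#'
#' The central estimator of the package. For every depth of a
#' [spectrum_series()] it (1) averages the d(y) spectra over a
#' `+/- window_mm` depth window, (2) reduces the averaged spectrum to the
#' saturation-corrected dose-mean specific energy per event z*_1D
#' ([z_star_1d()]), (3) maps z*_1D to the LQ linear coefficient
#' `alpha = alpha0 + beta * z*_1D` ([alpha_from_zstar()]), (4) forms the RBE
#' at the survival endpoint against the reference radiation
#' ([rbe_at_endpoint()]), and (5) multiplies the physical dose by the RBE to
#' obtain the RBE-weighted dose. Depths whose window contains no spectrum
#' are excluded and reported, never interpolated.
#'
#' @param series a [spectrum_series()] (or the result of [generate_beam()],
#'   whose series and dose are used directly).
#' @param physical_dose physical dose per depth, Gy; defaults to the dose
#'   stored in the series.
#' @param params [mkm_params()] set or preset name; default `SET_B`, the
#'   RBE-weighted-dose parameter set.
#' @param reference [reference_radiation()]; default 200 kVp X-rays.
#' @param survival endpoint surviving fraction; default 0.1 (RBE at 10%
#'   survival, independent of dose and dose rate).
#' @param window_mm spectral averaging half-width, mm; default 1.5.
#' @param depths depths (mm) at which to evaluate; defaults to the series
#'   depths. A depth whose averaging window contains no spectrum is excluded
#'   from the fit and listed in `$excluded` — never interpolated.
#' @return An object of class `"mkm_profile"` with components `data` (a
#'   data frame with columns `depth_mm`, `physical_dose_Gy`, `z_star_Gy`,
#'   `alpha_Gy.1`, `rbe`, `rbe_weighted_dose_Gy`), `excluded` (depths
#'   dropped for missing spectra), and the fitting configuration.
#' @examples
#' beam <- generate_beam(beam_config(depth_grid = seq(0, 150, by = 1)))
#' fit <- mkm_rbe(beam)
#' summary(fit)
#' @seealso [normalize_profile()], [survival_depth_profile()]
#' @export
mkm_rbe <- function(series, physical_dose = NULL,
                    params = mkm_preset("SET_B"),
                    reference = reference_radiation(),
                    survival = 0.1, window_mm = 1.5, depths = NULL) {
  if (inherits(series, "synthetic_beam"))
    series <- series$series   # carries the aligned dose for its depths
  if (!inherits(series, "spectrum_series"))
    stop_mkm("type_error", "expected a 'spectrum_series' or 'synthetic_beam'")
  params <- as_mkm_params(params)
  reference <- as_reference(reference)
  check_survival_fraction(survival)
  if (is.null(depths)) {
    depths <- series$depths
    if (is.null(physical_dose)) physical_dose <- series$dose
  }
  if (is.null(physical_dose))
    stop_mkm("invalid_parameter",
             "physical_dose missing and the series carries no dose")
  if (length(physical_dose) != length(depths))
    stop_mkm("invalid_parameter", "physical_dose must align with depths")

  n <- length(depths)
  z_star <- rbe <- rep(NA_real_, n)
  keep <- logical(n)
  reasons <- character(0); excl_depth <- numeric(0)
  for (i in seq_len(n)) {
    sp <- tryCatch(depth_window_average(series, depths[i], window_mm),
                   mkm_error = function(e) e)
    if (inherits(sp, "mkm_error")) {
      excl_depth <- c(excl_depth, depths[i])
      reasons <- c(reasons, mkm_error_code(sp))
      next
    }
    keep[i] <- TRUE
    z_star[i] <- z_star_1d(sp, params)
  }
  alpha <- ifelse(keep, params$alpha0 + params$beta * z_star, NA_real_)
  rbe[keep] <- rbe_at_endpoint(alpha[keep], params$beta, reference, survival)

  data <- data.frame(
    depth_mm = depths[keep],
    physical_dose_Gy = physical_dose[keep],
    z_star_Gy = z_star[keep],
    alpha_Gy.1 = alpha[keep],
    rbe = rbe[keep],
    rbe_weighted_dose_Gy = rbe[keep] * physical_dose[keep])
  structure(list(
    data = data,
    excluded = data.frame(depth_mm = excl_depth, reason = reasons),
    params = params, reference = reference,
    survival = survival, window_mm = window_mm,
    normalization = NULL, call = match.call()),
    class = "mkm_profile")
}

#' @export
print.mkm_profile <- function(x, ...) {
  d <- x$data
  cat("MKM RBE-weighted depth-dose profile\n")
  cat(sprintf("  %d depths on [%.4g, %.4g] mm (%d excluded: missing spectra)\n",
              nrow(d), min(d$depth_mm), max(d$depth_mm), nrow(x$excluded)))
  preset <- attr(x$params, "preset")
  cat(sprintf("  params: %salpha0 %g, beta %g, rd %g um, y0 %g keV/um\n",
              if (!is.null(preset)) paste0(preset, ": ") else "",
              x$params$alpha0, x$params$beta, x$params$rd, x$params$y0))
  cat(sprintf("  reference: %s; endpoint S = %g; window +/- %g mm\n",
              x$reference$label, x$survival, x$window_mm))
  cat(sprintf("  RBE range: %.4g (entrance %.4g) to %.4g\n",
              min(d$rbe), d$rbe[1], max(d$rbe)))
  if (!is.null(x$normalization))
    cat(sprintf("  normalized: %s dose = %g Gy at %s (%.4g mm)\n",
                x$normalization$on, x$normalization$target_dose,
                x$normalization$mode, x$normalization$anchor_depth))
  invisible(x)
}

#' @export
summary.mkm_profile <- function(object, ...) {
  d <- object$data
  bp <- anchor_depth(object, "bragg_peak")
  sc <- tryCatch(anchor_depth(object, "sobp_center"), error = function(e) NA_real_)
  out <- list(
    n_depths = nrow(d), excluded = object$excluded,
    bragg_peak_mm = bp, sobp_center_mm = sc,
    entrance = d[1, ], peak = d[which.max(d$physical_dose_Gy), ],
    rbe_range = range(d$rbe), params = object$params,
    reference = object$reference, survival = object$survival,
    normalization = object$normalization, profile = object)
  class(out) <- "summary.mkm_profile"
  out
}

#' @export
print.summary.mkm_profile <- function(x, ...) {
  print(x$profile)
  cat(sprintf("  Bragg peak (argmax dose): %.4g mm; SOBP center (95%% rule): %.4g mm\n",
              x$bragg_peak_mm, x$sobp_center_mm))
  cat(sprintf("  entrance: dose %.4g Gy, RBE %.4g, weighted %.4g Gy\n",
              x$entrance$physical_dose_Gy, x$entrance$rbe,
              x$entrance$rbe_weighted_dose_Gy))
  cat(sprintf("  at peak:  dose %.4g Gy, RBE %.4g, weighted %.4g Gy\n",
              x$peak$physical_dose_Gy, x$peak$rbe, x$peak$rbe_weighted_dose_Gy))
  invisible(x)
}

#' @export
coef.mkm_profile <- function(object, ...) {
  d <- object$data
  m <- cbind(alpha = d$alpha_Gy.1, beta = object$params$beta)
  rownames(m) <- format(d$depth_mm)
  m
}

#' @export
as.data.frame.mkm_profile <- function(x, ...) x$data

#' Interpolate fitted quantities at new depths
#'
#' Linear interpolation of the fitted per-depth quantities; for
#' `type = "survival"` the LQ survival is evaluated at the interpolated
#' alpha and physical dose (or at `dose`, if supplied).
#'
#' @param object an `"mkm_profile"`.
#' @param depth depths (mm) at which to evaluate; default the fitted depths.
#' @param type one of `"rbe"`, `"alpha"`, `"z_star"`, `"physical_dose"`,
#'   `"rbe_weighted_dose"`, `"survival"`.
#' @param dose optional dose (Gy) overriding the profile dose when
#'   `type = "survival"`.
#' @param ... unused.
#' @return Numeric vector aligned with `depth`.
#' @export
predict.mkm_profile <- function(object, depth = NULL, type = "rbe",
                                dose = NULL, ...) {
  d <- object$data
  if (is.null(depth)) depth <- d$depth_mm
  type <- match.arg(type, c("rbe", "alpha", "z_star", "physical_dose",
                            "rbe_weighted_dose", "survival"))
  col <- switch(type, rbe = "rbe", alpha = "alpha_Gy.1", z_star = "z_star_Gy",
                physical_dose = "physical_dose_Gy",
                rbe_weighted_dose = "rbe_weighted_dose_Gy", survival = NULL)
  ip <- function(v) stats::approx(d$depth_mm, v, xout = depth, rule = 2)$y
  if (type != "survival") return(ip(d[[col]]))
  a <- ip(d$alpha_Gy.1)
  D <- if (is.null(dose)) ip(d$physical_dose_Gy) else rep_len(dose, length(depth))
  survival_for_dose(a, object$params$beta, D)
}

#' Plot an MKM profile
#'
#' Physical and RBE-weighted depth-dose curves (left axis) with the RBE
#' overlaid on the right axis.
#'
#' @param x an `"mkm_profile"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.mkm_profile <- function(x, ...) {
  d <- x$data
  op <- graphics::par(mar = c(5, 4, 2, 4)); on.exit(graphics::par(op))
  graphics::matplot(d$depth_mm,
                    cbind(d$physical_dose_Gy, d$rbe_weighted_dose_Gy),
                    type = "l", lty = c(1, 2), col = c("black", "firebrick"),
                    xlab = "depth [mm]", ylab = "dose [Gy]", ...)
  graphics::par(new = TRUE)
  graphics::plot(d$depth_mm, d$rbe, type = "l", col = "steelblue",
                 axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4); graphics::mtext("RBE", side = 4, line = 2.5)
  graphics::legend("topleft", bty = "n", lty = c(1, 2, 1),
                   col = c("black", "firebrick", "steelblue"),
                   legend = c("physical", "RBE-weighted", "RBE"))
  invisible(x)
}

## anchor depth used by normalization and prescriptions.
## bragg_peak: argmax of physical dose. sobp_center: midpoint between the
## proximal and distal depths where the dose first/last reaches 95% of max.
anchor_depth <- function(profile, mode, depth = NULL) {
  d <- profile$data
  switch(mode,
    bragg_peak = d$depth_mm[which.max(d$physical_dose_Gy)],
    sobp_center = {
      thr <- 0.95 * max(d$physical_dose_Gy)
      idx <- which(d$physical_dose_Gy >= thr)
      (d$depth_mm[min(idx)] + d$depth_mm[max(idx)]) / 2
    },
    custom_depth = {
      if (is.null(depth))
        stop_mkm("invalid_parameter", "custom_depth mode requires 'depth'")
      depth
    },
    stop_mkm("invalid_parameter", sprintf("unknown anchor mode '%s'", mode)))
}

#' Normalize a fitted profile at an anchor depth
#'
#' Rescales both the physical and the RBE-weighted dose arrays by the single
#' factor that makes the selected array equal `target_dose` at the anchor:
#' the Bragg peak (argmax of physical dose), the SOBP center (midpoint of
#' the region where the dose is within 95% of its maximum), or a custom
#' depth. RBE is invariant under this pure rescale.
#'
#' @param profile an `"mkm_profile"`.
#' @param mode `"bragg_peak"`, `"sobp_center"` or `"custom_depth"`.
#' @param target_dose anchor dose, Gy; default 2.
#' @param on which array the target applies to: `"physical"` or
#'   `"rbe_weighted"`.
#' @param depth anchor depth (mm) when `mode = "custom_depth"`.
#' @return The rescaled `"mkm_profile"`, with the normalization convention
#'   recorded in `$normalization`.
#' @export
normalize_profile <- function(profile,
                              mode = c("bragg_peak", "sobp_center", "custom_depth"),
                              target_dose = 2,
                              on = c("physical", "rbe_weighted"),
                              depth = NULL) {
  if (!inherits(profile, "mkm_profile"))
    stop_mkm("type_error", "expected an 'mkm_profile' object")
  if (!nrow(profile$data)) stop_mkm("empty_profile", "profile has no depths")
  mode <- match.arg(mode); on <- match.arg(on)
  anchor <- anchor_depth(profile, mode, depth)
  d <- profile$data
  col <- if (on == "physical") "physical_dose_Gy" else "rbe_weighted_dose_Gy"
  at <- stats::approx(d$depth_mm, d[[col]], xout = anchor, rule = 2)$y
  if (!is.finite(at) || at <= 0)
    stop_mkm("invalid_anchor", sprintf("%s dose at anchor %.4g mm is not positive",
                                       on, anchor))
  f <- target_dose / at
  profile$data$physical_dose_Gy <- d$physical_dose_Gy * f
  profile$data$rbe_weighted_dose_Gy <- d$rbe_weighted_dose_Gy * f
  profile$normalization <- list(mode = mode, anchor_depth = anchor,
                                target_dose = target_dose, on = on,
                                convention = "plateau edges at 95% of max dose",
                                factor = f)
  profile
}

#' Cell-survival depth profile under a prescription
#'
#' Scales the physical depth-dose so that the prescription holds at the SOBP
#' center — either a prescribed physical dose there (`dose_at_center`) or a
#' prescribed surviving fraction there (`survival_at_center`, inverted
#' through the local LQ coefficients) — then evaluates the per-depth
#' surviving fraction `S(z) = exp(-alpha(z) D(z) - beta D(z)^2)` with the
#' profile's per-depth alpha and its parameter-set beta.
#'
#' @param profile an `"mkm_profile"` fitted by [mkm_rbe()].
#' @param dose_at_center prescribed physical dose at the SOBP center, Gy.
#' @param survival_at_center prescribed surviving fraction at the SOBP
#'   center (exclusive with `dose_at_center`).
#' @return A data frame with columns `depth_mm`, `physical_dose_Gy`,
#'   `survival`; the prescription and center dose are stored in attributes
#'   `prescription` and `center_dose_Gy`.
#' @export
survival_depth_profile <- function(profile, dose_at_center = NULL,
                                   survival_at_center = NULL) {
  if (!inherits(profile, "mkm_profile"))
    stop_mkm("type_error", "expected an 'mkm_profile' object")
  if (is.null(dose_at_center) == is.null(survival_at_center))
    stop_mkm("invalid_parameter",
             "supply exactly one of dose_at_center or survival_at_center")
  d <- profile$data
  center <- anchor_depth(profile, "sobp_center")
  dose_c <- stats::approx(d$depth_mm, d$physical_dose_Gy, xout = center,
                          rule = 2)$y
  if (!is.finite(dose_c) || dose_c <= 0)
    stop_mkm("invalid_anchor", "zero physical dose at the SOBP center")
  beta <- profile$params$beta
  if (is.null(dose_at_center)) {
    check_survival_fraction(survival_at_center)
    alpha_c <- stats::approx(d$depth_mm, d$alpha_Gy.1, xout = center, rule = 2)$y
    dose_at_center <- dose_for_survival(alpha_c, beta, survival_at_center)
    prescription <- list(type = "survival_at_center",
                         value = survival_at_center)
  } else {
    if (dose_at_center < 0)
      stop_mkm("invalid_parameter", "dose_at_center must be non-negative")
    prescription <- list(type = "dose_at_center", value = dose_at_center)
  }
  D <- d$physical_dose_Gy * (dose_at_center / dose_c)
  out <- data.frame(depth_mm = d$depth_mm, physical_dose_Gy = D,
                    survival = survival_for_dose(d$alpha_Gy.1, beta, D))
  attr(out, "prescription") <- prescription
  attr(out, "center_dose_Gy") <- dose_at_center
  attr(out, "center_depth_mm") <- center
  out
}
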