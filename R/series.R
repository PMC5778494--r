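#' Depth-indexed series of lineal-energy spectra
#'
#' Pairs each depth along the beam axis with the d(y) spectrum scored there,
#' optionally carrying the physical dose per depth for dose-weighted
#' averaging.
#'
#' @param depths numeric vector of depths, mm, strictly increasing.
#' @param spectra list of [lineal_spectrum()] objects, one per depth.
#' @param dose optional numeric vector of physical dose per depth, Gy
#'   (arbitrary common scale is fine); non-negative.
#' @return An object of class `"spectrum_series"`.
#' @export
spectrum_series <- function(depths, spectra, dose = NULL) {
  depths <- as.numeric(depths)
  if (any(diff(depths) <= 0))
    stop_mkm("invalid_grid", "depths must be strictly increasing")
  if (!is.list(spectra) || length(spectra) != length(depths))
    stop_mkm("type_error", "spectra must be a list with one entry per depth")
  ok <- vapply(spectra, inherits, logical(1), what = "lineal_spectrum")
  if (!all(ok))
    stop_mkm("type_error", "all spectra entries must be 'lineal_spectrum' objects")
  if (!is.null(dose)) {
    dose <- as.numeric(dose)
    if (length(dose) != length(depths) || any(!is.finite(dose)) || any(dose < 0))
      stop_mkm("invalid_parameter",
               "dose must be non-negative and aligned with depths")
  }
  structure(list(depths = depths, spectra = spectra, dose = dose),
            class = "spectrum_series")
}

#' @export
print.spectrum_series <- function(x, ...) {
  cat(sprintf("Spectrum series: %d depths on [%.4g, %.4g] mm%s\n",
              length(x$depths), min(x$depths), max(x$depths),
              if (is.null(x$dose)) "" else " (with physical dose)"))
  invisible(x)
}

#' Average spectra over a depth window
#'
#' Emulates the finite axial extent of a tissue-equivalent proportional
#' counter by averaging the per-depth d(y) spectra within
#' `center +/- halfwidth` (default half-width 1.5 mm). Member spectra are
#' linearly interpolated onto the union of their y grids (zero outside a
#' member's support), combined as a dose-weighted mean when the series
#' carries physical dose (uniform weights otherwise), and renormalized.
#'
#' @param series a [spectrum_series()].
#' @param center window center, mm.
#' @param halfwidth window half-width, mm.
#' @return A normalized [lineal_spectrum()] with the window recorded in
#'   its metadata.
#' @export
depth_window_average <- function(series, center, halfwidth = 1.5) {
  if (!inherits(series, "spectrum_series"))
    stop_mkm("type_error", "expected a 'spectrum_series' object")
  idx <- which(abs(series$depths - center) <= halfwidth + 1e-9)
  if (!length(idx))
    stop_mkm("empty_window", sprintf(
      "no spectra within the depth window [%.3f, %.3f] mm",
      center - halfwidth, center + halfwidth))
  members <- series$spectra[idx]
  w <- if (is.null(series$dose)) rep(1, length(idx)) else series$dose[idx]
  if (sum(w) <= 0) w <- rep(1, length(idx))
  w <- w / sum(w)
  grid <- sort(unique(unlist(lapply(members, `[[`, "y"))))
  acc <- numeric(length(grid))
  for (k in seq_along(members)) {
    m <- ensure_normalized(members[[k]])
    acc <- acc + w[k] *
      stats::approx(m$y, m$d, xout = grid, yleft = 0, yright = 0)$y
  }
  lineal_spectrum(grid, acc,
                  metadata = list(depth_mm = center, window_mm = halfwidth),
                  normalize = TRUE)
}
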