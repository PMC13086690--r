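#' Construct an absorbance spectrum
#'
#' A sampled absorbance-versus-wavelength curve with minimal metadata.
#' Wavelengths must be strictly increasing. Negative absorbance values are
#' physically meaningless for measured spectra and are rejected, except for
#' difference spectra (where they carry the photoproduct signature) and
#' synthetic spectra (where additive noise can dip below the baseline).
#'
#' @param wavelength_nm Strictly increasing numeric vector, nm.
#' @param absorbance Numeric vector, same length.
#' @param label Free-text label.
#' @param condition One of `"dark"`, `"acid_denatured"`,
#'   `"hydroxylamine_illuminated"`, `"difference"`, `"synthetic"`.
#' @return An object of class `absorbance_spectrum` (a data frame with
#'   columns `wavelength_nm`, `absorbance` and attributes `label`,
#'   `condition`).
#' @export
absorbance_spectrum <- function(wavelength_nm, absorbance, label = "",
                                condition = c("dark", "acid_denatured",
                                              "hydroxylamine_illuminated",
                                              "difference", "synthetic")) {
  condition <- match.arg(condition)
  wavelength_nm <- as.numeric(wavelength_nm)
  absorbance <- as.numeric(absorbance)
  if (length(wavelength_nm) != length(absorbance)) {
    stop_domain("wavelength and absorbance must have equal length")
  }
  if (any(!is.finite(wavelength_nm)) || any(!is.finite(absorbance))) {
    stop_domain("spectrum values must be finite")
  }
  if (any(diff(wavelength_nm) <= 0)) {
    stop_domain("wavelengths must be strictly increasing")
  }
  if (any(absorbance < 0) && !condition %in% c("difference", "synthetic")) {
    stop_domain(sprintf(
      "negative absorbance not allowed for condition '%s'", condition))
  }
  structure(
    data.frame(wavelength_nm = wavelength_nm, absorbance = absorbance),
    label = label, condition = condition,
    class = c("absorbance_spectrum", "data.frame")
  )
}

#' @export
print.absorbance_spectrum <- function(x, ...) {
  cat(sprintf("<absorbance_spectrum> '%s' (%s): %d points, %g-%g nm\n",
              attr(x, "label"), attr(x, "condition"), nrow(x),
              min(x$wavelength_nm), max(x$wavelength_nm)))
  invisible(x)
}

#' Difference of two absorbance spectra
#'
#' Pointwise `minuend - subtrahend`, used to isolate a pigment's
#' contribution from shared contaminants (e.g. free retinal) in
#' acid-denaturation assays: the contaminant is identical in both
#' measurements and cancels, leaving a positive lobe at the pigment peak
#' and a negative lobe at the photoproduct peak.
#'
#' @param minuend,subtrahend `absorbance_spectrum` objects.
#' @param interpolate If `TRUE`, linearly interpolate the subtrahend onto
#'   the minuend's grid over their overlap; if `FALSE` (default) the grids
#'   must match exactly.
#' @return An `absorbance_spectrum` with condition `"difference"`.
#' @export
difference_spectrum <- function(minuend, subtrahend, interpolate = FALSE) {
  stopifnot(inherits(minuend, "absorbance_spectrum"),
            inherits(subtrahend, "absorbance_spectrum"))
  if (!interpolate) {
    if (length(minuend$wavelength_nm) != length(subtrahend$wavelength_nm) ||
        any(minuend$wavelength_nm != subtrahend$wavelength_nm)) {
      stop(errorCondition(
        "wavelength grids differ; set interpolate = TRUE to resample",
        class = c("mothvis_grid_mismatch_error", "mothvis_error")))
    }
    wl <- minuend$wavelength_nm
    diff_ab <- minuend$absorbance - subtrahend$absorbance
  } else {
    lo <- max(min(minuend$wavelength_nm), min(subtrahend$wavelength_nm))
    hi <- min(max(minuend$wavelength_nm), max(subtrahend$wavelength_nm))
    if (lo >= hi) {
      stop(errorCondition("wavelength ranges do not overlap",
        class = c("mothvis_grid_mismatch_error", "mothvis_error")))
    }
    keep <- minuend$wavelength_nm >= lo & minuend$wavelength_nm <= hi
    wl <- minuend$wavelength_nm[keep]
    sub_i <- stats::approx(subtrahend$wavelength_nm, subtrahend$absorbance,
                           xout = wl)$y
    diff_ab <- minuend$absorbance[keep] - sub_i
  }
  absorbance_spectrum(wl, diff_ab,
                      label = paste0(attr(minuend, "label"), " - ",
                                     attr(subtrahend, "label")),
                      condition = "difference")
}

#' Wavelength of maximum absorbance
#'
#' Argmax of the (optionally smoothed) absorbance curve. Smoothing is a
#' centred moving average whose window is given in nm and converted to
#' samples using the median grid spacing. A maximum at the first or last
#' wavelength cannot be distinguished from a curve still rising beyond the
#' measured range, so it triggers a boundary warning.
#'
#' @param spectrum An `absorbance_spectrum` with at least 5 points.
#' @param smoothing_window_nm Moving-average window, nm; 0 disables
#'   smoothing.
#' @return Peak wavelength, nm.
#' @export
peak_wavelength <- function(spectrum, smoothing_window_nm = 0) {
  stopifnot(inherits(spectrum, "absorbance_spectrum"))
  if (nrow(spectrum) < 5L) stop_domain("need at least 5 points")
  check_nonnegative(smoothing_window_nm, "smoothing_window_nm")
  step <- stats::median(diff(spectrum$wavelength_nm))
  window <- if (smoothing_window_nm > 0) {
    max(1L, as.integer(round(smoothing_window_nm / step)))
  } else 1L
  y <- moving_average(spectrum$absorbance, window)
  i <- which.max(y)
  if (i == 1L || i == nrow(spectrum)) {
    warning("absorbance maximum lies at the boundary of the measured range",
            call. = FALSE)
  }
  spectrum$wavelength_nm[i]
}

#' Retinal-oxime shift check
#'
#' Hydroxylamine converts released retinal to retinal oxime, which absorbs
#' near 360 nm. A functional pigment therefore shows a hypsochromic
#' (blue-)shift after hydroxylamine treatment and illumination: the peak
#' moves into the 345--375 nm oxime band and below the dark-state peak.
#'
#' @param before,after `absorbance_spectrum` objects measured before and
#'   after the hydroxylamine/illumination treatment.
#' @param smoothing_window_nm Passed to [peak_wavelength()].
#' @return A list with `peak_before_nm`, `peak_after_nm` and logical
#'   `shifted`.
#' @export
oxime_check <- function(before, after, smoothing_window_nm = 0) {
  pb <- peak_wavelength(before, smoothing_window_nm)
  pa <- peak_wavelength(after, smoothing_window_nm)
  list(
    peak_before_nm = pb,
    peak_after_nm = pa,
    shifted = (pa >= 345 && pa <= 375 && pa < pb)
  )
}
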