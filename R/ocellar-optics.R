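#' Construct a z-stack focus series
#'
#' Focus scores per frame from an automated z-stack through the image
#' formed by a hanging-drop lens preparation. Any unimodal sharpness score
#' (higher = sharper) is accepted; the score is typically the per-frame
#' intensity variance of the grating image. The stack steps through the
#' aqueous medium, so physical distances are the frame count times the
#' step size times the refractive index of the medium (water: 1.33).
#'
#' @param frame_index Integer frame indices.
#' @param focus_score Finite numeric sharpness score per frame.
#' @param step_um Z-step between frames, \eqn{\mu m}.
#' @param refractive_index_n Refractive index of the immersion medium
#'   (default 1.33, water).
#' @param reference_frame Frame at which the lens back surface is in
#'   focus (default 0).
#' @return An object of class `zstack_series`.
#' @export
zstack_series <- function(frame_index, focus_score, step_um,
                          refractive_index_n = 1.33, reference_frame = 0L) {
  frame_index <- as.integer(frame_index)
  focus_score <- as.numeric(focus_score)
  if (length(frame_index) != length(focus_score)) {
    stop_domain("frame_index and focus_score must have equal length")
  }
  if (any(!is.finite(focus_score))) stop_domain("focus scores must be finite")
  check_positive(step_um, "step_um")
  if (!is.numeric(refractive_index_n) || refractive_index_n < 1) {
    stop_domain("refractive_index_n must be >= 1")
  }
  structure(
    data.frame(frame_index = frame_index, focus_score = focus_score),
    step_um = step_um, refractive_index_n = refractive_index_n,
    reference_frame = as.integer(reference_frame),
    class = c("zstack_series", "data.frame")
  )
}

#' Back focal distance from a z-stack focus series
#'
#' Distance from the inner lens surface to the plane of best focus:
#' the number of frames between the sharpest frame (argmax of the,
#' optionally smoothed, focus score) and the reference frame, times the
#' z-step, times the refractive index of the immersion medium.
#'
#' @param series A [zstack_series()].
#' @param smoothing_window Moving-average window (frames) applied to the
#'   focus score before taking the argmax; 1 (default) disables smoothing.
#' @return Back focal distance, \eqn{\mu m}.
#' @examples
#' z <- make_zstack(true_bfd_um = 34.58, step_um = 2, n_frames = 30)
#' back_focal_distance(z)
#' @export
back_focal_distance <- function(series, smoothing_window = 1L) {
  stopifnot(inherits(series, "zstack_series"))
  score <- moving_average(series$focus_score, smoothing_window)
  if (diff(range(score)) == 0) {
    stop(errorCondition(
      "flat focus series: no maximum above the noise floor",
      class = c("mothvis_estimation_error", "mothvis_error")))
  }
  i <- which.max(score)
  if (i == 1L || i == nrow(series)) {
    warning("best focus at the boundary of the z-stack; BFD may be truncated",
            call. = FALSE)
  }
  best <- series$frame_index[i]
  abs(best - attr(series, "reference_frame")) * attr(series, "step_um") *
    attr(series, "refractive_index_n")
}

#' Focal length from grating magnification
#'
#' For an object at effective infinity, the lens focal length follows from
#' the linear magnification of a displayed grating:
#' \deqn{f = s_0 \times \mathrm{image\ period} / \mathrm{object\ period}}
#' where \eqn{s_0} is the object distance. Distances below 100 mm are not
#' effectively at infinity and trigger a warning.
#'
#' @param s0_um Object (grating-to-lens) distance, \eqn{\mu m}.
#' @param image_period_um Period of the grating's image, \eqn{\mu m}.
#' @param object_period_um Period of the displayed grating, same unit
#'   convention as `image_period_um` is arbitrary but must match across
#'   the two periods.
#' @return Focal length, \eqn{\mu m}.
#' @examples
#' focal_length(100000, 19, 10000) # 190 um
#' @export
focal_length <- function(s0_um, image_period_um, object_period_um) {
  check_positive(s0_um, "s0_um")
  check_positive(image_period_um, "image_period_um")
  check_positive(object_period_um, "object_period_um")
  if (s0_um < 1e5) {
    warning("s0 < 100 mm: object not at effective infinity", call. = FALSE)
  }
  s0_um * image_period_um / object_period_um
}

#' Michelson contrast
#'
#' \deqn{M = (I_{max} - I_{min}) / (I_{max} + I_{min})}
#'
#' @param i_max,i_min Maximal and minimal intensity (greyscale), with
#'   `i_max >= i_min >= 0` and a positive sum.
#' @return Contrast in \[0, 1\].
#' @export
michelson_contrast <- function(i_max, i_min) {
  if (!is.finite(i_max) || !is.finite(i_min) || i_min < 0) {
    stop_domain("intensities must be finite and non-negative")
  }
  if (i_min > i_max) stop_domain("i_min exceeds i_max")
  if (i_max + i_min == 0) {
    stop(errorCondition("contrast undefined: both intensities are zero",
      class = c("mothvis_undefined_contrast_error", "mothvis_error")))
  }
  (i_max - i_min) / (i_max + i_min)
}

#' Construct a grating intensity line profile
#'
#' Greyscale intensities sampled along a line perpendicular to the grating
#' stripes, with the grating's known spatial frequency.
#'
#' @param position Sample positions (degrees of visual angle, or pixels —
#'   document the unit per dataset).
#' @param intensity Non-negative greyscale values, same length.
#' @param spatial_frequency_cpd Spatial frequency of the displayed
#'   grating, cycles/degree.
#' @return An object of class `grating_profile`.
#' @export
grating_profile <- function(position, intensity, spatial_frequency_cpd) {
  position <- as.numeric(position)
  intensity <- as.numeric(intensity)
  if (length(position) != length(intensity)) {
    stop_domain("position and intensity must have equal length")
  }
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop_domain("intensities must be finite and non-negative")
  }
  if (any(diff(position) <= 0)) {
    stop_domain("positions must be strictly increasing")
  }
  check_positive(spatial_frequency_cpd, "spatial_frequency_cpd")
  structure(
    data.frame(position = position, intensity = intensity),
    spatial_frequency_cpd = spatial_frequency_cpd,
    class = c("grating_profile", "data.frame")
  )
}

#' Michelson contrast of a grating line profile
#'
#' Applies optional moving-average smoothing, trims an edge fraction on
#' each side (edge samples are contaminated by the window of the imaged
#' patch), and returns the Michelson contrast of the remaining minimum and
#' maximum. At least two full grating periods must remain after trimming.
#'
#' @param profile A [grating_profile()] whose positions are in degrees.
#' @param smoothing_window Moving-average window (samples); 1 = none.
#' @param edge_trim Fraction trimmed from each end (default 0.1).
#' @return Contrast in \[0, 1\].
#' @export
profile_contrast <- function(profile, smoothing_window = 1L,
                             edge_trim = 0.1) {
  stopifnot(inherits(profile, "grating_profile"))
  if (edge_trim < 0 || edge_trim >= 0.5) {
    stop_domain("edge_trim must be in [0, 0.5)")
  }
  n <- nrow(profile)
  drop <- floor(n * edge_trim)
  keep <- seq.int(drop + 1L, n - drop)
  pos <- profile$position[keep]
  span <- diff(range(pos))
  if (span * attr(profile, "spatial_frequency_cpd") < 2) {
    stop(errorCondition(
      "fewer than 2 grating periods remain after trimming",
      class = c("mothvis_insufficient_data_error", "mothvis_error")))
  }
  y <- moving_average(profile$intensity, smoothing_window)[keep]
  michelson_contrast(max(y), min(y))
}

#' Optical cutoff frequency from contrast measurements
#'
#' Fits an unweighted ordinary least-squares line to contrast versus
#' spatial frequency and extrapolates to the frequency at which contrast
#' reaches zero (the x-intercept), the optical cutoff. Points at or below
#' a contrast floor sit in the flat noise tail and are excluded from the
#' fit (but kept in the returned record); the fitted slope must be
#' negative for a cutoff to exist.
#'
#' @param points Data frame with columns `frequency_cpd` (positive,
#'   strictly increasing) and `contrast` (in \[0, 1\]).
#' @param contrast_floor Points with contrast at or below this value are
#'   excluded from the regression. Default 0.02; a floor of 0 disables
#'   the exclusion entirely (all points are fitted).
#' @return An object of class `contrast_curve`: list with `points` (the
#'   input, plus logical `used`), `cutoff_fc_cpd`, `slope`, `intercept`.
#' @examples
#' pts <- data.frame(frequency_cpd = c(0.1, 0.2, 0.3, 0.4),
#'                   contrast = c(0.4, 0.3, 0.2, 0.1))
#' cutoff_frequency(pts)$cutoff_fc_cpd # 0.5
#' @export
cutoff_frequency <- function(points, contrast_floor = 0.02) {
  stopifnot(is.data.frame(points),
            all(c("frequency_cpd", "contrast") %in% names(points)))
  f <- points$frequency_cpd
  m <- points$contrast
  if (any(f <= 0) || any(diff(f) <= 0)) {
    stop_domain("frequencies must be positive and strictly increasing")
  }
  if (any(m < 0 | m > 1)) stop_domain("contrasts must lie in [0, 1]")
  used <- if (contrast_floor > 0) m > contrast_floor else rep(TRUE, length(m))
  if (sum(used) < 3L) {
    stop(errorCondition("fewer than 3 usable contrast points",
      class = c("mothvis_insufficient_data_error", "mothvis_error")))
  }
  fit <- stats::lm(m[used] ~ f[used])
  b0 <- unname(stats::coef(fit)[1])
  b1 <- unname(stats::coef(fit)[2])
  if (b1 >= 0) {
    stop(errorCondition(
      "contrast does not decrease with frequency: no cutoff",
      class = c("mothvis_no_cutoff_error", "mothvis_error")))
  }
  structure(
    list(points = cbind(points, used = used),
         cutoff_fc_cpd = -b0 / b1, slope = b1, intercept = b0),
    class = "contrast_curve"
  )
}

#' @export
print.contrast_curve <- function(x, ...) {
  cat(sprintf(
    "<contrast_curve> %d points (%d fitted), cutoff %.3f cycles/deg\n",
    nrow(x$points), sum(x$points$used), x$cutoff_fc_cpd))
  invisible(x)
}

#' Group summaries of lens measurements
#'
#' Per-group mean, sample standard deviation and count of back focal
#' distances or focal lengths, grouped by grating background color (to
#' expose chromatic aberration) or orientation (astigmatism). A
#' descriptive summary; groups with a single value report sd = 0.
#'
#' @param measurements Data frame with a numeric `value` column and the
#'   grouping column named by `group_by`.
#' @param group_by Name of the grouping column, typically `"color"` or
#'   `"orientation"`.
#' @return Data frame with columns `group`, `mean`, `sd`, `n`.
#' @export
summarize_lens_measurements <- function(measurements, group_by = "color") {
  stopifnot(is.data.frame(measurements), "value" %in% names(measurements),
            group_by %in% names(measurements))
  g <- factor(measurements[[group_by]])
  if (nrow(measurements) == 0L || nlevels(g) == 0L) {
    stop_domain("no groups to summarize")
  }
  out <- do.call(rbind, lapply(levels(g), function(lev) {
    v <- measurements$value[g == lev]
    data.frame(group = lev, mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else 0,
               n = length(v))
  }))
  rownames(out) <- NULL
  out
}
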