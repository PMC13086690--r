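#' Interommatidial angle of a superposition compound eye
#'
#' Anatomical resolution of a spherical superposition eye is set by the
#' angular spacing between neighbouring ommatidia, the facet
#' centre-to-centre spacing `D` divided by the eye's radius of curvature
#' `R` (an angle in radians). The result is reported in degrees, the unit
#' used throughout the comparative literature.
#'
#' @param facet_diameter_um Facet lens diameter `D` (\eqn{\mu m}).
#' @param eye_radius_um Eye radius of curvature `R` (\eqn{\mu m}).
#' @return Interommatidial angle in degrees.
#' @examples
#' interommatidial_angle(22, 969) # ~1.30 degrees
#' @export
interommatidial_angle <- function(facet_diameter_um, eye_radius_um) {
  check_nonnegative(facet_diameter_um, "facet_diameter_um")
  check_positive(eye_radius_um, "eye_radius_um")
  (facet_diameter_um / eye_radius_um) * 180 / pi
}

#' F-number of an optical system
#'
#' Focal length divided by aperture diameter. Lower F-numbers give brighter
#' images; nocturnal superposition eyes reach values well below 1 because
#' the effective aperture (the superposition pupil, visible as eye glow)
#' spans hundreds of facets.
#'
#' @param focal_length_um Focal length `f` (any length unit, consistent
#'   with `aperture_um`).
#' @param aperture_um Aperture (pupil) diameter `A` (same unit as `f`).
#' @return Dimensionless F-number `f/A`.
#' @examples
#' f_number(485, 857)     # moth superposition eye, ~0.57
#' f_number(16700, 8000)  # dark-adapted human eye, ~2.1
#' @export
f_number <- function(focal_length_um, aperture_um) {
  check_positive(focal_length_um, "focal_length_um")
  check_positive(aperture_um, "aperture_um")
  focal_length_um / aperture_um
}

#' Effective rhabdom length
#'
#' A reflective tracheolar tapetum at the basement membrane sends
#' unabsorbed light back up through the rhabdom, so photons traverse the
#' photoreceptor twice and the effective absorbing length is double the
#' physical one. The doubling is an explicit operation here so that the
#' physical anatomy and the optically effective value are never conflated.
#'
#' @param length_physical_um Physical rhabdom length (\eqn{\mu m}).
#' @param has_tapetum Logical; is a reflective tapetum present?
#' @return Effective rhabdom length (\eqn{\mu m}).
#' @export
effective_rhabdom_length <- function(length_physical_um, has_tapetum) {
  check_nonnegative(length_physical_um, "length_physical_um")
  stopifnot(is.logical(has_tapetum), length(has_tapetum) == 1L, !is.na(has_tapetum))
  if (has_tapetum) 2 * length_physical_um else length_physical_um
}

#' Optical sensitivity of an eye viewing an extended scene
#'
#' The classical sensitivity measure
#' \deqn{S = (\pi/4)^2 A^2 (d/f)^2 \frac{kl}{2.3 + kl} \quad (\mu m^2 sr)}
#' where `A` is the aperture diameter, `d` and `f` the rhabdom diameter and
#' focal length, `l` the (effective) rhabdom length and `k` the absorption
#' coefficient of the photoreceptor. Wider pupils, lower F-numbers and
#' larger photoreceptors all increase `S`.
#'
#' @param aperture_um Aperture diameter `A` (\eqn{\mu m}).
#' @param rhabdom_diameter_um Rhabdom diameter `d` (\eqn{\mu m}).
#' @param focal_length_um Focal length `f` (\eqn{\mu m}).
#' @param rhabdom_length_eff_um Effective rhabdom length `l` (\eqn{\mu m});
#'   see [effective_rhabdom_length()].
#' @param absorption_coeff_per_um Absorption coefficient `k`
#'   (\eqn{\mu m^{-1}}); defaults to 0.0067, a value measured in crustacean
#'   rhabdoms and conventional for insect superposition eyes.
#' @return Optical sensitivity in \eqn{\mu m^2 sr}.
#' @examples
#' optical_sensitivity(857, 10, 485, 94) # ~41.4
#' @export
optical_sensitivity <- function(aperture_um, rhabdom_diameter_um,
                                focal_length_um, rhabdom_length_eff_um,
                                absorption_coeff_per_um = 0.0067) {
  check_positive(aperture_um, "aperture_um")
  check_nonnegative(rhabdom_diameter_um, "rhabdom_diameter_um")
  check_positive(focal_length_um, "focal_length_um")
  check_nonnegative(rhabdom_length_eff_um, "rhabdom_length_eff_um")
  check_positive(absorption_coeff_per_um, "absorption_coeff_per_um")
  kl <- absorption_coeff_per_um * rhabdom_length_eff_um
  (pi / 4)^2 * aperture_um^2 * (rhabdom_diameter_um / focal_length_um)^2 *
    (kl / (2.3 + kl))
}

#' Relative image brightness of two eyes from their F-numbers
#'
#' Retinal image brightness for an extended scene scales as \eqn{1/F^2},
#' so eye "a" forms an image \eqn{(F_b/F_a)^2} times brighter than eye "b".
#'
#' @param f_number_a,f_number_b F-numbers of the two eyes.
#' @return How many times brighter eye a's image is than eye b's.
#' @examples
#' brightness_ratio(0.57, 2.1) # ~13.6
#' @export
brightness_ratio <- function(f_number_a, f_number_b) {
  check_positive(f_number_a, "f_number_a")
  check_positive(f_number_b, "f_number_b")
  (f_number_b / f_number_a)^2
}

#' Ratio of optical sensitivities
#'
#' @param sensitivity_a,sensitivity_b Optical sensitivities
#'   (\eqn{\mu m^2 sr}); `sensitivity_b` must be positive.
#' @return `sensitivity_a / sensitivity_b`.
#' @examples
#' sensitivity_ratio(41.4, 0.93) # ~44.5, moth eye vs dark-adapted human
#' @export
sensitivity_ratio <- function(sensitivity_a, sensitivity_b) {
  check_nonnegative(sensitivity_a, "sensitivity_a")
  check_positive(sensitivity_b, "sensitivity_b")
  sensitivity_a / sensitivity_b
}

#' Construct a validated eye-geometry parameter set
#'
#' Bundles the physical parameters of a (superposition) compound eye.
#' For a superposition eye the pupil spans many facets, so `aperture_um`
#' should be at least `facet_diameter_um`; a violation is only a warning
#' because for apposition eyes (e.g. honeybee) aperture and facet diameter
#' coincide and the same container is convenient for comparisons.
#'
#' @param facet_diameter_um Facet diameter `D` (\eqn{\mu m}).
#' @param eye_radius_um Eye radius `R` (\eqn{\mu m}).
#' @param focal_length_um Focal length `f` (\eqn{\mu m}).
#' @param aperture_um Superposition pupil / eye-glow diameter `A`
#'   (\eqn{\mu m}).
#' @param rhabdom_diameter_um Rhabdom diameter `d` (\eqn{\mu m}).
#' @param rhabdom_length_physical_um Physical rhabdom length (\eqn{\mu m}).
#' @param has_tapetum Logical; reflective tapetum present?
#' @param absorption_coeff_per_um Absorption coefficient `k`
#'   (\eqn{\mu m^{-1}}).
#' @return An object of class `eye_geometry`.
#' @seealso [optical_metrics()]
#' @export
eye_geometry <- function(facet_diameter_um, eye_radius_um, focal_length_um,
                         aperture_um, rhabdom_diameter_um,
                         rhabdom_length_physical_um, has_tapetum = TRUE,
                         absorption_coeff_per_um = 0.0067) {
  check_nonnegative(facet_diameter_um, "facet_diameter_um")
  check_positive(eye_radius_um, "eye_radius_um")
  check_positive(focal_length_um, "focal_length_um")
  check_positive(aperture_um, "aperture_um")
  check_nonnegative(rhabdom_diameter_um, "rhabdom_diameter_um")
  check_nonnegative(rhabdom_length_physical_um, "rhabdom_length_physical_um")
  check_positive(absorption_coeff_per_um, "absorption_coeff_per_um")
  stopifnot(is.logical(has_tapetum), length(has_tapetum) == 1L, !is.na(has_tapetum))
  if (aperture_um < facet_diameter_um) {
    warning("aperture_um < facet_diameter_um: not a superposition pupil ",
            "(expected for apposition eyes)", call. = FALSE)
  }
  structure(
    list(
      facet_diameter_um = facet_diameter_um,
      eye_radius_um = eye_radius_um,
      focal_length_um = focal_length_um,
      aperture_um = aperture_um,
      rhabdom_diameter_um = rhabdom_diameter_um,
      rhabdom_length_physical_um = rhabdom_length_physical_um,
      has_tapetum = has_tapetum,
      absorption_coeff_per_um = absorption_coeff_per_um
    ),
    class = "eye_geometry"
  )
}

#' Derived optical metrics for an eye geometry
#'
#' Computes the interommatidial angle, F-number, effective rhabdom length
#' and optical sensitivity from a validated [eye_geometry()].
#'
#' @param geometry An `eye_geometry` object.
#' @return An object of class `optical_metrics`: a list with elements
#'   `interommatidial_angle_deg`, `f_number`, `effective_rhabdom_length_um`
#'   and `optical_sensitivity_um2sr` (unrounded; printing rounds to 3
#'   significant figures).
#' @examples
#' geom <- eye_geometry(22, 969, 485, 857, 10, 47)
#' optical_metrics(geom)
#' @export
optical_metrics <- function(geometry) {
  stopifnot(inherits(geometry, "eye_geometry"))
  l_eff <- effective_rhabdom_length(geometry$rhabdom_length_physical_um,
                                    geometry$has_tapetum)
  structure(
    list(
      interommatidial_angle_deg = interommatidial_angle(
        geometry$facet_diameter_um, geometry$eye_radius_um),
      f_number = f_number(geometry$focal_length_um, geometry$aperture_um),
      effective_rhabdom_length_um = l_eff,
      optical_sensitivity_um2sr = optical_sensitivity(
        geometry$aperture_um, geometry$rhabdom_diameter_um,
        geometry$focal_length_um, l_eff, geometry$absorption_coeff_per_um)
    ),
    class = "optical_metrics"
  )
}

#' @export
print.optical_metrics <- function(x, ...) {
  cat("Compound-eye optical metrics\n")
  cat(sprintf("  interommatidial angle : %s deg\n",
              format(report_signif(x$interommatidial_angle_deg))))
  cat(sprintf("  F-number              : %s\n", format(report_signif(x$f_number))))
  cat(sprintf("  effective rhabdom     : %s um\n",
              format(report_signif(x$effective_rhabdom_length_um))))
  cat(sprintf("  optical sensitivity S : %s um^2 sr\n",
              format(report_signif(x$optical_sensitivity_um2sr))))
  invisible(x)
}
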