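# Govardovskii A1 visual-pigment template and derived quantities.
# Alpha-band constants are the published A1 (11-cis retinal) literature
# values; they are fixed, not tunable.

.A1 <- list(
  A = 69.7, B = 28, C = -14.9, D = 0.674,
  b = 0.922, c = 1.104,
  beta_A = 0.26
)

#' Govardovskii A1 visual-pigment absorbance template
#'
#' Parametric absorbance of an A1 (11-cis-retinal based) visual pigment as
#' a function of wavelength and its peak wavelength \eqn{\lambda_{max}}.
#' The alpha band is
#' \deqn{S_\alpha(x) = [\exp(A(a-x)) + \exp(B(b-x)) + \exp(C(c-x)) + D]^{-1}}
#' with \eqn{x = \lambda_{max}/\lambda} and
#' \eqn{a = 0.8795 + 0.0459 \exp(-(\lambda_{max}-300)^2/11940)}.
#' The beta band (the chromophore's secondary UV absorbance) is a Gaussian
#' of amplitude 0.26 centred at \eqn{189 + 0.315\,\lambda_{max}} with width
#' parameter \eqn{-40.5 + 0.195\,\lambda_{max}}.
#'
#' @param wavelength_nm Wavelength(s), nm (vectorised).
#' @param lambda_max_nm Peak wavelength of the pigment, nm; must lie in
#'   300--700 nm.
#' @param include_beta Include the beta band? Default `TRUE`.
#' @return Relative absorbance (peak approximately 1), same length as
#'   `wavelength_nm`.
#' @examples
#' govardovskii_a1(c(450, 547, 650), 547)
#' @export
govardovskii_a1 <- function(wavelength_nm, lambda_max_nm, include_beta = TRUE) {
  if (!is.numeric(lambda_max_nm) || length(lambda_max_nm) != 1L ||
      !is.finite(lambda_max_nm) || lambda_max_nm < 300 || lambda_max_nm > 700) {
    stop_domain("`lambda_max_nm` must be a single value in [300, 700] nm")
  }
  if (any(!is.finite(wavelength_nm)) || any(wavelength_nm <= 0)) {
    stop_domain("`wavelength_nm` must be positive and finite")
  }
  x <- lambda_max_nm / wavelength_nm
  a <- 0.8795 + 0.0459 * exp(-(lambda_max_nm - 300)^2 / 11940)
  s <- 1 / (exp(.A1$A * (a - x)) + exp(.A1$B * (.A1$b - x)) +
              exp(.A1$C * (.A1$c - x)) + .A1$D)
  if (include_beta) {
    lm_beta <- 189 + 0.315 * lambda_max_nm
    b_beta <- -40.5 + 0.195 * lambda_max_nm
    s <- s + .A1$beta_A * exp(-((wavelength_nm - lm_beta) / b_beta)^2)
  }
  s
}

#' Wavelength at which a pigment falls to a given sensitivity level
#'
#' Solves `template(lambda, lambda_max) = level` on one limb of the A1
#' template by bisection (0.01 nm tolerance). The long limb is the
#' descending branch above the peak and sets, for example, the longest
#' wavelength a pigment can usefully detect at a 5% sensitivity criterion.
#'
#' @param lambda_max_nm Pigment peak, nm.
#' @param level Sensitivity level as a fraction of the peak, in (0, 1).
#'   Default 0.05 (the conventional 5% shoulder).
#' @param limb `"long"` (descending branch, \eqn{\lambda > \lambda_{max}})
#'   or `"short"`.
#' @param include_beta Include the beta band in the template? Default
#'   `TRUE`.
#' @return Crossing wavelength, nm.
#' @examples
#' threshold_wavelength(547)        # ~647 nm: red limit of a 547-nm pigment
#' threshold_wavelength(525)        # ~621 nm
#' @export
threshold_wavelength <- function(lambda_max_nm, level = 0.05,
                                 limb = c("long", "short"),
                                 include_beta = TRUE) {
  limb <- match.arg(limb)
  if (!is.numeric(level) || length(level) != 1L || !is.finite(level) ||
      level <= 0 || level >= 1) {
    stop_domain("`level` must be a single fraction in (0, 1)")
  }
  f <- function(l) govardovskii_a1(l, lambda_max_nm, include_beta) - level
  if (limb == "long") {
    lo <- lambda_max_nm
    hi <- 800
  } else {
    lo <- 300
    hi <- lambda_max_nm
  }
  flo <- f(lo)
  fhi <- f(hi)
  # On the long limb the template decreases from ~1 at the peak; on the
  # short limb it increases towards the peak. Either way the crossing needs
  # a sign change inside the bracket.
  if (flo * fhi > 0) {
    stop(errorCondition(
      sprintf("level %.3g not attained on the %s limb within [%g, %g] nm",
              level, limb, lo, hi),
      class = c("mothvis_no_crossing_error", "mothvis_error")))
  }
  while (hi - lo > 0.01) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (flo * fm <= 0) {
      hi <- mid
      fhi <- fm
    } else {
      lo <- mid
      flo <- fm
    }
  }
  (lo + hi) / 2
}
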