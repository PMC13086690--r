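# Deterministic synthetic-data generators. Every generator records its
# ground truth (and seed) in the "ground_truth" attribute of its output,
# and identical arguments give identical output. Noise is Gaussian
# throughout; amplitudes are documented per generator.

#' Generate a synthetic pigment absorbance spectrum
#'
#' Unit-amplitude [govardovskii_a1()] template plus an optional flat
#' baseline, an optional free-retinal contamination band (Gaussian centred
#' at 380 nm, sd 30 nm — within the 350--450 nm range where unbound
#' retinal absorbs), and i.i.d. Gaussian noise.
#'
#' @param lambda_max_nm True pigment peak, nm.
#' @param grid Length-3 numeric `(from, to, by)` wavelength grid in nm;
#'   default `c(300, 700, 1)`.
#' @param noise_sd Gaussian noise sd (fraction of peak absorbance).
#' @param baseline Flat additive baseline (fraction of peak).
#' @param contamination_amplitude Amplitude of the free-retinal band
#'   (fraction of peak).
#' @param seed Integer seed (mandatory; recorded in the output metadata).
#' @param include_beta Include the template beta band. Default `TRUE`.
#' @return An [absorbance_spectrum()] with condition `"synthetic"` and a
#'   `ground_truth` attribute.
#' @examples
#' s <- make_spectrum(547, noise_sd = 0.01, seed = 42)
#' attr(s, "ground_truth")$lambda_max_nm
#' @export
make_spectrum <- function(lambda_max_nm, grid = c(300, 700, 1),
                          noise_sd = 0, baseline = 0,
                          contamination_amplitude = 0, seed,
                          include_beta = TRUE) {
  if (missing(seed)) stop_domain("`seed` is mandatory")
  if (length(grid) != 3L || grid[1] >= grid[2] || grid[3] <= 0) {
    stop_domain("`grid` must be (from, to, by) with from < to and by > 0")
  }
  check_nonnegative(noise_sd, "noise_sd")
  check_nonnegative(contamination_amplitude, "contamination_amplitude")
  wl <- seq(grid[1], grid[2], by = grid[3])
  y <- govardovskii_a1(wl, lambda_max_nm, include_beta) + baseline +
    contamination_amplitude * exp(-(wl - 380)^2 / (2 * 30^2))
  if (noise_sd > 0) {
    y <- y + withr::with_seed(as.integer(seed),
                              stats::rnorm(length(wl), 0, noise_sd))
  }
  out <- absorbance_spectrum(wl, y,
                             label = sprintf("synthetic lmax %.1f", lambda_max_nm),
                             condition = "synthetic")
  attr(out, "ground_truth") <- list(
    lambda_max_nm = lambda_max_nm, noise_sd = noise_sd, baseline = baseline,
    contamination_amplitude = contamination_amplitude,
    contamination_center_nm = 380, contamination_sd_nm = 30,
    include_beta = include_beta, seed = as.integer(seed))
  out
}

#' Generate a blurred grating intensity profile
#'
#' A mean-128, amplitude-127 sine or square wave sampled in degrees of
#' visual angle, circularly convolved with a Gaussian blur of angular
#' width `blur_sigma_deg` (the 1-D point-spread of a defocused lens), plus
#' Gaussian greyscale noise. For sine waveforms the modulation transfer of
#' a Gaussian blur has the closed form
#' \eqn{\exp(-2\pi^2\sigma^2 f^2)}, which is recorded as
#' `true_contrast` in the ground-truth metadata.
#'
#' @param frequency_cpd Spatial frequency, cycles/degree.
#' @param waveform `"sine"` or `"square"`.
#' @param blur_sigma_deg Gaussian blur sigma, degrees. 0 = no blur.
#' @param samples_per_period Samples per grating period (>= 16).
#' @param n_periods Number of full periods (>= 3).
#' @param noise_sd Gaussian noise sd, greyscale units.
#' @param seed Integer seed (mandatory).
#' @return A [grating_profile()] with a `ground_truth` attribute.
#' @export
make_grating_profile <- function(frequency_cpd,
                                 waveform = c("sine", "square"),
                                 blur_sigma_deg = 0,
                                 samples_per_period = 64L, n_periods = 4L,
                                 noise_sd = 0, seed) {
  if (missing(seed)) stop_domain("`seed` is mandatory")
  waveform <- match.arg(waveform)
  check_positive(frequency_cpd, "frequency_cpd")
  check_nonnegative(blur_sigma_deg, "blur_sigma_deg")
  check_nonnegative(noise_sd, "noise_sd")
  samples_per_period <- as.integer(samples_per_period)
  n_periods <- as.integer(n_periods)
  if (samples_per_period < 16L) stop_domain("samples_per_period must be >= 16")
  if (n_periods < 3L) stop_domain("n_periods must be >= 3")
  n <- samples_per_period * n_periods
  dx <- 1 / (frequency_cpd * samples_per_period)  # degrees per sample
  pos <- (seq_len(n) - 1L) * dx
  phase <- 2 * pi * frequency_cpd * pos
  y <- if (waveform == "sine") {
    128 + 127 * sin(phase)
  } else {
    128 + 127 * ifelse(sin(phase) >= 0, 1, -1)
  }
  if (blur_sigma_deg > 0) {
    # Circular convolution (the profile spans whole periods, so wrapping
    # is exact) with a normalized discrete Gaussian kernel via FFT.
    sigma_samp <- blur_sigma_deg / dx
    half <- min(n %/% 2L, ceiling(6 * sigma_samp))
    offs <- c(0:half, if (half >= 1L) -(half:1L))
    kern <- numeric(n)
    kern[((offs %% n) + 1L)] <- exp(-(offs^2) / (2 * sigma_samp^2))
    kern <- kern / sum(kern)
    y <- Re(stats::fft(stats::fft(y) * stats::fft(kern), inverse = TRUE)) / n
  }
  if (noise_sd > 0) {
    y <- y + withr::with_seed(as.integer(seed),
                              stats::rnorm(n, 0, noise_sd))
    y <- pmax(y, 0)
  }
  out <- grating_profile(pos, y, frequency_cpd)
  attr(out, "ground_truth") <- list(
    frequency_cpd = frequency_cpd, waveform = waveform,
    blur_sigma_deg = blur_sigma_deg, noise_sd = noise_sd,
    samples_per_period = samples_per_period, n_periods = n_periods,
    true_contrast = if (waveform == "sine") {
      (127 / 128) * exp(-2 * pi^2 * blur_sigma_deg^2 * frequency_cpd^2)
    } else NA_real_,
    seed = as.integer(seed))
  out
}

#' Generate a z-stack focus series with known best-focus plane
#'
#' Unimodal Gaussian focus-score profile whose peak sits at the frame
#' corresponding to the requested back focal distance
#' (`true_bfd_um / (step_um * refractive_index_n)` frames above the
#' reference frame 0), plus Gaussian noise.
#'
#' @param true_bfd_um Ground-truth back focal distance, \eqn{\mu m};
#'   must fall inside the stack span.
#' @param step_um Z-step between frames, \eqn{\mu m}.
#' @param n_frames Number of frames.
#' @param focus_width_um Gaussian width (sd) of the focus-score profile in
#'   physical stage \eqn{\mu m}.
#' @param noise_sd Gaussian noise sd (fraction of the peak score).
#' @param refractive_index_n Refractive index of the medium (default 1.33).
#' @param seed Integer seed (mandatory).
#' @return A [zstack_series()] with a `ground_truth` attribute.
#' @export
make_zstack <- function(true_bfd_um, step_um, n_frames, focus_width_um = 6,
                        noise_sd = 0, refractive_index_n = 1.33, seed) {
  if (missing(seed)) stop_domain("`seed` is mandatory")
  check_nonnegative(true_bfd_um, "true_bfd_um")
  check_positive(step_um, "step_um")
  check_positive(focus_width_um, "focus_width_um")
  check_nonnegative(noise_sd, "noise_sd")
  n_frames <- as.integer(n_frames)
  if (n_frames < 3L) stop_domain("n_frames must be >= 3")
  center <- true_bfd_um / (step_um * refractive_index_n)
  if (center < 0 || center > n_frames - 1L) {
    stop_domain("true_bfd_um lies outside the stack span")
  }
  frames <- 0:(n_frames - 1L)
  score <- exp(-((frames - center) * step_um)^2 / (2 * focus_width_um^2))
  if (noise_sd > 0) {
    score <- score + withr::with_seed(as.integer(seed),
                                      stats::rnorm(n_frames, 0, noise_sd))
  }
  out <- zstack_series(frames, score, step_um, refractive_index_n,
                       reference_frame = 0L)
  attr(out, "ground_truth") <- list(
    true_bfd_um = true_bfd_um, step_um = step_um, n_frames = n_frames,
    focus_width_um = focus_width_um, noise_sd = noise_sd,
    refractive_index_n = refractive_index_n, seed = as.integer(seed))
  out
}

#' Generate a chromatic-aberration lens measurement dataset
#'
#' Per-ocellus back focal distances and focal lengths for black-on-red,
#' -green and -blue gratings at four orientations. Chromatic aberration is
#' emulated by per-color BFD means (defaults: red 40, green 35, blue 30
#' \eqn{\mu m}, matching the observed longer projection of long-wavelength
#' images); ocellus-to-ocellus variability by a random intercept per
#' ocellus. The total marginal sd equals `bfd_sd`: the intercept
#' contributes `bfd_sd/2` and the residual `bfd_sd * sqrt(3)/2`.
#'
#' @param n_ocelli Number of ocelli (>= 2).
#' @param bfd_means_by_color Named numeric `c(red=, green=, blue=)` of
#'   per-color BFD means, \eqn{\mu m}.
#' @param bfd_sd Total BFD sd, \eqn{\mu m}.
#' @param f_mean,f_sd Focal-length mean and sd, \eqn{\mu m}.
#' @param seed Integer seed (mandatory).
#' @return Data frame with columns `ocellus_id`, `color`,
#'   `orientation_deg`, `bfd_um`, `f_um`, plus a `ground_truth` attribute.
#' @export
make_lens_dataset <- function(n_ocelli = 10L,
                              bfd_means_by_color = c(red = 40, green = 35,
                                                     blue = 30),
                              bfd_sd = 10, f_mean = 190, f_sd = 24, seed) {
  if (missing(seed)) stop_domain("`seed` is mandatory")
  n_ocelli <- as.integer(n_ocelli)
  if (n_ocelli < 2L) stop_domain("n_ocelli must be >= 2")
  if (!all(c("red", "green", "blue") %in% names(bfd_means_by_color))) {
    stop_domain("bfd_means_by_color must name red, green and blue")
  }
  check_nonnegative(bfd_sd, "bfd_sd")
  check_nonnegative(f_sd, "f_sd")
  colors <- c("red", "green", "blue")
  orientations <- c(0, 45, 90, 135)
  design <- expand.grid(ocellus_id = seq_len(n_ocelli), color = colors,
                        orientation_deg = orientations,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[order(design$ocellus_id, design$color,
                         design$orientation_deg), ]
  rownames(design) <- NULL
  m <- nrow(design)
  out <- withr::with_seed(as.integer(seed), {
    icpt_bfd <- stats::rnorm(n_ocelli, 0, bfd_sd / 2)
    icpt_f <- stats::rnorm(n_ocelli, 0, f_sd / 2)
    resid_bfd <- stats::rnorm(m, 0, bfd_sd * sqrt(3) / 2)
    resid_f <- stats::rnorm(m, 0, f_sd * sqrt(3) / 2)
    design$bfd_um <- bfd_means_by_color[design$color] +
      icpt_bfd[design$ocellus_id] + resid_bfd
    design$f_um <- f_mean + icpt_f[design$ocellus_id] + resid_f
    design
  })
  attr(out, "ground_truth") <- list(
    n_ocelli = n_ocelli, bfd_means_by_color = bfd_means_by_color,
    bfd_sd = bfd_sd, f_mean = f_mean, f_sd = f_sd, seed = as.integer(seed))
  out
}
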