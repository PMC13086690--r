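test_that("generators are deterministic and record their ground truth", {
  s1 <- make_spectrum(427, noise_sd = 0.01, seed = 7)
  s2 <- make_spectrum(427, noise_sd = 0.01, seed = 7)
  expect_identical(s1, s2)
  expect_false(identical(s1, make_spectrum(427, noise_sd = 0.01, seed = 8)))
  expect_equal(attr(s1, "ground_truth")$lambda_max_nm, 427)
  expect_equal(attr(s1, "ground_truth")$seed, 7L)

  g1 <- make_grating_profile(0.2, "square", blur_sigma_deg = 0.3,
                             noise_sd = 1, seed = 5)
  g2 <- make_grating_profile(0.2, "square", blur_sigma_deg = 0.3,
                             noise_sd = 1, seed = 5)
  expect_identical(g1, g2)

  z1 <- make_zstack(30, 2, 30, noise_sd = 0.05, seed = 4)
  expect_identical(z1, make_zstack(30, 2, 30, noise_sd = 0.05, seed = 4))

  l1 <- make_lens_dataset(seed = 2)
  expect_identical(l1, make_lens_dataset(seed = 2))

  # written files are byte-identical too
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_spectrum_csv(s1, f1); write_spectrum_csv(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("zero-noise spectra equal the template exactly", {
  s <- make_spectrum(547, seed = 99)
  expect_equal(s$absorbance, govardovskii_a1(s$wavelength_nm, 547))
  sb <- make_spectrum(547, baseline = 0.1, seed = 99)
  expect_equal(sb$absorbance - s$absorbance, rep(0.1, nrow(s)))
  expect_error(make_spectrum(547, grid = c(700, 300, 1), seed = 1),
               class = "mothvis_domain_error")
  expect_error(make_spectrum(547, noise_sd = 0.01), "seed")
})

test_that("free-retinal contamination biases direct fits; the difference workflow removes it", {
  wl <- seq(300, 700, 1)
  mk_acid <- function(seed) {
    # acid-denatured counterpart: photoproduct peak at 436 nm plus the
    # *same* contamination band, so subtraction cancels the contaminant
    absorbance_spectrum(wl,
      0.9 * govardovskii_a1(wl, 436) + 0.3 * exp(-(wl - 380)^2 / (2 * 30^2)) +
        withr::with_seed(seed, rnorm(length(wl), 0, 0.02)),
      condition = "synthetic")
  }
  direct <- vapply(1:10, function(i) {
    fit_lambda_max(make_spectrum(362, noise_sd = 0.02,
                                 contamination_amplitude = 0.3,
                                 seed = i))$lambda_max_nm
  }, numeric(1))
  expect_gt(mean(direct) - 362, 2)  # pulled toward the 380-nm contaminant
  via_diff <- vapply(1:10, function(i) {
    dark <- make_spectrum(362, noise_sd = 0.02, contamination_amplitude = 0.3,
                          seed = i)
    d <- difference_spectrum(dark, mk_acid(500L + i))
    # fit below the photoproduct's short-wavelength limb
    fit_lambda_max(d, fit_window_nm = c(300, 375))$lambda_max_nm
  }, numeric(1))
  expect_lt(abs(mean(via_diff) - 362), 2)
})

test_that("grating generator: unblurred contrast, MTF truth, square-wave decay", {
  g0 <- make_grating_profile(0.25, "sine", seed = 1)
  expect_equal(profile_contrast(g0), 127 / 128, tolerance = 0.01)
  # sigma chosen so the closed-form MTF is 0.5 at f = 0.25
  sigma <- sqrt(-log(0.5) / (2 * pi^2 * 0.25^2))
  g <- make_grating_profile(0.25, "sine", blur_sigma_deg = sigma, seed = 1)
  expect_equal(profile_contrast(g) / (127 / 128), 0.5, tolerance = 0.02)
  expect_equal(attr(g, "ground_truth")$true_contrast, (127 / 128) * 0.5,
               tolerance = 1e-9)
  sq <- vapply(c(0.1, 0.2, 0.3, 0.4, 0.5), function(f) {
    profile_contrast(make_grating_profile(f, "square", blur_sigma_deg = 0.6,
                                          seed = 1))
  }, numeric(1))
  expect_true(all(diff(sq) < 0))
  expect_error(make_grating_profile(0.2, samples_per_period = 8, seed = 1),
               class = "mothvis_domain_error")
  expect_error(make_grating_profile(0.2, n_periods = 2, seed = 1),
               class = "mothvis_domain_error")
})

test_that("z-stack generator: noiseless recovery, noisy recovery, span check", {
  z <- make_zstack(34.58, 2, 30, focus_width_um = 6, seed = 1)
  expect_equal(back_focal_distance(z), 34.58, tolerance = 2 * 1.33)
  errs <- vapply(1:100, function(i) {
    zi <- make_zstack(34.58, 2, 30, focus_width_um = 6, noise_sd = 0.05,
                      seed = i)
    abs(back_focal_distance(zi, smoothing_window = 3) - 34.58)
  }, numeric(1))
  expect_lt(mean(errs), 2 * 1.33)  # under one step equivalent on average
  expect_error(make_zstack(500, 2, 30, seed = 1), class = "mothvis_domain_error")
})

test_that("lens dataset: exact means at zero sd, ordering recovery, size guard", {
  exact <- make_lens_dataset(n_ocelli = 4, bfd_sd = 0, f_sd = 0, seed = 3)
  s <- summarize_lens_measurements(data.frame(value = exact$bfd_um,
                                              color = exact$color))
  expect_equal(setNames(s$mean, s$group)[c("red", "green", "blue")],
               c(red = 40, green = 35, blue = 30))
  expect_true(all(s$sd == 0))
  expect_equal(mean(exact$f_um), 190)
  expect_error(make_lens_dataset(n_ocelli = 1, seed = 1),
               class = "mothvis_domain_error")
})
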