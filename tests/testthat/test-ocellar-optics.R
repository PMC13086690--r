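test_that("back focal distance follows the frames-times-step-times-n recipe", {
  score <- exp(-((0:30) - 13)^2 / 8)
  z <- zstack_series(0:30, score, step_um = 2, refractive_index_n = 1.33)
  expect_equal(back_focal_distance(z), 13 * 2 * 1.33)  # 34.58 um
  # best focus at the reference frame -> zero
  z0 <- zstack_series(0:30, exp(-((0:30))^2 / 8), step_um = 2)
  expect_warning(expect_equal(back_focal_distance(z0), 0), "boundary")
  # n = 1 medium
  z1 <- zstack_series(0:30, score, step_um = 2, refractive_index_n = 1,
                      reference_frame = 3L)
  expect_equal(back_focal_distance(z1), 10 * 2 * 1)
})

test_that("BFD is linear in step size and refractive index", {
  score <- exp(-((0:40) - 17)^2 / 10)
  for (step in c(0.5, 1, 2, 4)) {
    for (n in c(1, 1.33, 1.5)) {
      z <- zstack_series(0:40, score, step_um = step, refractive_index_n = n)
      expect_equal(back_focal_distance(z), 17 * step * n)
    }
  }
})

test_that("flat or boundary-peaked focus series are rejected or flagged", {
  flat <- zstack_series(0:20, rep(1, 21), step_um = 2)
  expect_error(back_focal_distance(flat), class = "mothvis_estimation_error")
  edge <- zstack_series(0:20, seq(0, 1, length.out = 21), step_um = 2)
  expect_warning(back_focal_distance(edge), "boundary")
})

test_that("focal length is object distance times magnification", {
  expect_equal(focal_length(100000, 19, 10000), 190)
  expect_equal(focal_length(100000, 7, 7), 100000)       # unit magnification
  expect_equal(focal_length(200000, 19, 10000), 380)     # linear in s0
  expect_warning(focal_length(50000, 19, 10000), "infinity")
  expect_error(focal_length(0, 19, 10000), class = "mothvis_domain_error")
  expect_error(focal_length(100000, -1, 10000), class = "mothvis_domain_error")
})

test_that("Michelson contrast formula and its domain errors", {
  expect_equal(michelson_contrast(200, 100), 1 / 3)
  expect_equal(michelson_contrast(128, 128), 0)
  expect_equal(michelson_contrast(255, 0), 1)
  expect_error(michelson_contrast(0, 0), class = "mothvis_undefined_contrast_error")
  expect_error(michelson_contrast(100, 200), class = "mothvis_domain_error")
  expect_error(michelson_contrast(100, -1), class = "mothvis_domain_error")
})

test_that("profile contrast: square waves, flat fields, and edge trimming", {
  pos <- seq(0, 40, by = 0.25)[-1]
  sq <- grating_profile(pos, ifelse(sin(2 * pi * 0.1 * pos) >= 0, 200, 100), 0.1)
  expect_equal(profile_contrast(sq), 1 / 3)
  flat <- grating_profile(pos, rep(128, length(pos)), 0.1)
  expect_equal(profile_contrast(flat), 0)
  short <- grating_profile(seq(0, 5, by = 0.1), rep(128, 51), 0.1)
  expect_error(profile_contrast(short), class = "mothvis_insufficient_data_error")
})

test_that("contrast is invariant to gain but not to offset", {
  g <- make_grating_profile(0.2, "sine", blur_sigma_deg = 0.5, noise_sd = 2,
                            seed = 8)
  m1 <- profile_contrast(g)
  scaled <- grating_profile(g$position, 3.7 * g$intensity, 0.2)
  expect_equal(profile_contrast(scaled), m1, tolerance = 1e-12)
  offset <- grating_profile(g$position, g$intensity + 100, 0.2)
  expect_lt(profile_contrast(offset), m1)
})

test_that("blurred sinusoids follow the Gaussian modulation transfer function", {
  sigma <- 0.8
  prev <- Inf
  for (f in c(0.1, 0.2, 0.3, 0.4, 0.5)) {
    g <- make_grating_profile(f, "sine", blur_sigma_deg = sigma,
                              samples_per_period = 64L, seed = 1)
    m <- profile_contrast(g)
    expected <- (127 / 128) * exp(-2 * pi^2 * sigma^2 * f^2)
    expect_equal(m, expected, tolerance = 0.02)
    expect_lt(m, prev)
    prev <- m
  }
})

test_that("cutoff frequency: exact intercepts, OLS oracle, and error modes", {
  exact <- data.frame(frequency_cpd = c(0.1, 0.2, 0.3, 0.4),
                      contrast = c(0.40, 0.30, 0.20, 0.10))
  cc <- cutoff_frequency(exact)
  expect_equal(cc$cutoff_fc_cpd, 0.5, tolerance = 1e-12)
  expect_equal(cc$slope, -1, tolerance = 1e-12)
  # hand-computed OLS: slope -1.125, intercept 0.57083, fc 0.507407
  three <- data.frame(frequency_cpd = c(0.1, 0.3, 0.5),
                      contrast = c(0.45, 0.25, 0.00))
  cc3 <- cutoff_frequency(three, contrast_floor = 0)
  expect_equal(cc3$slope, -1.125, tolerance = 1e-9)
  expect_equal(cc3$intercept, 0.5708333, tolerance = 1e-6)
  expect_equal(cc3$cutoff_fc_cpd, 0.5074074, tolerance = 1e-6)
  rising <- data.frame(frequency_cpd = c(0.1, 0.2, 0.3),
                       contrast = c(0.1, 0.2, 0.3))
  expect_error(cutoff_frequency(rising), class = "mothvis_no_cutoff_error")
  floor_all <- data.frame(frequency_cpd = c(0.1, 0.2, 0.3, 0.4),
                          contrast = c(0.01, 0.01, 0.02, 0.0))
  expect_error(cutoff_frequency(floor_all),
               class = "mothvis_insufficient_data_error")
})

test_that("small symmetric noise moves the cutoff by under 5%", {
  f <- seq(0.1, 0.45, by = 0.05)
  m <- 0.5 - f
  fc0 <- cutoff_frequency(data.frame(frequency_cpd = f, contrast = m))$cutoff_fc_cpd
  noisy <- pmin(pmax(m + withr::with_seed(12L, rnorm(length(f), 0, 0.01)), 0), 1)
  fc1 <- cutoff_frequency(data.frame(frequency_cpd = f, contrast = noisy))$cutoff_fc_cpd
  expect_lt(abs(fc1 - fc0) / fc0, 0.05)
})

test_that("lens measurement summaries: arithmetic and single-value groups", {
  one <- data.frame(value = c(30, 40), color = c("red", "red"))
  s <- summarize_lens_measurements(one)
  expect_equal(s$mean, 35)
  expect_equal(s$sd, sd(c(30, 40)), tolerance = 1e-12)
  expect_equal(s$n, 2L)
  single <- data.frame(value = 42, color = "blue")
  ss <- summarize_lens_measurements(single)
  expect_equal(ss$sd, 0)
  expect_equal(ss$n, 1L)
  expect_error(summarize_lens_measurements(data.frame(value = numeric(),
                                                      color = character())),
               class = "mothvis_domain_error")
})

test_that("chromatic ordering and group means recover from synthetic lenses", {
  ld <- make_lens_dataset(n_ocelli = 10, seed = 1)
  s <- summarize_lens_measurements(data.frame(value = ld$bfd_um,
                                              color = ld$color))
  truth <- attr(ld, "ground_truth")$bfd_means_by_color
  for (col in c("red", "green", "blue")) {
    row <- s[s$group == col, ]
    se <- row$sd / sqrt(row$n)
    expect_lt(abs(row$mean - truth[[col]]), 2 * se)
  }
  means <- setNames(s$mean, s$group)
  expect_true(means[["red"]] > means[["green"]] &&
                means[["green"]] > means[["blue"]])
})
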