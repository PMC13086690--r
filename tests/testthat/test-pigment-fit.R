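test_that("fitter matches the exhaustive grid-search oracle", {
  cases <- list(
    list(lmax = 427, noise = 0, seed = 1),
    list(lmax = 547, noise = 0.01, seed = 2),
    list(lmax = 360, noise = 0.02, seed = 3),
    list(lmax = 620, noise = 0.01, seed = 4)
  )
  for (cs in cases) {
    s <- make_spectrum(cs$lmax, noise_sd = cs$noise, seed = cs$seed)
    fit <- fit_lambda_max(s)
    oracle <- grid_search_lmax(s)
    expect_equal(fit$lambda_max_nm, oracle, tolerance = 0.05,
                 info = sprintf("lmax %g", cs$lmax))
  }
})

test_that("noiseless template spectra are recovered to 0.1 nm", {
  for (lmax in c(362, 427, 547, 555)) {
    s <- make_spectrum(lmax, seed = 1)
    fit <- fit_lambda_max(s)
    expect_equal(fit$lambda_max_nm, lmax, tolerance = 0.1)
    expect_equal(fit$amplitude, 1, tolerance = 0.01)
    expect_lt(fit$rss, 1e-6)
  }
})

test_that("peak recovery from noisy spectra is unbiased to within 1 nm", {
  # 50 seeds per pigment, noise sd 0.01 on a unit-peak spectrum
  for (lmax in c(360, 427, 547, 555)) {
    est <- vapply(1:50, function(i) {
      fit_lambda_max(make_spectrum(lmax, noise_sd = 0.01,
                                   seed = lmax * 100 + i))$lambda_max_nm
    }, numeric(1))
    expect_lt(mean(abs(est - lmax)), 1)
    expect_lt(abs(mean(est) - lmax), 0.5)
  }
})

test_that("the duplicate long-wavelength pigments keep their 8-nm red shift", {
  e1 <- vapply(1:25, function(i)
    fit_lambda_max(make_spectrum(547, noise_sd = 0.01, seed = i))$lambda_max_nm,
    numeric(1))
  e2 <- vapply(1:25, function(i)
    fit_lambda_max(make_spectrum(555, noise_sd = 0.01, seed = 500 + i))$lambda_max_nm,
    numeric(1))
  expect_equal(mean(e2) - mean(e1), 8, tolerance = 1)
})

test_that("fitter agrees with an independent nls fit", {
  s <- make_spectrum(505, noise_sd = 0.01, seed = 9)
  fit <- fit_lambda_max(s)
  df <- data.frame(wl = s$wavelength_nm, y = s$absorbance / max(s$absorbance))
  nls_fit <- stats::nls(y ~ amp * govardovskii_a1(wl, lmax), data = df,
                        start = list(amp = 1, lmax = 500),
                        algorithm = "port", lower = c(0.1, 350),
                        upper = c(5, 650))
  expect_equal(fit$lambda_max_nm, unname(coef(nls_fit)["lmax"]),
               tolerance = 0.05)
})

test_that("degenerate spectra fail loudly; bound optima warn", {
  flat <- absorbance_spectrum(300:700, rep(0.5, 401), condition = "synthetic")
  expect_error(fit_lambda_max(flat), class = "mothvis_fit_failure_error")
  few <- absorbance_spectrum(seq(400, 480, 10), govardovskii_a1(seq(400, 480, 10), 440),
                             condition = "synthetic")
  expect_error(fit_lambda_max(few), "at least 10 points")
  # a spectrum still rising at the red end of the search range
  rising <- absorbance_spectrum(300:700, govardovskii_a1(300:700, 660),
                                condition = "synthetic")
  expect_warning(fit_lambda_max(rising, bounds_nm = c(300, 620)), "bound")
})

test_that("bootstrap CI is deterministic, tight on clean data, and seed-gated", {
  s <- make_spectrum(547, noise_sd = 0.01, seed = 3)
  b1 <- bootstrap_ci(s, n_boot = 200, seed = 42)
  b2 <- bootstrap_ci(s, n_boot = 200, seed = 42)
  expect_identical(b1$lambda_max_boot, b2$lambda_max_boot)
  expect_identical(c(b1$lower_nm, b1$upper_nm), c(b2$lower_nm, b2$upper_nm))
  b3 <- bootstrap_ci(s, n_boot = 200, seed = 43)
  expect_false(identical(b1$lambda_max_boot, b3$lambda_max_boot))
  expect_error(bootstrap_ci(s, n_boot = 200), class = "mothvis_domain_error")

  clean <- make_spectrum(547, seed = 1)
  bc <- bootstrap_ci(clean, n_boot = 200, seed = 7)
  fit <- fit_lambda_max(clean)
  expect_lt(bc$upper_nm - bc$lower_nm, 0.5)
  expect_true(bc$lower_nm <= fit$lambda_max_nm + 1e-6 &&
                fit$lambda_max_nm <= bc$upper_nm + 1e-6)
})

test_that("CI width grows with noise and the fit result carries the CI", {
  s_lo <- make_spectrum(547, noise_sd = 0.01, seed = 11)
  s_hi <- make_spectrum(547, noise_sd = 0.05, seed = 11)
  w_lo <- with(bootstrap_ci(s_lo, n_boot = 300, seed = 5), upper_nm - lower_nm)
  w_hi <- with(bootstrap_ci(s_hi, n_boot = 300, seed = 5), upper_nm - lower_nm)
  expect_gt(w_hi, w_lo)
  fit <- fit_lambda_max(s_lo, n_boot = 300, seed = 5)
  expect_length(fit$ci_95, 2)
  expect_true(fit$ci_95[1] <= fit$lambda_max_nm &&
                fit$lambda_max_nm <= fit$ci_95[2])
})
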