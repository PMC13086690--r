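# Nonlinear least-squares fitting of the Govardovskii A1 template.
#
# The optimizer is a deterministic nested scheme: for any candidate
# lambda-max the amplitude (and optional additive baseline) minimizing the
# residual sum of squares has a closed form, so the problem reduces to a
# 1-D search over lambda-max. That search is a coarse 1-nm grid scan
# followed by local refinement with stats::optimize to 0.01 nm. This is
# reproducible to the digit, unlike generic black-box minimizers.

# Template values for all candidate peaks at once; rows = wavelengths,
# columns = candidates.
.template_matrix <- function(wavelength_nm, lambda_max_grid, include_beta) {
  x <- outer(1 / wavelength_nm, lambda_max_grid)  # lambda_max / lambda
  a <- 0.8795 + 0.0459 * exp(-(lambda_max_grid - 300)^2 / 11940)
  amat <- matrix(a, nrow = length(wavelength_nm),
                 ncol = length(lambda_max_grid), byrow = TRUE)
  s <- 1 / (exp(.A1$A * (amat - x)) + exp(.A1$B * (.A1$b - x)) +
              exp(.A1$C * (.A1$c - x)) + .A1$D)
  if (include_beta) {
    lm_beta <- 189 + 0.315 * lambda_max_grid
    b_beta <- -40.5 + 0.195 * lambda_max_grid
    dev <- sweep(outer(wavelength_nm, lm_beta, "-"), 2, b_beta, "/")
    s <- s + .A1$beta_A * exp(-dev^2)
  }
  s
}

# Closed-form least-squares score of each candidate template column
# against y. Returns rss per column; columns whose optimal amplitude is
# non-positive are invalid (Inf).
.score_candidates <- function(tm, y, baseline) {
  if (!baseline) {
    cty <- as.numeric(crossprod(tm, y))
    ctt <- colSums(tm^2)
    rss <- sum(y^2) - cty^2 / ctt
    rss[cty <= 0] <- Inf
    amp <- cty / ctt
    base <- rep(0, ncol(tm))
  } else {
    n <- length(y)
    st <- colSums(tm)
    stt <- colSums(tm^2)
    sty <- as.numeric(crossprod(tm, y))
    sy <- sum(y)
    denom <- n * stt - st^2
    amp <- (n * sty - st * sy) / denom
    base <- (sy - amp * st) / n
    rss <- sum(y^2) + amp^2 * stt + n * base^2 +
      2 * amp * base * st - 2 * amp * sty - 2 * base * sy
    rss[amp <= 0] <- Inf
  }
  list(rss = rss, amp = amp, base = base)
}

.rss_at <- function(lmax, wavelength_nm, y, include_beta, baseline) {
  tm <- matrix(govardovskii_a1(wavelength_nm, lmax, include_beta), ncol = 1)
  .score_candidates(tm, y, baseline)$rss
}

# Full nested fit on raw vectors. Returns list(lambda_max_nm, amplitude,
# baseline, rss, at_bound) or throws on degenerate input.
.fit_lmax_core <- function(wavelength_nm, y, bounds_nm, include_beta,
                           baseline) {
  if (stats::sd(y) == 0) {
    stop(errorCondition("flat spectrum: no interior optimum",
      class = c("mothvis_fit_failure_error", "mothvis_error")))
  }
  grid <- seq(bounds_nm[1], bounds_nm[2], by = 1)
  tm <- .template_matrix(wavelength_nm, grid, include_beta)
  sc <- .score_candidates(tm, y, baseline)
  if (all(!is.finite(sc$rss))) {
    stop(errorCondition(
      "no candidate peak fits with positive amplitude",
      class = c("mothvis_fit_failure_error", "mothvis_error")))
  }
  j <- which.min(sc$rss)
  lo <- grid[max(1L, j - 1L)]
  hi <- grid[min(length(grid), j + 1L)]
  opt <- stats::optimize(.rss_at, interval = c(lo, hi),
                         wavelength_nm = wavelength_nm, y = y,
                         include_beta = include_beta, baseline = baseline,
                         tol = 0.005)
  lmax <- opt$minimum
  at_bound <- (lmax - bounds_nm[1] < 0.5) || (bounds_nm[2] - lmax < 0.5)
  final <- .score_candidates(
    matrix(govardovskii_a1(wavelength_nm, lmax, include_beta), ncol = 1),
    y, baseline)
  list(lambda_max_nm = lmax, amplitude = final$amp[1],
       baseline = final$base[1], rss = final$rss[1], at_bound = at_bound)
}

#' Fit the pigment peak wavelength to an absorbance spectrum
#'
#' Estimates \eqn{\lambda_{max}} by least squares against the
#' [govardovskii_a1()] template: the objective
#' \eqn{\sum_i (A_i - \alpha\, T(\lambda_i; \lambda_{max}))^2} is minimized
#' over \eqn{(\lambda_{max}, \alpha)}, with the amplitude \eqn{\alpha}
#' solved in closed form for every candidate peak, a 1-nm grid scan over
#' the fit bounds, and local refinement to 0.01 nm. The spectrum is
#' normalized internally to unit maximum within the fit window (this does
#' not move the optimum; it makes amplitudes comparable across spectra).
#'
#' @param spectrum An [absorbance_spectrum()].
#' @param fit_window_nm Length-2 numeric: only points inside this window
#'   enter the fit. Default `c(300, 700)`. Restricting the window is the
#'   standard remedy for UV pigments whose long-wavelength slope overlaps
#'   free-retinal absorbance; fitting the difference spectrum is the other
#'   (see [difference_spectrum()]).
#' @param bounds_nm Search bounds for the peak, default `c(300, 700)` nm.
#' @param include_beta Include the template beta band. Default `TRUE`.
#' @param baseline If `TRUE`, an additive constant is co-estimated in
#'   closed form alongside the amplitude. Off by default: a free baseline
#'   can absorb contaminant shoulders.
#' @param n_boot If > 0, a bootstrap 95% confidence interval with this many
#'   replicates is attached (requires `seed`); see [bootstrap_ci()].
#' @param seed Integer seed for the bootstrap; mandatory when `n_boot > 0`.
#' @return An object of class `template_fit`: list with `lambda_max_nm`,
#'   `amplitude`, `baseline`, `rss`, `fitted_curve` (an
#'   `absorbance_spectrum` over the fit window), `ci_95` (length-2 numeric
#'   or `NULL`), `n_boot`, `seed`, `at_bound`.
#' @examples
#' s <- make_spectrum(547, noise_sd = 0.01, seed = 1)
#' fit <- fit_lambda_max(s)
#' fit$lambda_max_nm
#' @export
fit_lambda_max <- function(spectrum, fit_window_nm = c(300, 700),
                           bounds_nm = c(300, 700), include_beta = TRUE,
                           baseline = FALSE, n_boot = 0, seed = NULL) {
  stopifnot(inherits(spectrum, "absorbance_spectrum"),
            length(fit_window_nm) == 2L, length(bounds_nm) == 2L)
  keep <- spectrum$wavelength_nm >= fit_window_nm[1] &
    spectrum$wavelength_nm <= fit_window_nm[2]
  wl <- spectrum$wavelength_nm[keep]
  y <- spectrum$absorbance[keep]
  if (length(wl) < 10L) {
    stop_domain("need at least 10 points inside the fit window")
  }
  ymax <- max(y)
  if (ymax <= 0) {
    stop(errorCondition("no positive absorbance inside the fit window",
      class = c("mothvis_fit_failure_error", "mothvis_error")))
  }
  y <- y / ymax
  fit <- .fit_lmax_core(wl, y, bounds_nm, include_beta, baseline)
  if (fit$at_bound) {
    warning("fitted peak lies at a search bound; estimate unreliable",
            call. = FALSE)
  }
  curve <- fit$amplitude *
    govardovskii_a1(wl, fit$lambda_max_nm, include_beta) + fit$baseline
  ci <- NULL
  if (n_boot > 0) {
    if (is.null(seed)) stop_domain("`seed` is required when n_boot > 0")
    bs <- bootstrap_ci(spectrum, n_boot = n_boot, seed = seed,
                       fit_window_nm = fit_window_nm, bounds_nm = bounds_nm,
                       include_beta = include_beta, baseline = baseline)
    ci <- c(bs$lower_nm, bs$upper_nm)
  }
  structure(
    list(lambda_max_nm = fit$lambda_max_nm, amplitude = fit$amplitude,
         baseline = fit$baseline, rss = fit$rss,
         fitted_curve = absorbance_spectrum(wl, curve, label = "fitted",
                                            condition = "synthetic"),
         ci_95 = ci, n_boot = n_boot, seed = seed, at_bound = fit$at_bound),
    class = "template_fit"
  )
}

#' @export
print.template_fit <- function(x, ...) {
  cat(sprintf("<template_fit> lambda_max = %.1f nm (amplitude %.3g, rss %.3g)\n",
              x$lambda_max_nm, x$amplitude, x$rss))
  if (!is.null(x$ci_95)) {
    cat(sprintf("  95%% CI [%.1f, %.1f] nm (%d bootstrap replicates, seed %d)\n",
                x$ci_95[1], x$ci_95[2], x$n_boot, x$seed))
  }
  invisible(x)
}

#' Bootstrap confidence interval for the fitted pigment peak
#'
#' Case-resamples the (wavelength, absorbance) pairs of the spectrum with
#' replacement, refits the template to each replicate, and returns the
#' 2.5th and 97.5th percentiles of the recovered peaks. The resampling
#' stream is fully determined by `seed`, so identical calls give identical
#' intervals. Replicates whose fit fails (no positive-amplitude candidate,
#' or a peak pinned at a search bound) are dropped; if more than 10% fail
#' the interval is flagged unreliable with a warning.
#'
#' For speed the candidate-template matrix over the spectrum's wavelength
#' grid is computed once and every replicate is scored against it in
#' closed form (case resampling only permutes rows of that matrix), then
#' refined locally exactly as in [fit_lambda_max()].
#'
#' @inheritParams fit_lambda_max
#' @param n_boot Number of bootstrap replicates; default 1000.
#' @param seed Integer seed (mandatory).
#' @return List with `lower_nm`, `upper_nm`, `lambda_max_boot` (the vector
#'   of replicate estimates, `NA` where a replicate failed), `n_failed`,
#'   `n_boot`, `seed`, and logical `reliable`.
#' @export
bootstrap_ci <- function(spectrum, n_boot = 1000, seed,
                         fit_window_nm = c(300, 700),
                         bounds_nm = c(300, 700), include_beta = TRUE,
                         baseline = FALSE) {
  stopifnot(inherits(spectrum, "absorbance_spectrum"))
  if (missing(seed) || is.null(seed)) stop_domain("`seed` is mandatory")
  seed <- as.integer(seed)
  # The full-spectrum fit must succeed before resampling means anything.
  fit_lambda_max(spectrum, fit_window_nm, bounds_nm, include_beta, baseline)
  keep <- spectrum$wavelength_nm >= fit_window_nm[1] &
    spectrum$wavelength_nm <= fit_window_nm[2]
  wl <- spectrum$wavelength_nm[keep]
  y <- spectrum$absorbance[keep] / max(spectrum$absorbance[keep])
  n <- length(wl)
  grid <- seq(bounds_nm[1], bounds_nm[2], by = 1)
  tm <- .template_matrix(wl, grid, include_beta)
  tm2 <- tm^2
  est <- rep(NA_real_, n_boot)
  withr::with_seed(seed, {
    idx_mat <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  })
  for (b in seq_len(n_boot)) {
    idx <- idx_mat[, b]
    yb <- y[idx]
    if (stats::sd(yb) == 0) next
    sc <- if (!baseline) {
      cty <- as.numeric(crossprod(tm[idx, , drop = FALSE], yb))
      ctt <- colSums(tm2[idx, , drop = FALSE])
      rss <- -cty^2 / ctt  # sum(yb^2) constant across candidates
      rss[cty <= 0] <- Inf
      rss
    } else {
      .score_candidates(tm[idx, , drop = FALSE], yb, TRUE)$rss
    }
    if (all(!is.finite(sc))) next
    j <- which.min(sc)
    if (j == 1L || j == length(grid)) next
    opt <- stats::optimize(.rss_at, interval = c(grid[j - 1L], grid[j + 1L]),
                           wavelength_nm = wl[idx], y = yb,
                           include_beta = include_beta, baseline = baseline,
                           tol = 0.005)
    est[b] <- opt$minimum
  }
  n_failed <- sum(is.na(est))
  reliable <- n_failed <= 0.1 * n_boot
  if (!reliable) {
    warning(sprintf("%d of %d bootstrap fits failed; CI unreliable",
                    n_failed, n_boot), call. = FALSE)
  }
  qs <- stats::quantile(est, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(lower_nm = qs[1], upper_nm = qs[2], lambda_max_boot = est,
       n_failed = n_failed, n_boot = n_boot, seed = seed,
       reliable = reliable)
}
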