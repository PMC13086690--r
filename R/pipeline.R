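#' Run a configured multi-stage analysis
#'
#' Executes the requested analysis stages in order and assembles a
#' structured report. Stages are independent: a failing stage is recorded
#' under `errors` with its message and the remaining stages still run.
#' Reported numbers use the package's documented precision (metrics to 3
#' significant figures, peak wavelengths to 0.1 nm).
#'
#' `config` is a named list:
#' \describe{
#'   \item{seed}{Integer; mandatory if any stochastic stage (a bootstrap)
#'     is requested.}
#'   \item{output_dir}{Optional; if set, `report.json` is written there.}
#'   \item{stages}{Named list, each entry enabling one stage:
#'     \describe{
#'       \item{eye_metrics}{Arguments for [eye_geometry()].}
#'       \item{bfd}{`zstack` (path or [zstack_series()]), optional
#'         `smoothing_window`.}
#'       \item{contrast}{`profile` (path or [grating_profile()]), optional
#'         `smoothing_window`, `edge_trim`.}
#'       \item{cutoff}{`curve` (path or data frame), optional
#'         `contrast_floor`.}
#'       \item{fit_opsin}{`spectrum` (path or [absorbance_spectrum()]),
#'         optional `fit_window_nm`, `bounds_nm`, `include_beta`,
#'         `baseline`, `n_boot`.}
#'     }}
#' }
#'
#' @param config Configuration list, see Details.
#' @return A report list with `package_version`, `timestamp`, `config`,
#'   `results`, `errors` and `n_errors`. The `timestamp` is the only
#'   field that differs between reruns with identical config.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config))
  stages <- config$stages %||% list()
  needs_seed <- !is.null(stages$fit_opsin) &&
    (stages$fit_opsin$n_boot %||% 0) > 0
  if (needs_seed && is.null(config$seed)) {
    stop_domain("config$seed is mandatory when a bootstrap stage is enabled")
  }
  results <- list()
  errors <- list()
  run_stage <- function(name, fun) {
    tryCatch(results[[name]] <<- fun(),
             error = function(e) errors[[name]] <<- conditionMessage(e))
  }

  if (!is.null(stages$eye_metrics)) {
    run_stage("eye_metrics", function() {
      geom <- do.call(eye_geometry, stages$eye_metrics)
      m <- optical_metrics(geom)
      list(inputs = unclass(geom),
           metrics = lapply(unclass(m), report_signif),
           units = list(interommatidial_angle_deg = "deg", f_number = "",
                        effective_rhabdom_length_um = "um",
                        optical_sensitivity_um2sr = "um^2 sr"))
    })
  }
  if (!is.null(stages$bfd)) {
    run_stage("bfd", function() {
      st <- stages$bfd
      z <- if (is.character(st$zstack)) read_zstack_csv(st$zstack) else st$zstack
      list(bfd_um = report_signif(
        back_focal_distance(z, st$smoothing_window %||% 1L)),
        units = "um")
    })
  }
  if (!is.null(stages$contrast)) {
    run_stage("contrast", function() {
      st <- stages$contrast
      p <- if (is.character(st$profile)) read_profile_csv(st$profile) else st$profile
      list(frequency_cpd = attr(p, "spatial_frequency_cpd"),
           michelson_contrast = report_signif(profile_contrast(
             p, st$smoothing_window %||% 1L, st$edge_trim %||% 0.1)))
    })
  }
  if (!is.null(stages$cutoff)) {
    run_stage("cutoff", function() {
      st <- stages$cutoff
      crv <- if (is.character(st$curve)) read_contrast_curve_csv(st$curve) else st$curve
      cc <- cutoff_frequency(crv, st$contrast_floor %||% 0.02)
      list(cutoff_fc_cpd = report_signif(cc$cutoff_fc_cpd),
           slope = report_signif(cc$slope),
           intercept = report_signif(cc$intercept), units = "cycles/deg")
    })
  }
  if (!is.null(stages$fit_opsin)) {
    run_stage("fit_opsin", function() {
      st <- stages$fit_opsin
      s <- if (is.character(st$spectrum)) read_spectrum_csv(st$spectrum) else st$spectrum
      fit <- fit_lambda_max(
        s, fit_window_nm = st$fit_window_nm %||% c(300, 700),
        bounds_nm = st$bounds_nm %||% c(300, 700),
        include_beta = st$include_beta %||% TRUE,
        baseline = st$baseline %||% FALSE,
        n_boot = st$n_boot %||% 0, seed = config$seed)
      out <- list(lambda_max_nm = round(fit$lambda_max_nm, 1),
                  amplitude = report_signif(fit$amplitude),
                  rss = report_signif(fit$rss), units = "nm")
      if (!is.null(fit$ci_95)) {
        out$ci_95_nm <- round(fit$ci_95, 1)
        out$n_boot <- fit$n_boot
        out$seed <- fit$seed
      }
      out
    })
  }

  report <- list(
    package_version = as.character(utils::packageVersion("mothvis")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config[setdiff(names(config), "output_dir")],
    results = results,
    errors = errors,
    n_errors = length(errors))
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, file.path(config$output_dir, "report.json"))
  }
  report
}
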