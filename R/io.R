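# CSV readers and writers. One dialect everywhere: comma-separated,
# '.' decimal, UTF-8, mandatory header; '#'-prefixed "key: value" lines
# before the header carry metadata. All writers round-trip through their
# readers.

.read_csv_with_meta <- function(path, expected_header) {
  if (!file.exists(path)) stop_domain(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (ln in lines[is_meta]) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  body_idx <- which(!is_meta & nzchar(trimws(lines)))
  if (length(body_idx) == 0L) {
    stop_domain(sprintf("%s: no header line found", path))
  }
  header_line <- body_idx[1]
  header <- strsplit(lines[header_line], ",", fixed = TRUE)[[1]]
  if (!identical(trimws(header), expected_header)) {
    stop_domain(sprintf("%s line %d: expected header '%s'", path,
                        header_line, paste(expected_header, collapse = ",")))
  }
  data_idx <- body_idx[-1]
  ncol <- length(expected_header)
  vals <- matrix(NA_real_, nrow = length(data_idx), ncol = ncol)
  for (i in seq_along(data_idx)) {
    ln_no <- data_idx[i]
    fields <- strsplit(lines[ln_no], ",", fixed = TRUE)[[1]]
    if (length(fields) != ncol) {
      stop_domain(sprintf("%s line %d: expected %d fields, found %d",
                          path, ln_no, ncol, length(fields)))
    }
    v <- suppressWarnings(as.numeric(fields))
    if (any(is.na(v))) {
      stop_domain(sprintf("%s line %d: non-numeric value", path, ln_no))
    }
    vals[i, ] <- v
  }
  df <- as.data.frame(vals)
  names(df) <- expected_header
  list(data = df, meta = meta, data_lines = data_idx, path = path)
}

#' Read an absorbance spectrum from CSV
#'
#' Expects columns `wavelength_nm,absorbance` (header mandatory);
#' '#'-prefixed `key: value` lines before the header are parsed as
#' metadata (`label`, `condition`).
#'
#' @param path Path to the CSV file.
#' @return An [absorbance_spectrum()].
#' @export
read_spectrum_csv <- function(path) {
  parsed <- .read_csv_with_meta(path, c("wavelength_nm", "absorbance"))
  wl <- parsed$data$wavelength_nm
  bad <- which(diff(wl) <= 0)
  if (length(bad) > 0L) {
    stop_domain(sprintf(
      "%s line %d: wavelengths not strictly increasing", path,
      parsed$data_lines[bad[1] + 1L]))
  }
  cond <- parsed$meta$condition %||% "dark"
  absorbance_spectrum(wl, parsed$data$absorbance,
                      label = parsed$meta$label %||% "", condition = cond)
}

#' Write an absorbance spectrum to CSV
#'
#' @param spectrum An [absorbance_spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "absorbance_spectrum"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# label: %s", attr(spectrum, "label")),
               sprintf("# condition: %s", attr(spectrum, "condition")),
               "wavelength_nm,absorbance"), con)
  writeLines(sprintf("%s,%s",
                     format(spectrum$wavelength_nm, trim = TRUE, digits = 15),
                     format(spectrum$absorbance, trim = TRUE, digits = 15)),
             con)
  invisible(path)
}

#' Read a z-stack focus series from CSV
#'
#' Expects columns `frame,focus_score` and metadata lines `step_um`,
#' `refractive_index_n`, `reference_frame`.
#'
#' @param path Path to the CSV file.
#' @return A [zstack_series()].
#' @export
read_zstack_csv <- function(path) {
  parsed <- .read_csv_with_meta(path, c("frame", "focus_score"))
  step <- as.numeric(parsed$meta$step_um %||% NA)
  if (!is.finite(step)) {
    stop_domain(sprintf("%s: missing '# step_um:' metadata", path))
  }
  zstack_series(parsed$data$frame, parsed$data$focus_score, step_um = step,
                refractive_index_n =
                  as.numeric(parsed$meta$refractive_index_n %||% 1.33),
                reference_frame =
                  as.integer(parsed$meta$reference_frame %||% 0L))
}

#' Write a z-stack focus series to CSV
#' @param series A [zstack_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_zstack_csv <- function(series, path) {
  stopifnot(inherits(series, "zstack_series"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# step_um: %s", format(attr(series, "step_um"))),
               sprintf("# refractive_index_n: %s",
                       format(attr(series, "refractive_index_n"))),
               sprintf("# reference_frame: %d", attr(series, "reference_frame")),
               "frame,focus_score"), con)
  writeLines(sprintf("%d,%s", series$frame_index,
                     format(series$focus_score, trim = TRUE, digits = 15)),
             con)
  invisible(path)
}

#' Read a grating intensity profile from CSV
#'
#' Expects columns `position,intensity` and a `spatial_frequency_cpd`
#' metadata line.
#'
#' @param path Path to the CSV file.
#' @return A [grating_profile()].
#' @export
read_profile_csv <- function(path) {
  parsed <- .read_csv_with_meta(path, c("position", "intensity"))
  f <- as.numeric(parsed$meta$spatial_frequency_cpd %||% NA)
  if (!is.finite(f)) {
    stop_domain(sprintf("%s: missing '# spatial_frequency_cpd:' metadata", path))
  }
  grating_profile(parsed$data$position, parsed$data$intensity, f)
}

#' Write a grating intensity profile to CSV
#' @param profile A [grating_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "grating_profile"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# spatial_frequency_cpd: %s",
                       format(attr(profile, "spatial_frequency_cpd"))),
               "position,intensity"), con)
  writeLines(sprintf("%s,%s",
                     format(profile$position, trim = TRUE, digits = 15),
                     format(profile$intensity, trim = TRUE, digits = 15)),
             con)
  invisible(path)
}

#' Read contrast-versus-frequency points from CSV
#'
#' Expects columns `frequency_cpd,contrast`.
#'
#' @param path Path to the CSV file.
#' @return Data frame suitable for [cutoff_frequency()].
#' @export
read_contrast_curve_csv <- function(path) {
  .read_csv_with_meta(path, c("frequency_cpd", "contrast"))$data
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Recursively reject non-finite numbers, reporting the offending field.
.check_finite_rec <- function(x, name) {
  if (is.list(x)) {
    for (nm in names(x)) {
      .check_finite_rec(x[[nm]], paste(name, nm, sep = "$"))
    }
  } else if (is.numeric(x) && any(!is.finite(x))) {
    stop_domain(sprintf("non-finite value in report field %s", name))
  }
  invisible(TRUE)
}

#' Write an analysis report as JSON
#'
#' Serializes a report (any nested named list of finite numbers, strings
#' and data frames) to pretty-printed JSON with stable field ordering.
#' Non-finite numeric values abort with the offending field named.
#'
#' @param report Named list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(is.list(report))
  .check_finite_rec(report, "report")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
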