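#' Write a canonical spectrum file
#'
#' The canonical on-disk format (".art" extension by convention) is a plain
#' ASCII file of exactly 512 real numbers separated by spaces, the first
#' being the intensity at 7.1 ppm. Numbers are written with 7 significant
#' digits, which preserves single precision; readers accept any whitespace.
#'
#' @param spectrum a [canonical_spectrum()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_canonical()]
#' @export
write_canonical <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "canonical_spectrum"))
  tokens <- formatC(spectrum$intensities, digits = 7, format = "g")
  ok <- tryCatch({
    writeLines(paste(tokens, collapse = " "), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok)
    .mrsdx_stop(sprintf("cannot write canonical file '%s'", path),
                "mrsdx_io_error")
  invisible(path)
}

#' Read a canonical spectrum file
#'
#' @param path file containing exactly 512 whitespace-separated reals.
#' @param te_class TE class to attach (`"short"`, `"long"`, `"other"`);
#'   the file itself carries no metadata.
#' @return a [canonical_spectrum()].
#' @export
read_canonical <- function(path, te_class = "other") {
  if (!file.exists(path))
    .mrsdx_stop(sprintf("file not found: '%s'", path), "mrsdx_io_error")
  tokens <- scan(path, what = character(), quiet = TRUE)
  if (length(tokens) != 512L)
    .mrsdx_stop(sprintf("canonical file '%s' has %d tokens, expected 512",
                        path, length(tokens)), "mrsdx_format_error")
  values <- suppressWarnings(as.numeric(tokens))
  if (anyNA(values))
    .mrsdx_stop(sprintf("canonical file '%s' contains non-numeric tokens", path),
                "mrsdx_format_error")
  canonical_spectrum(values, te_class = te_class,
                     provenance = sprintf("read_canonical(%s)", basename(path)))
}

#' Read a jMRUI-style text FID
#'
#' Parses the minimal key/value + two-column dialect this package reads and
#' writes: header lines of the form `Key: value` (unknown keys are ignored),
#' followed by data rows of two numeric columns holding the real and
#' imaginary FID samples. Mandatory keys are `SamplingInterval` (in ms) and
#' `TransmitterFrequency` (in MHz); `TE` and `TR` (ms), `Sequence` and
#' `WaterReference` are honoured when present.
#'
#' @param path input text file.
#' @return a [raw_fid()].
#' @seealso [write_jmrui_text()]
#' @export
read_jmrui_text <- function(path) {
  if (!file.exists(path))
    .mrsdx_stop(sprintf("file not found: '%s'", path), "mrsdx_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  header <- list()
  data_re <- numeric()
  data_im <- numeric()
  for (ln in lines) {
    if (grepl(":", ln, fixed = TRUE)) {
      key <- trimws(sub(":.*$", "", ln))
      val <- trimws(sub("^[^:]*:", "", ln))
      header[[key]] <- val
    } else {
      fields <- suppressWarnings(as.numeric(strsplit(ln, "[[:space:],]+")[[1]]))
      fields <- fields[!is.na(fields)]
      if (length(fields) >= 2L) {
        data_re <- c(data_re, fields[1L])
        data_im <- c(data_im, fields[2L])
      }
    }
  }

  need <- function(key) {
    if (is.null(header[[key]]))
      .mrsdx_stop(sprintf("missing mandatory header key '%s' in '%s'", key, path),
                  "mrsdx_format_error")
    as.numeric(header[[key]])
  }
  sampling_ms <- need("SamplingInterval")
  ft_mhz <- need("TransmitterFrequency")
  if (length(data_re) == 0L)
    .mrsdx_stop(sprintf("no data rows in '%s'", path), "mrsdx_format_error")

  raw_fid(
    samples = complex(real = data_re, imaginary = data_im),
    dwell_time = sampling_ms * 1e-3,
    transmitter_frequency = ft_mhz,
    te = if (!is.null(header$TE)) as.numeric(header$TE) else NA_real_,
    tr = if (!is.null(header$TR)) as.numeric(header$TR) else NA_real_,
    sequence = if (!is.null(header$Sequence) &&
                   toupper(header$Sequence) %in% c("PRESS", "STEAM"))
      toupper(header$Sequence) else "PRESS",
    is_water_reference = !is.null(header$WaterReference) &&
      tolower(header$WaterReference) %in% c("true", "yes", "1")
  )
}

#' Write a jMRUI-style text FID
#'
#' Inverse of [read_jmrui_text()]; writes the minimal dialect documented
#' there with full double precision, so a write/read roundtrip reproduces
#' the samples.
#'
#' @param fid a [raw_fid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_jmrui_text <- function(fid, path) {
  stopifnot(inherits(fid, "raw_fid"))
  header <- c(
    sprintf("PointsInDataset: %d", length(fid$samples)),
    sprintf("SamplingInterval: %.17g", fid$dwell_time * 1e3),
    sprintf("TransmitterFrequency: %.17g", fid$transmitter_frequency),
    if (!is.na(fid$te)) sprintf("TE: %.17g", fid$te),
    if (!is.na(fid$tr)) sprintf("TR: %.17g", fid$tr),
    sprintf("Sequence: %s", fid$sequence),
    sprintf("WaterReference: %s", if (fid$is_water_reference) "true" else "false"),
    "SignalPoints (real imaginary):"
  )
  body <- sprintf("%.17g %.17g", Re(fid$samples), Im(fid$samples))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Resample a spectrum onto the canonical grid
#'
#' Piecewise-linear interpolation of intensities given on an arbitrary
#' monotone ppm axis onto the canonical endpoint-inclusive grid. Formats
#' with a different number of points across the 7.1 to -2.7 ppm interval
#' are thereby brought to the fixed 512-point representation. Target grid
#' points outside the coverage of the source axis are set to 0 rather than
#' extrapolated.
#'
#' @param values numeric intensities.
#' @param source_axis ppm value of each entry of `values`; must be
#'   monotone (either direction) with at least 2 points.
#' @param n_points target grid size (default 512).
#' @param te_class TE class to attach to the result.
#' @param provenance provenance entries to carry over.
#' @return a [canonical_spectrum()] when `n_points` is 512, otherwise a
#'   plain numeric vector on `ppm_axis(n_points)`.
#' @export
resample_linear <- function(values, source_axis, n_points = 512L,
                            te_class = "other", provenance = character()) {
  values <- as.numeric(values)
  source_axis <- as.numeric(source_axis)
  if (length(values) != length(source_axis))
    .mrsdx_stop("values and source_axis lengths differ", "mrsdx_invalid_argument")
  if (length(values) < 2L)
    .mrsdx_stop("need at least 2 source points", "mrsdx_invalid_argument")
  d <- diff(source_axis)
  if (!(all(d > 0) || all(d < 0)))
    .mrsdx_stop("source_axis must be strictly monotone", "mrsdx_invalid_argument")

  target <- ppm_axis(n_points)
  out <- approx(x = source_axis, y = values, xout = target,
                method = "linear", rule = 1)$y
  out[is.na(out)] <- 0
  if (as.integer(n_points) == 512L) {
    canonical_spectrum(out, te_class = te_class,
                       provenance = c(provenance, "resample_linear(512)"))
  } else {
    out
  }
}
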