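#' Raw free induction decay
#'
#' Container for a complex time-domain single-voxel acquisition together
#' with the metadata the processing pipeline needs: the dwell time (seconds
#' per sample), the transmitter frequency in MHz (which converts Hz offsets
#' to ppm), the echo and repetition times, and the localisation sequence.
#'
#' The echo time determines the TE class used throughout the package:
#' 20-32 ms is "short", 135-144 ms is "long", anything else is "other".
#'
#' @param samples complex vector, the acquired FID (arbitrary units).
#' @param dwell_time sampling interval in seconds; must be > 0.
#' @param transmitter_frequency transmitter (carrier) frequency in MHz.
#' @param te echo time, ms.
#' @param tr repetition time, ms.
#' @param sequence localisation sequence, `"PRESS"` or `"STEAM"`.
#' @param is_water_reference logical; `TRUE` for an unsuppressed-water
#'   acquisition.
#' @return an object of class `raw_fid`.
#' @export
raw_fid <- function(samples, dwell_time, transmitter_frequency,
                    te = NA_real_, tr = NA_real_,
                    sequence = c("PRESS", "STEAM"),
                    is_water_reference = FALSE) {
  if (length(samples) == 0L)
    .mrsdx_stop("samples must be non-empty", "mrsdx_invalid_argument")
  if (!is.numeric(dwell_time) || dwell_time <= 0)
    .mrsdx_stop("dwell_time must be > 0", "mrsdx_invalid_argument")
  if (!is.numeric(transmitter_frequency) || transmitter_frequency <= 0)
    .mrsdx_stop("transmitter_frequency must be > 0 MHz", "mrsdx_invalid_argument")
  sequence <- match.arg(sequence)
  structure(
    list(
      samples = as.complex(samples),
      dwell_time = as.numeric(dwell_time),
      transmitter_frequency = as.numeric(transmitter_frequency),
      te = as.numeric(te),
      tr = as.numeric(tr),
      sequence = sequence,
      is_water_reference = isTRUE(is_water_reference)
    ),
    class = "raw_fid"
  )
}

#' @export
print.raw_fid <- function(x, ...) {
  cat(sprintf(
    "<raw_fid> %d samples, dwell %g s, transmitter %.2f MHz, TE %s ms (%s), %s%s\n",
    length(x$samples), x$dwell_time, x$transmitter_frequency,
    format(x$te), te_class(x), x$sequence,
    if (x$is_water_reference) ", water reference" else ""
  ))
  invisible(x)
}

#' TE class of an acquisition
#'
#' Maps an echo time to the band it falls in: short (20-32 ms), long
#' (135-144 ms) or other.
#'
#' @param x a `raw_fid`, or a numeric echo time in ms.
#' @return `"short"`, `"long"` or `"other"`.
#' @export
te_class <- function(x) {
  te <- if (inherits(x, "raw_fid")) x$te else as.numeric(x)
  if (is.na(te)) return("other")
  if (te >= 20 && te <= 32) return("short")
  if (te >= 135 && te <= 144) return("long")
  "other"
}

#' Canonical processed spectrum
#'
#' The exchange currency of the toolkit: exactly 512 real intensities on
#' the fixed, endpoint-inclusive 7.1 to -2.7 ppm grid (see [ppm_axis()]).
#' Carries the TE class and a free-text provenance log listing the
#' processing stages the spectrum went through.
#'
#' @param intensities numeric vector of exactly 512 finite reals.
#' @param te_class `"short"`, `"long"` or `"other"`.
#' @param provenance character vector, one entry per processing stage.
#' @return an object of class `canonical_spectrum`.
#' @export
canonical_spectrum <- function(intensities, te_class = "other",
                               provenance = character()) {
  intensities <- as.numeric(intensities)
  if (length(intensities) != 512L)
    .mrsdx_stop(sprintf("canonical spectrum must have 512 points, got %d",
                        length(intensities)), "mrsdx_format_error")
  te_class <- match.arg(te_class, c("short", "long", "other"))
  structure(
    list(intensities = intensities, te_class = te_class,
         provenance = as.character(provenance)),
    class = "canonical_spectrum"
  )
}

#' @export
print.canonical_spectrum <- function(x, ...) {
  cat(sprintf("<canonical_spectrum> 512 points, 7.1 .. -2.7 ppm, TE class %s\n",
              x$te_class))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " | "), "\n")
  invisible(x)
}

# append a provenance entry, returning the spectrum
log_stage <- function(spectrum, entry) {
  spectrum$provenance <- c(spectrum$provenance, entry)
  spectrum
}
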