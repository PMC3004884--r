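#' Processing parameters
#'
#' Bundles every tunable constant of the automatic processing pipeline.
#' Defaults reflect the standard automated protocol: 10-component HLSVD
#' water removal, 1 Hz exponential line broadening, baseline offset taken
#' on both sides of the water peak (-2 to -1 ppm and 9 to 11 ppm), and the
#' alignment search for creatine (3.03 ppm), choline (3.21 ppm) and lipid
#' (1.29 ppm) references within +/-5 data points, accepting a candidate
#' whose SNR is at least 1/5 of the SNR of the tallest peak in the
#' 0-4.5 ppm band.
#'
#' @param hlsvd_components HLSVD model order (count, default 10).
#' @param water_band ppm interval of components removed as water.
#' @param lb_hz exponential line broadening, Hz.
#' @param baseline_regions list of two ppm intervals averaged for the
#'   baseline offset.
#' @param reference_peaks named numeric vector of alignment references in
#'   the order they are tried.
#' @param search_halfwidth_pts half-width of the peak search window, points.
#' @param tp_search_band ppm band searched for the tallest peak.
#' @param tp_ratio acceptance factor: a reference is accepted when its SNR
#'   is at least `SNR(tallest peak) / tp_ratio`.
#' @param noise_region ppm interval whose intensity standard deviation
#'   estimates the noise level.
#' @param noise_region_canonical fallback noise interval used when only the
#'   canonical axis (which ends at 7.1 ppm) is available.
#' @param phase_band ppm band whose real-part integral is maximised by
#'   zero-order phasing.
#' @param snr_threshold quality-control SNR threshold (pass when SNR > 10).
#' @param linewidth_threshold_hz quality-control water linewidth threshold
#'   (pass when FWHM < 8 Hz).
#' @return a named list of class `processing_params`.
#' @export
processing_params <- function(hlsvd_components = 10L,
                              water_band = c(4.33, 5.07),
                              lb_hz = 1.0,
                              baseline_regions = list(c(-2, -1), c(9, 11)),
                              reference_peaks = c(Cr = 3.03, Cho = 3.21, Lip = 1.29),
                              search_halfwidth_pts = 5L,
                              tp_search_band = c(0, 4.5),
                              tp_ratio = 5,
                              noise_region = c(9, 11),
                              noise_region_canonical = c(-2.7, -1.7),
                              phase_band = c(0.5, 4.2),
                              snr_threshold = 10,
                              linewidth_threshold_hz = 8) {
  stopifnot(hlsvd_components >= 1, search_halfwidth_pts >= 1, tp_ratio > 0,
            lb_hz >= 0, length(reference_peaks) >= 1)
  structure(
    list(hlsvd_components = as.integer(hlsvd_components),
         water_band = water_band, lb_hz = lb_hz,
         baseline_regions = baseline_regions,
         reference_peaks = reference_peaks,
         search_halfwidth_pts = as.integer(search_halfwidth_pts),
         tp_search_band = tp_search_band, tp_ratio = tp_ratio,
         noise_region = noise_region,
         noise_region_canonical = noise_region_canonical,
         phase_band = phase_band,
         snr_threshold = snr_threshold,
         linewidth_threshold_hz = linewidth_threshold_hz),
    class = c("processing_params", "list")
  )
}

#' Exponential apodization (line broadening)
#'
#' Multiplies sample `i` by `exp(-pi * lb_hz * t_i)` with `t_i = i * dwell`.
#' This adds exactly `lb_hz` to the full width at half maximum of every
#' lorentzian line (a damping increase of `pi * lb_hz` in 1/s).
#'
#' @param fid a [raw_fid()].
#' @param lb_hz line broadening in Hz; must be >= 0.
#' @return the apodized [raw_fid()].
#' @export
apodize <- function(fid, lb_hz = 1.0) {
  stopifnot(inherits(fid, "raw_fid"))
  if (!is.numeric(lb_hz) || lb_hz < 0)
    .mrsdx_stop("lb_hz must be >= 0", "mrsdx_invalid_argument")
  t <- (seq_along(fid$samples) - 1L) * fid$dwell_time
  fid$samples <- fid$samples * exp(-pi * lb_hz * t)
  fid
}

#' Fourier transform an FID to a ppm-calibrated spectrum
#'
#' Unitary discrete Fourier transform with the frequency axis converted to
#' chemical shift under the water-carrier convention:
#' `ppm = 4.7 - f / transmitter_frequency` (f in Hz, transmitter in MHz),
#' so a component at zero offset appears at 4.7 ppm. The returned values
#' are complex and ordered by strictly decreasing ppm; signal and spectrum
#' energies are equal (Parseval).
#'
#' @param fid a [raw_fid()].
#' @return list with complex `values` and numeric `ppm`, both ordered by
#'   decreasing ppm.
#' @export
to_spectrum <- function(fid) {
  stopifnot(inherits(fid, "raw_fid"))
  x <- fid$samples
  n <- length(x)
  spec <- fft(x) / sqrt(n)
  k <- 0:(n - 1L)
  f <- ifelse(k <= n %/% 2L - 1L, k, k - n) / (n * fid$dwell_time)
  ppm <- 4.7 - f / fid$transmitter_frequency
  ord <- order(ppm, decreasing = TRUE)
  list(values = spec[ord], ppm = ppm[ord])
}

#' Zero-order phase correction
#'
#' Finds the constant phase that maximises the integral of the real part
#' over the metabolite band (default 0.5-4.2 ppm) and returns the real
#' part after rotation. Because the integral of `Re(e^{i phi} S)` over the
#' band equals `|sum S| * cos(phi + Arg(sum S))`, the maximiser is exactly
#' `phi = -Arg(sum of S over the band)`; first-order phasing is not
#' attempted.
#'
#' @param values complex spectrum values.
#' @param ppm ppm value of each point.
#' @param band ppm band over which the real-part integral is maximised.
#' @return list with numeric `values` (the phased real part) and `phase`
#'   (radians applied).
#' @export
zero_order_phase <- function(values, ppm, band = c(0.5, 4.2)) {
  stopifnot(length(values) == length(ppm))
  sel <- ppm_in_band(ppm, band)
  s <- sum(values[if (any(sel)) sel else TRUE])
  phase <- if (Mod(s) > 0) -Arg(s) else 0
  list(values = Re(values * exp(complex(imaginary = phase))), phase = phase)
}

#' Baseline offset correction
#'
#' Subtracts from every point the mean intensity over the baseline
#' regions on both sides of the water peak (-2 to -1 ppm and 9 to 11 ppm
#' by default). Regions that fall outside the working axis contribute no
#' points (on the canonical axis, which ends at 7.1 ppm, only the
#' downfield -2 to -1 ppm region is available); it is an error only when
#' no baseline point at all is in range.
#'
#' @param values numeric intensities, or a [canonical_spectrum()].
#' @param ppm ppm axis (ignored when `values` is a canonical spectrum).
#' @param regions list of ppm intervals averaged as baseline.
#' @return same shape as `values`, baseline-corrected.
#' @export
baseline_offset <- function(values, ppm = NULL,
                            regions = list(c(-2, -1), c(9, 11))) {
  if (inherits(values, "canonical_spectrum")) {
    s <- values
    out <- baseline_offset(s$intensities, ppm_axis(512L), regions)
    s$intensities <- out
    return(log_stage(s, "baseline_offset"))
  }
  stopifnot(length(values) == length(ppm))
  sel <- Reduce(`|`, lapply(regions, function(r) ppm_in_band(ppm, r)))
  if (!any(sel))
    .mrsdx_stop("no baseline point falls inside the working axis",
                "mrsdx_configuration_error")
  values - mean(values[sel])
}

#' Locate a strict local maximum near an expected position
#'
#' Searches the window of `halfwidth_pts` points either side of the grid
#' point nearest `center_ppm`. A point qualifies as a peak only when its
#' intensity strictly exceeds both contiguous neighbours; among qualifying
#' points the tallest wins, ties going to the smaller index (higher ppm).
#'
#' @param values numeric intensities, or a [canonical_spectrum()].
#' @param ppm ppm axis (ignored for canonical spectra).
#' @param center_ppm expected peak position, ppm.
#' @param halfwidth_pts window half-width in points.
#' @return integer index of the peak, or `NA_integer_` when no strict
#'   local maximum exists in the window.
#' @export
find_local_peak <- function(values, ppm = NULL, center_ppm,
                            halfwidth_pts = 5L) {
  if (inherits(values, "canonical_spectrum")) {
    ppm <- ppm_axis(512L)
    values <- values$intensities
  }
  stopifnot(length(values) == length(ppm))
  n <- length(values)
  ci <- nearest_ppm_index(ppm, center_ppm)
  lo <- ci - halfwidth_pts
  hi <- ci + halfwidth_pts
  if (lo < 1L || hi > n)
    .mrsdx_stop("peak search window extends beyond the axis",
                "mrsdx_invalid_argument")
  idx <- lo:hi
  # strict local maximum against contiguous neighbours on the full axis
  interior <- idx[idx > 1L & idx < n]
  is_peak <- values[interior] > values[interior - 1L] &
    values[interior] > values[interior + 1L]
  cand <- interior[is_peak]
  if (length(cand) == 0L) return(NA_integer_)
  cand[which.max(values[cand])]
}

#' Signal-to-noise ratio of a peak
#'
#' Peak intensity divided by the standard deviation of the intensities in
#' the noise region (9-11 ppm by default; -2.7 to -1.7 ppm when only the
#' canonical axis is available).
#'
#' @param values numeric intensities, or a [canonical_spectrum()].
#' @param ppm ppm axis (ignored for canonical spectra, where the fallback
#'   noise region applies).
#' @param peak_index index of the peak whose SNR is wanted.
#' @param noise_region ppm interval used for the noise estimate; must
#'   contain at least 8 axis points.
#' @return the SNR (dimensionless).
#' @export
snr_estimate <- function(values, ppm = NULL, peak_index,
                         noise_region = c(9, 11)) {
  if (inherits(values, "canonical_spectrum")) {
    ppm <- ppm_axis(512L)
    values <- values$intensities
  }
  stopifnot(length(values) == length(ppm))
  sel <- ppm_in_band(ppm, noise_region)
  if (sum(sel) < 8L)
    .mrsdx_stop("noise region must contain at least 8 axis points",
                "mrsdx_configuration_error")
  noise_sd <- sd(values[sel])
  values[peak_index] / noise_sd
}

#' Shift a spectrum by whole grid points
#'
#' Moves spectral features along the index axis by zero-padding one end
#' and dropping the same number of points at the other, so the length is
#' conserved. Positive `k` prepends `k` zeros and drops the last `k`
#' points: features move toward higher index, i.e. lower ppm. Negative `k`
#' does the opposite.
#'
#' @param values numeric vector, or a [canonical_spectrum()].
#' @param k signed shift in points; `abs(k)` must be smaller than the
#'   length.
#' @return shifted object of the same shape.
#' @export
shift_spectrum <- function(values, k) {
  if (inherits(values, "canonical_spectrum")) {
    s <- values
    s$intensities <- shift_spectrum(s$intensities, k)
    return(log_stage(s, sprintf("shift_spectrum(%+d)", as.integer(k))))
  }
  n <- length(values)
  k <- as.integer(k)
  if (abs(k) >= n)
    .mrsdx_stop(sprintf("|k| must be < %d", n), "mrsdx_invalid_argument")
  if (k == 0L) return(values)
  if (k > 0L) c(rep(0, k), values[seq_len(n - k)])
  else c(values[(-k + 1L):n], rep(0, -k))
}

#' Choose an alignment reference peak
#'
#' Implements the automatic reference search: the tallest peak (TP) in the
#' 0-4.5 ppm band is located, then the creatine (3.03 ppm), choline
#' (3.21 ppm) and lipid (1.29 ppm) positions are tried in that order. A
#' candidate is accepted when a strict local peak exists within
#' `search_halfwidth_pts` points of its nominal position and its SNR is at
#' least `SNR(TP) / tp_ratio`. The returned shift is the signed number of
#' points that moves the found peak onto the grid point nearest its
#' nominal ppm. When every candidate fails the spectrum cannot be
#' automatically aligned and `("none", 0)` is returned.
#'
#' @param spectrum a [canonical_spectrum()].
#' @param params a [processing_params()].
#' @return list with `reference` (`"Cr"`, `"Cho"`, `"Lip"` or `"none"`)
#'   and integer `shift` in points.
#' @export
choose_alignment_reference <- function(spectrum, params = processing_params()) {
  stopifnot(inherits(spectrum, "canonical_spectrum"))
  values <- spectrum$intensities
  axis <- ppm_axis(512L)
  noise_region <- params$noise_region_canonical

  in_tp <- ppm_in_band(axis, params$tp_search_band)
  tp_index <- which(in_tp)[which.max(values[in_tp])]
  snr_tp <- snr_estimate(values, axis, tp_index, noise_region)

  for (name in names(params$reference_peaks)) {
    nominal <- params$reference_peaks[[name]]
    idx <- find_local_peak(values, axis, nominal, params$search_halfwidth_pts)
    if (is.na(idx)) next
    snr_cand <- snr_estimate(values, axis, idx, noise_region)
    if (is.finite(snr_cand) && is.finite(snr_tp) &&
        snr_cand >= snr_tp / params$tp_ratio) {
      target <- nearest_ppm_index(axis, nominal)
      return(list(reference = name, shift = as.integer(target - idx)))
    }
  }
  list(reference = "none", shift = 0L)
}

#' Automatically align a canonical spectrum
#'
#' Applies [choose_alignment_reference()] and, when a reference is
#' accepted, shifts the spectrum ([shift_spectrum()]) so the reference
#' peak sits at the grid point nearest its nominal chemical shift;
#' otherwise the spectrum is left unchanged.
#'
#' @param spectrum a [canonical_spectrum()].
#' @param params a [processing_params()].
#' @return list with the (possibly shifted) `spectrum` and a `report`
#'   holding `reference_used`, `shift_points` and `aligned`.
#' @export
align <- function(spectrum, params = processing_params()) {
  choice <- choose_alignment_reference(spectrum, params)
  aligned <- choice$reference != "none"
  out <- if (aligned && choice$shift != 0L)
    shift_spectrum(spectrum, choice$shift) else spectrum
  out <- log_stage(out, sprintf("align(reference=%s, shift=%+d)",
                                choice$reference, choice$shift))
  list(
    spectrum = out,
    report = list(reference_used = choice$reference,
                  shift_points = if (aligned) as.integer(choice$shift) else 0L,
                  aligned = aligned)
  )
}

#' Full automatic processing pipeline
#'
#' Runs the automated processing chain on a metabolite FID, in this fixed
#' order: HLSVD water filtering, exponential apodization, Fourier
#' transform with ppm calibration, zero-order phasing, baseline offset
#' correction on the acquisition axis, linear resampling onto the
#' canonical 512-point grid, and automatic alignment. Every stage and its
#' parameters are recorded in the provenance log.
#'
#' @param metabolite_fid a [raw_fid()] of the water-suppressed acquisition.
#' @param water_fid optional unsuppressed-water [raw_fid()]; not used by
#'   the spectral chain itself (it feeds quality control, see
#'   [qc_case()]), but its presence is logged.
#' @param params a [processing_params()].
#' @return an aligned [canonical_spectrum()]; the alignment report is
#'   attached as attribute `"alignment"`.
#' @export
process_pipeline <- function(metabolite_fid, water_fid = NULL,
                             params = processing_params()) {
  stopifnot(inherits(metabolite_fid, "raw_fid"))
  stage <- "water_filter"
  out <- tryCatch({
    fid <- water_filter(metabolite_fid, params)
    stage <- "apodize"
    fid <- apodize(fid, params$lb_hz)
    stage <- "to_spectrum"
    sp <- to_spectrum(fid)
    stage <- "zero_order_phase"
    ph <- zero_order_phase(sp$values, sp$ppm, params$phase_band)
    stage <- "baseline_offset"
    corrected <- baseline_offset(ph$values, sp$ppm, params$baseline_regions)
    stage <- "resample_linear"
    prov <- c(
      sprintf("water_filter(k=%d, band=[%g,%g])", params$hlsvd_components,
              params$water_band[1], params$water_band[2]),
      sprintf("apodize(lb=%g Hz)", params$lb_hz),
      "to_spectrum(carrier at 4.7 ppm)",
      sprintf("zero_order_phase(%+.4f rad)", ph$phase),
      "baseline_offset",
      if (!is.null(water_fid)) "water_reference: present"
    )
    canon <- resample_linear(corrected, sp$ppm, 512L,
                             te_class = te_class(metabolite_fid),
                             provenance = prov)
    stage <- "align"
    align(canon, params)
  }, error = function(e) {
    .mrsdx_stop(sprintf("pipeline stage '%s' failed: %s",
                        stage, conditionMessage(e)), "mrsdx_pipeline_error")
  })
  structure(out$spectrum, alignment = out$report)
}
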