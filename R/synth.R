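#' Acquisition specification for simulated FIDs
#'
#' Defaults emulate a 1.5 T single-voxel proton acquisition: 2048 complex
#' points over a 2500 Hz sweep at a 63.87 MHz transmitter.
#'
#' @param n_points complex samples per FID.
#' @param sweep_hz spectral width, Hz (dwell time is its reciprocal).
#' @param transmitter_mhz transmitter frequency, MHz.
#' @param noise_sd standard deviation of the complex Gaussian noise added
#'   per channel (a.u.).
#' @param water_amplitude amplitude of the residual water component at
#'   4.7 ppm (a.u.).
#' @return named list of class `acquisition_spec`.
#' @export
acquisition_spec <- function(n_points = 2048L, sweep_hz = 2500,
                             transmitter_mhz = 63.87,
                             noise_sd = 0.08, water_amplitude = 40) {
  structure(list(n_points = as.integer(n_points), sweep_hz = sweep_hz,
                 transmitter_mhz = transmitter_mhz, noise_sd = noise_sd,
                 water_amplitude = water_amplitude),
            class = c("acquisition_spec", "list"))
}

#' Class-conditional generation profiles
#'
#' Recipes for synthetic class-conditional spectra: per-metabolite mean
#' amplitude and coefficient of variation per TE class, plus a long-TE
#' lactate-inversion flag. The shapes are qualitative — high choline and
#' low NAA for meningioma, dominant mobile lipids for aggressive tumours
#' (glioblastoma/metastasis), moderate NAA and choline for low-grade
#' glial tumours, NAA-dominated normal brain, and mildly reduced NAA with
#' raised myo-inositol for pseudotumoural disease. They exist to exercise
#' the processing and classification machinery, not to claim clinical
#' realism.
#'
#' @param which character vector of profile names to return; default all
#'   of `"meningioma"`, `"aggressive"`, `"lowgrade"`, `"normal"`,
#'   `"pseudotumoural"`.
#' @return named list of `class_profile` objects, each with `name`,
#'   `peaks` (data.frame: metabolite, ppm, linewidth_hz, mean amplitude
#'   per TE class, cv) and `invert_lactate_long`.
#' @export
class_profiles <- function(which = NULL) {
  peak_tbl <- function(naa, cho, cr, mi, lip, lac,
                       naa_l = naa, cho_l = cho, cr_l = cr,
                       mi_l = mi * 0.4, lip_l = lip * 0.35, lac_l = lac) {
    data.frame(
      metabolite = c("NAA", "Cho", "Cr", "mI", "Lip", "Lac"),
      ppm = c(2.01, 3.21, 3.03, 3.55, 1.29, 1.33),
      linewidth_hz = c(4, 3.5, 3.5, 4.5, 9, 5),
      mean_short = c(naa, cho, cr, mi, lip, lac),
      mean_long = c(naa_l, cho_l, cr_l, mi_l, lip_l, lac_l),
      cv = 0.18
    )
  }
  profiles <- list(
    meningioma = list(
      name = "meningioma",
      peaks = peak_tbl(naa = 1.2, cho = 9, cr = 2, mi = 1.5, lip = 2, lac = 1),
      invert_lactate_long = FALSE
    ),
    aggressive = list(
      name = "aggressive",
      peaks = peak_tbl(naa = 1.8, cho = 5.5, cr = 2.2, mi = 1.8, lip = 12,
                       lac = 3),
      invert_lactate_long = TRUE
    ),
    lowgrade = list(
      name = "lowgrade",
      peaks = peak_tbl(naa = 5.5, cho = 4.5, cr = 4.5, mi = 4, lip = 1,
                       lac = 0.8),
      invert_lactate_long = FALSE
    ),
    normal = list(
      name = "normal",
      peaks = peak_tbl(naa = 10, cho = 3, cr = 5.5, mi = 3, lip = 0.5,
                       lac = 0.3),
      invert_lactate_long = FALSE
    ),
    pseudotumoural = list(
      name = "pseudotumoural",
      peaks = peak_tbl(naa = 4.5, cho = 3.5, cr = 4.5, mi = 5.5, lip = 2.5,
                       lac = 1.5),
      invert_lactate_long = TRUE
    )
  )
  profiles <- lapply(profiles, function(p) structure(p, class = "class_profile"))
  if (is.null(which)) return(profiles)
  missing <- setdiff(which, names(profiles))
  if (length(missing))
    .mrsdx_stop(sprintf("unknown profile(s): %s", paste(missing, collapse = ", ")),
                "mrsdx_invalid_argument")
  profiles[which]
}

#' Simulate a class-conditional FID
#'
#' Draws per-metabolite amplitudes from the profile (truncated-normal,
#' `cv` coefficient of variation), builds the FID as a sum of damped
#' complex exponentials at each metabolite's carrier-offset frequency
#' (`f = (4.7 - ppm) * transmitter_mhz` Hz, lorentzian damping
#' `pi * linewidth`), adds a residual water component at 4.7 ppm and
#' complex Gaussian noise, deterministically per seed. At long TE the
#' lactate doublet surrogate is phase-inverted when the profile says so.
#'
#' @param profile a profile from [class_profiles()].
#' @param te_mode `"short"` or `"long"`.
#' @param acq an [acquisition_spec()].
#' @param seed integer seed.
#' @return a [raw_fid()] (TE 30 ms for short, 136 ms for long).
#' @export
simulate_fid <- function(profile, te_mode = c("short", "long"),
                         acq = acquisition_spec(), seed) {
  stopifnot(inherits(profile, "class_profile"))
  te_mode <- match.arg(te_mode)
  if (missing(seed)) .mrsdx_stop("seed is mandatory", "mrsdx_invalid_argument")
  set.seed(as.integer(seed))
  dt <- 1 / acq$sweep_hz
  t <- (0:(acq$n_points - 1L)) * dt
  ft <- acq$transmitter_mhz

  x <- complex(real = rep(0, acq$n_points))
  pk <- profile$peaks
  means <- if (te_mode == "short") pk$mean_short else pk$mean_long
  for (i in seq_len(nrow(pk))) {
    amp <- max(0, rnorm(1L, means[i], means[i] * pk$cv[i]))
    phase <- 0
    if (pk$metabolite[i] == "Lac" && te_mode == "long" &&
        isTRUE(profile$invert_lactate_long)) phase <- pi
    f <- (4.7 - pk$ppm[i]) * ft
    d <- pi * pk$linewidth_hz[i]
    x <- x + amp * exp(complex(imaginary = phase)) * exp((-d + 2i * pi * f) * t)
  }
  # residual water at the carrier (4.7 ppm), broader than metabolites
  if (acq$water_amplitude > 0) {
    wamp <- max(0, rnorm(1L, acq$water_amplitude, acq$water_amplitude * 0.1))
    x <- x + wamp * exp((-pi * 6 + 0i) * t)
  }
  if (acq$noise_sd > 0) {
    x <- x + complex(real = rnorm(acq$n_points, 0, acq$noise_sd),
                     imaginary = rnorm(acq$n_points, 0, acq$noise_sd))
  }
  raw_fid(x, dwell_time = dt, transmitter_frequency = ft,
          te = if (te_mode == "short") 30 else 136, tr = 2000,
          sequence = "PRESS")
}

#' Simulate a labelled dataset of processed spectra
#'
#' Generates `n_per_class` FIDs per profile, runs each through the full
#' automatic pipeline ([process_pipeline()]) and assembles the canonical
#' spectra into a labelled dataset. For `te_mode = "concat"` a short- and
#' a long-TE acquisition are simulated per case and the rows are the
#' concatenated restricted feature vectors ([concat_te()]); otherwise the
#' rows are full 512-point canonical spectra.
#'
#' @param profiles named list from [class_profiles()] (at least 2).
#' @param n_per_class cases per class.
#' @param te_mode `"short"`, `"long"` or `"concat"`.
#' @param seed integer seed; per-case seeds are derived from it.
#' @param acq an [acquisition_spec()].
#' @param params a [processing_params()].
#' @return list of class `labeled_dataset`: `x` (n x p matrix), `labels`,
#'   `te_mode`, `ppm` (shift per column), and `spectra` (list of the
#'   canonical spectra; for concat, list of `list(short, long)` pairs).
#' @export
simulate_dataset <- function(profiles, n_per_class, te_mode = c("short", "long", "concat"),
                             seed, acq = acquisition_spec(),
                             params = processing_params()) {
  te_mode <- match.arg(te_mode)
  if (length(profiles) < 2L && n_per_class > 0L)
    .mrsdx_stop("need at least 2 profiles", "mrsdx_invalid_argument")
  if (missing(seed)) .mrsdx_stop("seed is mandatory", "mrsdx_invalid_argument")
  seed <- as.integer(seed)

  rows <- list()
  labels <- character()
  spectra <- list()
  case <- 0L
  for (ci in seq_along(profiles)) {
    prof <- profiles[[ci]]
    for (r in seq_len(n_per_class)) {
      case <- case + 1L
      base_seed <- (seed + 7919L * ci + 104729L * r) %% .Machine$integer.max
      if (te_mode %in% c("short", "concat")) {
        fs <- simulate_fid(prof, "short", acq, seed = base_seed)
        ss <- process_pipeline(fs, params = params)
      }
      if (te_mode %in% c("long", "concat")) {
        fl <- simulate_fid(prof, "long", acq, seed = base_seed + 1L)
        sl <- process_pipeline(fl, params = params)
      }
      if (te_mode == "short") {
        rows[[case]] <- ss$intensities
        spectra[[case]] <- ss
      } else if (te_mode == "long") {
        rows[[case]] <- sl$intensities
        spectra[[case]] <- sl
      } else {
        v <- concat_te(ss, sl)
        rows[[case]] <- as.numeric(v)
        spectra[[case]] <- list(short = ss, long = sl)
        if (case == 1L) concat_ppm <- attr(v, "ppm")
      }
      labels <- c(labels, prof$name)
    }
  }
  if (case == 0L) {
    p <- if (te_mode == "concat") 2L * length(restrict_indices()) else 512L
    return(structure(list(x = matrix(numeric(), 0L, p), labels = character(),
                          te_mode = te_mode,
                          ppm = if (te_mode == "concat") rep(ppm_axis(512L)[restrict_indices()], 2L)
                          else ppm_axis(512L),
                          spectra = list()),
                     class = "labeled_dataset"))
  }
  x <- do.call(rbind, rows)
  ppm <- if (te_mode == "concat") concat_ppm else ppm_axis(512L)
  structure(list(x = x, labels = labels, te_mode = te_mode, ppm = ppm,
                 spectra = spectra),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d cases x %d columns (%s TE); classes: %s\n",
              nrow(x$x), ncol(x$x), x$te_mode,
              paste(names(table(x$labels)), table(x$labels),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Feature matrix of a labelled dataset
#'
#' Applies the classification restriction (and optional unit
#' normalisation) to every row. Concatenated datasets are already
#' restricted and are returned as stored.
#'
#' @param dataset a `labeled_dataset`.
#' @param range ppm restriction for single-TE datasets.
#' @param normalisation `"unit"` or `"none"`.
#' @return n x p numeric feature matrix.
#' @export
dataset_features <- function(dataset, range = c(0.01, 4.05),
                             normalisation = "unit") {
  stopifnot(inherits(dataset, "labeled_dataset"))
  X <- if (dataset$te_mode == "concat") dataset$x
  else dataset$x[, restrict_indices(range), drop = FALSE]
  if (identical(normalisation, "unit") && nrow(X) > 0L) {
    nrm <- sqrt(rowSums(X^2))
    nrm[nrm == 0] <- 1
    X <- X / nrm
  }
  X
}

#' Displace a canonical spectrum for alignment testing
#'
#' Shifts a base spectrum by `k` grid points ([shift_spectrum()]) and
#' optionally adds fresh Gaussian noise, producing fixtures whose
#' restoration by [align()] can be checked.
#'
#' @param base a [canonical_spectrum()].
#' @param k signed shift in points.
#' @param noise_sd standard deviation of added noise (0 for none).
#' @param seed integer seed, used when `noise_sd > 0`.
#' @return displaced [canonical_spectrum()].
#' @export
displaced_spectrum <- function(base, k, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(base, "canonical_spectrum"))
  out <- shift_spectrum(base, k)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    out$intensities <- out$intensities + rnorm(512L, 0, noise_sd)
  }
  log_stage(out, sprintf("displaced_spectrum(k=%+d)", as.integer(k)))
}
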