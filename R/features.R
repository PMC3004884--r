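#' Restrict a spectrum to the classification feature range
#'
#' Classifier features are taken from the 4.05 to 0.01 ppm band of the
#' canonical grid: the contiguous slice of columns whose chemical shift
#' lies inside the closed interval.
#'
#' @param spectrum a [canonical_spectrum()], or a numeric length-512
#'   vector.
#' @param range ppm interval retained (default `c(0.01, 4.05)`).
#' @return numeric feature vector with attributes `ppm` (shift per
#'   column) and `index` (1-based canonical column indices).
#' @export
restrict_range <- function(spectrum, range = c(0.01, 4.05)) {
  values <- if (inherits(spectrum, "canonical_spectrum"))
    spectrum$intensities else as.numeric(spectrum)
  axis <- ppm_axis(length(values))
  idx <- which(ppm_in_band(axis, range))
  structure(values[idx], ppm = axis[idx], index = idx)
}

# column indices of the restriction on the canonical 512 grid
restrict_indices <- function(range = c(0.01, 4.05)) {
  which(ppm_in_band(ppm_axis(512L), range))
}

#' Concatenate short- and long-TE feature vectors
#'
#' Builds the joint representation used by the concatenated-TE
#' classifiers: the restricted short-TE vector followed by the restricted
#' long-TE vector. Column `i` of the long half maps to the same chemical
#' shift as column `i` of the short half.
#'
#' @param short a [canonical_spectrum()] with `te_class == "short"`.
#' @param long a [canonical_spectrum()] with `te_class == "long"`.
#' @param range ppm restriction applied to each half.
#' @return numeric vector of twice the single-TE feature length, with
#'   attributes `ppm` and `te` (per-column TE class).
#' @export
concat_te <- function(short, long, range = c(0.01, 4.05)) {
  stopifnot(inherits(short, "canonical_spectrum"),
            inherits(long, "canonical_spectrum"))
  if (short$te_class != "short" || long$te_class != "long")
    .mrsdx_stop(sprintf(
      "te_class mismatch: expected short+long, got %s+%s",
      short$te_class, long$te_class), "mrsdx_invalid_argument")
  a <- restrict_range(short, range)
  b <- restrict_range(long, range)
  structure(c(as.numeric(a), as.numeric(b)),
            ppm = c(attr(a, "ppm"), attr(b, "ppm")),
            te = rep(c("short", "long"), c(length(a), length(b))))
}

#' Normalise a feature vector
#'
#' Default normalisation scales the vector to unit Euclidean norm, making
#' classification insensitive to overall acquisition scale; `"none"` is
#' the identity.
#'
#' @param vector numeric feature vector.
#' @param spec `"unit"` or `"none"`.
#' @return normalised numeric vector (attributes preserved).
#' @export
normalize_features <- function(vector, spec = c("unit", "none")) {
  spec <- match.arg(spec)
  if (spec == "none") return(vector)
  nrm <- sqrt(sum(as.numeric(vector)^2))
  if (nrm == 0)
    .mrsdx_stop("cannot unit-normalise the zero vector", "mrsdx_invalid_argument")
  out <- vector / nrm
  attributes(out) <- attributes(vector)
  out
}

#' Peak height with dataset positivity offset
#'
#' Maximum intensity in a window of `halfwidth_pts` points around the
#' grid point nearest `ppm_target`, plus `dataset_offset`. The offset
#' (see [dataset_offset()]) turns every point in the active dataset
#' positive, so downstream height ratios cannot divide by zero or a
#' negative value.
#'
#' @param spectrum a [canonical_spectrum()] or numeric 512-vector.
#' @param ppm_target window centre, ppm.
#' @param halfwidth_pts window half-width, points.
#' @param dataset_offset nonnegative offset added to the height.
#' @return the offset peak height (a.u.).
#' @export
peak_height <- function(spectrum, ppm_target, halfwidth_pts = 5L,
                        dataset_offset = 0) {
  values <- if (inherits(spectrum, "canonical_spectrum"))
    spectrum$intensities else as.numeric(spectrum)
  axis <- ppm_axis(length(values))
  ci <- nearest_ppm_index(axis, ppm_target)
  lo <- ci - halfwidth_pts
  hi <- ci + halfwidth_pts
  if (lo < 1L || hi > length(values))
    .mrsdx_stop("peak window extends beyond the axis", "mrsdx_invalid_argument")
  max(values[lo:hi]) + dataset_offset
}

#' Positivity offset of a dataset
#'
#' The offset that turns all points of all spectra in the active set
#' positive: minus the global minimum when that minimum is negative or
#' zero, else 0. Recompute whenever the active set changes (e.g. a new
#' case is added); a small epsilon keeps the shifted minimum strictly
#' positive.
#'
#' @param spectra list of [canonical_spectrum()] objects (or numeric
#'   vectors), or a numeric matrix with one row per spectrum.
#' @param eps strictly-positive margin added when the minimum is <= 0.
#' @return nonnegative scalar offset.
#' @export
dataset_offset <- function(spectra, eps = 1e-9) {
  vals <- if (is.matrix(spectra)) spectra
  else unlist(lapply(spectra, function(s)
    if (inherits(s, "canonical_spectrum")) s$intensities else as.numeric(s)))
  if (length(vals) == 0L) return(0)
  m <- min(vals)
  if (m > 0) 0 else -m + eps
}

#' Ratio rule definition
#'
#' The two-axis peak-height ratio display: x is choline over N-acetyl
#' aspartate on the short-TE spectrum, y is myo-inositol over N-acetyl
#' aspartate on the long-TE spectrum. The decision boundary is
#' user-configurable piecewise-linear in the (x, y) plane and ships unset.
#'
#' @param x_num,x_den numerator/denominator ppm for the short-TE axis
#'   (defaults Cho 3.21 / NAA 2.01).
#' @param y_num,y_den numerator/denominator ppm for the long-TE axis
#'   (defaults mI 3.55 / NAA 2.01).
#' @param halfwidth_pts peak window half-width, points.
#' @param boundary optional list with `points` (2-column matrix of
#'   boundary vertices ordered by x) and `classes` (labels assigned
#'   above/below the polyline).
#' @return list of class `ratio_rule`.
#' @export
ratio_rule <- function(x_num = 3.21, x_den = 2.01,
                       y_num = 3.55, y_den = 2.01,
                       halfwidth_pts = 5L, boundary = NULL) {
  if (x_num == x_den || y_num == y_den)
    .mrsdx_stop("ratio numerator and denominator must differ",
                "mrsdx_invalid_argument")
  if (!is.null(boundary)) {
    stopifnot(is.matrix(boundary$points), ncol(boundary$points) == 2,
              length(boundary$classes) == 2)
    if (is.unsorted(boundary$points[, 1]))
      .mrsdx_stop("boundary vertices must be ordered by x",
                  "mrsdx_invalid_argument")
  }
  structure(list(x_num = x_num, x_den = x_den, y_num = y_num, y_den = y_den,
                 halfwidth_pts = as.integer(halfwidth_pts),
                 boundary = boundary),
            class = "ratio_rule")
}

#' Classify a case by peak-height ratios
#'
#' Computes the two ratio coordinates of a case (x from the short-TE
#' spectrum, y from the long-TE spectrum) after applying the dataset
#' positivity offset to every height, and assigns a class from the rule's
#' boundary when one is configured (above the piecewise-linear boundary:
#' first class; below: second class).
#'
#' @param short short-TE [canonical_spectrum()].
#' @param long long-TE [canonical_spectrum()].
#' @param rule a [ratio_rule()].
#' @param offset_short,offset_long positivity offsets for each TE's
#'   active dataset (see [dataset_offset()]); defaults computed from the
#'   two spectra alone.
#' @return list with `x`, `y` and `class` (`NA` when no boundary is set).
#' @export
ratio_classify <- function(short, long, rule = ratio_rule(),
                           offset_short = dataset_offset(list(short)),
                           offset_long = dataset_offset(list(long))) {
  stopifnot(inherits(rule, "ratio_rule"))
  hx_num <- peak_height(short, rule$x_num, rule$halfwidth_pts, offset_short)
  hx_den <- peak_height(short, rule$x_den, rule$halfwidth_pts, offset_short)
  hy_num <- peak_height(long, rule$y_num, rule$halfwidth_pts, offset_long)
  hy_den <- peak_height(long, rule$y_den, rule$halfwidth_pts, offset_long)
  if (hx_den <= 0 || hy_den <= 0)
    .mrsdx_stop("non-positive denominator after offset; recompute dataset_offset",
                "mrsdx_computation_error")
  x <- hx_num / hx_den
  y <- hy_num / hy_den
  cls <- NA_character_
  if (!is.null(rule$boundary)) {
    pts <- rule$boundary$points
    yb <- approx(pts[, 1], pts[, 2], xout = x, rule = 2)$y
    cls <- if (y >= yb) rule$boundary$classes[1] else rule$boundary$classes[2]
  }
  list(x = x, y = y, class = cls)
}

#' Manual 2D overview of a dataset
#'
#' Per-case coordinates for a user-chosen 2D display. In `"height"` mode
#' `ppm_a` and `ppm_b` are single chemical shifts and each case maps to
#' its two peak heights. In `"ratio"` mode each of `ppm_a`, `ppm_b` is a
#' `(numerator, denominator)` pair and each case maps to the two height
#' ratios, with the dataset positivity offset applied to every height so
#' denominators are strictly positive.
#'
#' @param spectra list of [canonical_spectrum()] (or numeric 512-vectors).
#' @param ppm_a,ppm_b chemical shift(s) for the x and y features.
#' @param mode `"height"` or `"ratio"`.
#' @param halfwidth_pts peak window half-width, points.
#' @return data.frame with columns `case`, `x`, `y` (zero rows for an
#'   empty dataset).
#' @export
manual_overview <- function(spectra, ppm_a, ppm_b,
                            mode = c("height", "ratio"),
                            halfwidth_pts = 5L) {
  mode <- match.arg(mode)
  if (length(spectra) == 0L)
    return(data.frame(case = integer(), x = numeric(), y = numeric()))
  off <- if (mode == "ratio") dataset_offset(spectra) else 0
  coord <- function(s, p) {
    if (mode == "height") peak_height(s, p[1], halfwidth_pts, 0)
    else peak_height(s, p[1], halfwidth_pts, off) /
      peak_height(s, p[2], halfwidth_pts, off)
  }
  if (mode == "ratio" && (length(ppm_a) != 2L || length(ppm_b) != 2L))
    .mrsdx_stop("ratio mode needs (numerator, denominator) ppm pairs",
                "mrsdx_invalid_argument")
  xs <- vapply(spectra, coord, numeric(1), p = ppm_a)
  ys <- vapply(spectra, coord, numeric(1), p = ppm_b)
  data.frame(case = seq_along(spectra), x = xs, y = ys)
}
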