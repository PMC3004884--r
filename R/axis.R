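#' Canonical chemical-shift axis
#'
#' The canonical processed-spectrum grid spans 7.1 ppm down to -2.7 ppm.
#' The grid is endpoint-inclusive and uniform: the first point sits exactly
#' at `ppm_max`, the last exactly at `ppm_min`, so the step is
#' `(ppm_max - ppm_min) / (n_points - 1)` (9.8/511 ppm for the default
#' 512-point grid). Chemical shift decreases strictly with index, matching
#' the convention that the first stored intensity is the one at 7.1 ppm.
#'
#' @param n_points number of grid points (default 512).
#' @param ppm_max chemical shift of the first point, ppm (default 7.1).
#' @param ppm_min chemical shift of the last point, ppm (default -2.7).
#' @return numeric vector of `n_points` strictly decreasing ppm values.
#' @examples
#' ax <- ppm_axis()
#' c(ax[1], ax[512])   # 7.1, -2.7
#' @export
ppm_axis <- function(n_points = 512L, ppm_max = 7.1, ppm_min = -2.7) {
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < 2)
    .mrsdx_stop("n_points must be a single count >= 2", "mrsdx_invalid_argument")
  seq(ppm_max, ppm_min, length.out = as.integer(n_points))
}

# index (1-based) of the grid point nearest a ppm value
nearest_ppm_index <- function(axis, ppm) {
  which.min(abs(axis - ppm))
}

# logical mask of axis points lying inside [lo, hi]
ppm_in_band <- function(axis, band) {
  lo <- min(band)
  hi <- max(band)
  axis >= lo & axis <= hi
}
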