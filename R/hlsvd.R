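#' Fit damped complex sinusoids to an FID (HLSVD model)
#'
#' Models the time-domain signal as a sum of exponentially damped complex
#' sinusoids ("lorentzians"), the state-space subspace model behind
#' HLSVD-style residual-water removal. The FID is arranged into a Hankel
#' matrix whose row space is spanned by the signal poles; the dominant
#' left singular subspace is estimated (via the eigendecomposition of the
#' Hermitian product, equivalent to a truncated SVD), the poles are
#' recovered from its shift-invariance (least-squares solution of the
#' rotated-subspace equation, then eigenvalues), and complex amplitudes
#' follow by linear least squares against the pole basis.
#'
#' @param fid a [raw_fid()] with at least `4 * k` samples.
#' @param k model order: maximum number of damped sinusoids (default 10).
#' @param hankel_rows number of Hankel rows; default half the signal
#'   length, capped at 256.
#' @return a data.frame with one row per component and columns
#'   `amplitude` (a.u.), `phase` (radians), `frequency` (Hz, carrier
#'   offset), `damping` (1/s; positive means decaying).
#' @seealso [water_filter()], [reconstruct_fid()]
#' @export
hlsvd_fit <- function(fid, k = 10L, hankel_rows = NULL) {
  stopifnot(inherits(fid, "raw_fid"))
  x <- fid$samples
  n <- length(x)
  k <- as.integer(k)
  if (k < 1L) .mrsdx_stop("k must be >= 1", "mrsdx_invalid_argument")
  if (n < 4L * k)
    .mrsdx_stop(sprintf("FID too short for k=%d: need >= %d samples, have %d",
                        k, 4L * k, n), "mrsdx_invalid_argument")
  dt <- fid$dwell_time

  if (sum(Mod(x)^2) < 1e-300) {
    return(data.frame(amplitude = numeric(), phase = numeric(),
                      frequency = numeric(), damping = numeric()))
  }

  L <- if (is.null(hankel_rows)) min(n %/% 2L, 256L) else as.integer(hankel_rows)
  L <- max(L, k + 1L)
  m <- n - L + 1L

  # Hankel matrix H[i, j] = x[i + j - 1], L x m
  H <- matrix(x[outer(seq_len(L), seq_len(m) - 1L, `+`)], nrow = L)

  # dominant left singular subspace via the L x L Hermitian product
  G <- H %*% Conj(t(H))
  eg <- eigen(G, symmetric = TRUE)
  U <- eg$vectors[, seq_len(k), drop = FALSE]

  # shift invariance: U[-L, ] %*% E ~= U[-1, ]; poles are eigenvalues of E
  Ut <- U[-L, , drop = FALSE]
  Ub <- U[-1L, , drop = FALSE]
  A <- Conj(t(Ut)) %*% Ut
  B <- Conj(t(Ut)) %*% Ub
  E <- solve(A, B)
  z <- eigen(E, only.values = TRUE)$values

  # drop numerically dead poles
  z <- z[Mod(z) > 1e-12]
  if (length(z) == 0L) {
    return(data.frame(amplitude = numeric(), phase = numeric(),
                      frequency = numeric(), damping = numeric()))
  }

  freq <- Arg(z) / (2 * pi * dt)
  damping <- -log(Mod(z)) / dt

  # complex amplitudes by least squares on the full signal
  V <- exp(outer(0:(n - 1L), log(z)))   # n x k basis z^t
  VhV <- Conj(t(V)) %*% V
  Vhx <- Conj(t(V)) %*% x
  a <- tryCatch(solve(VhV, Vhx), error = function(e) {
    # degenerate basis (coincident poles): ridge fallback
    solve(VhV + diag(1e-10 * max(Mod(diag(VhV))), nrow(VhV)), Vhx)
  })
  a <- as.complex(a)

  res <- data.frame(
    amplitude = Mod(a),
    phase = Arg(a),
    frequency = freq,
    damping = damping
  )
  res[order(res$amplitude, decreasing = TRUE), , drop = FALSE]
}

#' Reconstruct a time-domain signal from fitted components
#'
#' @param components data.frame as returned by [hlsvd_fit()].
#' @param n number of samples.
#' @param dwell_time sampling interval, s.
#' @return complex vector of length `n`.
#' @export
reconstruct_fid <- function(components, n, dwell_time) {
  t <- (0:(n - 1L)) * dwell_time
  out <- complex(real = rep(0, n))
  for (i in seq_len(nrow(components))) {
    out <- out + components$amplitude[i] *
      exp(complex(imaginary = components$phase[i])) *
      exp((-components$damping[i] + 2i * pi * components$frequency[i]) * t)
  }
  out
}

#' Remove the residual water signal from an FID
#'
#' Fits the HLSVD model ([hlsvd_fit()]) and subtracts, in the time domain,
#' every component whose chemical shift falls inside the water band.
#' Frequencies map to ppm through the carrier convention used throughout
#' the package: the transmitter sits on water, so 0 Hz offset is 4.7 ppm
#' and `ppm = 4.7 - f / transmitter_frequency`.
#'
#' @param fid a [raw_fid()].
#' @param params a [processing_params()] list; uses `hlsvd_components`
#'   and `water_band`.
#' @return the filtered [raw_fid()].
#' @export
water_filter <- function(fid, params = processing_params()) {
  stopifnot(inherits(fid, "raw_fid"))
  comps <- hlsvd_fit(fid, k = params$hlsvd_components)
  if (nrow(comps) == 0L) return(fid)
  ppm <- 4.7 - comps$frequency / fid$transmitter_frequency
  in_water <- ppm >= min(params$water_band) & ppm <= max(params$water_band)
  if (!any(in_water)) return(fid)
  water <- reconstruct_fid(comps[in_water, , drop = FALSE],
                           length(fid$samples), fid$dwell_time)
  fid$samples <- fid$samples - water
  fid
}
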