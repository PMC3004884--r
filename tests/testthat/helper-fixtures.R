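# shared fixture builders; everything is generated in code at test time

canonical_axis <- ppm_axis(512L)

# lorentzian-shaped bump on the canonical grid, centred at the grid point
# nearest `center_ppm`
lorentzian_bump <- function(center_ppm, height = 100, width_pts = 2) {
  ci <- which.min(abs(canonical_axis - center_ppm))
  height / (1 + ((seq_len(512L) - ci) / width_pts)^2)
}

# creatine-dominated canonical spectrum with low fixed-seed noise
creatine_spectrum <- function(noise_sd = 0.5, seed = 1L) {
  set.seed(seed)
  canonical_spectrum(lorentzian_bump(3.03) + rnorm(512L, 0, noise_sd))
}

# damped complex exponential FID at a given ppm position
exp_fid <- function(ppm = 4.7, amplitude = 1, damping = 10, phase = 0,
                    n = 2048L, sweep = 2500, ft = 63.87, te = 30,
                    water_ref = FALSE) {
  dt <- 1 / sweep
  t <- (0:(n - 1L)) * dt
  f <- (4.7 - ppm) * ft
  raw_fid(amplitude * exp(complex(imaginary = phase)) *
            exp((-damping + 2i * pi * f) * t),
          dwell_time = dt, transmitter_frequency = ft, te = te,
          is_water_reference = water_ref)
}

# memoised heavy fixtures, built once per test run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# the three-superclass study dataset: 60 cases per class, short TE, seed 20
study_dataset <- function() {
  cached("study_dataset", function() {
    simulate_dataset(class_profiles(c("meningioma", "aggressive", "lowgrade")),
                     n_per_class = 60L, te_mode = "short", seed = 20L)
  })
}

# separable 2D gaussian toy set in feature space
toy_gaussians <- function(n_per_class = 10L, p = 4L, sep = 6, sd = 1,
                          seed = 5L, classes = c("a", "b", "c")) {
  set.seed(seed)
  centers <- diag(sep, length(classes), p)
  x <- do.call(rbind, lapply(seq_along(classes), function(i)
    matrix(rnorm(n_per_class * p, 0, sd), n_per_class, p) +
      matrix(centers[i, ], n_per_class, p, byrow = TRUE)))
  list(x = x, labels = rep(classes, each = n_per_class))
}
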