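Package: mrsdx
Title: Single-Voxel MRS Processing, Quality Control and Brain-Mass
    Classification
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Processing and classification toolkit for in-vivo single-voxel
    proton magnetic resonance spectroscopy (1H-MRS) of brain masses.
    Converts time-domain free induction decays to a canonical 512-point
    spectrum on a fixed 7.1 to -2.7 ppm grid via HLSVD-based residual-water
    removal, exponential apodization, Fourier transformation, zero-order
    phasing, baseline-offset correction, linear resampling and automatic
    peak alignment on creatine, choline or lipid references. Provides
    acquisition quality control (spectral signal-to-noise ratio and
    unsuppressed-water linewidth), Fisher linear discriminant classifiers
    with sequential forward feature selection and bootstrap out-of-bag
    evaluation, a peak-height ratio rule, explicit 2D decision boundaries,
    a portable text-backed case database with per-user edit permissions,
    synthetic class-conditional spectrum generation, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
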