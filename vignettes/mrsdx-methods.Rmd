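---
title: "Methods: spectral processing and discriminant classification in mrsdx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral processing and discriminant classification in mrsdx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsdx)
```

This vignette is the package's own account of the science it
implements: the signal model behind each processing stage, the
classification machinery, the parameters that matter, the numerical
choices made where the design was genuinely open, and what the
synthetic-data validation does and does not establish.

## The canonical spectrum

All downstream analysis operates on a fixed exchange format: 512 real
intensities on a uniform chemical-shift grid from 7.1 ppm down to
−2.7 ppm, the first stored value being the intensity at 7.1 ppm. The
grid is *endpoint-inclusive*: both 7.1 and −2.7 ppm are grid points, so
the step is 9.8/511 ≈ 0.0192 ppm. An endpoint-inclusive convention is a
deliberate choice — it honours both stated endpoints exactly with no
dangling half-bin — and the grid helper (`ppm_axis()`) is parameterised
so a half-open variant could be produced if ever needed. Because
scanner formats differ in points-per-ppm, arbitrary source grids are
brought onto this one by piecewise-linear interpolation
(`resample_linear()`), which is exact for locally affine spectra;
target points outside the source coverage are set to zero rather than
extrapolated, consistent with the zero-padding used by the alignment
shift.

The on-disk form is one line of space-separated reals written with 7
significant digits ("single precision" in spirit: write/read roundtrips
are exact to about 1e−7 relative). Readers accept any whitespace.

## The time-domain signal model

A free induction decay (FID) is modelled throughout as a sum of
exponentially damped complex sinusoids,

$$x(t) = \sum_k a_k e^{i\varphi_k} e^{(-d_k + 2\pi i f_k)t} + \varepsilon(t),$$

whose Fourier transform is a sum of lorentzian lines of FWHM
$d_k/\pi$ Hz. Frequencies map to chemical shift through the water-carrier
convention: the transmitter sits on water, so 0 Hz offset is 4.7 ppm and
$\mathrm{ppm} = 4.7 - f/f_T$ with $f_T$ the transmitter frequency in
MHz. This convention is the standard one for in-vivo proton MRS at
1.5 T and is what makes the Hz↔ppm conversions in water filtering and
alignment well defined.

### Residual-water removal (HLSVD subspace fit)

Water suppression at acquisition leaves a residual water signal one to
two orders of magnitude above the metabolites. The package fits the
damped-sinusoid model by the classical Hankel subspace route: the FID
fills a Hankel matrix (rows = half the signal length, capped at 256),
whose dominant left singular subspace is estimated from the
eigendecomposition of the Hermitian product $HH^{\mathsf H}$ —
algebraically a truncated SVD, at a fraction of the cost, and adequate
because the retained components sit far above the numerical noise
floor. Signal poles come from the shift-invariance of that subspace
(least-squares rotation, then eigenvalues), amplitudes and phases from
a final linear least squares against the pole basis. The default model
order is **10 components**; components whose chemical shift falls in
the **4.33–5.07 ppm** water band (±0.37 ppm around 4.7; the band is a
documented, configurable choice) are reconstructed and subtracted in
the time domain, leaving metabolite-band components untouched. On
noiseless sums of up to 10 damped exponentials the fit reconstructs the
signal below 1e−6 relative energy; a 100:1 water-to-metabolite fixture
retains under 5% water-band energy after filtering — both are asserted
in the test suite.

### Apodization, transform, phasing, baseline

Line broadening multiplies sample $i$ by $e^{-\pi\,\mathrm{lb}\,t_i}$,
which adds exactly `lb` Hz to every lorentzian linewidth; the default
is **1 Hz**. The operation is an exponential semigroup
(`lb1` then `lb2` equals `lb1+lb2`), which the tests use as an
invariant. The DFT is unitary (energies preserved) and the frequency
axis is reordered to strictly decreasing ppm.

Zero-order phasing picks the constant phase maximising the integral of
the real part over the metabolite band 0.5–4.2 ppm. That objective has
a closed form: the band integral of $\mathrm{Re}(e^{i\varphi}S)$ is
$|\Sigma|\cos(\varphi + \arg\Sigma)$ with $\Sigma$ the band sum, so the
maximiser is exactly $\varphi = -\arg\Sigma$. The implementation uses
this analytic solution rather than a 1-D search — same criterion, no
iteration, no tolerance. First-order (frequency-dependent) phasing is
deliberately out of scope; acquisitions needing it are the domain of
manual processing.

The baseline offset is the mean intensity over two regions flanking the
water peak, **−2…−1 ppm and 9…11 ppm**, subtracted everywhere. On the
full acquisition axis (a 2500 Hz sweep at 63.87 MHz spans ≈ 39 ppm)
both regions exist; on the canonical axis, which ends at 7.1 ppm, the
upfield region is empty and only the in-range points are used. It is an
error only when *no* baseline point is in range. The correction is
idempotent and translation-equivariant, both asserted as properties.

### Automatic alignment

Small frequency-referencing errors shift the whole spectrum by a few
grid points; alignment undoes this by integer shifts. The algorithm:
locate the tallest peak (TP) in 0–4.5 ppm; try **creatine (3.03 ppm),
choline (3.21 ppm), lipid (1.29 ppm)** in that order; accept the first
candidate that (a) has a *strict* local maximum — strictly greater than
both contiguous neighbours — within ±5 points of its nominal position,
and (b) passes the SNR gate; shift the spectrum by whole points
(zero-fill one end, trim the other, length conserved) so the found peak
lands on the grid point nearest its nominal ppm. If every candidate
fails, the spectrum is left unchanged and the report says so.

Two readings of the SNR gate are possible from its terse statement; read
literally as "candidate SNR must be at least five *times* the TP's SNR"
it would reject essentially every candidate (no peak can beat the
tallest peak fivefold), so the package implements the only reading
under which the procedure can terminate at a non-TP reference:
**accept when SNR(candidate) ≥ SNR(TP)/5**. The factor (`tp_ratio`) is
configurable. SNR itself is peak height divided by the standard
deviation of the 9–11 ppm noise region, falling back to
−2.7…−1.7 ppm when only the canonical axis exists (no exact formula is
canonical here; this definition is documented and scale-invariant).
Equal-height peaks in a window tie-break to the smaller index (higher
ppm), the positive shift direction moves features toward lower ppm, and
alignment is idempotent — all covered by tests.

The pipeline order is fixed: water filter → apodize → transform →
phase → baseline → interpolate → align, and the provenance log of every
canonical spectrum records each stage with its parameters.

## Quality control

Two acceptance checks gate every case: spectral **SNR > 10** and
unsuppressed-water **linewidth < 8 Hz**. The linewidth estimator
zero-fills the water FID (factor 8), takes the magnitude spectrum —
insensitive to phase, which is why it was chosen — and interpolates the
two half-height crossings linearly. Because the magnitude of a
lorentzian is exactly $\sqrt 3$ wider at half height than its
absorption shape, the measured width is rescaled by $1/\sqrt 3$, so the
reported number is the conventional absorption-mode FWHM ($d/\pi$ for
damping $d$); the estimator is within 2% of that closed form across
5–30 Hz lines. A line at the acquisition's resolution limit (an
essentially undamped signal measuring the truncation window instead)
is flagged `NA` with a warning, not reported as a small number. Without
a water acquisition the verdict rests on SNR alone — mirroring older
cases for which no unsuppressed water file exists.

## Classification

### Features

Classifier features are canonical intensities restricted to
**4.05–0.01 ppm** — the metabolite region, excluding residual water and
empty baseline. On the endpoint-inclusive grid this slice holds 210
columns (0-based indices 160–369; the count follows from the grid
convention and is asserted by brute force in the tests). Concatenated
short+long TE vectors put the short half first, and column *i* of each
half maps to the same ppm. Rows are scaled to unit Euclidean norm by
default: overall signal scale is acquisition-dependent and carries no
class information; `"none"` is available since raw-intensity training
is also defensible.

### Sequential forward selection

The number of informative spectral points is far below 210 and
neighbouring columns are highly collinear, so a greedy wrapper
selection is used: at each step add the candidate column that maximises
the criterion — the training accuracy of a Fisher LDA refit on the
candidate set (ties to the lower index) — skipping candidates whose
absolute Pearson correlation with any selected column exceeds **0.8**
(the correlation-based validation; near-duplicate grid points never
enter twice). Selection stops at the cap (**13** features by default,
the classical classifier size), when no admissible candidate remains,
or when no candidate improves the criterion. On well-separated
synthetic data the criterion often saturates at 1.0 after very few
features and selection stops early; that is the intended behaviour of
the improvement rule, not a truncation.

### Fisher LDA and its geometry

With selected features $X$, the fit solves the generalized eigenproblem
$S_b w = \lambda S_w w$ (between- vs within-class scatter) and keeps
the top two directions as the 2D latent space — at most
$(\text{classes}-1)$ axes are non-degenerate, so with two classes the
second axis is the zero-eigenvalue complement kept for plotting. $S_w$
is regularised by a trace-scaled ridge ($\lambda = 10^{-6}\,
\mathrm{tr}(S_w)/d$) so $p>n$ slices remain solvable. The
implementation's eigen route is cross-checked in the tests against an
independent symmetric-whitening solver ($S_w^{-1/2}S_bS_w^{-1/2}$) and
against `MASS::lda` directions, to 1e−8 projection correlation.

Prediction assigns the nearest 2D class mean (ties to the
first-declared class). This choice makes the "true" decision boundaries
exactly computable: they are the perpendicular bisectors of the latent
means, and the class regions are convex polygons (half-plane
intersections clipped to the plot rectangle, Sutherland–Hodgman). Under
equal priors and a shared isotropic latent covariance the nearest-mean
rule coincides with the Fisher discriminant rule, which is why the
bisector geometry and the "true LDA boundary" description agree here.
The region polygons are validated against nearest-mean prediction on
10,000 random latent points via an independent point-in-polygon route.

### Bootstrap evaluation

Accuracy is estimated by the bootstrap: B resamples drawn *with
replacement, stratified by class* (so no class can vanish — the redraw
path for a degenerate resample exists but cannot trigger under
stratification), the **full training procedure including feature
selection** refit on each resample, and accuracy measured on the
out-of-bag rows. Reported: mean OOB accuracy, the 2.5–97.5 percentile
interval, and the aggregated OOB confusion matrix. B defaults to 200
and the seed is mandatory, making every evaluation exactly
reproducible.

### The peak-ratio rule and manual overviews

The two-axis ratio display plots Cho/NAA height ratios at short TE
against mI/NAA at long TE. Peak heights are window maxima (±5 points)
plus the *dataset positivity offset*: minus the global minimum over all
spectra in the active set (recomputed whenever the set changes), which
guarantees strictly positive denominators even for long-TE spectra with
strongly inverted lactate. The mI position is not universal across
hardware and processing chains; the default is **3.55 ppm**,
configurable in the rule, as is NAA (2.01 ppm). No decision boundary
ships by default — published thresholds belong to their source
datasets — so the rule returns coordinates, and a user-configured
piecewise-linear boundary turns them into classes. Manual overviews
generalise the same mechanics to user-chosen ppm features (heights, or
ratio pairs with the offset rule).

## The case store

Persistence is a directory of human-readable JSON documents — one per
case, plus users, registered classifiers and per-classifier (x, y)
coordinates — rather than an embedded SQL engine: the relational
semantics (unique ids, one coordinate row per case×classifier,
uploader ownership) are enforced as invariants, and the store is
portable and diffable. Doubles are serialised with 17 significant
digits, so reloaded coordinates and model projections are bit-identical
to the originals. The permission model: any registered user sees every
case; only the uploader may edit a case's fields, except that
administrators may edit anything (the natural reading of administration
rights, made configurable in spirit by the admin flag) and *any* user
may append shared case notes. Case sets are `reference`, `secondary`,
`example` and `user`; the user set is empty on a fresh installation.

## The synthetic generator

`class_profiles()` defines qualitative per-superclass recipes over six
resonances (NAA 2.01, Cho 3.21, Cr 3.03, mI 3.55, lipids 1.29,
lactate 1.33 ppm): meningioma with high choline and low NAA; aggressive
tumours dominated by mobile lipids with inverted long-TE lactate;
low-grade glial with moderate NAA/Cho; NAA-dominated normal brain;
pseudotumoural with reduced NAA and raised mI. Amplitudes are truncated
normals with an 18% coefficient of variation; long TE attenuates mI and
lipids. The acquisition default is 2048 complex points over a 2500 Hz
sweep at 63.87 MHz (1.5 T proton), residual water amplitude 40 (about
4–30× the metabolites) and complex noise s.d. 0.08. These numbers are
invented, documented fixture parameters chosen once to look like the
qualitative MRS literature; they make no claim of clinical realism.

What passing tests therefore show: the *machinery* — water removal,
phasing, alignment, feature selection, discriminant geometry, bootstrap
accounting — behaves correctly on signals with the right mathematical
structure. What they cannot show: performance on real patient spectra,
whose baselines, macromolecule humps, J-coupled multiplets, eddy-current
distortions and class overlap the generator does not emulate. The
synthetic three-superclass study (60 cases per class, short TE, fixed
seed; bootstrap B = 200) is required to reach OOB accuracy ≥ 0.85 with
a shuffled-label null at chance (1/3 ± 0.05) — a sanity band
establishing that the pipeline separates separable classes and does not
hallucinate signal, *not* a reproduction of any clinical accuracy
figure, which would require the original clinical datasets.

## Numerical choices and problem sizes

- Hankel rows capped at 256; subspace via Hermitian eigendecomposition;
  ridge fallback (1e−10, trace-scaled) for coincident poles in the
  amplitude solve.
- Golden rule for degenerate inputs: total functions where the contract
  demands it (phasing of pure noise, alignment of a flat spectrum) and
  classed errors elsewhere (`mrsdx_invalid_argument`,
  `mrsdx_format_error`, `mrsdx_permission_error`, ...), so callers can
  discriminate failure modes.
- Alignment tie-breaks, the shift sign convention and the ±5-point
  window are all explicit parameters with documented defaults.
- The test suite scales stochastic property checks to desk-size
  problems chosen as representative rather than exhaustive: 200
  canonical roundtrips, 100-seed SNR Monte-Carlo, 20-seed class-ordering
  checks, the 180-case study set, 10,000-point geometry audits.

## Known limitations

- First-order phasing, eddy-current correction and frequency-domain
  water removal are out of scope by design.
- Vendor binary formats are not read; the jMRUI-style text dialect and
  the canonical format are the interchange boundary.
- The SFS criterion (training accuracy) is the simplest faithful
  wrapper criterion; cross-validated criteria would cost more and may
  select differently on noisy data.
- Nearest-mean classification in 2D discards discriminant axes beyond
  the second; with many classes of comparable separation this loses
  information relative to full-rank LDA.
- The ratio rule ships without a decision boundary; it is a display and
  a hook for locally calibrated thresholds, not a turnkey classifier.
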