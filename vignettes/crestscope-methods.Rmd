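---
title: "Quantifying T-tubule regularity and surface-crest morphometry with crestscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying T-tubule regularity and surface-crest morphometry with crestscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crestscope)
```

## The measurement model

In a longitudinally oriented cardiomyocyte, a T-tubule marker stains a
striation whose period is the sarcomere length, ~1.8–2.2 µm. `crestscope`
turns one image into two numbers:

* **TT power** — how much spectral power is concentrated at the sarcomeric
  spatial frequency; the regularity index.
* **TT frequency** — where that concentration sits, in cycles/µm; the
  periodicity (≈ 1 / sarcomere length, so ~0.5 µm⁻¹).

The pipeline is: align the long axis horizontally (`rotate_image()`,
bilinear, mean fill), crop a fixed 500 × 35 px window (`extract_roi()`;
50 µm × 3.5 µm at the default 0.1 µm/pixel sampling), compute
\(P_{2D} = |\mathrm{FFT}_{2D}|^2 / N\) (`power_spectrum_2d()`, N = pixel
count, mean-detrended by default), extract the zero-vertical-frequency row
(`central_profile()`), and fit
\(A\,e^{-(f-\mu)^2/(2\sigma^2)} + b\) on the band 0.45–0.7 µm⁻¹
(`fit_tt_peak()`), reporting \(A\) as TT power and \(\mu\) as TT
frequency.

### Why a band, and why a baseline

The 0.45–0.7 µm⁻¹ band brackets the physiological sarcomere spacing
(1.43–2.22 µm): fitting only inside it makes the estimate immune to the
large low-frequency background that any tissue image carries. Power
spectra also carry broadband background *inside* the band, so the model
includes a constant offset \(b \ge 0\); the plain-Gaussian fit (\(b\)
frozen at 0) remains available via `baseline = FALSE`.

### Numerical choices in the fit

* **Bounded least squares** (Levenberg–Marquardt): \(A \ge 0\),
  \(b \ge 0\), \(\mu\) constrained to the band.
* **Deterministic initialization**: \(\mu_0\) at the in-band argmax,
  \(A_0 = \max - \min\), \(b_0 = \min\), \(\sigma_0 = 2\) frequency bins.
  No RNG enters the fit.
* **σ is bounded below by one frequency bin** (1/(W·pixel size) =
  0.02 µm⁻¹ for the default window). A spectral peak narrower than the bin
  spacing is unresolvable on the sampled axis; if σ were allowed to shrink
  further, the amplitude could sharpen arbitrarily between samples and
  stop being comparable across images. The finite 50 µm window itself
  imposes a linewidth of this order.
* **`fit_ok` gating**: a result is flagged unreliable unless the fit
  converged, \(A \ge 3\times\) the in-band residual SD (`snr_threshold`),
  and \(A\) reaches at least 1 % of the largest non-DC bin of the profile
  (`min_rel_amplitude`). The last floor matters for degenerate inputs: if
  the striation frequency lies outside the band, the in-band bins are all
  ≈ 0 and a noise-level "peak" would otherwise pass the SNR ratio
  vacuously. Failures are flagged, never raised.
* **Detrending** is mean subtraction only; no apodization window is
  applied by default, keeping the closed-form spectral oracles exact.
  Power is reported on a linear scale.
* The "middle horizontal line" of an even-height centered spectrum is
  defined as the row at index `height %/% 2 + 1` — the unique row with
  exactly zero vertical frequency.

## The synthetic striation generator

`simulate_striation_image()` emulates the confocal acquisition the
pipeline targets: 0.1 µm/pixel sampling, stripe period defaulting to
1.9 µm, a cosine intensity profile
\(\textrm{mean} + \textrm{amplitude}\cdot\cos(2\pi u/T)\) along the
rotated coordinate, Gaussian PSF blur (default σ = 0.1 µm, the scale of a
high-NA confocal point-spread function), and additive Gaussian noise. The
cosine profile is deliberate: its DFT is closed-form, which gives the test
suite exact oracles (a unit-amplitude cosine with 25 cycles across a
500 × 35 window puts exactly \(a^2WH/4 = 4375\) in the (0, 0.5 µm⁻¹)
bin). A `gaussian_line` profile is available for narrow-line stainings.

Two disorder mechanisms degrade regularity the way immature or diseased
tissue does:

* **per-stripe positional jitter** (`phase_jitter_sd_um`) — each stripe is
  rigidly displaced by a Gaussian offset, mimicking Z-line misalignment
  (not per-pixel speckle);
* **stripe dropout** (`dropout_prob`) — whole stripes are erased,
  mimicking local loss of the T-tubule network.

Both reduce the coherent in-band power monotonically while leaving the
underlying period untouched — exactly the dissociation the TT power /
TT frequency pair is designed to resolve. What the generator does *not*
emulate: curved or branching cells, intensity gradients, multi-cell
fields, anisotropic PSFs, detector artifacts. Tests passing on these
images validate the computation, not performance on real tissue.

Images are kept in floating point; quantization happens only at TIFF
export with an explicit scale recorded in a sidecar JSON.

## The morphometry model

`simulate_morphometry()` emulates a TEM surface-crest campaign with the
standard nested design — groups → animals → cells → structures — at the
common scale of 6 animals/group, 4–8 cells/animal and ~70 crests/animal
(12 crests in each of 4–8 cells). For every metric an animal-level random
effect is drawn first, then per-structure noise, so measurements within an
animal are correlated and the animal is the honest unit of analysis;
`summarize_morphometry()` exposes the choice (`nesting = "animal"` is the
default, `"cell"` and `"structure"` are available because published
figures often plot per-structure points).

Crest height is analyzed as the ratio to the sarcomere length measured on
the first myofibril layer below the crest (`normalized_crest_height()`,
`crest_ratios()`): the ratio cancels the unknown contraction state of the
fixed tissue. The lateral interspace follows the five-measurements-per-site
protocol; interspaces are stored in nm, crest/sarcomere lengths in µm and
SSM areas in µm², fixed in the schema to prevent silent unit mixing.

No per-group numeric means for these metrics are available in text form
from the biological literature this design mirrors, so the generator's
default magnitudes are **synthetic**, chosen once at biologically
plausible scales; only their *directions* across the default P20/P60
groups encode the known maturation pattern (crest ratio, SSM count, SSM
area and sarcomere height increase; interspace decreases; sarcomere length
and myofibril count unchanged). Continuous draws are floored at 1 % of the
group mean to keep measurements positive (≲0.4 % of draws at the default
scales, a negligible mean bias); counts are rounded, with myofibril counts
floored at 1.

## The statistical battery

`shapiro_wilk()`, `t_unpaired()` (pooled-variance Student by default —
`welch = TRUE` for the unequal-variance form), `anova_tukey()` (one-way,
or two-way with interaction when a second factor is given; Tukey HSD over
the factor levels or over the A:B cell means, recorded in
`pairwise_over`), `fisher_exact()` (two-sided, by hypergeometric
enumeration) and `logrank_test()` (two groups, chi-square with 1 df, plus
Kaplan–Meier curves). All tests are two-sided and RNG-free. The wrappers
delegate to the reference implementations in base R and `survival`; the
test suite cross-checks them against independent hand-built oracles
(pooled-variance formula, exhaustive 2×2 enumeration, per-event-time
O−E/variance accumulation) and calibrates type-I error by simulation.
One calibration fact worth knowing: the log-rank chi-square approximation
is mildly liberal (empirical size ≈ 0.054 at n = 30–100/group under an
exponential null), a property of the test, not of the wrapper.

## The packaged demo

`run_demo()` simulates two cohorts sharing the 1.9 µm period: "P20-like"
(jitter SD 0.25 µm, dropout 0.15) and "P60-like" (jitter SD 0.05 µm,
dropout 0.02), both with noise SD 4 on an amplitude-30 signal, 8 images
per cohort at 560 × 80 px. It runs the full pipeline per image and
compares cohorts with the unpaired t test. The expected outcome — higher
TT power at unchanged TT frequency in the low-jitter cohort — is a
property of the synthetic generator, illustrating the dissociation the
method measures; it is not a reproduction of any biological dataset.
All randomness flows from the single `seed` argument, and the report
records it.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run on desk-scale problems
chosen to keep the whole suite in the low minutes: 560–1024 px synthetic
images, 20 seeds per condition for the jitter-monotonicity check, 5,000
replicates for t-test calibration and 10,000–20,000 for log-rank (the
larger count keeps Monte-Carlo noise small relative to the ±0.01
calibration band), and the full 6-animal morphometry design. Every
simulation is seeded; `scripts/acceptance.R` derives all of its RNG from
the single `--seed` flag.

## Known limitations

* The ROI must fit entirely inside the rotated image; no padding is
  invented at the borders (overhangs raise a bounds error naming the
  overhang).
* `estimate_long_axis_angle()` assumes a single dominant orientation; it
  flags (rather than guesses) white-noise-like inputs, and its ±1°
  accuracy relies on the power-weighted centroid refinement around the
  spectral peak, which needs images a few hundred pixels across.
* TT power is a windowed, band-limited quantity: values are comparable
  only across images analyzed with the same ROI size, pixel size, band
  and detrending choices.
* No mixed-effects modeling: the battery mirrors the conventional
  analysis; the nested generator would support hierarchical models, but
  they are out of scope.
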