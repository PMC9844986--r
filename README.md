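# crestscope

Spectral quantification of transverse-tubule (T-tubule, TT) regularity in
striated cardiac tissue images, with a companion data model for
electron-microscopy surface-crest morphometry and the statistical battery
used alongside such measurements.

## The problem and the method

The T-tubule network of a healthy adult cardiomyocyte is anchored at the
sarcomere Z-lines, so a confocal image of a TT marker (e.g. caveolin-3)
shows a striation with a spatial period equal to the sarcomere length
(~1.8–2.2 µm). How *regular* that striation is — how sharply the pattern
repeats — is a sensitive index of cardiomyocyte maturity and health.

`crestscope` quantifies it the standard way:

1. rotate the image so the cell long axis is horizontal, and crop a fixed
   **500 × 35 px** region of interest (50 µm × 3.5 µm at 0.1 µm/pixel);
2. compute the normalized 2D FFT power spectrum
   **P₂D = |FFT₂D|² / N**, with N the total pixel count;
3. take the middle horizontal line (the zero-vertical-frequency row) as a
   1D profile P₁D over horizontal spatial frequency (µm⁻¹);
4. fit a Gaussian `A·exp(−(f−μ)²/(2σ²)) + b` to the peak inside the
   sarcomeric band **0.45–0.7 µm⁻¹**.

The fitted amplitude **A** is the *TT power* (regularity index) and the
fitted center **μ** is the *TT frequency* (periodicity; ~0.5 µm⁻¹ for a
~2 µm sarcomere spacing).

The package also ships:

- seeded synthetic generators for striation images
  (`simulate_striation_image()`: contrast, per-stripe positional jitter,
  stripe dropout, PSF blur, noise) and for nested TEM morphometry tables
  (`simulate_morphometry()`: crest heights, sarcomere lengths, SSM counts
  and areas, lateral interspace, myofibril counts, with animal-level
  random effects);
- morphometry aggregation at the structure / cell / animal nesting level,
  crest-height normalization by sarcomere length, table validation, and
  CSV round-trip;
- the statistical battery: Shapiro–Wilk, unpaired Student *t*, one- and
  two-way ANOVA with Tukey HSD, Fisher exact, log-rank with Kaplan–Meier
  curves.

## Worked example

```r
library(crestscope)

img <- simulate_striation_image(striation_params(
  width_px = 600, height_px = 128, period_um = 2.0,
  phase_jitter_sd_um = 0, noise_sd = 0, blur_sigma_um = 0, seed = 1
))
roi <- extract_roi(img, roi_spec(center_xy = c(300, 64)))
fit <- fit_tt_peak(central_profile(power_spectrum_2d(roi)))
fit
#> Band-limited Gaussian T-tubule peak fit
#>   band: 0.45-0.70 um^-1
#>   TT power (amplitude A): 2.6241e+06
#>   TT frequency (center mu): 0.4997 um^-1 (period 2.001 um)
#>   sigma: 0.02 um^-1, baseline: 4.268e-26
```

The peak sits at 0.50 µm⁻¹ — the 2.0 µm stripe period — and the
amplitude is the spectral power concentrated there. Degrading the
striation raises nothing but lowers TT power:

```r
d <- run_demo(seed = 1)
d
#> Synthetic two-cohort T-tubule regularity demo
#>   seed 1, 8 images/cohort, shared period 1.90 um
#>   P20_like: mean TT power 690594.0, mean TT frequency 0.5191 um^-1 (n = 8)
#>   P60_like: mean TT power 1842155.4, mean TT frequency 0.5221 um^-1 (n = 8)
#>   t test, TT power: t = -23.633, p = 1.107e-12
#>   t test, TT frequency: t = -1.707, p = 0.11
```

The high-jitter ("P20-like") cohort has markedly lower TT power than the
low-jitter ("P60-like") cohort, while both share the same TT frequency
(within one 0.02 µm⁻¹ frequency bin of the configured 1/1.9 µm⁻¹): the
pipeline separates *regularity* from *periodicity*.

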