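Package: crestscope
Title: Quantification of T-Tubule Regularity and Cardiomyocyte Surface-Crest Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spectral quantification of transverse-tubule (T-tubule) regularity
    in striated cardiomyocyte images: fixed-size region-of-interest extraction
    along the cell long axis, 2D FFT power spectrum normalized by pixel count,
    central one-dimensional spatial-frequency profile, and a band-limited
    Gaussian peak fit whose amplitude ("TT power") indexes striation regularity
    and whose center ("TT frequency") indexes sarcomeric periodicity. Also
    provides a data model and nested aggregation for transmission electron
    microscopy surface-crest morphometry (crest height normalized to sarcomere
    length, subsarcolemmal mitochondria counts and areas, lateral membrane
    interspace, myofibril counts), the accompanying statistical battery
    (Shapiro-Wilk, unpaired Student t, one- and two-way ANOVA with Tukey HSD,
    Fisher exact, log-rank with Kaplan-Meier curves), and seeded synthetic
    generators for striation images and morphometry tables with known ground
    truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    survival,
    tiff,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
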