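# shared fixtures for the crestscope suite: everything is generated in code

# a clean, noiseless, aligned striation image whose ROI-sized version has an
# integer number of stripe periods (exact single-bin spectra)
clean_stripes <- function(width_px = 500L, height_px = 35L, period_um = 2.0,
                          amplitude = 1, mean_intensity = 0, seed = 1,
                          ...) {
  simulate_striation_image(striation_params(
    width_px = width_px, height_px = height_px, period_um = period_um,
    amplitude = amplitude, mean_intensity = mean_intensity,
    phase_jitter_sd_um = 0, dropout_prob = 0, noise_sd = 0,
    blur_sigma_um = 0, seed = seed, ...
  ))
}

# run the full spectral pipeline on a centered default-size ROI
pipeline_fit <- function(img, band = c(0.45, 0.7), ...) {
  roi <- extract_roi(img, roi_spec(c(ncol(img) / 2, nrow(img) / 2)))
  fit_tt_peak(central_profile(power_spectrum_2d(roi)), band = band, ...)
}

# independent brute-force oracle for the two-sided Fisher exact p-value:
# sum the hypergeometric probabilities of all tables with the observed
# margins that are no more likely than the observed table (standard
# 1 + 1e-7 tie tolerance)
fisher_oracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# independent log-rank oracle: chi-square from the observed-minus-expected
# and hypergeometric variance accumulated over pooled distinct event times
logrank_oracle <- function(times, events, groups) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2L)
  g1 <- levels(groups)[1]
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(times[events]))) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & groups == g1)
    d <- sum(events & times == t)
    d1 <- sum(events & times == t & groups == g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  o_minus_e^2 / v
}

# design-based standard error of an animal-level group mean, from the
# generator's own configuration: animal random effect plus per-structure
# noise averaged over the expected number of structures per animal
morpho_se <- function(p, metric) {
  cfg <- p$metrics[[metric]]
  cells <- mean(p$cells_per_animal)
  m <- switch(cfg$level,
    crest = cells * p$crests_per_cell,
    cell = cells,
    site = cells * p$interspace_sites_per_cell * 5,
    ssm = cells * p$crests_per_cell * 2  # rough; ssm count varies
  )
  sqrt(cfg$animal_sd^2 + cfg$sd^2 / m) / sqrt(p$n_animals_per_group)
}

# pooled-variance two-sample t statistic, written out long-hand
student_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}
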