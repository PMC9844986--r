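test_that("noiseless stripes at period 2.0 um give a peak at 0.50 um^-1", {
  fit <- fit_tt_peak(central_profile(power_spectrum_2d(clean_stripes())))
  expect_true(fit$fit_ok)
  expect_lt(abs(fit$tt_frequency - 0.5), 0.02)  # within one frequency bin
  expect_gt(fit$tt_power, 0)
  expect_gt(fit$sigma, 0)
  expect_gte(fit$tt_frequency, fit$band[1])
  expect_lte(fit$tt_frequency, fit$band[2])
})

test_that("a stripe frequency outside the band is not reported as a peak", {
  img <- clean_stripes(width_px = 500L, period_um = 5, amplitude = 10,
                       mean_intensity = 100)
  fit <- fit_tt_peak(central_profile(power_spectrum_2d(img)))
  expect_false(fit$fit_ok)
})

test_that("TT power scales with the square of the image contrast", {
  f1 <- pipeline_fit(clean_stripes(width_px = 560L, height_px = 80L,
                                   amplitude = 10, mean_intensity = 100))
  f2 <- pipeline_fit(clean_stripes(width_px = 560L, height_px = 80L,
                                   amplitude = 20, mean_intensity = 100))
  expect_true(f1$fit_ok && f2$fit_ok)
  expect_equal(f2$tt_power / f1$tt_power, 4, tolerance = 0.05)
})

test_that("band validation rejects impossible or under-sampled bands", {
  p1 <- central_profile(power_spectrum_2d(clean_stripes()))
  expect_error(fit_tt_peak(p1, band = c(0.7, 0.45)),
               class = "crestscope_validation")
  expect_error(fit_tt_peak(p1, band = c(0.45, 99)),
               class = "crestscope_validation")
  expect_error(fit_tt_peak(p1, band = c(0.45, 0.5)),
               class = "crestscope_validation")  # only 3 bins
})

test_that("the fitted model object behaves like a fitted model", {
  fit <- fit_tt_peak(central_profile(power_spectrum_2d(
    clean_stripes(amplitude = 5, mean_intensity = 50)
  )))
  cf <- coef(fit)
  expect_named(cf, c("A", "mu", "sigma", "b"))
  expect_equal(unname(cf["A"]), fit$tt_power)
  # predict at the center returns A + b
  expect_equal(unname(predict(fit, cf["mu"])),
               unname(cf["A"] + cf["b"]), tolerance = 1e-12)
  expect_length(residuals(fit), nrow(fit$data))
  expect_equal(fitted(fit) + residuals(fit), fit$data$power,
               tolerance = 1e-9)
  expect_output(print(fit), "TT power")
  expect_output(print(summary(fit)), "fit_ok")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("the plain no-baseline Gaussian variant is available", {
  p1 <- central_profile(power_spectrum_2d(clean_stripes()))
  fit <- fit_tt_peak(p1, baseline = FALSE)
  expect_true(fit$fit_ok)
  expect_equal(fit$baseline, 0)
  expect_lt(abs(fit$tt_frequency - 0.5), 0.02)
})

test_that("frequency recovery within one bin across the sarcomeric range", {
  for (period in seq(1.5, 2.2, by = 0.1)) {
    img <- clean_stripes(width_px = 560L, height_px = 80L,
                         period_um = period, amplitude = 30,
                         mean_intensity = 100)
    fit <- pipeline_fit(img)
    expect_true(fit$fit_ok)
    expect_lt(abs(fit$tt_frequency - 1 / period), 0.02)
  }
})

test_that("tt_analysis composes the pipeline and flags bad ROIs", {
  img <- simulate_striation_image(striation_params(
    width_px = 700L, height_px = 100L, noise_sd = 3, seed = 8
  ))
  expect_equal(nrow(tt_analysis(img, list())), 0L)
  specs <- list(roi_spec(c(350, 50)), roi_spec(c(-100, 50)))
  res <- tt_analysis(img, specs)
  expect_equal(nrow(res), 2L)
  expect_true(res$fit_ok[1])
  expect_false(res$fit_ok[2])
  expect_match(res$error[2], "bounds|exceeds")
  # row 1 equals running the three steps manually
  manual <- fit_tt_peak(central_profile(power_spectrum_2d(
    extract_roi(img, specs[[1]])
  )))
  expect_equal(res$tt_power[1], manual$tt_power)
  expect_equal(res$tt_frequency_um_inv[1], manual$tt_frequency)
})

test_that("mean TT power does not increase with stripe jitter or dropout", {
  power_at <- function(jitter, dropout, seeds) {
    mean(vapply(seeds, function(s) {
      img <- simulate_striation_image(striation_params(
        width_px = 560L, height_px = 80L, phase_jitter_sd_um = jitter,
        dropout_prob = dropout, noise_sd = 4, seed = s
      ))
      pipeline_fit(img)$tt_power
    }, numeric(1)))
  }
  seeds <- 1:8
  expect_gt(power_at(0, 0, seeds), power_at(0.4, 0, seeds))
  expect_gt(power_at(0, 0, seeds), power_at(0, 0.4, seeds))
})
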