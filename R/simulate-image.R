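#' Parameters for the synthetic striation image generator
#'
#' Bundles and validates the generative parameters for
#' [simulate_striation_image()]. Defaults emulate confocal imaging of
#' striated cardiac tissue at 100 nm sampling with a ~1.9 um sarcomere
#' spacing (spatial frequency ~0.53 um^-1, inside the 0.45-0.7 um^-1
#' sarcomeric band).
#'
#' @param width_px,height_px image dimensions in pixels.
#' @param pixel_size_um physical pixel size (um).
#' @param period_um stripe period (um); must exceed twice the pixel size
#'   (Nyquist).
#' @param orientation_deg angle of the stripe normal relative to the image
#'   x-axis; 0 means intensity varies along x (vertical stripes, the
#'   "long-axis aligned" configuration).
#' @param mean_intensity,amplitude mean level and stripe contrast (arbitrary
#'   units, amplitude >= 0).
#' @param phase_jitter_sd_um SD of the rigid per-stripe positional jitter
#'   (um), mimicking Z-line misalignment.
#' @param dropout_prob probability in \[0, 1\] that an individual stripe is
#'   erased (its contrast set to zero).
#' @param noise_sd SD of additive Gaussian pixel noise (arbitrary units).
#' @param blur_sigma_um SD of the Gaussian point-spread blur (um).
#' @param profile stripe profile: `"cosine"` (a smooth grating with
#'   closed-form spectrum) or `"gaussian_line"` (narrow bright lines at the
#'   stripe positions).
#' @param line_sd_um line width (SD, um) used by the `"gaussian_line"`
#'   profile.
#' @param seed RNG seed; the same seed with the same parameters gives a
#'   bit-identical image. `NULL` draws from the current RNG stream.
#' @return a validated `striation_params` list.
#' @export
striation_params <- function(width_px = 600L, height_px = 128L,
                             pixel_size_um = 0.1, period_um = 1.9,
                             orientation_deg = 0, mean_intensity = 100,
                             amplitude = 30, phase_jitter_sd_um = 0,
                             dropout_prob = 0, noise_sd = 0,
                             blur_sigma_um = 0.1,
                             profile = c("cosine", "gaussian_line"),
                             line_sd_um = period_um / 8, seed = NULL) {
  profile <- match.arg(profile)
  check_scalar(width_px, "width_px", positive = TRUE, integerish = TRUE)
  check_scalar(height_px, "height_px", positive = TRUE, integerish = TRUE)
  check_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  check_scalar(period_um, "period_um", positive = TRUE)
  check_scalar(orientation_deg, "orientation_deg")
  check_scalar(mean_intensity, "mean_intensity")
  check_scalar(amplitude, "amplitude", nonneg = TRUE)
  check_scalar(phase_jitter_sd_um, "phase_jitter_sd_um", nonneg = TRUE)
  check_scalar(dropout_prob, "dropout_prob", nonneg = TRUE)
  if (dropout_prob > 1) stop_validation("dropout_prob must be in [0, 1]")
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(blur_sigma_um, "blur_sigma_um", nonneg = TRUE)
  check_scalar(line_sd_um, "line_sd_um", positive = TRUE)
  if (period_um <= 2 * pixel_size_um) {
    stop_validation(
      "Nyquist violation: period_um (", period_um,
      ") must exceed 2 * pixel_size_um (", 2 * pixel_size_um, ")"
    )
  }
  structure(
    list(
      width_px = as.integer(width_px), height_px = as.integer(height_px),
      pixel_size_um = pixel_size_um, period_um = period_um,
      orientation_deg = orientation_deg, mean_intensity = mean_intensity,
      amplitude = amplitude, phase_jitter_sd_um = phase_jitter_sd_um,
      dropout_prob = dropout_prob, noise_sd = noise_sd,
      blur_sigma_um = blur_sigma_um, profile = profile,
      line_sd_um = line_sd_um, seed = seed
    ),
    class = "striation_params"
  )
}

#' Simulate a striated (sarcomere-like) image
#'
#' Generates a periodic stripe pattern standing in for a caveolin-3-type
#' T-tubule staining: intensity
#' `mean + amplitude * cos(2*pi*u / period)` along the rotated coordinate
#' `u`, where each stripe (one period) may be rigidly displaced by Gaussian
#' jitter and erased with the dropout probability; the pattern is then
#' blurred by a Gaussian point-spread function and corrupted by additive
#' Gaussian noise. Jitter acts per stripe, not per pixel, mimicking Z-line
#' misalignment rather than speckle.
#'
#' @param params a [striation_params()] object.
#' @return an [image2d()] of size `height_px` x `width_px` carrying
#'   `pixel_size_um`.
#' @examples
#' img <- simulate_striation_image(striation_params(seed = 1))
#' img
#' @export
simulate_striation_image <- function(params) {
  stopifnot(inherits(params, "striation_params"))
  p <- params
  with_seed(p$seed, {
    th <- p$orientation_deg * pi / 180
    x_um <- (seq_len(p$width_px) - 1) * p$pixel_size_um
    y_um <- (seq_len(p$height_px) - 1) * p$pixel_size_um
    # u = coordinate along the stripe normal, um; rows = y, cols = x
    u <- outer(y_um * sin(th), x_um * cos(th), "+")
    # stripe index: stripe k is centered at u = k * period (cosine crest)
    k <- floor(u / p$period_um + 0.5)
    kr <- range(k)
    k_levels <- kr[1]:kr[2]
    n_stripes <- length(k_levels)
    jitter <- if (p$phase_jitter_sd_um > 0) {
      rnorm(n_stripes, sd = p$phase_jitter_sd_um)
    } else {
      rep(0, n_stripes)
    }
    kept <- if (p$dropout_prob > 0) {
      runif(n_stripes) >= p$dropout_prob
    } else {
      rep(TRUE, n_stripes)
    }
    ki <- k - kr[1] + 1L  # map stripe index to 1..n_stripes
    u_eff <- u - matrix(jitter[ki], nrow(u), ncol(u))
    amp <- p$amplitude * matrix(as.numeric(kept[ki]), nrow(u), ncol(u))
    mat <- if (p$profile == "cosine") {
      p$mean_intensity + amp * cos(2 * pi * u_eff / p$period_um)
    } else {
      centers <- matrix(k_levels[ki] * p$period_um + jitter[ki],
                        nrow(u), ncol(u))
      p$mean_intensity + amp * exp(-(u - centers)^2 / (2 * p$line_sd_um^2))
    }
    if (p$blur_sigma_um > 0) {
      mat <- gauss_blur(mat, p$blur_sigma_um / p$pixel_size_um)
    }
    if (p$noise_sd > 0) {
      mat <- mat + matrix(rnorm(length(mat), sd = p$noise_sd),
                          nrow(mat), ncol(mat))
    }
    image2d(mat, p$pixel_size_um)
  })
}
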