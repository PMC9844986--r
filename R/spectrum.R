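#' Centered 2D FFT power spectrum
#'
#' Computes the normalized power spectrum of an image or ROI:
#' \deqn{P_{2D} = |FFT_{2D}|^2 / N}
#' where the FFT is the unnormalized forward 2D discrete Fourier transform
#' and N the total number of pixels. The grid is shifted so zero frequency
#' sits at index `(height %/% 2 + 1, width %/% 2 + 1)` and the axes are
#' physical spatial frequencies in cycles per micrometer derived from the
#' pixel size. With this normalization the spectrum obeys Parseval's
#' identity: the sum of all power bins equals the sum of squared
#' (detrended) intensities.
#'
#' @param roi an [image2d()] (typically an ROI from [extract_roi()]).
#' @param detrend subtract the mean intensity first (default TRUE), removing
#'   the DC term so the striation peak dominates.
#' @return a `power_spectrum_2d` object: list with `power` (matrix, rows =
#'   vertical frequency), `fx_axis`, `fy_axis` (um^-1, monotone increasing,
#'   zero at the center index), `n_pixels` and `pixel_size_um`.
#' @examples
#' img <- simulate_striation_image(striation_params(seed = 1))
#' ps <- power_spectrum_2d(img)
#' sum(ps$power)  # equals sum of squared detrended intensities
#' @export
power_spectrum_2d <- function(roi, detrend = TRUE) {
  stopifnot(inherits(roi, "image2d"))
  m <- unclass(roi)
  if (!all(is.finite(m))) stop_validation("image contains non-finite pixels")
  if (detrend) m <- m - mean(m)
  h <- nrow(m); w <- ncol(m)
  n <- h * w
  pw <- Mod(fft(m))^2 / n
  pw <- pw[fftshift_index(h), fftshift_index(w), drop = FALSE]
  px <- pixel_size(roi)
  obj <- list(
    power = pw,
    fx_axis = freq_axis(w, px),
    fy_axis = freq_axis(h, px),
    n_pixels = n,
    pixel_size_um = px,
    detrended = isTRUE(detrend)
  )
  # Parseval self-check (exact up to FFT round-off)
  total <- sum(m^2)
  if (total > 0 && abs(sum(pw) - total) > 1e-6 * total) {
    stop("internal error: Parseval identity violated beyond tolerance")
  }
  class(obj) <- "power_spectrum_2d"
  obj
}

#' @export
print.power_spectrum_2d <- function(x, ...) {
  cat(sprintf(
    "<power_spectrum_2d> %d x %d bins, fx in [%.3g, %.3g] um^-1, total power %.4g\n",
    nrow(x$power), ncol(x$power), min(x$fx_axis), max(x$fx_axis), sum(x$power)
  ))
  invisible(x)
}

#' Central 1D power profile
#'
#' Extracts the middle horizontal line of the centered 2D power spectrum —
#' the unique row with exactly zero vertical frequency — and folds it to
#' nonnegative horizontal frequencies, taking the value at +f from the +f
#' half of the axis. Frequency spacing is `1 / (width_px * pixel_size_um)`.
#'
#' @param spec2d a [power_spectrum_2d()] result.
#' @return a `power_spectrum_1d` object: list with `frequency` (um^-1,
#'   starting at 0) and `power`.
#' @export
central_profile <- function(spec2d) {
  stopifnot(inherits(spec2d, "power_spectrum_2d"))
  h <- length(spec2d$fy_axis)
  row0 <- h %/% 2L + 1L  # fy = 0 exactly
  keep <- spec2d$fx_axis >= 0
  obj <- list(
    frequency = spec2d$fx_axis[keep],
    power = spec2d$power[row0, keep],
    n_pixels = spec2d$n_pixels,
    pixel_size_um = spec2d$pixel_size_um
  )
  class(obj) <- "power_spectrum_1d"
  obj
}

#' @export
print.power_spectrum_1d <- function(x, ...) {
  cat(sprintf(
    "<power_spectrum_1d> %d bins, f in [0, %.3g] um^-1 (spacing %.4g), peak %.4g at %.3g um^-1\n",
    length(x$frequency), max(x$frequency), x$frequency[2] - x$frequency[1],
    max(x$power[-1]), x$frequency[-1][which.max(x$power[-1])]
  ))
  invisible(x)
}

#' @export
plot.power_spectrum_1d <- function(x, band = NULL, ...) {
  plot(x$frequency, x$power, type = "h",
       xlab = expression(paste("spatial frequency (", mu, m^-1, ")")),
       ylab = "power", ...)
  if (!is.null(band)) abline(v = band, lty = 2, col = "grey40")
  invisible(x)
}
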