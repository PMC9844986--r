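#' Grayscale image with physical pixel size
#'
#' Thin container for a single-channel image: a numeric matrix (rows = y,
#' columns = x, origin at the top-left) plus the isotropic physical pixel
#' size in micrometers. All image computations in the package consume and
#' return this class.
#'
#' @param pixels numeric matrix of intensities (arbitrary units); all values
#'   must be finite.
#' @param pixel_size_um physical size of one pixel in micrometers (> 0).
#'   The default 0.1 corresponds to 100 nm confocal sampling.
#' @return An `image2d` object: the pixel matrix with attributes
#'   `pixel_size_um` and class `"image2d"`.
#' @examples
#' img <- image2d(matrix(runif(64), 8, 8), pixel_size_um = 0.1)
#' dim(img)
#' @export
image2d <- function(pixels, pixel_size_um = 0.1) {
  if (!is.matrix(pixels) || !is.numeric(pixels) ||
      nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop_validation("pixels must be a non-empty numeric matrix")
  }
  if (!all(is.finite(pixels))) {
    stop_validation("all pixel intensities must be finite")
  }
  check_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  structure(pixels,
    pixel_size_um = as.numeric(pixel_size_um),
    class = c("image2d", "matrix", "array")
  )
}

#' @export
print.image2d <- function(x, ...) {
  px <- attr(x, "pixel_size_um")
  cat(sprintf(
    "<image2d> %d x %d px (%.3g x %.3g um at %.3g um/px), intensity [%.4g, %.4g]\n",
    ncol(x), nrow(x), ncol(x) * px, nrow(x) * px, px, min(x), max(x)
  ))
  invisible(x)
}

#' Pixel size accessor
#' @param image an [image2d()] object.
#' @return pixel size in micrometers.
#' @export
pixel_size <- function(image) {
  px <- attr(image, "pixel_size_um")
  if (is.null(px)) stop_validation("object carries no pixel_size_um attribute")
  px
}

#' Write an image to TIFF with a JSON sidecar
#'
#' Images are held in floating point in arbitrary units; quantization to
#' 8/16-bit happens only here, with an explicit linear scaling recorded in a
#' sidecar JSON file (`<path>.json`) together with the physical pixel size
#' (also stored in the TIFF x/y resolution fields, in pixels per cm).
#'
#' @param image an [image2d()] object.
#' @param path output TIFF path.
#' @param bits bits per sample, 8 or 16.
#' @param range intensity range mapped to the integer range; defaults to the
#'   image min/max.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path, bits = 16L, range = NULL) {
  stopifnot(inherits(image, "image2d"))
  bits <- as.integer(bits)
  if (!bits %in% c(8L, 16L)) stop_validation("bits must be 8 or 16")
  if (is.null(range)) range <- c(min(image), max(image))
  lo <- range[1]; hi <- range[2]
  scaled <- if (hi > lo) (unclass(image) - lo) / (hi - lo) else
    matrix(0, nrow(image), ncol(image))
  scaled <- pmin(pmax(scaled, 0), 1)
  px_cm <- 1e4 / pixel_size(image)  # pixels per centimeter
  tiff::writeTIFF(scaled, path,
    bits.per.sample = bits, compression = "none",
    reduce = TRUE
  )
  sidecar <- list(
    pixel_size_um = pixel_size(image),
    intensity_min = lo, intensity_max = hi,
    bits_per_sample = bits,
    resolution_px_per_cm = px_cm
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a TIFF image written by [write_image_tiff()]
#'
#' Restores the original intensity scale and pixel size from the sidecar
#' JSON when present; otherwise `pixel_size_um` must be supplied and
#' intensities are returned on the [0, 1] scale.
#'
#' @param path TIFF path.
#' @param pixel_size_um fallback pixel size when no sidecar exists.
#' @return an [image2d()] object.
#' @export
read_image_tiff <- function(path, pixel_size_um = NULL) {
  mat <- tiff::readTIFF(path)
  if (length(dim(mat)) == 3L) mat <- mat[, , 1L]  # single channel only
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    mat <- mat * (sc$intensity_max - sc$intensity_min) + sc$intensity_min
    pixel_size_um <- sc$pixel_size_um
  } else if (is.null(pixel_size_um)) {
    stop_validation(
      "no sidecar JSON found for ", path, "; supply pixel_size_um"
    )
  }
  image2d(mat, pixel_size_um)
}
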