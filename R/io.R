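#' Read an AP radiograph from PNG or TIFF
#'
#' Loads an 8-bit grayscale image as an intensity matrix in [0, 255]
#' (row 1 = image top). Colour images are converted to grayscale by channel
#' averaging; intensities outside the 8-bit range are min-max windowed to
#' [0, 255] with a warning.
#'
#' @param path File path ending in .png, .tif or .tiff.
#' @return Numeric matrix of grey levels in [0, 255].
#' @export
read_radiograph <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(arr)) == 3) arr <- apply(arr[, , 1:min(3, dim(arr)[3])], c(1, 2), mean)
  img <- arr * 255
  if (min(img) < 0 || max(img) > 255) {
    warning("intensities outside [0, 255]: applying min-max windowing")
    rng <- range(img)
    img <- (img - rng[1]) / (rng[2] - rng[1]) * 255
  }
  round(img)
}

#' Write an intensity matrix as an 8-bit grayscale PNG
#'
#' @param image Matrix of grey levels in [0, 255].
#' @param path Output .png path.
#' @return `path`, invisibly.
#' @export
write_radiograph <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}
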