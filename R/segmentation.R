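#' Optimum global threshold (between-class variance criterion)
#'
#' Finds the intensity cut that maximizes the between-class variance of the
#' 256-bin grey-level histogram (Otsu's criterion); pixels above the returned
#' value are foreground. Ties are broken toward the lower threshold. The result
#' depends on the histogram only, never on pixel positions.
#'
#' @param image Intensity matrix with values in [0, 255].
#' @return A single intensity value `t` in 0..254; foreground is `image > t`.
#' @examples
#' img <- matrix(c(60, 60, 200, 200), 2)
#' optimum_global_threshold(img)
#' @export
optimum_global_threshold <- function(image) {
  v <- as.vector(image)
  if (any(v < 0 | v > 255)) stop("intensities must lie in [0, 255]", call. = FALSE)
  bins <- floor(v)
  if (min(bins) == max(bins)) {
    stop("constant image: no threshold separates two classes", call. = FALSE)
  }
  counts <- tabulate(bins + 1L, nbins = 256L)
  p <- counts / sum(counts)
  levels <- 0:255
  w0 <- cumsum(p)                 # P(class <= k)
  mu <- cumsum(p * levels)        # first moment up to k
  mu_t <- mu[256]
  k <- 1:255                      # candidate cuts t = 0..254
  w0k <- w0[k]
  valid <- w0k > 0 & w0k < 1
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (mu_t * w0k[valid] - mu[k][valid])^2 /
    (w0k[valid] * (1 - w0k[valid]))
  which.max(sigma_b) - 1L         # first max = lower threshold on ties
}

#' Extract the spinal column from a radiograph
#'
#' The pre-processing stage of the pipeline: binarize at the optimum global
#' threshold, morphologically close small gaps (bridging inter-vertebral disc
#' spaces) with a disc structuring element, keep the largest 8-connected
#' foreground component as the column envelope, and mask the original
#' intensities back onto it (logical AND), zero elsewhere.
#'
#' @param image Intensity matrix in [0, 255], non-constant.
#' @param closing_radius Radius (pixels) of the disc used for morphological
#'   closing; default 5 at the 925 x 475 working scale.
#' @return List with `mask` (0/1 integer matrix of the column envelope),
#'   `masked` (original intensities under the mask, 0 outside) and
#'   `threshold` (the global threshold used).
#' @export
extract_spinal_column <- function(image, closing_radius = 5) {
  thr <- optimum_global_threshold(image)
  raw <- as_binary_matrix(image > thr)
  if (sum(raw) == 0L) stop("no column found: empty foreground", call. = FALSE)
  closed <- if (closing_radius >= 1) {
    padded_morph(raw, closing_radius, EBImage::closing)
  } else raw
  lab <- label_components(closed)
  if (max(lab) == 0L) stop("no column found: empty foreground", call. = FALSE)
  mask <- as_binary_matrix(lab == 1L)
  masked <- image * mask
  list(mask = mask, masked = masked, threshold = thr)
}

#' Fourier (zero-padded spectrum) interpolation of a 1-D series
#'
#' Resamples an ordered real-valued series to `factor` times its length by
#' zero-padding its discrete Fourier spectrum, preserving amplitude. Used to
#' densify per-row column profiles and the medial-axis series; a band-limited
#' signal is reproduced exactly at the new sample positions.
#'
#' @param series Numeric vector, length >= 4.
#' @param factor Integer upsampling factor >= 1; 1 returns the input (up to
#'   round-off).
#' @return Numeric vector of length `factor * length(series)`; sample `j`
#'   (1-based) corresponds to original position `(j - 1) / factor` (0-based).
#' @examples
#' fft_interpolate(sin(2 * pi * (0:15) / 16), 2)
#' @export
fft_interpolate <- function(series, factor = 1L) {
  n <- length(series)
  if (n < 4) stop("series must have length >= 4", call. = FALSE)
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be a positive integer", call. = FALSE)
  if (factor == 1L) return(as.numeric(series))
  m <- n * factor
  sp <- stats::fft(series)
  half <- n %/% 2
  pad <- complex(m)
  if (n %% 2 == 0) {
    # split the Nyquist bin symmetrically so the result stays real
    pad[1:half] <- sp[1:half]
    pad[half + 1] <- sp[half + 1] / 2
    pad[m - half + 1] <- sp[half + 1] / 2
    if (half > 1) pad[(m - half + 2):m] <- sp[(half + 2):n]
  } else {
    pad[1:(half + 1)] <- sp[1:(half + 1)]
    pad[(m - half + 1):m] <- sp[(half + 2):n]
  }
  Re(stats::fft(pad, inverse = TRUE)) / n
}
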