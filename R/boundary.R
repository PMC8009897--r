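#' Boundary band of a binary mask (morphological inner gradient)
#'
#' Subtracts the erosion of the mask (disc structuring element of the given
#' radius) from the mask itself, leaving a band up to `radius` pixels thick
#' along the object border. At radius 1 the band is exactly the set of
#' foreground pixels with at least one 8-neighbour outside the mask.
#'
#' @param mask 0/1 matrix, non-empty.
#' @param erosion_radius Disc radius in pixels (default 1: thin boundary).
#' @return 0/1 integer matrix of the boundary band.
#' @export
boundary_pixels <- function(mask, erosion_radius = 1) {
  mask <- as_binary_matrix(mask)
  if (sum(mask) == 0L) stop("mask is empty", call. = FALSE)
  er <- padded_morph(mask, erosion_radius, EBImage::erode)
  if (sum(er) == 0L) {
    stop("erosion annihilates the mask: object thinner than 2 x radius",
         call. = FALSE)
  }
  as_binary_matrix(mask & !er)
}

# Moore-neighbour tracing of one 8-connected component, clockwise from its
# topmost-then-leftmost pixel (initial backtrack to its west). Pixels may be
# visited more than once (spurs); 0-based (row, col) coordinates. Directions
# are 0..7 = N, NE, E, SE, S, SW, W, NW (clockwise in image coordinates).
moore_trace <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask != 0)
  r <- (fg - 1L) %% nr; c <- (fg - 1L) %/% nr
  start_i <- order(r, c)[1]
  sr <- r[start_i]; sc <- c[start_i]
  dr <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dc <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  inside <- function(rr, cc) rr >= 0L && rr < nr && cc >= 0L && cc < nc &&
    mask[rr + 1L, cc + 1L] != 0
  if (length(fg) == 1L) return(cbind(row = sr, col = sc))
  cap <- 8L * length(fg) + 16L
  rows <- integer(cap); cols <- integer(cap)
  n_out <- 1L; rows[1] <- sr; cols[1] <- sc
  cr <- sr; cc <- sc
  back <- 6L                     # came "from" the west of the start pixel
  # the walk is a deterministic map on (pixel, backtrack) states, so the
  # trace is complete exactly when a state repeats
  seen <- new.env(hash = TRUE, size = 4L * length(fg))
  repeat {
    key <- as.character((cr * nc + cc) * 8L + back)
    if (!is.null(seen[[key]])) break
    seen[[key]] <- TRUE
    d <- NA_integer_
    for (s in 1:8) {
      cand <- (back + s) %% 8L   # first scan position: one past the backtrack
      rr <- cr + dr[cand + 1L]; c2 <- cc + dc[cand + 1L]
      if (inside(rr, c2)) { d <- cand; break }
    }
    if (is.na(d)) break          # isolated pixel
    # backtrack seen from the new pixel = the last-scanned background
    # neighbour of the old pixel (direction d-1), re-expressed from there
    new_back <- (2L * (d %/% 2L) + 6L) %% 8L
    if (rr == sr && c2 == sc && new_back == 6L) break  # closed the loop
    n_out <- n_out + 1L
    rows[n_out] <- rr; cols[n_out] <- c2
    back <- new_back
    cr <- rr; cc <- c2
    if (n_out >= cap) break      # safety net
  }
  cbind(row = rows[1:n_out], col = cols[1:n_out])
}

#' Select and trace the largest boundary component
#'
#' Labels the 8-connected components of a boundary-band mask, keeps the one
#' with the most pixels (the outer border when inner hole borders exist; ties
#' go to the component whose topmost-leftmost pixel comes first in raster
#' order), and traces it into an ordered closed contour by Moore-neighbour
#' tracing, clockwise from the topmost-then-leftmost pixel.
#'
#' @param boundary_mask 0/1 matrix (e.g. from [boundary_pixels()]).
#' @return A contour: tibble with 0-based columns `row`, `col`, one entry per
#'   traced step (consecutive points are 8-neighbours, last neighbours first),
#'   with attribute `closed = TRUE`.
#' @export
select_largest_boundary <- function(boundary_mask) {
  boundary_mask <- as_binary_matrix(boundary_mask)
  if (sum(boundary_mask) == 0L) stop("boundary mask is empty", call. = FALSE)
  lab <- label_components(boundary_mask)
  comp <- as_binary_matrix(lab == 1L)
  pts <- moore_trace(comp)
  # drop the duplicated closing point if tracing re-appended the start
  n <- nrow(pts)
  if (n > 1 && pts[n, 1] == pts[1, 1] && pts[n, 2] == pts[1, 2]) {
    pts <- pts[-n, , drop = FALSE]
  }
  out <- tibble::tibble(row = as.integer(pts[, 1]), col = as.integer(pts[, 2]))
  attr(out, "closed") <- TRUE
  out
}

#' Gaussian smoothing of a closed contour
#'
#' Circularly convolves the row and column coordinate sequences of a closed
#' contour with a Gaussian kernel of standard deviation `sigma`, then
#' re-quantizes to integer pixel coordinates. Smoothing suppresses the
#' per-vertebra scalloping of the traced spinal-column outline; the contour
#' stays closed. `sigma = 0` returns the input unchanged.
#'
#' @param contour Tibble with `row`, `col` (closed, > 8 points).
#' @param sigma Gaussian standard deviation in pixels.
#' @return Smoothed contour tibble (consecutive duplicate points removed).
#' @export
smooth_boundary <- function(contour, sigma = 3) {
  n <- nrow(contour)
  if (n <= 8) stop("contour too short to smooth (need > 8 points)", call. = FALSE)
  if (sigma <= 0) return(contour)
  hw <- max(1L, as.integer(ceiling(3 * sigma)))
  hw <- min(hw, (n - 1L) %/% 2L)
  k <- exp(-(seq(-hw, hw))^2 / (2 * sigma^2))
  k <- k / sum(k)
  circ_conv <- function(v) {
    vp <- c(v[(n - hw + 1L):n], v, v[1:hw])
    as.numeric(stats::filter(vp, k, sides = 2))[(hw + 1L):(hw + n)]
  }
  r <- round(circ_conv(contour$row))
  c <- round(circ_conv(contour$col))
  dup <- c(FALSE, r[-1] == r[-n] & c[-1] == c[-n])
  out <- tibble::tibble(row = as.integer(r[!dup]), col = as.integer(c[!dup]))
  attr(out, "closed") <- TRUE
  out
}
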