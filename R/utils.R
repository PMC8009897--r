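# Internal helpers shared across modules. All user-facing coordinates are
# 0-based pixels: row 0 = image top (superior), x increasing rightward.

`%||%` <- function(a, b) if (is.null(a)) b else a

deg <- function(rad) rad * 180 / pi

stop_stage <- function(stage, msg) {
  stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}

as_binary_matrix <- function(mask) {
  m <- (mask != 0) * 1L
  storage.mode(m) <- "integer"
  m
}

#' Disc structuring element
#'
#' Binary (2r+1) x (2r+1) kernel containing the offsets with
#' `i^2 + j^2 <= (r + 0.5)^2`. At radius 1 this is the full 3x3 square, so the
#' radius-1 morphological inner gradient coincides with the 8-neighbour border
#' definition; at larger radii the kernel is disc-shaped.
#'
#' @param radius Kernel radius in pixels (positive integer).
#' @return Integer 0/1 matrix of size `2*radius + 1` squared.
#' @keywords internal
disc_kernel <- function(radius) {
  stopifnot(length(radius) == 1, radius >= 1)
  off <- seq(-radius, radius)
  k <- outer(off^2, off^2, `+`) <= (radius + 0.5)^2
  as_binary_matrix(k)
}

# Morphology with explicit zero padding: EBImage treats pixels beyond the
# image border as foreground during erosion, whereas this package defines the
# outside of the image as background. Pad by the kernel radius, apply, crop.
padded_morph <- function(mask, radius, op) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- as.integer(radius) + 1L
  big <- matrix(0L, nr + 2L * p, nc + 2L * p)
  big[(p + 1L):(p + nr), (p + 1L):(p + nc)] <- mask
  out <- op(big, disc_kernel(radius))
  as_binary_matrix(out[(p + 1L):(p + nr), (p + 1L):(p + nc)])
}

# 8-connected component labelling via igraph. Returns an integer matrix of the
# same shape: 0 = background, components numbered by decreasing pixel count
# (ties broken by raster order of the topmost-leftmost pixel).
label_components <- function(mask) {
  mask <- mask != 0
  n <- sum(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (n == 0L) return(lab)
  nr <- nrow(mask)
  idx <- which(mask)                       # column-major linear indices
  pos <- integer(length(mask)); pos[idx] <- seq_along(idx)
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  edges <- integer(0)
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + d[1]; c2 <- c + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(mask)
    j <- idx[ok]; j2 <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- mask[j2]
    if (any(keep)) edges <- c(edges, rbind(pos[j[keep]], pos[j2[keep]]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  memb <- igraph::components(g)$membership
  # renumber by size, ties by first (raster-order) pixel
  sizes <- tabulate(memb)
  first <- order(memb)[!duplicated(sort(memb))]  # first index per label
  ord <- order(-sizes, first)
  renum <- integer(length(sizes)); renum[ord] <- seq_along(ord)
  lab[idx] <- renum[memb]
  lab
}

# Running-mean smoothing with edge replication; half-width in samples.
running_mean <- function(x, half_width) {
  if (half_width < 1) return(x)
  n <- length(x)
  k <- 2L * as.integer(half_width) + 1L
  xp <- c(rep(x[1], half_width), x, rep(x[n], half_width))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2))[
    (half_width + 1L):(half_width + n)]
}

# Least-squares slope dx/drow of x over a sliding window, for samples on a
# regular row grid. half_window is in row units; windows are clipped at the
# series ends (matching tangent_slope()'s clipping rule).
rolling_slope <- function(rows, x, half_window) {
  n <- length(x)
  step <- if (n > 1) (rows[n] - rows[1]) / (n - 1) else 1
  h <- max(1L, as.integer(round(half_window / step)))
  slope <- numeric(n)
  # interior: closed-form weights sum_k k*x[t+k] / (step * sum_k k^2)
  if (n >= 2L * h + 1L) {
    k <- seq(-h, h)
    denom <- sum(k^2) * step
    filt <- as.numeric(stats::filter(x, rev(k), sides = 2))
    interior <- (h + 1L):(n - h)
    slope[interior] <- filt[interior] / denom
  }
  edge <- c(seq_len(min(h, n)), seq.int(max(1L, n - h + 1L), n))
  for (i in unique(edge)) {
    j <- max(1L, i - h):min(n, i + h)
    rv <- rows[j] - mean(rows[j])
    slope[i] <- sum(rv * x[j]) / sum(rv^2)
  }
  slope
}

# Angle (degrees) at vertex `at` between rays to p1 and p2; points are
# c(row, x). Returns the interior angle in [0, 180].
vertex_angle <- function(at, p1, p2) {
  v1 <- p1 - at
  v2 <- p2 - at
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) {
    stop("degenerate angle: apex coincides with an end point", call. = FALSE)
  }
  deg(acos(pmin(1, pmax(-1, sum(v1 * v2) / (n1 * n2)))))
}
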