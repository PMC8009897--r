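# Shared phantom builders with memoization: rendering a 925x475 phantom and
# running the pipeline are the slow steps, and several test files probe the
# same cases.

.case_cache <- new.env(parent = emptyenv())

single_curve_spec <- function(amplitude, half_span = 200, center_row = 400,
                              noise_sigma = 10, seed = 1L) {
  midline_spec(
    curves = list(list(center_row = center_row, half_span = half_span,
                       amplitude = amplitude)),
    noise_sigma = noise_sigma, seed = seed
  )
}

double_curve_spec <- function(amplitude = 35, noise_sigma = 10, seed = 1L) {
  midline_spec(
    curves = list(
      list(center_row = 280, half_span = 150, amplitude = amplitude),
      list(center_row = 620, half_span = 150, amplitude = -amplitude)
    ),
    noise_sigma = noise_sigma, seed = seed
  )
}

cached <- function(key, expr) {
  if (is.null(.case_cache[[key]])) .case_cache[[key]] <- force(expr)
  .case_cache[[key]]
}

get_phantom <- function(spec, tag) {
  cached(paste0("ph_", tag), render_radiograph(spec))
}

get_report <- function(image, tag, config = pipeline_config()) {
  cached(paste0("rep_", tag), run_pipeline(image, config))
}

# Forced full-extent segment (apex pinned at the midpoint) used to measure a
# spine that produced no detected curve.
forced_full_segment <- function(ma) {
  tr <- range(ma$row)
  tibble::tibble(segment = 1L, start_row = tr[1], apex_row = mean(tr),
                 end_row = tr[2], direction = 1L)
}

# Brute-force 8-neighbour inner border, the independent oracle for
# boundary_pixels at radius 1.
brute_border <- function(mask) {
  mask <- (mask != 0) * 1L
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (mask[i, j] == 0) next
    nb <- expand.grid(i + (-1:1), j + (-1:1))
    edge <- FALSE
    for (k in seq_len(nrow(nb))) {
      r <- nb[k, 1]; c <- nb[k, 2]
      if (r < 1 || r > nr || c < 1 || c > nc || mask[r, c] == 0) edge <- TRUE
    }
    if (edge) out[i, j] <- 1L
  }
  out
}

# Random blob mask: union of a few filled discs, morphologically closed so
# the border is well defined.
random_blob_mask <- function(n = 40, seed = 1) {
  set.seed(seed)
  m <- matrix(0L, n, n)
  for (k in 1:3) {
    cr <- runif(1, n * 0.3, n * 0.7); cc <- runif(1, n * 0.3, n * 0.7)
    rad <- runif(1, n * 0.1, n * 0.25)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if ((i - cr)^2 + (j - cc)^2 <= rad^2) m[i, j] <- 1L
    }
  }
  m
}
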