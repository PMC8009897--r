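#' Specification of a synthetic AP spine phantom
#'
#' Describes a parametric vertebral midline and the rendering parameters of a
#' synthetic antero-posterior radiograph: a bright, possibly curved vertebral
#' column over a darker noisy background. The midline is a vertical baseline
#' (the true central sacral line) plus one raised-cosine lateral bump per
#' scoliotic curve, so every geometric ground-truth quantity has a closed form.
#'
#' Default image size is 925 x 475 pixels at 256 grey levels, the format of
#' conventional standing AP scoliosis radiographs this generator emulates, with
#' 17 vertebrae (12 thoracic + 5 lumbar) evenly spaced over the column extent.
#'
#' @param image_height,image_width Image size in pixels.
#' @param baseline_x Column (0-based x) of the straight baseline; the default
#'   centres the column so that mirror symmetry is exact.
#' @param curves List of curves, each `list(center_row, half_span, amplitude)`:
#'   a raised-cosine lateral displacement of `amplitude` signed pixels peaking
#'   at `center_row` and vanishing outside `center_row +/- half_span`. Spans of
#'   distinct curves must not overlap.
#' @param n_vertebrae Number of rendered vertebral bodies.
#' @param vertebra_width Width of each vertebral body in pixels.
#' @param noise_sigma Standard deviation of additive Gaussian intensity noise.
#' @param seed Integer seed making the rendering reproducible.
#' @return A `midline_spec` object (list) with the validated fields plus the
#'   derived column extent `column_top`/`column_bottom` (rows occupied by the
#'   rendered column).
#' @examples
#' spec <- midline_spec(curves = list(list(center_row = 400, half_span = 200,
#'                                         amplitude = 40)))
#' @export
midline_spec <- function(image_height = 925, image_width = 475,
                         baseline_x = 237, curves = list(),
                         n_vertebrae = 17, vertebra_width = 60,
                         noise_sigma = 10, seed = 1L) {
  stopifnot(image_height >= 50, image_width >= 50, n_vertebrae >= 1,
            vertebra_width >= 4, noise_sigma >= 0)
  curves <- lapply(curves, function(cv) {
    cv <- as.list(cv)
    stopifnot(all(c("center_row", "half_span", "amplitude") %in% names(cv)))
    if (cv$half_span <= 0) stop("curve half_span must be positive", call. = FALSE)
    lo <- cv$center_row - cv$half_span
    hi <- cv$center_row + cv$half_span
    if (lo < 0 || hi >= image_height) {
      stop("curve span must lie within [0, image_height)", call. = FALSE)
    }
    cv[c("center_row", "half_span", "amplitude")]
  })
  if (length(curves) > 1) {
    iv <- t(vapply(curves, function(cv) {
      c(cv$center_row - cv$half_span, cv$center_row + cv$half_span)
    }, numeric(2)))
    ord <- order(iv[, 1])
    iv <- iv[ord, , drop = FALSE]
    if (any(iv[-1, 1] < iv[-nrow(iv), 2])) {
      stop("curve spans must not overlap", call. = FALSE)
    }
  }
  max_amp <- if (length(curves)) max(abs(vapply(curves, `[[`, 1, "amplitude"))) else 0
  if (baseline_x - max_amp - vertebra_width / 2 < 0 ||
      baseline_x + max_amp + vertebra_width / 2 > image_width - 1) {
    stop("column (baseline_x +/- amplitude +/- vertebra_width/2) leaves the image",
         call. = FALSE)
  }
  margin <- round(0.04 * image_height)
  structure(list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    baseline_x = baseline_x,
    curves = curves,
    n_vertebrae = as.integer(n_vertebrae),
    vertebra_width = vertebra_width,
    noise_sigma = noise_sigma,
    seed = as.integer(seed),
    column_top = as.integer(margin),
    column_bottom = as.integer(image_height - 1 - margin)
  ), class = "midline_spec")
}

# Closed-form midline x(row) and its derivative dx/drow.
midline_fun <- function(spec, rows, derivative = FALSE) {
  out <- if (derivative) numeric(length(rows)) else rep(spec$baseline_x, length(rows))
  for (cv in spec$curves) {
    u <- rows - cv$center_row
    inside <- abs(u) <= cv$half_span
    if (!any(inside)) next
    if (derivative) {
      out[inside] <- out[inside] -
        cv$amplitude * pi / (2 * cv$half_span) * sin(pi * u[inside] / cv$half_span)
    } else {
      out[inside] <- out[inside] +
        cv$amplitude * (1 + cos(pi * u[inside] / cv$half_span)) / 2
    }
  }
  out
}

#' Analytic phantom midline
#'
#' Evaluates the closed-form midline x-coordinate at every row of the column
#' extent: baseline plus the raised-cosine bump of each curve. The result is
#' continuous and differentiable in the row coordinate.
#'
#' @param spec A [midline_spec()].
#' @return Tibble with columns `row` (integer, `column_top:column_bottom`) and
#'   `x` (midline column coordinate).
#' @export
make_midline <- function(spec) {
  stopifnot(inherits(spec, "midline_spec"))
  rows <- spec$column_top:spec$column_bottom
  tibble::tibble(row = rows, x = midline_fun(spec, rows))
}

#' Ground-truth curvature angles from an analytic midline
#'
#' Computes the Cobb, Ferguson, Greenspan-index and Diab values of each curve
#' segment directly from a noise-free midline series, using the same geometric
#' constructions as the curvature estimators (extreme-tangent Cobb, landmark
#' triangle Ferguson, normalized cumulative displacement Greenspan, apex rays
#' to three-band centroid anchors for Diab). Serves as the analytic oracle for
#' the image pipeline.
#'
#' @param midline Tibble with columns `row`, `x` (e.g. from [make_midline()]).
#' @param segments Tibble of curve segments with columns `start_row`,
#'   `apex_row`, `end_row` (e.g. from [true_curve_segments()]).
#' @param csl_anchor Where the vertical reference line is anchored; see
#'   [central_sacral_line()].
#' @param half_window Tangent estimation half-window in rows.
#' @return Tibble with columns `segment`, `method`, `value`, `severity`.
#' @export
analytic_angles <- function(midline, segments,
                            csl_anchor = c("bottom", "top", "mean"),
                            half_window = 36) {
  if (nrow(segments) > 0 &&
      any(segments$start_row >= segments$end_row)) {
    stop("degenerate segment: start_row must be < end_row", call. = FALSE)
  }
  if (nrow(segments) > 0 &&
      (min(segments$start_row) < min(midline$row) ||
       max(segments$end_row) > max(midline$row))) {
    stop("segments must lie within the midline's row range", call. = FALSE)
  }
  csl <- central_sacral_line(midline, anchor = match.arg(csl_anchor))
  measure_curvature(midline, csl, segments, half_window = half_window)
}

#' Curve segments of an analytic displacement signal
#'
#' Applies the displacement-threshold curve-detection convention to the exact
#' analytic midline: the true central sacral line is the midline anchored per
#' `csl_anchor`, and segments are the maximal excursions where the absolute
#' displacement exceeds `epsilon`. This defines the ground-truth SEV/IEV rows
#' that the image pipeline's detector is compared against; the true apex row of
#' each raised-cosine curve equals its `center_row`.
#'
#' @inheritParams analytic_angles
#' @param epsilon Displacement threshold in pixels.
#' @param min_span Minimum segment length in rows.
#' @return Segment tibble as from [detect_curves()].
#' @export
true_curve_segments <- function(midline, csl_anchor = "bottom",
                                epsilon = 2, min_span = 30) {
  csl <- central_sacral_line(midline, anchor = csl_anchor)
  detect_curves(displacement(midline, csl), epsilon = epsilon,
                min_span = min_span)
}

#' Bump amplitude for a target Cobb angle
#'
#' Closed-form calibration of the raised-cosine phantom: the extreme midline
#' tangents of a bump of amplitude `A` and half-span `s` enclose the angle
#' `2 * atan(A * pi / (2 * s))`, so the amplitude producing a given Cobb
#' angle is `A = tan(theta / 2) * 2 * s / pi`.
#'
#' @param cobb_deg Target Cobb angle in degrees (0 < angle < 180).
#' @param half_span Bump half-span in rows.
#' @return Amplitude in pixels.
#' @examples
#' amplitude_for_cobb(25, half_span = 200)
#' @export
amplitude_for_cobb <- function(cobb_deg, half_span) {
  stopifnot(cobb_deg > 0, cobb_deg < 180, half_span > 0)
  tan(cobb_deg * pi / 360) * 2 * half_span / pi
}

#' Render a synthetic AP spine radiograph
#'
#' Renders the phantom described by a [midline_spec()]: `n_vertebrae` bright
#' rectangular vertebral bodies (intensity 200) of width `vertebra_width`,
#' centred on the analytic midline at evenly spaced rows, each rotated to the
#' local midline tangent, separated by darker disc gaps, over a mid-grey
#' (intensity 60) background with additive Gaussian noise clipped to [0, 255].
#' Rendering is deterministic given the spec's seed.
#'
#' @param spec A [midline_spec()].
#' @param epsilon,min_span Curve-detection convention used to derive the
#'   ground-truth segments (see [true_curve_segments()]).
#' @return A `phantom_case` object: list with `image` (matrix, grey levels
#'   0-255), `true_midline`, `true_centroids`, `true_segments`, `true_angles`
#'   (tibbles) and `spec`.
#' @examples
#' ph <- render_radiograph(midline_spec(curves = list(
#'   list(center_row = 400, half_span = 200, amplitude = 40))))
#' dim(ph$image)
#' @export
render_radiograph <- function(spec, epsilon = 2, min_span = 30) {
  stopifnot(inherits(spec, "midline_spec"))
  h <- spec$image_height; w <- spec$image_width
  bg <- 60; fg <- 200
  base <- matrix(bg, h, w)

  extent <- spec$column_bottom - spec$column_top + 1L
  pitch <- extent / spec$n_vertebrae
  gap <- min(8, pitch / 4)
  vh <- pitch - gap
  centers_row <- spec$column_top + (seq_len(spec$n_vertebrae) - 0.5) * pitch
  centers_x <- midline_fun(spec, centers_row)
  slopes <- midline_fun(spec, centers_row, derivative = TRUE)

  for (k in seq_len(spec$n_vertebrae)) {
    rk <- centers_row[k]; xk <- centers_x[k]; m <- slopes[k]
    norm <- sqrt(1 + m^2)
    half_r <- vh / 2 + spec$vertebra_width / 2 * abs(m) + 2
    half_c <- spec$vertebra_width / 2 + vh / 2 * abs(m) + 2
    rr <- max(0, floor(rk - half_r)):min(h - 1, ceiling(rk + half_r))
    cc <- max(0, floor(xk - half_c)):min(w - 1, ceiling(xk + half_c))
    dv <- rr - rk                      # along image rows
    du <- cc - xk                      # along image columns
    # longitudinal / transverse coordinates in the tilted vertebra frame
    lon <- (outer(dv, du * 0, `+`) + outer(dv * 0, du) * m) / norm
    tra <- (outer(dv * 0, du) - outer(dv, du * 0, `+`) * m) / norm
    inside <- abs(lon) <= vh / 2 & abs(tra) <= spec$vertebra_width / 2
    sub <- base[rr + 1, cc + 1]
    sub[inside] <- fg
    base[rr + 1, cc + 1] <- sub
  }

  img <- base
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    img <- img + matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w)
  }
  img <- round(pmin(pmax(img, 0), 255))  # matrix first: pmin/pmax keep its dim

  midline <- make_midline(spec)
  segs <- true_curve_segments(midline, epsilon = epsilon, min_span = min_span)
  # true apex of a raised-cosine curve is its center_row: snap apex rows of
  # segments that contain a curve centre
  if (nrow(segs) > 0 && length(spec$curves) > 0) {
    for (cv in spec$curves) {
      hit <- which(segs$start_row <= cv$center_row & segs$end_row >= cv$center_row)
      if (length(hit) == 1) segs$apex_row[hit] <- cv$center_row
    }
  }
  angles <- analytic_angles(midline, segs)
  structure(list(
    image = img,
    true_midline = midline,
    true_centroids = tibble::tibble(row = centers_row, x = centers_x),
    true_segments = segs,
    true_angles = angles,
    spec = spec
  ), class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %d x %d image, %d vertebrae, %d curve(s)\n",
              x$spec$image_height, x$spec$image_width,
              x$spec$n_vertebrae, length(x$spec$curves)))
  if (nrow(x$true_angles) > 0) {
    cobb <- dplyr::filter(x$true_angles, .data$method == "cobb")
    cat(sprintf("  analytic Cobb: %s deg\n",
                paste(round(cobb$value, 1), collapse = ", ")))
  } else {
    cat("  straight spine (no curve)\n")
  }
  invisible(x)
}

#' Mirror an image horizontally
#'
#' @param image Intensity matrix.
#' @return The matrix with column order reversed (left-right flip).
#' @export
mirror_image <- function(image) {
  image[, ncol(image):1, drop = FALSE]
}
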