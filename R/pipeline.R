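#' Pipeline configuration
#'
#' Every tunable of the end-to-end spinal-curvature pipeline, with the
#' defaults used throughout the package. All lengths are in pixels at the
#' 925 x 475 working scale.
#'
#' @param closing_radius Disc radius for morphological closing of the column
#'   mask (bridges inter-vertebral disc gaps).
#' @param erosion_radius Disc radius of the boundary inner gradient.
#' @param boundary_sigma Gaussian sigma (pixels) for contour smoothing.
#' @param fft_factor Fourier densification factor for the MA series (1 = off).
#' @param csl_anchor CSL anchor rule: `"bottom"` (S1 end, default), `"top"`,
#'   or `"mean"`.
#' @param epsilon Displacement tolerance (pixels) for curve detection.
#' @param min_span Minimum curve extent in rows.
#' @param tangent_half_window Half-window (rows) for MA tangent slopes; the
#'   default 36 nulls the least-squares slope filter at one vertebra pitch.
#' @param diab_band_height Vertebra band height (rows) for the Diab anchors,
#'   or `"auto"` for MA extent / 17.
#' @param disp_smooth_halfwidth Running-mean half-width (rows) applied to the
#'   displacement signal before curve detection; suppresses per-vertebra
#'   scalloping of the extracted MA (about half a vertebra pitch).
#' @param seed Integer seed recorded with the run (the pipeline itself is
#'   deterministic; the seed governs phantom generation in batch drivers).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(closing_radius = 5, erosion_radius = 1,
                            boundary_sigma = 3, fft_factor = 1L,
                            csl_anchor = c("bottom", "top", "mean"),
                            epsilon = 2, min_span = 30,
                            tangent_half_window = 36,
                            diab_band_height = "auto",
                            disp_smooth_halfwidth = 25, seed = 1L) {
  csl_anchor <- match.arg(csl_anchor)
  stopifnot(closing_radius >= 0, erosion_radius >= 1, boundary_sigma >= 0,
            fft_factor >= 1, epsilon > 0, min_span >= 1,
            tangent_half_window >= 1, disp_smooth_halfwidth >= 0)
  if (!identical(diab_band_height, "auto")) stopifnot(diab_band_height > 0)
  structure(list(
    closing_radius = closing_radius, erosion_radius = erosion_radius,
    boundary_sigma = boundary_sigma, fft_factor = as.integer(fft_factor),
    csl_anchor = csl_anchor, epsilon = epsilon, min_span = min_span,
    tangent_half_window = tangent_half_window,
    diab_band_height = diab_band_height,
    disp_smooth_halfwidth = disp_smooth_halfwidth, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read / write a pipeline configuration file (JSON)
#'
#' @param path File path.
#' @param config A [pipeline_config()].
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run the full spinal-curvature pipeline on a radiograph
#'
#' Orchestrates segmentation (optimum global threshold, closing, largest
#' component), boundary description (inner gradient, largest-boundary Moore
#' trace, Gaussian contour smoothing), axis extraction (medial axis, central
#' sacral line, displacement signal), landmark detection (curve segments with
#' SEV/AV/IEV and vertebral level labels) and curvature estimation by the
#' Cobb, Ferguson, Greenspan-index and Diab methods with severity grading.
#' Deterministic for a fixed image and configuration; a straight spine yields
#' an empty segment table and an explanatory note, not an error.
#'
#' @param image Intensity matrix in [0, 255] (e.g. from [read_radiograph()]
#'   or [render_radiograph()]`$image`).
#' @param config A [pipeline_config()].
#' @return A `spine_report` object: list with `threshold`, `mask`, `contour`,
#'   `ma`, `csl`, `disp` (raw displacement), `disp_smooth`, `segments`,
#'   `landmarks`, `angles`, `notes`, `config` and `image_dim`.
#' @examples
#' ph <- render_radiograph(midline_spec(curves = list(
#'   list(center_row = 400, half_span = 200, amplitude = 40))))
#' rep <- run_pipeline(ph$image)
#' rep$angles
#' @export
run_pipeline <- function(image, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_stage(name, conditionMessage(e))
    })
  }
  seg <- stage("segmentation", extract_spinal_column(image, config$closing_radius))
  band <- stage("boundary", boundary_pixels(seg$mask, config$erosion_radius))
  contour <- stage("boundary", select_largest_boundary(band))
  contour_s <- stage("boundary", smooth_boundary(contour, config$boundary_sigma))
  ma <- stage("axes", medial_axis(contour_s, config$fft_factor))
  csl <- stage("axes", central_sacral_line(ma, config$csl_anchor))
  disp <- stage("axes", displacement(ma, csl))
  disp_s <- disp
  if (config$disp_smooth_halfwidth > 0) {
    step <- if (nrow(disp) > 1) (disp$row[nrow(disp)] - disp$row[1]) / (nrow(disp) - 1) else 1
    hw <- max(1L, as.integer(round(config$disp_smooth_halfwidth / step)))
    disp_s$d <- running_mean(disp$d, hw)
    disp_s$ma_x <- disp_s$csl_x + disp_s$d
  }
  segments <- stage("landmarks",
                    detect_curves(disp_s, config$epsilon, config$min_span))
  if (nrow(segments) > 0) {
    for (i in seq_len(nrow(segments))) {
      segments$apex_row[i] <-
        apical_vertebra(disp_s, segments[i, ], refine = "parabolic")$row
    }
  }
  extent <- c(min(ma$row), max(ma$row))
  landmarks <- if (nrow(segments) > 0) {
    stage("landmarks", purrr::map_dfr(seq_len(nrow(segments)), function(i) {
      dplyr::bind_cols(
        tibble::tibble(segment = segments$segment[i]),
        segment_landmarks(disp_s, segments[i, ], column_extent = extent)
      )
    }))
  } else {
    tibble::tibble(segment = integer(), landmark = character(),
                   row = numeric(), x = numeric(), label = character())
  }
  angles <- stage("curvature", measure_curvature(
    ma, csl, segments,
    half_window = config$tangent_half_window,
    band_height = config$diab_band_height
  ))
  notes <- if (nrow(segments) == 0) {
    "no scoliotic curve (<10\u00b0): displacement never leaves the epsilon band"
  } else {
    character(0)
  }
  structure(list(
    image_dim = dim(image), threshold = seg$threshold, mask = seg$mask,
    contour = contour_s, ma = ma, csl = csl, disp = disp,
    disp_smooth = disp_s, segments = segments, landmarks = landmarks,
    angles = angles, notes = notes, config = config
  ), class = "spine_report")
}

#' @export
print.spine_report <- function(x, ...) {
  cat(sprintf("<spine_report> %d x %d image, threshold %d, %d segment(s)\n",
              x$image_dim[1], x$image_dim[2], x$threshold, nrow(x$segments)))
  if (nrow(x$angles) > 0) print(x$angles) else cat(" ", x$notes, "\n")
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' Serializes the tabular content of a `spine_report` (threshold, CSL,
#' segments, landmarks, angle reports, notes, configuration and the MA/CSL
#' displacement table) with fixed numeric precision, so identical runs give
#' byte-identical files.
#'
#' @param report A `spine_report`.
#' @param path Output .json path.
#' @param include_series Also embed the full per-row MA/CSL/displacement
#'   table (default TRUE).
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path, include_series = TRUE) {
  payload <- list(
    image_dim = report$image_dim,
    threshold = report$threshold,
    csl = report$csl,
    segments = report$segments,
    landmarks = report$landmarks,
    angles = report$angles,
    notes = report$notes,
    config = unclass(report$config)
  )
  if (include_series) payload$series <- report$disp
  json <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                           digits = 6, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}
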