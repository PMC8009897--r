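#' Tangent slope of the medial axis at a row
#'
#' Least-squares slope dx/drow of the MA over the window
#' `[row - half_window, row + half_window]` (clipped to the MA extent). This
#' operationalizes the endplate tangent of a vertebra for a centreline-based
#' pipeline: the local inclination of the spine at that level.
#'
#' @param ma Medial-axis tibble (`row`, `x`).
#' @param row Centre row of the window.
#' @param half_window Half-window in rows; the window must contain >= 3 MA
#'   samples.
#' @return Dimensionless slope (pixels of x per pixel of row).
#' @export
tangent_slope <- function(ma, row, half_window = 25) {
  j <- which(ma$row >= row - half_window & ma$row <= row + half_window)
  if (length(j) < 3) {
    stop("tangent window contains fewer than 3 MA samples", call. = FALSE)
  }
  rv <- ma$row[j] - mean(ma$row[j])
  sum(rv * ma$x[j]) / sum(rv^2)
}

#' Cobb angle of a curve segment
#'
#' The Cobb construction measures the angle between the endplate tangents of
#' the two most tilted (limiting) vertebrae of a curve. On the medial axis
#' this is the angle between the extreme tangent directions over the segment:
#' `max(atan(slope)) - min(atan(slope))` across the segment's rows, in
#' degrees, identical to the classical angle between the endplate
#' perpendiculars.
#'
#' @param ma Medial-axis tibble.
#' @param segment One-row segment (`start_row`, `end_row`, optionally
#'   `apex_row`).
#' @param half_window Tangent half-window in rows (see [tangent_slope()]).
#'   The default 36 places the first null of the least-squares slope filter
#'   at one vertebra pitch (~50 rows at the 925-row working scale), so
#'   per-vertebra scalloping of an extracted MA cancels while the anatomical
#'   curve is attenuated by under 1 percent.
#' @return One-row angle report tibble: `method`, `value` (degrees),
#'   `severity`.
#' @export
cobb_angle <- function(ma, segment, half_window = 36) {
  j <- which(ma$row >= segment$start_row & ma$row <= segment$end_row)
  if (length(j) < 3) stop("segment too short on the MA", call. = FALSE)
  # slopes are estimated with windows drawn from the full MA so that every
  # segment row gets a two-sided window (one-sided windows let per-vertebra
  # scalloping leak through the slope filter)
  jw <- which(ma$row >= segment$start_row - half_window &
              ma$row <= segment$end_row + half_window)
  slopes <- rolling_slope(ma$row[jw], ma$x[jw], half_window)
  keep <- ma$row[jw] >= segment$start_row & ma$row[jw] <= segment$end_row
  theta <- atan(slopes[keep])
  value <- deg(max(theta) - min(theta))
  angle_report("cobb", value)
}

#' Ferguson angle from the three landmark centres
#'
#' Angle construction from the lines joining the end-vertebra centres to the
#' apical-vertebra centre: `180 deg` minus the interior angle at the apex, so
#' collinear landmarks (a straight spine) score 0.
#'
#' @param sev,av,iev Landmark centres as numeric `c(row, x)`.
#' @return One-row angle report tibble.
#' @export
ferguson_angle <- function(sev, av, iev) {
  sev <- as.numeric(sev); av <- as.numeric(av); iev <- as.numeric(iev)
  value <- 180 - vertex_angle(av, sev, iev)
  angle_report("ferguson", value)
}

#' Greenspan deformity index of a curve segment
#'
#' Cumulative normalized displacement of the vertebral centres from the global
#' axis: the sum of |d| over the segment's MA samples divided by the
#' Euclidean distance between the MA points at the segment's ends.
#' Dimensionless (both numerator and denominator are lengths; scaling the
#' whole geometry cancels); no severity band applies.
#'
#' @param ma Medial-axis tibble.
#' @param csl One-row CSL tibble.
#' @param segment One-row segment.
#' @return One-row angle report tibble (`severity` is `NA`).
#' @export
greenspan_index <- function(ma, csl, segment) {
  j <- which(ma$row >= segment$start_row & ma$row <= segment$end_row)
  if (length(j) < 2) stop("segment too short on the MA", call. = FALSE)
  rows <- ma$row[j]; x <- ma$x[j]
  p1 <- c(rows[1], x[1]); p2 <- c(rows[length(rows)], x[length(rows)])
  L <- sqrt(sum((p2 - p1)^2))
  if (L == 0) stop("degenerate segment: zero end-to-end length", call. = FALSE)
  value <- sum(abs(x - csl$x)) / L
  angle_report("greenspan", value, severity = NA_character_)
}

#' Diab angle of a curve segment
#'
#' Apex-centred angle construction whose end anchors are the mean MA points
#' over the three successive vertebra-height bands at each curve end (upper
#' anchor: three bands inward from the superior end; lower anchor: three bands
#' inward from the inferior end). The value is `180 deg` minus the interior
#' angle at the apical-vertebra centre between the rays to the two anchors, so
#' collinear geometry scores 0.
#'
#' @param ma Medial-axis tibble.
#' @param segment One-row segment (`start_row`, `apex_row`, `end_row`).
#' @param band_height Height of one nominal vertebra in rows; default
#'   (`"auto"`) is the MA extent divided by 17.
#' @return One-row angle report tibble.
#' @export
diab_angle <- function(ma, segment, band_height = "auto") {
  if (identical(band_height, "auto")) {
    band_height <- (max(ma$row) - min(ma$row) + 1) / 17
  }
  three <- 3 * band_height
  if (segment$start_row + three > segment$end_row - three + 1) {
    stop("segment too short for three vertebra bands at each end", call. = FALSE)
  }
  upper_j <- which(ma$row >= segment$start_row & ma$row < segment$start_row + three)
  lower_j <- which(ma$row > segment$end_row - three & ma$row <= segment$end_row)
  if (length(upper_j) < 2 || length(lower_j) < 2) {
    stop("segment too short for three vertebra bands at each end", call. = FALSE)
  }
  upper <- c(mean(ma$row[upper_j]), mean(ma$x[upper_j]))
  lower <- c(mean(ma$row[lower_j]), mean(ma$x[lower_j]))
  k <- which.min(abs(ma$row - segment$apex_row))
  apex <- c(ma$row[k], ma$x[k])
  value <- 180 - vertex_angle(apex, upper, lower)
  angle_report("diab", value)
}

#' Severity grade of a curvature angle
#'
#' Standard clinical bands for a lateral curvature angle on an AP radiograph:
#' below 10 degrees is not scoliosis (`normal`), 10 to below 20 is `mild`,
#' 20 to below 40 is `moderate`, 40 and above is `severe`.
#'
#' @param angle Angle(s) in degrees, >= 0.
#' @return Character vector of severity categories.
#' @examples
#' classify_severity(c(5, 15, 30, 45))
#' @export
classify_severity <- function(angle) {
  if (any(angle < 0)) stop("angle must be non-negative", call. = FALSE)
  cut(angle, breaks = c(-Inf, 10, 20, 40, Inf), right = FALSE,
      labels = c("normal", "mild", "moderate", "severe")) |> as.character()
}

angle_report <- function(method, value, severity = classify_severity(value)) {
  tibble::tibble(method = method, value = value, severity = severity)
}

#' Measure curvature of detected segments by all four methods
#'
#' Convenience wrapper running the Cobb, Ferguson, Greenspan-index and Diab
#' constructions on each curve segment of a medial axis.
#'
#' @param ma Medial-axis tibble.
#' @param csl One-row CSL tibble.
#' @param segments Segment tibble (from [detect_curves()] or
#'   [true_curve_segments()]); an `apex_row` column is required (computed from
#'   the displacement signal if absent).
#' @param methods Subset of `c("cobb", "ferguson", "greenspan", "diab")`.
#' @param half_window Tangent half-window in rows for the Cobb method.
#' @param band_height Vertebra band height for the Diab method (`"auto"`:
#'   MA extent / 17).
#' @return Tibble with columns `segment`, `method`, `value`, `severity`. A
#'   method inapplicable to a segment (e.g. Diab on a curve too short for
#'   three vertebra bands at each end) yields `NA` for that row rather than
#'   failing the whole report.
#' @export
measure_curvature <- function(ma, csl, segments,
                              methods = c("cobb", "ferguson", "greenspan", "diab"),
                              half_window = 36, band_height = "auto") {
  methods <- match.arg(methods, several.ok = TRUE)
  if (nrow(segments) == 0) {
    return(tibble::tibble(segment = integer(), method = character(),
                          value = numeric(), severity = character()))
  }
  disp <- displacement(ma, csl)
  purrr::map_dfr(seq_len(nrow(segments)), function(i) {
    seg <- segments[i, ]
    if (is.null(seg$apex_row) || is.na(seg$apex_row)) {
      seg$apex_row <- apical_vertebra(disp, seg)$row
    }
    ma_at <- function(r) {
      k <- which.min(abs(ma$row - r)); c(ma$row[k], ma$x[k])
    }
    reports <- purrr::map(methods, function(m) {
      tryCatch(
        switch(m,
          cobb = cobb_angle(ma, seg, half_window = half_window),
          ferguson = ferguson_angle(ma_at(seg$start_row), ma_at(seg$apex_row),
                                    ma_at(seg$end_row)),
          greenspan = greenspan_index(ma, csl, seg),
          diab = diab_angle(ma, seg, band_height = band_height)
        ),
        error = function(e) angle_report(m, NA_real_, NA_character_)
      )
    })
    dplyr::bind_cols(
      tibble::tibble(segment = rep(seg$segment %||% i, length(methods))),
      dplyr::bind_rows(reports)
    )
  })
}
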