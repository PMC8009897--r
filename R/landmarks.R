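#' Detect scoliotic curves from the displacement signal
#'
#' Scans the MA-CSL displacement series top to bottom. A curve opens at the
#' first row where |d| exceeds `epsilon` (its superior end vertebra row is the
#' last row before the exceedance) and closes at the next row where |d|
#' returns to <= `epsilon` (the inferior end vertebra row). A sign change of d
#' without an intervening sub-threshold row also closes the current segment
#' and opens the next, which is what separates the two limbs of an S-shaped
#' double curve. Segments spanning fewer than `min_span` rows are discarded as
#' noise blips. A curve still open at the last row is closed there and flagged
#' `truncated`.
#'
#' @param disp Displacement tibble from [displacement()] (columns `row`,
#'   `ma_x`, `csl_x`, `d`).
#' @param epsilon Displacement tolerance in pixels (> 0) deciding when MA and
#'   CSL X-coordinates "overlap".
#' @param min_span Minimum segment extent in rows.
#' @return Tibble with one row per curve, superior to inferior: `segment`,
#'   `start_row`, `apex_row`, `end_row`, `direction` (sign of d at the apex),
#'   `max_displacement` (|d| at the apex), `truncated`. Zero rows mean a
#'   straight (non-scoliotic) spine.
#' @export
detect_curves <- function(disp, epsilon = 2, min_span = 30) {
  stopifnot(nrow(disp) > 0, epsilon > 0)
  d <- disp$d
  rows <- disp$row
  n <- length(d)
  state <- ifelse(abs(d) <= epsilon, 0L, as.integer(sign(d)))
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  segs <- list()
  for (i in seq_along(runs$values)) {
    if (runs$values[i] == 0L) next
    i1 <- starts[i]; i2 <- ends[i]
    start_row <- if (i1 > 1L) rows[i1 - 1L] else rows[i1]
    trunc_start <- i1 == 1L
    if (i2 < n) {
      # close where |d| re-enters the tolerance band; on a direct sign flip
      # (no sub-threshold row in between) close at the last row of this run
      end_row <- if (state[i2 + 1L] == 0L) rows[i2 + 1L] else rows[i2]
      truncated <- FALSE
    } else {
      end_row <- rows[n]
      truncated <- TRUE
    }
    if (end_row - start_row < min_span) next
    j <- i1:i2
    apex_j <- j[which.max(abs(d[j]))]   # ties -> smallest row (first max)
    segs[[length(segs) + 1L]] <- tibble::tibble(
      start_row = start_row,
      apex_row = rows[apex_j],
      end_row = end_row,
      direction = as.integer(sign(d[apex_j])),
      max_displacement = abs(d[apex_j]),
      truncated = truncated || trunc_start
    )
  }
  out <- dplyr::bind_rows(segs)
  if (nrow(out) == 0) {
    return(tibble::tibble(segment = integer(), start_row = numeric(),
                          apex_row = numeric(), end_row = numeric(),
                          direction = integer(), max_displacement = numeric(),
                          truncated = logical()))
  }
  dplyr::bind_cols(tibble::tibble(segment = seq_len(nrow(out))), out)
}

#' Apical vertebra of a curve
#'
#' The apical vertebra is the one displaced farthest laterally from the
#' central sacral line: the row maximizing |d| over the segment (ties broken
#' toward the smallest row), with the medial-axis X-coordinate there.
#'
#' @param disp Displacement tibble (`row`, `ma_x`, `d`).
#' @param segment One-row segment (list or tibble row with `start_row`,
#'   `end_row`).
#' @param refine `"none"` (default) returns the raw argmax row;
#'   `"parabolic"` additionally fits a quadratic to |d| over +/- 40 rows
#'   around the argmax and returns the vertex row (clamped to the segment),
#'   which stabilizes the apex against the flat top of a wide curve.
#' @return One-row tibble with `row`, `x`.
#' @export
apical_vertebra <- function(disp, segment, refine = c("none", "parabolic")) {
  refine <- match.arg(refine)
  j <- which(disp$row >= segment$start_row & disp$row <= segment$end_row)
  stopifnot(length(j) > 0)
  k <- j[which.max(abs(disp$d[j]))]
  row <- disp$row[k]
  if (refine == "parabolic") {
    w <- j[disp$row[j] >= row - 40 & disp$row[j] <= row + 40]
    if (length(w) >= 5) {
      rv <- disp$row[w]
      fit <- stats::lm.fit(cbind(1, rv, rv^2), abs(disp$d[w]))
      a2 <- fit$coefficients[3]; a1 <- fit$coefficients[2]
      if (is.finite(a2) && a2 < 0) {
        vertex <- -a1 / (2 * a2)
        row <- min(max(vertex, segment$start_row), segment$end_row)
        k <- j[which.min(abs(disp$row[j] - row))]
        row <- disp$row[k]
      }
    }
  }
  tibble::tibble(row = row, x = disp$ma_x[k])
}

VERTEBRA_LEVELS <- c(paste0("T", 1:12), paste0("L", 1:5))

#' Assign vertebral level labels to landmarks
#'
#' Divides the column extent into 17 equal-height bands named T1..T12, L1..L5
#' (12 thoracic + 5 lumbar vertebrae, the region scoliosis affects) and labels
#' each landmark with the band containing its row. An admitted simplification
#' (real vertebral heights vary); the labels feed inter-rater agreement
#' bookkeeping, never angle geometry.
#'
#' @param landmarks Tibble with a `row` column (e.g. SEV/AV/IEV rows).
#' @param column_extent Numeric `c(top_row, bottom_row)` of the column.
#' @return `landmarks` with a `label` character column added.
#' @export
label_vertebrae <- function(landmarks, column_extent) {
  top <- column_extent[1]; bottom <- column_extent[2]
  stopifnot(bottom > top)
  if (any(landmarks$row < top | landmarks$row > bottom)) {
    stop("landmark row outside the column extent", call. = FALSE)
  }
  band <- floor((landmarks$row - top) / (bottom - top + 1) * 17) + 1
  band <- pmin(17, pmax(1, band))
  landmarks$label <- VERTEBRA_LEVELS[band]
  landmarks
}

# LandmarkSet for one curve segment: SEV/AV/IEV rows with MA x-coordinates.
# Uses the segment's apex_row when present (it may carry a refined apex).
segment_landmarks <- function(disp, segment, column_extent = NULL) {
  ma_at <- function(r) disp$ma_x[which.min(abs(disp$row - r))]
  av_row <- if (!is.null(segment$apex_row) && !is.na(segment$apex_row)) {
    segment$apex_row
  } else {
    apical_vertebra(disp, segment)$row
  }
  lm <- tibble::tibble(
    landmark = c("SEV", "AV", "IEV"),
    row = c(segment$start_row, av_row, segment$end_row),
    x = c(ma_at(segment$start_row), ma_at(av_row), ma_at(segment$end_row))
  )
  if (!is.null(column_extent)) lm <- label_vertebrae(lm, column_extent)
  lm
}
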