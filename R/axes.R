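#' Left/right boundary crossings at a row
#'
#' For a closed contour, every occupied row has two X-values where the
#' boundary is crossed; this returns the outermost pair (minimum and maximum
#' contour column at that row), which is also the rule applied when a
#' concavity makes the contour cross a row more than twice.
#'
#' @param contour Tibble with columns `row`, `col`.
#' @param row Row (0-based) to query.
#' @return Named numeric vector `c(x_left, x_right)`.
#' @export
row_crossings <- function(contour, row) {
  cols <- contour$col[contour$row == row]
  if (length(cols) == 0) {
    stop(sprintf("no contour point at row %s", format(row)), call. = FALSE)
  }
  c(x_left = min(cols), x_right = max(cols))
}

#' Medial axis of the spinal column
#'
#' The medial axis (MA) is the curve through the centroids of the vertebral
#' bodies; on the traced column boundary it is computed per row as the average
#' of the two outermost boundary X-values, `x = (x_left + x_right) / 2`. Rows
#' inside the contour's vertical extent with no contour point are filled by
#' linear interpolation between neighbouring rows. Optionally the series is
#' densified by Fourier interpolation ([fft_interpolate()]).
#'
#' @param contour Closed contour tibble (`row`, `col`) spanning >= 20 rows.
#' @param fft_factor Integer >= 1; values > 1 resample the MA series to
#'   `fft_factor` times as many (fractional) rows.
#' @return Tibble with columns `row` (strictly increasing) and `x`.
#' @export
medial_axis <- function(contour, fft_factor = 1L) {
  rows_present <- sort(unique(contour$row))
  top <- min(rows_present); bottom <- max(rows_present)
  if (bottom - top + 1 < 20) {
    stop("column too short: contour spans fewer than 20 rows", call. = FALSE)
  }
  f <- factor(contour$row, levels = rows_present)
  mid <- (as.numeric(tapply(contour$col, f, min)) +
          as.numeric(tapply(contour$col, f, max))) / 2
  all_rows <- top:bottom
  x <- stats::approx(rows_present, mid, xout = all_rows, method = "linear")$y
  if (fft_factor > 1L) {
    x2 <- fft_interpolate(x, fft_factor)
    rows2 <- top + (seq_along(x2) - 1) / fft_factor
    return(tibble::tibble(row = rows2, x = x2))
  }
  tibble::tibble(row = as.numeric(all_rows), x = x)
}

#' Central sacral line
#'
#' The central sacral line (CSL) is the vertical global-axis reference of the
#' spine, running from the C1 region to S1. Because a vertical line has a
#' single X-coordinate, it is anchored on the medial axis: by default at the
#' inferior (S1-end) sample, since the sacral end defines the global axis
#' clinically; anchoring at the top (C1-end) sample or at the mean MA
#' X-coordinate is available as an option.
#'
#' @param ma Medial-axis tibble (`row`, `x`), non-empty.
#' @param anchor One of `"bottom"` (default), `"top"`, `"mean"`.
#' @return One-row tibble with columns `x`, `top_row`, `bottom_row`.
#' @export
central_sacral_line <- function(ma, anchor = c("bottom", "top", "mean")) {
  if (nrow(ma) == 0) stop("medial axis is empty", call. = FALSE)
  anchor <- match.arg(anchor)
  x <- switch(anchor,
    bottom = ma$x[which.max(ma$row)],
    top = ma$x[which.min(ma$row)],
    mean = mean(ma$x)
  )
  tibble::tibble(x = x, top_row = min(ma$row), bottom_row = max(ma$row))
}

#' MA-CSL displacement series
#'
#' The per-row signed lateral displacement of the medial axis from the central
#' sacral line, `d(row) = MA_x(row) - CSL_x`; positive values mean the MA lies
#' to the right of the CSL in image coordinates. This signal carries the whole
#' deformity: its excursions are the scoliotic curves and its extrema their
#' apices.
#'
#' @param ma Medial-axis tibble (`row`, `x`).
#' @param csl One-row CSL tibble from [central_sacral_line()].
#' @return Tibble with columns `row`, `ma_x`, `csl_x`, `d` restricted to the
#'   CSL's `[top_row, bottom_row]` extent.
#' @export
displacement <- function(ma, csl) {
  keep <- ma$row >= csl$top_row & ma$row <= csl$bottom_row
  if (!any(keep)) stop("MA and CSL extents do not overlap", call. = FALSE)
  tibble::tibble(
    row = ma$row[keep],
    ma_x = ma$x[keep],
    csl_x = csl$x,
    d = ma$x[keep] - csl$x
  )
}
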