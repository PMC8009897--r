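#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a spine report into one row per segment and method
#'
#' @param x A `spine_report` from [run_pipeline()].
#' @param ... Unused.
#' @return Tibble joining the angle reports with the segment geometry:
#'   `segment`, `method`, `value`, `severity`, `start_row`, `apex_row`,
#'   `end_row`, `direction`.
#' @method tidy spine_report
#' @export
tidy.spine_report <- function(x, ...) {
  if (nrow(x$angles) == 0) return(x$angles)
  dplyr::left_join(
    x$angles,
    dplyr::select(x$segments, "segment", "start_row", "apex_row",
                  "end_row", "direction"),
    by = "segment"
  )
}

#' One-row summary of a spine report
#'
#' @param x A `spine_report`.
#' @param ... Unused.
#' @return One-row tibble: `n_segments`, `cobb_max` (largest Cobb value, NA
#'   for a straight spine), `severity` (grade of `cobb_max`, `"normal"` when
#'   no curve was detected), `threshold`, `csl_x`, `ma_rows`.
#' @method glance spine_report
#' @export
glance.spine_report <- function(x, ...) {
  cobb <- x$angles$value[x$angles$method == "cobb"]
  cobb_max <- if (length(cobb)) max(cobb) else NA_real_
  tibble::tibble(
    n_segments = nrow(x$segments),
    cobb_max = cobb_max,
    severity = if (is.na(cobb_max)) "normal" else classify_severity(cobb_max),
    threshold = x$threshold,
    csl_x = x$csl$x,
    ma_rows = nrow(x$ma)
  )
}

#' Tidy a phantom case into its ground-truth angle table
#'
#' @param x A `phantom_case` from [render_radiograph()].
#' @param ... Unused.
#' @return The `true_angles` tibble joined with the true segment geometry.
#' @method tidy phantom_case
#' @export
tidy.phantom_case <- function(x, ...) {
  if (nrow(x$true_angles) == 0) return(x$true_angles)
  dplyr::left_join(
    x$true_angles,
    dplyr::select(x$true_segments, "segment", "start_row", "apex_row",
                  "end_row", "direction"),
    by = "segment"
  )
}
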