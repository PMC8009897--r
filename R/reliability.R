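#' Inter-rater contingency table
#'
#' K x K cross-tabulation of two raters' categorical labels over the same
#' ordered cases, on the union of the two label alphabets. Row and column
#' sums each total the number of cases.
#'
#' @param a,b Equal-length character (or factor) label vectors, one entry per
#'   case, in the same case order.
#' @return Integer matrix; rows index rater a's labels, columns rater b's.
#' @export
agreement_table <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (length(a) != length(b)) stop("raters must label the same cases", call. = FALSE)
  if (length(a) < 2) stop("need at least 2 cases", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("missing labels are not allowed", call. = FALSE)
  alphabet <- sort(unique(c(a, b)))
  table(factor(a, levels = alphabet), factor(b, levels = alphabet)) |>
    unclass()
}

#' Cohen's kappa for inter-rater landmark agreement
#'
#' Chance-corrected agreement between two raters assigning categorical labels
#' (e.g. the vertebral level chosen as SEV) to the same cases:
#' `kappa = (p_o - p_e) / (1 - p_e)`, where `p_o` is the observed fraction of
#' identical labels and `p_e` the agreement expected by chance from the two
#' raters' marginal label frequencies. Unweighted (labels treated as
#' nominal).
#'
#' The reported `interpretation` uses conventional bands (reporting only, no
#' computation depends on it): values of 0.7-0.9 indicate good agreement.
#'
#' @inheritParams agreement_table
#' @return One-row tibble: `n_cases`, `p_o`, `p_e`, `kappa`,
#'   `interpretation`.
#' @examples
#' cohen_kappa(c("X", "X", "Y", "Y"), c("X", "Y", "X", "Y"))  # kappa = 0
#' @export
cohen_kappa <- function(a, b) {
  tab <- agreement_table(a, b)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (p_e >= 1) {
    stop("kappa undefined: both raters constant on the same label", call. = FALSE)
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  tibble::tibble(
    n_cases = n, p_o = p_o, p_e = p_e, kappa = kappa,
    interpretation = kappa_band(kappa)
  )
}

kappa_band <- function(kappa) {
  dplyr::case_when(
    kappa < 0.2 ~ "poor",
    kappa < 0.4 ~ "fair",
    kappa < 0.7 ~ "moderate",
    kappa < 0.9 ~ "good",
    TRUE ~ "excellent"
  )
}

#' Mean absolute difference between paired angle measurements
#'
#' Summary of inter-observer or inter-method disagreement on continuous
#' angles: the mean over cases of `|x_i - y_i|`, in the input's units
#' (degrees).
#'
#' @param x,y Equal-length numeric vectors of per-case angle values.
#' @return Single non-negative number.
#' @examples
#' mean_absolute_difference(c(10, 20), c(12, 17))  # 2.5
#' @export
mean_absolute_difference <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 1) stop("need at least one case", call. = FALSE)
  mean(abs(x - y))
}

#' Read rater label CSVs
#'
#' Reads a per-case landmark label file with columns `case_id`, `landmark`,
#' `label` (one row per case and landmark), the exchange format for
#' inter-rater agreement studies.
#'
#' @param path CSV file path.
#' @param landmark Optional filter: keep only rows for this landmark
#'   (`"SEV"`, `"IEV"` or `"AV"`).
#' @return Tibble ordered by `case_id`.
#' @export
read_rater_labels <- function(path, landmark = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "landmark", "label")
  if (!all(need %in% names(df))) {
    stop("label CSV needs columns case_id, landmark, label", call. = FALSE)
  }
  if (!is.null(landmark)) df <- df[df$landmark == landmark, , drop = FALSE]
  tibble::as_tibble(df[order(df$case_id), need])
}
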