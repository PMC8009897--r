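analytic_disp <- function(spec) {
  ml <- make_midline(spec)
  displacement(ml, central_sacral_line(ml))
}

test_that("zero displacement yields no curves", {
  disp <- tibble::tibble(row = 0:200, ma_x = 237, csl_x = 237, d = 0)
  expect_equal(nrow(detect_curves(disp)), 0)
})

test_that("a single bump gives one segment near the analytic bounds", {
  spec <- single_curve_spec(40, noise_sigma = 10, seed = 4)
  truth <- true_curve_segments(make_midline(spec))
  rep <- get_report(render_radiograph(spec)$image, "a40_s4")
  segs <- rep$segments
  expect_equal(nrow(segs), 1)
  expect_lte(abs(segs$start_row - truth$start_row), 10)
  expect_lte(abs(segs$end_row - truth$end_row), 10)
  expect_lte(abs(segs$apex_row - 400), 10)
})

test_that("an S-shaped spine gives two segments of opposite direction", {
  spec <- double_curve_spec(35, noise_sigma = 10, seed = 5)
  rep <- get_report(render_radiograph(spec)$image, "dbl_s5")
  segs <- rep$segments
  expect_equal(nrow(segs), 2)
  expect_equal(segs$direction, c(1L, -1L))
  expect_lte(abs(segs$apex_row[1] - 280), 10)
  expect_lte(abs(segs$apex_row[2] - 620), 10)
})

test_that("apex follows the argmax with smallest-row tie-break", {
  seg <- tibble::tibble(start_row = 0, end_row = 100)
  ramp <- tibble::tibble(row = 0:100, ma_x = 237 + 0:100, csl_x = 237, d = 0:100)
  expect_equal(apical_vertebra(ramp, seg)$row, 100)   # max at the boundary
  plateau <- tibble::tibble(row = 0:100, csl_x = 237,
                            d = pmin(0:100, 50))
  plateau$ma_x <- plateau$csl_x + plateau$d
  expect_equal(apical_vertebra(plateau, seg)$row, 50) # first of the plateau
})

test_that("segments below the minimum span are discarded", {
  d <- rep(0, 200); d[50:60] <- 5; d[100:180] <- 5
  disp <- tibble::tibble(row = 0:199, ma_x = 237 + d, csl_x = 237, d = d)
  segs <- detect_curves(disp, epsilon = 2, min_span = 30)
  expect_equal(nrow(segs), 1)
  expect_gte(segs$start_row, 98)
})

test_that("a curve running off the column end is closed and flagged truncated", {
  d <- c(rep(0, 100), seq(0, 30, length.out = 100))
  disp <- tibble::tibble(row = 0:199, ma_x = 237 + d, csl_x = 237, d = d)
  segs <- detect_curves(disp, epsilon = 2, min_span = 30)
  expect_equal(nrow(segs), 1)
  expect_true(segs$truncated)
  expect_equal(segs$end_row, 199)
})

test_that("shrinking epsilon never decreases the curve count", {
  for (spec in list(single_curve_spec(40, noise_sigma = 0),
                    double_curve_spec(35, noise_sigma = 0))) {
    disp <- analytic_disp(spec)
    counts <- vapply(c(8, 4, 2, 1, 0.5), function(eps) {
      nrow(detect_curves(disp, epsilon = eps))
    }, numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("segments tile the displacement extent without overlap", {
  disp <- analytic_disp(double_curve_spec(35, noise_sigma = 0))
  segs <- detect_curves(disp)
  expect_true(all(diff(segs$start_row) > 0))
  expect_true(all(segs$end_row[-nrow(segs)] <= segs$start_row[-1]))
  expect_true(all(segs$start_row < segs$apex_row & segs$apex_row < segs$end_row))
})

test_that("mirroring flips directions but preserves rows", {
  disp <- analytic_disp(double_curve_spec(35, noise_sigma = 0))
  mirrored <- disp
  mirrored$d <- -disp$d
  mirrored$ma_x <- mirrored$csl_x + mirrored$d
  a <- detect_curves(disp); b <- detect_curves(mirrored)
  expect_equal(b$start_row, a$start_row)
  expect_equal(b$end_row, a$end_row)
  expect_equal(b$direction, -a$direction)
})

test_that("vertebral level labels follow the 17-band split", {
  lm <- tibble::tibble(landmark = "AV", row = 500, x = 237)
  expect_equal(label_vertebrae(lm, c(0, 999))$label, "T9")   # midpoint -> T9
  expect_equal(label_vertebrae(tibble::tibble(row = 0), c(0, 999))$label, "T1")
  expect_equal(label_vertebrae(tibble::tibble(row = 999), c(0, 999))$label, "L5")
  expect_error(label_vertebrae(tibble::tibble(row = 1500), c(0, 999)), "extent")
})

test_that("phantom centroids get their own vertebra labels back", {
  ph <- get_phantom(single_curve_spec(40, noise_sigma = 0), "a40_clean")
  cen <- tibble::tibble(row = ph$true_centroids$row)
  lab <- label_vertebrae(cen, c(ph$spec$column_top, ph$spec$column_bottom))
  levels <- c(paste0("T", 1:12), paste0("L", 1:5))
  expect_gte(sum(lab$label == levels), 15)
})
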