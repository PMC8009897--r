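test_that("midline is the baseline plus raised-cosine bumps", {
  straight <- midline_spec(noise_sigma = 0)
  ml <- make_midline(straight)
  expect_true(all(ml$x == straight$baseline_x))

  spec <- single_curve_spec(40, half_span = 200, center_row = 400)
  ml <- make_midline(spec)
  expect_equal(ml$x[ml$row == 400], spec$baseline_x + 40)
  expect_equal(ml$x[ml$row == 200], spec$baseline_x)  # span edge
  expect_equal(ml$x[ml$row == 600], spec$baseline_x)
  expect_equal(ml$x[ml$row == 100], spec$baseline_x)  # outside the span
})

test_that("midline slope maximum matches the closed-form derivative", {
  spec <- single_curve_spec(40, half_span = 200)
  ml <- make_midline(spec)
  # dense finite differences over all rows as the independent oracle
  fd <- diff(ml$x) / diff(ml$row)
  expect_equal(max(abs(fd)), pi * 40 / (2 * 200), tolerance = 1e-4)
})

test_that("invalid midline specs are rejected", {
  expect_error(midline_spec(curves = list(
    list(center_row = 300, half_span = 150, amplitude = 10),
    list(center_row = 400, half_span = 150, amplitude = -10)
  )), "overlap")
  expect_error(midline_spec(curves = list(
    list(center_row = 50, half_span = 100, amplitude = 10)
  )), "within")
  expect_error(midline_spec(baseline_x = 450, curves = list(
    list(center_row = 400, half_span = 100, amplitude = 30)
  )), "leaves the image")
})

test_that("analytic angles are zero for a straight spine and errors are typed", {
  ml <- make_midline(midline_spec())
  expect_equal(nrow(true_curve_segments(ml)), 0)
  seg <- forced_full_segment(ml)
  ang <- analytic_angles(ml, seg)
  expect_true(all(ang$value == 0))
  bad <- tibble::tibble(segment = 1L, start_row = 300, apex_row = 300, end_row = 300)
  expect_error(analytic_angles(ml, bad), "degenerate")
})

test_that("analytic Cobb equals twice the arctangent of the maximal slope", {
  spec <- single_curve_spec(40, half_span = 200)
  ml <- make_midline(spec)
  segs <- true_curve_segments(ml)
  closed_form <- 2 * atan(40 * pi / (2 * 200)) * 180 / pi
  # near-exact with a small tangent window; within the filter attenuation at
  # the default window
  cobb_tight <- analytic_angles(ml, segs, half_window = 5)
  expect_equal(cobb_tight$value[cobb_tight$method == "cobb"], closed_form,
               tolerance = 0.005)
  cobb_def <- analytic_angles(ml, segs)
  expect_equal(cobb_def$value[cobb_def$method == "cobb"], closed_form,
               tolerance = 0.04)
})

test_that("doubling a small amplitude approximately doubles the Cobb value", {
  vals <- vapply(c(10, 20), function(a) {
    ml <- make_midline(single_curve_spec(a, half_span = 200))
    segs <- true_curve_segments(ml)
    ang <- analytic_angles(ml, segs)
    ang$value[ang$method == "cobb"]
  }, numeric(1))
  expect_equal(vals[2] / vals[1], 2, tolerance = 0.05)
})

test_that("amplitude_for_cobb inverts the analytic Cobb relation", {
  a <- amplitude_for_cobb(25, half_span = 200)
  ml <- make_midline(single_curve_spec(a, half_span = 200))
  segs <- true_curve_segments(ml)
  ang <- analytic_angles(ml, segs, half_window = 5)
  expect_equal(ang$value[ang$method == "cobb"], 25, tolerance = 0.1)
})

test_that("rendering is deterministic and respects the noise model", {
  spec <- single_curve_spec(40, noise_sigma = 10, seed = 42)
  ph1 <- render_radiograph(spec)
  ph2 <- render_radiograph(spec)
  expect_identical(ph1$image, ph2$image)

  clean <- render_radiograph(single_curve_spec(40, noise_sigma = 0))
  expect_true(all(clean$image %in% c(60, 200)))

  noisy <- render_radiograph(single_curve_spec(40, noise_sigma = 30, seed = 3))
  fg <- clean$image == 200   # true vertebra footprint (same geometry)
  expect_gt(mean(noisy$image[fg]), mean(noisy$image[!fg]))
})

test_that("negating amplitudes mirrors the noise-free image exactly", {
  a <- 35
  ph_pos <- render_radiograph(single_curve_spec(a, noise_sigma = 0))
  ph_neg <- render_radiograph(single_curve_spec(-a, noise_sigma = 0))
  expect_identical(ph_neg$image, mirror_image(ph_pos$image))
})

test_that("phantom ground truth is internally consistent", {
  ph <- get_phantom(single_curve_spec(40, seed = 7), "a40_s7")
  expect_true(all(diff(ph$true_midline$row) > 0))
  expect_true(all(diff(ph$true_centroids$row) > 0))
  expect_equal(nrow(ph$true_segments), 1)
  expect_equal(ph$true_segments$apex_row, 400)
  straight <- render_radiograph(midline_spec(noise_sigma = 0))
  expect_equal(nrow(straight$true_segments), 0)
})
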