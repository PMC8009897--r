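test_that("tangent slope is exact on linear medial axes", {
  vert <- tibble::tibble(row = 0:100, x = 237)
  expect_equal(tangent_slope(vert, 50), 0)
  lin <- tibble::tibble(row = 0:100, x = 0.5 * (0:100))
  expect_equal(tangent_slope(lin, 50), 0.5)
  expect_equal(tangent_slope(lin, 0), 0.5)        # clipped window still exact
  expect_error(tangent_slope(lin[c(1, 50, 90), ], 50, half_window = 2), "fewer")
})

test_that("tangent slope matches the analytic derivative on a raised cosine", {
  spec <- single_curve_spec(40, half_span = 200)
  ml <- make_midline(spec)
  for (r in c(300, 350, 450, 500)) {
    truth <- -40 * pi / (2 * 200) * sin(pi * (r - 400) / 200)
    expect_equal(tangent_slope(ml, r, half_window = 15), truth,
                 tolerance = 0.02)
  }
})

test_that("Cobb angle recovers constructed tangent geometry", {
  # V-shaped midline: tangents at +/-15 degrees from vertical -> 30 degrees
  s <- tan(15 * pi / 180)
  x <- c(seq(0, 100 * s, length.out = 101), seq(100 * s, 0, length.out = 101)[-1])
  ma <- tibble::tibble(row = 0:200, x = 237 + x)
  seg <- tibble::tibble(segment = 1L, start_row = 0, apex_row = 100, end_row = 200)
  est <- cobb_angle(ma, seg, half_window = 10)
  expect_equal(est$value, 30, tolerance = 0.5)
})

test_that("pipeline Cobb agrees with the analytic oracle across noise seeds", {
  for (seed in 1:3) {
    spec <- single_curve_spec(amplitude_for_cobb(25, 200), noise_sigma = 10,
                              seed = seed)
    ph <- render_radiograph(spec)
    truth <- ph$true_angles$value[ph$true_angles$method == "cobb"]
    rep <- get_report(ph$image, paste0("c25_s", seed))
    est <- rep$angles$value[rep$angles$method == "cobb"]
    expect_lte(abs(est - truth), 3)
  }
})

test_that("Ferguson angle follows the vector-algebra construction", {
  expect_equal(ferguson_angle(c(0, 0), c(100, 0), c(200, 0))$value, 0)
  # independent dot-product computation for sev=(0,0), av=(100,40), iev=(200,0)
  v1 <- c(0, 0) - c(100, 40); v2 <- c(200, 0) - c(100, 40)
  oracle <- 180 - acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  est <- ferguson_angle(c(0, 0), c(100, 40), c(200, 0))
  expect_equal(est$value, oracle, tolerance = 1e-10)
  expect_equal(ferguson_angle(c(200, 0), c(100, 40), c(0, 0))$value, est$value)
  expect_error(ferguson_angle(c(0, 0), c(0, 0), c(200, 0)), "coincides")
})

test_that("Greenspan index equals the direct summation oracle", {
  ma <- tibble::tibble(row = 0:100, x = 247)
  csl <- tibble::tibble(x = 237, top_row = 0, bottom_row = 100)
  seg <- tibble::tibble(start_row = 0, end_row = 100)
  est <- greenspan_index(ma, csl, seg)
  expect_equal(est$value, sum(rep(10, 101)) / 100, tolerance = 1e-12)
  expect_true(is.na(est$severity))
})

test_that("Greenspan index is invariant under geometric scaling", {
  spec <- single_curve_spec(30, noise_sigma = 0)
  ml <- make_midline(spec)
  segs <- true_curve_segments(ml)
  csl <- central_sacral_line(ml)
  a <- greenspan_index(ml, csl, segs[1, ])$value
  # double the geometry, then resample back to the original row count
  ml2 <- tibble::tibble(row = ml$row * 2, x = ml$x * 2)
  rows <- seq(min(ml2$row), max(ml2$row), length.out = nrow(ml))
  ml2 <- tibble::tibble(row = rows,
                        x = stats::approx(ml2$row, ml2$x, xout = rows)$y)
  segs2 <- segs[1, ]; segs2$start_row <- segs2$start_row * 2
  segs2$end_row <- segs2$end_row * 2; segs2$apex_row <- segs2$apex_row * 2
  csl2 <- central_sacral_line(ml2)
  b <- greenspan_index(ml2, csl2, segs2)$value
  expect_equal(b, a, tolerance = 0.02)
})

test_that("Diab angle is zero for collinear geometry and near Ferguson on bumps", {
  lin <- tibble::tibble(row = 0:900, x = 237)
  seg <- tibble::tibble(segment = 1L, start_row = 100, apex_row = 450,
                        end_row = 800)
  expect_equal(diab_angle(lin, seg)$value, 0)
  expect_error(diab_angle(lin, tibble::tibble(start_row = 100, apex_row = 150,
                                              end_row = 250)), "three vertebra")

  for (a in c(30, 40)) {
    ml <- make_midline(single_curve_spec(a, noise_sigma = 0))
    segs <- true_curve_segments(ml)
    ang <- analytic_angles(ml, segs)
    diab <- ang$value[ang$method == "diab"]
    ferg <- ang$value[ang$method == "ferguson"]
    expect_lte(abs(diab - ferg), 5)
  }
})

test_that("severity bands reproduce the clinical cut points", {
  probes <- c(9.9, 10, 19.9, 20, 39.9, 40, 45)
  expect_equal(classify_severity(probes),
               c("normal", "mild", "mild", "moderate", "moderate",
                 "severe", "severe"))
  expect_error(classify_severity(-1), "non-negative")
})

test_that("all methods are near zero on straight spines and increase with amplitude", {
  ph <- render_radiograph(midline_spec(noise_sigma = 5, seed = 11))
  rep <- run_pipeline(ph$image)
  expect_equal(nrow(rep$segments), 0)
  ang <- measure_curvature(rep$ma, rep$csl, forced_full_segment(rep$ma))
  expect_true(all(ang$value[ang$method != "greenspan"] <= 2))
  expect_lte(ang$value[ang$method == "greenspan"], 0.5)

  vals <- sapply(c(10, 20, 30, 40), function(a) {
    spec <- single_curve_spec(a, half_span = 250, noise_sigma = 0)
    rep <- get_report(render_radiograph(spec)$image, paste0("mono_", a))
    stats::setNames(rep$angles$value, rep$angles$method)
  })
  expect_true(all(apply(vals, 1, function(v) all(diff(v) > 0))))
})
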