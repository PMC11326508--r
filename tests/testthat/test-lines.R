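test_that("control point collection follows the corner groupings", {
  ann <- generate_case(spine_sim_params(seed = 6), render = FALSE)$annotation
  left <- collect_line_points(ann, "left")
  right <- collect_line_points(ann, "right")
  middle <- collect_line_points(ann, "middle")
  expect_equal(nrow(left), 34)
  expect_equal(nrow(right), 34)
  expect_equal(nrow(middle), 17)

  v1c3 <- ann[ann$vertebra == 1 & ann$corner == 3, ]
  expect_equal(left$x[2], v1c3$x)
  expect_equal(left$y[2], v1c3$y)
  v1c2 <- ann[ann$vertebra == 1 & ann$corner == 2, ]
  expect_equal(right$x[1], v1c2$x)
  expect_error(collect_line_points(ann, "diagonal"))
})

test_that("the spline interpolates every control point", {
  ann <- generate_case(spine_sim_params(seed = 10), render = FALSE)$annotation
  for (side in c("left", "middle", "right")) {
    pts <- collect_line_points(ann, side)
    crv <- fit_interpolating_spline(pts)
    at_knots <- cbind(crv$fx(crv$knots), crv$fy(crv$knots))
    expect_lt(max(abs(at_knots - cbind(pts$x, pts$y))), 1e-6)
  }

  col <- tibble::tibble(x = seq(0, 30, length.out = 12),
                        y = seq(0, 60, length.out = 12))
  crv <- fit_interpolating_spline(col)
  sm <- sample_equidistant(crv, spline_config(n_samples = 50))
  # collinear input stays collinear: x = y/2 along the whole curve
  expect_lt(max(abs(sm$x - sm$y / 2)), 1e-6)

  th <- seq(0, pi / 2, length.out = 34)
  circ <- fit_interpolating_spline(tibble::tibble(x = 10 * cos(th),
                                                  y = 10 * sin(th)))
  smc <- sample_equidistant(circ, spline_config())
  expect_lt(max(abs(sqrt(smc$x^2 + smc$y^2) - 10)), 0.01)  # 0.1% of R

  dup <- tibble::tibble(x = c(0, 1, 1, 2), y = c(0, 1, 1, 2))
  expect_error(fit_interpolating_spline(dup), "duplicate")
})

test_that("equidistant sampling matches analytic arc lengths", {
  seg <- fit_interpolating_spline(
    tibble::tibble(x = rep(0, 4), y = c(0, 33, 66, 99)),
    spline_config(degree = 1))
  sm <- sample_equidistant(seg, spline_config(degree = 1))
  expect_equal(sm$x, rep(0, 100))
  expect_equal(sm$y, 0:99, tolerance = 1e-9)

  th <- seq(0, pi / 2, length.out = 34)
  circ <- fit_interpolating_spline(tibble::tibble(x = 10 * cos(th),
                                                  y = 10 * sin(th)))
  smc <- sample_equidistant(circ, spline_config())
  expect_equal(nrow(smc), 100)
  gaps <- sqrt(diff(smc$x)^2 + diff(smc$y)^2)
  analytic <- (pi * 10 / 2) / 99
  expect_lt(max(abs(gaps - analytic)) / analytic, 0.005)
})

test_that("arc spacings are equal within tolerance on random spines", {
  cfg <- spline_config(sides = c("left", "middle", "right"))
  for (s in 1:30) {
    ann <- generate_case(spine_sim_params(seed = s),
                         render = FALSE)$annotation
    for (side in cfg$sides) {
      pts <- collect_line_points(ann, side)
      crv <- fit_interpolating_spline(pts, cfg)
      sm <- sample_equidistant(crv, cfg)
      tt <- attr(sm, "t")
      # measure arc between consecutive samples on a dense subdivision
      spacings <- vapply(seq_len(99), function(i) {
        tg <- seq(tt[i], tt[i + 1], length.out = 200)
        sum(sqrt(diff(crv$fx(tg))^2 + diff(crv$fy(tg))^2))
      }, numeric(1))
      expect_lt((max(spacings) - min(spacings)) / mean(spacings), 0.01,
                label = paste("seed", s, side))
      # the sampled polyline recovers the curve length on the smooth
      # middle line (corner lines zigzag between samples by construction)
      if (side == "middle") {
        poly_len <- sum(sqrt(diff(sm$x)^2 + diff(sm$y)^2))
        expect_lt(abs(poly_len - attr(sm, "arc_length")) /
                    attr(sm, "arc_length"), 0.005)
      }
    }
  }
})

test_that("line sets honour the enabled sides", {
  ann <- generate_case(spine_sim_params(seed = 13), render = FALSE)$annotation
  vl <- encode_vertebral_lines(ann)
  expect_named(vl, "middle")
  expect_equal(nrow(vl$middle), 100)

  all3 <- encode_vertebral_lines(
    ann, spline_config(sides = c("left", "middle", "right")))
  expect_named(all3, c("left", "middle", "right"))
  expect_true(all(vapply(all3, nrow, integer(1)) == 100))

  straight <- generate_case(
    spine_sim_params(curve_amplitudes = 0, curve_frequencies = 1,
                     vertebra_width_range = c(80, 80), seed = 2),
    render = FALSE)$annotation
  vs <- encode_vertebral_lines(
    straight, spline_config(sides = c("left", "middle", "right")))
  for (side in names(vs)) {
    expect_lt(max(abs(vs[[side]]$x - mean(vs[[side]]$x))), 1e-6)
  }
})
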