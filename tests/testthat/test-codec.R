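cc_small <- codec_config(downsample_k = 4L, input_height = 128L,
                         input_width = 64L, sigma_policy = "fixed",
                         sigma = 2)

test_that("heatmap discs peak at 1 and follow the Gaussian closed form", {
  ctr <- tibble::tibble(x = 30, y = 50)
  hm <- encode_heatmap(ctr, cc_small)
  qx <- floor(30 / 4); qy <- floor(50 / 4)
  expect_equal(hm[qy + 1, qx + 1], 1)
  expect_true(all(hm >= 0 & hm <= 1))
  for (d in 1:4) {
    expect_equal(hm[qy + 1, qx + 1 + d], exp(-d^2 / (2 * 2^2)))
  }

  # two centres one full-resolution pixel apart: max-merge keeps both peaks
  two <- tibble::tibble(x = c(28, 29), y = c(48, 48))
  hm2 <- encode_heatmap(two, cc_small)
  per_center <- pmax(
    encode_heatmap(two[1, ], cc_small),
    encode_heatmap(two[2, ], cc_small))
  expect_equal(hm2, per_center)
  expect_equal(max(hm2), 1)
})

test_that("centre offsets store the exact fractional part", {
  ctr <- tibble::tibble(x = c(10, 8), y = c(20, 16))
  co <- encode_center_offset(ctr, cc_small)
  expect_equal(co$offset[floor(20 / 4) + 1, floor(10 / 4) + 1, 1], 0.5)
  expect_equal(co$offset[floor(16 / 4) + 1, floor(8 / 4) + 1, 1], 0)
  expect_true(all(co$offset >= 0 & co$offset < 1))
  expect_equal(sum(co$mask), 2)
})

test_that("polar conversion follows the image-frame axis conventions", {
  pc <- corners_to_polar(matrix(c(101, 200, 100, 201), 2, 2, byrow = TRUE),
                         c(100, 200))
  expect_equal(pc$r, c(1, 1))
  expect_equal(pc$theta, c(0, pi / 2))

  expect_equal(polar_to_cartesian(c(100, 200), 5, 0),
               tibble::tibble(x = 105, y = 200))
  expect_equal(polar_to_cartesian(c(100, 200), 5, pi),
               tibble::tibble(x = 95, y = 200), tolerance = 1e-12)
  expect_equal(polar_to_cartesian(c(100, 200), 0, 2.3),
               tibble::tibble(x = 100, y = 200))

  # coincident corner: r = 0, theta = 0 by convention
  pc0 <- corners_to_polar(matrix(c(7, 7), 1, 2), c(7, 7))
  expect_equal(pc0$r, 0)
  expect_equal(pc0$theta, 0)

  for (s in 1:20) {
    set.seed(s)
    ctr <- c(stats::runif(1, 20, 40), stats::runif(1, 40, 80))
    quad <- cbind(ctr[1] + stats::runif(4, -10, 10),
                  ctr[2] + stats::runif(4, -10, 10))
    pc <- corners_to_polar(quad, ctr)
    back <- polar_to_cartesian(ctr, pc$r, pc$theta)
    expect_lt(max(abs(cbind(back$x, back$y) - quad)), 1e-9)
  }
})

test_that("CPIE stores adjacent centre intervals with telescoping sums", {
  ctr <- tibble::tibble(x = rep(32, 17), y = seq(10, 10 + 16 * 6, by = 6))
  cc <- codec_config(4L, 128L, 64L)
  ci <- encode_cpie(ctr, cc)
  expect_equal(sum(ci$mask), 16)
  vals <- ci$cpie[cbind(rep(which(ci$mask, arr.ind = TRUE)[, 1], 2),
                        rep(which(ci$mask, arr.ind = TRUE)[, 2], 2),
                        rep(1:2, each = 16))]
  expect_equal(matrix(vals, 16, 2)[, 1], rep(0, 16))
  expect_equal(matrix(vals, 16, 2)[, 2], rep(6, 16))

  ann <- generate_case(spine_sim_params(seed = 4), render = FALSE)$annotation
  ctr2 <- spine_centers(ann)
  ci2 <- encode_cpie(ctr2, codec_config())
  idx <- which(ci2$mask, arr.ind = TRUE)
  sums <- c(sum(ci2$cpie[, , 1][ci2$mask]), sum(ci2$cpie[, , 2][ci2$mask]))
  expect_lt(abs(ctr2$x[1] + sums[1] - ctr2$x[17]), 1e-9)
  expect_lt(abs(ctr2$y[1] + sums[2] - ctr2$y[17]), 1e-9)
})

test_that("AVIE measures bottom-to-top corner offsets between neighbours", {
  ann <- stacked_rect_annotation(n = 3, height = 20, gap = 0,
                                 image_height = 128, image_width = 64,
                                 x_center = 32, width = 20)
  cc <- codec_config(4L, 128L, 64L)
  av <- encode_avie(ann, cc)
  expect_equal(sum(av$mask), 2)
  expect_true(all(abs(av$avie) < 1e-12))   # abutting rectangles

  shifted <- ann
  move <- shifted$vertebra == 2
  shifted$x[move] <- shifted$x[move] + 3
  shifted$y[move] <- shifted$y[move] + 7
  av2 <- encode_avie(shifted, cc)
  ctr2 <- spine_centers(shifted)
  qx <- floor(ctr2$x[2] / 4) + 1; qy <- floor(ctr2$y[2] / 4) + 1
  expect_equal(as.numeric(av2$avie[qy, qx, ]), c(3, 7, 3, 7))
})

test_that("nms keeps exactly the 3x3 local maxima with ties retained", {
  hm <- matrix(0, 10, 10)
  hm[5, 5] <- 0.9
  expect_equal(nms(hm), hm)

  hm[5, 6] <- 0.8                       # adjacent, weaker -> suppressed
  out <- nms(hm)
  expect_equal(out[5, 5], 0.9)
  expect_equal(out[5, 6], 0)

  plateau <- matrix(0.4, 4, 4)          # all equal -> all retained
  expect_equal(nms(plateau), plateau)

  # brute-force window oracle on a random map
  set.seed(1)
  rnd <- matrix(stats::runif(15 * 12), 15, 12)
  out <- nms(rnd)
  for (i in 1:15) for (j in 1:12) {
    win <- rnd[max(1, i - 1):min(15, i + 1), max(1, j - 1):min(12, j + 1)]
    expected <- if (rnd[i, j] == max(win)) rnd[i, j] else 0
    expect_identical(out[i, j], expected)
  }
})

test_that("encode/decode round trip restores all 68 landmarks", {
  cc <- codec_config()
  for (s in 1:25) {
    ann <- generate_case(spine_sim_params(seed = s),
                         render = FALSE)$annotation
    tg <- encode_all(ann, cc)
    expect_equal(max(tg$heatmap), 1)
    expect_equal(sum(tg$center_mask), 17)
    expect_equal(sum(tg$cpie_mask), 16)
    expect_equal(sum(tg$avie_mask), 16)

    ctrs <- topk_centers(tg$heatmap, tg$center_offset, cc)
    expect_equal(nrow(ctrs), 17)
    expect_true(all(diff(ctrs$y) >= 0))
    lm <- decode_landmarks(ctrs, tg$corner_polar, cc)
    expect_equal(nrow(lm), 68)
    expect_lt(max(abs(as_landmark_matrix(lm) - as_landmark_matrix(ann))),
              1e-6)
  }
})

test_that("encoding is deterministic", {
  ann <- generate_case(spine_sim_params(seed = 8), render = FALSE)$annotation
  t1 <- encode_all(ann, codec_config())
  t2 <- encode_all(ann, codec_config())
  expect_identical(t1$heatmap, t2$heatmap)
  expect_identical(t1$corner_polar, t2$corner_polar)
  expect_identical(t1$vertebral_lines$middle, t2$vertebral_lines$middle)
})

test_that("adaptive centre decoding follows the intensity threshold", {
  # 19 isolated synthetic peaks above 0.05 -> 19 centres
  cc <- codec_config(4L, 256L, 64L)
  hm <- matrix(0, 64, 16)
  set.seed(3)
  rows <- seq(2, 60, length.out = 19)
  for (i in seq_along(rows)) hm[round(rows[i]), 8] <- 0.06 + 0.04 * (i %% 3)
  off <- array(0.5, c(64, 16, 2))
  ac <- adaptive_centers(hm, off, cc, threshold = 0.05)
  expect_equal(nrow(ac), 19)

  # strict comparison: peaks exactly at the threshold are dropped
  hm2 <- matrix(0, 64, 16); hm2[10, 8] <- 0.05; hm2[30, 8] <- 0.051
  expect_equal(nrow(adaptive_centers(hm2, off, cc, threshold = 0.05)), 1)

  # equivalence with top-k when exactly 17 peaks clear the threshold
  ann <- generate_case(spine_sim_params(seed = 12),
                       render = FALSE)$annotation
  tg <- encode_all(ann, codec_config())
  tk <- topk_centers(tg$heatmap, tg$center_offset, codec_config())
  ad <- adaptive_centers(tg$heatmap, tg$center_offset, codec_config())
  expect_equal(ad[, c("x", "y")], tk[, c("x", "y")])
})

test_that("zero radii collapse corners onto centres", {
  cc <- codec_config(4L, 128L, 64L)
  ctr <- tibble::tibble(vertebra = 1:2, x = c(30, 34), y = c(40, 80))
  polar <- array(0, c(32, 16, 8))
  lm <- decode_landmarks(ctr, polar, cc)
  expect_equal(nrow(lm), 8)
  expect_equal(lm$x, rep(c(30, 34), each = 4))
  expect_equal(lm$y, rep(c(40, 80), each = 4))
})

test_that("decoding errors are informative", {
  cc <- codec_config(4L, 128L, 64L)
  hm <- matrix(0, 32, 16); hm[5, 5] <- 1
  off <- array(0, c(32, 16, 2))
  expect_error(topk_centers(hm, off, cc, k_points = 17), "1")
  expect_error(encode_heatmap(tibble::tibble(x = 999, y = 10), cc_small),
               "outside")
})
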