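test_that("parallel vertebrae give zero Cobb angles", {
  ann <- stacked_rect_annotation()
  angles <- cobb_from_landmarks(ann)
  expect_equal(as.numeric(angles), c(0, 0, 0))
})

test_that("a two-tilt spine yields the tilt difference as MT", {
  tilts <- c(rep(10, 8), rep(-10, 9))
  ann <- tilted_annotation(tilts)
  angles <- cobb_from_landmarks(ann)
  expect_equal(angles$mt, 20, tolerance = 1e-9)
})

test_that("Cobb angles are invariant to rigid motions and scaling", {
  case <- generate_case(spine_sim_params(seed = 21), render = FALSE)
  m <- as_landmark_matrix(case$annotation)
  H <- attr(case$annotation, "image_height")
  base <- cobb_from_landmarks(m, image_height = H)

  shifted <- m + matrix(rep(c(13.7, -8.2), each = 68), 68, 2)
  expect_equal(as.numeric(cobb_from_landmarks(shifted, image_height = H)),
               as.numeric(base), tolerance = 1e-9)

  phi <- 0.17
  rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  rotated <- m %*% t(rot)
  expect_equal(as.numeric(cobb_from_landmarks(rotated,
                                              image_height = H)),
               as.numeric(base), tolerance = 1e-9)

  scaled <- m * 2.5
  expect_equal(as.numeric(cobb_from_landmarks(scaled,
                                              image_height = H * 2.5)),
               as.numeric(base), tolerance = 1e-9)

  degen <- m; degen[1:4, ] <- matrix(rep(degen[1, ], 4), 4, 2, byrow = TRUE)
  expect_error(cobb_from_landmarks(degen), "degenerate")
})

test_that("analytic Cobb truth is recovered from landmarks", {
  for (s in 1:100) {
    case <- generate_case(spine_sim_params(seed = s), render = FALSE)
    est <- cobb_from_landmarks(case$annotation)
    expect_lt(max(abs(as.numeric(est) - as.numeric(case$true_cobb))), 1.0,
              label = paste("seed", s))
  }
})

test_that("MDE follows its closed forms", {
  ann <- stacked_rect_annotation()
  m <- as_landmark_matrix(ann)
  expect_equal(mde(m, m), 0)

  disp <- m; disp[10, ] <- disp[10, ] + c(3, 4)
  expect_equal(mde(disp, m), 5 / 68)

  trans <- m; trans[, 2] <- trans[, 2] + 12.5
  expect_equal(mde(trans, m), 12.5)

  expect_error(mde(m[1:10, ], m), "mismatch")
})

test_that("SMAPE follows Cobb-angle algebra and is symmetric", {
  gt <- tibble::tibble(pt = c(10, 20), mt = c(30, 25), tl = c(5, 15))
  expect_equal(smape(gt, gt)$smape, 0)

  one <- gt[1, ]
  doubled <- one
  doubled[1, ] <- one[1, ] * 2
  expect_equal(smape(doubled, one)$smape, 100 / 3, tolerance = 1e-9)

  set.seed(9)
  pred <- tibble::tibble(pt = stats::runif(5, 5, 30),
                         mt = stats::runif(5, 10, 40),
                         tl = stats::runif(5, 2, 20))
  gt5 <- tibble::tibble(pt = stats::runif(5, 5, 30),
                        mt = stats::runif(5, 10, 40),
                        tl = stats::runif(5, 2, 20))
  expect_equal(smape(pred, gt5), smape(gt5, pred))

  zero <- tibble::tibble(pt = 0, mt = 0, tl = 0)
  expect_error(smape(zero, zero), "case")
})

test_that("hungarian matching equals brute force on small instances", {
  gtc <- spine_centers(stacked_rect_annotation())
  perm <- sample(17)
  permuted <- gtc[perm, ]
  m <- hungarian_match(permuted, gtc)
  expect_equal(m$total_cost, 0)
  expect_equal(nrow(m$pairs), 17)

  for (s in 1:100) {
    set.seed(s)
    n <- sample(2:7, 1)
    pred <- matrix(stats::runif(2 * n, 0, 100), n, 2)
    gt <- matrix(stats::runif(2 * n, 0, 100), n, 2)
    cost <- sqrt(outer(pred[, 1], gt[, 1], "-")^2 +
                   outer(pred[, 2], gt[, 2], "-")^2)
    m <- hungarian_match(pred, gt)
    expect_equal(m$total_cost, brute_force_assignment(cost),
                 tolerance = 1e-9)
  }

  extra <- rbind(as.matrix(gtc[, c("x", "y")]),
                 matrix(c(5, 5, 200, 400), 2, 2, byrow = TRUE))
  m2 <- hungarian_match(extra, gtc)
  expect_equal(nrow(m2$pairs), 17)
  expect_equal(length(m2$unmatched_pred), 2)
  expect_error(hungarian_match(matrix(numeric(), 0, 2), gtc), "empty")
})

test_that("self-adaptive MDE isolates localization from ordering error", {
  cc <- codec_config()
  ann <- generate_case(spine_sim_params(seed = 31), render = FALSE)$annotation
  tg <- encode_all(ann, cc)
  clean <- self_adaptive_mde(tg$heatmap, tg$center_offset, tg$corner_polar,
                             ann, cc)
  expect_lt(clean, 1e-6)

  # spurious low-confidence peaks far from the spine leave the value intact
  hm2 <- tg$heatmap
  hm2[cbind(c(5, 120, 250), c(120, 125, 122))] <- 0.06
  with_spur <- self_adaptive_mde(hm2, tg$center_offset, tg$corner_polar,
                                 ann, cc)
  expect_equal(with_spur, clean, tolerance = 1e-9)

  # misordered-but-exact landmarks: index-aligned MDE > 0, matched MDE = 0
  gtc <- spine_centers(ann)
  swap <- seq_len(17); swap[3] <- 4; swap[4] <- 3
  swapped_lm <- tibble::tibble(vertebra = swap[ann$vertebra],
                               corner = ann$corner, x = ann$x, y = ann$y) |>
    dplyr::arrange(vertebra, corner)
  expect_gt(mde(swapped_lm, ann), 0)
  m <- hungarian_match(spine_centers(swapped_lm), gtc)
  expect_equal(m$total_cost, 0, tolerance = 1e-9)
})

test_that("dataset evaluation pools landmarks and averages cases", {
  cases <- lapply(c(52, 58), function(s) {
    generate_case(spine_sim_params(seed = s), render = FALSE)$annotation
  })
  ident <- evaluate_dataset(cases, cases)
  expect_equal(ident$mde, 0)
  expect_equal(ident$smape, 0)

  shifted <- lapply(cases, function(a) {
    b <- a; b$x <- b$x + 3; b$y <- b$y + 4; b
  })
  rep <- evaluate_dataset(shifted, cases)
  expect_equal(rep$mde, 5, tolerance = 1e-12)
  expect_equal(rep$mde_upper, 5, tolerance = 1e-12)
  expect_equal(rep$mde_lower, 5, tolerance = 1e-12)

  # pooled MDE equals the metric on the concatenated landmark list
  concat_pred <- do.call(rbind, lapply(shifted, as_landmark_matrix))
  concat_gt <- do.call(rbind, lapply(cases, as_landmark_matrix))
  expect_equal(rep$mde, mde(concat_pred, concat_gt))

  lng <- tidy(rep)
  expect_true(all(c("metric", "value") %in% names(lng)))
})
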