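n_params_of <- function(m) {
  count <- function(x) if (is.list(x)) sum(vapply(x, count, numeric(1)))
                       else length(x)
  count(m$params)
}

test_that("the model honours its shape contract", {
  cfg <- model_config("toy")
  m <- build_model(cfg, seed = 1)
  expect_lt(n_params_of(m), 2e5)

  img <- matrix(stats::runif(192 * 64), 192, 64)
  out <- predict(m, img)
  expect_equal(dim(out$heatmap), c(48, 16))
  expect_equal(dim(out$center_offset), c(48, 16, 2))
  expect_equal(dim(out$corner_polar), c(48, 16, 8))
  expect_equal(dim(out$cpie), c(48, 16, 2))
  expect_equal(dim(out$avie), c(48, 16, 4))
  expect_true(all(out$heatmap > 0 & out$heatmap < 1))
  expect_equal(length(out$vil_raw), 200)     # middle line, 100 x (x, y)
  expect_equal(nrow(out$vil$middle), 100)

  # deeper preset at a reduced input size: same contract
  cfg2 <- model_config("resnet34", input_height = 64, input_width = 32)
  m2 <- build_model(cfg2, seed = 1)
  out2 <- predict(m2, matrix(stats::runif(64 * 32), 64, 32))
  expect_equal(dim(out2$heatmap), c(16, 8))
  expect_equal(dim(out2$corner_polar), c(16, 8, 8))

  expect_error(model_config("toy", decoder_blocks = c(24L, 24L)),
               "skip")
  expect_error(model_config("toy", input_height = 100L), "divisible")
})

test_that("weight initialization is deterministic in the seed", {
  a <- build_model(model_config("toy"), seed = 7)
  b <- build_model(model_config("toy"), seed = 7)
  expect_identical(a$params, b$params)
  c2 <- build_model(model_config("toy"), seed = 8)
  expect_false(identical(a$params, c2$params))
})

test_that("backprop agrees with numeric gradients on a tiny model", {
  cfg <- model_config("toy", encoder_blocks = c(3L, 4L),
                      decoder_blocks = c(3L), downsample_k = 2L,
                      input_height = 16L, input_width = 8L,
                      head_channels = 5L, n_samples = 4L)
  m <- build_model(cfg, seed = 1)
  set.seed(42)
  Hk <- 8; Wk <- 4
  hm <- matrix(stats::runif(Hk * Wk) * 0.3, Hk, Wk)
  hm[3, 2] <- 1; hm[6, 3] <- 1
  tg <- list(
    heatmap = hm,
    center_offset = array(stats::runif(Hk * Wk * 2), c(Hk, Wk, 2)),
    corner_polar = array(stats::runif(Hk * Wk * 8, -1, 1), c(Hk, Wk, 8)),
    cpie = array(stats::runif(Hk * Wk * 2, -2, 2), c(Hk, Wk, 2)),
    avie = array(stats::runif(Hk * Wk * 4, -2, 2), c(Hk, Wk, 4)),
    center_mask = matrix(stats::runif(Hk * Wk) > 0.6, Hk, Wk),
    cpie_mask = matrix(stats::runif(Hk * Wk) > 0.6, Hk, Wk),
    avie_mask = matrix(stats::runif(Hk * Wk) > 0.6, Hk, Wk))
  gt_lines <- list(middle = tibble::tibble(x = stats::runif(4) * 8,
                                           y = stats::runif(4) * 16))
  img <- matrix(stats::runif(16 * 8), 16, 8)

  lg <- spinemark:::network_loss_grads(m, img, tg, gt_lines)
  f <- function(params) {
    m$params <- params
    spinemark:::network_loss_grads(m, img, tg, gt_lines)$total
  }
  eps <- 1e-6
  probes <- list(
    list(\(p) p$enc[[1]]$W, \(p, v) { p$enc[[1]]$W <- v; p },
         \(g) g$enc[[1]]$W),
    list(\(p) p$dec[[1]]$W, \(p, v) { p$dec[[1]]$W <- v; p },
         \(g) g$dec[[1]]$W),
    list(\(p) p$heads$corner_polar$W,
         \(p, v) { p$heads$corner_polar$W <- v; p },
         \(g) g$heads$corner_polar$W),
    list(\(p) p$vil$W, \(p, v) { p$vil$W <- v; p }, \(g) g$vil$W))
  for (pr in probes) {
    for (idx in c(1L, 2L)) {
      p_plus <- m$params; p_minus <- m$params
      v <- pr[[1]](p_plus)
      v[idx] <- v[idx] + eps
      p_plus <- pr[[2]](p_plus, v)
      v[idx] <- v[idx] - 2 * eps
      p_minus <- pr[[2]](p_minus, v)
      num <- (f(p_plus) - f(p_minus)) / (2 * eps)
      ana <- pr[[3]](lg$grads)[idx]
      expect_equal(ana, num, tolerance = 1e-4)
    }
  }
})

test_that("zero training steps leave the model unchanged", {
  cases <- list(generate_case(toy_sim_params(seed = 1)))
  m <- build_model(model_config("toy"), seed = 0)
  fit <- train_toy(m, cases, steps = 0)
  expect_identical(fit$model$params, m$params)
  expect_equal(nrow(fit$trace), 0)
})

test_that("a short training run reduces the loss", {
  cases <- lapply(1:2, function(s) generate_case(toy_sim_params(seed = s)))
  m <- build_model(model_config("toy"), seed = 0)
  fit <- train_toy(m, cases, steps = 60)
  tr <- tidy(fit)
  expect_equal(nrow(tr), 60)
  expect_lt(tr$total[60], 0.5 * tr$total[1])
  expect_true(all(is.finite(tr$total)))
  g <- glance(fit)
  expect_equal(g$steps, 60)
  expect_lt(g$loss_ratio, 0.5)
})
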