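#' Network configuration
#'
#' A U-shaped encoder-decoder with six output pathways: the centre heatmap,
#' Cartesian centre offsets, polar corner offsets, the two inter-vertebral
#' interval estimators (CPIE, AVIE) — all as grids at 1/`downsample_k`
#' resolution — and a vertebral-line regression head (global average pool of
#' the bottleneck followed by a fully connected layer emitting normalized
#' line coordinates in \[0, 1\]). Every encoder block halves the spatial
#' resolution; every decoder block doubles it and adds the skip feature from
#' the matching encoder stage, so
#' `2^length(encoder_blocks) / 2^length(decoder_blocks)` must equal
#' `downsample_k` and each decoder width must equal the encoder width at its
#' resolution.
#'
#' The `"toy"` preset (4 + 2 blocks, narrow widths, about 33k parameters,
#' 192 x 64 inputs) exercises every pathway and loss on a CPU in seconds;
#' the `"resnet34"` preset reproduces the 5-block / 3-block layout and
#' 1024 x 512 input geometry of a full-scale detector (without pretrained
#' weights).
#'
#' @param preset `"toy"` or `"resnet34"`.
#' @param input_height,input_width Input size in px.
#' @param downsample_k Output grid stride (matches [codec_config()]).
#' @param encoder_blocks,decoder_blocks Channel widths per block.
#' @param head_channels Width of the shared 3x3 conv feeding the grid heads.
#' @param n_samples,sides Vertebral-line head geometry (see
#'   [spline_config()]).
#' @param coord_channels Append two normalized coordinate channels to the
#'   input (helps sub-pixel regression at toy scale).
#' @param lr Default Adam learning rate for [train_toy()].
#' @return A list of class `model_config`.
#' @export
model_config <- function(preset = c("toy", "resnet34"),
                         input_height = NULL, input_width = NULL,
                         downsample_k = 4L,
                         encoder_blocks = NULL, decoder_blocks = NULL,
                         head_channels = NULL,
                         n_samples = 100L, sides = "middle",
                         coord_channels = TRUE,
                         lr = NULL) {
  preset <- match.arg(preset)
  if (preset == "toy") {
    encoder_blocks <- encoder_blocks %||% c(8L, 16L, 24L, 32L)
    decoder_blocks <- decoder_blocks %||% c(24L, 16L)
    head_channels <- head_channels %||% 16L
    input_height <- input_height %||% 192L
    input_width <- input_width %||% 64L
    lr <- lr %||% 1e-3
  } else {
    encoder_blocks <- encoder_blocks %||% c(64L, 64L, 128L, 256L, 512L)
    decoder_blocks <- decoder_blocks %||% c(256L, 128L, 64L)
    head_channels <- head_channels %||% 64L
    input_height <- input_height %||% 1024L
    input_width <- input_width %||% 512L
    lr <- lr %||% 1.25e-4
  }
  nE <- length(encoder_blocks); nD <- length(decoder_blocks)
  if (2^nE / 2^nD != downsample_k) {
    stop("2^encoder / 2^decoder blocks must equal downsample_k",
         call. = FALSE)
  }
  for (j in seq_len(nD)) {
    if (decoder_blocks[j] != encoder_blocks[nE - j]) {
      stop("decoder width ", j, " must match encoder width ", nE - j,
           " for the skip connection", call. = FALSE)
    }
  }
  if (input_height %% 2^nE != 0L || input_width %% 2^nE != 0L) {
    stop("input dims must be divisible by the total encoder stride ",
         2^nE, call. = FALSE)
  }
  sides <- match.arg(sides, c("left", "middle", "right"), several.ok = TRUE)
  structure(list(preset = preset,
                 input_height = as.integer(input_height),
                 input_width = as.integer(input_width),
                 downsample_k = as.integer(downsample_k),
                 encoder_blocks = as.integer(encoder_blocks),
                 decoder_blocks = as.integer(decoder_blocks),
                 head_channels = as.integer(head_channels),
                 n_samples = as.integer(n_samples), sides = sides,
                 coord_channels = isTRUE(coord_channels),
                 lr = lr),
            class = "model_config")
}

#' Build a detection network
#'
#' Initializes all parameters (He-scaled Gaussian weights; the heatmap head
#' bias starts at `log(0.1/0.9)` so the initial heatmap is a flat 0.1).
#' Deterministic for a given seed.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the weight initialization.
#' @return A list of class `vldet_model` with elements `params`, `config`.
#' @export
build_model <- function(config = model_config(), seed = 0L) {
  stopifnot(inherits(config, "model_config"))
  with_seed(seed, {
    cin <- 1L + if (config$coord_channels) 2L else 0L
    enc <- list()
    prev <- cin
    for (w in config$encoder_blocks) {
      enc[[length(enc) + 1L]] <- conv_init(prev, w)
      prev <- w
    }
    dec <- list()
    for (w in config$decoder_blocks) {
      dec[[length(dec) + 1L]] <- conv_init(prev, w)
      prev <- w
    }
    head_conv <- conv_init(prev, config$head_channels)
    hc <- config$head_channels
    heads <- list(
      heatmap = conv1x1_init(hc, 1L, bias = log(0.1 / 0.9)),
      center_offset = conv1x1_init(hc, 2L),
      corner_polar = conv1x1_init(hc, 8L),
      cpie = conv1x1_init(hc, 2L),
      avie = conv1x1_init(hc, 4L)
    )
    nvil <- 2L * config$n_samples * length(config$sides)
    vil <- dense_init(config$encoder_blocks[length(config$encoder_blocks)],
                      nvil)
    params <- list(enc = enc, dec = dec, head_conv = head_conv,
                   heads = heads, vil = vil)
    structure(list(params = params, config = config),
              class = "vldet_model")
  })
}

n_params <- function(model) {
  count <- function(x) if (is.list(x)) sum(vapply(x, count, numeric(1)))
                       else length(x)
  count(model$params)
}

#' @export
print.vldet_model <- function(x, ...) {
  cat(sprintf("<vldet_model: preset '%s', %d x %d input, k=%d, %s params>\n",
              x$config$preset, x$config$input_height, x$config$input_width,
              x$config$downsample_k, format(n_params(x), big.mark = ",")))
  invisible(x)
}

input_tensor <- function(config, image) {
  H <- config$input_height; W <- config$input_width
  if (!all(dim(image) == c(H, W))) {
    stop("image is ", paste(dim(image), collapse = " x "),
         ", model expects ", H, " x ", W, call. = FALSE)
  }
  cin <- 1L + if (config$coord_channels) 2L else 0L
  x <- array(0, c(H, W, cin))
  x[, , 1L] <- image
  if (config$coord_channels) {
    x[, , 2L] <- matrix(rep(seq(0, 1, length.out = W), each = H), H, W)
    x[, , 3L] <- matrix(rep(seq(0, 1, length.out = H), times = W), H, W)
  }
  x
}

network_forward <- function(model, image, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  x <- input_tensor(cfg, image)
  nE <- length(p$enc); nD <- length(p$dec)

  e <- vector("list", nE)
  conv_caches <- vector("list", nE)
  relu_caches <- vector("list", nE)
  cur <- x
  for (i in seq_len(nE)) {
    cf <- conv_forward(cur, p$enc[[i]], stride = 2L)
    rf <- relu_forward(cf$out)
    conv_caches[[i]] <- cf$cache
    relu_caches[[i]] <- rf$cache
    e[[i]] <- rf$out
    cur <- rf$out
  }

  dec_conv_caches <- vector("list", nD)
  dec_relu_caches <- vector("list", nD)
  d <- e[[nE]]
  for (j in seq_len(nD)) {
    up <- upsample2_forward(d)
    cf <- conv_forward(up, p$dec[[j]], stride = 1L)
    rf <- relu_forward(cf$out)
    dec_conv_caches[[j]] <- cf$cache
    dec_relu_caches[[j]] <- rf$cache
    d <- rf$out + e[[nE - j]]
  }

  hcf <- conv_forward(d, p$head_conv, stride = 1L)
  hrf <- relu_forward(hcf$out)
  hfeat <- hrf$out

  head_out <- list()
  head_caches <- list()
  for (h in names(p$heads)) {
    f <- conv1x1_forward(hfeat, p$heads[[h]])
    head_out[[h]] <- f$out
    head_caches[[h]] <- f$cache
  }
  z_hm <- head_out$heatmap[, , 1L]
  heatmap <- sigmoid(z_hm)

  gp <- global_avg_pool_forward(e[[nE]])
  df <- dense_forward(gp$out, p$vil)
  vraw <- sigmoid(df$out)
  vil_px <- vil_vector_to_lines(vraw, cfg)

  out <- list(heatmap = heatmap,
              center_offset = head_out$center_offset,
              corner_polar = head_out$corner_polar,
              cpie = head_out$cpie,
              avie = head_out$avie,
              vil = vil_px, vil_raw = vraw)
  if (keep_cache) {
    out$cache <- list(x = x, e = e, conv = conv_caches, relu = relu_caches,
                      dec_conv = dec_conv_caches, dec_relu = dec_relu_caches,
                      head_conv = hcf$cache, head_relu = hrf$cache,
                      heads = head_caches, gp_dims = gp$cache,
                      dense_v = df$cache, vraw = vraw, heatmap = heatmap)
  }
  out
}

vil_vector_to_lines <- function(vraw, cfg) {
  n <- cfg$n_samples
  out <- list()
  for (s in seq_along(cfg$sides)) {
    base <- (s - 1L) * 2L * n
    out[[cfg$sides[s]]] <- tibble::tibble(
      x = vraw[base + seq_len(n)] * cfg$input_width,
      y = vraw[base + n + seq_len(n)] * cfg$input_height)
  }
  out
}

#' Predict all six pathways for one image
#'
#' @param object A `vldet_model`.
#' @param image An input matrix matching the model's configured size,
#'   values in \[0, 1\].
#' @param ... Unused.
#' @return A named list: `heatmap` (H/k x W/k matrix in (0,1)),
#'   `center_offset` (H/k x W/k x 2), `corner_polar` (... x 8), `cpie`
#'   (... x 2), `avie` (... x 4), `vil` (named list of line tibbles in px),
#'   `vil_raw` (normalized coordinate vector).
#' @export
predict.vldet_model <- function(object, image, ...) {
  network_forward(object, image, keep_cache = FALSE)
}

# ---- loss + gradients ------------------------------------------------------

signed_wrap <- function(d) ((d + pi) %% (2 * pi)) - pi

# terms, total and gradients w.r.t. every parameter for one case
network_loss_grads <- function(model, image, targets, gt_lines_px,
                               weights = loss_weights()) {
  cfg <- model$config
  fw <- network_forward(model, image, keep_cache = TRUE)
  cache <- fw$cache
  p <- model$params
  eps <- 1e-7

  hm_p <- pmin(pmax(fw$heatmap, eps), 1 - eps)
  gt_hm <- targets$heatmap
  pos <- gt_hm == 1
  n_pos <- max(sum(pos), 1L)
  l_hm <- focal_loss(fw$heatmap, gt_hm)
  d_p <- matrix(0, nrow(hm_p), ncol(hm_p))
  d_p[pos] <- (2 * (1 - hm_p[pos]) * log(hm_p[pos]) -
                 (1 - hm_p[pos])^2 / hm_p[pos]) / n_pos
  d_p[!pos] <- (1 - gt_hm[!pos])^4 *
    (-2 * hm_p[!pos] * log(1 - hm_p[!pos]) +
       hm_p[!pos]^2 / (1 - hm_p[!pos])) / n_pos
  d_z_hm <- d_p * hm_p * (1 - hm_p)

  grad_masked_l1 <- function(pred, gt, mask) {
    msk <- expand_mask(mask, dim(pred))
    n <- sum(msk)
    g <- array(0, dim(pred))
    if (n > 0) g[msk] <- sign(pred[msk] - gt[msk]) / n
    g
  }
  l_center <- masked_l1(fw$center_offset, targets$center_offset,
                        targets$center_mask)
  g_center <- grad_masked_l1(fw$center_offset, targets$center_offset,
                             targets$center_mask)
  l_cpie <- masked_l1(fw$cpie, targets$cpie, targets$cpie_mask)
  g_cpie <- grad_masked_l1(fw$cpie, targets$cpie, targets$cpie_mask)
  l_avie <- masked_l1(fw$avie, targets$avie, targets$avie_mask)
  g_avie <- grad_masked_l1(fw$avie, targets$avie, targets$avie_mask)

  l_corner <- corner_polar_loss(fw$corner_polar, targets$corner_polar,
                                targets$center_mask)
  g_corner <- array(0, dim(fw$corner_polar))
  msk4 <- expand_mask(targets$center_mask, c(dim(fw$corner_polar)[1:2], 4L))
  nm <- sum(msk4)
  r_ch <- seq(1L, 8L, by = 2L); th_ch <- seq(2L, 8L, by = 2L)
  gr <- array(0, dim(msk4))
  gr[msk4] <- sign(fw$corner_polar[, , r_ch][msk4] -
                     targets$corner_polar[, , r_ch][msk4]) / nm
  g_corner[, , r_ch] <- gr
  wd <- array(0, dim(msk4))
  wd[msk4] <- sign(signed_wrap(fw$corner_polar[, , th_ch][msk4] -
                                 targets$corner_polar[, , th_ch][msk4])) / nm
  g_corner[, , th_ch] <- wd

  vl <- vil_loss(fw$vil, gt_lines_px)
  n <- cfg$n_samples
  d_vraw <- numeric(length(fw$vil_raw))
  for (s in seq_along(cfg$sides)) {
    side <- cfg$sides[s]
    base <- (s - 1L) * 2L * n
    gx <- sign(fw$vil[[side]]$x - gt_lines_px[[side]]$x) / (2 * n)
    gy <- sign(fw$vil[[side]]$y - gt_lines_px[[side]]$y) / (2 * n)
    d_vraw[base + seq_len(n)] <- gx * cfg$input_width
    d_vraw[base + n + seq_len(n)] <- gy * cfg$input_height
  }
  d_u <- d_vraw * fw$vil_raw * (1 - fw$vil_raw) * weights[["alpha6"]]

  terms <- tibble::tibble(l_hm = l_hm, l_center = l_center,
                          l_corner = l_corner, l_cpie = l_cpie,
                          l_avie = l_avie,
                          l_vil_l = vl$l_vil_l, l_vil_m = vl$l_vil_m,
                          l_vil_r = vl$l_vil_r, l_vil = vl$l_vil)
  total <- total_loss(terms, weights)
  if (!is.finite(total)) {
    stop("non-finite loss: ",
         paste(sprintf("%s=%.3g", names(terms), as.numeric(terms[1, ])),
               collapse = " "), call. = FALSE)
  }

  # ---- backward ----
  head_grads_out <- list(
    heatmap = array(d_z_hm * weights[["alpha1"]],
                    c(dim(d_z_hm), 1L)),
    center_offset = g_center * weights[["alpha2"]],
    corner_polar = g_corner * weights[["alpha3"]],
    cpie = g_cpie * weights[["alpha4"]],
    avie = g_avie * weights[["alpha5"]]
  )

  grads <- tree_zero(p)
  d_hfeat <- NULL
  for (h in names(p$heads)) {
    bk <- conv1x1_backward(head_grads_out[[h]], p$heads[[h]],
                           cache$heads[[h]])
    grads$heads[[h]]$W <- bk$dW
    grads$heads[[h]]$b <- bk$db
    d_hfeat <- if (is.null(d_hfeat)) bk$dx else d_hfeat + bk$dx
  }

  d_hc <- relu_backward(d_hfeat, cache$head_relu)
  bk <- conv_backward(d_hc, p$head_conv, cache$head_conv)
  grads$head_conv$W <- bk$dW
  grads$head_conv$b <- bk$db
  d_d <- bk$dx

  nE <- length(p$enc); nD <- length(p$dec)
  g_e <- vector("list", nE)
  for (j in rev(seq_len(nD))) {
    sk <- nE - j
    g_e[[sk]] <- if (is.null(g_e[[sk]])) d_d else g_e[[sk]] + d_d
    d_r <- relu_backward(d_d, cache$dec_relu[[j]])
    bk <- conv_backward(d_r, p$dec[[j]], cache$dec_conv[[j]])
    grads$dec[[j]]$W <- bk$dW
    grads$dec[[j]]$b <- bk$db
    d_d <- upsample2_backward(bk$dx)
  }

  dvil <- dense_backward(d_u, p$vil, cache$dense_v)
  grads$vil$W <- dvil$dW
  grads$vil$b <- dvil$db
  d_bottleneck <- global_avg_pool_backward(dvil$dv, cache$gp_dims)
  g_e[[nE]] <- if (is.null(g_e[[nE]])) d_d + d_bottleneck
               else g_e[[nE]] + d_d + d_bottleneck

  d_cur <- NULL
  for (i in rev(seq_len(nE))) {
    g <- g_e[[i]]
    if (!is.null(d_cur)) g <- if (is.null(g)) d_cur else g + d_cur
    d_r <- relu_backward(g, cache$relu[[i]])
    bk <- conv_backward(d_r, p$enc[[i]], cache$conv[[i]])
    grads$enc[[i]]$W <- bk$dW
    grads$enc[[i]]$b <- bk$db
    d_cur <- bk$dx
  }

  list(terms = terms, total = total, grads = grads)
}

#' Simulator parameters scaled to the toy network
#'
#' The same anatomy as [spine_sim_params()] shrunk onto the toy 192 x 64
#' canvas (sizes, margins and bow amplitudes scaled down about 1/6).
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [spine_sim_params()].
#' @return A [spine_sim_params()].
#' @export
toy_sim_params <- function(seed = 1L, ...) {
  args <- list(
    image_height = 192L, image_width = 64L,
    curve_amplitudes = c(6, 2), curve_frequencies = c(1, 2),
    vertebra_width_range = c(9, 13),
    vertebra_height_range = c(6.5, 9),
    gap_fraction = 0.25, noise_sd = 0.02, lower_region_clutter = 0.3,
    margin = 8, seed = seed
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(spine_sim_params, args)
}

#' Train the network on a handful of simulated cases
#'
#' Full-batch Adam on the composite loss: every step encodes nothing anew —
#' targets are encoded once — and accumulates gradients over all supplied
#' cases (the spirit of small-batch training at desk scale). Intended for
#' overfitting tests that verify the end-to-end learning signal, not for
#' producing a clinically meaningful detector.
#'
#' @param model A `vldet_model` from [build_model()].
#' @param cases List of `simulated_case` (with rendered images matching the
#'   model input size).
#' @param steps Number of optimizer steps; 0 returns the model unchanged.
#' @param lr Adam learning rate (default from the model config).
#' @param weights A [loss_weights()].
#' @param lines A [spline_config()] for the line targets; defaults to the
#'   model's sides and sample count.
#' @return A list of class `vldet_fit`: `model` (trained), `trace` (tibble
#'   with per-step loss terms), `config`.
#' @export
train_toy <- function(model, cases, steps = 500L, lr = NULL,
                      weights = loss_weights(), lines = NULL) {
  cfg <- model$config
  lr <- lr %||% cfg$lr
  lines <- lines %||% spline_config(n_samples = cfg$n_samples,
                                    sides = cfg$sides)
  codec <- codec_config(downsample_k = cfg$downsample_k,
                        input_height = cfg$input_height,
                        input_width = cfg$input_width)
  prep <- lapply(cases, function(cs) {
    if (is.null(cs$image)) stop("case has no rendered image", call. = FALSE)
    tg <- encode_all(cs$annotation, codec, lines)
    list(image = cs$image, targets = tg, gt_lines = tg$vertebral_lines)
  })

  params <- model$params
  opt <- adam_init(params)
  trace <- vector("list", steps)
  for (step in seq_len(steps)) {
    acc <- NULL
    terms_sum <- NULL
    for (cs in prep) {
      model$params <- params
      lg <- network_loss_grads(model, cs$image, cs$targets, cs$gt_lines,
                               weights)
      acc <- if (is.null(acc)) lg$grads else tree_map2(`+`, acc, lg$grads)
      tvec <- c(unlist(lg$terms[1, ]), total = lg$total)
      terms_sum <- if (is.null(terms_sum)) tvec else terms_sum + tvec
    }
    nc <- length(prep)
    acc <- tree_map2(function(g, dummy) g / nc, acc, acc)
    st <- adam_step(params, acc, opt, lr = lr)
    params <- st$params
    opt <- st$state
    avg <- terms_sum / nc
    trace[[step]] <- tibble::tibble(step = step, !!!as.list(avg))
  }
  model$params <- params
  structure(list(model = model,
                 trace = if (steps > 0) dplyr::bind_rows(trace)
                         else tibble::tibble(),
                 lr = lr, weights = weights, codec = codec, lines = lines),
            class = "vldet_fit")
}

#' Decode landmarks from a network prediction
#'
#' Runs the fixed-k or adaptive centre decoding on the predicted heatmap and
#' reads the polar corner field at each centre.
#'
#' @param outputs A prediction from [predict.vldet_model()].
#' @param config A [codec_config()] matching the model geometry.
#' @param mode `"fixed"` (top-17) or `"adaptive"` (threshold).
#' @param k_points,threshold Decoding parameters.
#' @return A landmark tibble (`vertebra`, `corner`, `x`, `y`).
#' @export
decode_prediction <- function(outputs, config, mode = c("fixed", "adaptive"),
                              k_points = 17L, threshold = 0.05) {
  mode <- match.arg(mode)
  centers <- if (mode == "fixed") {
    topk_centers(outputs$heatmap, outputs$center_offset, config, k_points)
  } else {
    adaptive_centers(outputs$heatmap, outputs$center_offset, config,
                     threshold)
  }
  decode_landmarks(centers, outputs$corner_polar, config)
}
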