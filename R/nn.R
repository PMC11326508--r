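# Minimal dense/convolutional primitives with hand-written backprop.
# Feature maps are arrays (H, W, C); convolutions are 3x3 with zero padding 1
# and stride 1 or 2, implemented by im2col so the inner loop is a matrix
# product. Each forward returns a cache consumed by the matching backward.

conv_init <- function(cin, cout, gain = sqrt(2)) {
  list(W = matrix(stats::rnorm(9L * cin * cout, 0, gain / sqrt(9 * cin)),
                  9L * cin, cout),
       b = rep(0, cout))
}

conv1x1_init <- function(cin, cout, bias = 0) {
  list(W = matrix(stats::rnorm(cin * cout, 0, 1 / sqrt(cin)), cin, cout),
       b = rep(bias, cout))
}

dense_init <- function(nin, nout) {
  list(W = matrix(stats::rnorm(nin * nout, 0, 1 / sqrt(nin)), nin, nout),
       b = rep(0, nout))
}

pad_hw <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1] + 2L, d[2] + 2L, d[3]))
  out[2:(d[1] + 1L), 2:(d[2] + 1L), ] <- x
  out
}

im2col3 <- function(xp, Ho, Wo, cin, stride) {
  cols <- matrix(0, Ho * Wo, 9L * cin)
  rows_base <- (seq_len(Ho) - 1L) * stride
  cols_base <- (seq_len(Wo) - 1L) * stride
  k <- 0L
  for (c in seq_len(cin)) for (dj in 1:3) for (di in 1:3) {
    k <- k + 1L
    cols[, k] <- xp[rows_base + di, cols_base + dj, c]
  }
  cols
}

col2im3 <- function(dcols, dims_pad, Ho, Wo, cin, stride) {
  dxp <- array(0, dims_pad)
  rows_base <- (seq_len(Ho) - 1L) * stride
  cols_base <- (seq_len(Wo) - 1L) * stride
  k <- 0L
  for (c in seq_len(cin)) for (dj in 1:3) for (di in 1:3) {
    k <- k + 1L
    dxp[rows_base + di, cols_base + dj, c] <-
      dxp[rows_base + di, cols_base + dj, c] + matrix(dcols[, k], Ho, Wo)
  }
  dxp
}

conv_forward <- function(x, layer, stride = 1L) {
  d <- dim(x)
  Ho <- (d[1] + 2L - 3L) %/% stride + 1L
  Wo <- (d[2] + 2L - 3L) %/% stride + 1L
  xp <- pad_hw(x)
  cols <- im2col3(xp, Ho, Wo, d[3], stride)
  out_mat <- sweep(cols %*% layer$W, 2L, layer$b, "+")
  list(out = array(out_mat, c(Ho, Wo, ncol(layer$W))),
       cache = list(cols = cols, dims = d, stride = stride, Ho = Ho, Wo = Wo))
}

conv_backward <- function(dout, layer, cache) {
  cout <- ncol(layer$W)
  dmat <- matrix(dout, cache$Ho * cache$Wo, cout)
  dW <- crossprod(cache$cols, dmat)
  db <- colSums(dmat)
  dcols <- tcrossprod(dmat, layer$W)
  dxp <- col2im3(dcols, c(cache$dims[1] + 2L, cache$dims[2] + 2L,
                          cache$dims[3]),
                 cache$Ho, cache$Wo, cache$dims[3], cache$stride)
  dx <- dxp[2:(cache$dims[1] + 1L), 2:(cache$dims[2] + 1L), , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

conv1x1_forward <- function(x, layer) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  out <- sweep(xm %*% layer$W, 2L, layer$b, "+")
  list(out = array(out, c(d[1], d[2], ncol(layer$W))),
       cache = list(xm = xm, dims = d))
}

conv1x1_backward <- function(dout, layer, cache) {
  d <- cache$dims
  dmat <- matrix(dout, d[1] * d[2], ncol(layer$W))
  list(dx = array(tcrossprod(dmat, layer$W), d),
       dW = crossprod(cache$xm, dmat),
       db = colSums(dmat))
}

relu_forward <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_backward <- function(dout, cache) dout * cache

sigmoid <- function(x) 1 / (1 + exp(-x))

upsample2_forward <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
    drop = FALSE]
}

upsample2_backward <- function(dout) {
  d <- dim(dout)
  o <- seq(1L, d[1], by = 2L); e <- seq(2L, d[1], by = 2L)
  oc <- seq(1L, d[2], by = 2L); ec <- seq(2L, d[2], by = 2L)
  dout[o, oc, , drop = FALSE] + dout[e, oc, , drop = FALSE] +
    dout[o, ec, , drop = FALSE] + dout[e, ec, , drop = FALSE]
}

global_avg_pool_forward <- function(x) {
  d <- dim(x)
  list(out = colMeans(matrix(x, d[1] * d[2], d[3])), cache = d)
}

global_avg_pool_backward <- function(dout, d) {
  array(rep(dout, each = d[1] * d[2]) / (d[1] * d[2]), d)
}

dense_forward <- function(v, layer) {
  list(out = drop(v %*% layer$W) + layer$b, cache = v)
}

dense_backward <- function(dout, layer, v) {
  list(dv = drop(layer$W %*% dout), dW = outer(v, dout), db = dout)
}

# ---- parameter-tree utilities (Adam over nested lists of W/b) -------------

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE)
    out
  } else {
    f(a, b)
  }
}

tree_zero <- function(a) {
  if (is.list(a)) lapply(a, tree_zero) else a * 0
}

adam_init <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mhat <- tree_map2(function(m, g) m / bc1, state$m, state$m)
  vhat <- tree_map2(function(v, g) v / bc2, state$v, state$v)
  upd <- tree_map2(function(m, v) lr * m / (sqrt(v) + eps), mhat, vhat)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}
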