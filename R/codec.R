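#' Codec configuration for supervision targets
#'
#' Controls how annotations are rasterized into the six network supervision
#' targets and how grid outputs are decoded back to landmarks. The grid is
#' the input image downsampled by `downsample_k`; a landmark at full-
#' resolution position `x` lands on grid cell `floor(x / k)` and the lost
#' fraction `x / k - floor(x / k)` is stored as a sub-pixel offset.
#'
#' The Gaussian disc radius around each centre follows either a fixed sigma
#' (`sigma_policy = "fixed"`) or the detection-style overlap rule
#' (`"iou_radius"`): the largest displacement radius at which a shifted copy
#' of the vertebra's bounding box still overlaps the original with IoU at
#' least `iou_threshold`, with `sigma = radius / 3`.
#'
#' @param downsample_k Integer downsampling factor; input dims must divide.
#' @param input_height,input_width Full-resolution input size in px.
#' @param sigma_policy `"iou_radius"` (default) or `"fixed"`.
#' @param sigma Fixed sigma in grid cells (used when `sigma_policy="fixed"`,
#'   or as fallback when box sizes are unavailable).
#' @param iou_threshold Minimum overlap for the radius rule.
#' @param heatmap_peak Peak value at each quantized centre (1.0).
#' @return A list of class `codec_config`.
#' @export
codec_config <- function(downsample_k = 4L,
                         input_height = 1024L, input_width = 512L,
                         sigma_policy = c("iou_radius", "fixed"),
                         sigma = 2, iou_threshold = 0.7,
                         heatmap_peak = 1.0) {
  sigma_policy <- match.arg(sigma_policy)
  if (input_height %% downsample_k != 0L || input_width %% downsample_k != 0L) {
    stop("input dimensions must be divisible by downsample_k", call. = FALSE)
  }
  stopifnot(sigma > 0, iou_threshold > 0, iou_threshold < 1)
  structure(list(downsample_k = as.integer(downsample_k),
                 input_height = as.integer(input_height),
                 input_width = as.integer(input_width),
                 grid_height = as.integer(input_height %/% downsample_k),
                 grid_width = as.integer(input_width %/% downsample_k),
                 sigma_policy = sigma_policy, sigma = sigma,
                 iou_threshold = iou_threshold,
                 heatmap_peak = heatmap_peak),
            class = "codec_config")
}

check_centers_inside <- function(centers, config) {
  if (any(centers$x < 0 | centers$x >= config$input_width |
            centers$y < 0 | centers$y >= config$input_height)) {
    stop("centre outside the input image", call. = FALSE)
  }
  invisible(centers)
}

quantize <- function(v, k) floor(v / k)

# CenterNet-style radius: largest shift of a w x h box keeping IoU >= overlap
gaussian_radius <- function(height, width, min_overlap = 0.7) {
  a1 <- 1; b1 <- height + width
  c1 <- width * height * (1 - min_overlap) / (1 + min_overlap)
  r1 <- (b1 - sqrt(b1^2 - 4 * a1 * c1)) / (2 * a1)
  a2 <- 4; b2 <- 2 * (height + width)
  c2 <- (1 - min_overlap) * width * height
  r2 <- (b2 - sqrt(b2^2 - 4 * a2 * c2)) / (2 * a2)
  a3 <- 4 * min_overlap; b3 <- -2 * min_overlap * (height + width)
  c3 <- (min_overlap - 1) * width * height
  r3 <- (-b3 + sqrt(b3^2 - 4 * a3 * c3)) / (2 * a3)
  max(min(r1, r2, r3), 1e-3)
}

center_sigmas <- function(config, sizes, n) {
  if (config$sigma_policy == "fixed" || is.null(sizes)) {
    rep(config$sigma, n)
  } else {
    k <- config$downsample_k
    vapply(seq_len(n), function(i) {
      gaussian_radius(sizes$h[i] / k, sizes$w[i] / k,
                      config$iou_threshold) / 3
    }, numeric(1))
  }
}

#' Encode the centre-point heatmap
#'
#' Places an unnormalized 2-D Gaussian disc (`exp(-d^2 / (2 sigma^2))`,
#' peak 1) around each quantized vertebra centre on the downsampled grid;
#' overlapping discs merge by element-wise maximum.
#'
#' @param centers Centre table with columns `x`, `y` (full-resolution px).
#' @param config A [codec_config()].
#' @param sizes Optional per-centre bounding-box sizes, a data frame with
#'   columns `w`, `h` in full-resolution px, used by the `iou_radius` sigma
#'   policy (as produced inside [encode_all()]).
#' @return A `grid_height` x `grid_width` matrix with values in \[0, 1\].
#' @export
encode_heatmap <- function(centers, config, sizes = NULL) {
  check_centers_inside(centers, config)
  k <- config$downsample_k
  H <- config$grid_height; W <- config$grid_width
  hm <- matrix(0, H, W)
  sig <- center_sigmas(config, sizes, nrow(centers))
  gx_all <- matrix(rep(0:(W - 1L), each = H), H, W)
  gy_all <- matrix(rep(0:(H - 1L), times = W), H, W)
  for (i in seq_len(nrow(centers))) {
    qx <- quantize(centers$x[i], k); qy <- quantize(centers$y[i], k)
    d2 <- (gx_all - qx)^2 + (gy_all - qy)^2
    hm <- pmax(hm, config$heatmap_peak * exp(-d2 / (2 * sig[i]^2)))
  }
  hm
}

#' Encode sub-pixel centre offsets
#'
#' At each quantized centre cell stores the fractional part
#' `(x/k - floor(x/k), y/k - floor(y/k))` lost to downsampling, so decoding
#' can restore the centre exactly.
#'
#' @inheritParams encode_heatmap
#' @return A list: `offset` (H x W x 2 array, channels x then y, values in
#'   \[0,1)) and `mask` (H x W logical, `TRUE` at supervised cells).
#' @export
encode_center_offset <- function(centers, config) {
  check_centers_inside(centers, config)
  k <- config$downsample_k
  off <- array(0, c(config$grid_height, config$grid_width, 2L))
  mask <- matrix(FALSE, config$grid_height, config$grid_width)
  for (i in seq_len(nrow(centers))) {
    qx <- quantize(centers$x[i], k); qy <- quantize(centers$y[i], k)
    off[qy + 1L, qx + 1L, 1L] <- centers$x[i] / k - qx
    off[qy + 1L, qx + 1L, 2L] <- centers$y[i] / k - qy
    mask[qy + 1L, qx + 1L] <- TRUE
  }
  list(offset = off, mask = mask)
}

#' Polar corner representation
#'
#' `corners_to_polar()` expresses the four corners of one vertebra relative
#' to its centre (the pole) as polar diameter `r` (px) and polar angle
#' `theta` (radians in (-pi, pi\], measured from the positive-x axis in the
#' y-down image frame); `polar_to_cartesian()` is the exact inverse,
#' `x = x_ct + r cos(theta)`, `y = y_ct + r sin(theta)`.
#'
#' @param quad A 4 x 2 matrix of corners (rows 1=TL, 2=TR, 3=BL, 4=BR) or a
#'   landmark table for one vertebra.
#' @param center Centre as `c(x, y)` or a one-row table.
#' @return `corners_to_polar()`: a tibble with columns `corner`, `r`,
#'   `theta`; `polar_to_cartesian()`: a tibble with columns `x`, `y`.
#' @export
corners_to_polar <- function(quad, center) {
  qm <- if (is.matrix(quad)) quad else as_landmark_matrix(quad)
  ctr <- if (is.numeric(center) && length(center) == 2L) center
         else c(center$x[1], center$y[1])
  dx <- qm[, 1] - ctr[1]; dy <- qm[, 2] - ctr[2]
  r <- sqrt(dx^2 + dy^2)
  theta <- ifelse(r == 0, 0, atan2(dy, dx))
  tibble::tibble(corner = seq_len(nrow(qm)), r = r, theta = theta)
}

#' @rdname corners_to_polar
#' @param r,theta Polar diameter (>= 0) and angle in radians.
#' @export
polar_to_cartesian <- function(center, r, theta) {
  ctr <- if (is.numeric(center) && length(center) == 2L) center
         else c(center$x[1], center$y[1])
  stopifnot(all(r >= 0))
  tibble::tibble(x = ctr[1] + r * cos(theta), y = ctr[2] + r * sin(theta))
}

#' Encode polar corner offsets
#'
#' At each quantized centre cell stores `(r, theta)` for corners 1..4 in
#' eight channels (r1, theta1, ..., r4, theta4); radii are full-resolution
#' pixels so decoding is exact.
#'
#' @param ann A [spine_annotation()].
#' @inheritParams encode_heatmap
#' @return A list: `polar` (H x W x 8 array) and `mask` (H x W logical).
#' @export
encode_corner_polar <- function(ann, config) {
  centers <- spine_centers(ann)
  check_centers_inside(centers, config)
  k <- config$downsample_k
  arr <- array(0, c(config$grid_height, config$grid_width, 8L))
  mask <- matrix(FALSE, config$grid_height, config$grid_width)
  for (i in seq_len(nrow(centers))) {
    v <- centers$vertebra[i]
    pc <- corners_to_polar(ann[ann$vertebra == v, ],
                           c(centers$x[i], centers$y[i]))
    qx <- quantize(centers$x[i], k); qy <- quantize(centers$y[i], k)
    arr[qy + 1L, qx + 1L, seq(1L, 8L, by = 2L)] <- pc$r
    arr[qy + 1L, qx + 1L, seq(2L, 8L, by = 2L)] <- pc$theta
    mask[qy + 1L, qx + 1L] <- TRUE
  }
  list(polar = arr, mask = mask)
}

#' Encode adjacent centre-point intervals (CPIE)
#'
#' At the quantized centre cell of vertebra i (i = 1..16) stores the
#' full-resolution vector from centre i to centre i+1; the last vertebra is
#' unsupervised. The telescoping sum of the 16 intervals reconstructs the
#' last centre from the first.
#'
#' @inheritParams encode_heatmap
#' @return A list: `cpie` (H x W x 2 array) and `mask` (H x W logical with
#'   16 supervised cells for 17 centres).
#' @export
encode_cpie <- function(centers, config) {
  check_centers_inside(centers, config)
  k <- config$downsample_k
  arr <- array(0, c(config$grid_height, config$grid_width, 2L))
  mask <- matrix(FALSE, config$grid_height, config$grid_width)
  n <- nrow(centers)
  for (i in seq_len(n - 1L)) {
    qx <- quantize(centers$x[i], k); qy <- quantize(centers$y[i], k)
    arr[qy + 1L, qx + 1L, 1L] <- centers$x[i + 1L] - centers$x[i]
    arr[qy + 1L, qx + 1L, 2L] <- centers$y[i + 1L] - centers$y[i]
    mask[qy + 1L, qx + 1L] <- TRUE
  }
  list(cpie = arr, mask = mask)
}

#' Encode adjacent vertebra interval offsets (AVIE)
#'
#' At the quantized centre cell of vertebra i (i = 2..17) stores the
#' four-vector from the bottom corners (3, 4) of vertebra i-1 to the top
#' corners (1, 2) of vertebra i:
#' `(x1_i - x3_{i-1}, y1_i - y3_{i-1}, x2_i - x4_{i-1}, y2_i - y4_{i-1})`.
#' The first vertebra is unsupervised.
#'
#' @param ann A [spine_annotation()].
#' @inheritParams encode_heatmap
#' @return A list: `avie` (H x W x 4 array) and `mask` (H x W logical with
#'   16 supervised cells).
#' @export
encode_avie <- function(ann, config) {
  centers <- spine_centers(ann)
  check_centers_inside(centers, config)
  k <- config$downsample_k
  arr <- array(0, c(config$grid_height, config$grid_width, 4L))
  mask <- matrix(FALSE, config$grid_height, config$grid_width)
  m <- as_landmark_matrix(ann)
  n <- nrow(centers)
  for (i in 2:n) {
    up <- (i - 2L) * 4L; lo <- (i - 1L) * 4L
    qx <- quantize(centers$x[i], k); qy <- quantize(centers$y[i], k)
    arr[qy + 1L, qx + 1L, 1L] <- m[lo + 1L, 1] - m[up + 3L, 1]
    arr[qy + 1L, qx + 1L, 2L] <- m[lo + 1L, 2] - m[up + 3L, 2]
    arr[qy + 1L, qx + 1L, 3L] <- m[lo + 2L, 1] - m[up + 4L, 1]
    arr[qy + 1L, qx + 1L, 4L] <- m[lo + 2L, 2] - m[up + 4L, 2]
    mask[qy + 1L, qx + 1L] <- TRUE
  }
  list(avie = arr, mask = mask)
}

#' Encode all supervision targets for one annotation
#'
#' Composes the heatmap, centre offset, polar corner, CPIE and AVIE
#' encodings plus the vertebral line set into the full target bundle used
#' for training and for decoding tests. Deterministic.
#'
#' @param ann A [spine_annotation()].
#' @param config A [codec_config()].
#' @param lines A [spline_config()] for the vertebral line targets.
#' @return A list of class `encoded_targets` with elements `heatmap`,
#'   `center_offset`, `corner_polar`, `cpie`, `avie`, `vertebral_lines`,
#'   `center_mask`, `cpie_mask`, `avie_mask`, `config`.
#' @export
encode_all <- function(ann, config = codec_config(), lines = spline_config()) {
  stop_if_invalid(ann)
  centers <- spine_centers(ann)
  wide <- tidyr::pivot_wider(ann, id_cols = "vertebra",
                             names_from = "corner",
                             values_from = c("x", "y"))
  sizes <- tibble::tibble(
    w = pmax(wide$x_2, wide$x_4) - pmin(wide$x_1, wide$x_3),
    h = pmax(wide$y_3, wide$y_4) - pmin(wide$y_1, wide$y_2)
  )
  co <- encode_center_offset(centers, config)
  cp <- encode_corner_polar(ann, config)
  ci <- encode_cpie(centers, config)
  av <- encode_avie(ann, config)
  structure(list(
    heatmap = encode_heatmap(centers, config, sizes = sizes),
    center_offset = co$offset,
    corner_polar = cp$polar,
    cpie = ci$cpie,
    avie = av$avie,
    vertebral_lines = encode_vertebral_lines(ann, lines),
    center_mask = co$mask,
    cpie_mask = ci$mask,
    avie_mask = av$mask,
    config = config
  ), class = "encoded_targets")
}

#' Non-maximum suppression on a heatmap
#'
#' A cell keeps its value iff it equals the maximum over its 3 x 3
#' neighbourhood (ties within a window are all kept); all other cells are
#' zeroed.
#'
#' @param heatmap A numeric matrix.
#' @return A matrix of the same shape.
#' @export
nms <- function(heatmap) {
  H <- nrow(heatmap); W <- ncol(heatmap)
  pad <- matrix(-Inf, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- heatmap
  local_max <- matrix(-Inf, H, W)
  for (di in 0:2) for (dj in 0:2) {
    local_max <- pmax(local_max, pad[di + seq_len(H), dj + seq_len(W)])
  }
  ifelse(heatmap == local_max, heatmap, 0)
}

decode_centers_at <- function(idx, heatmap, center_offset, config) {
  k <- config$downsample_k
  H <- nrow(heatmap)
  gy <- (idx - 1L) %% H          # 0-based row
  gx <- (idx - 1L) %/% H         # 0-based col
  # sub-pixel offsets are fractional parts by construction; clamp network
  # outputs to the same [0, 1) range before restoring full resolution
  ox <- pmin(pmax(center_offset[cbind(gy + 1L, gx + 1L, 1L)], 0), 1 - 1e-9)
  oy <- pmin(pmax(center_offset[cbind(gy + 1L, gx + 1L, 2L)], 0), 1 - 1e-9)
  x <- (gx + ox) * k
  y <- (gy + oy) * k
  out <- tibble::tibble(x = x, y = y, score = heatmap[idx])
  out <- out[order(out$y), ]
  out$vertebra <- seq_len(nrow(out))
  out[, c("vertebra", "x", "y", "score")]
}

#' Decode centres with fixed k (top-k) or adaptive thresholding
#'
#' `topk_centers()` applies NMS, takes the `k_points` highest-valued cells
#' (ties broken by value then row-major cell index), restores sub-pixel
#' offsets, rescales to full resolution, and assigns vertebra indices 1..k
#' in order of increasing y. `adaptive_centers()` instead keeps every NMS
#' survivor with value strictly above `threshold`, so the number of detected
#' centres can differ from 17.
#'
#' @param heatmap Heatmap matrix (raw; NMS is applied internally).
#' @param center_offset H x W x 2 offset array.
#' @param config A [codec_config()].
#' @param k_points Number of centres to keep.
#' @return A tibble `vertebra`, `x`, `y`, `score` sorted by y.
#' @export
topk_centers <- function(heatmap, center_offset, config, k_points = 17L) {
  supp <- nms(heatmap)
  nz <- which(supp > 0)
  if (length(nz) < k_points) {
    stop("only ", length(nz), " nonzero heatmap peaks, need ", k_points,
         call. = FALSE)
  }
  H <- nrow(supp)
  rowmajor <- ((nz - 1L) %% H) * ncol(supp) + (nz - 1L) %/% H
  ord <- order(-supp[nz], rowmajor)
  decode_centers_at(nz[ord[seq_len(k_points)]], supp, center_offset, config)
}

#' @rdname topk_centers
#' @param threshold Strict heatmap intensity threshold in (0, 1).
#' @export
adaptive_centers <- function(heatmap, center_offset, config,
                             threshold = 0.05) {
  supp <- nms(heatmap)
  keep <- which(supp > threshold)
  if (length(keep) == 0L) {
    return(tibble::tibble(vertebra = integer(), x = numeric(),
                          y = numeric(), score = numeric()))
  }
  decode_centers_at(keep, supp, center_offset, config)
}

#' Decode 68 landmarks from centres and the polar corner field
#'
#' For each centre, reads `(r, theta)` for corners 1..4 at the centre's
#' quantized grid cell and applies the polar-to-Cartesian transform.
#'
#' @param centers Centre tibble (`vertebra`, `x`, `y`), e.g. from
#'   [topk_centers()].
#' @param corner_polar H x W x 8 polar array.
#' @param config A [codec_config()].
#' @return A landmark tibble `vertebra`, `corner`, `x`, `y` (4 rows per
#'   centre, grouped by vertebra).
#' @export
decode_landmarks <- function(centers, corner_polar, config) {
  k <- config$downsample_k
  H <- dim(corner_polar)[1]; W <- dim(corner_polar)[2]
  rows <- vector("list", nrow(centers))
  for (i in seq_len(nrow(centers))) {
    qx <- quantize(centers$x[i], k); qy <- quantize(centers$y[i], k)
    if (qx < 0 || qx >= W || qy < 0 || qy >= H) {
      stop("centre ", i, " outside the decoding grid", call. = FALSE)
    }
    r <- pmax(corner_polar[qy + 1L, qx + 1L, seq(1L, 8L, by = 2L)], 0)
    theta <- corner_polar[qy + 1L, qx + 1L, seq(2L, 8L, by = 2L)]
    xy <- polar_to_cartesian(c(centers$x[i], centers$y[i]), r, theta)
    rows[[i]] <- tibble::tibble(vertebra = centers$vertebra[i],
                                corner = 1:4, x = xy$x, y = xy$y)
  }
  dplyr::bind_rows(rows)
}
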