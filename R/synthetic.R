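#' Simulation parameters for a synthetic scoliotic spine
#'
#' The simulator draws a smooth scoliotic centerline as a sum of sinusoids in
#' the lateral (x) direction, places `n_vertebrae` vertebral bodies at equal
#' arc-length spacing along it, and rotates each body to the local tangent.
#' Because the centerline and its tangents are closed-form, every simulated
#' case carries analytic ground-truth tilt angles and Cobb angles.
#'
#' Defaults emulate a standard AP study: a 1024 x 512 pixel radiograph with
#' 17 thoracic/lumbar vertebrae whose bodies grow from thoracic to lumbar
#' size, a main lateral bow plus a shorter secondary bow (giving realistic
#' S-shaped curves with Cobb angles roughly in the 10-45 degree range), and
#' background clutter that strengthens toward the lower half of the image,
#' where abdominal tissue obscures real radiographs.
#'
#' @param n_vertebrae Number of vertebrae (>= 2).
#' @param image_height,image_width Canvas size in pixels.
#' @param curve_amplitudes Peak lateral deviations of the sinusoidal bows, px.
#' @param curve_frequencies Cycles of each bow over the spine length.
#' @param vertebra_width_range,vertebra_height_range Body size in px,
#'   linearly interpolated from the most superior to the most inferior
#'   vertebra.
#' @param gap_fraction Inter-vertebral gap as a fraction of body height;
#'   centre spacing is `mean(height) * (1 + gap_fraction)` along the arc.
#' @param noise_sd Additive Gaussian pixel noise (intensity units, image in
#'   \[0, 1\]).
#' @param lower_region_clutter Strength in \[0, 1\] of extra background
#'   texture ramping from zero at the top row to this value at the bottom.
#' @param margin Vertical margin in px between the canvas border and the
#'   first/last vertebra centre.
#' @param randomize If `TRUE`, each seed jitters bow amplitudes (50-100%),
#'   frequencies (+-10%) and phases; if `FALSE` the stated amplitudes are
#'   used exactly with zero phase.
#' @param seed Integer seed; identical seeds give byte-identical cases.
#' @return A list of class `spine_sim_params`.
#' @export
spine_sim_params <- function(n_vertebrae = 17L,
                             image_height = 1024L, image_width = 512L,
                             curve_amplitudes = c(40, 12),
                             curve_frequencies = c(1, 2),
                             vertebra_width_range = c(64, 100),
                             vertebra_height_range = c(36, 50),
                             gap_fraction = 0.25,
                             noise_sd = 0.02,
                             lower_region_clutter = 0.35,
                             margin = 60,
                             randomize = TRUE,
                             seed = 1L) {
  stopifnot(n_vertebrae >= 2L, gap_fraction > 0, gap_fraction < 1,
            length(curve_amplitudes) == length(curve_frequencies),
            lower_region_clutter >= 0, lower_region_clutter <= 1)
  structure(list(
    n_vertebrae = as.integer(n_vertebrae),
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    curve_amplitudes = curve_amplitudes,
    curve_frequencies = curve_frequencies,
    vertebra_width_range = vertebra_width_range,
    vertebra_height_range = vertebra_height_range,
    gap_fraction = gap_fraction,
    noise_sd = noise_sd,
    lower_region_clutter = lower_region_clutter,
    margin = margin,
    randomize = isTRUE(randomize),
    seed = as.integer(seed)
  ), class = "spine_sim_params")
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Generate one synthetic scoliotic spine case
#'
#' Places vertebrae at equal arc spacing on a sinusoidal centerline, emits
#' the corner annotation (corner order 1=TL, 2=TR, 3=BL, 4=BR), renders a
#' pseudo-radiograph, and computes the analytic true Cobb angles from the
#' closed-form tangent tilts using the same regional partition rule as
#' [cobb_from_landmarks()].
#'
#' @param params A [spine_sim_params()].
#' @param render If `FALSE`, skip image rendering (annotation-only, fast).
#' @return A list of class `simulated_case` with elements `annotation`
#'   ([spine_annotation()]), `image` (H x W matrix in \[0,1\], or `NULL`),
#'   `true_cobb` (one-row tibble `pt`, `mt`, `tl` in degrees) and
#'   `tilt_per_vertebra` (degrees from vertical, signed).
#' @export
generate_case <- function(params, render = TRUE) {
  stopifnot(inherits(params, "spine_sim_params"))
  p <- params
  geom <- with_seed(p$seed, spine_geometry(p))

  ann <- spine_annotation(geom$landmarks, p$image_width, p$image_height,
                          n_vertebrae = p$n_vertebrae)
  dims <- img_dims(ann)
  if (any(ann$x < 0 | ann$x >= dims["width"] |
            ann$y < 0 | ann$y >= dims["height"])) {
    stop("simulated geometry exceeds the canvas; reduce amplitudes or sizes",
         call. = FALSE)
  }

  # analytic truth: angle between two rigidly rotated bodies = tilt difference
  angle_mat <- abs(outer(geom$tilt, geom$tilt, "-"))
  mid_pv <- endplate_midpoints(as_landmark_matrix(ann))
  cobb <- cobb_partition(angle_mat, mid_pv, p$image_height)

  image <- if (render) render_xray(ann, p) else NULL
  structure(list(annotation = ann, image = image,
                 true_cobb = cobb$angles,
                 tilt_per_vertebra = geom$tilt,
                 params = p),
            class = "simulated_case")
}

# centerline, tangents and corner geometry (expects an active RNG stream)
spine_geometry <- function(p) {
  n <- p$n_vertebrae
  k <- length(p$curve_amplitudes)
  if (p$randomize && k > 0) {
    amp <- p$curve_amplitudes * stats::runif(k, 0.5, 1)
    freq <- p$curve_frequencies * stats::runif(k, 0.9, 1.1)
    phase <- stats::runif(k, 0, 2 * pi)
  } else {
    amp <- p$curve_amplitudes
    freq <- p$curve_frequencies
    phase <- rep(0, k)
  }
  y0 <- p$margin
  y1 <- p$image_height - p$margin
  xc <- function(t) {
    out <- rep(p$image_width / 2, length(t))
    for (j in seq_len(k)) {
      out <- out + amp[j] * sin(2 * pi * freq[j] * t + phase[j])
    }
    out
  }
  dxdt <- function(t) {
    out <- rep(0, length(t))
    for (j in seq_len(k)) {
      out <- out + amp[j] * 2 * pi * freq[j] * cos(2 * pi * freq[j] * t +
                                                     phase[j])
    }
    out
  }
  dydt <- y1 - y0

  ts <- seq(0, 1, length.out = 4001L)
  arc <- c(0, cumsum(sqrt(diff(xc(ts))^2 + (dydt / 4000)^2)))
  total <- arc[length(arc)]

  spacing <- mean(p$vertebra_height_range) * (1 + p$gap_fraction)
  span <- (n - 1L) * spacing
  if (span > total) {
    stop("spine span exceeds centerline length; lower gap_fraction or sizes",
         call. = FALSE)
  }
  arc_i <- (total - span) / 2 + (seq_len(n) - 1L) * spacing
  t_i <- stats::approx(arc, ts, xout = arc_i, ties = "ordered")$y

  cx <- xc(t_i)
  cy <- y0 + t_i * dydt
  tilt <- atan2(dxdt(t_i), dydt) * 180 / pi

  w_i <- seq(p$vertebra_width_range[1], p$vertebra_width_range[2],
             length.out = n)
  h_i <- seq(p$vertebra_height_range[1], p$vertebra_height_range[2],
             length.out = n)

  tan_x <- dxdt(t_i)
  norm <- sqrt(tan_x^2 + dydt^2)
  tx <- tan_x / norm; ty <- dydt / norm       # unit tangent, points inferior
  nx <- ty; ny <- -tx                          # unit normal, points right

  corners <- matrix(0, n * 4L, 2L)
  for (i in seq_len(n)) {
    hw <- w_i[i] / 2; hh <- h_i[i] / 2
    base <- (i - 1L) * 4L
    corners[base + 1L, ] <- c(cx[i] - hw * nx[i] - hh * tx[i],
                              cy[i] - hw * ny[i] - hh * ty[i])   # TL
    corners[base + 2L, ] <- c(cx[i] + hw * nx[i] - hh * tx[i],
                              cy[i] + hw * ny[i] - hh * ty[i])   # TR
    corners[base + 3L, ] <- c(cx[i] - hw * nx[i] + hh * tx[i],
                              cy[i] - hw * ny[i] + hh * ty[i])   # BL
    corners[base + 4L, ] <- c(cx[i] + hw * nx[i] + hh * tx[i],
                              cy[i] + hw * ny[i] + hh * ty[i])   # BR
  }
  list(landmarks = corners, tilt = tilt, center = cbind(cx, cy))
}

#' Render a pseudo-radiograph for an annotation
#'
#' Vertebral bodies are filled bright quadrilaterals over a dark background,
#' softened with a small Gaussian blur; background clutter (smoothed positive
#' texture) ramps linearly from zero at the top row to
#' `lower_region_clutter` at the bottom row, and i.i.d. Gaussian noise of sd
#' `noise_sd` is added before clipping to \[0, 1\].
#'
#' @param ann A [spine_annotation()].
#' @param params A [spine_sim_params()] (supplies noise, clutter and seed).
#' @return An `image_height` x `image_width` numeric matrix in \[0, 1\].
#' @export
render_xray <- function(ann, params) {
  stop_if_invalid(ann)
  p <- params
  H <- p$image_height; W <- p$image_width
  with_seed(p$seed + 104729L, {
    img <- matrix(0.10, H, W)

    if (p$lower_region_clutter > 0) {
      coarse <- matrix(stats::runif((H %/% 16 + 2) * (W %/% 16 + 2)),
                       H %/% 16 + 2, W %/% 16 + 2)
      tex <- coarse[ceiling(seq_len(H) / 16), ceiling(seq_len(W) / 16)]
      tex <- blur_gaussian(tex, sigma = 6)
      ramp <- matrix(seq(0, 1, length.out = H), H, W)
      img <- img + p$lower_region_clutter * 0.5 * ramp * tex
    }

    quads <- matrix(0, H, W)
    for (v in sort(unique(ann$vertebra))) {
      sub <- ann[ann$vertebra == v, ]
      poly_x <- sub$x[c(1, 2, 4, 3)]    # TL, TR, BR, BL outline
      poly_y <- sub$y[c(1, 2, 4, 3)]
      xs <- max(0L, floor(min(poly_x)) - 2L):min(W - 1L,
                                                 ceiling(max(poly_x)) + 2L)
      ys <- max(0L, floor(min(poly_y)) - 2L):min(H - 1L,
                                                 ceiling(max(poly_y)) + 2L)
      gx <- rep(xs, each = length(ys))
      gy <- rep(ys, times = length(xs))
      inside <- point_in_convex_quad(gx, gy, poly_x, poly_y)
      val <- 0.75 + stats::runif(1, -0.05, 0.05)
      idx <- cbind(gy[inside] + 1L, gx[inside] + 1L)
      quads[idx] <- pmax(quads[idx], val)
    }
    quads <- blur_gaussian(quads, sigma = 1.5)
    img <- img + quads
    if (p$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(H * W, 0, p$noise_sd), H, W)
    }
    pmin(pmax(img, 0), 1)
  })
}

point_in_convex_quad <- function(px, py, qx, qy) {
  sgn <- NULL
  ok <- rep(TRUE, length(px))
  for (e in 1:4) {
    a <- e; b <- if (e == 4) 1 else e + 1
    cross <- (qx[b] - qx[a]) * (py - qy[a]) - (qy[b] - qy[a]) * (px - qx[a])
    if (is.null(sgn)) sgn <- sign(sum(cross))
    ok <- ok & (cross * sgn >= 0)
  }
  ok
}

# separable Gaussian blur with reflected edges
blur_gaussian <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth_1d <- function(mat) {
    n <- nrow(mat)
    idx <- outer(seq_len(n), seq(-r, r), "+")
    idx[idx < 1L] <- 2L - idx[idx < 1L]
    idx[idx > n] <- 2L * n - idx[idx > n]
    out <- matrix(0, n, ncol(mat))
    for (j in seq_len(2L * r + 1L)) {
      out <- out + k[j] * mat[idx[, j], , drop = FALSE]
    }
    out
  }
  t(smooth_1d(t(smooth_1d(m))))
}

#' Generate a dataset of simulated cases
#'
#' Derives one seed per case (`seed + case index`), generates each case, and
#' (optionally) writes PNG images, annotation files and a `manifest.csv`
#' listing the true Cobb angles.
#'
#' @param n_cases Number of cases (>= 1).
#' @param params Base [spine_sim_params()]; the per-case seed replaces
#'   `params$seed`.
#' @param seed Base seed; defaults to `params$seed`.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param annotation_format `"json"` or `"csv"`.
#' @param render Render images (needed when `out_dir` is given).
#' @return A list with `cases` (list of `simulated_case`) and `manifest`
#'   (tibble: case, seed, files, pt/mt/tl in degrees).
#' @export
generate_dataset <- function(n_cases, params = spine_sim_params(),
                             seed = params$seed, out_dir = NULL,
                             annotation_format = c("json", "csv"),
                             render = !is.null(out_dir)) {
  stopifnot(n_cases >= 1L)
  annotation_format <- match.arg(annotation_format)
  cases <- vector("list", n_cases)
  rows <- vector("list", n_cases)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  for (i in seq_len(n_cases)) {
    pi <- params
    pi$seed <- as.integer(seed + i)
    cs <- generate_case(pi, render = render)
    cases[[i]] <- cs
    img_file <- ann_file <- NA_character_
    if (!is.null(out_dir)) {
      img_file <- sprintf("case_%03d.png", i)
      ann_file <- sprintf("case_%03d.%s", i, annotation_format)
      png::writePNG(cs$image, file.path(out_dir, img_file))
      write_spine_annotation(cs$annotation, file.path(out_dir, ann_file))
    }
    rows[[i]] <- tibble::tibble(case = i, seed = pi$seed,
                                image = img_file, annotation = ann_file,
                                pt = cs$true_cobb$pt,
                                mt = cs$true_cobb$mt,
                                tl = cs$true_cobb$tl)
  }
  manifest <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(cases = cases, manifest = manifest)
}

#' @export
print.simulated_case <- function(x, ...) {
  cat(sprintf(
    "<simulated_case: %d vertebrae, Cobb PT/MT/TL = %.1f/%.1f/%.1f deg%s>\n",
    length(x$tilt_per_vertebra),
    x$true_cobb$pt, x$true_cobb$mt, x$true_cobb$tl,
    if (is.null(x$image)) ", no image" else ""))
  invisible(x)
}
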