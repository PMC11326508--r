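#' Vertebral line configuration
#'
#' Settings for sparse-to-dense vertebral line interpolation: a smooth
#' interpolating spline is drawn through per-vertebra control points (left
#' corners, centres, or right corners) and resampled at `n_samples`
#' arc-length-equidistant points, densifying 17-34 sparse annotations into
#' a 100-point curve that describes the overall spine morphology.
#'
#' @param degree Spline degree: 3 (cubic, default) or 1 (polyline).
#' @param n_samples Number of equidistant samples per line (>= 2).
#' @param arc_resolution Dense subdivisions used to compute arc length and
#'   invert it (>= 10 * n_samples).
#' @param sides Subset of `c("left", "middle", "right")`; the default
#'   middle-only keeps the parameter count down, which in practice loses
#'   almost nothing.
#' @return A list of class `spline_config`.
#' @export
spline_config <- function(degree = 3L, n_samples = 100L,
                          arc_resolution = 10000L,
                          sides = "middle") {
  sides <- match.arg(sides, c("left", "middle", "right"),
                     several.ok = TRUE)
  stopifnot(n_samples >= 2L, degree >= 1L,
            arc_resolution >= 10L * n_samples)
  structure(list(degree = as.integer(degree),
                 n_samples = as.integer(n_samples),
                 arc_resolution = as.integer(arc_resolution),
                 sides = sides),
            class = "spline_config")
}

#' Collect ordered control points for one vertebral line
#'
#' Left line: corners 1 (top-left) then 3 (bottom-left) of each vertebra,
#' superior to inferior (34 points for 17 vertebrae); right line: corners 2
#' then 4 (34 points); middle line: the 17 vertebra centres.
#'
#' @param ann A [spine_annotation()].
#' @param side `"left"`, `"middle"` or `"right"`.
#' @return A tibble with columns `x`, `y` in control-point order.
#' @export
collect_line_points <- function(ann, side) {
  side <- match.arg(side, c("left", "middle", "right"))
  if (side == "middle") {
    ctr <- spine_centers(ann)
    return(tibble::tibble(x = ctr$x, y = ctr$y))
  }
  corners <- if (side == "left") c(1L, 3L) else c(2L, 4L)
  sub <- ann[ann$corner %in% corners, ]
  sub <- sub[order(sub$vertebra, match(sub$corner, corners)), ]
  tibble::tibble(x = sub$x, y = sub$y)
}

#' Fit an interpolating spline through ordered control points
#'
#' Chord-length parameterized interpolating spline, one coordinate function
#' per axis; every control point lies on the curve. Degree 3 uses a cubic
#' spline, degree 1 linear interpolation.
#'
#' @param points A data frame with columns `x`, `y` in curve order.
#' @param config A [spline_config()].
#' @return A list of class `spine_curve`: `fx(t)`, `fy(t)` on `t` in
#'   \[0, 1\], `knots` (control-point parameters), `points`.
#' @export
fit_interpolating_spline <- function(points, config = spline_config()) {
  n <- nrow(points)
  if (n < config$degree + 1L) {
    stop("need at least degree+1 control points", call. = FALSE)
  }
  chord <- sqrt(diff(points$x)^2 + diff(points$y)^2)
  if (any(chord == 0)) {
    stop("duplicate consecutive control points at position ",
         paste(which(chord == 0), collapse = ","), call. = FALSE)
  }
  t_knots <- c(0, cumsum(chord))
  t_knots <- t_knots / t_knots[n]
  if (config$degree == 1L) {
    fx <- stats::approxfun(t_knots, points$x)
    fy <- stats::approxfun(t_knots, points$y)
  } else {
    fx <- stats::splinefun(t_knots, points$x, method = "fmm")
    fy <- stats::splinefun(t_knots, points$y, method = "fmm")
  }
  structure(list(fx = fx, fy = fy, knots = t_knots,
                 points = tibble::as_tibble(points[, c("x", "y")])),
            class = "spine_curve")
}

#' Sample a curve at arc-length-equidistant points
#'
#' Arc length is computed on a dense piecewise-linear subdivision
#' (`arc_resolution` segments) and inverted by interpolation; the samples
#' include both curve endpoints.
#'
#' @param curve A `spine_curve` from [fit_interpolating_spline()].
#' @param config A [spline_config()].
#' @return A tibble with columns `x`, `y` (`n_samples` rows) and attribute
#'   `arc_length` (dense-subdivision curve length).
#' @export
sample_equidistant <- function(curve, config = spline_config()) {
  ts <- seq(0, 1, length.out = config$arc_resolution + 1L)
  xs <- curve$fx(ts); ys <- curve$fy(ts)
  seg <- sqrt(diff(xs)^2 + diff(ys)^2)
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  if (total <= 0) stop("zero-length curve", call. = FALSE)
  target <- seq(0, total, length.out = config$n_samples)
  tt <- stats::approx(arc, ts, xout = target, ties = "ordered")$y
  out <- tibble::tibble(x = curve$fx(tt), y = curve$fy(tt))
  attr(out, "arc_length") <- total
  attr(out, "t") <- tt
  out
}

#' Encode the vertebral line set for an annotation
#'
#' Fits and resamples each enabled line (left/middle/right).
#'
#' @param ann A [spine_annotation()].
#' @param config A [spline_config()].
#' @return A named list of class `vertebral_lines`; each element is an
#'   `n_samples`-row tibble `x`, `y`.
#' @export
encode_vertebral_lines <- function(ann, config = spline_config()) {
  out <- lapply(config$sides, function(s) {
    pts <- collect_line_points(ann, s)
    sample_equidistant(fit_interpolating_spline(pts, config), config)
  })
  names(out) <- config$sides
  structure(out, class = "vertebral_lines", config = config)
}
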