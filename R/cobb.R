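#' Cobb angles from 68 vertebra landmarks
#'
#' Implements the standard landmark-based Cobb measurement used for AP
#' scoliosis radiographs with 17 annotated vertebrae. For each vertebra the
#' slope vector runs from the midpoint of its left edge (corners 1, 3) to the
#' midpoint of its right edge (corners 2, 4). The angle between every pair of
#' vertebrae is the arccosine of the normalized dot product of their slope
#' vectors; the main thoracic (MT) angle is the maximum entry of this 17 x 17
#' matrix, attained between an upper end vertebra `p1` and a lower end
#' vertebra `p2`. For a C-shaped (single-bow) spine the proximal thoracic
#' (PT) angle is the angle between the first vertebra and `p1` and the
#' thoracolumbar (TL) angle is the angle between the last vertebra and `p2`.
#' For an S-shaped spine (detected by a sign test of the endplate midpoints'
#' lateral displacement relative to the first-to-last chord) the PT and TL
#' angles are the maximal angles within the regions above `p1` and below
#' `p2`. Parallel endplates give a zero angle.
#'
#' @param landmarks A [spine_annotation()] or a 68 x 2 landmark matrix
#'   ordered vertebra-major, corner-minor (1=TL, 2=TR, 3=BL, 4=BR).
#' @param image_height Canvas height in px, used only by the S-curve region
#'   test; defaults to the annotation attribute or the landmark extent.
#' @param s_curve_rule Apply the S-shaped-curve partition branch (the
#'   behaviour of the AASCE reference measurement); `FALSE` always uses the
#'   C-shaped rule.
#' @return A one-row tibble of class `cobb_angles` with columns `pt`, `mt`,
#'   `tl` (degrees) and attribute `mt_pair` (the two most-tilted vertebra
#'   indices).
#' @examples
#' case <- generate_case(spine_sim_params(seed = 3), render = FALSE)
#' cobb_from_landmarks(case$annotation)
#' case$true_cobb
#' @export
cobb_from_landmarks <- function(landmarks, image_height = NULL,
                                s_curve_rule = TRUE) {
  if (inherits(landmarks, "spine_annotation")) {
    image_height <- image_height %||% unname(img_dims(landmarks)["height"])
    m <- as_landmark_matrix(landmarks)
  } else if (is.data.frame(landmarks)) {
    m <- as_landmark_matrix(landmarks)
  } else {
    m <- as.matrix(landmarks)
  }
  if (ncol(m) != 2L || nrow(m) %% 4L != 0L) {
    stop("landmarks must be an n*4 x 2 matrix", call. = FALSE)
  }
  n <- nrow(m) %/% 4L
  image_height <- image_height %||% max(m[, 2])

  i0 <- (seq_len(n) - 1L) * 4L
  left_mid <- (m[i0 + 1L, , drop = FALSE] + m[i0 + 3L, , drop = FALSE]) / 2
  right_mid <- (m[i0 + 2L, , drop = FALSE] + m[i0 + 4L, , drop = FALSE]) / 2
  slope <- right_mid - left_mid
  norms <- sqrt(rowSums(slope^2))
  if (any(norms < 1e-12)) {
    stop("degenerate vertebra: zero-length slope vector at index ",
         paste(which(norms < 1e-12), collapse = ","), call. = FALSE)
  }
  unit <- slope / norms
  cosm <- pmin(pmax(unit %*% t(unit), 0), 1)  # angles capped at 90 degrees
  angle_mat <- acos(cosm) * 180 / pi

  part <- cobb_partition(angle_mat, endplate_midpoints(m), image_height,
                         s_curve_rule = s_curve_rule)
  part$angles
}

# 2n x 2 matrix of endplate midpoints: top midpoint then bottom midpoint per
# vertebra, superior to inferior
endplate_midpoints <- function(m) {
  n <- nrow(m) %/% 4L
  i0 <- (seq_len(n) - 1L) * 4L
  top <- (m[i0 + 1L, , drop = FALSE] + m[i0 + 2L, , drop = FALSE]) / 2
  bot <- (m[i0 + 3L, , drop = FALSE] + m[i0 + 4L, , drop = FALSE]) / 2
  out <- matrix(0, 2L * n, 2L)
  out[seq(1L, 2L * n, by = 2L), ] <- top
  out[seq(2L, 2L * n, by = 2L), ] <- bot
  out
}

# sign test: does the lateral displacement of the endplate midpoints relative
# to the first-to-last chord change sign anywhere? (S- vs C-shaped curve)
is_s_curve <- function(mid_pv) {
  num <- nrow(mid_pv)
  dy <- mid_pv[1L, 2L] - mid_pv[num, 2L]
  dx <- mid_pv[1L, 1L] - mid_pv[num, 1L]
  if (abs(dy) < 1e-12 || abs(dx) < 1e-12) return(FALSE)
  i <- seq_len(num - 2L)
  ll <- (mid_pv[i, 2L] - mid_pv[num, 2L]) / dy -
    (mid_pv[i, 1L] - mid_pv[num, 1L]) / dx
  if (!all(is.finite(ll))) return(FALSE)
  outer_ll <- tcrossprod(ll)
  abs(sum(outer_ll) - sum(abs(outer_ll))) > 1e-4
}

# PT/MT/TL partition over a symmetric inter-vertebra angle matrix (degrees)
cobb_partition <- function(angle_mat, mid_pv, image_height,
                           s_curve_rule = TRUE) {
  n <- nrow(angle_mat)
  maxt <- apply(angle_mat, 1L, max)
  pos1 <- apply(angle_mat, 1L, which.max)
  p1 <- which.max(maxt)              # first row attaining the global max
  p2 <- pos1[p1]
  mt <- angle_mat[p1, p2]
  p_up <- min(p1, p2); p_lo <- max(p1, p2)

  s_shaped <- s_curve_rule && is_s_curve(mid_pv)
  if (!s_shaped) {
    pt <- angle_mat[1L, p_up]
    tl <- angle_mat[n, p_lo]
  } else if (mid_pv[2L * p_up - 1L, 2L] + mid_pv[2L * p_lo - 1L, 2L] <
               image_height) {
    # main bow sits in the upper half: secondary bows above p_up / below p_lo
    pt <- max(angle_mat[1:p_up, 1:p_up])
    tl <- max(angle_mat[p_lo:n, p_lo:n])
  } else {
    # main bow sits low: both secondary angles come from the region above
    sub <- angle_mat[1:p_up, 1:p_up, drop = FALSE]
    pt <- max(sub)
    hit <- which(sub == pt, arr.ind = TRUE)[1L, ]
    q <- min(hit)
    tl <- max(angle_mat[1:q, 1:q])
  }

  angles <- tibble::tibble(pt = pt, mt = mt, tl = tl)
  class(angles) <- c("cobb_angles", class(angles))
  attr(angles, "mt_pair") <- c(p_up, p_lo)
  list(angles = angles, mt_pair = c(p_up, p_lo))
}
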