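#' Loss weights for the composite training objective
#'
#' The total loss is
#' `a1*L_hm + a2*L_center + a3*L_corner + a4*L_CPIE + a5*L_AVIE + a6*L_VIL`,
#' with defaults 1, 1, 1, 1, 1, 0.05: the five point/offset terms are kept
#' on a similar scale and the dense vertebral-line term is down-weighted.
#'
#' @param alpha1,alpha2,alpha3,alpha4,alpha5,alpha6 Non-negative weights
#'   for heatmap, centre offset, polar corner, CPIE, AVIE and vertebral
#'   line losses respectively.
#' @return A named numeric vector of class `loss_weights`.
#' @export
loss_weights <- function(alpha1 = 1, alpha2 = 1, alpha3 = 1,
                         alpha4 = 1, alpha5 = 1, alpha6 = 0.05) {
  w <- c(alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
         alpha4 = alpha4, alpha5 = alpha5, alpha6 = alpha6)
  if (any(w < 0)) stop("loss weights must be non-negative", call. = FALSE)
  structure(w, class = "loss_weights")
}

#' Penalty-reduced focal loss for the centre heatmap
#'
#' The keypoint-heatmap focal loss of the CenterNet lineage: at ground-truth
#' peak cells (`gt == 1`), `-(1-p)^alpha * log(p)`; elsewhere
#' `-(1-gt)^beta * p^alpha * log(1-p)`; summed over cells and divided by the
#' number of peak cells. `alpha = 2`, `beta = 4`. Predictions are clamped to
#' `[eps, 1-eps]`.
#'
#' @param pred,gt Heatmap matrices of equal shape; `gt` in \[0, 1\] with
#'   exact 1 at peaks.
#' @param alpha,beta Focusing exponents.
#' @param eps Clamping epsilon.
#' @return Scalar loss (>= 0).
#' @export
focal_loss <- function(pred, gt, alpha = 2, beta = 4, eps = 1e-7) {
  if (!all(dim(pred) == dim(gt))) stop("shape mismatch", call. = FALSE)
  p <- pmin(pmax(pred, eps), 1 - eps)
  pos <- gt == 1
  n_pos <- sum(pos)
  pos_loss <- sum(-(1 - p[pos])^alpha * log(p[pos]))
  neg_loss <- sum(-(1 - gt[!pos])^beta * p[!pos]^alpha * log(1 - p[!pos]))
  (pos_loss + neg_loss) / max(n_pos, 1L)
}

#' Masked mean absolute error
#'
#' Mean `|pred - gt|` over supervised cells only; returns 0 on an empty
#' mask. For multi-channel arrays the mask marks grid cells and applies to
#' every channel.
#'
#' @param pred,gt Matrices or 3-D arrays of equal shape.
#' @param mask Logical matrix of supervised cells.
#' @return Scalar loss (>= 0).
#' @export
masked_l1 <- function(pred, gt, mask) {
  if (!all(dim(pred) == dim(gt))) stop("shape mismatch", call. = FALSE)
  mask <- expand_mask(mask, dim(pred))
  if (!any(mask)) return(0)
  mean(abs(pred[mask] - gt[mask]))
}

expand_mask <- function(mask, dims) {
  if (length(dims) == 2L) return(mask)
  array(rep(as.logical(mask), times = dims[3]), dims)
}

#' Masked loss for the polar corner field
#'
#' Masked L1 on the radius channels plus masked L1 on the wrapped angular
#' difference `min(|dtheta|, 2*pi - |dtheta|)` on the angle channels (plain
#' L1 on theta would spike spuriously at the +-pi branch cut).
#'
#' @param pred,gt H x W x 8 arrays, channel layout (r1, theta1, ..., r4,
#'   theta4).
#' @param mask Logical matrix of supervised cells.
#' @return Scalar loss (>= 0).
#' @export
corner_polar_loss <- function(pred, gt, mask) {
  if (!all(dim(pred) == dim(gt))) stop("shape mismatch", call. = FALSE)
  if (dim(pred)[3] != 8L) stop("expected 8 channels", call. = FALSE)
  if (!any(mask)) return(0)
  r_ch <- seq(1L, 8L, by = 2L); th_ch <- seq(2L, 8L, by = 2L)
  msk3 <- expand_mask(mask, c(dim(pred)[1:2], 4L))
  r_loss <- mean(abs(pred[, , r_ch][msk3] - gt[, , r_ch][msk3]))
  dth <- abs(pred[, , th_ch][msk3] - gt[, , th_ch][msk3])
  dth <- dth %% (2 * pi)
  dth <- pmin(dth, 2 * pi - dth)
  r_loss + mean(dth)
}

#' Vertebral line interpolation loss
#'
#' Per enabled line, the mean absolute coordinate error between predicted
#' and target line samples; the total is the sum of the left, middle and
#' right components (disabled lines contribute 0).
#'
#' @param pred_lines,gt_lines `vertebral_lines` lists (or named lists of
#'   tibbles with `x`, `y`); the same sides must be enabled with matching
#'   point counts.
#' @return A tibble with columns `l_vil_l`, `l_vil_m`, `l_vil_r`, `l_vil`.
#' @export
vil_loss <- function(pred_lines, gt_lines) {
  sides <- names(gt_lines)
  if (!setequal(names(pred_lines), sides)) {
    stop("enabled lines differ between prediction and target", call. = FALSE)
  }
  comp <- c(left = 0, middle = 0, right = 0)
  for (s in sides) {
    p <- pred_lines[[s]]; g <- gt_lines[[s]]
    if (nrow(p) != nrow(g)) {
      stop("point-count mismatch on ", s, " line: ", nrow(p), " vs ",
           nrow(g), call. = FALSE)
    }
    comp[[s]] <- mean(abs(c(p$x - g$x, p$y - g$y)))
  }
  tibble::tibble(l_vil_l = comp[["left"]], l_vil_m = comp[["middle"]],
                 l_vil_r = comp[["right"]], l_vil = sum(comp))
}

#' Combine the six loss terms
#'
#' @param terms A list or one-row data frame with elements `l_hm`,
#'   `l_center`, `l_corner`, `l_cpie`, `l_avie`, `l_vil`.
#' @param weights A [loss_weights()].
#' @return Scalar total loss.
#' @export
total_loss <- function(terms, weights = loss_weights()) {
  stopifnot(all(vapply(terms[c("l_hm", "l_center", "l_corner", "l_cpie",
                               "l_avie", "l_vil")],
                       function(v) is.finite(as.numeric(v)), logical(1))))
  weights[["alpha1"]] * terms$l_hm +
    weights[["alpha2"]] * terms$l_center +
    weights[["alpha3"]] * terms$l_corner +
    weights[["alpha4"]] * terms$l_cpie +
    weights[["alpha5"]] * terms$l_avie +
    weights[["alpha6"]] * terms$l_vil
}
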