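#' Mean detection error (MDE)
#'
#' Mean Euclidean distance in pixels between index-aligned predicted and
#' ground-truth landmarks. Optionally restricted to a subset of vertebrae
#' (e.g. the upper ten vs lower seven split used to characterise the
#' stronger background interference in the lower spine).
#'
#' @param pred,gt Landmark tables (`vertebra`, `corner`, `x`, `y`) or n x 2
#'   matrices with equal, index-aligned rows.
#' @param vertebrae Optional vertebra indices to restrict to (tables only).
#' @return Mean distance in pixels (a single number).
#' @export
mde <- function(pred, gt, vertebrae = NULL) {
  if (!is.null(vertebrae)) {
    if (is.matrix(pred) || is.matrix(gt)) {
      stop("vertebra subsetting needs landmark tables, not matrices",
           call. = FALSE)
    }
    pred <- pred[pred$vertebra %in% vertebrae, ]
    gt <- gt[gt$vertebra %in% vertebrae, ]
  }
  pm <- if (is.matrix(pred)) pred else as_landmark_matrix(pred)
  gm <- if (is.matrix(gt)) gt else as_landmark_matrix(gt)
  if (nrow(pm) != nrow(gm)) {
    stop("landmark count mismatch: ", nrow(pm), " vs ", nrow(gm),
         call. = FALSE)
  }
  mean(sqrt(rowSums((pm - gm)^2)))
}

#' Symmetric mean absolute percentage error over Cobb angles
#'
#' Per case, the summed absolute PT/MT/TL errors divided by the summed
#' (prediction + ground truth) over the three angles; averaged over cases
#' and reported in percent. A case whose three angles sum to zero in both
#' prediction and ground truth has an undefined ratio and raises an error
#' naming the case. Per-angle variants use only that angle in numerator
#' and denominator; since a single regional angle is legitimately zero for
#' C-shaped spines, per-angle variants average over the cases where that
#' angle's denominator is positive (`NA` if there are none). Symmetric in
#' prediction and ground truth.
#'
#' @param pred,gt Data frames with columns `pt`, `mt`, `tl` in degrees, one
#'   row per case (e.g. rows of [cobb_from_landmarks()] output).
#' @return A one-row tibble: `smape`, `smape_pt`, `smape_mt`, `smape_tl`
#'   (percent).
#' @export
smape <- function(pred, gt) {
  stopifnot(nrow(pred) == nrow(gt))
  cols <- c("pt", "mt", "tl")
  pm <- as.matrix(pred[, cols]); gm <- as.matrix(gt[, cols])
  denom <- rowSums(pm + gm)
  if (any(denom <= 0)) {
    stop("zero pred+gt angle sum for case(s) ",
         paste(which(denom <= 0), collapse = ","), call. = FALSE)
  }
  overall <- mean(rowSums(abs(pm - gm)) / denom) * 100
  per <- vapply(cols, function(cn) {
    d <- pred[[cn]] + gt[[cn]]
    ok <- d > 0
    if (!any(ok)) return(NA_real_)
    mean(abs(pred[[cn]][ok] - gt[[cn]][ok]) / d[ok]) * 100
  }, numeric(1))
  tibble::tibble(smape = overall, smape_pt = per[["pt"]],
                 smape_mt = per[["mt"]], smape_tl = per[["tl"]])
}

#' Optimal prediction-to-ground-truth vertebra matching
#'
#' Minimum-total-Euclidean-distance assignment between predicted and
#' ground-truth vertebra centres (the Hungarian / linear sum assignment
#' problem). Rectangular inputs are allowed: with more predictions than
#' ground-truth vertebrae the surplus predictions are left unmatched.
#'
#' @param pred_centers,gt_centers Centre tables with columns `x`, `y` (and
#'   optionally `vertebra`), or n x 2 matrices.
#' @return A list of class `match_result`: `pairs` (tibble `pred`, `gt`,
#'   `cost` — row indices into the inputs), `total_cost`, and
#'   `unmatched_pred` (row indices).
#' @export
hungarian_match <- function(pred_centers, gt_centers) {
  pm <- centers_matrix(pred_centers)
  gm <- centers_matrix(gt_centers)
  if (nrow(pm) == 0L) stop("empty prediction set", call. = FALSE)

  cost <- sqrt(outer(pm[, 1], gm[, 1], "-")^2 +
                 outer(pm[, 2], gm[, 2], "-")^2)
  if (nrow(cost) <= ncol(cost)) {
    sol <- clue::solve_LSAP(cost)
    pairs <- tibble::tibble(pred = seq_len(nrow(cost)),
                            gt = as.integer(sol))
  } else {
    sol <- clue::solve_LSAP(t(cost))
    pairs <- tibble::tibble(pred = as.integer(sol),
                            gt = seq_len(ncol(cost)))
  }
  pairs$cost <- cost[cbind(pairs$pred, pairs$gt)]
  unmatched <- setdiff(seq_len(nrow(pm)), pairs$pred)
  structure(list(pairs = pairs, total_cost = sum(pairs$cost),
                 unmatched_pred = unmatched),
            class = "match_result")
}

centers_matrix <- function(x) {
  if (is.matrix(x)) {
    m <- x
  } else {
    m <- cbind(x$x, x$y)
  }
  storage.mode(m) <- "double"
  m
}

#' Self-adaptive mean detection error
#'
#' MDE computed after thresholded (rather than fixed-k) centre detection and
#' optimal vertebra matching, which separates landmark localization error
#' from vertebra-ordering error. Centres are decoded from the heatmap with
#' an intensity threshold (default 0.05), each surviving centre decodes its
#' four corners from the polar corner field, centres are matched to the
#' ground truth by [hungarian_match()], and the mean Euclidean landmark
#' error is taken over the matched vertebrae only (4 landmarks per matched
#' pair).
#'
#' @param heatmap,center_offset,corner_polar Prediction grids in the encoded
#'   target layout (see [encode_all()]).
#' @param gt_ann Ground-truth [spine_annotation()].
#' @param config A [codec_config()].
#' @param threshold Heatmap intensity threshold (strict `>`).
#' @return Mean matched-landmark distance in pixels.
#' @export
self_adaptive_mde <- function(heatmap, center_offset, corner_polar, gt_ann,
                              config, threshold = 0.05) {
  centers <- adaptive_centers(heatmap, center_offset, config,
                              threshold = threshold)
  if (nrow(centers) == 0L) {
    stop("no heatmap centre above threshold ", threshold, call. = FALSE)
  }
  pred_lm <- decode_landmarks(centers, corner_polar, config)
  gt_centers <- spine_centers(gt_ann)
  m <- hungarian_match(centers, gt_centers)

  gt_m <- as_landmark_matrix(gt_ann)
  pred_m <- as_landmark_matrix(pred_lm)
  err <- 0; nlm <- 0L
  for (r in seq_len(nrow(m$pairs))) {
    pi <- (m$pairs$pred[r] - 1L) * 4L + 1:4
    gi <- (m$pairs$gt[r] - 1L) * 4L + 1:4
    err <- err + sum(sqrt(rowSums((pred_m[pi, , drop = FALSE] -
                                     gt_m[gi, , drop = FALSE])^2)))
    nlm <- nlm + 4L
  }
  err / nlm
}

#' Per-case and dataset-level metric reports
#'
#' `evaluate_case()` compares one predicted landmark set against its ground
#' truth; `evaluate_dataset()` aggregates a list of such pairs the way the
#' metrics are defined on a test set: MDE pooled over all landmarks of the
#' dataset, SMAPE averaged over cases. The upper/lower split is vertebrae
#' 1-10 vs 11-17.
#'
#' @param pred,gt Landmark tables (`spine_annotation` or compatible).
#' @param preds,gts Lists of landmark tables, index-aligned.
#' @param s_curve_rule Passed to [cobb_from_landmarks()].
#' @return A one-row tibble of class `metric_report`: `mde`, `mde_upper`,
#'   `mde_lower`, `mde_centers`, `smape`, `smape_pt`, `smape_mt`,
#'   `smape_tl`, `n_cases`.
#' @export
evaluate_case <- function(pred, gt, s_curve_rule = TRUE) {
  evaluate_dataset(list(pred), list(gt), s_curve_rule = s_curve_rule)
}

#' @rdname evaluate_case
#' @export
evaluate_dataset <- function(preds, gts, s_curve_rule = TRUE) {
  stopifnot(length(preds) == length(gts), length(preds) >= 1L)
  upper <- 1:10; lower <- 11:17

  pool <- function(subset_fun) {
    num <- 0; den <- 0L
    for (i in seq_along(preds)) {
      pm <- subset_fun(preds[[i]]); gm <- subset_fun(gts[[i]])
      num <- num + sum(sqrt(rowSums((pm - gm)^2)))
      den <- den + nrow(pm)
    }
    num / den
  }
  all_lm <- function(a) as_landmark_matrix(a)
  up_lm <- function(a) as_landmark_matrix(a[a$vertebra %in% upper, ])
  lo_lm <- function(a) as_landmark_matrix(a[a$vertebra %in% lower, ])
  ctr <- function(a) {
    cc <- spine_centers(a)
    cbind(cc$x, cc$y)
  }

  pred_angles <- dplyr::bind_rows(lapply(preds, cobb_from_landmarks,
                                         s_curve_rule = s_curve_rule))
  gt_angles <- dplyr::bind_rows(lapply(gts, cobb_from_landmarks,
                                       s_curve_rule = s_curve_rule))
  sm <- smape(pred_angles, gt_angles)

  out <- tibble::tibble(
    mde = pool(all_lm),
    mde_upper = pool(up_lm),
    mde_lower = pool(lo_lm),
    mde_centers = pool(ctr),
    smape = sm$smape, smape_pt = sm$smape_pt,
    smape_mt = sm$smape_mt, smape_tl = sm$smape_tl,
    n_cases = length(preds)
  )
  class(out) <- c("metric_report", class(out))
  out
}
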