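#' Construct a spine landmark annotation
#'
#' A spine annotation is a tidy table of the 68 corner landmarks of the 17
#' thoracic/lumbar vertebrae visible on an anterior-posterior radiograph:
#' one row per landmark, ordered vertebra-major. Coordinates follow the image
#' convention — origin at the top-left pixel, `x` along columns, `y` along
#' rows increasing downward, 0-based and real-valued (sub-pixel positions are
#' allowed).
#'
#' Corner indices are fixed as 1 = top-left, 2 = top-right, 3 = bottom-left,
#' 4 = bottom-right of each vertebral body, so that corners \{1,3\} trace the
#' left vertebral line, \{2,4\} the right, and the bottom corners \{3,4\} of a
#' vertebra face the top corners \{1,2\} of the next one down.
#'
#' @param landmarks A data frame with columns `vertebra` (1..n), `corner`
#'   (1..4), `x`, `y`, or a 4*n x 2 matrix ordered vertebra-major,
#'   corner-minor.
#' @param image_width,image_height Image dimensions in pixels.
#' @param n_vertebrae Expected vertebra count (17 for standard AP studies).
#' @return A tibble of class `spine_annotation` with columns
#'   `vertebra`, `corner`, `x`, `y` and attributes `image_width`,
#'   `image_height`.
#' @examples
#' ann <- generate_case(spine_sim_params(seed = 1))$annotation
#' spine_centers(ann)
#' @export
spine_annotation <- function(landmarks, image_width, image_height,
                             n_vertebrae = 17L) {
  if (is.matrix(landmarks)) {
    if (ncol(landmarks) != 2L) {
      stop("landmark matrix must have 2 columns (x, y)", call. = FALSE)
    }
    n <- nrow(landmarks) / 4L
    landmarks <- tibble::tibble(
      vertebra = rep(seq_len(n), each = 4L),
      corner   = rep(1:4, times = n),
      x = as.numeric(landmarks[, 1L]),
      y = as.numeric(landmarks[, 2L])
    )
  }
  landmarks <- tibble::as_tibble(landmarks)
  need <- c("vertebra", "corner", "x", "y")
  if (!all(need %in% names(landmarks))) {
    stop("landmarks need columns vertebra, corner, x, y", call. = FALSE)
  }
  out <- landmarks |>
    dplyr::select(dplyr::all_of(need)) |>
    dplyr::mutate(vertebra = as.integer(.data$vertebra),
                  corner = as.integer(.data$corner),
                  x = as.numeric(.data$x), y = as.numeric(.data$y)) |>
    dplyr::arrange(.data$vertebra, .data$corner)
  attr(out, "image_width") <- as.integer(image_width)
  attr(out, "image_height") <- as.integer(image_height)
  attr(out, "n_vertebrae") <- as.integer(n_vertebrae)
  class(out) <- c("spine_annotation", class(tibble::tibble()))
  out
}

#' @export
print.spine_annotation <- function(x, ...) {
  cat(sprintf("<spine_annotation: %d vertebrae, image %d x %d (w x h)>\n",
              length(unique(x$vertebra)),
              attr(x, "image_width"), attr(x, "image_height")))
  NextMethod()
}

img_dims <- function(ann) {
  c(width = attr(ann, "image_width"), height = attr(ann, "image_height"))
}

#' Landmarks as a 68 x 2 matrix
#'
#' @param ann A `spine_annotation` (or any landmark table with `vertebra`,
#'   `corner`, `x`, `y`).
#' @return A numeric matrix, rows ordered vertebra-major corner-minor,
#'   columns `x`, `y`.
#' @export
as_landmark_matrix <- function(ann) {
  ann <- dplyr::arrange(ann, .data$vertebra, .data$corner)
  cbind(x = ann$x, y = ann$y)
}

#' Vertebra centres from corner landmarks
#'
#' The centre of each vertebra is the arithmetic mean of its four annotated
#' corners; centres are the poles of the per-vertebra polar corner encoding
#' and the control points of the middle vertebral line.
#'
#' @param ann A `spine_annotation`.
#' @return A tibble with columns `vertebra`, `x`, `y`, ordered by vertebra.
#' @export
spine_centers <- function(ann) {
  counts <- table(ann$vertebra)
  if (any(counts != 4L) || !all(is.finite(ann$x), is.finite(ann$y))) {
    stop("invalid annotation: every vertebra needs 4 finite corners",
         call. = FALSE)
  }
  ann |>
    dplyr::group_by(.data$vertebra) |>
    dplyr::summarise(x = mean(.data$x), y = mean(.data$y), .groups = "drop") |>
    dplyr::arrange(.data$vertebra)
}

#' Validate a spine annotation
#'
#' Report-style check of the structural invariants: expected vertebra count,
#' four corners per vertebra, finite in-image coordinates, corner order
#' (top edge above bottom edge, left corners left of right corners), and
#' strictly increasing centre `y` down the spine.
#'
#' @param ann A `spine_annotation`.
#' @return A tibble with columns `check`, `pass`, `detail`; one row per
#'   invariant.
#' @export
validate_spine_annotation <- function(ann) {
  n_expect <- attr(ann, "n_vertebrae") %||% 17L
  dims <- img_dims(ann)
  res <- list()
  add <- function(check, pass, detail = "") {
    res[[length(res) + 1L]] <<- tibble::tibble(check = check, pass = pass,
                                               detail = detail)
  }

  verts <- unique(ann$vertebra)
  add("vertebra count", length(verts) == n_expect,
      sprintf("found %d, expected %d", length(verts), n_expect))

  corner_counts <- table(ann$vertebra)
  add("four corners per vertebra", all(corner_counts == 4L),
      paste0("vertebrae with != 4 corners: ",
             paste(names(corner_counts)[corner_counts != 4L], collapse = ",")))

  finite <- all(is.finite(ann$x)) && all(is.finite(ann$y))
  add("finite coordinates", finite, "")

  inside <- finite && all(ann$x >= 0 & ann$x < dims["width"] &
                            ann$y >= 0 & ann$y < dims["height"])
  add("landmarks inside image", inside, "")

  wide <- tidyr::pivot_wider(ann, id_cols = "vertebra",
                             names_from = "corner", values_from = c("x", "y"))
  order_ok <- FALSE
  bad <- integer()
  if (all(c("x_1", "x_2", "x_3", "x_4", "y_1", "y_2", "y_3", "y_4")
          %in% names(wide))) {
    ok <- wide$x_1 < wide$x_2 & wide$x_3 < wide$x_4 &
      (wide$y_1 + wide$y_2) / 2 < (wide$y_3 + wide$y_4) / 2
    order_ok <- all(ok)
    bad <- wide$vertebra[!ok]
  }
  add("corner order", isTRUE(order_ok),
      if (length(bad)) paste0("vertebrae: ", paste(bad, collapse = ","))
      else "")

  ctr_ok <- FALSE
  if (all(corner_counts == 4L)) {
    cy <- ann |>
      dplyr::group_by(.data$vertebra) |>
      dplyr::summarise(y = mean(.data$y), .groups = "drop") |>
      dplyr::arrange(.data$vertebra)
    ctr_ok <- all(diff(cy$y) > 0)
  }
  add("centre y strictly increasing", isTRUE(ctr_ok), "")

  dplyr::bind_rows(res)
}

stop_if_invalid <- function(ann) {
  rep <- validate_spine_annotation(ann)
  if (!all(rep$pass)) {
    bad <- rep[!rep$pass, ]
    stop("invalid spine annotation: ",
         paste(sprintf("%s (%s)", bad$check, bad$detail), collapse = "; "),
         call. = FALSE)
  }
  invisible(ann)
}
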