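#' Read and write spine annotations
#'
#' Lossless annotation I/O in three on-disk forms:
#' \describe{
#'   \item{csv}{header `vertebra,corner,x,y`, one row per landmark, full
#'     float precision.}
#'   \item{json}{nested object: image dimensions plus a `vertebrae` array of
#'     `{index, corners: [{corner, x, y}, ...]}`.}
#'   \item{mat}{MATLAB v5 file carrying a 68 x 2 double matrix named `p2`,
#'     ordered vertebra-major, corner-minor (the AASCE challenge layout).
#'     The MAT form does not carry image dimensions; supply them via
#'     `image_width`/`image_height` when reading.}
#' }
#'
#' @param path File path.
#' @param format One of `"csv"`, `"json"`, `"mat"`; default guessed from the
#'   file extension.
#' @param image_width,image_height Image dimensions, required for `mat`
#'   (other formats store them in the file).
#' @param n_vertebrae Expected vertebra count.
#' @return `read_spine_annotation()` returns a [spine_annotation()];
#'   `write_spine_annotation()` returns `path` invisibly.
#' @export
read_spine_annotation <- function(path, format = NULL,
                                  image_width = NULL, image_height = NULL,
                                  n_vertebrae = 17L) {
  format <- format %||% tolower(tools::file_ext(path))
  format <- match.arg(format, c("csv", "json", "mat"))
  switch(format,
    csv = {
      df <- utils::read.csv(path, comment.char = "#",
                            colClasses = "numeric")
      need <- c("vertebra", "corner", "x", "y")
      if (!all(need %in% names(df))) {
        stop("malformed annotation csv ", path,
             ": expected header vertebra,corner,x,y", call. = FALSE)
      }
      if (nrow(df) != 4L * n_vertebrae) {
        stop("malformed annotation csv ", path, ": ", nrow(df),
             " landmark rows, expected ", 4L * n_vertebrae, call. = FALSE)
      }
      dims <- parse_csv_dims(path)
      spine_annotation(df, dims["width"], dims["height"], n_vertebrae)
    },
    json = {
      obj <- jsonlite::read_json(path, simplifyVector = TRUE)
      corners <- obj$vertebrae$corners
      if (is.null(corners)) stop("malformed annotation json ", path,
                                 call. = FALSE)
      df <- dplyr::bind_rows(lapply(seq_along(corners), function(i) {
        ci <- corners[[i]]
        tibble::tibble(vertebra = obj$vertebrae$index[i],
                       corner = ci$corner, x = ci$x, y = ci$y)
      }))
      if (nrow(df) != 4L * n_vertebrae) {
        stop("malformed annotation json ", path, ": ", nrow(df),
             " landmarks, expected ", 4L * n_vertebrae, call. = FALSE)
      }
      spine_annotation(df, obj$image_width, obj$image_height, n_vertebrae)
    },
    mat = {
      p2 <- read_mat_matrix(path)
      if (nrow(p2) != 4L * n_vertebrae || ncol(p2) != 2L) {
        stop("malformed MAT annotation ", path, ": array is ",
             nrow(p2), " x ", ncol(p2), ", expected ",
             4L * n_vertebrae, " x 2", call. = FALSE)
      }
      image_width <- image_width %||% as.integer(ceiling(max(p2[, 1]) + 1))
      image_height <- image_height %||% as.integer(ceiling(max(p2[, 2]) + 1))
      spine_annotation(p2, image_width, image_height, n_vertebrae)
    }
  )
}

# csv files carry image dims in a trailing comment line written by
# write_spine_annotation; fall back to bounding the landmarks.
parse_csv_dims <- function(path) {
  lines <- readLines(path)
  meta <- grep("^# image ", lines, value = TRUE)
  if (length(meta) == 1L) {
    nums <- as.integer(strsplit(sub("^# image ", "", meta[1]), "x")[[1]])
    return(c(width = nums[1], height = nums[2]))
  }
  df <- utils::read.csv(path, comment.char = "#")
  c(width = as.integer(ceiling(max(df$x) + 1)),
    height = as.integer(ceiling(max(df$y) + 1)))
}

#' @rdname read_spine_annotation
#' @param ann A `spine_annotation`.
#' @export
write_spine_annotation <- function(ann, path, format = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  format <- match.arg(format, c("csv", "json", "mat"))
  dims <- img_dims(ann)
  switch(format,
    csv = {
      con <- file(path, "w", encoding = "UTF-8")
      on.exit(close(con))
      writeLines("vertebra,corner,x,y", con)
      writeLines(sprintf("%d,%d,%.17g,%.17g", ann$vertebra, ann$corner,
                         ann$x, ann$y), con)
      writeLines(sprintf("# image %dx%d", dims["width"], dims["height"]), con)
    },
    json = {
      verts <- lapply(sort(unique(ann$vertebra)), function(v) {
        sub <- ann[ann$vertebra == v, ]
        list(index = v,
             corners = data.frame(corner = sub$corner, x = sub$x, y = sub$y))
      })
      obj <- list(image_width = unname(dims["width"]),
                  image_height = unname(dims["height"]),
                  vertebrae = list(index = vapply(verts, `[[`, 1L, "index"),
                                   corners = lapply(verts, `[[`, "corners")))
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
    },
    mat = write_mat_matrix(as_landmark_matrix(ann), path, name = "p2")
  )
  invisible(path)
}

# ---- minimal MAT v5 support (single uncompressed double matrix) ------------
# Only the subset used by AASCE-style annotation files: a level-5 MAT file
# whose first data element is an uncompressed miMATRIX of class double.

MI_INT8 <- 1L; MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_DOUBLE <- 9L
MI_MATRIX <- 14L; MX_DOUBLE_CLASS <- 6L

read_mat_matrix <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 116L)
  readBin(con, "raw", 8L)                      # subsystem offset
  version <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  endian_tag <- rawToChar(readBin(con, "raw", 2L))
  endian <- if (endian_tag == "IM") "little" else "big"

  tag <- readBin(con, "integer", 2L, size = 4L, endian = endian)
  if (tag[1] == 15L) {
    stop("compressed MAT elements are not supported; save uncompressed",
         call. = FALSE)
  }
  if (tag[1] != MI_MATRIX) {
    stop("unsupported MAT file: first element is not a matrix", call. = FALSE)
  }

  read_sub <- function() {
    t <- readBin(con, "integer", 1L, size = 4L, endian = endian)
    if (bitwAnd(t, bitwShiftL(65535L, 16L)) != 0L) {  # small element format
      nbytes <- bitwShiftR(t, 16L)
      type <- bitwAnd(t, 65535L)
      data <- readBin(con, "raw", 4L)
      list(type = type, nbytes = nbytes, data = data[seq_len(nbytes)])
    } else {
      nbytes <- readBin(con, "integer", 1L, size = 4L, endian = endian)
      data <- readBin(con, "raw", nbytes)
      pad <- (8L - nbytes %% 8L) %% 8L
      if (pad > 0L) readBin(con, "raw", pad)
      list(type = t, nbytes = nbytes, data = data)
    }
  }

  flags <- read_sub()
  cls <- as.integer(flags$data[1])
  if (cls != MX_DOUBLE_CLASS) {
    stop("unsupported MAT array class ", cls, " (need double)", call. = FALSE)
  }
  dims_sub <- read_sub()
  dims <- readBin(dims_sub$data, "integer", dims_sub$nbytes %/% 4L,
                  size = 4L, endian = endian)
  read_sub()                                    # array name, unused
  real <- read_sub()
  if (real$type != MI_DOUBLE) {
    stop("unsupported MAT numeric storage type ", real$type, call. = FALSE)
  }
  vals <- readBin(real$data, "double", real$nbytes %/% 8L, endian = endian)
  matrix(vals, nrow = dims[1], ncol = dims[2])
}

write_mat_matrix <- function(m, path, name = "p2") {
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- sprintf("MATLAB 5.0 MAT-file, written by spinemark on %s",
                  format(Sys.time(), "%Y-%m-%d"))
  hdr <- c(charToRaw(desc), rep(as.raw(32L), 116L))[1:116]
  writeBin(hdr, con)
  writeBin(raw(8L), con)
  writeBin(c(0x00L, 0x01L), con, size = 1L)    # version 0x0100 little-endian
  writeBin(charToRaw("IM"), con)

  name_raw <- charToRaw(name)
  pad8 <- function(n) (8L - n %% 8L) %% 8L
  name_bytes <- length(name_raw)
  data_bytes <- 8L * length(m)
  total <- (8L + 8L) +                          # array flags
    (8L + 8L) +                                 # dims (2 x int32 padded)
    (8L + name_bytes + pad8(name_bytes)) +      # name
    (8L + data_bytes + pad8(data_bytes))        # real data

  writeBin(as.integer(c(MI_MATRIX, total)), con, size = 4L, endian = "little")
  writeBin(as.integer(c(MI_UINT32, 8L)), con, size = 4L, endian = "little")
  writeBin(as.integer(c(MX_DOUBLE_CLASS, 0L)), con, size = 4L,
           endian = "little")
  writeBin(as.integer(c(MI_INT32, 8L)), con, size = 4L, endian = "little")
  writeBin(as.integer(dim(m)), con, size = 4L, endian = "little")
  writeBin(as.integer(c(MI_INT8, name_bytes)), con, size = 4L,
           endian = "little")
  writeBin(name_raw, con)
  if (pad8(name_bytes) > 0L) writeBin(raw(pad8(name_bytes)), con)
  writeBin(as.integer(c(MI_DOUBLE, data_bytes)), con, size = 4L,
           endian = "little")
  writeBin(as.numeric(m), con, size = 8L, endian = "little")
  invisible(path)
}
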