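# Shared fixtures: hand-built annotations and independent oracles.

# n stacked congruent axis-aligned rectangles (a perfectly straight spine)
stacked_rect_annotation <- function(n = 17, width = 40, height = 20,
                                    gap = 10, x_center = 100,
                                    image_width = 256,
                                    image_height = n * (height + gap) + 40) {
  rows <- lapply(seq_len(n), function(i) {
    top <- 20 + (i - 1) * (height + gap)
    tibble::tibble(
      vertebra = i, corner = 1:4,
      x = x_center + c(-width / 2, width / 2, -width / 2, width / 2),
      y = c(top, top, top + height, top + height)
    )
  })
  spine_annotation(dplyr::bind_rows(rows), image_width, image_height,
                   n_vertebrae = n)
}

# spine of tilted rectangles: vertebra i rotated by tilt_deg[i] about its
# centre (centres on a vertical line)
tilted_annotation <- function(tilt_deg, width = 40, height = 20, gap = 15,
                              x_center = 100, image_width = 256) {
  n <- length(tilt_deg)
  rows <- lapply(seq_len(n), function(i) {
    cy <- 40 + (i - 1) * (height + gap)
    phi <- tilt_deg[i] * pi / 180
    tx <- sin(phi); ty <- cos(phi)       # unit tangent (down the spine)
    nx <- ty; ny <- -tx                  # unit normal (to the right)
    hw <- width / 2; hh <- height / 2
    tibble::tibble(
      vertebra = i, corner = 1:4,
      x = x_center + c(-hw * nx - hh * tx, hw * nx - hh * tx,
                       -hw * nx + hh * tx, hw * nx + hh * tx),
      y = cy + c(-hw * ny - hh * ty, hw * ny - hh * ty,
                 -hw * ny + hh * ty, hw * ny + hh * ty)
    )
  })
  spine_annotation(dplyr::bind_rows(rows), image_width,
                   40 + n * (height + gap) + 40, n_vertebrae = n)
}

# factorial brute-force minimum-cost assignment (oracle for n <= 7)
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- Inf
  for (p in perms(seq_len(ncol(cost)))) {
    tc <- sum(cost[cbind(seq_len(n), p[seq_len(n)])])
    if (tc < best) best <- tc
  }
  best
}

toy_codec <- function() {
  codec_config(downsample_k = 4L, input_height = 192L, input_width = 64L)
}
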