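# Shared helpers: 8-bit clipping, Euclidean disc kernels, sliding-window
# means via summed-area tables, and coordinate ordering conventions.
# Convention: matrices are indexed (row, col), 0-origin only in C++; masks
# are {0,1} integer matrices with 1 = foreground.

clip8 <- function(x) pmin(pmax(x, 0), 255)

#' Euclidean disc structuring element
#'
#' Binary kernel containing all offsets (dr, dc) with dr^2 + dc^2 <= r^2.
#' `disc_kernel(1)` is the 4-neighbour plus shape.
#'
#' @param r disc radius in pixels (>= 0)
#' @return (2r+1) x (2r+1) binary matrix
#' @export
disc_kernel <- function(r) {
  r <- as.integer(r)
  stopifnot(r >= 0)
  d <- seq(-r, r)
  k <- outer(d^2, d^2, "+") <= r^2
  matrix(as.integer(k), 2 * r + 1, 2 * r + 1)
}

# Mean over a w x w window around each pixel, window clipped to image bounds
# (mean of in-bounds pixels only). Odd w centres the window; even w uses
# offsets -w/2 .. w/2-1. Computed with a summed-area table.
window_mean_image <- function(img, w) {
  stopifnot(w >= 1)
  h <- nrow(img); wd <- ncol(img)
  lo <- -(w %/% 2)
  hi <- if (w %% 2 == 1) w %/% 2 else w %/% 2 - 1
  S <- matrix(0, h + 1, wd + 1)
  S[-1, -1] <- apply(apply(img, 2, cumsum), 1, cumsum) |> t()
  r1 <- pmax(seq_len(h) + lo, 1); r2 <- pmin(seq_len(h) + hi, h)
  c1 <- pmax(seq_len(wd) + lo, 1); c2 <- pmin(seq_len(wd) + hi, wd)
  sums <- S[r2 + 1, c2 + 1] - S[r1, c2 + 1] - S[r2 + 1, c1] + S[r1, c1]
  cnts <- outer(r2 - r1 + 1, c2 - c1 + 1)
  sums / cnts
}

# Indices of TRUE pixels of a logical/binary matrix in row-major (reading)
# order: row 1 left-to-right, then row 2, ... Returns an n x 2 (row, col)
# matrix.
which_rowmajor <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

# Deterministic half-up rounding (round() halves-to-even would make centroids
# platform-lore dependent).
round_half_up <- function(x) floor(x + 0.5)

as_binary_mask <- function(x) {
  m <- (as.matrix(x) != 0) * 1L
  storage.mode(m) <- "integer"
  m
}

# 4-connected neighbour shifts of a matrix, padding with `fill`.
shift_mat <- function(m, dr, dc, fill = 0L) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- seq_len(h) - dr; cs <- seq_len(w) - dc
  ok_r <- rs >= 1 & rs <= h; ok_c <- cs >= 1 & cs <= w
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# EBImage morphology returns Image objects; coerce back to a plain matrix.
as_plain_matrix <- function(x) {
  m <- EBImage::imageData(x)
  dim(m) <- dim(m)[1:2]
  m
}
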