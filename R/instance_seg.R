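#' Watershed parameters
#'
#' @param gaussian_sigma SD (px) of the Gaussian applied to the distance
#'   transform before marker detection (0 disables smoothing)
#' @param min_marker_distance minimum separation (px) between watershed
#'   markers; roughly half a typical cell diameter
#' @param min_area_px instances with area less than or equal to this are
#'   discarded by [filter_instances()] (490 px at the 512 px working scale)
#' @return object of class `watershed_params`
#' @export
watershed_params <- function(gaussian_sigma = 2, min_marker_distance = 10,
                             min_area_px = 490) {
  if (gaussian_sigma < 0) stop("gaussian_sigma must be >= 0")
  if (min_area_px < 0) stop("min_area_px must be >= 0")
  structure(list(gaussian_sigma = gaussian_sigma,
                 min_marker_distance = min_marker_distance,
                 min_area_px = as.integer(min_area_px)),
            class = "watershed_params")
}

# 4-connected component labelling by repeated flood fill (deterministic:
# labels ordered by each component's first pixel in row-major order).
label_components <- function(mask) {
  mask <- as_binary_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0L, h, w)
  lab_n <- 0L
  zero <- matrix(0, h, w)
  repeat {
    rem <- mask == 1L & out == 0L
    if (!any(rem)) break
    p <- which_rowmajor(rem)[1, ]
    markers <- matrix(0L, h, w)
    markers[p[1], p[2]] <- 1L
    fl <- watershed_flood(zero, markers, rem)
    lab_n <- lab_n + 1L
    out[fl == 1L] <- lab_n
  }
  out
}

#' Split a semantic cell mask into instances
#'
#' Marker-controlled watershed on the negated (Gaussian-smoothed) Euclidean
#' distance transform of the mask: markers are local distance maxima at
#' least `min_marker_distance` apart (detected per connected component, so
#' no component is left without a marker), flooding is restricted to the
#' mask, 4-connected. Masks of disjoint convex cells therefore reduce
#' exactly to connected-component labelling.
#'
#' @param mask binary semantic mask (1 = cell tissue)
#' @param params a [watershed_params()]
#' @return integer instance label map (0 = background, labels 1..n)
#' @export
instance_segment <- function(mask, params = watershed_params()) {
  mask <- as_binary_mask(mask)
  if (sum(mask) == 0) return(matrix(0L, nrow(mask), ncol(mask)))
  D <- as_plain_matrix(EBImage::distmap(mask))
  Ds <- if (params$gaussian_sigma > 0)
    as_plain_matrix(EBImage::gblur(D, params$gaussian_sigma)) else D
  Ds[mask == 0] <- 0
  comp <- label_components(mask)
  # local maxima of the smoothed distance map (max filter = grey dilation)
  w <- 2L * as.integer(ceiling(params$min_marker_distance / 2)) + 1L
  mx <- as_plain_matrix(EBImage::dilate(Ds, matrix(1L, w, w)))
  cand <- which(mask == 1 & Ds >= mx - 1e-9, arr.ind = TRUE)
  markers <- matrix(0L, nrow(mask), ncol(mask))
  lab_n <- 0L
  vals <- Ds[cand]
  for (cid in seq_len(max(comp))) {
    in_comp <- comp[cand] == cid
    if (!any(in_comp)) next
    cc <- cand[in_comp, , drop = FALSE]
    vv <- vals[in_comp]
    o <- order(-vv, cc[, 1], cc[, 2])
    kept <- matrix(numeric(0), 0, 2)
    for (i in o) {
      p <- cc[i, ]
      if (nrow(kept) == 0 ||
          min((kept[, 1] - p[1])^2 + (kept[, 2] - p[2])^2) >=
            params$min_marker_distance^2) {
        kept <- rbind(kept, p)
      }
    }
    for (i in seq_len(nrow(kept))) {
      lab_n <- lab_n + 1L
      markers[kept[i, 1], kept[i, 2]] <- lab_n
    }
  }
  lab <- watershed_flood(-Ds, markers, mask == 1)
  relabel_rowmajor(lab)
}

# renumber labels 1..n in row-major order of each label's first pixel
relabel_rowmajor <- function(lab) {
  pos <- which_rowmajor(lab > 0)
  if (nrow(pos) == 0) return(matrix(0L, nrow(lab), ncol(lab)))
  first_seen <- unique(lab[pos])
  remap <- integer(max(lab))
  remap[first_seen] <- seq_along(first_seen)
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  storage.mode(out) <- "integer"
  out
}

#' Filter instances by area
#'
#' Keeps instances whose pixel area is strictly greater than `min_area_px`
#' and renumbers the survivors contiguously. 490 px corresponds to the
#' pipeline's small-fragment cut at the 512 px working scale.
#'
#' @param lm integer instance label map
#' @param min_area_px area threshold (strict)
#' @return filtered label map
#' @export
filter_instances <- function(lm, min_area_px = 490) {
  if (max(lm) == 0) return(lm)
  areas <- tabulate(lm[lm > 0], nbins = max(lm))
  keep <- which(areas > min_area_px)
  remap <- integer(max(lm))
  remap[keep] <- seq_along(keep)
  out <- lm
  out[lm > 0] <- remap[lm[lm > 0]]
  storage.mode(out) <- "integer"
  out
}

#' Instance boundary pixels
#'
#' A pixel is boundary if it belongs to an instance and at least one of its
#' 4-neighbours (or the image edge) carries a different label.
#'
#' @param lm integer instance label map
#' @return binary mask of boundary pixels
#' @export
extract_boundaries <- function(lm) {
  b <- (lm > 0) &
    (shift_mat(lm, 1, 0, -1L) != lm | shift_mat(lm, -1, 0, -1L) != lm |
     shift_mat(lm, 0, 1, -1L) != lm | shift_mat(lm, 0, -1, -1L) != lm)
  as_binary_mask(b)
}
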