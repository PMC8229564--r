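#' Intensity plane
#'
#' A 2-D 8-bit grey image plane with its physical pixel size attached.
#'
#' @param pixels numeric/integer matrix of intensities
#' @param pixel_size_um physical size of one pixel edge, micrometres (> 0)
#' @return matrix of class `intensity_plane` with attribute `pixel_size_um`
#' @export
intensity_plane <- function(pixels, pixel_size_um = 0.3604) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels)) stop("pixels must be numeric")
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  structure(pixels, pixel_size_um = pixel_size_um,
            class = c("intensity_plane", class(matrix())))
}

#' @export
print.intensity_plane <- function(x, ...) {
  cat(sprintf("intensity plane: %d x %d px, %.4f um/px, range [%g, %g]\n",
              nrow(x), ncol(x), attr(x, "pixel_size_um"), min(x), max(x)))
  invisible(x)
}

pixel_size <- function(x) {
  ps <- attr(x, "pixel_size_um")
  if (is.null(ps)) 1 else ps
}

#' Resize a square image plane
#'
#' Bilinear interpolation for intensity data, nearest neighbour for masks
#' (so label/mask values are never blended). The physical pixel size is
#' rescaled by `input_size / target`; a 2048 px plane at 0.0901 um/px
#' resized to 512 px therefore carries 0.3604 um/px.
#'
#' @param img matrix or `intensity_plane` (must be square)
#' @param target output side length in pixels (>= 1)
#' @param method "bilinear" (intensities) or "nearest" (masks/labels)
#' @return resized plane; `intensity_plane` input keeps its class with the
#'   rescaled pixel size
#' @export
resize_plane <- function(img, target, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (nrow(img) != ncol(img)) stop("resize_plane expects a square plane")
  target <- as.integer(target)
  if (target < 1) stop("target must be >= 1")
  ps <- attr(img, "pixel_size_um")
  m <- unclass(img); attributes(m) <- list(dim = dim(m))
  if (target == nrow(m)) out <- m
  else out <- as_plain_matrix(EBImage::resize(
    m, w = target, h = target,
    filter = if (method == "bilinear") "bilinear" else "none"))
  if (method == "nearest") storage.mode(out) <- storage.mode(m)
  if (!is.null(ps))
    out <- intensity_plane(out, ps * nrow(img) / target)
  out
}

#' Augmentation specification
#'
#' Ranges for the random geometric transforms used to expand a training
#' set: rotation, shear, shift and mirroring. Defaults follow common image
#' generator settings; all are configurable.
#'
#' @param n_iterations augmented copies per source image (>= 0, default 8)
#' @param rotation_deg rotation drawn uniformly from +/- this angle
#' @param shear shear factor drawn uniformly from +/- this value
#' @param shift_frac shift drawn uniformly from +/- this fraction of the
#'   image side, independently per axis
#' @param flip_h,flip_v allow horizontal / vertical mirroring (each applied
#'   with probability 1/2 when allowed)
#' @param seed RNG seed for [augment_dataset()]
#' @return object of class `augment_spec`
#' @export
augment_spec <- function(n_iterations = 8, rotation_deg = 90, shear = 0.15,
                         shift_frac = 0.1, flip_h = TRUE, flip_v = TRUE,
                         seed = 1L) {
  if (n_iterations < 0) stop("n_iterations must be >= 0")
  structure(list(n_iterations = as.integer(n_iterations),
                 rotation_deg = rotation_deg, shear = shear,
                 shift_frac = shift_frac, flip_h = isTRUE(flip_h),
                 flip_v = isTRUE(flip_v), seed = as.integer(seed)),
            class = "augment_spec")
}

# Apply a 3x3 homogeneous affine transform (target <- source inverse
# mapping) with reflect padding. interp "bilinear" or "nearest".
apply_affine <- function(img, M, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  h <- nrow(img); w <- ncol(img)
  Minv <- solve(M)
  grid <- cbind(rep(seq_len(h), times = w), rep(seq_len(w), each = h), 1)
  src <- grid %*% t(Minv)
  reflect <- function(x, n) {
    # mirror continuous coordinates into [1, n]
    x <- (x - 1) %% (2 * (n - 1))
    x <- ifelse(x > (n - 1), 2 * (n - 1) - x, x)
    x + 1
  }
  sr <- reflect(src[, 1], h); sc <- reflect(src[, 2], w)
  if (interp == "nearest") {
    out <- img[cbind(round_half_up(sr), round_half_up(sc))]
  } else {
    r0 <- pmin(floor(sr), h - 1); c0 <- pmin(floor(sc), w - 1)
    fr <- sr - r0; fc <- sc - c0
    out <- img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
      img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
      img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
      img[cbind(r0 + 1, c0 + 1)] * fr * fc
  }
  matrix(out, h, w)
}

# Build the affine matrix for a draw of transform parameters, about the
# image centre.
affine_matrix <- function(h, w, angle_deg, shear, shift_r, shift_c,
                          flip_h, flip_v) {
  a <- angle_deg * pi / 180
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  R <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  S <- matrix(c(1, shear, 0, 0, 1, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Fl <- diag(c(if (flip_v) -1 else 1, if (flip_h) -1 else 1, 1))
  Tc <- matrix(c(1, 0, cr + shift_r, 0, 1, cc + shift_c, 0, 0, 1), 3, 3,
               byrow = TRUE)
  Tm <- matrix(c(1, 0, -cr, 0, 1, -cc, 0, 0, 1), 3, 3, byrow = TRUE)
  Tc %*% R %*% S %*% Fl %*% Tm
}

#' Augment an image/mask training set
#'
#' Produces exactly `n_iterations x length(images)` new pairs; each draw of
#' transform parameters is applied identically to the image (bilinear,
#' reflect padding) and its mask (nearest neighbour, so masks stay binary).
#' Deterministic for a fixed `spec$seed`. The originals are not included in
#' the output.
#'
#' @param images list of intensity matrices (or multi-channel arrays)
#' @param masks list of binary mask matrices, aligned 1:1 with `images`
#' @param spec an [augment_spec()]
#' @return list with `images`, `masks` and `transforms` (the parameter draw
#'   for each output pair)
#' @export
augment_dataset <- function(images, masks, spec = augment_spec()) {
  if (length(images) != length(masks))
    stop("images and masks must have the same length")
  set.seed(spec$seed)
  out_i <- list(); out_m <- list(); out_t <- list()
  k <- 0L
  for (i in seq_along(images)) {
    img <- images[[i]]; msk <- masks[[i]]
    for (it in seq_len(spec$n_iterations)) {
      h <- nrow(msk); w <- ncol(msk)
      par <- list(angle_deg = runif(1, -spec$rotation_deg, spec$rotation_deg),
                  shear = runif(1, -spec$shear, spec$shear),
                  shift_r = runif(1, -spec$shift_frac, spec$shift_frac) * h,
                  shift_c = runif(1, -spec$shift_frac, spec$shift_frac) * w,
                  flip_h = spec$flip_h && runif(1) < 0.5,
                  flip_v = spec$flip_v && runif(1) < 0.5,
                  source = i)
      M <- affine_matrix(h, w, par$angle_deg, par$shear, par$shift_r,
                         par$shift_c, par$flip_h, par$flip_v)
      k <- k + 1L
      if (length(dim(img)) == 3) {
        out_i[[k]] <- array(apply(img, 3, apply_affine, M = M,
                                  interp = "bilinear"), dim(img))
      } else {
        out_i[[k]] <- apply_affine(img, M, "bilinear")
      }
      mm <- apply_affine(msk, M, "nearest")
      storage.mode(mm) <- "integer"
      out_m[[k]] <- mm
      out_t[[k]] <- par
    }
  }
  list(images = out_i, masks = out_m, transforms = out_t)
}

#' Voxel geometry
#'
#' @param xy_um lateral voxel spacing, micrometres (> 0)
#' @param z_um axial spacing between planes, micrometres (> 0)
#' @return object of class `voxel_geometry`
#' @export
voxel_geometry <- function(xy_um = 0.0902, z_um = 0.3362) {
  if (xy_um <= 0 || z_um <= 0) stop("voxel spacings must be > 0")
  structure(list(xy_um = xy_um, z_um = z_um), class = "voxel_geometry")
}

#' Stack mask planes into a scaled 3-D volume
#'
#' Assembles z-ordered planes into a volume and records the anisotropy
#' factor `z_um / xy_um` as metadata (the voxels are not resampled; viewers
#' consume the scale factor losslessly). For the confocal geometry
#' 0.0902 x 0.0902 x 0.3362 um the factor is 3.727..., i.e. 1:1:3.7.
#'
#' @param planes list of equally sized matrices, bottom to top
#' @param geom a [voxel_geometry()]
#' @return object of class `islet_volume`: list with `voxels` (z, row, col
#'   array), `geom` and `z_scale`
#' @export
stack_masks <- function(planes, geom = voxel_geometry()) {
  if (length(planes) < 1) stop("need at least one plane")
  dims <- vapply(planes, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all planes must share the same shape")
  vox <- array(0, c(length(planes), dims[1, 1], dims[2, 1]))
  for (k in seq_along(planes)) vox[k, , ] <- as.matrix(planes[[k]])
  structure(list(voxels = vox, geom = geom, z_scale = geom$z_um / geom$xy_um),
            class = "islet_volume")
}

#' @export
print.islet_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("islet volume: %d planes of %d x %d, z scale %.1f\n",
              d[1], d[2], d[3], x$z_scale))
  invisible(x)
}

#' Export a volume as a multi-page TIFF
#'
#' One page per z-plane plus a JSON sidecar (`<path>.json`) carrying the
#' voxel geometry and bit depth; [read_volume()] restores the identical
#' voxel values and metadata.
#'
#' @param vol an [stack_masks()] volume
#' @param path output TIFF path
#' @param bits 8 or 16 bits per sample
#' @return invisibly, `path`
#' @export
export_volume <- function(vol, path, bits = 8) {
  if (!inherits(vol, "islet_volume") || length(vol$voxels) == 0)
    stop("empty or invalid volume")
  if (!bits %in% c(8, 16)) stop("bits must be 8 or 16")
  mx <- 2^bits - 1
  if (min(vol$voxels) < 0 || max(vol$voxels) > mx)
    stop("voxel values out of range for requested bit depth")
  pages <- lapply(seq_len(dim(vol$voxels)[1]),
                  function(k) vol$voxels[k, , ] / mx)
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = bits), silent = TRUE)
  if (inherits(ok, "try-error")) stop("could not write TIFF: ", path)
  jsonlite::write_json(list(xy_um = vol$geom$xy_um, z_um = vol$geom$z_um,
                            z_scale = vol$z_scale, bits = bits),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a volume written by [export_volume()]
#'
#' @param path TIFF path (the `<path>.json` sidecar must be present)
#' @return an `islet_volume`
#' @export
read_volume <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  mx <- 2^meta$bits - 1
  planes <- lapply(pages, function(p) round_half_up(p * mx))
  stack_masks(planes, voxel_geometry(meta$xy_um, meta$z_um))
}

#' Read / write an 8-bit grey PNG plane
#'
#' @param path PNG file path
#' @param pixel_size_um pixel size to attach on read
#' @return [read_plane()]: an `intensity_plane` with values in 0..255
#' @export
read_plane <- function(path, pixel_size_um = 0.3604) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  intensity_plane(round_half_up(px * 255), pixel_size_um)
}

#' @rdname read_plane
#' @param plane matrix with values in 0..255
#' @export
write_plane <- function(plane, path) {
  png::writePNG(pmin(pmax(unclass(plane), 0), 255) / 255, path)
  invisible(path)
}
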