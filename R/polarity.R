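#' Line-scan parameters
#'
#' @param boundary_width_px width of the morphological boundary region drawn
#'   around each cell (dilation radius, px)
#' @param laminin_window_px side of the (odd) square window scanned over the
#'   boundary region to find the laminin extrema
#' @param insulin_window_px side of the square window averaged around each
#'   scan-line coordinate (even windows anchor at offsets -w/2 .. w/2-1)
#' @return object of class `scan_params`
#' @export
scan_params <- function(boundary_width_px = 10, laminin_window_px = 9,
                        insulin_window_px = 10) {
  if (boundary_width_px < 1 || laminin_window_px < 1 || insulin_window_px < 1)
    stop("all scan parameters must be >= 1")
  if (laminin_window_px %% 2 == 0)
    stop("laminin_window_px must be odd")
  structure(list(boundary_width_px = as.integer(boundary_width_px),
                 laminin_window_px = as.integer(laminin_window_px),
                 insulin_window_px = as.integer(insulin_window_px)),
            class = "scan_params")
}

#' Boundary region of a cell mask
#'
#' Binary dilation of the mask with a Euclidean disc of radius `width_px`,
#' minus the mask itself: the ring of pixels just outside the cell, clipped
#' at image edges, in which the laminin extrema are sought.
#'
#' @param cell_mask binary mask of one cell
#' @param width_px dilation radius in pixels
#' @return binary mask of the boundary region (disjoint from `cell_mask`)
#' @export
boundary_region <- function(cell_mask, width_px = 10) {
  cell_mask <- as_binary_mask(cell_mask)
  if (sum(cell_mask) == 0) stop("empty cell mask")
  dil <- as_binary_mask(as_plain_matrix(
    EBImage::dilate(cell_mask, disc_kernel(width_px))))
  as_binary_mask(dil == 1 & cell_mask == 0)
}

#' Locate the vascular and avascular face points
#'
#' Scans a `window_px` x `window_px` window over every position whose centre
#' lies in the boundary region, computing the mean laminin of the in-bounds
#' window pixels. The vascular point is the centre of the winning (argmax)
#' window and the avascular point that of the argmin; ties are broken by
#' row-major scan order, first occurrence winning.
#'
#' @param region binary boundary-region mask
#' @param laminin laminin channel matrix
#' @param window_px odd window side
#' @return object of class `face_pair`: list with `vascular_pt`,
#'   `avascular_pt` (c(row, col)) and `laminin_vascular`,
#'   `laminin_avascular` (the winning window means)
#' @export
find_face_points <- function(region, laminin, window_px = 9) {
  region <- as_binary_mask(region)
  if (sum(region) == 0) stop("empty boundary region")
  if (window_px %% 2 == 0) stop("window_px must be odd")
  W <- window_mean_image(unclass(laminin), window_px)
  pts <- which_rowmajor(region)
  vals <- W[pts]
  iv <- which.max(vals)  # first max in row-major order
  ia <- which.min(vals)
  structure(list(vascular_pt = unname(pts[iv, ]),
                 avascular_pt = unname(pts[ia, ]),
                 laminin_vascular = vals[iv],
                 laminin_avascular = vals[ia]),
            class = "face_pair")
}

#' Cell centre
#'
#' Unweighted centroid of the mask pixels, rounded half-up to the nearest
#' pixel.
#'
#' @param cell_mask binary mask of one cell
#' @return c(row, col)
#' @export
cell_centre <- function(cell_mask) {
  px <- which(as_binary_mask(cell_mask) == 1, arr.ind = TRUE)
  if (nrow(px) == 0) stop("empty cell mask")
  unname(round_half_up(colMeans(px)))
}

#' Bresenham line rasterisation
#'
#' 8-connected integer line from `from_pt` to `to_pt` inclusive, monotone in
#' the dominant axis. Identical endpoints give a single-point line.
#'
#' @param from_pt,to_pt c(row, col) integer points
#' @return n x 2 matrix of (row, col) coordinates in order
#' @export
scan_line <- function(from_pt, to_pt) {
  r0 <- as.integer(from_pt[1]); c0 <- as.integer(from_pt[2])
  r1 <- as.integer(to_pt[1]); c1 <- as.integer(to_pt[2])
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- if (r0 < r1) 1L else -1L
  sc <- if (c0 < c1) 1L else -1L
  err <- dr - dc
  pts <- matrix(NA_integer_, dr + dc + 1L, 2)
  k <- 0L
  repeat {
    k <- k + 1L
    pts[k, ] <- c(r0, c0)
    if (r0 == r1 && c0 == c1) break
    e2 <- 2L * err
    if (e2 > -dc) { err <- err - dc; r0 <- r0 + sr }
    if (e2 < dr) { err <- err + dr; c0 <- c0 + sc }
  }
  pts[seq_len(k), , drop = FALSE]
}

#' Maximum windowed insulin along a scan line
#'
#' For every line coordinate lying inside the cell mask, averages insulin
#' over the `window_px` x `window_px` neighbourhood intersected with the
#' cell mask and the image bounds, and returns the maximum such mean. Only
#' in-cell pixels ever contribute. Returns `NA` if no line coordinate falls
#' inside the cell.
#'
#' @param line n x 2 matrix from [scan_line()]
#' @param insulin insulin channel matrix
#' @param cell_mask binary mask of the cell
#' @param window_px window side; even windows anchor at offsets
#'   `-w/2 .. w/2-1` around the coordinate
#' @return maximum windowed mean (numeric), or `NA_real_`
#' @export
insulin_along_line <- function(line, insulin, cell_mask, window_px = 10) {
  if (is.null(dim(line))) line <- matrix(line, ncol = 2)
  if (nrow(line) == 0) stop("empty line")
  cell_mask <- as_binary_mask(cell_mask)
  insulin <- unclass(insulin)
  h <- nrow(insulin); w <- ncol(insulin)
  lo <- -(window_px %/% 2)
  hi <- if (window_px %% 2 == 1) window_px %/% 2 else window_px %/% 2 - 1
  best <- NA_real_
  for (i in seq_len(nrow(line))) {
    r <- line[i, 1]; c <- line[i, 2]
    if (r < 1 || r > h || c < 1 || c > w) next
    if (cell_mask[r, c] == 0) next
    rr <- max(1, r + lo):min(h, r + hi)
    cc <- max(1, c + lo):min(w, c + hi)
    sel <- cell_mask[rr, cc] == 1
    if (!any(sel)) next
    m <- mean(insulin[rr, cc][sel])
    if (is.na(best) || m > best) best <- m
  }
  best
}

#' Analyse one cell instance
#'
#' Composes the face-detection chain for a single cell: boundary region,
#' laminin face points, centroid, two centre-directed scan lines and the
#' windowed insulin maxima along them.
#'
#' @param cell_id positive label present in `lm`
#' @param lm instance label map
#' @param channels named list with `insulin` and `laminin` matrices
#' @param params a [scan_params()]
#' @param islet_id,plane_index identifiers copied into the record
#' @return one-row data.frame (a polarity record); insulin fields are `NA`
#'   when no scan-line coordinate lies inside the cell
#' @export
analyse_cell <- function(cell_id, lm, channels, params = scan_params(),
                         islet_id = "islet", plane_index = 1L) {
  px <- which(lm == cell_id, arr.ind = TRUE)
  if (nrow(px) == 0) stop("cell_id not present in label map")
  # work on a bounding box padded by the boundary width plus the window
  # extents; all operators used are local, so the crop is exact
  pad <- params$boundary_width_px + params$laminin_window_px +
    params$insulin_window_px
  r0 <- max(1L, min(px[, 1]) - pad); r1 <- min(nrow(lm), max(px[, 1]) + pad)
  c0 <- max(1L, min(px[, 2]) - pad); c1 <- min(ncol(lm), max(px[, 2]) + pad)
  cm <- as_binary_mask(lm[r0:r1, c0:c1] == cell_id)
  lam <- unclass(channels$laminin)[r0:r1, c0:c1]
  ins <- unclass(channels$insulin)[r0:r1, c0:c1]
  region <- boundary_region(cm, params$boundary_width_px)
  face <- find_face_points(region, lam, params$laminin_window_px)
  cen <- cell_centre(cm)
  iv <- insulin_along_line(scan_line(face$vascular_pt, cen),
                           ins, cm, params$insulin_window_px)
  ia <- insulin_along_line(scan_line(face$avascular_pt, cen),
                           ins, cm, params$insulin_window_px)
  off <- c(r0 - 1L, c0 - 1L)
  data.frame(islet_id = islet_id, plane = as.integer(plane_index),
             cell_id = as.integer(cell_id), area_px = sum(cm),
             centroid_r = cen[1] + off[1], centroid_c = cen[2] + off[2],
             vasc_r = face$vascular_pt[1] + off[1],
             vasc_c = face$vascular_pt[2] + off[2],
             avasc_r = face$avascular_pt[1] + off[1],
             avasc_c = face$avascular_pt[2] + off[2],
             laminin_vascular = face$laminin_vascular,
             laminin_avascular = face$laminin_avascular,
             insulin_vascular = iv, insulin_avascular = ia,
             stringsAsFactors = FALSE)
}

#' Analyse all cell instances of an islet
#'
#' Iterates [analyse_cell()] over every instance of every plane; one record
#' (CSV row) per cell instance per plane. Per-cell failures are logged as
#' messages and skipped, never fatal.
#'
#' @param channels_per_plane list (one element per plane) of named channel
#'   lists with `insulin` and `laminin`
#' @param lm_per_plane list of instance label maps aligned with the planes
#' @param params a [scan_params()]
#' @param islet_id identifier copied into the records
#' @param csv optional path; records are written as UTF-8 CSV with header
#' @return data.frame of polarity records
#' @export
analyse_islet <- function(channels_per_plane, lm_per_plane,
                          params = scan_params(), islet_id = "islet",
                          csv = NULL) {
  if (length(channels_per_plane) != length(lm_per_plane))
    stop("planes and label maps must be aligned")
  recs <- list()
  for (p in seq_along(lm_per_plane)) {
    lm <- lm_per_plane[[p]]
    for (k in seq_len(max(0L, max(lm)))) {
      rec <- try(analyse_cell(k, lm, channels_per_plane[[p]], params,
                              islet_id, p), silent = TRUE)
      if (inherits(rec, "try-error")) {
        message(sprintf("skipping %s plane %d cell %d: %s", islet_id, p, k,
                        attr(rec, "condition")$message))
        next
      }
      recs[[length(recs) + 1L]] <- rec
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    analyse_islet_empty_frame()
  if (!is.null(csv)) write.csv(out, csv, row.names = FALSE,
                               fileEncoding = "UTF-8")
  out
}

analyse_islet_empty_frame <- function() {
  data.frame(islet_id = character(0), plane = integer(0),
             cell_id = integer(0), area_px = integer(0),
             centroid_r = numeric(0), centroid_c = numeric(0),
             vasc_r = numeric(0), vasc_c = numeric(0),
             avasc_r = numeric(0), avasc_c = numeric(0),
             laminin_vascular = numeric(0), laminin_avascular = numeric(0),
             insulin_vascular = numeric(0), insulin_avascular = numeric(0),
             stringsAsFactors = FALSE)
}

#' Manual-style face-to-face line scan
#'
#' Emulates the manual protocol: rasterise the line from the vascular to the
#' avascular boundary point and average insulin over the first
#' `round(depth_um / pixel_size_um)` in-cell pixels inward from each face.
#' If fewer in-cell pixels are available at a face (short cells), the
#' available ones are averaged and the result is flagged truncated.
#'
#' @param insulin insulin channel matrix
#' @param p_vascular,p_avascular boundary points c(row, col) at the two faces
#' @param cell_mask binary mask of the cell
#' @param depth_um measurement depth into the cell from each face (default
#'   2 um)
#' @param pixel_size_um physical pixel size (default taken from the channel
#'   attribute, else 0.3604)
#' @return list with `vascular_mean`, `avascular_mean`, `depth_px` and
#'   `truncated`
#' @export
manual_linescan <- function(insulin, p_vascular, p_avascular, cell_mask,
                            depth_um = 2,
                            pixel_size_um = NULL) {
  if (all(p_vascular == p_avascular)) stop("endpoints must differ")
  if (depth_um <= 0) stop("depth_um must be > 0")
  if (is.null(pixel_size_um)) pixel_size_um <- pixel_size(insulin)
  n_px <- max(1L, round_half_up(depth_um / pixel_size_um))
  cell_mask <- as_binary_mask(cell_mask)
  insulin <- unclass(insulin)
  line <- scan_line(p_vascular, p_avascular)
  inside <- cell_mask[line] == 1
  if (!any(inside)) stop("line does not cross the cell")
  idx <- which(inside)
  take_v <- idx[seq_len(min(n_px, length(idx)))]
  ridx <- rev(idx)
  take_a <- ridx[seq_len(min(n_px, length(ridx)))]
  truncated <- length(idx) < 2 * n_px
  list(vascular_mean = mean(insulin[line[take_v, , drop = FALSE]]),
       avascular_mean = mean(insulin[line[take_a, , drop = FALSE]]),
       depth_px = n_px, truncated = truncated)
}
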