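#' Parameters for the synthetic islet generator
#'
#' The generator emulates a single confocal plane of an intact islet at the
#' working resolution of the analysis (512 x 512 px, ~0.36 um/px): a
#' connected capillary network carrying the laminin signal, irregular
#' close-packed beta cells seeded against the capillaries, and per-cell
#' insulin with a programmed enrichment towards the capillary contact.
#'
#' @param image_size pixels per side (>= 64)
#' @param n_cells target number of cells (>= 1)
#' @param cell_radius_px mean cell radius in pixels (20 px ~ 7.2 um at the
#'   0.3604 um/px resized scale, i.e. a ~14 um beta cell)
#' @param cell_radius_sd_px SD of the per-cell radius
#' @param capillary_width_px capillary tube half-width in pixels (0 gives an
#'   empty capillary mask; contacts then refer to the centreline)
#' @param enrichment_ratio r >= 1, the programmed vascular:avascular expected
#'   insulin ratio (1 = unpolarised)
#' @param base_insulin 8-bit insulin level away from the vascular face
#' @param noise_sd additive Gaussian noise SD, 8-bit units
#' @param granule_density expected number of granule speckles per cell
#' @param granule_contrast multiplicative contrast of a granule speckle
#'   (granules modulate the local insulin content, so the programmed
#'   vascular:avascular ratio is preserved in expectation)
#' @param laminin_tube 8-bit laminin level in the capillary lumen
#' @param laminin_sheath extra laminin in the basement-membrane sheath (the
#'   outer ~2.5 px of the tube)
#' @param laminin_interface_boost extra laminin where the capillary sheath
#'   borders a cell (basement membrane is brightest at the endothelium-cell
#'   interface)
#' @param laminin_background 8-bit laminin level outside capillaries
#' @param contact_halfwidth_px half-width of the arc over which a cell may
#'   press against the capillary (cells contact the vessel over a compact
#'   patch, not their whole flank)
#' @param enrichment_plateau,enrichment_extent the insulin enrichment is a
#'   cortical zone near the contact: full strength out to
#'   `enrichment_plateau` x (contact-to-centroid distance), decaying smoothly
#'   to zero by `enrichment_extent` x that distance
#' @param pixel_size_um physical pixel size recorded on the channels
#' @param seed RNG seed used by [simulate_islet()]
#' @return an object of class `synth_params`
#' @export
synth_params <- function(image_size = 512, n_cells = 28,
                         cell_radius_px = 25, cell_radius_sd_px = 2.5,
                         capillary_width_px = 5, enrichment_ratio = 1.4,
                         base_insulin = 100, noise_sd = 6,
                         granule_density = 20, granule_contrast = 0.25,
                         laminin_tube = 60, laminin_sheath = 30,
                         laminin_interface_boost = 140,
                         laminin_background = 4, contact_halfwidth_px = 5,
                         enrichment_plateau = 0.55, enrichment_extent = 0.63,
                         pixel_size_um = 0.3604, seed = 1L) {
  p <- list(image_size = as.integer(image_size), n_cells = as.integer(n_cells),
            cell_radius_px = cell_radius_px,
            cell_radius_sd_px = cell_radius_sd_px,
            capillary_width_px = as.integer(capillary_width_px),
            enrichment_ratio = enrichment_ratio, base_insulin = base_insulin,
            noise_sd = noise_sd, granule_density = granule_density,
            granule_contrast = granule_contrast,
            laminin_tube = laminin_tube, laminin_sheath = laminin_sheath,
            laminin_interface_boost = laminin_interface_boost,
            laminin_background = laminin_background,
            contact_halfwidth_px = contact_halfwidth_px,
            enrichment_plateau = enrichment_plateau,
            enrichment_extent = enrichment_extent,
            pixel_size_um = pixel_size_um, seed = as.integer(seed))
  if (p$image_size < 64) stop("image_size must be >= 64")
  if (p$n_cells < 1) stop("n_cells must be >= 1")
  if (p$enrichment_ratio < 1) stop("enrichment_ratio must be >= 1")
  for (f in c("base_insulin", "noise_sd", "laminin_tube", "laminin_sheath",
              "laminin_interface_boost", "laminin_background"))
    if (p[[f]] < 0 || p[[f]] > 255)
      stop(sprintf("%s must lie in [0, 255]", f))
  if (p$enrichment_plateau <= 0 || p$enrichment_extent <= p$enrichment_plateau ||
      p$enrichment_extent > 1)
    stop("need 0 < enrichment_plateau < enrichment_extent <= 1")
  structure(p, class = "synth_params")
}

#' Generate a connected capillary network mask
#'
#' Correlated random-walk centrelines (later walks branch from earlier ones,
#' keeping the network connected) dilated to the tube half-width. The
#' centreline pixel coordinates are attached as attribute `"centreline"` so
#' that degenerate zero-width networks still define contact targets.
#'
#' @param params a [synth_params()] object
#' @return binary mask (integer matrix) with attribute `centreline`
#' @export
generate_capillaries <- function(params) {
  n <- params$image_size
  n_walks <- max(1L, as.integer(round(n / 170)))
  n_steps <- as.integer(round(1.2 * n))
  pts <- matrix(numeric(0), 0, 2)
  for (w in seq_len(n_walks)) {
    if (w == 1 || nrow(pts) == 0) {
      side <- sample.int(4, 1)
      pos <- switch(side,
                    c(1, runif(1, 1, n)), c(n, runif(1, 1, n)),
                    c(runif(1, 1, n), 1), c(runif(1, 1, n), n))
      heading <- atan2(n / 2 - pos[1], n / 2 - pos[2]) + runif(1, -0.4, 0.4)
    } else {
      # branch from the existing network to keep it connected
      start <- pts[sample.int(nrow(pts), 1), ]
      pos <- start
      heading <- runif(1, 0, 2 * pi)
    }
    walk <- matrix(NA_real_, n_steps, 2)
    for (s in seq_len(n_steps)) {
      heading <- heading + rnorm(1, 0, 0.12)
      pos <- pos + 1.5 * c(sin(heading), cos(heading))
      # reflect at the image border so the network length is seed-stable
      if (pos[1] < 1) { pos[1] <- 2 - pos[1]; heading <- -heading }
      if (pos[1] > n) { pos[1] <- 2 * n - pos[1]; heading <- -heading }
      if (pos[2] < 1) { pos[2] <- 2 - pos[2]; heading <- pi - heading }
      if (pos[2] > n) { pos[2] <- 2 * n - pos[2]; heading <- pi - heading }
      walk[s, ] <- pos
    }
    pts <- rbind(pts, walk)
  }
  cl <- unique(round_half_up(pts))
  cl <- cl[cl[, 1] >= 1 & cl[, 1] <= n & cl[, 2] >= 1 & cl[, 2] <= n, ,
           drop = FALSE]
  mask <- matrix(0L, n, n)
  wpx <- max(0L, params$capillary_width_px)
  if (nrow(cl) > 0 && wpx > 0) {
    m <- matrix(0L, n, n)
    m[cl] <- 1L
    mask <- as_binary_mask(as_plain_matrix(EBImage::dilate(m, disc_kernel(wpx))))
  }
  attr(mask, "centreline") <- cl
  mask
}

#' Place beta cells against the capillary network
#'
#' Cells are seeded just outside the capillary wall and grown by seeded
#' region growing on a noise-roughened distance-to-seed metric, giving
#' irregular, close-packed, non-overlapping cells. Each cell may press
#' against the vessel only over a compact arc near its seed (its contact
#' patch); elsewhere a thin extracellular gap remains. The ground-truth
#' contact point is the cell boundary pixel nearest the capillary, ties
#' resolved towards the middle of the contact arc.
#'
#' @param capillaries binary capillary mask from [generate_capillaries()]
#' @param params a [synth_params()] object
#' @return list with `instances` (integer label map, 0 background, labels
#'   1..n) and `contacts` (n x 2 matrix of (row, col) contact points)
#' @export
place_cells <- function(capillaries, params) {
  n <- params$image_size
  stopifnot(nrow(capillaries) == n, ncol(capillaries) == n)
  cl <- attr(capillaries, "centreline")
  # distance from every pixel to the capillary (or its centreline if width 0)
  ref <- capillaries
  if (sum(ref) == 0) {
    ref <- matrix(0L, n, n)
    if (!is.null(cl) && nrow(cl) > 0) ref[cl] <- 1L
  }
  if (sum(ref) == 0) {
    warning("no capillary pixels; no cells placed")
    return(list(instances = matrix(0L, n, n),
                contacts = matrix(numeric(0), 0, 2)))
  }
  dcap <- as_plain_matrix(EBImage::distmap(1L - ref))
  # candidate seeds: just outside the vessel wall, away from the border
  cand <- which(dcap >= 2 & dcap <= 4 & capillaries == 0, arr.ind = TRUE)
  margin <- ceiling(params$cell_radius_px * 0.5)
  cand <- cand[cand[, 1] > margin & cand[, 1] <= n - margin &
               cand[, 2] > margin & cand[, 2] <= n - margin, , drop = FALSE]
  if (nrow(cand) == 0) {
    warning("no seed sites adjacent to capillaries; no cells placed")
    return(list(instances = matrix(0L, n, n),
                contacts = matrix(numeric(0), 0, 2)))
  }
  cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
  min_sep <- 1.7 * params$cell_radius_px
  seeds <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(seeds) == 0 ||
        min(sqrt((seeds[, 1] - p[1])^2 + (seeds[, 2] - p[2])^2)) >= min_sep) {
      seeds <- rbind(seeds, p)
      if (nrow(seeds) == params$n_cells) break
    }
  }
  n_placed <- nrow(seeds)
  if (n_placed < params$n_cells)
    warning(sprintf("placed %d of %d requested cells", n_placed,
                    params$n_cells))
  radii <- rnorm(n_placed, params$cell_radius_px, params$cell_radius_sd_px)
  radii <- pmin(pmax(radii, 0.6 * params$cell_radius_px),
                1.4 * params$cell_radius_px)
  # cells may touch the vessel only within contact_halfwidth_px of a seed
  near_seed <- matrix(FALSE, n, n)
  chw <- params$contact_halfwidth_px
  for (i in seq_len(n_placed)) {
    r0 <- max(1, seeds[i, 1] - chw - 2):min(n, seeds[i, 1] + chw + 2)
    c0 <- max(1, seeds[i, 2] - chw - 2):min(n, seeds[i, 2] + chw + 2)
    dd <- outer((r0 - seeds[i, 1])^2, (c0 - seeds[i, 2])^2, "+")
    near_seed[r0, c0] <- near_seed[r0, c0] | dd <= (chw + 2)^2
  }
  allowed <- capillaries == 0 & (dcap > 2 | near_seed)
  # roughen the growth metric with a smooth random field
  rough <- matrix(rnorm(n * n), n, n)
  rough <- as_plain_matrix(EBImage::gblur(rough, sigma = 4))
  rough <- 1 + 0.45 * (rough - mean(rough)) / (sd(rough) + 1e-12)
  rough <- pmax(rough, 0.6)
  lab <- grow_regions(as.integer(seeds[, 1] - 1), as.integer(seeds[, 2] - 1),
                      allowed, radii, rough)
  # drop empty labels, renumber contiguously
  areas <- tabulate(lab[lab > 0], nbins = n_placed)
  keep <- which(areas > 0)
  remap <- integer(n_placed); remap[keep] <- seq_along(keep)
  lab[lab > 0] <- remap[lab[lab > 0]]
  contacts <- matrix(NA_real_, length(keep), 2)
  dref <- dcap
  for (k in seq_along(keep)) {
    cm <- lab == k
    bnd <- cm & !(shift_mat(cm, 1, 0, TRUE) & shift_mat(cm, -1, 0, TRUE) &
                  shift_mat(cm, 0, 1, TRUE) & shift_mat(cm, 0, -1, TRUE))
    bp <- which(bnd, arr.ind = TRUE)
    dv <- dref[bp]
    tied <- bp[dv <= min(dv) + 0.5, , drop = FALSE]
    mid <- colMeans(tied)
    j <- which.min((tied[, 1] - mid[1])^2 + (tied[, 2] - mid[2])^2)
    contacts[k, ] <- tied[j, ]
  }
  list(instances = lab, contacts = contacts)
}

# Cortical enrichment profile: 1 on the plateau, smooth cosine decay, 0
# beyond the extent. d and the breakpoints are in pixels.
enrichment_profile <- function(d, d0, d1) {
  g <- numeric(length(d))
  g[d <= d0] <- 1
  ramp <- d > d0 & d < d1
  g[ramp] <- 0.5 * (1 + cos(pi * (d[ramp] - d0) / (d1 - d0)))
  g
}

#' Render the insulin, laminin and nuclei channels of a synthetic islet
#'
#' Laminin: capillary tube plus an interface sheath enhancement where the
#' vessel borders a cell. Insulin inside cell c is
#' `base_insulin * (1 + (r - 1) * g(p))` where g is 1 at the contact point,
#' stays 1 over a cortical plateau, and decays smoothly to 0 well before the
#' pixel of the cell farthest from the contact; granule speckles and
#' additive Gaussian noise are applied afterwards. Nuclei: one blurred disc
#' per cell. All channels are clipped to [0, 255] and rounded (8-bit).
#'
#' @param instances integer label map from [place_cells()]
#' @param contacts matrix of per-cell contact points
#' @param capillaries binary capillary mask
#' @param params a [synth_params()] object
#' @return object of class `synthetic_islet`: list with `channels`
#'   (insulin, laminin, nuclei matrices), `truth_instances`,
#'   `truth_contacts`, `capillaries`, `params`
#' @export
render_channels <- function(instances, contacts, capillaries, params) {
  n <- params$image_size
  ncell <- max(0L, max(instances))
  r <- params$enrichment_ratio
  insulin <- matrix(0, n, n)
  nuclei <- matrix(0, n, n)
  cell_any <- instances > 0
  for (k in seq_len(ncell)) {
    px <- which(instances == k, arr.ind = TRUE)
    ct <- contacts[k, ]
    cen <- colMeans(px)
    d <- sqrt((px[, 1] - ct[1])^2 + (px[, 2] - ct[2])^2)
    dcen <- max(sqrt(sum((cen - ct)^2)), 2)
    g <- enrichment_profile(d, params$enrichment_plateau * dcen,
                            params$enrichment_extent * dcen)
    insulin[px] <- params$base_insulin * (1 + (r - 1) * g)
    # granule speckle: small discs that multiply the local insulin content,
    # preserving the programmed vascular:avascular ratio in expectation
    ng <- rpois(1, params$granule_density)
    if (ng > 0 && nrow(px) > 0) {
      gi <- px[sample.int(nrow(px), ng, replace = TRUE), , drop = FALSE]
      for (j in seq_len(ng)) {
        rr <- max(1, gi[j, 1] - 1):min(n, gi[j, 1] + 1)
        cc <- max(1, gi[j, 2] - 1):min(n, gi[j, 2] + 1)
        insulin[rr, cc] <- insulin[rr, cc] * (1 + params$granule_contrast)
      }
    }
    # nucleus: blurred disc at the centroid
    nr <- max(2, 0.35 * params$cell_radius_px)
    rr <- max(1, round(cen[1] - nr)):min(n, round(cen[1] + nr))
    cc <- max(1, round(cen[2] - nr)):min(n, round(cen[2] + nr))
    dd <- outer((rr - cen[1])^2, (cc - cen[2])^2, "+")
    nuclei[rr, cc] <- pmax(nuclei[rr, cc], 180 * (dd <= nr^2))
  }
  if (any(nuclei > 0)) nuclei <- as_plain_matrix(EBImage::gblur(nuclei, 2))
  laminin <- matrix(params$laminin_background, n, n)
  if (sum(capillaries) > 0) {
    # lumen + basement-membrane sheath (outer rim of the tube)
    dedge <- as_plain_matrix(EBImage::distmap(capillaries))
    tube <- capillaries == 1
    laminin[tube] <- params$laminin_tube +
      params$laminin_sheath * exp(-(pmax(dedge[tube] - 1, 0))^2 / (2 * 1.5^2))
    if (sum(cell_any) > 0) {
      # basement membrane is brightest at the endothelium-cell interface: a
      # band straddling the tube edge wherever a cell presses against it
      dcell <- as_plain_matrix(EBImage::distmap(1L - (instances > 0)))
      dtube <- as_plain_matrix(EBImage::distmap(1L - capillaries))
      boost <- params$laminin_interface_boost *
        exp(-dtube^2 / (2 * 2^2)) * exp(-dcell^2 / (2 * 2^2))
      laminin <- laminin + boost
    }
  }
  if (params$noise_sd > 0) {
    insulin <- insulin + matrix(rnorm(n * n, 0, params$noise_sd), n, n)
    laminin <- laminin + matrix(rnorm(n * n, 0, params$noise_sd), n, n)
    nuclei <- nuclei + matrix(rnorm(n * n, 0, params$noise_sd), n, n)
  }
  channels <- lapply(list(insulin = insulin, laminin = laminin,
                          nuclei = nuclei),
                     function(ch) {
                       ch <- round_half_up(clip8(ch))
                       intensity_plane(ch, params$pixel_size_um)
                     })
  structure(list(channels = channels, truth_instances = instances,
                 truth_contacts = contacts, capillaries = capillaries,
                 params = params),
            class = "synthetic_islet")
}

#' Simulate one synthetic islet plane
#'
#' Seeds the RNG from `params$seed` and runs capillary generation, cell
#' placement and channel rendering. Identical parameters (including seed)
#' give bit-identical output.
#'
#' @param params a [synth_params()] object
#' @return a `synthetic_islet` object (see [render_channels()])
#' @export
simulate_islet <- function(params = synth_params()) {
  set.seed(params$seed)
  cap <- generate_capillaries(params)
  pc <- place_cells(cap, params)
  render_channels(pc$instances, pc$contacts, cap, params)
}

#' @export
print.synthetic_islet <- function(x, ...) {
  cat(sprintf("synthetic islet: %d x %d px, %d cells, r = %.2f, seed = %d\n",
              x$params$image_size, x$params$image_size,
              max(x$truth_instances), x$params$enrichment_ratio,
              x$params$seed))
  invisible(x)
}

#' Write a synthetic islet to disk
#'
#' One 8-bit grey PNG per channel, a 16-bit PNG instance label map, and a
#' JSON sidecar holding the parameters and ground-truth contact points.
#'
#' @param islet a `synthetic_islet`
#' @param dir output directory (created if needed)
#' @param prefix file name prefix
#' @return invisibly, the vector of files written
#' @export
write_islet <- function(islet, dir, prefix = "islet") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (ch in names(islet$channels)) {
    f <- file.path(dir, sprintf("%s_%s.png", prefix, ch))
    png::writePNG(unclass(islet$channels[[ch]]) / 255, f)
    files <- c(files, f)
  }
  f <- file.path(dir, sprintf("%s_instances.png", prefix))
  png::writePNG(islet$truth_instances / 65535, f)
  files <- c(files, f)
  side <- file.path(dir, sprintf("%s_truth.json", prefix))
  jsonlite::write_json(list(params = islet$params[names(islet$params)],
                            contacts = islet$truth_contacts),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(c(files, side))
}

#' Ground-truth semantic mask of a synthetic islet
#'
#' @param islet a `synthetic_islet`
#' @return binary mask: 1 wherever any cell instance lies
#' @export
semantic_mask <- function(islet) {
  as_binary_mask(islet$truth_instances > 0)
}
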