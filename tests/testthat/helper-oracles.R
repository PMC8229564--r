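# Independent brute-force oracles and small fixture builders. Every oracle
# is a direct, loop-based restatement of the operation's definition and
# shares no code with the implementation under test.

# Euclidean dilation minus mask, by exhaustive pixel scan.
oracle_boundary_region <- function(mask, width) {
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask == 1, arr.ind = TRUE)
  out <- matrix(0L, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (mask[r, c] == 1) next
    d2 <- min((fg[, 1] - r)^2 + (fg[, 2] - c)^2)
    if (d2 <= width^2) out[r, c] <- 1L
  }
  out
}

# Mean over a square window clipped to image bounds, explicit loops.
oracle_window_mean <- function(img, r, c, wlo, whi) {
  acc <- 0; n <- 0
  for (dr in wlo:whi) for (dc in wlo:whi) {
    rr <- r + dr; cc <- c + dc
    if (rr >= 1 && rr <= nrow(img) && cc >= 1 && cc <= ncol(img)) {
      acc <- acc + img[rr, cc]; n <- n + 1
    }
  }
  acc / n
}

# Exhaustive search over all window centres in the region, row-major ties.
oracle_face_points <- function(region, laminin, window) {
  half <- window %/% 2
  best_max <- -Inf; best_min <- Inf; pmax_ <- NULL; pmin_ <- NULL
  for (r in seq_len(nrow(region))) for (c in seq_len(ncol(region))) {
    if (region[r, c] != 1) next
    m <- oracle_window_mean(laminin, r, c, -half, half)
    if (m > best_max) { best_max <- m; pmax_ <- c(r, c) }
    if (m < best_min) { best_min <- m; pmin_ <- c(r, c) }
  }
  list(vascular_pt = pmax_, avascular_pt = pmin_,
       laminin_vascular = best_max, laminin_avascular = best_min)
}

# Max of masked window means along a pixel path, explicit loops.
oracle_insulin_along_line <- function(line, insulin, cell_mask, window) {
  wlo <- -(window %/% 2)
  whi <- if (window %% 2 == 1) window %/% 2 else window %/% 2 - 1
  best <- NA_real_
  for (i in seq_len(nrow(line))) {
    r <- line[i, 1]; c <- line[i, 2]
    if (r < 1 || r > nrow(insulin) || c < 1 || c > ncol(insulin)) next
    if (cell_mask[r, c] != 1) next
    acc <- 0; n <- 0
    for (dr in wlo:whi) for (dc in wlo:whi) {
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= nrow(insulin) && cc >= 1 && cc <= ncol(insulin) &&
          cell_mask[rr, cc] == 1) {
        acc <- acc + insulin[rr, cc]; n <- n + 1
      }
    }
    if (n > 0) {
      m <- acc / n
      if (is.na(best) || m > best) best <- m
    }
  }
  best
}

# Confusion counts by explicit scan.
oracle_confusion <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1
    else if (pred[i] == 1) fp <- fp + 1
    else if (truth[i] == 1) fn <- fn + 1
    else tn <- tn + 1
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Boundary pixels by explicit 4-neighbour scan (image edge counts).
oracle_boundaries <- function(lm) {
  h <- nrow(lm); w <- ncol(lm)
  out <- matrix(0L, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (lm[r, c] == 0) next
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr < 1 || rr > h || cc < 1 || cc > w || lm[rr, cc] != lm[r, c]) {
        out[r, c] <- 1L
        break
      }
    }
  }
  out
}

# DDA line rasterisation: round the minor axis along the dominant axis.
# Agrees with Bresenham except exactly at half-integer ties.
oracle_dda_line <- function(from, to) {
  dr <- to[1] - from[1]; dc <- to[2] - from[2]
  n <- max(abs(dr), abs(dc))
  if (n == 0) return(matrix(from, 1, 2))
  t(vapply(0:n, function(s)
    c(from[1] + s * dr / n, from[2] + s * dc / n), numeric(2)))
}

# Slow marker flood by repeated global-minimum search over the labelled,
# not-yet-expanded set (no queue; same claim rule and tie order as the
# compiled flood: ascending (priority, insertion order), labels assigned
# when the claiming pixel expands).
oracle_watershed <- function(priority, markers, mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  ins <- matrix(Inf, h, w)     # insertion order
  expanded <- matrix(FALSE, h, w)
  nxt <- 0
  for (c in seq_len(w)) for (r in seq_len(h))
    if (markers[r, c] > 0 && mask[r, c]) {
      lab[r, c] <- markers[r, c]
      ins[r, c] <- (nxt <- nxt + 1)
    }
  repeat {
    cand <- which(lab > 0 & !expanded)
    if (length(cand) == 0) break
    b <- cand[order(priority[cand], ins[cand])][1]
    r <- (b - 1) %% h + 1; c <- (b - 1) %/% h + 1
    expanded[r, c] <- TRUE
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr < 1 || rr > h || cc < 1 || cc > w) next
      if (!mask[rr, cc] || lab[rr, cc] != 0) next
      lab[rr, cc] <- lab[r, c]
      ins[rr, cc] <- (nxt <- nxt + 1)
    }
  }
  lab
}

# Random blob mask (a few overlapping discs) for property tests.
random_blob_mask <- function(n, n_discs = 3, rmax = 5) {
  m <- matrix(0L, n, n)
  for (i in seq_len(n_discs)) {
    r <- runif(1, 2, rmax); p <- runif(2, r + 1, n - r - 1)
    m[outer((seq_len(n) - p[1])^2, (seq_len(n) - p[2])^2, "+") <= r^2] <- 1L
  }
  m
}

# Disc-based instance fixture: n_discs discs, disjoint or moderately
# overlapping, with the true count.
disc_fixture <- function(n_img, n_discs, rmin, rmax, overlap, seed) {
  set.seed(seed)
  m <- matrix(0L, n_img, n_img)
  cent <- matrix(numeric(0), 0, 2); rads <- numeric(0)
  tries <- 0
  while (nrow(cent) < n_discs && tries < 500) {
    tries <- tries + 1
    r <- runif(1, rmin, rmax); p <- runif(2, r + 2, n_img - r - 2)
    if (nrow(cent) > 0) {
      dd <- sqrt((cent[, 1] - p[1])^2 + (cent[, 2] - p[2])^2)
      lim <- if (overlap) (rads + r) * 0.75 else rads + r + 3
      if (any(dd < lim)) next
    }
    cent <- rbind(cent, p); rads <- c(rads, r)
    m[outer((seq_len(n_img) - p[1])^2,
            (seq_len(n_img) - p[2])^2, "+") <= r^2] <- 1L
  }
  list(mask = m, n = nrow(cent), centres = cent)
}

# Small, fast synthetic islet used across tests.
small_islet <- function(seed, ...) {
  suppressWarnings(simulate_islet(synth_params(image_size = 256, n_cells = 8,
                                               seed = seed, ...)))
}
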