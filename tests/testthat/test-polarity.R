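test_that("boundary region is a disjoint surrounding ring", {
  msk <- matrix(0L, 30, 30); msk[10:20, 12:22] <- 1L
  reg <- boundary_region(msk, 3)
  expect_equal(sum(reg == 1 & msk == 1), 0)
  expect_gt(sum(reg), 0)
  expect_error(boundary_region(matrix(0L, 5, 5), 2), "empty")
})

test_that("single pixel with width 1 dilates to the 4-neighbour plus shape", {
  msk <- matrix(0L, 7, 7); msk[4, 4] <- 1L
  reg <- boundary_region(msk, 1)
  expect_identical(reg, oracle_boundary_region(msk, 1))
  expect_equal(sum(reg), 4)
  expect_equal(reg[3, 4] + reg[5, 4] + reg[4, 3] + reg[4, 5], 4L)
})

test_that("boundary region equals brute-force dilation minus mask", {
  set.seed(60)
  for (i in 1:12) {
    msk <- random_blob_mask(24)
    if (sum(msk) == 0) next
    w <- sample(1:4, 1)
    expect_identical(boundary_region(msk, w), oracle_boundary_region(msk, w))
  }
})

test_that("face points match exhaustive window search, ties row-major", {
  # constant laminin: both points tie to the first region pixel in scan order
  msk <- matrix(0L, 20, 20); msk[8:13, 8:13] <- 1L
  reg <- boundary_region(msk, 2)
  fp <- find_face_points(reg, matrix(50, 20, 20), 3)
  expect_equal(fp$vascular_pt, fp$avascular_pt)
  first <- isletpol:::which_rowmajor(reg)[1, ]
  expect_equal(fp$vascular_pt, unname(first))
  expect_equal(fp$laminin_vascular, 50)
  # left-to-right ramp: vascular point on the right arc
  ramp <- matrix(rep(1:20, each = 20), 20, 20)
  fp2 <- find_face_points(reg, ramp, 3)
  expect_gt(fp2$vascular_pt[2], 13)
  expect_lt(fp2$avascular_pt[2], 8)
  o <- oracle_face_points(reg, ramp, 3)
  expect_equal(fp2$vascular_pt, o$vascular_pt)
  expect_equal(fp2$laminin_vascular, o$laminin_vascular)
})

test_that("cell centre is the rounded centroid", {
  sq <- matrix(0L, 5, 5); sq[1:3, 1:3] <- 1L
  expect_equal(cell_centre(sq), c(2, 2))
  ell <- matrix(0L, 10, 10); ell[2:8, 3] <- 1L; ell[8, 3:7] <- 1L
  px <- which(ell == 1, arr.ind = TRUE)
  expect_equal(cell_centre(ell),
               unname(floor(colMeans(px) + 0.5)))
  expect_error(cell_centre(matrix(0L, 3, 3)), "empty")
})

test_that("scan lines are inclusive, 8-connected and monotone", {
  expect_equal(scan_line(c(0, 0), c(0, 3)),
               cbind(0L, 0:3), ignore_attr = TRUE)
  expect_equal(scan_line(c(0, 0), c(2, 2)),
               cbind(0:2, 0:2), ignore_attr = TRUE)
  expect_equal(nrow(scan_line(c(4, 4), c(4, 4))), 1)
  set.seed(70)
  for (i in 1:50) {
    a <- sample.int(30, 2); b <- sample.int(30, 2)
    ln <- scan_line(a, b)
    expect_equal(ln[1, ], a, ignore_attr = TRUE)
    expect_equal(ln[nrow(ln), ], b, ignore_attr = TRUE)
    expect_equal(nrow(ln), max(abs(b - a)) + 1)
    if (nrow(ln) > 1) {
      steps <- diff(ln)
      expect_true(all(abs(steps) <= 1))            # 8-connected
      dom <- which.max(abs(b - a))
      expect_true(all(steps[, dom] == sign(b[dom] - a[dom])))  # monotone
    }
    # each point lies within rounding distance of the continuous segment
    dda <- oracle_dda_line(a, b)
    expect_true(all(abs(ln - dda) <= 0.5 + 1e-9))
  }
})

test_that("windowed insulin maxima match the brute-force oracle", {
  msk <- matrix(0L, 25, 25); msk[6:20, 6:20] <- 1L
  const <- matrix(100, 25, 25)
  ln <- scan_line(c(2, 2), c(13, 13))
  expect_equal(insulin_along_line(ln, const, msk, 10), 100)
  # line entirely outside the cell is flagged missing
  expect_true(is.na(insulin_along_line(scan_line(c(1, 1), c(1, 24)),
                                       const, msk, 10)))
  # linear ramp: maximum at the in-cell end nearest the high side
  ramp <- matrix(rep(seq(0, 240, length.out = 25), each = 25), 25, 25,
                 byrow = TRUE)
  set.seed(80)
  for (i in 1:30) {
    a <- sample.int(25, 2); b <- sample.int(25, 2)
    ln <- scan_line(a, b)
    w <- sample(c(3, 9, 10), 1)
    expect_equal(insulin_along_line(ln, ramp, msk, w),
                 oracle_insulin_along_line(ln, ramp, msk, w))
  }
})

test_that("per-cell records compose the chain and respect invariants", {
  is1 <- small_islet(301)
  lm <- is1$truth_instances
  rec <- analyse_islet(list(is1$channels), list(lm))
  expect_equal(nrow(rec), max(lm))
  expect_true(all(rec$laminin_vascular >= rec$laminin_avascular))
  expect_true(all(rec$area_px > 0))
  # reported face points lie inside each cell's boundary region
  for (k in sample(seq_len(max(lm)), 3)) {
    reg <- boundary_region(isletpol:::as_binary_mask(lm == k), 10)
    r1 <- rec[rec$cell_id == k, ]
    expect_equal(reg[r1$vasc_r, r1$vasc_c], 1L)
    expect_equal(reg[r1$avasc_r, r1$avasc_c], 1L)
  }
})

test_that("polarised cells read vascular > avascular insulin without noise", {
  is1 <- small_islet(302, enrichment_ratio = 1.5, noise_sd = 0,
                     granule_density = 0)
  rec <- analyse_islet(list(is1$channels), list(is1$truth_instances))
  ok <- stats::complete.cases(rec[, c("insulin_vascular",
                                      "insulin_avascular")])
  expect_gte(mean(ok), 0.8)   # degenerate cells are flagged, not fabricated
  expect_true(all(rec$insulin_vascular[ok] > rec$insulin_avascular[ok]))
})

test_that("islet analysis yields one record per instance per plane and round-trips CSV", {
  a <- small_islet(303); b <- small_islet(304)
  f <- file.path(withr::local_tempdir(), "records.csv")
  rec <- analyse_islet(list(a$channels, b$channels),
                       list(a$truth_instances, b$truth_instances), csv = f)
  expect_equal(nrow(rec), max(a$truth_instances) + max(b$truth_instances))
  expect_setequal(unique(rec$plane), 1:2)
  back <- read.csv(f)
  expect_equal(back, rec, ignore_attr = TRUE)
  expect_error(analyse_islet(list(a$channels), list()), "aligned")
})

test_that("manual line scan averages the stated depth from each face", {
  cm <- matrix(0L, 40, 40); cm[10:30, 10:30] <- 1L
  ins <- matrix(100, 40, 40)
  ml <- manual_linescan(ins, c(20, 5), c(20, 36), cm, depth_um = 2,
                        pixel_size_um = 0.3604)
  expect_equal(ml$depth_px, 6)   # round(2 / 0.3604) = round(5.55)
  expect_equal(ml$vascular_mean, 100)
  expect_equal(ml$avascular_mean, 100)
  expect_false(ml$truncated)
  # step profile: the vascular mean tracks the high side
  step <- ins; step[, 1:20] <- 200
  ms <- manual_linescan(step, c(20, 5), c(20, 36), cm, 2, 0.3604)
  expect_gt(ms$vascular_mean, ms$avascular_mean)
  # depth beyond the half-length flags truncation
  tiny <- matrix(0L, 40, 40); tiny[20, 18:22] <- 1L
  mt <- manual_linescan(ins, c(20, 15), c(20, 25), tiny, 10, 0.3604)
  expect_true(mt$truncated)
  expect_error(manual_linescan(ins, c(1, 1), c(1, 1), cm, 2, 1), "differ")
})

test_that("automated and manual vascular readings agree on clean cells", {
  # pool cells across polarisation strengths so both methods see real
  # between-cell variation; the manual line runs from the true contact to
  # the diametrically opposite boundary pixel, as drawn by eye
  auto <- c(); man <- c()
  for (r in c(1.0, 1.3, 1.6, 1.9)) {
    is1 <- small_islet(305, enrichment_ratio = r, noise_sd = 0,
                       granule_density = 0)
    lm <- is1$truth_instances
    rec <- analyse_islet(list(is1$channels), list(lm))
    m <- vapply(rec$cell_id, function(k) {
      cm <- isletpol:::as_binary_mask(lm == k)
      ct <- is1$truth_contacts[k, ]
      bnd <- which(extract_boundaries(cm) == 1, arr.ind = TRUE)
      far <- bnd[which.max((bnd[, 1] - ct[1])^2 + (bnd[, 2] - ct[2])^2), ]
      manual_linescan(is1$channels$insulin, ct, far, cm, 2,
                      0.3604)$vascular_mean
    }, numeric(1))
    auto <- c(auto, rec$insulin_vascular); man <- c(man, m)
  }
  expect_gt(cor(auto, man), 0.8)
})
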