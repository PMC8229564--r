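test_that("identical seeds reproduce the islet bit for bit", {
  a <- small_islet(101)
  b <- small_islet(101)
  expect_identical(a, b)
  expect_false(identical(unclass(a$channels$insulin),
                         unclass(small_islet(102)$channels$insulin)))
})

test_that("parameter validation rejects out-of-range settings", {
  expect_error(synth_params(image_size = 32), "image_size")
  expect_error(synth_params(n_cells = 0), "n_cells")
  expect_error(synth_params(enrichment_ratio = 0.8), "enrichment_ratio")
  expect_error(synth_params(base_insulin = 300), "\\[0, 255\\]")
})

test_that("capillary mask is tube-like and its fraction sits in a plausible band", {
  fr <- vapply(1:8, function(s) {
    set.seed(s)
    mean(generate_capillaries(synth_params(seed = s)))
  }, numeric(1))
  expect_true(all(fr >= 0.02 & fr <= 0.15))
})

test_that("zero-width capillaries give an empty mask but contacts still exist", {
  p <- synth_params(image_size = 128, n_cells = 3, capillary_width_px = 0,
                    seed = 5)
  set.seed(5)
  cap <- generate_capillaries(p)
  expect_equal(sum(cap), 0)
  cl <- attr(cap, "centreline")
  expect_gt(nrow(cl), 0)
  pc <- suppressWarnings(place_cells(cap, p))
  if (max(pc$instances) > 0) {
    d <- vapply(seq_len(nrow(pc$contacts)), function(k)
      min(sqrt((cl[, 1] - pc$contacts[k, 1])^2 +
               (cl[, 2] - pc$contacts[k, 2])^2)), numeric(1))
    expect_true(all(d <= p$capillary_width_px + 2))
  }
})

test_that("cells never overlap each other or the capillary, labels contiguous", {
  for (s in c(11, 12)) {
    is1 <- small_islet(s)
    lm <- is1$truth_instances
    expect_setequal(unique(as.vector(lm)), 0:max(lm))
    expect_equal(sum(lm > 0 & is1$capillaries == 1), 0)
  }
})

test_that("every contact point touches the capillary wall", {
  is1 <- small_islet(13)
  cap <- which(is1$capillaries == 1, arr.ind = TRUE)
  d <- vapply(seq_len(nrow(is1$truth_contacts)), function(k)
    min(sqrt((cap[, 1] - is1$truth_contacts[k, 1])^2 +
             (cap[, 2] - is1$truth_contacts[k, 2])^2)), numeric(1))
  expect_true(all(d <= is1$params$capillary_width_px + 1))
})

test_that("most requested cells are placed across seeds", {
  placed <- vapply(1:10, function(s)
    max(suppressWarnings(simulate_islet(
      synth_params(seed = 200 + s)))$truth_instances), integer(1))
  expect_gte(mean(placed / 28), 0.9)
})

test_that("r = 1 with no noise renders uniform insulin within each cell", {
  is1 <- small_islet(21, enrichment_ratio = 1, noise_sd = 0,
                     granule_density = 0)
  ins <- unclass(is1$channels$insulin)
  for (k in seq_len(max(is1$truth_instances))) {
    v <- ins[is1$truth_instances == k]
    expect_equal(max(v) - min(v), 0)
  }
})

test_that("noise-free contact/farthest intensity ratio equals the programmed r", {
  is1 <- small_islet(22, enrichment_ratio = 1.5, noise_sd = 0,
                     granule_density = 0)
  ins <- unclass(is1$channels$insulin)
  for (k in seq_len(max(is1$truth_instances))) {
    px <- which(is1$truth_instances == k, arr.ind = TRUE)
    ct <- is1$truth_contacts[k, ]
    d <- sqrt((px[, 1] - ct[1])^2 + (px[, 2] - ct[2])^2)
    far <- px[which.max(d), , drop = FALSE]
    expect_equal(ins[ct[1], ct[2]] / ins[far], 1.5, tolerance = 0.011)
  }
})

test_that("channel values are 8-bit and shapes agree", {
  is1 <- small_islet(23)
  for (ch in is1$channels) {
    expect_equal(dim(ch), c(256L, 256L))
    expect_gte(min(ch), 0)
    expect_lte(max(ch), 255)
  }
})

test_that("written islet round-trips through PNG and JSON", {
  d <- withr::local_tempdir()
  is1 <- suppressWarnings(simulate_islet(
    synth_params(image_size = 128, n_cells = 3, seed = 31)))
  write_islet(is1, d, "t")
  ins <- read_plane(file.path(d, "t_insulin.png"))
  expect_equal(unclass(ins), unclass(is1$channels$insulin),
               ignore_attr = TRUE)
  meta <- jsonlite::read_json(file.path(d, "t_truth.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$params$seed, 31)
})
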