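toy_cfg <- function(epochs_max = 3, ...)
  unet_config(input_size = 32, depth = 2, base_filters = 4, channels = 2,
              epochs_max = epochs_max, seed = 7, ...)

toy_pair <- function(seed) {
  set.seed(seed)
  y <- matrix(0L, 32, 32)
  r <- sample(6:12, 1); p <- sample(10:22, 2)
  y[outer((1:32 - p[1])^2, (1:32 - p[2])^2, "+") <= r^2] <- 1L
  x <- array(0, c(32, 32, 2))
  x[, , 1] <- y * 0.8 + matrix(runif(1024, 0, 0.2), 32, 32)
  x[, , 2] <- matrix(runif(1024, 0, 0.3), 32, 32)
  list(x = x, y = y)
}

test_that("model output matches input shape, stays in (0,1), reproducible", {
  m <- build_unet(toy_cfg())
  p <- toy_pair(1)
  out <- isletpol:::unet_forward(m, p$x)$prob
  expect_equal(dim(out), c(32L, 32L))
  expect_true(all(out > 0 & out < 1))
  m2 <- build_unet(toy_cfg())
  expect_identical(out, isletpol:::unet_forward(m2, p$x)$prob)
  expect_error(build_unet(unet_config(input_size = 100, depth = 3)),
               "divisible")
})

test_that("analytic gradient agrees with finite differences", {
  cfg <- unet_config(input_size = 8, depth = 1, base_filters = 2,
                     channels = 1, seed = 3)
  m <- build_unet(cfg)
  set.seed(4)
  x <- matrix(runif(64), 8, 8)
  y <- matrix(rbinom(64, 1, 0.4), 8, 8)
  fw <- isletpol:::unet_forward(m, x, cache = TRUE)
  g <- isletpol:::unet_backward(m, fw$cache, (fw$prob - y) / length(y))
  eps <- 1e-6
  for (nm in c("enc1a", "mida", "dec1b", "out")) {
    i <- sample(length(m$par[[nm]]$w), 1)
    mp <- m; mp$par[[nm]]$w[i] <- mp$par[[nm]]$w[i] + eps
    mm <- m; mm$par[[nm]]$w[i] <- mm$par[[nm]]$w[i] - eps
    num <- (isletpol:::bce_loss(isletpol:::unet_forward(mp, x)$prob, y) -
            isletpol:::bce_loss(isletpol:::unet_forward(mm, x)$prob, y)) /
      (2 * eps)
    expect_equal(g[[nm]]$w[i], num, tolerance = 1e-4)
  }
})

test_that("training reduces the loss, records history, reproducibly", {
  pairs <- lapply(1:6, toy_pair)
  cfg <- toy_cfg(epochs_max = 4, learning_rate = 5e-3)
  fit <- train_unet(build_unet(cfg), pairs[1:4], pairs[5:6], cfg)
  expect_equal(nrow(fit$history), 4)
  expect_lt(fit$history$val_loss[fit$stop_epoch], fit$history$val_loss[1])
  fit2 <- train_unet(build_unet(cfg), pairs[1:4], pairs[5:6], cfg)
  expect_identical(fit$history, fit2$history)
  cfg1 <- toy_cfg(epochs_max = 1)
  expect_equal(nrow(train_unet(build_unet(cfg1), pairs[1:4],
                               pairs[5:6], cfg1)$history), 1)
  expect_error(train_unet(build_unet(cfg), list(), pairs[5:6], cfg), "empty")
})

test_that("prediction thresholds the probability map", {
  m <- build_unet(toy_cfg())
  p <- toy_pair(2)
  out <- predict_mask(m, p$x, prob = TRUE)
  expect_identical(out$mask, isletpol:::as_binary_mask(out$prob >= 0.5))
  expect_identical(predict_mask(m, p$x, threshold = 1 - 1e-9),
                   matrix(0L, 32, 32))
  expect_error(predict_mask(m, matrix(0, 16, 16)), "size")
})

test_that("evaluation reproduces the hand-counted confusion example", {
  pred <- matrix(0L, 4, 4); truth <- matrix(0L, 4, 4)
  truth[1, 1:3] <- 1L                  # 3 positives
  pred[1, 1:2] <- 1L; pred[2, 1] <- 1L # TP=2, FP=1, FN=1, TN=12
  m <- evaluate_segmentation(pred, truth)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 2 / 3)
  expect_equal(m$accuracy, 14 / 16)
  perfect <- evaluate_segmentation(truth, truth)
  expect_equal(c(perfect$accuracy, perfect$precision, perfect$recall,
                 perfect$f1), rep(1, 4))
  nothing <- evaluate_segmentation(matrix(0L, 4, 4), truth)
  expect_equal(c(nothing$precision, nothing$recall, nothing$f1), rep(0, 3))
  expect_error(evaluate_segmentation(matrix(0L, 2, 2), truth), "mismatch")
})

test_that("evaluation matches brute-force confusion counts on random masks", {
  set.seed(90)
  for (i in 1:25) {
    pred <- matrix(rbinom(64, 1, runif(1)), 8, 8)
    truth <- matrix(rbinom(64, 1, runif(1)), 8, 8)
    m <- evaluate_segmentation(pred, truth)
    o <- oracle_confusion(pred, truth)
    expect_equal(unname(m$counts), unname(o))
    # F1 identity
    if (m$precision + m$recall > 0)
      expect_equal(m$f1, 2 * m$precision * m$recall /
                     (m$precision + m$recall))
  }
})

test_that("cross-validation partitions by image into a disjoint cover", {
  pairs <- lapply(1:6, toy_pair)
  cfg <- toy_cfg(epochs_max = 2)
  cv <- cross_validate_unet(pairs, crossval_config(K = 3, seed = 1), cfg)
  expect_equal(sort(unique(cv$folds)), 1:3)
  expect_length(cv$folds, 6)
  expect_equal(nrow(cv$fold_metrics), 3)
  expect_equal(cv$mean$accuracy, mean(cv$fold_metrics$accuracy))
  expect_equal(cv$mean$epoch, mean(cv$fold_metrics$epoch))
  expect_error(cross_validate_unet(pairs[1:2], crossval_config(K = 3), cfg),
               "exceeds")
})
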