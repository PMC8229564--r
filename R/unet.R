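# Compact U-Net implemented over the package's compiled conv/pool/upsample
# primitives: contracting path, expanding path with skip concatenation,
# sigmoid head, per-pixel binary cross-entropy, Adam. Single-image batches;
# everything is deterministic for a fixed seed on one CPU.

unet_layer_plan <- function(cfg) {
  d <- cfg$depth; f <- cfg$base_filters
  plan <- list()
  cin <- cfg$channels
  for (i in seq_len(d)) {
    fi <- f * 2^(i - 1)
    plan[[paste0("enc", i, "a")]] <- c(cin, fi, 3L)
    plan[[paste0("enc", i, "b")]] <- c(fi, fi, 3L)
    cin <- fi
  }
  fb <- f * 2^d
  plan[["mida"]] <- c(cin, fb, 3L)
  plan[["midb"]] <- c(fb, fb, 3L)
  cin <- fb
  for (i in rev(seq_len(d))) {
    fi <- f * 2^(i - 1)
    plan[[paste0("dec", i, "a")]] <- c(cin + fi, fi, 3L)
    plan[[paste0("dec", i, "b")]] <- c(fi, fi, 3L)
    cin <- fi
  }
  plan[["out"]] <- c(cin, 1L, 1L)
  plan
}

#' U-Net configuration
#'
#' @param input_size square input side in pixels; must be divisible by
#'   `2^depth` (512 for full planes, 128 is ample for desk-scale runs)
#' @param depth number of encoder levels (>= 2 per the U-Net design; the
#'   constructor accepts >= 1 for toy models)
#' @param base_filters filters in the first encoder level (doubled per level)
#' @param channels input channels fed to the network
#' @param threshold probability cut for binarising predictions (0 < t < 1)
#' @param epochs_max maximum training epochs
#' @param early_stop_patience epochs without validation-loss improvement
#'   before stopping (best weights are restored)
#' @param learning_rate Adam step size
#' @param seed seed for weight initialisation and shuffling
#' @return object of class `unet_config`
#' @export
unet_config <- function(input_size = 512, depth = 2, base_filters = 8,
                        channels = 3, threshold = 0.5, epochs_max = 50,
                        early_stop_patience = 10, learning_rate = 1e-3,
                        seed = 1L) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (depth < 1) stop("depth must be >= 1")
  structure(list(input_size = as.integer(input_size),
                 depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 channels = as.integer(channels), threshold = threshold,
                 epochs_max = as.integer(epochs_max),
                 early_stop_patience = as.integer(early_stop_patience),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "unet_config")
}

#' Build an untrained U-Net
#'
#' He-initialised weights drawn from the config seed; identical configs give
#' identical models and hence reproducible predictions.
#'
#' @param cfg a [unet_config()]
#' @return object of class `unet_model`
#' @export
build_unet <- function(cfg = unet_config()) {
  if (cfg$input_size %% 2^cfg$depth != 0)
    stop("input_size must be divisible by 2^depth")
  set.seed(cfg$seed)
  plan <- unet_layer_plan(cfg)
  par <- lapply(plan, function(p) {
    k2 <- p[3]^2
    fan_in <- k2 * p[1]
    list(w = matrix(rnorm(fan_in * p[2], 0, sqrt(2 / fan_in)), fan_in, p[2]),
         b = rep(0, p[2]))
  })
  structure(list(cfg = cfg, par = par, plan = plan), class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  np <- sum(vapply(x$par, function(p) length(p$w) + length(p$b), numeric(1)))
  cat(sprintf("u-net: depth %d, %d base filters, %d input channels, %s px, %d parameters\n",
              x$cfg$depth, x$cfg$base_filters, x$cfg$channels,
              x$cfg$input_size, as.integer(np)))
  invisible(x)
}

unet_forward <- function(model, x, cache = FALSE) {
  cfg <- model$cfg; d <- cfg$depth
  if (is.matrix(x)) x <- array(x, c(dim(x), 1))
  if (dim(x)[3] != cfg$channels) stop("wrong number of input channels")
  cc <- list()
  conv_block <- function(h, name) {
    for (s in c("a", "b")) {
      nm <- paste0(name, s)
      p <- model$par[[nm]]
      fw <- conv2d_fwd(h, p$w, p$b, 3L)
      if (cache) cc[[nm]] <<- list(cols = fw$cols, pre = fw$out,
                                   dims = dim(h))
      h <- fw$out * (fw$out > 0)
    }
    h
  }
  skips <- vector("list", d)
  h <- x
  for (i in seq_len(d)) {
    h <- conv_block(h, paste0("enc", i))
    skips[[i]] <- h
    mp <- maxpool2_fwd(h)
    if (cache) cc[[paste0("pool", i)]] <- list(idx = mp$idx, dims = dim(h))
    h <- mp$out
  }
  h <- conv_block(h, "mid")
  for (i in rev(seq_len(d))) {
    up <- upsample2(h)
    h <- array(c(up, skips[[i]]),
               c(dim(up)[1], dim(up)[2], dim(up)[3] + dim(skips[[i]])[3]))
    if (cache) cc[[paste0("cat", i)]] <- dim(up)[3]
    h <- conv_block(h, paste0("dec", i))
  }
  p <- model$par[["out"]]
  fw <- conv2d_fwd(h, p$w, p$b, 1L)
  if (cache) cc[["out"]] <- list(cols = fw$cols, dims = dim(h))
  logit <- fw$out[, , 1]
  list(prob = 1 / (1 + exp(-logit)), cache = if (cache) cc else NULL)
}

unet_backward <- function(model, cache, dlogit) {
  d <- model$cfg$depth
  grads <- list()
  cch <- cache[["out"]]
  p <- model$par[["out"]]
  bw <- conv2d_bwd(array(dlogit, c(dim(dlogit), 1)), cch$cols, p$w, 1L,
                   cch$dims[1], cch$dims[2], cch$dims[3])
  grads[["out"]] <- list(w = bw$dw, b = bw$db)
  dh <- bw$dx
  conv_block_bwd <- function(dh, name) {
    for (s in c("b", "a")) {
      nm <- paste0(name, s)
      cch <- cache[[nm]]
      dpre <- dh * (cch$pre > 0)
      p <- model$par[[nm]]
      bw <- conv2d_bwd(dpre, cch$cols, p$w, 3L, cch$dims[1], cch$dims[2],
                       cch$dims[3])
      grads[[nm]] <<- list(w = bw$dw, b = bw$db)
      dh <- bw$dx
    }
    dh
  }
  dskips <- vector("list", d)
  for (i in seq_len(d)) {
    dh <- conv_block_bwd(dh, paste0("dec", i))
    nup <- cache[[paste0("cat", i)]]
    tot <- dim(dh)[3]
    dup <- array(dh[, , seq_len(nup)], c(dim(dh)[1], dim(dh)[2], nup))
    dskips[[i]] <- array(dh[, , (nup + 1):tot],
                         c(dim(dh)[1], dim(dh)[2], tot - nup))
    dh <- upsample2_bwd(dup)
  }
  dh <- conv_block_bwd(dh, "mid")
  for (i in rev(seq_len(d))) {
    pc <- cache[[paste0("pool", i)]]
    dh <- maxpool2_bwd(dh, pc$idx, pc$dims[1], pc$dims[2])
    dh <- dh + dskips[[i]]
    dh <- conv_block_bwd(dh, paste0("enc", i))
  }
  grads
}

bce_loss <- function(prob, y) {
  p <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train a U-Net
#'
#' Minimises per-pixel binary cross-entropy with Adam (single-image
#' batches). Training stops at `epochs_max` or once the validation loss has
#' not improved for `early_stop_patience` epochs; the best-validation
#' weights are restored and the stopping epoch recorded. Deterministic for
#' a fixed seed.
#'
#' @param model a [build_unet()] model
#' @param train_pairs list of `list(x = input array/matrix, y = binary
#'   mask)` pairs (>= 1)
#' @param val_pairs validation pairs monitored for early stopping; if
#'   `NULL`, the training loss is monitored instead
#' @param cfg training configuration (defaults to the model's)
#' @return list with `model` (best weights), `history` (per-epoch losses)
#'   and `stop_epoch`
#' @export
train_unet <- function(model, train_pairs, val_pairs = NULL,
                       cfg = model$cfg) {
  if (length(train_pairs) < 1) stop("empty training set")
  set.seed(cfg$seed + 1L)
  adam <- lapply(model$par, function(p)
    list(mw = 0 * p$w, vw = 0 * p$w, mb = 0 * p$b, vb = 0 * p$b))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t_step <- 0
  best <- list(loss = Inf, par = model$par, epoch = 0L)
  hist <- vector("list", cfg$epochs_max)
  for (epoch in seq_len(cfg$epochs_max)) {
    tl <- 0
    for (j in sample.int(length(train_pairs))) {
      pair <- train_pairs[[j]]
      fw <- unet_forward(model, pair$x, cache = TRUE)
      tl <- tl + bce_loss(fw$prob, pair$y)
      dlogit <- (fw$prob - pair$y) / length(pair$y)
      g <- unet_backward(model, fw$cache, dlogit)
      t_step <- t_step + 1
      for (nm in names(model$par)) {
        a <- adam[[nm]]
        a$mw <- b1 * a$mw + (1 - b1) * g[[nm]]$w
        a$vw <- b2 * a$vw + (1 - b2) * g[[nm]]$w^2
        a$mb <- b1 * a$mb + (1 - b1) * g[[nm]]$b
        a$vb <- b2 * a$vb + (1 - b2) * g[[nm]]$b^2
        corr1 <- 1 - b1^t_step; corr2 <- 1 - b2^t_step
        model$par[[nm]]$w <- model$par[[nm]]$w -
          cfg$learning_rate * (a$mw / corr1) / (sqrt(a$vw / corr2) + eps)
        model$par[[nm]]$b <- model$par[[nm]]$b -
          cfg$learning_rate * (a$mb / corr1) / (sqrt(a$vb / corr2) + eps)
        adam[[nm]] <- a
      }
    }
    tl <- tl / length(train_pairs)
    vl <- if (is.null(val_pairs) || length(val_pairs) == 0) tl else
      mean(vapply(val_pairs, function(pr)
        bce_loss(unet_forward(model, pr$x)$prob, pr$y), numeric(1)))
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = tl,
                                val_loss = vl)
    if (vl < best$loss - 1e-7) best <- list(loss = vl, par = model$par,
                                            epoch = epoch)
    if (epoch - best$epoch >= cfg$early_stop_patience) break
  }
  model$par <- best$par
  list(model = model, history = do.call(rbind, hist),
       stop_epoch = best$epoch)
}

#' Predict a binary mask
#'
#' Runs the forward pass and thresholds the probability map at
#' `cfg$threshold` (overridable).
#'
#' @param model a trained `unet_model`
#' @param x input matrix (one channel) or H x W x C array, spatial size
#'   `cfg$input_size`
#' @param threshold probability cut (default from the model config)
#' @param prob if TRUE, also return the probability map
#' @return binary mask, or list(mask, prob) when `prob = TRUE`
#' @export
predict_mask <- function(model, x, threshold = model$cfg$threshold,
                         prob = FALSE) {
  sz <- if (is.matrix(x)) dim(x) else dim(x)[1:2]
  if (any(sz != model$cfg$input_size))
    stop("input spatial size does not match model input_size")
  pm <- unet_forward(model, x)$prob
  mask <- as_binary_mask(pm >= threshold)
  if (prob) list(mask = mask, prob = pm) else mask
}

# Assemble a normalised network input from islet channels.
#' Stack islet channels into a network input
#'
#' @param channels named list of channel matrices with values in 0..255
#' @param use channel names to stack, in order
#' @return H x W x length(use) array scaled to [0, 1]
#' @export
unet_input <- function(channels, use = c("insulin", "laminin", "nuclei")) {
  mats <- lapply(use, function(nm) unclass(channels[[nm]]) / 255)
  array(unlist(mats), c(dim(mats[[1]]), length(mats)))
}
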