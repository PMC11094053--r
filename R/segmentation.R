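# Compact encoder-decoder segmentation network and the two-step
# frozen/unfrozen transfer-learning schedule.
#
# The network is a 2-level U-Net: two 3x3 convolution blocks, a 2x2
# mean-pool, two bottleneck convolutions at half resolution, nearest
# upsampling, a skip concatenation, one fusion convolution and a 1x1
# classification head over 3 classes (background, cavity, myocardium).
# The head is the designated "final parameter group": during the frozen
# training phase only the head is trainable. Training minimizes a soft
# (generalized) Dice loss with Adam under a one-cycle learning-rate policy
# capped at the schedule's maximum learning rate.

# ---- tensor primitives (H x W x C arrays, single image) ----

im2col3 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  xp <- array(0, c(H + 2, W + 2, C))
  xp[2:(H + 1), 2:(W + 1), ] <- x
  out <- matrix(0, H * W, 9 * C)
  k <- 0
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1
    out[, ((k - 1) * C + 1):(k * C)] <-
      matrix(xp[di + seq_len(H), dj + seq_len(W), , drop = FALSE], H * W, C)
  }
  out
}

col2im3 <- function(dcols, H, W, C) {
  dxp <- array(0, c(H + 2, W + 2, C))
  k <- 0
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1
    blk <- array(dcols[, ((k - 1) * C + 1):(k * C)], c(H, W, C))
    dxp[di + seq_len(H), dj + seq_len(W), ] <-
      dxp[di + seq_len(H), dj + seq_len(W), , drop = FALSE] + blk
  }
  dxp[2:(H + 1), 2:(W + 1), , drop = FALSE]
}

conv3_fwd <- function(x, w, b) {
  H <- dim(x)[1]; W <- dim(x)[2]
  cols <- im2col3(x)
  y <- cols %*% w
  y <- sweep(y, 2, b, "+")
  list(y = array(y, c(H, W, length(b))), cols = cols)
}

conv3_bwd <- function(dy, cache, w, Cin) {
  H <- dim(dy)[1]; W <- dim(dy)[2]; Cout <- dim(dy)[3]
  dym <- matrix(dy, H * W, Cout)
  list(dw = crossprod(cache$cols, dym),
       db = colSums(dym),
       dx = col2im3(dym %*% t(w), H, W, Cin))
}

relu_fwd <- function(x) { x[x < 0] <- 0; x }
relu_bwd <- function(dy, y) { dy[y <= 0] <- 0; dy }

meanpool2 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]
  0.25 * (x[seq(1, H, 2), seq(1, W, 2), , drop = FALSE] +
          x[seq(2, H, 2), seq(1, W, 2), , drop = FALSE] +
          x[seq(1, H, 2), seq(2, W, 2), , drop = FALSE] +
          x[seq(2, H, 2), seq(2, W, 2), , drop = FALSE])
}

upsample2 <- function(x) {
  h <- dim(x)[1]; w <- dim(x)[2]
  x[rep(seq_len(h), each = 2), rep(seq_len(w), each = 2), , drop = FALSE]
}

meanpool2_bwd <- function(dy) 0.25 * upsample2(dy)
upsample2_bwd <- function(dy) 4 * meanpool2(dy)

# ---- model ----

#' Initialize a compact U-Net segmentation model
#'
#' @param input_size Side length of the model's input grid; must be even.
#' @param base_filters Number of filters in the first level.
#' @param n_classes Number of output classes (default 3: background,
#'   cavity, myocardium).
#' @param seed Integer seed for He-scaled weight initialization.
#' @return A `unet_model` list holding parameters in two groups: `body`
#'   (encoder/decoder convolutions) and `head` (the final 1x1 parameter
#'   group).
#' @export
unet_init <- function(input_size = 32, base_filters = 8, n_classes = 3,
                      seed = 1L) {
  if (input_size %% 2 != 0) stop("`input_size` must be even", call. = FALSE)
  C <- base_filters
  he <- function(fan_in, nr, nc) matrix(stats::rnorm(nr * nc,
                                                     sd = sqrt(2 / fan_in)),
                                        nr, nc)
  params <- with_seed(seed, list(
    w1 = he(9 * 1, 9 * 1, C),        b1 = numeric(C),
    w2 = he(9 * C, 9 * C, C),        b2 = numeric(C),
    w3 = he(9 * C, 9 * C, 2 * C),    b3 = numeric(2 * C),
    w4 = he(9 * 2 * C, 9 * 2 * C, 2 * C), b4 = numeric(2 * C),
    w5 = he(9 * 3 * C, 9 * 3 * C, C), b5 = numeric(C),
    wh = he(C, C, n_classes),        bh = numeric(n_classes)
  ))
  structure(list(params = params, input_size = as.integer(input_size),
                 base_filters = as.integer(C),
                 n_classes = as.integer(n_classes),
                 body_names = c("w1", "b1", "w2", "b2", "w3", "b3",
                                "w4", "b4", "w5", "b5"),
                 head_names = c("wh", "bh")),
            class = "unet_model")
}

unet_forward <- function(model, img, keep_cache = FALSE) {
  p <- model$params
  C <- model$base_filters
  x <- array(img, c(dim(img), 1))
  c1 <- conv3_fwd(x, p$w1, p$b1);  a1 <- relu_fwd(c1$y)
  c2 <- conv3_fwd(a1, p$w2, p$b2); a2 <- relu_fwd(c2$y)
  pl <- meanpool2(a2)
  c3 <- conv3_fwd(pl, p$w3, p$b3); a3 <- relu_fwd(c3$y)
  c4 <- conv3_fwd(a3, p$w4, p$b4); a4 <- relu_fwd(c4$y)
  up <- upsample2(a4)
  ct <- array(c(a2, up), c(dim(a2)[1], dim(a2)[2], 3 * C))
  c5 <- conv3_fwd(ct, p$w5, p$b5); a5 <- relu_fwd(c5$y)
  H <- dim(a5)[1]; W <- dim(a5)[2]
  logits <- sweep(matrix(a5, H * W, C) %*% p$wh, 2, p$bh, "+")
  mx <- apply(logits, 1, max)
  e <- exp(logits - mx)
  probs <- e / rowSums(e)
  out <- list(probs = probs, H = H, W = W)
  if (keep_cache)
    out$cache <- list(c1 = c1, a1 = a1, c2 = c2, a2 = a2, c3 = c3, a3 = a3,
                      c4 = c4, a4 = a4, ct = ct, c5 = c5, a5 = a5)
  out
}

# Soft (generalized) Dice loss over classes; returns loss and d(loss)/d(probs).
soft_dice_loss <- function(probs, onehot, eps = 1e-6) {
  K <- ncol(probs)
  num <- den <- numeric(K)
  for (k in seq_len(K)) {
    num[k] <- 2 * sum(probs[, k] * onehot[, k]) + eps
    den[k] <- sum(probs[, k]) + sum(onehot[, k]) + eps
  }
  loss <- 1 - mean(num / den)
  dprobs <- matrix(0, nrow(probs), K)
  for (k in seq_len(K))
    dprobs[, k] <- -(2 * onehot[, k] * den[k] - num[k]) / den[k]^2 / K
  list(loss = loss, dprobs = dprobs)
}

unet_backward <- function(model, fwd, dprobs) {
  p <- model$params
  C <- model$base_filters
  probs <- fwd$probs
  # softmax backward
  dl <- probs * (dprobs - rowSums(dprobs * probs))
  cc <- fwd$cache
  H <- fwd$H; W <- fwd$W
  a5m <- matrix(cc$a5, H * W, C)
  g <- list()
  g$wh <- crossprod(a5m, dl)
  g$bh <- colSums(dl)
  da5 <- array(dl %*% t(p$wh), c(H, W, C))
  da5 <- relu_bwd(da5, cc$a5)
  b5 <- conv3_bwd(da5, cc$c5, p$w5, 3 * C)
  g$w5 <- b5$dw; g$b5 <- b5$db
  da2_skip <- b5$dx[, , seq_len(C), drop = FALSE]
  dup <- b5$dx[, , C + seq_len(2 * C), drop = FALSE]
  da4 <- relu_bwd(upsample2_bwd(dup), cc$a4)
  b4 <- conv3_bwd(da4, cc$c4, p$w4, 2 * C)
  g$w4 <- b4$dw; g$b4 <- b4$db
  da3 <- relu_bwd(b4$dx, cc$a3)
  b3 <- conv3_bwd(da3, cc$c3, p$w3, C)
  g$w3 <- b3$dw; g$b3 <- b3$db
  dpl <- b3$dx
  da2 <- relu_bwd(meanpool2_bwd(dpl) + da2_skip, cc$a2)
  b2 <- conv3_bwd(da2, cc$c2, p$w2, C)
  g$w2 <- b2$dw; g$b2 <- b2$db
  da1 <- relu_bwd(b2$dx, cc$a1)
  b1 <- conv3_bwd(da1, cc$c1, p$w1, 1)
  g$w1 <- b1$dw; g$b1 <- b1$db
  g
}

# ---- preprocessing & augmentation ----

#' Scale an image to the model input grid and normalize intensities
#'
#' Images are resized with bilinear interpolation and standardized to zero
#' mean and unit variance (per image). Companion masks should be resized
#' with [resize_mask()], which uses nearest-neighbor interpolation and
#' therefore preserves the label set.
#'
#' @param image 2D numeric matrix with finite intensities.
#' @param size Target side length (default 256).
#' @return `size` x `size` matrix.
#' @export
preprocess <- function(image, size = 256) {
  if (length(dim(image)) != 2L || any(dim(image) == 0))
    stop("`image` must be a non-empty 2D matrix", call. = FALSE)
  if (!all(is.finite(image)))
    stop("`image` must have finite intensities", call. = FALSE)
  out <- if (all(dim(image) == size)) image else
    EBImage::resize(image, w = size, h = size, filter = "bilinear")
  s <- stats::sd(out)
  if (s > 0) (out - mean(out)) / s else out - mean(out)
}

#' Resize a label mask with nearest-neighbor interpolation
#'
#' @param mask 2D integer matrix of labels.
#' @param size Target side length.
#' @return Integer matrix whose label set is a subset of the input's.
#' @export
resize_mask <- function(mask, size) {
  if (all(dim(mask) == size)) return(mask)
  out <- EBImage::resize(mask, w = size, h = size, filter = "none")
  storage.mode(out) <- "integer"
  out
}

#' Augmentation policy
#'
#' Mirrors a standard cine-segmentation augmentation recipe: left-right
#' flip, rotation up to 90 degrees, lighting change of 0.4 and zoom up
#' to 1.2. Geometric transforms are applied jointly to image and mask
#' (mask with nearest-neighbor sampling); lighting affects the image only.
#'
#' @param flip_lr Enable random left-right flips.
#' @param rotation_deg Maximum absolute rotation in degrees.
#' @param lighting Maximum relative brightness/contrast change.
#' @param zoom Maximum zoom factor (> 0; values > 1 magnify).
#' @param seed Optional integer seed used by [augment()] when given.
#' @return An `augment_policy` list.
#' @export
augment_policy <- function(flip_lr = TRUE, rotation_deg = 90, lighting = 0.4,
                           zoom = 1.2, seed = NULL) {
  if (zoom <= 0) stop("`zoom` must be > 0", call. = FALSE)
  structure(list(flip_lr = isTRUE(flip_lr), rotation_deg = rotation_deg,
                 lighting = lighting, zoom = zoom, seed = seed),
            class = "augment_policy")
}

# Rotate about the image center by `angle` degrees and magnify by `zoom`,
# sampling the input at back-mapped coordinates. filter: "bilinear" or
# "nearest". Out-of-bounds samples take the `fill` value.
warp_rotate_zoom <- function(img, angle, zoom = 1, filter = "bilinear",
                             fill = 0) {
  H <- nrow(img); W <- ncol(img)
  if (angle == 0 && zoom == 1) return(img)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  th <- -angle * pi / 180
  r <- matrix(rep(seq_len(H), times = W), H, W) - cy
  cl <- matrix(rep(seq_len(W), each = H), H, W) - cx
  sr <- (cos(th) * r - sin(th) * cl) / zoom + cy
  sc <- (sin(th) * r + cos(th) * cl) / zoom + cx
  out <- matrix(fill, H, W)
  if (filter == "nearest") {
    ri <- round(sr); ci <- round(sc)
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    out[ok] <- img[cbind(ri[ok], ci[ok])]
  } else {
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    ok <- r0 >= 1 & r0 + 1 <= H & c0 >= 1 & c0 + 1 <= W
    idx <- function(dr, dc) img[cbind(r0[ok] + dr, c0[ok] + dc)]
    out[ok] <- idx(0, 0) * (1 - fr[ok]) * (1 - fc[ok]) +
      idx(1, 0) * fr[ok] * (1 - fc[ok]) +
      idx(0, 1) * (1 - fr[ok]) * fc[ok] +
      idx(1, 1) * fr[ok] * fc[ok]
  }
  out
}

#' Apply a random augmentation to an image/mask pair
#'
#' Draws a flip, a rotation angle in `[-rotation_deg, rotation_deg]`, a
#' zoom factor in `[1, zoom]` and lighting factors, then applies the
#' geometric transforms identically to image and mask and the photometric
#' transform to the image only. With the same inputs and seed the output
#' is identical.
#'
#' @param image 2D numeric matrix.
#' @param mask 2D integer label matrix of the same shape.
#' @param policy An [augment_policy()].
#' @param seed Optional integer seed; falls back to `policy$seed`, else the
#'   current RNG stream.
#' @return List with transformed `image` and `mask`.
#' @export
augment <- function(image, mask, policy = augment_policy(), seed = NULL) {
  if (!all(dim(image) == dim(mask)))
    stop("image and mask must have the same shape", call. = FALSE)
  if (is.null(seed)) seed <- policy$seed
  go <- function() {
    flip <- policy$flip_lr && stats::runif(1) < 0.5
    ang <- stats::runif(1, -policy$rotation_deg, policy$rotation_deg)
    zm <- stats::runif(1, 1, max(1, policy$zoom))
    bright <- stats::runif(1, -policy$lighting, policy$lighting)
    contr <- 1 + stats::runif(1, -policy$lighting, policy$lighting)
    img <- image; msk <- mask
    if (flip) { img <- img[, rev(seq_len(ncol(img)))]
                msk <- msk[, rev(seq_len(ncol(msk)))] }
    img <- warp_rotate_zoom(img, ang, zm, "bilinear", fill = min(image))
    msk <- warp_rotate_zoom(msk, ang, zm, "nearest", fill = 0L)
    m <- mean(img)
    img <- (img - m) * contr + m + bright * stats::sd(image)
    storage.mode(msk) <- "integer"
    list(image = img, mask = msk)
  }
  if (is.null(seed)) go() else with_seed(seed, go())
}

# ---- prediction & validation metric ----

#' Predict a 3-class label mask for one image
#'
#' The image is preprocessed to the model grid, classified by per-pixel
#' argmax over the class probabilities, and the mask is resized back to
#' the source geometry with nearest-neighbor interpolation. The result may
#' be entirely background, in which case downstream agreement code treats
#' the label as missing.
#'
#' @param model A `unet_model`.
#' @param image 2D numeric matrix.
#' @return Integer matrix of labels in `{0, 1, 2}` with `dim(image)`.
#' @export
predict_mask <- function(model, image) {
  z <- preprocess(image, model$input_size)
  fwd <- unet_forward(model, z)
  lab <- max.col(fwd$probs, ties.method = "first") - 1L
  m <- matrix(as.integer(lab), fwd$H, fwd$W)
  if (all(dim(image) == model$input_size)) return(m)
  out <- EBImage::resize(m, w = nrow(image), h = ncol(image), filter = "none")
  storage.mode(out) <- "integer"
  out
}

# Mean foreground Dice over a validation set: per image, Dice of classes 1
# and 2 (pairs where both reference and prediction of a class are empty are
# dropped); images with no defined class are excluded.
validation_dice <- function(model, val_set) {
  per_img <- vapply(val_set, function(ex) {
    pred <- predict_mask(model, ex$image)
    ref <- ex$mask
    ds <- c(dice_score(pred == 1L, ref == 1L),
            dice_score(pred == 2L, ref == 2L))
    if (all(is.na(ds))) NA_real_ else mean(ds, na.rm = TRUE)
  }, numeric(1))
  if (all(is.na(per_img))) NA_real_ else mean(per_img, na.rm = TRUE)
}

# ---- training ----

#' Training schedule for two-step transfer learning
#'
#' The reference schedule trains 100 epochs with all but the final
#' parameter group frozen at a maximum learning rate of 1e-4, then 100
#' epochs with all parameters trainable at 1e-5, saving a checkpoint every
#' 10 epochs; the checkpoint with the highest validation Dice is selected.
#'
#' @param frozen_epochs,unfrozen_epochs Epochs per phase.
#' @param frozen_max_lr,unfrozen_max_lr Maximum (one-cycle) learning rates.
#' @param checkpoint_every Checkpoint interval in epochs; must divide both
#'   phase lengths evenly.
#' @param batch_size Mini-batch size.
#' @return A `train_schedule` list.
#' @export
train_schedule <- function(frozen_epochs = 100, frozen_max_lr = 1e-4,
                           unfrozen_epochs = 100, unfrozen_max_lr = 1e-5,
                           checkpoint_every = 10, batch_size = 4) {
  if (frozen_max_lr <= 0 || unfrozen_max_lr <= 0)
    stop("learning rates must be positive", call. = FALSE)
  if (frozen_epochs %% checkpoint_every != 0 ||
      unfrozen_epochs %% checkpoint_every != 0)
    stop("`checkpoint_every` must divide both phase lengths evenly",
         call. = FALSE)
  structure(list(frozen_epochs = as.integer(frozen_epochs),
                 frozen_max_lr = frozen_max_lr,
                 unfrozen_epochs = as.integer(unfrozen_epochs),
                 unfrozen_max_lr = unfrozen_max_lr,
                 checkpoint_every = as.integer(checkpoint_every),
                 batch_size = as.integer(batch_size)),
            class = "train_schedule")
}

# One-cycle learning rate: linear warmup from max_lr/10 over the first 30%
# of iterations, then cosine annealing down to max_lr/100. The cap is the
# schedule's maximum learning rate.
one_cycle_lr <- function(it, total, max_lr) {
  pct <- it / max(1, total)
  if (pct <= 0.3) {
    max_lr * (0.1 + 0.9 * pct / 0.3)
  } else {
    q <- (pct - 0.3) / 0.7
    max_lr * (0.01 + 0.99 * (1 + cos(pi * q)) / 2)
  }
}

train_phase <- function(model, train_set, val_set, epochs, max_lr,
                        checkpoint_every, batch_size, trainable, phase_name,
                        policy = NULL) {
  p <- model$params
  mstate <- lapply(p, function(x) x * 0)
  vstate <- lapply(p, function(x) x * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  K <- model$n_classes
  n <- length(train_set)
  iters_per_epoch <- ceiling(n / batch_size)
  total_iters <- epochs * iters_per_epoch
  it <- 0L; step <- 0L
  checkpoints <- list()
  onehot_of <- function(mask) {
    v <- as.integer(mask)
    oh <- matrix(0, length(v), K)
    oh[cbind(seq_along(v), v + 1L)] <- 1
    oh
  }
  for (ep in seq_len(epochs)) {
    ord <- sample(n)
    for (bstart in seq(1, n, by = batch_size)) {
      it <- it + 1L
      idx <- ord[bstart:min(bstart + batch_size - 1, n)]
      grads <- NULL
      for (i in idx) {
        ex <- train_set[[i]]
        img <- ex$image; msk <- ex$mask
        if (!is.null(policy)) {
          aug <- augment(img, msk, policy)
          img <- aug$image; msk <- aug$mask
        }
        img <- preprocess(img, model$input_size)
        msk <- resize_mask(msk, model$input_size)
        fwd <- unet_forward(model, img, keep_cache = TRUE)
        ld <- soft_dice_loss(fwd$probs, onehot_of(msk))
        g <- unet_backward(model, fwd, ld$dprobs)
        grads <- if (is.null(grads)) g else Map(`+`, grads, g)
      }
      lr <- one_cycle_lr(it, total_iters, max_lr)
      step <- step + 1L
      for (nm in trainable) {
        gr <- grads[[nm]] / length(idx)
        mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * gr
        vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * gr^2
        mhat <- mstate[[nm]] / (1 - beta1^step)
        vhat <- vstate[[nm]] / (1 - beta2^step)
        model$params[[nm]] <- model$params[[nm]] -
          lr * mhat / (sqrt(vhat) + eps)
      }
    }
    if (ep %% checkpoint_every == 0) {
      vd <- validation_dice(model, val_set)
      checkpoints[[length(checkpoints) + 1L]] <- list(
        phase = phase_name, epoch = ep, validation_dice = vd,
        weights = model$params)
    }
  }
  list(model = model, checkpoints = checkpoints)
}

#' Two-step transfer-learning training
#'
#' Phase 1 trains with all parameters outside the final parameter group
#' (the classification head) frozen, for `frozen_epochs` at
#' `frozen_max_lr`, saving a checkpoint with its validation Dice every
#' `checkpoint_every` epochs. The frozen-phase checkpoint with the highest
#' validation Dice seeds phase 2, which trains all parameters for
#' `unfrozen_epochs` at `unfrozen_max_lr` with the same checkpointing.
#' The returned model is the checkpoint with the overall highest
#' validation Dice (ties broken by the earlier checkpoint).
#'
#' @param model A `unet_model` (e.g., pretrained on a source distribution).
#' @param train_set,val_set Lists of `list(image =, mask =)` pairs;
#'   empty-mask images participate in the loss exactly as labeled.
#' @param schedule A [train_schedule()].
#' @param policy Optional [augment_policy()] applied to training images.
#' @param seed Integer seed for shuffling and augmentation draws.
#' @return List with `best_model` (a `unet_model`), `checkpoints` (a data
#'   frame with phase, epoch, validation_dice and a selection flag) and
#'   `checkpoint_weights`.
#' @export
train_transfer <- function(model, train_set, val_set, schedule,
                           policy = NULL, seed = 1L) {
  stopifnot(inherits(model, "unet_model"), inherits(schedule, "train_schedule"))
  if (length(train_set) == 0 || length(val_set) == 0)
    stop("train and validation sets must be non-empty", call. = FALSE)
  with_seed(seed, {
    ph1 <- train_phase(model, train_set, val_set,
                       schedule$frozen_epochs, schedule$frozen_max_lr,
                       schedule$checkpoint_every, schedule$batch_size,
                       trainable = model$head_names, phase_name = "frozen",
                       policy = policy)
    vd1 <- vapply(ph1$checkpoints, `[[`, numeric(1), "validation_dice")
    best1 <- which.max(vd1)
    seed_model <- model
    seed_model$params <- ph1$checkpoints[[best1]]$weights
    ph2 <- train_phase(seed_model, train_set, val_set,
                       schedule$unfrozen_epochs, schedule$unfrozen_max_lr,
                       schedule$checkpoint_every, schedule$batch_size,
                       trainable = c(model$body_names, model$head_names),
                       phase_name = "unfrozen", policy = policy)
    cks <- c(ph1$checkpoints, ph2$checkpoints)
    vd <- vapply(cks, `[[`, numeric(1), "validation_dice")
    best <- which.max(vd)
    best_model <- model
    best_model$params <- cks[[best]]$weights
    records <- data.frame(
      phase = vapply(cks, `[[`, character(1), "phase"),
      epoch = vapply(cks, `[[`, integer(1), "epoch"),
      validation_dice = vd,
      selected = seq_along(cks) == best)
    list(best_model = best_model, checkpoints = records,
         checkpoint_weights = lapply(cks, `[[`, "weights"))
  })
}

#' Pretrain a model on a source distribution
#'
#' Plain single-phase training of all parameters, used to emulate the
#' pretrained starting point that transfer learning fine-tunes: the model
#' is first fitted to one phantom distribution, then [train_transfer()]
#' adapts it to a shifted target distribution.
#'
#' @param model A `unet_model`.
#' @param train_set List of `list(image =, mask =)` pairs.
#' @param epochs Number of epochs.
#' @param max_lr Maximum one-cycle learning rate.
#' @param batch_size Mini-batch size.
#' @param seed Integer seed.
#' @return The pretrained `unet_model`.
#' @export
pretrain_model <- function(model, train_set, epochs = 4, max_lr = 5e-3,
                           batch_size = 4, seed = 1L) {
  if (length(train_set) == 0) stop("empty training set", call. = FALSE)
  with_seed(seed, {
    ph <- train_phase(model, train_set, val_set = train_set[1],
                      epochs = epochs, max_lr = max_lr,
                      checkpoint_every = epochs + 1L,
                      batch_size = batch_size,
                      trainable = c(model$body_names, model$head_names),
                      phase_name = "pretrain", policy = NULL)
    ph$model
  })
}

#' Save a training run's checkpoint manifest and log
#'
#' Writes a JSON manifest (phase, epoch, validation Dice, selection flag)
#' and a CSV training log to a run directory.
#'
#' @param run Result of [train_transfer()].
#' @param dir Run directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
save_run_manifest <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- file.path(dir, "manifest.json")
  log_csv <- file.path(dir, "training_log.csv")
  jsonlite::write_json(run$checkpoints, manifest, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(run$checkpoints, log_csv, row.names = FALSE)
  invisible(c(manifest = manifest, log = log_csv))
}
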