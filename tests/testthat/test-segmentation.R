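# Network primitives (against brute-force oracles and finite differences),
# preprocessing, augmentation and the two-step transfer schedule contract.

test_that("3x3 convolution matches a brute-force sliding window", {
  set.seed(1)
  H <- 6; W <- 5; Cin <- 2; Cout <- 3
  x <- array(rnorm(H * W * Cin), c(H, W, Cin))
  w <- matrix(rnorm(9 * Cin * Cout), 9 * Cin, Cout)
  b <- rnorm(Cout)
  y <- conv3_fwd(x, w, b)$y
  # brute force: zero padding, kernel tap order (dj, di) as in im2col3
  xp <- array(0, c(H + 2, W + 2, Cin))
  xp[2:(H + 1), 2:(W + 1), ] <- x
  for (i in sample(H, 3)) for (j in sample(W, 3)) for (co in seq_len(Cout)) {
    acc <- b[co]; k <- 0
    for (dj in 0:2) for (di in 0:2) {
      k <- k + 1
      for (ci in seq_len(Cin))
        acc <- acc + xp[i + di, j + dj, ci] * w[(k - 1) * Cin + ci, co]
    }
    expect_equal(y[i, j, co], acc, tolerance = 1e-12)
  }
})

test_that("pooling and upsampling are exact adjoints (scaled)", {
  set.seed(2)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  y <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  # <meanpool(x), y> == <x, meanpool_bwd(y)>
  expect_equal(sum(meanpool2(x) * y), sum(x * meanpool2_bwd(y)),
               tolerance = 1e-12)
  # <upsample(y), x> == <y, upsample_bwd(x)>
  expect_equal(sum(upsample2(y) * x), sum(y * upsample2_bwd(x)),
               tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  model <- unet_init(input_size = 6, base_filters = 2, seed = 3)
  set.seed(4)
  img <- matrix(rnorm(36), 6, 6)
  mask <- matrix(sample(0:2, 36, replace = TRUE), 6, 6)
  onehot <- matrix(0, 36, 3)
  onehot[cbind(seq_len(36), as.integer(mask) + 1L)] <- 1

  loss_of <- function(m) {
    fwd <- unet_forward(m, img)
    soft_dice_loss(fwd$probs, onehot)$loss
  }
  fwd <- unet_forward(model, img, keep_cache = TRUE)
  ld <- soft_dice_loss(fwd$probs, onehot)
  g <- unet_backward(model, fwd, ld$dprobs)

  h <- 1e-6
  for (nm in c("w1", "w3", "w5", "wh", "b2", "bh")) {
    idx <- sample(length(model$params[[nm]]),
                  min(3, length(model$params[[nm]])))
    for (i in idx) {
      mp <- model; mp$params[[nm]][i] <- mp$params[[nm]][i] + h
      mm <- model; mm$params[[nm]][i] <- mm$params[[nm]][i] - h
      num <- (loss_of(mp) - loss_of(mm)) / (2 * h)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("softmax probabilities are a proper distribution", {
  model <- unet_init(input_size = 8, base_filters = 2, seed = 5)
  fwd <- unet_forward(model, matrix(rnorm(64), 8, 8))
  expect_equal(rowSums(fwd$probs), rep(1, 64), tolerance = 1e-12)
  expect_true(all(fwd$probs >= 0))
})

test_that("one-cycle learning rate warms up, peaks at the cap, anneals", {
  total <- 1000
  lr <- vapply(0:total, one_cycle_lr, numeric(1), total = total,
               max_lr = 1e-3)
  expect_equal(lr[1], 1e-4)                      # max_lr / 10 at start
  expect_equal(max(lr), 1e-3, tolerance = 1e-9)  # capped at max_lr
  expect_equal(which.max(lr) - 1, 0.3 * total)   # peak at 30%
  expect_equal(lr[total + 1], 1e-5, tolerance = 1e-9)  # max_lr / 100 at end
  expect_true(all(diff(lr[1:(0.3 * total)]) > 0))      # monotone warmup
  expect_true(all(diff(lr[(0.3 * total + 1):(total + 1)]) < 0))
})

test_that("preprocess standardizes and validates", {
  img <- matrix(runif(100, 1, 5), 10, 10)
  z <- preprocess(img, 16)
  expect_equal(dim(z), c(16, 16))
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(stats::sd(z), 1, tolerance = 1e-10)
  expect_error(preprocess(matrix(c(1, NA, 3, 4), 2, 2), 4), "finite")
  expect_error(preprocess(array(1, c(2, 2, 2)), 4), "2D")
  # constant image: centered, not divided by zero
  expect_true(all(is.finite(preprocess(matrix(2, 8, 8), 8))))
})

test_that("mask resizing preserves the label set", {
  m <- make_phantom_mask(r_endo = 10, wall = 5, size = 36)
  small <- resize_mask(m, 18)
  expect_equal(dim(small), c(18, 18))
  expect_true(all(small %in% unique(as.vector(m))))
  expect_identical(resize_mask(m, 36), m)
})

test_that("augmentation is label-preserving, joint and seed-deterministic", {
  m <- make_phantom_mask(r_endo = 9, wall = 4, size = 32)
  img <- matrix(runif(32 * 32), 32, 32)
  pol <- augment_policy()
  a1 <- augment(img, m, pol, seed = 42)
  a2 <- augment(img, m, pol, seed = 42)
  expect_identical(a1$image, a2$image)
  expect_identical(a1$mask, a2$mask)
  expect_true(all(a1$mask %in% 0:2))

  # pure flip (no rotation/zoom/lighting) either mirrors the image or
  # leaves it alone; the rotationally symmetric mask is unchanged either way
  pol0 <- augment_policy(flip_lr = TRUE, rotation_deg = 0, lighting = 0,
                         zoom = 1)
  for (sd in 1:6) {
    a <- augment(img, m, pol0, seed = sd)
    expect_true(isTRUE(all.equal(a$image, img)) ||
                  isTRUE(all.equal(a$image, img[, rev(seq_len(32))])))
    expect_identical(a$mask, m)   # symmetric mask: flip is the identity
  }

  # geometric transform is identical for image and mask: a mask used as
  # its own image stays aligned under rotation
  pol_rot <- augment_policy(flip_lr = FALSE, rotation_deg = 90,
                            lighting = 0, zoom = 1)
  a <- augment(matrix(as.numeric(m == 1L), 32, 32), m, pol_rot, seed = 3)
  interior <- a$image > 0.999  # bilinear-safe interior of the warped cavity
  expect_true(all(a$mask[interior] == 1L))

  expect_error(augment(img, m[1:16, 1:16], pol), "same shape")
  expect_error(augment_policy(zoom = 0), "zoom")
})

test_that("train_schedule validates checkpoint divisibility", {
  s <- train_schedule()
  expect_equal(s$frozen_epochs, 100L)
  expect_equal(s$frozen_max_lr, 1e-4)
  expect_equal(s$unfrozen_epochs, 100L)
  expect_equal(s$unfrozen_max_lr, 1e-5)
  expect_equal(s$checkpoint_every, 10L)
  expect_error(train_schedule(frozen_epochs = 7, checkpoint_every = 2),
               "divide")
  expect_error(train_schedule(frozen_max_lr = 0), "positive")
})

test_that("frozen phase trains only the final parameter group", {
  frames <- make_frame_set(4, seed = 21, image_size = 16)
  model <- unet_init(input_size = 16, base_filters = 4, seed = 1)
  sched <- train_schedule(frozen_epochs = 2, frozen_max_lr = 1e-3,
                          unfrozen_epochs = 2, unfrozen_max_lr = 1e-4,
                          checkpoint_every = 1, batch_size = 2)
  run <- train_transfer(model, frames[1:3], frames[4], sched, seed = 5)

  expect_equal(nrow(run$checkpoints), 4L)
  expect_equal(run$checkpoints$phase, rep(c("frozen", "unfrozen"), each = 2))
  expect_equal(run$checkpoints$epoch, c(1L, 2L, 1L, 2L))

  # frozen-phase checkpoints: body weights bit-identical to the input model
  for (i in 1:2) {
    wk <- run$checkpoint_weights[[i]]
    for (nm in model$body_names)
      expect_identical(wk[[nm]], model$params[[nm]])
    expect_false(identical(wk$wh, model$params$wh))
  }
  # the selected checkpoint is the validation-Dice maximum and the best
  # model carries exactly its weights
  best <- which(run$checkpoints$selected)
  expect_length(best, 1L)
  expect_equal(run$checkpoints$validation_dice[best],
               max(run$checkpoints$validation_dice))
  expect_identical(run$best_model$params, run$checkpoint_weights[[best]])
})

test_that("training is deterministic given the seed", {
  frames <- make_frame_set(3, seed = 22, image_size = 16)
  model <- unet_init(input_size = 16, base_filters = 4, seed = 2)
  sched <- train_schedule(frozen_epochs = 1, frozen_max_lr = 1e-3,
                          unfrozen_epochs = 1, unfrozen_max_lr = 1e-4,
                          checkpoint_every = 1, batch_size = 2)
  r1 <- train_transfer(model, frames[1:2], frames[3], sched, seed = 9)
  r2 <- train_transfer(model, frames[1:2], frames[3], sched, seed = 9)
  expect_identical(r1$best_model$params, r2$best_model$params)
  expect_identical(r1$checkpoints, r2$checkpoints)
})

test_that("predict_mask returns labels on the source grid", {
  frames <- make_frame_set(1, seed = 23, image_size = 24)
  model <- unet_init(input_size = 16, base_filters = 4, seed = 3)
  pm <- predict_mask(model, frames[[1]]$image)
  expect_equal(dim(pm), c(24, 24))
  expect_true(all(pm %in% 0:2))
  expect_identical(pm, predict_mask(model, frames[[1]]$image))
})

test_that("validation Dice follows the empty-class conventions", {
  m <- make_phantom_mask(r_endo = 4, wall = 2, size = 16)
  # model predicting everything background scores 0 against a labeled mask
  model <- unet_init(input_size = 16, base_filters = 2, seed = 4)
  model$params$bh <- c(100, 0, 0)   # force all-background argmax
  vs <- list(list(image = matrix(rnorm(256), 16, 16), mask = m))
  expect_equal(validation_dice(model, vs), 0)
  # an all-background reference with an all-background prediction has no
  # defined class and is excluded -> NA
  vs0 <- list(list(image = matrix(rnorm(256), 16, 16),
                   mask = matrix(0L, 16, 16)))
  expect_true(is.na(validation_dice(model, vs0)))
})

test_that("run manifest round-trips the checkpoint table", {
  frames <- make_frame_set(3, seed = 24, image_size = 16)
  model <- unet_init(input_size = 16, base_filters = 4, seed = 6)
  sched <- train_schedule(frozen_epochs = 1, frozen_max_lr = 1e-3,
                          unfrozen_epochs = 1, unfrozen_max_lr = 1e-4,
                          checkpoint_every = 1, batch_size = 2)
  run <- train_transfer(model, frames[1:2], frames[3], sched, seed = 7)
  d <- withr::local_tempdir()
  paths <- save_run_manifest(run, d)
  man <- jsonlite::read_json(paths["manifest"], simplifyVector = TRUE)
  expect_equal(man$epoch, run$checkpoints$epoch)
  expect_equal(man$validation_dice, run$checkpoints$validation_dice)
  log <- utils::read.csv(paths["log"])
  expect_equal(nrow(log), nrow(run$checkpoints))
})
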