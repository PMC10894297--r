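test_that("network construction obeys the shape and range contracts", {
  cfg <- net_config(depth = 3L, base_channels = 4L, input_channels = 6L,
                    patch_size = 64L, seed = 2L)
  model <- build_unet(cfg)
  set.seed(1)
  stack <- array(runif(64 * 64 * 6), dim = c(64, 64, 6))
  V <- predict_unet(model, stack)
  expect_equal(dim(V$values), c(64L, 64L))
  expect_true(all(V$values >= 0 & V$values <= 1))
  # same seed -> identical initial predictions; different seed -> different
  V2 <- predict_unet(build_unet(cfg), stack)
  expect_identical(V$values, V2$values)
  cfg3 <- net_config(depth = 3L, base_channels = 4L, input_channels = 6L,
                     patch_size = 64L, seed = 3L)
  expect_false(identical(V$values, predict_unet(build_unet(cfg3), stack)$values))
  expect_error(net_config(depth = 3L, patch_size = 30L), "divisible")
})

test_that("backpropagation matches numerical gradients", {
  ve <- asNamespace("vesselseg")
  cfg <- net_config(depth = 2L, base_channels = 4L, input_channels = 3L,
                    patch_size = 8L, seed = 3L)
  model <- build_unet(cfg)
  set.seed(42)
  X <- array(rnorm(8 * 8 * 3 * 2), dim = c(8, 8, 3, 2))
  G <- array(rbinom(8 * 8 * 2, 1, 0.3), dim = c(8, 8, 1, 2))
  Wm <- array(1, dim = c(8, 8, 1, 2))
  loss_of <- function(params) {
    fw <- ve$unet_forward(params, cfg, X)
    ve$seg_loss(fw$P, G, Wm, "bce_plus_dice")$loss
  }
  fw <- ve$unet_forward(model$params, cfg, X, training = TRUE)
  ls <- ve$seg_loss(fw$P, G, Wm, "bce_plus_dice")
  grads <- ve$unet_backward(model$params, cfg, ls$dz, fw$caches)
  eps <- 1e-5
  for (blk in c("enc1", "bott", "dec2", "out")) {
    nm <- names(grads[[blk]])[1]
    arr <- model$params[[blk]][[nm]]
    for (i in sample(length(arr), 2)) {
      p1 <- model$params; p1[[blk]][[nm]][i] <- arr[i] + eps
      p2 <- model$params; p2[[blk]][[nm]][i] <- arr[i] - eps
      num <- (loss_of(p1) - loss_of(p2)) / (2 * eps)
      ana <- grads[[blk]][[nm]][i]
      expect_equal(ana, num, tolerance = 1e-3)
    }
  }
})

test_that("zero-epoch training is a no-op with empty history", {
  cfg <- net_config(depth = 2L, base_channels = 4L, input_channels = 1L,
                    patch_size = 16L, epochs = 0L, seed = 4L)
  model <- build_unet(cfg)
  s <- make_phantom(seed = 2, height = 32, width = 32)
  stack <- array(s$image, dim = c(32, 32, 1))
  out <- train_unet(model, list(list(stack = stack, gt = s$gt_mask,
                                     fov = s$fov_mask)), cfg)
  expect_equal(nrow(out$history), 0L)
  expect_identical(out$params, model$params)
})

test_that("training rejects inconsistent samples", {
  cfg <- net_config(depth = 2L, base_channels = 4L, input_channels = 2L,
                    patch_size = 16L, epochs = 1L, seed = 4L)
  model <- build_unet(cfg)
  s <- make_phantom(seed = 2, height = 32, width = 32)
  one_ch <- array(s$image, dim = c(32, 32, 1))
  expect_error(train_unet(model, list(list(stack = one_ch, gt = s$gt_mask)), cfg),
               "channels")
  two_ch <- array(s$image, dim = c(32, 32, 2))
  expect_error(train_unet(model, list(list(stack = two_ch, gt = NULL)), cfg),
               "ground-truth")
  expect_error(train_unet(model, list(), cfg), "at least one")
})

test_that("the network overfits a single phantom to high Dice with finite loss", {
  s <- make_phantom(seed = 31, height = 96, width = 96)
  enh <- pipeline_config()$enhance
  fs <- compute_feature_stack(s$image, s$fov_mask, enh)
  cfg <- net_config(input_channels = 6L, patch_size = 48L, epochs = 30L,
                    patches_per_epoch = 64L, seed = 6L)
  model <- build_unet(cfg)
  trained <- train_unet(model, list(list(stack = fs, gt = s$gt_mask,
                                         fov = s$fov_mask)), cfg)
  expect_equal(nrow(trained$history), 30L)
  expect_true(all(is.finite(trained$history$loss)))
  expect_true(all(is.finite(trained$history$val_dice)))
  V <- predict_unet(trained, fs)
  B <- apply_threshold(V, 0.5) * s$fov_mask
  g <- s$gt_mask * s$fov_mask
  dice <- 2 * sum(B * g) / (sum(B) + sum(g))
  expect_gte(dice, 0.90)
})

test_that("tiled inference agrees with single-shot and masks the FOV", {
  cfg <- net_config(depth = 2L, base_channels = 4L, input_channels = 1L,
                    patch_size = 32L, seed = 9L)
  model <- build_unet(cfg)
  s <- make_phantom(seed = 12, height = 32, width = 32)
  stack <- array(s$image, dim = c(32, 32, 1))
  v_tiled <- predict_unet(model, stack, fov = s$fov_mask, tiled = TRUE)
  v_single <- predict_unet(model, stack, fov = s$fov_mask, tiled = FALSE)
  expect_equal(v_tiled$values, v_single$values, tolerance = 1e-5)
  expect_true(all(v_tiled$values[s$fov_mask == 0] == 0))
  # genuinely tiled path (image larger than patch) is deterministic and close
  s2 <- make_phantom(seed = 12, height = 48, width = 48)
  stack2 <- array(s2$image, dim = c(48, 48, 1))
  t1 <- predict_unet(model, stack2, fov = s2$fov_mask)
  t2 <- predict_unet(model, stack2, fov = s2$fov_mask)
  expect_identical(t1$values, t2$values)
  expect_error(predict_unet(model, array(0, dim = c(32, 32, 3))), "channels")
})

test_that("checkpoints round-trip weights, config, history and threshold", {
  tmp <- withr::local_tempdir()
  cfg <- net_config(depth = 2L, base_channels = 4L, input_channels = 1L,
                    patch_size = 16L, seed = 10L)
  model <- build_unet(cfg)
  model$threshold <- 0.65
  p <- file.path(tmp, "ck.rds")
  save_checkpoint(model, p)
  back <- load_checkpoint(p)
  expect_identical(back$params, model$params)
  expect_equal(back$threshold, 0.65)
  expect_equal(unclass(back$config), unclass(cfg))
  saveRDS(list(a = 1), p)
  expect_error(load_checkpoint(p), "checkpoint")
})

test_that("threshold calibration picks the Dice-optimal training cut", {
  # synthetic model-free check through a stub: probabilities equal to a
  # noisy version of the truth favour a mid threshold
  s <- make_phantom(seed = 14, height = 32, width = 32)
  cfg <- net_config(depth = 2L, base_channels = 4L, input_channels = 1L,
                    patch_size = 32L, epochs = 0L, seed = 3L)
  model <- build_unet(cfg)
  fake <- model
  # no training: calibration still returns a threshold from the grid
  stack <- array(s$image, dim = c(32, 32, 1))
  out <- calibrate_threshold(fake, list(list(stack = stack, gt = s$gt_mask,
                                             fov = s$fov_mask)))
  expect_true(out$threshold >= 0.2 && out$threshold <= 0.8)
})
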