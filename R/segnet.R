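#' Configuration of the segmentation network
#'
#' A compact encoder--decoder (U-Net) with residual double-convolution
#' blocks. Each encoder level halves the spatial resolution and doubles the
#' channel count; decoder levels mirror this with skip connections from the
#' matching encoder stage. Defaults are sized for CPU training on 128 x 128
#' phantoms.
#'
#' @param depth Number of encoder levels (pooling steps).
#' @param base_channels Channels of the first encoder block.
#' @param residual Use residual shortcuts inside each block (1 x 1 projection
#'   when channel counts differ).
#' @param input_channels Number of feature-stack channels C.
#' @param patch_size Training/inference tile size; must be divisible by
#'   `2^depth`.
#' @param batch_size Patches per optimizer step.
#' @param epochs Training epochs.
#' @param patches_per_epoch Random patches drawn per epoch.
#' @param learning_rate Adam learning rate.
#' @param loss One of `"bce"`, `"dice"`, `"bce_plus_dice"`.
#' @param seed Integer seed for weight initialisation and patch sampling.
#' @return A `vs_net_config` list.
#' @export
net_config <- function(depth = 3L, base_channels = 8L, residual = TRUE,
                       input_channels = 6L, patch_size = 64L,
                       batch_size = 8L, epochs = 20L,
                       patches_per_epoch = 96L,
                       learning_rate = 1e-3,
                       loss = c("bce_plus_dice", "bce", "dice"),
                       seed = 1L) {
  loss <- match.arg(loss)
  cfg <- list(depth = as.integer(depth), base_channels = as.integer(base_channels),
              residual = isTRUE(residual), input_channels = as.integer(input_channels),
              patch_size = as.integer(patch_size), batch_size = as.integer(batch_size),
              epochs = as.integer(epochs),
              patches_per_epoch = as.integer(patches_per_epoch),
              learning_rate = learning_rate, loss = loss, seed = as.integer(seed))
  if (cfg$patch_size %% 2L^cfg$depth != 0L) {
    stop_vs("patch_size (%d) must be divisible by 2^depth (%d)",
            cfg$patch_size, 2L^cfg$depth)
  }
  structure(cfg, class = "vs_net_config")
}

#' Build an untrained residual U-Net
#'
#' Weights are He-initialised from a private RNG stream derived from
#' `config$seed`, so two builds with the same seed produce identical initial
#' predictions.
#'
#' @param config A [net_config()].
#' @return A `vs_model`: list with `params`, `config`, `history`.
#' @export
build_unet <- function(config) {
  if (!inherits(config, "vs_net_config")) config <- do.call(net_config, config)
  d <- config$depth; f <- config$base_channels; C <- config$input_channels
  params <- with_local_rng(derive_seed(config$seed, "init"), {
    p <- list()
    cin <- C
    for (i in seq_len(d)) {
      cout <- f * 2L^(i - 1L)
      p[[paste0("enc", i)]] <- init_resblock(cin, cout, config$residual)
      cin <- cout
    }
    p$bott <- init_resblock(f * 2L^(d - 1L), f * 2L^d, config$residual)
    for (i in rev(seq_len(d))) {
      cin_i <- 3L * f * 2L^(i - 1L)
      p[[paste0("dec", i)]] <- init_resblock(cin_i, f * 2L^(i - 1L), config$residual)
    }
    p$out <- list(W = he_conv(1L, 1L, f, 1L), b = numeric(1L))
    p
  })
  structure(list(params = params, config = config, history = list()),
            class = "vs_model")
}

# Full network forward pass on X (H,W,C,B); H and W divisible by 2^depth.
unet_forward <- function(params, config, X, training = FALSE) {
  d <- config$depth
  enc_out <- vector("list", d)
  caches <- list(enc = vector("list", d), pool = vector("list", d),
                 dec = vector("list", d))
  x <- X
  for (i in seq_len(d)) {
    rb <- resblock_forward(x, params[[paste0("enc", i)]], config$residual, training)
    enc_out[[i]] <- rb$Y
    caches$enc[[i]] <- rb$cache
    mp <- maxpool_forward(rb$Y)
    caches$pool[[i]] <- list(win = mp$win, in_dim = dim(rb$Y))
    x <- mp$Y
  }
  rb <- resblock_forward(x, params$bott, config$residual, training)
  caches$bott <- rb$cache
  x <- rb$Y
  for (i in rev(seq_len(d))) {
    u <- upsample_forward(x)
    cat_in <- concat_channels(u, enc_out[[i]])
    rb <- resblock_forward(cat_in, params[[paste0("dec", i)]], config$residual, training)
    caches$dec[[i]] <- c(rb["cache"], list(n_up = dim(u)[3L]))
    x <- rb$Y
  }
  co <- conv_forward(x, params$out$W, params$out$b, keep_cols = training)
  caches$out <- list(X = x, Xcol = co$Xcol)
  P <- sigmoid(co$Y)
  list(P = P, z = co$Y, caches = if (training) caches else NULL)
}

# Backward pass from dz (gradient at the pre-sigmoid output).
unet_backward <- function(params, config, dz, caches) {
  d <- config$depth
  grads <- list()
  go <- conv_backward(dz, caches$out$X, caches$out$Xcol, params$out$W)
  grads$out <- list(W = go$dW, b = go$db)
  dx <- go$dX
  for (i in seq_len(d)) {
    bb <- resblock_backward(dx, params[[paste0("dec", i)]], config$residual,
                            caches$dec[[i]]$cache)
    grads[[paste0("dec", i)]] <- bb$grads
    n_up <- caches$dec[[i]]$n_up
    d_up <- bb$dX[, , seq_len(n_up), , drop = FALSE]
    d_skip <- bb$dX[, , n_up + seq_len(dim(bb$dX)[3L] - n_up), , drop = FALSE]
    dx <- upsample_backward(d_up)
    caches$skip_grad <- caches$skip_grad %||% vector("list", d)
    caches$skip_grad[[i]] <- d_skip
  }
  bb <- resblock_backward(dx, params$bott, config$residual, caches$bott)
  grads$bott <- bb$grads
  dx <- bb$dX
  for (i in rev(seq_len(d))) {
    dpool <- maxpool_backward(dx, caches$pool[[i]]$win, caches$pool[[i]]$in_dim)
    dpool <- dpool + caches$skip_grad[[i]]
    bb <- resblock_backward(dpool, params[[paste0("enc", i)]], config$residual,
                            caches$enc[[i]])
    grads[[paste0("enc", i)]] <- bb$grads
    dx <- bb$dX
  }
  grads
}

# Weighted segmentation loss on probabilities P with targets G and pixel
# weights Wm (all (H,W,1,B)). Returns the loss value and the gradient at the
# pre-sigmoid logits.
seg_loss <- function(P, G, Wm, kind) {
  eps <- 1e-7
  sw <- sum(Wm)
  if (sw == 0) return(list(loss = 0, dz = P * 0))
  Pc <- pmin(pmax(P, eps), 1 - eps)
  loss <- 0; dP <- 0
  if (kind %in% c("bce", "bce_plus_dice")) {
    loss <- loss + sum(Wm * (-G * log(Pc) - (1 - G) * log(1 - Pc))) / sw
    # d(bce)/dz collapses to (P - G) through the sigmoid
    dz_bce <- Wm * (P - G) / sw
  } else dz_bce <- 0
  if (kind %in% c("dice", "bce_plus_dice")) {
    smooth <- 1
    num <- 2 * sum(Wm * P * G) + smooth
    den <- sum(Wm * P) + sum(Wm * G) + smooth
    loss <- loss + (1 - num / den)
    dP <- Wm * (num / den^2 - 2 * G / den)
    dz_dice <- dP * P * (1 - P)
  } else dz_dice <- 0
  list(loss = loss, dz = dz_bce + dz_dice)
}

#' Train the segmentation network on feature stacks
#'
#' Patch-based training: each step draws `batch_size` random square patches
#' (uniform over positions whose patch lies inside the image), computes the
#' configured loss over in-FOV pixels, and takes one Adam step. Fully
#' reproducible given `config$seed` on a fixed platform (cross-platform
#' floating-point drift may occur).
#'
#' @param model A `vs_model` from [build_unet()].
#' @param samples List of training samples; each a list with `stack` (a
#'   `vs_feature_stack` or `H x W x C` array), `gt` (binary matrix) and
#'   optionally `fov`.
#' @param config Optional [net_config()] overriding the model's.
#' @param val_sample Optional single sample (same structure) whose central
#'   patch Dice is recorded per epoch; defaults to the first training sample.
#' @param verbose Print one line per epoch.
#' @return The trained `vs_model` with a `history` data frame (`epoch`,
#'   `loss`, `val_dice`).
#' @export
train_unet <- function(model, samples, config = NULL, val_sample = NULL,
                       verbose = FALSE) {
  config <- config %||% model$config
  if (length(samples) == 0L) stop_vs("at least one training sample is required")
  prep <- lapply(seq_along(samples), function(k) {
    s <- samples[[k]]
    arr <- if (inherits(s$stack, "vs_feature_stack")) s$stack$channels else s$stack
    if (is.null(s$gt)) stop_vs("training sample %d has no ground-truth mask", k)
    fov <- s$fov %||% matrix(1, dim(arr)[1L], dim(arr)[2L])
    if (dim(arr)[3L] != config$input_channels) {
      stop_vs("sample %d has %d channels; model expects %d", k,
              dim(arr)[3L], config$input_channels)
    }
    list(x = arr, g = s$gt, w = fov * 1)
  })
  params <- model$params
  if (config$epochs == 0L) {
    model$history <- data.frame(epoch = integer(0), loss = numeric(0),
                                val_dice = numeric(0))
    return(model)
  }
  ps <- config$patch_size
  vs <- val_sample %||% samples[[1L]]
  varr <- if (inherits(vs$stack, "vs_feature_stack")) vs$stack$channels else vs$stack
  vfov <- vs$fov %||% matrix(1, dim(varr)[1L], dim(varr)[2L])
  vr <- max(1L, (dim(varr)[1L] - ps) %/% 2L); vc <- max(1L, (dim(varr)[2L] - ps) %/% 2L)
  vX <- array(varr[vr:(vr + ps - 1L), vc:(vc + ps - 1L), ], dim = c(ps, ps, dim(varr)[3L], 1L))
  vG <- vs$gt[vr:(vr + ps - 1L), vc:(vc + ps - 1L)]
  vW <- vfov[vr:(vr + ps - 1L), vc:(vc + ps - 1L)]

  hist_loss <- numeric(config$epochs)
  hist_dice <- numeric(config$epochs)
  state <- adam_init(params)
  n_steps <- max(1L, ceiling(config$patches_per_epoch / config$batch_size))
  C <- config$input_channels

  with_local_rng(derive_seed(config$seed, "train"), {
    for (ep in seq_len(config$epochs)) {
      ep_loss <- 0
      for (st in seq_len(n_steps)) {
        X <- array(0, dim = c(ps, ps, C, config$batch_size))
        G <- array(0, dim = c(ps, ps, 1L, config$batch_size))
        Wm <- array(0, dim = c(ps, ps, 1L, config$batch_size))
        for (b in seq_len(config$batch_size)) {
          k <- sample.int(length(prep), 1L)
          hh <- dim(prep[[k]]$x)[1L]; ww <- dim(prep[[k]]$x)[2L]
          r0 <- sample.int(hh - ps + 1L, 1L); c0 <- sample.int(ww - ps + 1L, 1L)
          X[, , , b] <- prep[[k]]$x[r0:(r0 + ps - 1L), c0:(c0 + ps - 1L), ]
          G[, , 1L, b] <- prep[[k]]$g[r0:(r0 + ps - 1L), c0:(c0 + ps - 1L)]
          Wm[, , 1L, b] <- prep[[k]]$w[r0:(r0 + ps - 1L), c0:(c0 + ps - 1L)]
        }
        fw <- unet_forward(params, config, X, training = TRUE)
        ls <- seg_loss(fw$P, G, Wm, config$loss)
        grads <- unet_backward(params, config, ls$dz, fw$caches)
        upd <- adam_step(params, grads, state, config$learning_rate)
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + ls$loss
      }
      hist_loss[ep] <- ep_loss / n_steps
      pv <- unet_forward(params, config, vX)$P[, , 1L, 1L]
      pb <- (pv >= 0.5) * vW
      gtv <- vG * vW
      hist_dice[ep] <- if (sum(pb) + sum(gtv) == 0) 1 else
        2 * sum(pb * gtv) / (sum(pb) + sum(gtv))
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  val_dice %.4f",
                        ep, hist_loss[ep], hist_dice[ep]))
      }
    }
  })
  model$params <- params
  model$history <- data.frame(epoch = seq_len(config$epochs),
                              loss = hist_loss, val_dice = hist_dice)
  model$config <- config
  model
}

#' Calibrate the operating threshold on training data
#'
#' The network's probabilities need not be calibrated at 0.5: richer input
#' stacks in particular tend to over-segment at a fixed cut. This picks the
#' threshold that maximises mean Dice over training samples, evaluated
#' through the same post-processing chain used at deployment (when
#' `postproc` is given) or by plain thresholding otherwise. A per-model
#' calibration that uses no test data; ties break toward the lower
#' threshold.
#'
#' @param model A trained `vs_model`.
#' @param samples Training samples as in [train_unet()].
#' @param postproc Optional [postproc_params()] applied (with each candidate
#'   threshold substituted) before scoring.
#' @param grid Candidate thresholds.
#' @param max_samples Cap on the number of samples used.
#' @return The model with its `threshold` field set.
#' @export
calibrate_threshold <- function(model, samples, postproc = NULL,
                                grid = seq(0.2, 0.8, by = 0.05),
                                max_samples = 10L) {
  use <- samples[seq_len(min(length(samples), max_samples))]
  preds <- lapply(use, function(s) {
    fov <- s$fov %||% matrix(1, nrow(s$gt), ncol(s$gt))
    V <- predict_unet(model, s$stack, fov = fov)
    list(v = V$values, g = (s$gt != 0) * 1, keep = fov != 0)
  })
  dice_at <- vapply(grid, function(t) {
    mean(vapply(preds, function(p) {
      b <- if (is.null(postproc)) {
        (p$v >= t) * 1
      } else {
        pp <- postproc
        pp$threshold <- t
        postprocess(p$v, pp)
      }
      bk <- b[p$keep]; gk <- p$g[p$keep]
      s2 <- sum(bk) + sum(gk)
      if (s2 == 0) 1 else 2 * sum(bk * gk) / s2
    }, numeric(1)))
  }, numeric(1))
  model$threshold <- grid[which.max(dice_at)]
  model
}

#' Predict a vessel probability map
#'
#' Full-image inference by tiling with overlapping patches (overlap at least
#' `overlap` pixels; overlapping predictions are averaged). Images smaller
#' than the patch are reflect-padded. Probabilities outside the field of
#' view are forced to 0.
#'
#' @param model A trained `vs_model`.
#' @param stack `vs_feature_stack` or `H x W x C` array.
#' @param fov Optional binary mask (defaults to the stack's own).
#' @param overlap Minimum tile overlap in pixels.
#' @param tiled Force the tiling path even when one tile would suffice
#'   (used to validate tiling against single-shot inference).
#' @return A `vs_probability_map`: `values` (`H x W` in `[0,1]`), `source_id`.
#' @export
predict_unet <- function(model, stack, fov = NULL, overlap = 16L, tiled = TRUE) {
  arr <- if (inherits(stack, "vs_feature_stack")) stack$channels else stack
  if (is.null(fov) && inherits(stack, "vs_feature_stack")) fov <- stack$fov_mask
  H <- dim(arr)[1L]; W <- dim(arr)[2L]; C <- dim(arr)[3L]
  cfg <- model$config
  if (C != cfg$input_channels) {
    stop_vs("stack has %d channels; model expects %d", C, cfg$input_channels)
  }
  ps <- cfg$patch_size
  pad_to <- function(n) max(ps, ceiling(n / 2L^cfg$depth) * 2L^cfg$depth)
  if (!tiled || (H <= ps && W <= ps)) {
    Hp <- pad_to(H); Wp <- pad_to(W)
    Xp <- array(0, dim = c(Hp, Wp, C, 1L))
    for (c in seq_len(C)) {
      m <- arr[, , c]
      if (Hp > H) m <- rbind(m, m[H:(2L * H - Hp + 1L), , drop = FALSE])
      if (Wp > W) m <- cbind(m, m[, W:(2L * W - Wp + 1L), drop = FALSE])
      Xp[, , c, 1L] <- m
    }
    V <- unet_forward(model$params, cfg, Xp)$P[seq_len(H), seq_len(W), 1L, 1L]
  } else {
    stride <- max(1L, ps - overlap)
    starts <- function(n) {
      if (n <= ps) return(1L)
      s <- seq.int(1L, n - ps + 1L, by = stride)
      if (s[length(s)] != n - ps + 1L) s <- c(s, n - ps + 1L)
      s
    }
    acc <- matrix(0, H, W); wacc <- matrix(0, H, W)
    for (r0 in starts(H)) for (c0 in starts(W)) {
      ri <- r0:(min(r0 + ps - 1L, H)); ci <- c0:(min(c0 + ps - 1L, W))
      sub <- arr[ri, ci, , drop = FALSE]
      hs <- length(ri); ws <- length(ci)
      Hp <- pad_to(hs); Wp <- pad_to(ws)
      Xp <- array(0, dim = c(Hp, Wp, C, 1L))
      for (c in seq_len(C)) {
        m <- sub[, , c]
        if (Hp > hs) m <- rbind(m, m[hs:(2L * hs - Hp + 1L), , drop = FALSE])
        if (Wp > ws) m <- cbind(m, m[, ws:(2L * ws - Wp + 1L), drop = FALSE])
        Xp[, , c, 1L] <- m
      }
      p <- unet_forward(model$params, cfg, Xp)$P[seq_len(hs), seq_len(ws), 1L, 1L]
      acc[ri, ci] <- acc[ri, ci] + p
      wacc[ri, ci] <- wacc[ri, ci] + 1
    }
    V <- acc / wacc
  }
  if (!is.null(fov)) V <- V * (fov != 0)
  structure(list(values = V,
                 source_id = attr(stack, "id") %||% ""),
            class = "vs_probability_map")
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoint holding the weights, the network configuration and
#' the training history.
#' @param model A `vs_model`.
#' @param path Checkpoint file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the `vs_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "vs_model"))
  obj <- list(format = "vesselseg-checkpoint-1", config = unclass(model$config),
              params = model$params, history = model$history,
              threshold = model$threshold)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "vesselseg-checkpoint-1")) {
    stop_vs("'%s' is not a vesselseg checkpoint", path)
  }
  structure(list(params = obj$params,
                 config = structure(obj$config, class = "vs_net_config"),
                 history = obj$history, threshold = obj$threshold),
            class = "vs_model")
}
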