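# Minimal convolutional-network engine used by the segmentation module.
# Tensors are numeric arrays (H, W, C, B); convolutions are realised as
# im2col gathers followed by one BLAS matrix multiply, with hand-written
# backward passes and an Adam optimizer. Sized for CPU training on small
# fundus phantoms; no external deep-learning runtime is involved.

.vs_cache <- new.env(parent = emptyenv())

# Memoized im2col gather index for given geometry (1-based linear indices
# into the zero-padded array).
im2col_index <- function(H, W, C, B, kh, kw, pad) {
  key <- paste(H, W, C, B, kh, kw, pad, sep = "x")
  hit <- .vs_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  i <- rep.int(0:(H - 1L), W)
  j <- rep(0:(W - 1L), each = H)
  base <- i + Hp * j
  di <- rep.int(0:(kh - 1L), kw * C)
  dj <- rep.int(rep(0:(kw - 1L), each = kh), C)
  cc <- rep(0:(C - 1L), each = kh * kw)
  offs <- di + Hp * dj + Hp * Wp * cc
  base_all <- rep.int(base, B) + rep.int(0:(B - 1L) * (Hp * Wp * C), rep.int(H * W, B))
  # flat integer index (row-block per column) so the gather needs no copy
  idx <- rep.int(base_all, length(offs)) +
    rep.int(offs, rep.int(length(base_all), length(offs))) + 1L
  res <- list(idx = idx, nr = length(base_all), nc = length(offs))
  .vs_cache[[key]] <- res
  res
}

pad_zero_4d <- function(X, pad) {
  if (pad == 0L) return(X)
  d <- dim(X)
  out <- array(0, dim = c(d[1L] + 2L * pad, d[2L] + 2L * pad, d[3L], d[4L]))
  out[(pad + 1L):(pad + d[1L]), (pad + 1L):(pad + d[2L]), , ] <- X
  out
}

# 'same'-padded convolution (cross-correlation) of X (H,W,Cin,B) with
# weights W (kh,kw,Cin,Cout) + bias (Cout). Returns list(Y, Xcol) so the
# backward pass can reuse the gathered columns.
conv_forward <- function(X, Wt, bias, keep_cols = FALSE) {
  d <- dim(X); kd <- dim(Wt)
  H <- d[1L]; W <- d[2L]; Cin <- d[3L]; B <- d[4L]
  kh <- kd[1L]; kw <- kd[2L]; Cout <- kd[4L]
  stopifnot(kd[3L] == Cin)
  pad <- (kh - 1L) %/% 2L
  Xp <- pad_zero_4d(X, pad)
  ix <- im2col_index(H, W, Cin, B, kh, kw, pad)
  Xcol <- Xp[ix$idx]
  dim(Xcol) <- c(ix$nr, ix$nc)
  W2 <- Wt; dim(W2) <- c(kh * kw * Cin, Cout)
  Y <- Xcol %*% W2
  Y <- sweep(Y, 2L, bias, `+`)
  dim(Y) <- c(H, W, B, Cout)
  Y <- aperm(Y, c(1L, 2L, 4L, 3L))
  list(Y = Y, Xcol = if (keep_cols) Xcol else NULL)
}

conv_backward <- function(dY, X, Xcol, Wt) {
  d <- dim(X); kd <- dim(Wt)
  H <- d[1L]; W <- d[2L]; Cin <- d[3L]; B <- d[4L]
  kh <- kd[1L]; kw <- kd[2L]; Cout <- kd[4L]
  dY2 <- aperm(dY, c(1L, 2L, 4L, 3L))
  dim(dY2) <- c(H * W * B, Cout)
  dW <- crossprod(Xcol, dY2)
  dim(dW) <- kd
  db <- colSums(dY2)
  # gradient w.r.t. input = convolution of dY with the spatially flipped,
  # channel-transposed kernel
  Wr <- Wt[kh:1, kw:1, , , drop = FALSE]
  Wr <- aperm(Wr, c(1L, 2L, 4L, 3L))
  dX <- conv_forward(dY, Wr, numeric(Cin))$Y
  list(dX = dX, dW = dW, db = db)
}

relu_forward <- function(X) pmax(X, 0)
relu_backward <- function(dY, X) dY * (X > 0)

maxpool_forward <- function(X) {
  d <- dim(X)
  H <- d[1L]; W <- d[2L]
  io <- seq.int(1L, H, by = 2L); jo <- seq.int(1L, W, by = 2L)
  s <- list(X[io, jo, , , drop = FALSE], X[io + 1L, jo, , , drop = FALSE],
            X[io, jo + 1L, , , drop = FALSE], X[io + 1L, jo + 1L, , , drop = FALSE])
  m <- s[[1L]]
  win <- array(1L, dim = dim(m))
  for (k in 2:4) {
    upd <- s[[k]] > m
    m[upd] <- s[[k]][upd]
    win[upd] <- k
  }
  list(Y = m, win = win)
}

maxpool_backward <- function(dY, win, in_dim) {
  dX <- array(0, dim = in_dim)
  H <- in_dim[1L]; W <- in_dim[2L]
  io <- seq.int(1L, H, by = 2L); jo <- seq.int(1L, W, by = 2L)
  place <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (k in 1:4) {
    g <- dY * (win == k)
    dX[io + place[[k]][1L], jo + place[[k]][2L], , ] <-
      dX[io + place[[k]][1L], jo + place[[k]][2L], , , drop = FALSE] + g
  }
  dX
}

upsample_forward <- function(X) {
  d <- dim(X)
  ri <- rep(seq_len(d[1L]), each = 2L)
  ci <- rep(seq_len(d[2L]), each = 2L)
  X[ri, ci, , , drop = FALSE]
}

upsample_backward <- function(dY) {
  d <- dim(dY)
  io <- seq.int(1L, d[1L], by = 2L); jo <- seq.int(1L, d[2L], by = 2L)
  dY[io, jo, , , drop = FALSE] + dY[io + 1L, jo, , , drop = FALSE] +
    dY[io, jo + 1L, , , drop = FALSE] + dY[io + 1L, jo + 1L, , , drop = FALSE]
}

concat_channels <- function(A, B) {
  da <- dim(A); db <- dim(B)
  out <- array(0, dim = c(da[1L], da[2L], da[3L] + db[3L], da[4L]))
  out[, , seq_len(da[3L]), ] <- A
  out[, , da[3L] + seq_len(db[3L]), ] <- B
  out
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# ---- parameter initialisation -------------------------------------------

he_conv <- function(kh, kw, cin, cout) {
  n <- kh * kw * cin
  array(stats::rnorm(n * cout, 0, sqrt(2 / n)), dim = c(kh, kw, cin, cout))
}

init_resblock <- function(cin, cout, residual) {
  p <- list(W1 = he_conv(3L, 3L, cin, cout), b1 = numeric(cout),
            W2 = he_conv(3L, 3L, cout, cout), b2 = numeric(cout))
  if (residual && cin != cout) {
    p$Wp <- he_conv(1L, 1L, cin, cout)
    p$bp <- numeric(cout)
  }
  p
}

# Residual double-conv block: y = relu(conv2(relu(conv1(x))) + shortcut(x));
# without the residual flag, plain double conv with ReLUs.
resblock_forward <- function(X, p, residual, training = FALSE) {
  c1 <- conv_forward(X, p$W1, p$b1, keep_cols = training)
  a1 <- relu_forward(c1$Y)
  c2 <- conv_forward(a1, p$W2, p$b2, keep_cols = training)
  z <- c2$Y
  if (residual) {
    if (!is.null(p$Wp)) {
      sc <- conv_forward(X, p$Wp, p$bp, keep_cols = training)
      z <- z + sc$Y
    } else {
      sc <- NULL
      z <- z + X
    }
  } else sc <- NULL
  Y <- relu_forward(z)
  cache <- if (training) list(X = X, c1 = c1, a1 = a1, c2 = c2, sc = sc, z = z) else NULL
  list(Y = Y, cache = cache)
}

resblock_backward <- function(dY, p, residual, cache) {
  dz <- relu_backward(dY, cache$z)
  g2 <- conv_backward(dz, cache$a1, cache$c2$Xcol, p$W2)
  da1 <- relu_backward(g2$dX, cache$c1$Y)
  g1 <- conv_backward(da1, cache$X, cache$c1$Xcol, p$W1)
  dX <- g1$dX
  grads <- list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db)
  if (residual) {
    if (!is.null(p$Wp)) {
      gp <- conv_backward(dz, cache$X, cache$sc$Xcol, p$Wp)
      dX <- dX + gp$dX
      grads$Wp <- gp$dW; grads$bp <- gp$db
    } else {
      dX <- dX + dz
    }
  }
  list(dX = dX, grads = grads)
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(x) { x[] <- 0; x }
  list(m = rapply(params, zero_like, how = "replace"),
       v = rapply(params, zero_like, how = "replace"),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
      list(p = p, m = m, v = v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}
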