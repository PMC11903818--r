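# Minimal convolutional-network substrate (forward + backprop) used by the
# comparative segmentation network. Tensors are numeric arrays [H, W, C];
# convolutions are evaluated as im2col matrix products so the heavy lifting
# stays in BLAS. Nothing here is model-specific.

.im2col_cache <- new.env(parent = emptyenv())

# neighbour-index matrix (H*W x 9) into the zero-padded image, 3x3 kernel,
# pad 1; offset order: di (-1,0,1) fastest, dj outer
im2col_index <- function(H, W) {
  key <- paste(H, W, sep = "x")
  ni <- .im2col_cache[[key]]
  if (!is.null(ni)) return(ni)
  i <- rep(seq_len(H), W)
  j <- rep(seq_len(W), each = H)
  ni <- matrix(0L, H * W, 9L)
  o <- 1L
  for (dj in -1:1) for (di in -1:1) {
    ni[, o] <- (i + di + 1L) + (j + dj) * (H + 2L)
    o <- o + 1L
  }
  .im2col_cache[[key]] <- ni
  ni
}

conv3_forward <- function(x, Wm, b) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  xp <- array(0, c(H + 2L, W + 2L, C))
  xp[2:(H + 1L), 2:(W + 1L), ] <- x
  dim(xp) <- c((H + 2L) * (W + 2L), C)
  ni <- im2col_index(H, W)
  P <- xp[as.vector(ni), , drop = FALSE]
  dim(P) <- c(H * W, 9L * C)
  Fn <- ncol(Wm)
  out <- P %*% Wm
  out <- out + rep(b, each = H * W)
  dim(out) <- c(H, W, Fn)
  list(out = out, P = P, dims = c(H, W, C))
}

conv3_backward <- function(dout, cache, Wm) {
  H <- cache$dims[1]; W <- cache$dims[2]; C <- cache$dims[3]
  Fn <- ncol(Wm)
  dm <- dout; dim(dm) <- c(H * W, Fn)
  dW <- crossprod(cache$P, dm)
  db <- colSums(dm)
  dP <- dm %*% t(Wm)
  dim(dP) <- c(H * W, 9L, C)
  ni <- im2col_index(H, W)
  dxp <- matrix(0, (H + 2L) * (W + 2L), C)
  for (o in 1:9) {
    rows <- ni[, o]
    dxp[rows, ] <- dxp[rows, ] + dP[, o, ]
  }
  dim(dxp) <- c(H + 2L, W + 2L, C)
  dx <- dxp[2:(H + 1L), 2:(W + 1L), , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, mask = mask)
}

relu_backward <- function(dout, cache) dout * cache$mask

maxpool2_forward <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  i1 <- seq(1L, H, 2L); i2 <- seq(2L, H, 2L)
  j1 <- seq(1L, W, 2L); j2 <- seq(2L, W, 2L)
  cand <- array(0, c(H / 2, W / 2, C, 4))
  cand[, , , 1] <- x[i1, j1, , drop = FALSE]
  cand[, , , 2] <- x[i2, j1, , drop = FALSE]
  cand[, , , 3] <- x[i1, j2, , drop = FALSE]
  cand[, , , 4] <- x[i2, j2, , drop = FALSE]
  out <- pmax(cand[, , , 1, drop = FALSE], cand[, , , 2, drop = FALSE],
              cand[, , , 3, drop = FALSE], cand[, , , 4, drop = FALSE])
  dim(out) <- c(H / 2, W / 2, C)
  # deterministic argmax: first of the four candidates achieving the max
  arg <- array(4L, dim(out))
  for (k in 3:1) {
    ck <- cand[, , , k, drop = FALSE]
    dim(ck) <- dim(out)
    arg[ck == out] <- k
  }
  list(out = out, arg = arg, dims = d)
}

maxpool2_backward <- function(dout, cache) {
  d <- cache$dims; H <- d[1]; W <- d[2]; C <- d[3]
  dx <- array(0, d)
  i1 <- seq(1L, H, 2L); i2 <- seq(2L, H, 2L)
  j1 <- seq(1L, W, 2L); j2 <- seq(2L, W, 2L)
  sel <- list(list(i1, j1), list(i2, j1), list(i1, j2), list(i2, j2))
  for (k in 1:4) {
    mk <- cache$arg == k
    if (any(mk)) {
      sub <- dx[sel[[k]][[1]], sel[[k]][[2]], , drop = FALSE]
      sub[mk] <- sub[mk] + dout[mk]
      dx[sel[[k]][[1]], sel[[k]][[2]], ] <- sub
    }
  }
  dx
}

# transposed convolution, 2x2 kernel, stride 2; weight array [Cin, 2, 2, F]
upconv2_forward <- function(x, Wm, b, Fn) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  xm <- x; dim(xm) <- c(H * W, C)
  Y <- xm %*% Wm # HW x 4F, columns (dy, dx, f), dy fastest
  dim(Y) <- c(H, W, 2L, 2L, Fn)
  out <- aperm(Y, c(3, 1, 4, 2, 5))
  dim(out) <- c(2L * H, 2L * W, Fn)
  out <- out + rep(b, each = 4L * H * W)
  list(out = out, xm = xm, dims = d)
}

upconv2_backward <- function(dout, cache, Wm, Fn) {
  H <- cache$dims[1]; W <- cache$dims[2]; C <- cache$dims[3]
  db <- apply(dout, 3, sum)
  dArr <- dout
  dim(dArr) <- c(2L, H, 2L, W, Fn)
  dY <- aperm(dArr, c(2, 4, 1, 3, 5))
  dim(dY) <- c(H * W, 4L * Fn)
  dW <- crossprod(cache$xm, dY)
  dx <- dY %*% t(Wm)
  dim(dx) <- c(H, W, C)
  list(dx = dx, dW = dW, db = db)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

he_init <- function(n, fan_in) stats::rnorm(n, 0, sqrt(2 / fan_in))

# elementwise RMSprop update over arbitrarily nested parameter lists
rmsprop_update <- function(params, grads, state, lr, rho = 0.9, eps = 1e-7) {
  walk <- function(p, g, s) {
    if (is.list(p)) {
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], s[[nm]])
        p[[nm]] <- r$p; s[[nm]] <- r$s
      }
      list(p = p, s = s)
    } else {
      if (is.null(s)) s <- array(0, dim(as.array(g)))
      s <- rho * s + (1 - rho) * g * g
      p <- p - lr * g / (sqrt(s) + eps)
      list(p = p, s = s)
    }
  }
  walk(params, grads, state)
}

# Adam update; state is a list(m, v, t) of nested moment lists
adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  t <- (state$t %||% 0) + 1
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
      list(p = p, m = m, v = v)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      p <- p - lr * mh / (sqrt(vh) + eps)
      list(p = p, m = m, v = v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(p = r$p, s = list(m = r$m, v = r$v, t = t))
}

zero_like <- function(params) {
  if (is.list(params)) lapply(params, zero_like)
  else params * 0
}

add_grads <- function(a, b) {
  if (is.list(a)) mapply(add_grads, a, b, SIMPLIFY = FALSE)
  else a + b
}
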