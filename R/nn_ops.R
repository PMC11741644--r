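# Low-level CPU tensor operators for the configurable segmentation CNN.
#
# All activations are dense arrays with layout (C, H, W, D, B): channels
# first, batch last.  2-D models run with D = 1 so every operator has a
# single code path.  Convolutions are evaluated as a sum over kernel
# offsets of (Cout x Cin) %*% (Cin x N) matrix products, which routes the
# heavy lifting through BLAS; backward passes are the exact adjoints.

conv_same_pad <- function(k) (k - 1L) %/% 2L

# x: (Cin, H, W, D, B); w: (Cout, Cin, k1, k2, k3); b: length Cout
conv_fwd <- function(x, w, b, keep_cache = TRUE) {
  dx <- dim(x); dw <- dim(w)
  cin <- dx[1L]; H <- dx[2L]; W <- dx[3L]; D <- dx[4L]; B <- dx[5L]
  cout <- dw[1L]
  stopifnot(dw[2L] == cin)
  k <- dw[3:5]; p <- conv_same_pad(k)
  xp <- array(0, c(cin, H + 2L * p[1L], W + 2L * p[2L], D + 2L * p[3L], B))
  xp[, p[1L] + seq_len(H), p[2L] + seq_len(W), p[3L] + seq_len(D), ] <- x
  N <- H * W * D * B
  y <- matrix(b, cout, N)
  for (i3 in seq_len(k[3L])) for (i2 in seq_len(k[2L])) for (i1 in seq_len(k[1L])) {
    xs <- xp[, i1:(i1 + H - 1L), i2:(i2 + W - 1L), i3:(i3 + D - 1L), ,
             drop = FALSE]
    dim(xs) <- c(cin, N)
    y <- y + matrix(w[, , i1, i2, i3], cout) %*% xs
  }
  dim(y) <- c(cout, H, W, D, B)
  cache <- if (keep_cache) list(xp = xp, w = w, dims = dx, k = k, p = p) else NULL
  list(y = y, cache = cache)
}

conv_bwd <- function(dy, cache) {
  xp <- cache$xp; w <- cache$w; dxdims <- cache$dims
  k <- cache$k; p <- cache$p
  cin <- dxdims[1L]; H <- dxdims[2L]; W <- dxdims[3L]; D <- dxdims[4L]
  B <- dxdims[5L]
  cout <- dim(w)[1L]
  N <- H * W * D * B
  dym <- matrix(dy, cout, N)
  dw <- array(0, dim(w))
  dxp <- array(0, dim(xp))
  for (i3 in seq_len(k[3L])) for (i2 in seq_len(k[2L])) for (i1 in seq_len(k[1L])) {
    xs <- xp[, i1:(i1 + H - 1L), i2:(i2 + W - 1L), i3:(i3 + D - 1L), ,
             drop = FALSE]
    dim(xs) <- c(cin, N)
    dw[, , i1, i2, i3] <- dym %*% t(xs)
    dxs <- crossprod(matrix(w[, , i1, i2, i3], cout), dym)
    dim(dxs) <- c(cin, H, W, D, B)
    dxp[, i1:(i1 + H - 1L), i2:(i2 + W - 1L), i3:(i3 + D - 1L), ] <-
      dxp[, i1:(i1 + H - 1L), i2:(i2 + W - 1L), i3:(i3 + D - 1L), ,
          drop = FALSE] + dxs
  }
  dx <- dxp[, p[1L] + seq_len(H), p[2L] + seq_len(W), p[3L] + seq_len(D), ,
            drop = FALSE]
  dim(dx) <- dxdims
  list(dx = dx, dw = dw, db = rowSums(dym))
}

# Batch normalisation over batch + spatial positions, per channel.
bn_fwd <- function(x, gamma, beta, run_mean, run_var, training,
                   momentum = 0.1, eps = 1e-5) {
  C <- dim(x)[1L]
  xm <- matrix(x, C)
  N <- ncol(xm)
  if (training) {
    mu <- rowMeans(xm)
    xc <- xm - mu
    v <- rowMeans(xc * xc)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v * N / max(N - 1L, 1L)
  } else {
    mu <- run_mean
    v <- run_var
    xc <- xm - mu
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  y <- gamma * xhat + beta
  dim(y) <- dim(x)
  list(y = y, run_mean = run_mean, run_var = run_var,
       cache = list(xhat = xhat, istd = istd, gamma = gamma, N = N,
                    dims = dim(x), training = training))
}

bn_bwd <- function(dy, cache) {
  C <- length(cache$gamma)
  dym <- matrix(dy, C)
  xhat <- cache$xhat
  dgamma <- rowSums(dym * xhat)
  dbeta <- rowSums(dym)
  if (cache$training) {
    N <- cache$N
    dx <- (cache$gamma * cache$istd) *
      (dym - dbeta / N - xhat * (dgamma / N))
  } else {
    dx <- (cache$gamma * cache$istd) * dym
  }
  dim(dx) <- cache$dims
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(x) {
  mask <- x > 0
  x[!mask] <- 0
  list(y = x, cache = mask)
}

relu_bwd <- function(dy, mask) {
  dy[!mask] <- 0
  dy
}

# Channel concatenation of a list of (C_i, H, W, D, B) arrays.
ch_cat <- function(xs) {
  if (length(xs) == 1L) return(xs[[1L]])
  chans <- vapply(xs, function(a) dim(a)[1L], integer(1))
  d <- dim(xs[[1L]])
  out <- array(0, c(sum(chans), d[-1L]))
  at <- 0L
  for (i in seq_along(xs)) {
    out[at + seq_len(chans[i]), , , , ] <- xs[[i]]
    at <- at + chans[i]
  }
  out
}

ch_split <- function(x, chans) {
  out <- vector("list", length(chans))
  at <- 0L
  for (i in seq_along(chans)) {
    out[[i]] <- x[at + seq_len(chans[i]), , , , , drop = FALSE]
    at <- at + chans[i]
  }
  out
}

# Window-2 stride-2 pooling; win is c(2, 2, 2) in 3-D and c(2, 2, 1) in 2-D.
pool_fwd <- function(x, kind, win) {
  d <- dim(x)
  offs <- as.matrix(expand.grid(o1 = seq_len(win[1L]), o2 = seq_len(win[2L]),
                                o3 = seq_len(win[3L])))
  nwin <- nrow(offs)
  y <- NULL; sel <- NULL
  for (o in seq_len(nwin)) {
    xs <- x[, seq(offs[o, 1L], d[2L], by = win[1L]),
            seq(offs[o, 2L], d[3L], by = win[2L]),
            seq(offs[o, 3L], d[4L], by = win[3L]), , drop = FALSE]
    if (kind == "max") {
      if (is.null(y)) {
        y <- xs
        sel <- array(1L, dim(xs))
      } else {
        upd <- xs > y
        y[upd] <- xs[upd]
        sel[upd] <- o
      }
    } else {
      y <- if (is.null(y)) xs else y + xs
    }
  }
  if (kind == "average") y <- y / nwin
  list(y = y, cache = list(kind = kind, win = win, dims = d, sel = sel,
                           offs = offs, nwin = nwin))
}

pool_bwd <- function(dy, cache) {
  d <- cache$dims
  dx <- array(0, d)
  offs <- cache$offs; win <- cache$win
  for (o in seq_len(cache$nwin)) {
    g <- if (cache$kind == "max") dy * (cache$sel == o) else dy / cache$nwin
    dx[, seq(offs[o, 1L], d[2L], by = win[1L]),
       seq(offs[o, 2L], d[3L], by = win[2L]),
       seq(offs[o, 3L], d[4L], by = win[3L]), ] <- g
  }
  dx
}

# Nearest-neighbour upsampling by integer factors per spatial axis.
upsample_fwd <- function(x, win) {
  d <- dim(x)
  x[, rep(seq_len(d[2L]), each = win[1L]),
    rep(seq_len(d[3L]), each = win[2L]),
    rep(seq_len(d[4L]), each = win[3L]), , drop = FALSE]
}

upsample_bwd <- function(dy, win, in_dims) {
  d <- dim(dy)
  dx <- array(0, in_dims)
  for (o3 in seq_len(win[3L])) for (o2 in seq_len(win[2L])) for (o1 in seq_len(win[1L])) {
    dx <- dx + dy[, seq(o1, d[2L], by = win[1L]), seq(o2, d[3L], by = win[2L]),
                  seq(o3, d[4L], by = win[3L]), , drop = FALSE]
  }
  dx
}

# Softmax over the channel axis; x is (C, ...) -> probabilities, same shape.
softmax_fwd <- function(x) {
  C <- dim(x)[1L]
  xm <- matrix(x, C)
  m <- xm[1L, ]
  if (C > 1L) for (c in 2:C) m <- pmax(m, xm[c, ])
  e <- exp(xm - rep(m, each = C))
  p <- e / rep(colSums(e), each = C)
  dim(p) <- dim(x)
  p
}

# Combined voxel-wise cross-entropy + soft-Dice loss over tissue classes.
# probs: (C, N) matrix; target: integer vector in 1..C; dice_classes:
# class indices entering the soft-Dice term.  Returns the loss and the
# gradient with respect to the pre-softmax logits.
ce_dice_loss <- function(probs, target, dice_classes, eps = 1e-6) {
  C <- nrow(probs); N <- ncol(probs)
  li <- (seq_len(N) - 1L) * C + target
  pt <- probs[li]
  ce <- -mean(log(pmax(pt, 1e-12)))
  g <- matrix(0, C, N)
  dice_vals <- numeric(length(dice_classes))
  nd <- length(dice_classes)
  for (ci in seq_along(dice_classes)) {
    cc <- dice_classes[ci]
    tc <- as.numeric(target == cc)
    Ic <- sum(probs[cc, ] * tc)
    Uc <- sum(probs[cc, ]) + sum(tc) + eps
    dice_vals[ci] <- 2 * Ic / Uc
    # d(1 - mean dice)/dp_c = -(2 t U - 2 I) / U^2 / nd
    g[cc, ] <- -(2 * tc * Uc - 2 * Ic) / (Uc * Uc) / nd
  }
  dice_loss <- 1 - mean(dice_vals)
  # chain rule through softmax for the dice part, closed form for CE
  dz_ce <- probs / N
  dz_ce[li] <- dz_ce[li] - 1 / N
  gp <- colSums(g * probs)
  dz_dice <- probs * (g - rep(gp, each = C))
  list(loss = ce + dice_loss, ce = ce, dice_loss = dice_loss,
       soft_dice = mean(dice_vals), dz = dz_ce + dz_dice)
}

# Adam optimiser over a nested list of numeric arrays.
adam_init <- function(params) {
  zeros <- rapply(params, function(a) array(0, dim(a) %||% length(a)),
                  how = "replace")
  list(m = zeros, v = zeros, t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  step_one <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      step_one(p, g, m, v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}
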