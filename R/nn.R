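# Minimal neural-network engine used by the four classifier architectures.
#
# Internal tensor layout: feature-major arrays (C, T, N) for sequence layers
# (C features/channels, T timesteps, N batch) and matrices (F, N) for dense
# layers. All heavy lifting is BLAS matrix multiplication. Every layer is an
# environment exposing forward(x, training) / backward(dy), with `params` and
# `grads` as named lists of arrays, so the optimizer can walk them generically.

glorot <- function(fan_in, fan_out, dims = c(fan_out, fan_in)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

new_layer <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- list()
  e$grads <- list()
  e$extra_count <- 0L # non-trainable entries included in the total count
  e
}

# ---- 1-D convolution (strided, 'same' or 'valid' padding) ------------------

conv1d_geometry <- function(Tin, k, stride, padding) {
  if (padding == "same") {
    Lout <- ceiling(Tin / stride)
    pt <- max((Lout - 1) * stride + k - Tin, 0)
    c(Lout = Lout, pl = pt %/% 2, pr = pt - pt %/% 2)
  } else {
    c(Lout = (Tin - k) %/% stride + 1, pl = 0L, pr = 0L)
  }
}

layer_conv1d <- function(in_ch, filters, kernel, stride = 1,
                         padding = "same", bias = TRUE) {
  ly <- new_layer("conv1d")
  ly$in_ch <- in_ch; ly$filters <- filters; ly$kernel <- kernel
  ly$stride <- stride; ly$padding <- padding; ly$bias <- bias
  ly$params$W <- glorot(kernel * in_ch, filters, c(filters, in_ch, kernel))
  if (bias) ly$params$b <- numeric(filters)
  ly$forward <- function(x, training = FALSE) {
    d <- dim(x); C <- d[1]; Tin <- d[2]; N <- d[3]
    g <- conv1d_geometry(Tin, ly$kernel, ly$stride, ly$padding)
    Lout <- g[1]
    if (g[2] + g[3] > 0) {
      xp <- array(0, c(C, Tin + g[2] + g[3], N))
      xp[, g[2] + seq_len(Tin), ] <- x
    } else xp <- x
    y <- matrix(0, ly$filters, Lout * N)
    xs <- vector("list", ly$kernel)
    for (j in seq_len(ly$kernel)) {
      tj <- (seq_len(Lout) - 1L) * ly$stride + j
      xs[[j]] <- matrix(xp[, tj, , drop = FALSE], C, Lout * N)
      y <- y + ly$params$W[, , j] %*% xs[[j]]
    }
    if (ly$bias) y <- y + ly$params$b
    ly$cache <- list(xs = xs, Tin = Tin, Lout = Lout, g = g, N = N, C = C)
    array(y, c(ly$filters, Lout, N))
  }
  ly$backward <- function(dy) {
    cc <- ly$cache
    dym <- matrix(dy, ly$filters, cc$Lout * cc$N)
    dW <- array(0, dim(ly$params$W))
    Tp <- cc$Tin + cc$g[2] + cc$g[3]
    dxp <- array(0, c(cc$C, Tp, cc$N))
    for (j in seq_len(ly$kernel)) {
      dW[, , j] <- dym %*% t(cc$xs[[j]])
      tj <- (seq_len(cc$Lout) - 1L) * ly$stride + j
      dxp[, tj, ] <- dxp[, tj, , drop = FALSE] +
        array(t(ly$params$W[, , j]) %*% dym, c(cc$C, cc$Lout, cc$N))
    }
    ly$grads$W <- dW
    if (ly$bias) ly$grads$b <- rowSums(dym)
    dxp[, cc$g[2] + seq_len(cc$Tin), , drop = FALSE]
  }
  ly
}

# ---- batch normalization over the feature axis -----------------------------

layer_batchnorm <- function(ch, momentum = 0.9, eps = 1e-3) {
  ly <- new_layer("batchnorm")
  ly$ch <- ch
  ly$params$gamma <- rep(1, ch)
  ly$params$beta <- rep(0, ch)
  ly$running_mean <- rep(0, ch)
  ly$running_var <- rep(1, ch)
  ly$extra_count <- 2L * ch # running statistics enter the total-params count
  ly$momentum <- momentum; ly$eps <- eps
  ly$forward <- function(x, training = FALSE) {
    d <- dim(x)
    xm <- matrix(x, d[1])
    if (training) {
      mu <- rowMeans(xm)
      v <- rowMeans(xm^2) - mu^2
      ly$running_mean <- ly$momentum * ly$running_mean + (1 - ly$momentum) * mu
      ly$running_var <- ly$momentum * ly$running_var + (1 - ly$momentum) * v
    } else {
      mu <- ly$running_mean; v <- ly$running_var
    }
    istd <- 1 / sqrt(v + ly$eps)
    xhat <- (xm - mu) * istd
    y <- xhat * ly$params$gamma + ly$params$beta
    ly$cache <- list(xhat = xhat, istd = istd, d = d, training = training)
    array(y, d)
  }
  ly$backward <- function(dy) {
    cc <- ly$cache
    dym <- matrix(dy, cc$d[1])
    ly$grads$gamma <- rowSums(dym * cc$xhat)
    ly$grads$beta <- rowSums(dym)
    dxhat <- dym * ly$params$gamma
    if (cc$training) {
      dx <- cc$istd * (dxhat - rowMeans(dxhat) -
                         cc$xhat * rowMeans(dxhat * cc$xhat))
    } else {
      dx <- dxhat * cc$istd
    }
    array(dx, cc$d)
  }
  ly
}

# ---- activations -----------------------------------------------------------

layer_activation <- function(kind = c("leaky_relu", "relu", "elu"), alpha = 0.3) {
  kind <- match.arg(kind)
  ly <- new_layer(paste0("act_", kind))
  alpha_elu <- 1
  ly$forward <- function(x, training = FALSE) {
    pos <- x > 0
    y <- switch(kind,
      leaky_relu = x * (pos + alpha * !pos),
      relu = x * pos,
      elu = {
        y <- x
        y[!pos] <- alpha_elu * (exp(x[!pos]) - 1)
        y
      }
    )
    ly$cache <- list(pos = pos, y = if (kind == "elu") y)
    y
  }
  ly$backward <- function(dy) {
    pos <- ly$cache$pos
    switch(kind,
      leaky_relu = dy * (pos + alpha * !pos),
      relu = dy * pos,
      elu = {
        g <- dy
        g[!pos] <- dy[!pos] * (ly$cache$y[!pos] + alpha_elu)
        g
      }
    )
  }
  ly
}

# ---- dropout ---------------------------------------------------------------

layer_dropout <- function(p, spatial = FALSE) {
  ly <- new_layer(if (spatial) "spatial_dropout" else "dropout")
  ly$p <- p
  ly$forward <- function(x, training = FALSE) {
    if (!training || ly$p <= 0) { ly$cache <- NULL; return(x) }
    d <- dim(x)
    if (spatial && length(d) == 3) {
      # drop whole feature maps: one mask entry per (feature, sample)
      m <- array(stats::rbinom(d[1] * d[3], 1, 1 - ly$p), c(d[1], 1, d[3]))
      mask <- array(m[, rep(1, d[2]), , drop = FALSE], d) / (1 - ly$p)
    } else {
      mask <- array(stats::rbinom(length(x), 1, 1 - ly$p), d) / (1 - ly$p)
    }
    ly$cache <- list(mask = mask)
    x * mask
  }
  ly$backward <- function(dy) {
    if (is.null(ly$cache)) dy else dy * ly$cache$mask
  }
  ly
}

# ---- average pooling along time --------------------------------------------

layer_avgpool <- function(pool) {
  ly <- new_layer("avgpool")
  ly$pool <- pool
  ly$forward <- function(x, training = FALSE) {
    d <- dim(x)
    To <- d[2] %/% ly$pool
    y <- array(0, c(d[1], To, d[3]))
    for (j in seq_len(ly$pool)) {
      y <- y + x[, (seq_len(To) - 1L) * ly$pool + j, , drop = FALSE]
    }
    ly$cache <- list(d = d, To = To)
    y / ly$pool
  }
  ly$backward <- function(dy) {
    cc <- ly$cache
    dx <- array(0, cc$d)
    for (j in seq_len(ly$pool)) {
      dx[, (seq_len(cc$To) - 1L) * ly$pool + j, ] <- dy / ly$pool
    }
    dx
  }
  ly
}

# ---- flatten ---------------------------------------------------------------

layer_flatten <- function() {
  ly <- new_layer("flatten")
  ly$forward <- function(x, training = FALSE) {
    d <- dim(x)
    ly$cache <- list(d = d)
    matrix(x, prod(d[-length(d)]), d[length(d)])
  }
  ly$backward <- function(dy) array(dy, ly$cache$d)
  ly
}

# ---- dense -----------------------------------------------------------------

layer_dense <- function(in_f, out_f, bias = TRUE) {
  ly <- new_layer("dense")
  ly$params$W <- glorot(in_f, out_f)
  if (bias) ly$params$b <- numeric(out_f)
  ly$bias <- bias
  ly$forward <- function(x, training = FALSE) {
    ly$cache <- list(x = x)
    y <- ly$params$W %*% x
    if (ly$bias) y <- y + ly$params$b
    y
  }
  ly$backward <- function(dy) {
    ly$grads$W <- dy %*% t(ly$cache$x)
    if (ly$bias) ly$grads$b <- rowSums(dy)
    t(ly$params$W) %*% dy
  }
  ly
}

# ---- bidirectional LSTM ----------------------------------------------------
# Gate order i, f, g, o (as in the reference framework); forget-gate bias
# initialized to 1. Returns the concatenated last forward / first backward
# hidden states (2h x N).

lstm_dir_params <- function(in_f, h) {
  Wx <- glorot(in_f + h, 4 * h, c(4 * h, in_f))
  Wh <- glorot(in_f + h, 4 * h, c(4 * h, h))
  b <- numeric(4 * h)
  b[(h + 1):(2 * h)] <- 1
  list(Wx = Wx, Wh = Wh, b = b)
}

sigm <- function(z) 1 / (1 + exp(-z))

lstm_run <- function(x, p, h, reverse = FALSE) {
  d <- dim(x); C <- d[1]; Tt <- d[2]; N <- d[3]
  steps <- if (reverse) rev(seq_len(Tt)) else seq_len(Tt)
  WxX <- array(p$Wx %*% matrix(x, C, Tt * N) + p$b, c(4 * h, Tt, N))
  hs <- array(0, c(h, Tt, N)); cs <- array(0, c(h, Tt, N))
  gates <- array(0, c(4 * h, Tt, N))
  hp <- matrix(0, h, N); cp <- matrix(0, h, N)
  ii <- 1:h; ff <- (h + 1):(2 * h); gg <- (2 * h + 1):(3 * h); oo <- (3 * h + 1):(4 * h)
  for (t in steps) {
    z <- matrix(WxX[, t, ], 4 * h, N) + p$Wh %*% hp
    i <- sigm(z[ii, , drop = FALSE]); f <- sigm(z[ff, , drop = FALSE])
    g <- tanh(z[gg, , drop = FALSE]); o <- sigm(z[oo, , drop = FALSE])
    cp <- f * cp + i * g
    hp <- o * tanh(cp)
    hs[, t, ] <- hp; cs[, t, ] <- cp
    gates[ii, t, ] <- i; gates[ff, t, ] <- f; gates[gg, t, ] <- g; gates[oo, t, ] <- o
  }
  list(hs = hs, cs = cs, gates = gates, steps = steps, x = x)
}

lstm_backprop <- function(run, p, h, dh_last, reverse = FALSE) {
  x <- run$x; d <- dim(x); C <- d[1]; Tt <- d[2]; N <- d[3]
  ii <- 1:h; ff <- (h + 1):(2 * h); gg <- (2 * h + 1):(3 * h); oo <- (3 * h + 1):(4 * h)
  dWx <- array(0, dim(p$Wx)); dWh <- array(0, dim(p$Wh)); db <- numeric(4 * h)
  dz_all <- array(0, c(4 * h, Tt, N))
  dh <- dh_last; dc <- matrix(0, h, N)
  steps_rev <- rev(run$steps)
  for (si in seq_along(steps_rev)) {
    t <- steps_rev[si]
    t_prev <- if (si == length(steps_rev)) NA_integer_ else steps_rev[si + 1L]
    i <- matrix(run$gates[ii, t, ], h, N); f <- matrix(run$gates[ff, t, ], h, N)
    g <- matrix(run$gates[gg, t, ], h, N); o <- matrix(run$gates[oo, t, ], h, N)
    ct <- matrix(run$cs[, t, ], h, N)
    cprev <- if (is.na(t_prev)) matrix(0, h, N) else matrix(run$cs[, t_prev, ], h, N)
    hprev <- if (is.na(t_prev)) matrix(0, h, N) else matrix(run$hs[, t_prev, ], h, N)
    tc <- tanh(ct)
    do <- dh * tc
    dc <- dc + dh * o * (1 - tc^2)
    di <- dc * g; dg <- dc * i; df <- dc * cprev
    dz <- rbind(di * i * (1 - i), df * f * (1 - f),
                dg * (1 - g^2), do * o * (1 - o))
    dz_all[, t, ] <- dz
    dWh <- dWh + dz %*% t(hprev)
    dh <- t(p$Wh) %*% dz
    dc <- dc * f
  }
  dzm <- matrix(dz_all, 4 * h, Tt * N)
  dWx <- dzm %*% t(matrix(x, C, Tt * N))
  db <- rowSums(dzm)
  dx <- array(t(p$Wx) %*% dzm, c(C, Tt, N))
  list(dWx = dWx, dWh = dWh, db = db, dx = dx)
}

layer_bilstm <- function(in_f, units) {
  ly <- new_layer("bilstm")
  ly$units <- units
  fw <- lstm_dir_params(in_f, units)
  bw <- lstm_dir_params(in_f, units)
  ly$params <- list(fWx = fw$Wx, fWh = fw$Wh, fb = fw$b,
                    bWx = bw$Wx, bWh = bw$Wh, bb = bw$b)
  ly$forward <- function(x, training = FALSE) {
    h <- ly$units
    pf <- list(Wx = ly$params$fWx, Wh = ly$params$fWh, b = ly$params$fb)
    pb <- list(Wx = ly$params$bWx, Wh = ly$params$bWh, b = ly$params$bb)
    rf <- lstm_run(x, pf, h, reverse = FALSE)
    rb <- lstm_run(x, pb, h, reverse = TRUE)
    Tt <- dim(x)[2]; N <- dim(x)[3]
    ly$cache <- list(rf = rf, rb = rb, Tt = Tt, N = N)
    rbind(matrix(rf$hs[, Tt, ], h, N), matrix(rb$hs[, 1, ], h, N))
  }
  ly$backward <- function(dy) {
    h <- ly$units; cc <- ly$cache
    pf <- list(Wx = ly$params$fWx, Wh = ly$params$fWh, b = ly$params$fb)
    pb <- list(Wx = ly$params$bWx, Wh = ly$params$bWh, b = ly$params$bb)
    gf <- lstm_backprop(cc$rf, pf, h, dy[1:h, , drop = FALSE], reverse = FALSE)
    gb <- lstm_backprop(cc$rb, pb, h, dy[(h + 1):(2 * h), , drop = FALSE],
                        reverse = TRUE)
    ly$grads <- list(fWx = gf$dWx, fWh = gf$dWh, fb = gf$db,
                     bWx = gb$dWx, bWh = gb$dWh, bb = gb$db)
    gf$dx + gb$dx
  }
  ly
}

# ---- EEGNet-specific layers ------------------------------------------------

# Temporal convolution shared across EEG channels: input (C, T, N), output a
# 4-D array (F1, T, C, N). No bias (as in the original design).
layer_temporal_conv <- function(F1, kernel) {
  ly <- new_layer("temporal_conv")
  ly$F1 <- F1; ly$kernel <- kernel
  ly$params$W <- glorot(kernel, F1, c(F1, 1, kernel))
  inner <- layer_conv1d(1, F1, kernel, 1, "same", bias = FALSE)
  ly$forward <- function(x, training = FALSE) {
    d <- dim(x) # C, T, N
    inner$params$W <- ly$params$W
    xr <- array(aperm(x, c(2, 1, 3)), c(1, d[2], d[1] * d[3])) # (1, T, C*N)
    y <- inner$forward(xr, training) # (F1, T, C*N)
    ly$cache <- list(d = d)
    array(y, c(ly$F1, d[2], d[1], d[3]))
  }
  ly$backward <- function(dy) {
    d <- ly$cache$d
    dyr <- array(dy, c(ly$F1, d[2], d[1] * d[3]))
    dxr <- inner$backward(dyr) # (1, T, C*N)
    ly$grads$W <- inner$grads$W
    aperm(array(dxr, c(d[2], d[1], d[3])), c(2, 1, 3))
  }
  ly
}

# Depthwise spatial filter: for each temporal filter f1, D spatial filters
# over the C EEG channels. Input (F1, T, C, N), output (F1*D, T, N). No bias.
layer_depthwise_spatial <- function(F1, D, C) {
  ly <- new_layer("depthwise_spatial")
  ly$F1 <- F1; ly$D <- D; ly$C <- C
  ly$params$W <- glorot(C, D, c(D, C, F1))
  ly$forward <- function(x, training = FALSE) {
    d <- dim(x) # F1, T, C, N
    y <- array(0, c(ly$F1 * ly$D, d[2], d[4]))
    xs <- vector("list", ly$F1)
    for (f1 in seq_len(ly$F1)) {
      xc <- aperm(array(x[f1, , , ], d[2:4]), c(2, 1, 3)) # (C, T, N)
      xs[[f1]] <- matrix(xc, ly$C, d[2] * d[4])
      y[(f1 - 1) * ly$D + seq_len(ly$D), , ] <-
        array(ly$params$W[, , f1] %*% xs[[f1]], c(ly$D, d[2], d[4]))
    }
    ly$cache <- list(xs = xs, d = d)
    y
  }
  ly$backward <- function(dy) {
    cc <- ly$cache; d <- cc$d
    dW <- array(0, dim(ly$params$W))
    dx <- array(0, d)
    for (f1 in seq_len(ly$F1)) {
      dyf <- matrix(dy[(f1 - 1) * ly$D + seq_len(ly$D), , ], ly$D, d[2] * d[4])
      dW[, , f1] <- dyf %*% t(cc$xs[[f1]])
      dxc <- array(t(ly$params$W[, , f1]) %*% dyf, c(ly$C, d[2], d[4]))
      dx[f1, , , ] <- aperm(dxc, c(2, 1, 3))
    }
    ly$grads$W <- dW
    dx
  }
  ly
}

# Separable convolution = depthwise temporal conv (per feature) followed by a
# pointwise 1x1 mix. Input/output (C, T, N). No biases.
layer_separable_conv <- function(in_ch, out_ch, kernel) {
  ly <- new_layer("separable_conv")
  ly$in_ch <- in_ch; ly$out_ch <- out_ch; ly$kernel <- kernel
  ly$params$Wd <- glorot(kernel, 1, c(in_ch, kernel))
  ly$params$Wp <- glorot(in_ch, out_ch, c(out_ch, in_ch))
  ly$forward <- function(x, training = FALSE) {
    d <- dim(x)
    g <- conv1d_geometry(d[2], ly$kernel, 1L, "same")
    xp <- array(0, c(d[1], d[2] + g[2] + g[3], d[3]))
    xp[, g[2] + seq_len(d[2]), ] <- x
    yd <- array(0, d)
    for (j in seq_len(ly$kernel)) {
      yd <- yd + xp[, (seq_len(d[2]) - 1L) + j, , drop = FALSE] * ly$params$Wd[, j]
    }
    y <- array(ly$params$Wp %*% matrix(yd, d[1], d[2] * d[3]),
               c(ly$out_ch, d[2], d[3]))
    ly$cache <- list(xp = xp, yd = yd, d = d, g = g)
    y
  }
  ly$backward <- function(dy) {
    cc <- ly$cache; d <- cc$d
    dym <- matrix(dy, ly$out_ch, d[2] * d[3])
    ly$grads$Wp <- dym %*% t(matrix(cc$yd, d[1], d[2] * d[3]))
    dyd <- array(t(ly$params$Wp) %*% dym, d)
    dWd <- array(0, dim(ly$params$Wd))
    dxp <- array(0, dim(cc$xp))
    for (j in seq_len(ly$kernel)) {
      sl <- cc$xp[, (seq_len(d[2]) - 1L) + j, , drop = FALSE]
      dWd[, j] <- rowSums(matrix(dyd * sl, d[1]))
      dxp[, (seq_len(d[2]) - 1L) + j, ] <-
        dxp[, (seq_len(d[2]) - 1L) + j, , drop = FALSE] + dyd * ly$params$Wd[, j]
    }
    ly$grads$Wd <- dWd
    dxp[, cc$g[2] + seq_len(d[2]), , drop = FALSE]
  }
  ly
}

# ---- optimizer -------------------------------------------------------------

adam_new <- function(layers, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  st <- list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
             m = list(), v = list())
  for (i in seq_along(layers)) {
    for (nm in names(layers[[i]]$params)) {
      key <- paste0(i, ".", nm)
      st$m[[key]] <- array(0, dim(as.array(layers[[i]]$params[[nm]])))
      st$v[[key]] <- st$m[[key]]
    }
  }
  st
}

adam_step <- function(st, layers) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$beta1^st$t
  bc2 <- 1 - st$beta2^st$t
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    for (nm in names(ly$params)) {
      g <- ly$grads[[nm]]
      if (is.null(g)) next
      key <- paste0(i, ".", nm)
      st$m[[key]] <- st$beta1 * st$m[[key]] + (1 - st$beta1) * g
      st$v[[key]] <- st$beta2 * st$v[[key]] + (1 - st$beta2) * g^2
      upd <- st$lr * (st$m[[key]] / bc1) / (sqrt(st$v[[key]] / bc2) + st$eps)
      pnew <- ly$params[[nm]] - as.numeric(upd)
      dim(pnew) <- dim(ly$params[[nm]])
      ly$params[[nm]] <- pnew
    }
  }
  st
}

# ---- parameter bookkeeping -------------------------------------------------

snapshot_params <- function(layers) {
  lapply(layers, function(ly) {
    list(params = ly$params,
         running = if (ly$type == "batchnorm")
           list(mean = ly$running_mean, var = ly$running_var))
  })
}

restore_params <- function(layers, snap) {
  for (i in seq_along(layers)) {
    layers[[i]]$params <- snap[[i]]$params
    if (!is.null(snap[[i]]$running)) {
      layers[[i]]$running_mean <- snap[[i]]$running$mean
      layers[[i]]$running_var <- snap[[i]]$running$var
    }
  }
  invisible(layers)
}
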