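# Differentiable building blocks for the volumetric networks. Every op has a
# _fw returning (out, cache) and a _bw consuming (cache, gout). Volumetric
# activations are column-major arrays dim (X, Y, Z, C); channel matrices are
# views of shape (Nvox, C).

.as_mat <- function(x4) {
  d <- dim(x4)
  dim(x4) <- c(prod(d[1:3]), d[4])
  x4
}
.as_arr <- function(m, d3, C) {
  dim(m) <- c(d3, C)
  m
}

## -- 3D convolution (k x k x k, stride 1, zero same-padding) ----------------

conv_fw <- function(x4, W, b, k) {
  d <- dim(x4)
  if (k == 1L) {
    out <- .as_mat(x4) %*% W
    out <- out + rep(b, each = nrow(out))
    return(list(out = .as_arr(out, d[1:3], ncol(W)),
                cache = list(x = x4, k = 1L, d = d)))
  }
  fw <- conv3d_fw_cpp(x4, W, b, d[1], d[2], d[3], d[4], k)
  # keep the im2col matrix; the backward pass reuses it
  list(out = fw$out, cache = list(col = fw$col, k = k, d = d))
}

conv_bw <- function(cache, W, gout, need_xgrad = TRUE) {
  d <- cache$d
  if (cache$k == 1L) {
    gm <- .as_mat(gout)
    xm <- .as_mat(cache$x)
    res <- list(gW = crossprod(xm, gm), gb = colSums(gm))
    if (need_xgrad) res$gx <- .as_arr(gm %*% t(W), d[1:3], d[4])
    return(res)
  }
  conv3d_bw_cpp(cache$col, W, gout, d[1], d[2], d[3], d[4], cache$k,
                need_xgrad)
}

## -- batch normalization (batch of one volume; stats over voxels) -----------

# mode "sample": normalize with the current volume's statistics (used for
#   source training and test-time adaptation). mode "eval": use running stats.
bn_fw <- function(x4, gamma, beta, mode, run_mean, run_var,
                  eps = 1e-5, momentum = 0.1, update_running = FALSE) {
  d <- dim(x4)
  N <- prod(d[1:3])
  xm <- .as_mat(x4)
  if (mode == "sample") {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    v[v < 0] <- 0
  } else {
    mu <- run_mean
    v <- run_var
  }
  sig <- sqrt(v + eps)
  xhat <- (xm - rep(mu, each = N)) / rep(sig, each = N)
  out <- xhat * rep(gamma, each = N) + rep(beta, each = N)
  if (update_running && mode == "sample") {
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  }
  list(out = .as_arr(out, d[1:3], d[4]),
       cache = list(xhat = xhat, sig = sig, gamma = gamma, mode = mode,
                    d = d, N = N),
       run_mean = run_mean, run_var = run_var)
}

bn_bw <- function(cache, gout) {
  N <- cache$N
  gm <- .as_mat(gout)
  dgamma <- colSums(gm * cache$xhat)
  dbeta <- colSums(gm)
  scale <- cache$gamma / cache$sig
  if (cache$mode == "sample") {
    dx <- (gm - rep(dbeta / N, each = N) -
             cache$xhat * rep(dgamma / N, each = N)) * rep(scale, each = N)
  } else {
    dx <- gm * rep(scale, each = N)
  }
  list(gx = .as_arr(dx, cache$d[1:3], cache$d[4]),
       dgamma = dgamma, dbeta = dbeta)
}

## -- pointwise nonlinearities ----------------------------------------------

relu_fw <- function(x) {
  mask <- x > 0
  x[!mask] <- 0
  list(out = x, cache = mask)
}
relu_bw <- function(mask, gout) {
  gout[!mask] <- 0
  gout
}

sigmoid_fw <- function(x) {
  s <- 1 / (1 + exp(-x))
  list(out = s, cache = s)
}
sigmoid_bw <- function(s, gout) gout * s * (1 - s)

## -- resolution changes (factor-2, extents must be even for pooling) --------

avgpool2_fw <- function(x4) {
  d <- dim(x4)
  ix <- seq(1L, d[1], 2L); iy <- seq(1L, d[2], 2L); iz <- seq(1L, d[3], 2L)
  out <- array(0, c(length(ix), length(iy), length(iz), d[4]))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    out <- out + x4[ix + dx, iy + dy, iz + dz, , drop = FALSE]
  }
  list(out = out / 8, cache = d)
}
avgpool2_bw <- function(d_in, gout) {
  up <- upsample2_fw(gout)$out
  up / 8
}

upsample2_fw <- function(x4) {
  d <- dim(x4)
  ix <- rep(seq_len(d[1]), each = 2L)
  iy <- rep(seq_len(d[2]), each = 2L)
  iz <- rep(seq_len(d[3]), each = 2L)
  list(out = x4[ix, iy, iz, , drop = FALSE], cache = d)
}
upsample2_bw <- function(d_in, gout) {
  avgpool2_fw(gout)$out * 8
}

## -- sub-band attention (squeeze-excite over the 8 wavelet channels) --------

# bands4: (X, Y, Z, C) stack of sub-bands; params: W1 (Cr x C), b1, W2 (C x Cr),
# b2. Global average pool -> FC reduce -> ReLU -> FC expand -> sigmoid gate.
sa_fw <- function(bands4, p, override = NULL) {
  d <- dim(bands4)
  N <- prod(d[1:3])
  s <- colMeans(.as_mat(bands4))
  z1pre <- as.vector(p$W1 %*% s + p$b1)
  z1 <- pmax(z1pre, 0)
  apre <- as.vector(p$W2 %*% z1 + p$b2)
  a <- 1 / (1 + exp(-apre))
  a_used <- if (is.null(override)) a else rep(override, d[4])
  out <- bands4 * rep(a_used, each = N)
  list(out = out, weights = a_used,
       cache = list(bands = bands4, s = s, z1 = z1, z1pre = z1pre, a = a,
                    overridden = !is.null(override), d = d, N = N))
}

sa_bw <- function(cache, p, gout) {
  if (cache$overridden) {
    zero <- list(dW1 = p$W1 * 0, db1 = p$b1 * 0, dW2 = p$W2 * 0, db2 = p$b2 * 0)
    return(zero)
  }
  N <- cache$N
  da <- colSums(.as_mat(gout) * .as_mat(cache$bands))
  dapre <- da * cache$a * (1 - cache$a)
  dW2 <- outer(dapre, cache$z1)
  db2 <- dapre
  dz1 <- as.vector(t(p$W2) %*% dapre)
  dz1[cache$z1pre <= 0] <- 0
  dW1 <- outer(dz1, cache$s)
  db1 <- dz1
  list(dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

## -- channel concatenation --------------------------------------------------

concat_fw <- function(a4, b4) {
  da <- dim(a4); db <- dim(b4)
  stopifnot(all(da[1:3] == db[1:3]))
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a4
  out[, , , da[4] + seq_len(db[4])] <- b4
  list(out = out, cache = c(da[4], db[4]))
}
concat_bw <- function(split, gout) {
  list(ga = gout[, , , seq_len(split[1]), drop = FALSE],
       gb = gout[, , , split[1] + seq_len(split[2]), drop = FALSE])
}
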