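# Minimal CNN engine on H x W lattices.
#
# Feature maps are (H*W) x C matrices in column-major cell order
# (pos = r + (c-1)*H). Convolutions use im2col gathers against a padded
# row so all heavy lifting is BLAS matmul; every layer has an exact manual
# backward pass (verified against finite differences in the test suite).

# Gather table for a k x k stencil: N x k^2 matrix of input cell indices,
# with N+1 denoting the padding cell.
conv_index <- function(H, W, k) {
  pad <- (k - 1L) %/% 2L
  N <- H * W
  r <- rep.int(seq_len(H), W)
  c_ <- rep(seq_len(W), each = H)
  idx <- matrix(N + 1L, N, k * k)
  t_ <- 0L
  for (dc in -pad:pad) for (dr in -pad:pad) {
    t_ <- t_ + 1L
    rr <- r + dr; cc <- c_ + dc
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    idx[ok, t_] <- rr[ok] + (cc[ok] - 1L) * H
  }
  idx
}

im2col <- function(X, idx, pad_value = 0) {
  C <- ncol(X)
  Xaug <- rbind(X, rep(pad_value, C))
  k2 <- ncol(idx)
  out <- matrix(0, nrow(idx), k2 * C)
  for (t_ in seq_len(k2))
    out[, ((t_ - 1L) * C + 1L):(t_ * C)] <- Xaug[idx[, t_], , drop = FALSE]
  out
}

# fan-in uniform initialisation, as used by the unsupervised-segmentation CNNs
init_conv <- function(c_in, c_out, k) {
  fan_in <- k * k * c_in
  bound <- 1 / sqrt(fan_in)
  list(W = matrix(stats::runif(fan_in * c_out, -bound, bound), fan_in, c_out),
       b = stats::runif(c_out, -bound, bound),
       k = k, c_in = c_in, c_out = c_out)
}

conv_forward <- function(X, layer, idx) {
  if (layer$k == 1L) {
    Y <- X %*% layer$W
    cache <- list(Xp = X, k = 1L)
  } else {
    Xp <- im2col(X, idx)
    Y <- Xp %*% layer$W
    cache <- list(Xp = Xp, k = layer$k, idx = idx, c_in = layer$c_in)
  }
  Y <- sweep(Y, 2L, layer$b, `+`)
  list(Y = Y, cache = cache)
}

conv_backward <- function(dY, layer, cache) {
  grad <- list(W = crossprod(cache$Xp, dY), b = colSums(dY))
  if (cache$k == 1L) {
    dX <- dY %*% t(layer$W)
  } else {
    dXp <- dY %*% t(layer$W)
    N <- nrow(dY); C <- cache$c_in; k2 <- cache$k^2
    # scatter-add of stencil offset t is a gather under the mirrored offset
    # k2 + 1 - t (stencil enumeration is centrally symmetric)
    dXpAug <- rbind(dXp, rep(0, ncol(dXp)))
    dX <- matrix(0, N, C)
    for (t_ in seq_len(k2)) {
      rows <- cache$idx[, k2 + 1L - t_]
      dX <- dX + dXpAug[rows, ((t_ - 1L) * C + 1L):(t_ * C), drop = FALSE]
    }
  }
  list(dX = dX, grad = grad)
}

init_bn <- function(C) list(g = rep(1, C), b = rep(0, C), C = C)

bn_forward <- function(X, layer, eps = 1e-5) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  v <- colMeans(Xc * Xc)
  inv_sd <- 1 / sqrt(v + eps)
  Xhat <- sweep(Xc, 2L, inv_sd, `*`)
  Y <- sweep(sweep(Xhat, 2L, layer$g, `*`), 2L, layer$b, `+`)
  list(Y = Y, cache = list(Xhat = Xhat, inv_sd = inv_sd))
}

bn_backward <- function(dY, layer, cache) {
  N <- nrow(dY)
  Xhat <- cache$Xhat
  grad <- list(g = colSums(dY * Xhat), b = colSums(dY))
  dXhat <- sweep(dY, 2L, layer$g, `*`)
  # dX = inv_sd/N * (N*dXhat - sum(dXhat) - Xhat * sum(dXhat*Xhat))
  s1 <- colSums(dXhat)
  s2 <- colSums(dXhat * Xhat)
  dX <- sweep(N * dXhat, 2L, s1) - sweep(Xhat, 2L, s2, `*`)
  dX <- sweep(dX, 2L, cache$inv_sd / N, `*`)
  list(dX = dX, grad = grad)
}

relu_forward <- function(X) {
  M <- X > 0
  list(Y = X * M, cache = M)
}

relu_backward <- function(dY, cache) dY * cache

maxpool_forward <- function(X, idx) {
  N <- nrow(X); C <- ncol(X)
  Xaug <- rbind(X, rep(-Inf, C))
  M <- Xaug[idx[, 1L], , drop = FALSE]
  arg <- matrix(1L, N, C)
  for (t_ in 2:ncol(idx)) {
    cand <- Xaug[idx[, t_], , drop = FALSE]
    upd <- cand > M
    M[upd] <- cand[upd]
    arg[upd] <- t_
  }
  list(Y = M, cache = list(arg = arg, idx = idx, N = N, C = C))
}

maxpool_backward <- function(dY, cache) {
  dX <- matrix(0, cache$N, cache$C)
  for (t_ in seq_len(ncol(cache$idx))) {
    sel <- cache$arg == t_
    if (!any(sel)) next
    rows <- cache$idx[, t_]
    ok <- rows <= cache$N
    Z <- dY * sel
    dX[rows[ok], ] <- dX[rows[ok], , drop = FALSE] + Z[ok, , drop = FALSE]
  }
  dX
}

row_softmax <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}
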