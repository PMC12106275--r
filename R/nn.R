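# Minimal trainable 3D network primitives built on BLAS matrix products.
# Activations are stored as arrays of dim (voxels, batch, channels), voxels
# linearised column-major from the (height, width, depth) grid. Convolutions
# use an im2col gather (27 taps for a 3x3x3 kernel) followed by one GEMM;
# backward passes are the exact adjoints.

.nn_cache <- new.env(parent = emptyenv())

# index matrix (v_out x 27) gathering the 3x3x3 neighbourhood of every
# output voxel; out-of-range taps point at the sentinel row v_in + 1
conv3_index <- function(d3, stride) {
  key <- paste(c(d3, stride), collapse = "x")
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  h <- d3[1L]; w <- d3[2L]; d <- d3[3L]
  pad <- 1L; k <- 3L
  odim <- (d3 + 2L * pad - k) %/% stride + 1L
  oh <- odim[1L]; ow <- odim[2L]; od <- odim[3L]
  vout <- oh * ow * od
  sentinel <- h * w * d + 1L
  IDX <- matrix(0L, vout, 27L)
  t <- 0L
  for (dl in 0:2) for (dj in 0:2) for (di in 0:2) {
    t <- t + 1L
    ii <- stride * (seq_len(oh) - 1L) + di - pad + 1L
    jj <- stride * (seq_len(ow) - 1L) + dj - pad + 1L
    ll <- stride * (seq_len(od) - 1L) + dl - pad + 1L
    I1 <- rep(ii, times = ow * od)
    I2 <- rep(rep(jj, each = oh), times = od)
    I3 <- rep(ll, each = oh * ow)
    bad <- I1 < 1L | I1 > h | I2 < 1L | I2 > w | I3 < 1L | I3 > d
    lin <- I1 + (I2 - 1L) * h + (I3 - 1L) * h * w
    lin[bad] <- sentinel
    IDX[, t] <- lin
  }
  res <- list(idx = IDX, odim = odim, vout = vout)
  .nn_cache[[key]] <- res
  res
}

conv3_init <- function(cin, cout, k = 3L) {
  # Kaiming fan-out initialisation for ReLU networks
  sd <- sqrt(2 / (k^3 * cout))
  matrix(stats::rnorm(k^3 * cin * cout, sd = sd), k^3 * cin, cout)
}

# x: (v, N, C_in); returns list(out = (v_out, N, C_out), cache).
# im2col: one gather over all 27 taps, reordered to (vout*N) x (27*C) so a
# single GEMM against the (27*C) x C_out weight matrix gives the output.
conv3_forward <- function(x, d3, W, stride = 1L, keep_cache = TRUE) {
  dd <- dim(x); v <- dd[1L]; N <- dd[2L]; C <- dd[3L]
  ci <- conv3_index(d3, stride)
  Xz <- matrix(0, v + 1L, N * C)
  Xz[seq_len(v), ] <- x
  G <- Xz[as.vector(ci$idx), , drop = FALSE]   # (vout*27) x (N*C)
  dim(G) <- c(ci$vout, 27L, N, C)
  G <- aperm(G, c(1L, 3L, 2L, 4L))
  dim(G) <- c(ci$vout * N, 27L * C)
  out <- G %*% W
  dim(out) <- c(ci$vout, N, ncol(W))
  cache <- if (keep_cache) list(G = G, d3 = d3, stride = stride, v = v,
                                N = N, C = C, W = W) else NULL
  list(out = out, d3 = ci$odim, cache = cache)
}

conv3_backward <- function(cache, grad_out) {
  ci <- conv3_index(cache$d3, cache$stride)
  N <- cache$N; C <- cache$C
  go <- matrix(grad_out, ci$vout * N, dim(grad_out)[3L])
  gW <- crossprod(cache$G, go)
  S <- tcrossprod(go, cache$W)                 # (vout*N) x (27*C)
  dim(S) <- c(ci$vout, N, 27L, C)
  S <- aperm(S, c(1L, 3L, 2L, 4L))
  dim(S) <- c(ci$vout * 27L, N * C)
  gx <- rowsum(S, as.vector(ci$idx))           # accumulate per input voxel
  keep <- as.integer(rownames(gx))
  gXz <- matrix(0, cache$v + 1L, N * C)
  gXz[keep, ] <- gx
  gx <- gXz[seq_len(cache$v), , drop = FALSE]
  dim(gx) <- c(cache$v, N, C)
  list(gW = gW, gx = gx)
}

# conv with 1x1x1 kernel (channel projection), optional spatial stride via
# subsampling is not needed: projections always follow a DWT/strided step
conv1_init <- function(cin, cout) {
  matrix(stats::rnorm(cin * cout, sd = sqrt(2 / cout)), cin, cout)
}

conv1_forward <- function(x, W) {
  dd <- dim(x)
  out <- matrix(x, dd[1L] * dd[2L], dd[3L]) %*% W
  dim(out) <- c(dd[1L], dd[2L], ncol(W))
  out
}

conv1_backward <- function(x, W, grad_out) {
  dd <- dim(x)
  go <- matrix(grad_out, dd[1L] * dd[2L], ncol(W))
  xm <- matrix(x, dd[1L] * dd[2L], dd[3L])
  gx <- tcrossprod(go, W)
  dim(gx) <- dd
  list(gW = crossprod(xm, go), gx = gx)
}

bn_init <- function(C) {
  list(gamma = rep(1, C), beta = rep(0, C),
       run_mean = rep(0, C), run_var = rep(1, C))
}

bn_forward <- function(x, bn, training, momentum = 0.1, eps = 1e-5) {
  dd <- dim(x); M <- dd[1L] * dd[2L]; C <- dd[3L]
  xm <- matrix(x, M, C)
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm * xm) - mu^2
    bn$run_mean <- (1 - momentum) * bn$run_mean + momentum * mu
    bn$run_var <- (1 - momentum) * bn$run_var + momentum * va
  } else {
    mu <- bn$run_mean
    va <- bn$run_var
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- (xm - rep(mu, each = M)) * rep(istd, each = M)
  out <- xhat * rep(bn$gamma, each = M) + rep(bn$beta, each = M)
  dim(out) <- dd
  list(out = out, bn = bn,
       cache = if (training) list(xhat = xhat, istd = istd, M = M, dd = dd))
}

bn_backward <- function(bn, cache, grad_out) {
  M <- cache$M; dd <- cache$dd
  go <- matrix(grad_out, M, dd[3L])
  dgamma <- colSums(go * cache$xhat)
  dbeta <- colSums(go)
  dxhat <- go * rep(bn$gamma, each = M)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  gx <- (dxhat - rep(s1 / M, each = M) -
           cache$xhat * rep(s2 / M, each = M)) * rep(cache$istd, each = M)
  dim(gx) <- dd
  list(dgamma = dgamma, dbeta = dbeta, gx = gx)
}

relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, mask = mask)
}

dwt_low_mats <- function(bank, d3) {
  bank <- get_filter_bank(bank)
  lapply(d3, function(m) {
    key <- paste0("dwtL:", bank$name, ":", m)
    hit <- .nn_cache[[key]]
    if (is.null(hit)) {
      hit <- build_dwt_matrices(bank, m)$L
      .nn_cache[[key]] <- hit
    }
    hit
  })
}

# low-pass DWT of every channel of a (v, N, C) activation. The three axis
# transforms commute, so they are ordered to need only two aperm passes:
# height by left-multiplication, then width by left-multiplication and
# depth by right-multiplication after one permutation.
nn_dwt_low <- function(x, d3, bank) {
  dd <- dim(x); N <- dd[2L]; C <- dd[3L]; q <- N * C
  h <- d3[1L]; w <- d3[2L]; d <- d3[3L]
  mats <- dwt_low_mats(bank, d3)
  h2 <- h %/% 2L; w2 <- w %/% 2L; dp2 <- d %/% 2L
  X <- mats[[1L]] %*% matrix(x, h, w * d * q)
  dim(X) <- c(h2, w, d, q)
  X <- aperm(X, c(2L, 4L, 1L, 3L))             # (w, q, h2, d)
  X <- mats[[2L]] %*% matrix(X, w, q * h2 * d)
  dim(X) <- c(w2 * q * h2, d)
  X <- X %*% t(mats[[3L]])
  dim(X) <- c(w2, q, h2, dp2)
  X <- aperm(X, c(3L, 1L, 4L, 2L))             # (h2, w2, d2, q)
  dim(X) <- c(h2 * w2 * dp2, N, C)
  list(out = X, d3 = c(h2, w2, dp2))
}

# adjoint of nn_dwt_low (gradient propagation)
nn_dwt_low_backward <- function(grad_out, d3_in, bank) {
  dd <- dim(grad_out); N <- dd[2L]; C <- dd[3L]; q <- N * C
  h <- d3_in[1L]; w <- d3_in[2L]; d <- d3_in[3L]
  h2 <- h %/% 2L; w2 <- w %/% 2L; dp2 <- d %/% 2L
  mats <- dwt_low_mats(bank, d3_in)
  X <- array(grad_out, c(h2, w2, dp2, q))
  X <- aperm(X, c(2L, 4L, 1L, 3L))             # (w2, q, h2, d2)
  dim(X) <- c(w2 * q * h2, dp2)
  X <- X %*% mats[[3L]]                        # adjoint of right-mult by t(L)
  dim(X) <- c(w2, q * h2 * d)
  X <- t(mats[[2L]]) %*% X
  dim(X) <- c(w, q, h2, d)
  X <- aperm(X, c(3L, 1L, 4L, 2L))             # (h2, w, d, q)
  X <- t(mats[[1L]]) %*% matrix(X, h2, w * d * q)
  dim(X) <- c(h * w * d, N, C)
  X
}

gap_forward <- function(x) {
  dd <- dim(x)
  z <- colMeans(matrix(x, dd[1L], dd[2L] * dd[3L]))
  matrix(z, dd[2L], dd[3L])  # N x C
}

gap_backward <- function(dz, v) {
  # expand dz (N x C) to (v, N, C), dividing by the pooled voxel count
  dd <- dim(dz)
  out <- array(0, c(v, dd[1L], dd[2L]))
  out[] <- rep(dz / v, each = v)
  out
}

sgd_step <- function(param, grad, buf, lr, momentum, weight_decay) {
  g <- grad + weight_decay * param
  buf <- momentum * buf + g
  list(param = param - lr * buf, buf = buf)
}
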