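# Dense-tensor layer primitives with hand-written backward passes.
#
# Activations are 4-d arrays laid out [H, W, N, C] (row, column, batch,
# channel).  With channels last, a flattened activation IS the
# (H*W*N) x C matrix that BLAS consumes, so convolutions (im2col + one
# GEMM), batch norm and pooling run without aperm copies.  Gather
# indices for im2col are precomputed per shape (including batch size)
# and cached.  Every forward returns list(out, cache); every backward
# takes (cache, d_out) and returns the input gradient plus parameter
# gradients.

im2col_cache <- new.env(parent = emptyenv())

# linear gather indices into a zero-padded batch array [Hp, Wp, N, C]:
# rows = output pixel (i fastest, then j, then n); cols = offset (a, b, c)
im2col_idx <- function(H, W, N, C, k, pad) {
  key <- paste(H, W, N, C, k, pad, sep = "_")
  idx <- im2col_cache[[key]]
  if (!is.null(idx)) return(idx)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  pix <- as.vector(outer(0:(H - 1L), (0:(W - 1L)) * Hp, "+"))
  pixn <- as.vector(outer(pix, (0:(N - 1L)) * (Hp * Wp), "+"))
  off <- as.vector(outer(as.vector(outer(0:(k - 1L), (0:(k - 1L)) * Hp, "+")),
                         (0:(C - 1L)) * (Hp * Wp * N), "+"))
  idx <- outer(pixn, off, "+") + 1L
  im2col_cache[[key]] <- idx
  idx
}

pad_input <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

# patch matrix for a batch: (H*W*N) x (k*k*C), one cached gather
im2col <- function(x, k, pad) {
  d <- dim(x)
  if (k == 1L && pad == 0L) {
    dim(x) <- c(d[1] * d[2] * d[3], d[4])
    return(x)
  }
  xp <- pad_input(x, pad)
  idx <- im2col_idx(d[1], d[2], d[3], d[4], k, pad)
  out <- xp[idx]
  dim(out) <- dim(idx)
  out
}

add_bias_cols <- function(y, b) y + rep(b, each = nrow(y))

# W: (k*k*Cin) x Cout matrix; b: length Cout
conv2d_forward <- function(x, W, b, k, pad) {
  d <- dim(x)
  col <- im2col(x, k, pad)
  y <- add_bias_cols(col %*% W, b)
  dim(y) <- c(d[1], d[2], d[3], length(b))
  list(out = y, cache = list(col = col, W = W, k = k, pad = pad,
                             dims = d, cout = length(b)))
}

conv2d_backward <- function(cache, dy, need_dx = TRUE) {
  d <- cache$dims; Cin <- d[4]
  k <- cache$k; cout <- cache$cout
  dym <- dy
  dim(dym) <- c(d[1] * d[2] * d[3], cout)
  dW <- crossprod(cache$col, dym)
  db <- colSums(dym)
  dx <- NULL
  if (need_dx) {
    # input gradient = convolution of dy with the flipped kernel
    Warr <- array(cache$W, c(k, k, Cin, cout))
    if (k > 1L) Warr <- Warr[k:1, k:1, , , drop = FALSE]
    Wrot <- matrix(aperm(Warr, c(1, 2, 4, 3)), nrow = k * k * cout)
    dxm <- im2col(dy, k, k - 1L - cache$pad) %*% Wrot
    dim(dxm) <- d
    dx <- dxm
  }
  list(dx = dx, dW = dW, db = db)
}

# transposed convolution, kernel 2x2, stride 2 (doubles H and W)
# Wt: Cin x (2*2*Cout) with column order (a, b, cout), a fastest
tconv2_forward <- function(x, Wt, b) {
  d <- dim(x); h <- d[1]; w <- d[2]; N <- d[3]; Cin <- d[4]
  cout <- length(b)
  xm <- x
  dim(xm) <- c(h * w * N, Cin)
  y <- xm %*% Wt
  arr <- array(y, c(h, w, N, 2, 2, cout))
  out <- aperm(arr, c(4, 1, 5, 2, 3, 6))
  dim(out) <- c(2L * h, 2L * w, N, cout)
  out <- add_bias_cols(matrix_view(out), b)
  dim(out) <- c(2L * h, 2L * w, N, cout)
  list(out = out, cache = list(xm = xm, Wt = Wt, dims = d, cout = cout))
}

matrix_view <- function(x) {
  d <- dim(x)
  dim(x) <- c(prod(d) / d[length(d)], d[length(d)])
  x
}

tconv2_backward <- function(cache, dy) {
  d <- cache$dims; h <- d[1]; w <- d[2]; N <- d[3]; Cin <- d[4]
  cout <- cache$cout
  db <- colSums(matrix_view(dy))
  dim(dy) <- c(2L, h, 2L, w, N, cout)
  darr <- aperm(dy, c(2, 4, 5, 1, 3, 6))                  # h,w,N,a,b,co
  dym <- matrix(darr, nrow = h * w * N)
  dWt <- crossprod(cache$xm, dym)
  dxm <- dym %*% t(cache$Wt)
  dim(dxm) <- d
  list(dx = dxm, dW = dWt, db = db)
}

maxpool2_forward <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  i1 <- seq(1L, H, 2L); i2 <- seq(2L, H, 2L)
  j1 <- seq(1L, W, 2L); j2 <- seq(2L, W, 2L)
  x11 <- x[i1, j1, , , drop = FALSE]; x21 <- x[i2, j1, , , drop = FALSE]
  x12 <- x[i1, j2, , , drop = FALSE]; x22 <- x[i2, j2, , , drop = FALSE]
  y <- pmax(x11, x21, x12, x22)
  m11 <- x11 == y
  m21 <- (x21 == y) & !m11
  m12 <- (x12 == y) & !(m11 | m21)
  m22 <- !(m11 | m21 | m12)
  list(out = y, cache = list(m = list(m11, m21, m12, m22), dims = d))
}

maxpool2_backward <- function(cache, dy) {
  d <- cache$dims; H <- d[1]; W <- d[2]
  i1 <- seq(1L, H, 2L); i2 <- seq(2L, H, 2L)
  j1 <- seq(1L, W, 2L); j2 <- seq(2L, W, 2L)
  dx <- array(0, d)
  m <- cache$m
  dx[i1, j1, , ] <- dy * m[[1]]
  dx[i2, j1, , ] <- dy * m[[2]]
  dx[i1, j2, , ] <- dy * m[[3]]
  dx[i2, j2, , ] <- dy * m[[4]]
  dx
}

relu_forward <- function(x) {
  out <- pmax(x, 0)
  list(out = out, cache = x > 0)
}
relu_backward <- function(cache, dy) dy * cache

# batch normalization over (H, W, N) per channel; training mode uses
# batch statistics (population variance, eps-stabilized)
batchnorm_forward <- function(x, gamma, beta, eps = 1e-5, training = TRUE,
                              running = NULL, momentum = 0.1) {
  d <- dim(x); C <- d[4]; M <- d[1] * d[2] * d[3]
  xm <- x
  dim(xm) <- c(M, C)
  if (training) {
    mu <- colMeans(xm)
    vr <- colMeans(xm * xm) - mu * mu
  } else if (is.null(running)) {
    mu <- rep(0, C); vr <- rep(1, C)   # untrained: identity statistics
  } else {
    mu <- running$mean; vr <- running$var
  }
  inv_sd <- 1 / sqrt(vr + eps)
  xhat <- (xm - rep(mu, each = M)) * rep(inv_sd, each = M)
  ym <- xhat * rep(gamma, each = M) + rep(beta, each = M)
  dim(ym) <- d
  new_running <- NULL
  if (training) {
    if (is.null(running)) running <- list(mean = mu * 0, var = mu * 0 + 1)
    new_running <- list(mean = (1 - momentum) * running$mean + momentum * mu,
                        var  = (1 - momentum) * running$var + momentum * vr)
  }
  list(out = ym,
       cache = list(xhat = xhat, inv_sd = inv_sd, gamma = gamma, dims = d),
       running = new_running)
}

batchnorm_backward <- function(cache, dy) {
  d <- cache$dims; C <- d[4]; M <- d[1] * d[2] * d[3]
  dym <- dy
  dim(dym) <- c(M, C)
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- dym * rep(cache$gamma, each = M)
  t1 <- dxhat - rep(colMeans(dxhat), each = M)
  t2 <- xhat * rep(colMeans(dxhat * xhat), each = M)
  dxm <- (t1 - t2) * rep(cache$inv_sd, each = M)
  dim(dxm) <- d
  list(dx = dxm, dgamma = dgamma, dbeta = dbeta)
}

dense_forward <- function(x, W, b) {
  y <- add_bias_cols(x %*% W, b)
  list(out = y, cache = list(x = x, W = W))
}
dense_backward <- function(cache, dy) {
  list(dx = dy %*% t(cache$W), dW = crossprod(cache$x, dy), db = colSums(dy))
}

# global average pool: [H,W,N,C] -> N x C
gap_forward <- function(x) {
  d <- dim(x); hw <- d[1] * d[2]
  xm <- x
  dim(xm) <- c(hw * d[3], d[4])
  y <- rowsum(xm, rep(seq_len(d[3]), each = hw)) / hw
  rownames(y) <- NULL
  list(out = y, cache = d)
}
gap_backward <- function(cache, dy) {
  d <- cache; hw <- d[1] * d[2]
  dxm <- dy[rep(seq_len(d[3]), each = hw), , drop = FALSE] / hw
  dim(dxm) <- d
  dxm
}

# inverted dropout; mask drawn from the current RNG stream
dropout_forward <- function(x, rate, training = TRUE) {
  if (!training || rate <= 0) return(list(out = x, cache = NULL))
  keep <- (array(stats::runif(length(x)), dim(x) %||% length(x)) >= rate) /
    (1 - rate)
  list(out = x * keep, cache = keep)
}
dropout_backward <- function(cache, dy) if (is.null(cache)) dy else dy * cache

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

gelu_forward <- function(x) {
  list(out = x * stats::pnorm(x), cache = x)
}
gelu_backward <- function(cache, dy) {
  dy * (stats::pnorm(cache) + cache * stats::dnorm(cache))
}
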