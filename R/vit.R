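# Transformer primitives for the TransUNet-style segmentation head:
# patch embedding, positional encoding, scaled dot-product attention,
# multi-head self-attention, token-wise feed-forward net, layer norm.
#
# Public operations work on a TokenSequence: list(tokens = N x D matrix,
# D, pe_applied).  Patches are taken in row-major order (left-to-right,
# top-to-bottom), token indices 0-based for positional encoding.

#' Split an image into non-overlapping square patches
#'
#' Divides an H x W x C image into N = (H*W)/(P*P) patches of side `P`,
#' flattening each patch to a vector of length P*P*C.  Patches are ordered
#' row-major.  Dimensions must be divisible by `P`; no implicit padding.
#'
#' @param image Numeric H x W matrix or H x W x C array.
#' @param P Patch side in pixels.
#' @return list(patches = N x (P*P*C) matrix, grid = list(H, W, C, P, N)).
#' @export
patchify <- function(image, P) {
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
  d <- dim(image)
  if (length(d) != 3) stop_invalid("image must be H x W or H x W x C")
  H <- d[1]; W <- d[2]; C <- d[3]
  if (H %% P != 0 || W %% P != 0)
    stop_invalid("image dimensions (%d x %d) not divisible by patch size %d",
                 H, W, P)
  nr <- H %/% P; nc <- W %/% P; N <- nr * nc
  # reshape [P, nr, P, nc, C] -> rows (patch r, patch c) row-major
  arr <- array(image, c(P, nr, P, nc, C))
  arr <- aperm(arr, c(1, 3, 5, 4, 2))      # P, P, C, nc, nr
  patches <- t(matrix(arr, nrow = P * P * C))
  # rows currently ordered nc fastest then nr -> row-major patch order
  list(patches = patches, grid = list(H = H, W = W, C = C, P = P, N = N))
}

#' Reassemble an image from its patch matrix
#'
#' Inverse of [patchify()]: `unpatchify(patchify(x, P))` returns `x`.
#'
#' @param patches N x (P*P*C) matrix in row-major patch order.
#' @param grid Grid descriptor as returned by [patchify()].
#' @return H x W x C array.
#' @export
unpatchify <- function(patches, grid) {
  P <- grid$P; C <- grid$C; nr <- grid$H %/% P; nc <- grid$W %/% P
  arr <- array(t(patches), c(P, P, C, nc, nr))
  arr <- aperm(arr, c(1, 2, 5, 4, 3))      # P, P, nr, nc, C -> regroup
  arr <- aperm(arr, c(1, 3, 2, 4, 5))      # P, nr, P, nc, C
  array(arr, c(grid$H, grid$W, C))
}

#' Project flattened patches to D-dimensional tokens
#'
#' Applies a linear projection to each patch row, producing one token per
#' patch.  The result carries `pe_applied = FALSE` until positional
#' encoding is added.
#'
#' @param patches N x L matrix of flattened patches.
#' @param projection L x D projection matrix, or list(W =, b =) with an
#'   optional length-D offset.
#' @return TokenSequence: list(tokens = N x D matrix, D, pe_applied).
#' @export
embed_patches <- function(patches, projection) {
  if (is.list(projection)) { W <- projection$W; b <- projection$b }
  else { W <- projection; b <- NULL }
  if (ncol(patches) != nrow(W))
    stop_invalid("projection expects length-%d patches, got %d",
                 nrow(W), ncol(patches))
  tokens <- patches %*% W
  if (!is.null(b)) tokens <- sweep(tokens, 2, b, "+")
  list(tokens = tokens, D = ncol(W), pe_applied = FALSE)
}

#' Sinusoidal positional encoding table
#'
#' Standard fixed encoding: for 0-based position i and dimension pair k,
#' PE[i, 2k] = sin(i / 10000^(2k/D)) and PE[i, 2k+1] = cos(...).
#'
#' @param N Number of tokens.
#' @param D Embedding dimension.
#' @return N x D matrix.
#' @export
sinusoidal_pe <- function(N, D) {
  pos <- 0:(N - 1)
  pe <- matrix(0, N, D)
  for (k in 0:(ceiling(D / 2) - 1)) {
    freq <- 1 / 10000^(2 * k / D)
    pe[, 2 * k + 1] <- sin(pos * freq)
    if (2 * k + 2 <= D) pe[, 2 * k + 2] <- cos(pos * freq)
  }
  pe
}

#' Add positional encoding to a token sequence
#'
#' Token i becomes x_i + PE(i).  Applying the encoding twice is an error.
#' `mode = "none"` disables the encoding (PE identically 0), which makes
#' attention permutation-equivariant.
#'
#' @param seq TokenSequence from [embed_patches()].
#' @param mode "sinusoidal" (default), "none", or "table".
#' @param table Optional N x D table when `mode = "table"` (e.g. learned).
#' @return TokenSequence with `pe_applied = TRUE`.
#' @export
add_positional_encoding <- function(seq, mode = c("sinusoidal", "none", "table"),
                                    table = NULL) {
  mode <- match.arg(mode)
  if (isTRUE(seq$pe_applied))
    stop("positional encoding already applied", call. = FALSE)
  pe <- switch(mode,
               sinusoidal = sinusoidal_pe(nrow(seq$tokens), seq$D),
               none = 0,
               table = {
                 stopifnot(!is.null(table))
                 table
               })
  seq$tokens <- seq$tokens + pe
  seq$pe_applied <- TRUE
  seq
}

#' Scaled dot-product attention
#'
#' Attention(Q, K, V) = softmax(Q K^T / sqrt(d_k)) V, with the softmax
#' taken over each row of the score matrix.
#'
#' @param Q,K N x d_k query and key matrices.
#' @param V N x d_v value matrix.
#' @return list(out = N x d_v matrix, weights = N x N attention matrix).
#' @export
scaled_dot_attention <- function(Q, K, V) {
  if (ncol(Q) == 0) stop_invalid("d_k must be positive")
  if (ncol(Q) != ncol(K) || nrow(K) != nrow(V))
    stop_invalid("incompatible Q/K/V dimensions")
  S <- tcrossprod(Q, K) / sqrt(ncol(Q))
  P <- softmax_rows(S)
  list(out = P %*% V, weights = P)
}

#' Multi-head self-attention over a token sequence
#'
#' Runs `n_heads` scaled dot-product attentions in parallel on per-head
#' query/key/value projections of the tokens, concatenates the head
#' outputs in head order, and applies a final linear projection back to D.
#'
#' @param seq TokenSequence (or bare N x D token matrix).
#' @param cfg list(n_heads, head_dim, D) with D = n_heads * head_dim.
#' @param proj list(Wq, Wk, Wv = lists of D x head_dim matrices, one per
#'   head; Wo = (n_heads*head_dim) x D output projection; bo optional).
#' @return TokenSequence with attended tokens.
#' @export
multi_head_attention <- function(seq, cfg, proj) {
  tokens <- if (is.list(seq)) seq$tokens else seq
  validate_attention_cfg(cfg)
  if (ncol(tokens) != cfg$D)
    stop_invalid("token dimension %d != cfg D %d", ncol(tokens), cfg$D)
  f <- mhsa_forward(tokens, cfg, proj)
  out <- list(tokens = f$out, D = cfg$D,
              pe_applied = if (is.list(seq)) seq$pe_applied else NA)
  out
}

validate_attention_cfg <- function(cfg) {
  if (cfg$n_heads < 1 || cfg$head_dim < 1)
    stop_invalid("n_heads and head_dim must be positive")
  if (cfg$D != cfg$n_heads * cfg$head_dim)
    stop_invalid("D (%d) must equal n_heads * head_dim (%d)",
                 cfg$D, cfg$n_heads * cfg$head_dim)
  invisible(cfg)
}

mhsa_forward <- function(X, cfg, proj) {
  H <- cfg$n_heads; dk <- cfg$head_dim
  if (nrow(proj$Wo) != H * dk || ncol(proj$Wo) != cfg$D)
    stop_invalid("output projection must be (n_heads*head_dim) x D")
  U <- matrix(0, nrow(X), H * dk)
  hc <- vector("list", H)
  for (h in seq_len(H)) {
    Wq <- proj$Wq[[h]]; Wk <- proj$Wk[[h]]; Wv <- proj$Wv[[h]]
    if (nrow(Wq) != cfg$D || ncol(Wq) != dk)
      stop_invalid("head %d projection must be D x head_dim", h)
    Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
    S <- tcrossprod(Q, K) / sqrt(dk)
    P <- softmax_rows(S)
    U[, (h - 1L) * dk + seq_len(dk)] <- P %*% V
    hc[[h]] <- list(Q = Q, K = K, V = V, P = P)
  }
  out <- U %*% proj$Wo
  if (!is.null(proj$bo)) out <- sweep(out, 2, proj$bo, "+")
  list(out = out, cache = list(X = X, U = U, heads = hc, cfg = cfg,
                               proj = proj))
}

mhsa_backward <- function(cache, dY) {
  cfg <- cache$cfg; H <- cfg$n_heads; dk <- cfg$head_dim
  proj <- cache$proj; X <- cache$X
  dWo <- crossprod(cache$U, dY)
  dbo <- colSums(dY)
  dU <- dY %*% t(proj$Wo)
  dX <- matrix(0, nrow(X), ncol(X))
  dWq <- dWk <- dWv <- vector("list", H)
  for (h in seq_len(H)) {
    hc <- cache$heads[[h]]
    dO <- dU[, (h - 1L) * dk + seq_len(dk), drop = FALSE]
    dP <- tcrossprod(dO, hc$V)
    dV <- crossprod(hc$P, dO)
    dS <- hc$P * (dP - rowSums(dP * hc$P))
    dS <- dS / sqrt(dk)
    dQ <- dS %*% hc$K
    dK <- crossprod(dS, hc$Q)
    dWq[[h]] <- crossprod(X, dQ)
    dWk[[h]] <- crossprod(X, dK)
    dWv[[h]] <- crossprod(X, dV)
    dX <- dX + dQ %*% t(proj$Wq[[h]]) + dK %*% t(proj$Wk[[h]]) +
      dV %*% t(proj$Wv[[h]])
  }
  list(dX = dX, dWq = dWq, dWk = dWk, dWv = dWv, dWo = dWo, dbo = dbo)
}

#' Token-wise feed-forward network
#'
#' Two fully-connected layers with a nonlinearity in between, applied to
#' each token independently (no cross-token mixing).
#'
#' @param x Length-D vector or N x D matrix of tokens.
#' @param weights list(W1, b1, W2, b2, activation = "gelu" or "relu").
#' @return Same shape as `x`.
#' @export
feed_forward <- function(x, weights) {
  v <- is.null(dim(x))
  xm <- if (v) matrix(x, nrow = 1) else x
  if (ncol(xm) != nrow(weights$W1))
    stop_invalid("input dimension %d != W1 rows %d", ncol(xm),
                 nrow(weights$W1))
  f <- ffn_forward(xm, weights)
  if (v) drop(f$out) else f$out
}

ffn_forward <- function(X, w) {
  act <- w$activation %||% "gelu"
  h1 <- dense_forward(X, w$W1, w$b1)
  a <- if (act == "relu") relu_forward(h1$out) else gelu_forward(h1$out)
  h2 <- dense_forward(a$out, w$W2, w$b2)
  list(out = h2$out, cache = list(h1 = h1, a = a, h2 = h2, act = act))
}

ffn_backward <- function(cache, dY) {
  d2 <- dense_backward(cache$h2$cache, dY)
  da <- if (cache$act == "relu") relu_backward(cache$a$cache, d2$dx)
        else gelu_backward(cache$a$cache, d2$dx)
  d1 <- dense_backward(cache$h1$cache, da)
  list(dX = d1$dx, dW1 = d1$dW, db1 = d1$db, dW2 = d2$dW, db2 = d2$db)
}

#' Layer normalization
#'
#' Normalizes each token (row) to zero mean and unit variance
#' (eps-stabilized), then applies a learned per-dimension gain and offset.
#'
#' @param x Length-D vector or N x D matrix.
#' @param gain,offset Length-D vectors (default unit gain, zero offset).
#' @param eps Variance stabilizer.
#' @return Same shape as `x`.
#' @export
layer_norm <- function(x, gain = NULL, offset = NULL, eps = 1e-5) {
  v <- is.null(dim(x))
  xm <- if (v) matrix(x, nrow = 1) else x
  D <- ncol(xm)
  if (is.null(gain)) gain <- rep(1, D)
  if (is.null(offset)) offset <- rep(0, D)
  f <- layernorm_forward(xm, gain, offset, eps)
  if (v) drop(f$out) else f$out
}

layernorm_forward <- function(X, gain, offset, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  vr <- rowMeans(xc * xc)
  inv_sd <- 1 / sqrt(vr + eps)
  xhat <- xc * inv_sd
  out <- sweep(sweep(xhat, 2, gain, "*"), 2, offset, "+")
  list(out = out, cache = list(xhat = xhat, inv_sd = inv_sd, gain = gain))
}

layernorm_backward <- function(cache, dY) {
  xhat <- cache$xhat
  dgain <- colSums(dY * xhat)
  doffset <- colSums(dY)
  dxhat <- sweep(dY, 2, cache$gain, "*")
  dX <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) *
    cache$inv_sd
  list(dX = dX, dgain = dgain, doffset = doffset)
}

# pre-norm transformer block: X + MHSA(LN1 X); then + FFN(LN2 .)
transformer_block_forward <- function(X, p, cfg) {
  ln1 <- layernorm_forward(X, p$ln1_g, p$ln1_b)
  at <- mhsa_forward(ln1$out, cfg, p)
  X1 <- X + at$out
  ln2 <- layernorm_forward(X1, p$ln2_g, p$ln2_b)
  ff <- ffn_forward(ln2$out, p)
  list(out = X1 + ff$out, cache = list(ln1 = ln1, at = at, ln2 = ln2,
                                       ff = ff))
}

transformer_block_backward <- function(cache, dY) {
  ffb <- ffn_backward(cache$ff$cache, dY)
  ln2b <- layernorm_backward(cache$ln2$cache, ffb$dX)
  dX1 <- dY + ln2b$dX
  atb <- mhsa_backward(cache$at$cache, dX1)
  ln1b <- layernorm_backward(cache$ln1$cache, atb$dX)
  grads <- list(ln1_g = ln1b$dgain, ln1_b = ln1b$doffset,
                ln2_g = ln2b$dgain, ln2_b = ln2b$doffset,
                Wq = atb$dWq, Wk = atb$dWk, Wv = atb$dWv,
                Wo = atb$dWo, bo = atb$dbo,
                W1 = ffb$dW1, b1 = ffb$db1, W2 = ffb$dW2, b2 = ffb$db2)
  list(dX = dX1 + ln1b$dX, grads = grads)
}
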