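# Transformer primitives: patch embedding, positional encoding, scaled
# dot-product attention, multi-head attention, feed-forward, layer norm.

test_that("patchify produces row-major patches and inverts cleanly", {
  expect_equal(patchify(array(0, c(224, 224, 3)), 16)$grid$N, 196)

  img <- array(stats::runif(8 * 8 * 3), c(8, 8, 3))
  one <- patchify(img, 8)
  expect_equal(one$grid$N, 1)
  expect_equal(as.vector(one$patches), as.vector(img))

  p <- patchify(img, 2)
  expect_identical(dim(p$patches), c(16L, 12L))
  expect_equal(unpatchify(p$patches, p$grid), img)

  expect_error(patchify(array(0, c(224, 224, 3)), 15), "not divisible")
})

test_that("embed_patches is the stated linear projection", {
  img <- array(stats::runif(4 * 4 * 2), c(4, 4, 2))
  p <- patchify(img, 2)
  L <- ncol(p$patches)

  zero <- embed_patches(matrix(0, 4, L), matrix(stats::rnorm(L * 5), L, 5))
  expect_equal(zero$tokens, matrix(0, 4, 5))
  expect_false(zero$pe_applied)

  idty <- embed_patches(p$patches, diag(L))
  expect_equal(idty$tokens, p$patches)

  sums <- embed_patches(p$patches, matrix(1, L, 1))
  expect_equal(drop(sums$tokens), rowSums(p$patches))

  expect_error(embed_patches(p$patches, matrix(0, L + 1, 3)), "length")
})

test_that("positional encoding distinguishes positions and applies once", {
  tok <- list(tokens = matrix(1, 4, 6), D = 6L, pe_applied = FALSE)

  off <- add_positional_encoding(tok, mode = "none")
  expect_equal(off$tokens, tok$tokens)

  on <- add_positional_encoding(tok)
  expect_true(on$pe_applied)
  expect_false(isTRUE(all.equal(on$tokens[1, ], on$tokens[2, ])))
  expect_error(add_positional_encoding(on), "already applied")

  pe <- sinusoidal_pe(4, 6)
  expect_equal(pe[1, c(1, 3, 5)], c(0, 0, 0))   # sin(0) at position 0
  expect_equal(pe[1, c(2, 4, 6)], c(1, 1, 1))
})

test_that("scaled dot-product attention matches hand arithmetic", {
  v <- matrix(c(5, -2), 1, 2)
  expect_equal(scaled_dot_attention(matrix(1), matrix(1), v)$out, v)

  # equal scores -> uniform weights -> mean of V rows
  Q <- matrix(1, 2, 2); K <- matrix(1, 2, 2)
  V <- matrix(c(1, 3), 2, 1)
  expect_equal(drop(scaled_dot_attention(Q, K, V)$out), c(2, 2))

  # N = 2, d_k = 1, hand softmax: scores s_ij = q_i k_j
  Q <- matrix(c(1, 2), 2, 1); K <- matrix(c(0, 1), 2, 1); V <- matrix(c(10, 20), 2, 1)
  w1 <- exp(c(0, 1)) / sum(exp(c(0, 1)))
  w2 <- exp(c(0, 2)) / sum(exp(c(0, 2)))
  expect_equal(drop(scaled_dot_attention(Q, K, V)$out),
               c(sum(w1 * c(10, 20)), sum(w2 * c(10, 20))))

  expect_error(scaled_dot_attention(matrix(nrow = 2, ncol = 0),
                                    matrix(nrow = 2, ncol = 0),
                                    matrix(0, 2, 1)), "d_k")
})

test_that("attention softmax rows sum to 1 for random inputs", {
  withr::with_seed(1, {
    for (N in c(2, 7, 32)) {
      Q <- matrix(rnorm(N * 4), N); K <- matrix(rnorm(N * 4), N)
      V <- matrix(rnorm(N * 3), N)
      w <- scaled_dot_attention(Q, K, V)$weights
      expect_equal(rowSums(w), rep(1, N), tolerance = 1e-6)
    }
  })
})

rand_proj <- function(D, dk, H, seed) {
  withr::with_seed(seed, list(
    Wq = replicate(H, matrix(rnorm(D * dk), D), simplify = FALSE),
    Wk = replicate(H, matrix(rnorm(D * dk), D), simplify = FALSE),
    Wv = replicate(H, matrix(rnorm(D * dk), D), simplify = FALSE),
    Wo = matrix(rnorm(H * dk * D), H * dk, D)))
}

test_that("multi-head attention reduces, shapes, and is equivariant", {
  D <- 4L; N <- 6L
  X <- matrix(stats::rnorm(N * D), N, D)

  # one head = scaled dot attention + output projection
  cfg1 <- list(n_heads = 1L, head_dim = 4L, D = 4L)
  pr <- rand_proj(D, 4L, 1L, 3)
  got <- multi_head_attention(X, cfg1, pr)$tokens
  man <- scaled_dot_attention(X %*% pr$Wq[[1]], X %*% pr$Wk[[1]],
                              X %*% pr$Wv[[1]])$out %*% pr$Wo
  expect_equal(got, man, tolerance = 1e-12)

  cfg <- list(n_heads = 2L, head_dim = 2L, D = 4L)
  pr2 <- rand_proj(D, 2L, 2L, 4)
  out <- multi_head_attention(X, cfg, pr2)$tokens
  expect_identical(dim(out), c(N, D))

  # without positional encoding, permuting tokens permutes outputs
  withr::with_seed(9, sig <- sample(N))
  out_p <- multi_head_attention(X[sig, ], cfg, pr2)$tokens
  expect_equal(out_p, out[sig, ], tolerance = 1e-10)

  bad <- pr2; bad$Wq[[1]] <- matrix(0, D + 1, 2)
  expect_error(multi_head_attention(X, cfg, bad), "head 1")
})

test_that("feed-forward is token-wise with the stated reductions", {
  w <- list(W1 = matrix(0, 3, 5), b1 = rep(0, 5),
            W2 = matrix(0, 5, 3), b2 = rep(0, 3))
  expect_equal(feed_forward(c(1, 2, 3), w), c(0, 0, 0))

  # identity layers with ReLU on positive input = identity
  wi <- list(W1 = diag(3), b1 = rep(0, 3), W2 = diag(3), b2 = rep(0, 3),
             activation = "relu")
  expect_equal(feed_forward(c(1, 2, 3), wi), c(1, 2, 3))

  # changing token j leaves other tokens' outputs unchanged
  wr <- list(W1 = matrix(rnorm(3 * 5), 3), b1 = rnorm(5),
             W2 = matrix(rnorm(5 * 3), 5), b2 = rnorm(3))
  X <- matrix(rnorm(12), 4, 3)
  Y <- feed_forward(X, wr)
  X2 <- X; X2[2, ] <- X2[2, ] + 1
  Y2 <- feed_forward(X2, wr)
  expect_equal(Y2[-2, ], Y[-2, ])
  expect_error(feed_forward(c(1, 2), wr), "dimension")
})

test_that("layer norm satisfies the normalization contract", {
  expect_equal(layer_norm(c(1, 3)), c(-1, 1), tolerance = 1e-4)
  expect_equal(layer_norm(rep(5, 8)), rep(0, 8), tolerance = 1e-3)

  withr::with_seed(2, x <- rnorm(64, 3, 10))
  y <- layer_norm(x)
  expect_equal(mean(y), 0, tolerance = 1e-5)
  expect_equal(mean(y^2), 1, tolerance = 1e-4)

  expect_equal(layer_norm(c(1, 3), gain = c(2, 2), offset = c(1, 1)),
               c(-1, 3), tolerance = 1e-4)
})
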