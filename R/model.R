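# Multi-task model with learned task-to-task connectivity (TTC).
#
# Every task owns a full subnetwork column: a convolutional encoder
# (conv 3x3 -> batch norm -> ReLU -> 2x2 max pool per block) plus a
# task-specific head.  Sharing between tasks is soft: after every encoder
# block the feature entering task p's column is the connectivity-weighted
# sum over all columns, sum_q alpha[p,q] * h_q, with alpha = sigmoid(beta)
# off-diagonal and alpha[p,p] structurally 1.  With all off-diagonal
# alpha -> 0 the model decomposes exactly into independent single-task
# learners; the gradient of any task's loss with respect to any other
# task's weights and to beta then falls out of ordinary backpropagation
# through these coupling points.
#
# Heads:
#  - classification: global average pool -> dropout -> dense -> softmax
#  - segmentation (TransUNet-style): bottleneck -> patch embed + PE ->
#    transformer blocks -> linear back-projection -> transposed-conv
#    upsampling with skip connections to the column's encoder features ->
#    1x1 conv -> sigmoid

#' Task specification
#'
#' @param task_id Unique task name.
#' @param kind "classification" or "segmentation".
#' @param n_classes Number of classes (classification only).
#' @param frozen Whether the subnetwork is frozen.
#' @return TaskSpec list.
#' @export
task_spec <- function(task_id, kind = c("classification", "segmentation"),
                      n_classes = 4L, frozen = FALSE) {
  kind <- match.arg(kind)
  list(task_id = task_id, kind = kind, n_classes = as.integer(n_classes),
       frozen = frozen)
}

#' Encoder configuration
#'
#' @param n_blocks Number of conv blocks (each halves the resolution).
#' @param channels Output channels per block.
#' @param kernel Conv kernel side (odd; default 3).
#' @param dropout Dropout rate in the classification head (default 0.2).
#' @param batchnorm Enable batch normalization (default TRUE).
#' @param input_size Input image side in pixels.
#' @param in_channels Input channels (RGB = 3).
#' @return EncoderConfig list.
#' @export
encoder_config <- function(n_blocks = 4L, channels = c(32L, 64L, 128L, 256L),
                           kernel = 3L, dropout = 0.2, batchnorm = TRUE,
                           input_size = 224L, in_channels = 3L) {
  if (kernel %% 2 == 0) stop_invalid("kernel size must be odd")
  if (dropout < 0 || dropout >= 1) stop_invalid("dropout must be in [0, 1)")
  if (length(channels) != n_blocks)
    stop_invalid("channels must have one entry per block")
  if (input_size %% (2^n_blocks) != 0)
    stop_invalid("input_size must be divisible by 2^n_blocks")
  list(n_blocks = as.integer(n_blocks), channels = as.integer(channels),
       kernel = as.integer(kernel), dropout = dropout, batchnorm = batchnorm,
       input_size = as.integer(input_size), in_channels = as.integer(in_channels))
}

#' Attention configuration for the segmentation head
#'
#' Defaults follow the 100-head, 4-dimensional-per-head setting, giving
#' token dimension D = 400; desk-scale test configurations use 4 x 4.
#'
#' @param n_heads Number of attention heads.
#' @param head_dim Per-head feature dimension d_k.
#' @param patch_size Patch side on the bottleneck feature map.
#' @param n_tx_blocks Number of transformer blocks.
#' @param ffn_dim Hidden width of the token-wise feed-forward net
#'   (default 2 * D).
#' @param pe_mode "sinusoidal" or "none".
#' @param activation FFN nonlinearity, "gelu" (default) or "relu".
#' @return AttentionConfig list with derived D.
#' @export
attention_config <- function(n_heads = 100L, head_dim = 4L, patch_size = 2L,
                             n_tx_blocks = 1L, ffn_dim = NULL,
                             pe_mode = c("sinusoidal", "none"),
                             activation = c("gelu", "relu")) {
  D <- as.integer(n_heads * head_dim)
  cfg <- list(n_heads = as.integer(n_heads), head_dim = as.integer(head_dim),
              D = D, patch_size = as.integer(patch_size),
              n_tx_blocks = as.integer(n_tx_blocks),
              ffn_dim = as.integer(ffn_dim %||% (2L * D)),
              pe_mode = match.arg(pe_mode),
              activation = match.arg(activation))
  validate_attention_cfg(cfg)
  cfg
}

rnorm_mat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

# decoder channel plan: one upsampling level per encoder block; the
# final (full-resolution) level fuses with a 1x1 conv, deeper levels 3x3
seg_plan <- function(enc) {
  nb <- enc$n_blocks
  dec_ch <- pmax(rev(enc$channels) %/% 2L, 4L)
  skip_ch <- rev(enc$channels)
  dec_k <- rep(3L, nb)
  dec_k[nb] <- 1L
  list(dec_ch = dec_ch, skip_ch = skip_ch, dec_k = dec_k)
}

init_task_column <- function(spec, enc, att) {
  k <- enc$kernel
  p <- list()
  cin <- enc$in_channels
  for (bk in seq_len(enc$n_blocks)) {
    co <- enc$channels[bk]
    fan_in <- k * k * cin
    p[[sprintf("enc%d_W", bk)]] <- rnorm_mat(fan_in, co, sqrt(2 / fan_in))
    p[[sprintf("enc%d_b", bk)]] <- rep(0, co)
    if (enc$batchnorm) {
      p[[sprintf("enc%d_bn_g", bk)]] <- rep(1, co)
      p[[sprintf("enc%d_bn_b", bk)]] <- rep(0, co)
    }
    cin <- co
  }
  cb <- enc$channels[enc$n_blocks]
  if (spec$kind == "classification") {
    K <- spec$n_classes
    p$cls_ln_g <- rep(1, cb)       # layer norm on pooled features
    p$cls_ln_b <- rep(0, cb)
    p$cls_W <- rnorm_mat(cb, K, sqrt(2 / (cb + K)))
    p$cls_b <- rep(0, K)
  } else {
    P <- att$patch_size; D <- att$D
    L <- P * P * cb
    p$emb_W <- rnorm_mat(L, D, sqrt(2 / (L + D)))
    p$emb_b <- rep(0, D)
    for (t in seq_len(att$n_tx_blocks)) {
      pre <- sprintf("tx%d_", t)
      p[[paste0(pre, "ln1_g")]] <- rep(1, D)
      p[[paste0(pre, "ln1_b")]] <- rep(0, D)
      p[[paste0(pre, "ln2_g")]] <- rep(1, D)
      p[[paste0(pre, "ln2_b")]] <- rep(0, D)
      for (h in seq_len(att$n_heads)) {
        sd <- sqrt(1 / D)
        p[[sprintf("%sWq%d", pre, h)]] <- rnorm_mat(D, att$head_dim, sd)
        p[[sprintf("%sWk%d", pre, h)]] <- rnorm_mat(D, att$head_dim, sd)
        p[[sprintf("%sWv%d", pre, h)]] <- rnorm_mat(D, att$head_dim, sd)
      }
      p[[paste0(pre, "Wo")]] <- rnorm_mat(att$n_heads * att$head_dim, D,
                                          sqrt(1 / D))
      p[[paste0(pre, "bo")]] <- rep(0, D)
      p[[paste0(pre, "W1")]] <- rnorm_mat(D, att$ffn_dim, sqrt(2 / D))
      p[[paste0(pre, "b1")]] <- rep(0, att$ffn_dim)
      p[[paste0(pre, "W2")]] <- rnorm_mat(att$ffn_dim, D, sqrt(2 / att$ffn_dim))
      p[[paste0(pre, "b2")]] <- rep(0, D)
    }
    p$proj_W <- rnorm_mat(D, P * P * cb, sqrt(2 / D))
    p$proj_b <- rep(0, P * P * cb)
    plan <- seg_plan(enc)
    cin_d <- cb
    for (l in seq_len(enc$n_blocks)) {
      dc <- plan$dec_ch[l]; sc <- plan$skip_ch[l]
      p[[sprintf("dec%d_t_W", l)]] <- rnorm_mat(cin_d, 4L * dc,
                                                sqrt(2 / cin_d))
      p[[sprintf("dec%d_t_b", l)]] <- rep(0, dc)
      fan <- plan$dec_k[l]^2 * (dc + sc)
      p[[sprintf("dec%d_c_W", l)]] <- rnorm_mat(fan, dc, sqrt(2 / fan))
      p[[sprintf("dec%d_c_b", l)]] <- rep(0, dc)
      cin_d <- dc
    }
    p$out_W <- rnorm_mat(cin_d, 1, sqrt(2 / cin_d))
    p$out_b <- 0
  }
  p
}

#' Build a multi-task TTC model
#'
#' Each task column is initialized from an RNG stream derived from
#' (`seed`, task id), so a single-task model built with the same seed and
#' task id has bit-identical initial weights for that column.  The TTC
#' matrix starts with all off-diagonal couplings at `ttc_init_beta`
#' (alpha = sigmoid of that); the diagonal is the structural constant 1.
#'
#' @param task_specs List of [task_spec()]s with unique ids.
#' @param encoder_cfg [encoder_config()].
#' @param attention_cfg [attention_config()] (used by segmentation tasks).
#' @param ttc_init_beta Initial off-diagonal beta (default 0, alpha 0.5).
#' @param seed Integer initialization seed.
#' @return ModelState list.
#' @export
build_model <- function(task_specs, encoder_cfg = encoder_config(),
                        attention_cfg = attention_config(),
                        ttc_init_beta = 0, seed = 1L) {
  if (length(task_specs) < 1) stop_invalid("at least one task required")
  ids <- vapply(task_specs, `[[`, "", "task_id")
  if (anyDuplicated(ids)) stop_invalid("duplicate task_id")
  names(task_specs) <- ids
  params <- lapply(task_specs, function(sp)
    with_seed(task_seed(seed, sp$task_id),
              init_task_column(sp, encoder_cfg, attention_cfg)))
  n <- length(ids)
  beta <- matrix(ttc_init_beta, n, n, dimnames = list(ids, ids))
  diag(beta) <- NA_real_   # diagonal alpha is structural, not a parameter
  model <- list(task_specs = task_specs, encoder_cfg = encoder_cfg,
                attention_cfg = attention_cfg, params = params,
                ttc_beta = beta, ttc_init_beta = ttc_init_beta,
                bn_state = stats::setNames(vector("list", n), ids),
                seed = as.integer(seed), step = 0L)
  class(model) <- "ttc_model"
  model
}

#' Task-to-task connectivity matrix
#'
#' @param model A ttc_model.
#' @return alpha matrix: sigmoid(beta) for trainable couplings, exactly 1
#'   on the diagonal, exactly 0 for structurally absent connections
#'   (couplings from a later-added task into a frozen task, which would
#'   otherwise change the frozen task's behavior).
#' @export
ttc_matrix <- function(model) {
  a <- sigmoid(model$ttc_beta)
  a[is.na(model$ttc_beta)] <- 0
  diag(a) <- 1
  a
}

#' Add a new task to a trained model
#'
#' All existing tasks are frozen (their weights stay bit-identical, and
#' their coupling rows stop updating); a fresh column is initialized for
#' the new task, and the TTC matrix grows by one row and column with
#' off-diagonal entries at the model's initial beta.
#'
#' @param model A ttc_model.
#' @param new_spec [task_spec()] with an unused task_id.
#' @param seed Initialization seed for the new column (default: the
#'   model's build seed).
#' @return Updated model.
#' @export
add_task <- function(model, new_spec, seed = NULL) {
  if (new_spec$task_id %in% names(model$task_specs))
    stop_invalid("duplicate task_id '%s'", new_spec$task_id)
  seed <- seed %||% model$seed
  for (id in names(model$task_specs)) model$task_specs[[id]]$frozen <- TRUE
  model$task_specs[[new_spec$task_id]] <- new_spec
  model$params[[new_spec$task_id]] <-
    with_seed(task_seed(seed, new_spec$task_id),
              init_task_column(new_spec, model$encoder_cfg,
                               model$attention_cfg))
  ids <- names(model$task_specs)
  n <- length(ids)
  beta <- matrix(model$ttc_init_beta, n, n, dimnames = list(ids, ids))
  old <- rownames(model$ttc_beta)
  beta[old, old] <- model$ttc_beta
  # frozen tasks receive nothing from the new task (structural 0), so
  # their forward behavior is bit-identical after the addition; the new
  # task's row couples it to everything already learned
  beta[old, new_spec$task_id] <- NA_real_
  diag(beta) <- NA_real_
  model$ttc_beta <- beta
  model$bn_state[[new_spec$task_id]] <- NULL
  model
}

# ---- forward pass -------------------------------------------------------

# batched patchify: [Hb,Wb,N,C] -> (Ntok*N) x (P*P*C), token row-major,
# sample index slowest
patchify_batch <- function(x, P) {
  d <- dim(x); H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  nr <- H %/% P; nc <- W %/% P
  arr <- array(x, c(P, nr, P, nc, N, C))
  arr <- aperm(arr, c(1, 3, 6, 4, 2, 5))   # P,P,C,nc,nr,N
  t(matrix(arr, nrow = P * P * C))
}

unpatchify_batch <- function(tok, P, H, W, C, N) {
  nr <- H %/% P; nc <- W %/% P
  arr <- array(t(tok), c(P, P, C, nc, nr, N))
  arr <- aperm(arr, c(1, 5, 2, 4, 6, 3))   # P,nr,P,nc,N,C
  array(arr, c(H, W, N, C))
}

tx_proj <- function(p, pre, att) {
  list(Wq = lapply(seq_len(att$n_heads), function(h) p[[sprintf("%sWq%d", pre, h)]]),
       Wk = lapply(seq_len(att$n_heads), function(h) p[[sprintf("%sWk%d", pre, h)]]),
       Wv = lapply(seq_len(att$n_heads), function(h) p[[sprintf("%sWv%d", pre, h)]]),
       Wo = p[[paste0(pre, "Wo")]], bo = p[[paste0(pre, "bo")]],
       ln1_g = p[[paste0(pre, "ln1_g")]], ln1_b = p[[paste0(pre, "ln1_b")]],
       ln2_g = p[[paste0(pre, "ln2_g")]], ln2_b = p[[paste0(pre, "ln2_b")]],
       W1 = p[[paste0(pre, "W1")]], b1 = p[[paste0(pre, "b1")]],
       W2 = p[[paste0(pre, "W2")]], b2 = p[[paste0(pre, "b2")]],
       activation = att$activation)
}

# full forward with caches; dropout masks drawn from dropout_seed streams
forward_full <- function(model, x, training = FALSE, dropout_seed = NULL,
                         update_bn = training, bn_momentum = 0.1) {
  enc <- model$encoder_cfg; att <- model$attention_cfg
  ids <- names(model$task_specs)
  alpha <- ttc_matrix(model)
  k <- enc$kernel; pad <- (k - 1L) %/% 2L
  h <- stats::setNames(rep(list(x), length(ids)), ids)
  cache <- list(enc = list(), mix_raw = list(), skips = list())
  new_bn <- model$bn_state
  for (bk in seq_len(enc$n_blocks)) {
    raw <- list()
    for (id in ids) {
      p <- model$params[[id]]
      cv <- conv2d_forward(h[[id]], p[[sprintf("enc%d_W", bk)]],
                           p[[sprintf("enc%d_b", bk)]], k, pad)
      z <- cv$out; bnc <- NULL
      if (enc$batchnorm) {
        run <- model$bn_state[[id]][[bk]]
        bn <- batchnorm_forward(z, p[[sprintf("enc%d_bn_g", bk)]],
                                p[[sprintf("enc%d_bn_b", bk)]],
                                training = training, running = run,
                                momentum = bn_momentum)
        z <- bn$out; bnc <- bn$cache
        if (training && update_bn && !model$task_specs[[id]]$frozen)
          new_bn[[id]][[bk]] <- bn$running
      }
      rl <- relu_forward(z)
      pl <- maxpool2_forward(rl$out)
      cache$enc[[id]][[bk]] <- list(cv = cv$cache, bn = bnc, rl = rl$cache,
                                    pool = pl$cache)
      cache$skips[[id]][[bk]] <- rl$out
      raw[[id]] <- pl$out
    }
    # TTC coupling point: connectivity-weighted feature exchange
    if (length(ids) > 1) {
      mixed <- list()
      for (p_id in ids) {
        acc <- raw[[p_id]]
        for (q_id in ids) if (q_id != p_id)
          acc <- acc + alpha[p_id, q_id] * raw[[q_id]]
        mixed[[p_id]] <- acc
      }
      cache$mix_raw[[bk]] <- raw
      h <- mixed
    } else {
      h <- raw
    }
  }
  preds <- list(); heads <- list()
  for (id in ids) {
    p <- model$params[[id]]
    sp <- model$task_specs[[id]]
    if (sp$kind == "classification") {
      g <- gap_forward(h[[id]])
      # per-sample layer norm conditions the pooled features for the
      # softmax head without any train/eval statistics mismatch
      ln <- layernorm_forward(g$out, p$cls_ln_g, p$cls_ln_b)
      feat <- ln$out
      if (training && enc$dropout > 0) {
        dr <- with_seed(task_seed((dropout_seed %||% model$step) + 1L, id),
                        dropout_forward(feat, enc$dropout, TRUE))
      } else dr <- dropout_forward(feat, 0, FALSE)
      dn <- dense_forward(dr$out, p$cls_W, p$cls_b)
      probs <- softmax_rows(dn$out)
      preds[[id]] <- probs
      heads[[id]] <- list(gap = g$cache, ln = ln$cache, drop = dr$cache,
                          dense = dn$cache, probs = probs)
    } else {
      d <- dim(h[[id]]); Hb <- d[1]; Wb <- d[2]; N <- d[3]; Cb <- d[4]
      P <- att$patch_size
      ntok <- (Hb %/% P) * (Wb %/% P)
      pat <- patchify_batch(h[[id]], P)
      emb <- dense_forward(pat, p$emb_W, p$emb_b)
      tok <- emb$out
      if (att$pe_mode == "sinusoidal") {
        pe <- sinusoidal_pe(ntok, att$D)
        tok <- tok + pe[rep(seq_len(ntok), N), ]
      }
      txc <- list(); Xs <- vector("list", N)
      for (n in seq_len(N)) Xs[[n]] <- tok[(n - 1L) * ntok + seq_len(ntok), , drop = FALSE]
      for (t in seq_len(att$n_tx_blocks)) {
        pre <- sprintf("tx%d_", t)
        pj <- tx_proj(p, pre, att)
        txc[[t]] <- vector("list", N)
        for (n in seq_len(N)) {
          tb <- transformer_block_forward(Xs[[n]], pj, att)
          Xs[[n]] <- tb$out
          txc[[t]][[n]] <- tb$cache
        }
      }
      tok_out <- do.call(rbind, Xs)
      bp <- dense_forward(tok_out, p$proj_W, p$proj_b)
      f <- unpatchify_batch(bp$out, P, Hb, Wb, Cb, N)
      plan <- seg_plan(enc)
      decc <- list()
      for (l in seq_len(enc$n_blocks)) {
        tc <- tconv2_forward(f, p[[sprintf("dec%d_t_W", l)]],
                             p[[sprintf("dec%d_t_b", l)]])
        skip <- cache$skips[[id]][[enc$n_blocks - l + 1L]]
        dcat <- dim(tc$out)
        cat_f <- array(0, c(dcat[1], dcat[2], dcat[3], dcat[4] + dim(skip)[4]))
        cat_f[, , , seq_len(dcat[4])] <- tc$out
        cat_f[, , , dcat[4] + seq_len(dim(skip)[4])] <- skip
        kd <- plan$dec_k[l]
        cv <- conv2d_forward(cat_f, p[[sprintf("dec%d_c_W", l)]],
                             p[[sprintf("dec%d_c_b", l)]], kd, (kd - 1L) %/% 2L)
        rl <- relu_forward(cv$out)
        decc[[l]] <- list(tc = tc$cache, cv = cv$cache, rl = rl$cache,
                          n_dec = dcat[4], n_skip = dim(skip)[4])
        f <- rl$out
      }
      oc <- conv2d_forward(f, p$out_W, p$out_b, 1L, 0L)
      probs <- sigmoid(oc$out)
      preds[[id]] <- array(probs, dim(probs)[1:3])
      heads[[id]] <- list(ntok = ntok, N = N, Hb = Hb, Wb = Wb, Cb = Cb,
                          emb = emb$cache, tx = txc, bp = bp$cache,
                          dec = decc, outc = oc$cache, probs = probs)
    }
  }
  list(preds = preds, cache = list(enc = cache$enc, mix_raw = cache$mix_raw,
                                   skips = cache$skips, heads = heads,
                                   alpha = alpha, ids = ids),
       bn_state = new_bn)
}

#' Re-estimate batch-norm population statistics
#'
#' Batch-norm running averages lag behind fast-moving weights during
#' short training runs.  This pass recomputes the population statistics
#' for the current weights as an equal-weight average over a few batches
#' (no parameter updates; frozen tasks keep their stored statistics).
#'
#' @param model A ttc_model.
#' @param samples Samples to estimate on (typically training data).
#' @param batch_size Batch size for the estimation passes.
#' @param max_batches Number of batches to average over.
#' @return Model with refreshed bn_state.
#' @export
recalibrate_bn <- function(model, samples, batch_size = 32L,
                           max_batches = 4L) {
  if (!model$encoder_cfg$batchnorm) return(model)
  frozen <- vapply(model$task_specs, `[[`, TRUE, "frozen")
  keep <- model$bn_state          # frozen tasks keep their statistics
  for (id in names(model$task_specs)[!frozen]) model$bn_state[[id]] <- NULL
  nb <- min(max_batches, ceiling(length(samples) / batch_size))
  for (i in seq_len(nb)) {
    idx <- ((i - 1L) * batch_size + 1L):min(i * batch_size, length(samples))
    bt <- samples_to_batch(samples[idx], model$task_specs)
    fw <- forward_full(model, bt$x, training = TRUE, dropout_seed = i,
                       update_bn = TRUE, bn_momentum = 1 / i)
    model$bn_state <- fw$bn_state
  }
  for (id in names(model$task_specs)[frozen])
    model$bn_state[[id]] <- keep[[id]]
  model
}

#' Run the model on a batch of images
#'
#' @param model A ttc_model.
#' @param image_batch H x W x 3 x N array (or a single H x W x 3 image),
#'   preprocessed to the model's input size and range.
#' @return Named list of per-task predictions: classification tasks give
#'   an N x K matrix of class probabilities (rows sum to 1); segmentation
#'   tasks give an H x W x N array of foreground probabilities.
#' @export
predict_tasks <- function(model, image_batch) {
  if (length(dim(image_batch)) == 3) dim(image_batch) <- c(dim(image_batch), 1L)
  d <- dim(image_batch)
  if (d[1] != model$encoder_cfg$input_size || d[3] != model$encoder_cfg$in_channels)
    stop_invalid("expected %dx%dx%d input",
                 model$encoder_cfg$input_size, model$encoder_cfg$input_size,
                 model$encoder_cfg$in_channels)
  x <- aperm(image_batch, c(1, 2, 4, 3))       # internal [H, W, N, C]
  forward_full(model, x, training = FALSE)$preds
}

# ---- checkpoints --------------------------------------------------------

#' Save a model checkpoint
#'
#' The checkpoint is a key-value container {schema_version, encoder_cfg,
#' attention_cfg, task_specs, ttc_beta, params, bn_state, step, seed};
#' load/save round-trips bit-exactly.
#'
#' @param model A ttc_model.
#' @param path Destination file.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(schema_version = 1L,
              encoder_cfg = model$encoder_cfg,
              attention_cfg = model$attention_cfg,
              task_specs = model$task_specs,
              ttc_beta = model$ttc_beta,
              ttc_init_beta = model$ttc_init_beta,
              params = model$params,
              bn_state = model$bn_state,
              seed = model$seed,
              step = model$step)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint file written by [save_checkpoint()].
#' @return A ttc_model.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_invalid("checkpoint '%s' not found", path)
  obj <- readRDS(path)
  if (!identical(obj$schema_version, 1L))
    stop_invalid("unsupported checkpoint schema")
  model <- obj[c("task_specs", "encoder_cfg", "attention_cfg", "params",
                 "ttc_beta", "ttc_init_beta", "bn_state", "seed", "step")]
  class(model) <- "ttc_model"
  model
}

#' @export
print.ttc_model <- function(x, ...) {
  cat("Multi-task TTC model\n")
  cat("  tasks:", paste(sprintf("%s (%s%s)", names(x$task_specs),
                                vapply(x$task_specs, `[[`, "", "kind"),
                                ifelse(vapply(x$task_specs, `[[`, TRUE, "frozen"),
                                       ", frozen", "")),
                        collapse = ", "), "\n")
  cat("  encoder:", x$encoder_cfg$n_blocks, "blocks, channels",
      paste(x$encoder_cfg$channels, collapse = "/"), "\n")
  cat("  step:", x$step, "\n")
  invisible(x)
}
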