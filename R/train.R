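# TTC-modulated training: joint backward pass through the coupling
# points, beta updates via the sigmoid chain rule, Adam (default) or
# plain SGD (exact hand-checkable oracle mode), freezing, and the epoch
# loop.  The applied update V_{t+1} is stored per parameter so that
# W_{t+1} = W_t + V_{t+1} holds exactly as bookkeeping.

#' Loss configuration for one task
#'
#' @param kind "categorical" (K-class cross-entropy), "bce", or "focal".
#' @param gamma Focal focusing parameter (>= 0, default 2).
#' @param class_weight "from_batch" (a_c = N_b/N_f computed on each
#'   batch's masks) or a fixed numeric a_c.
#' @param eps Probability clamp.
#' @param standard_focal Use the conventional symmetric focal form.
#' @return LossConfig list.
#' @export
loss_config <- function(kind = c("categorical", "focal", "bce"),
                        gamma = 2, class_weight = "from_batch",
                        eps = 1e-7, standard_focal = FALSE) {
  if (gamma < 0) stop_invalid("gamma must be >= 0")
  if (eps <= 0 || eps > 1e-3) stop_invalid("eps must be in (0, 1e-3]")
  list(kind = match.arg(kind), gamma = gamma, class_weight = class_weight,
       eps = eps, standard_focal = standard_focal)
}

#' Training configuration
#'
#' Defaults: Adam, learning rate 0.001, batch size 32, 50 epochs.
#'
#' @param lr Learning rate.
#' @param optimizer "adam" or "sgd" (plain SGD exists so that single
#'   steps can be checked against hand-computed oracles).
#' @param batch_size Samples per step.
#' @param epochs Number of epochs.
#' @param seed Seed controlling shuffling and dropout streams.
#' @param beta1,beta2,adam_eps Adam moment parameters.
#' @return TrainConfig list.
#' @export
train_config <- function(lr = 0.001, optimizer = c("adam", "sgd"),
                         batch_size = 32L, epochs = 50L, seed = 1L,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8) {
  if (lr <= 0 || batch_size < 1 || epochs < 0)
    stop_invalid("invalid training configuration")
  list(lr = lr, optimizer = match.arg(optimizer),
       batch_size = as.integer(batch_size), epochs = as.integer(epochs),
       seed = as.integer(seed), beta1 = beta1, beta2 = beta2,
       adam_eps = adam_eps)
}

zero_like <- function(p) lapply(p, function(w) w * 0)

init_update_state <- function(model) {
  st <- list(t = 0L,
             m = lapply(model$params, zero_like),
             v = lapply(model$params, zero_like),
             mb = model$ttc_beta * 0, vb = model$ttc_beta * 0,
             V = NULL, V_beta = NULL)
  st$mb[is.na(st$mb)] <- 0; st$vb[is.na(st$vb)] <- 0
  st
}

# optimizer transform of the negative gradient; returns the update V
optim_update <- function(g, m, v, t, cfg) {
  if (cfg$optimizer == "sgd") {
    return(list(V = -cfg$lr * g, m = m, v = v))
  }
  m <- cfg$beta1 * m + (1 - cfg$beta1) * g
  v <- cfg$beta2 * v + (1 - cfg$beta2) * g * g
  mhat <- m / (1 - cfg$beta1^t)
  vhat <- v / (1 - cfg$beta2^t)
  list(V = -cfg$lr * mhat / (sqrt(vhat) + cfg$adam_eps), m = m, v = v)
}

# per-task loss value and gradient w.r.t. the head logits
task_loss_grad <- function(spec, lcfg, pred_cache, target) {
  if (spec$kind == "classification") {
    probs <- pred_cache$probs
    N <- nrow(probs); K <- ncol(probs)
    loss <- categorical_ce(target, probs, eps = lcfg$eps)
    onehot <- matrix(0, N, K)
    onehot[cbind(seq_len(N), target)] <- 1
    dlogits <- (probs - onehot) / N
    list(loss = loss, dlogits = dlogits)
  } else {
    probs <- pred_cache$probs                 # H x W x 1 x N
    y <- array(target, dim(probs))
    a_c <- lcfg$class_weight
    if (identical(a_c, "from_batch")) {
      a_c <- if (sum(y) == 0) 1 else sum(y == 0) / sum(y)
    }
    if (lcfg$kind == "bce") {
      loss <- bce_loss(y, probs, eps = lcfg$eps)
      gp <- focal_loss_grad_p(y, probs, a_c = 1, gamma = 0, eps = lcfg$eps)
    } else {
      loss <- focal_loss(y, probs, a_c = a_c, gamma = lcfg$gamma,
                         eps = lcfg$eps, standard = lcfg$standard_focal)
      gp <- focal_loss_grad_p(y, probs, a_c = a_c, gamma = lcfg$gamma,
                              eps = lcfg$eps, standard = lcfg$standard_focal)
    }
    # the loss clamps p to [eps, 1-eps]; beyond the clamp it is flat in
    # p, so saturated pixels contribute no gradient
    inside <- (probs > lcfg$eps & probs < 1 - lcfg$eps)
    dlogits <- gp * probs * (1 - probs) * inside / length(probs)
    list(loss = loss, dlogits = dlogits)
  }
}

acc_grad <- function(g, name, val) {
  if (is.null(g[[name]])) g[[name]] <- val else g[[name]] <- g[[name]] + val
  g
}

# joint backward through heads, coupling points, and encoder columns;
# dlogits: per-task gradient at head logits (NULL for frozen tasks)
backward_full <- function(model, cache, dlogits) {
  enc <- model$encoder_cfg; att <- model$attention_cfg
  ids <- cache$ids
  alpha <- cache$alpha
  nb <- enc$n_blocks
  k <- enc$kernel
  grads <- stats::setNames(vector("list", length(ids)), ids)
  dskips <- stats::setNames(vector("list", length(ids)), ids)
  dh <- stats::setNames(vector("list", length(ids)), ids)
  dbeta <- model$ttc_beta * 0; dbeta[is.na(dbeta)] <- 0

  for (id in ids) {
    grads[[id]] <- list()
    dskips[[id]] <- vector("list", nb)
    hc <- cache$heads[[id]]
    sp <- model$task_specs[[id]]
    if (is.null(dlogits[[id]])) { dh[[id]] <- NULL; next }
    if (sp$kind == "classification") {
      dd <- dense_backward(hc$dense, dlogits[[id]])
      grads[[id]]$cls_W <- dd$dW; grads[[id]]$cls_b <- dd$db
      dg <- dropout_backward(hc$drop, dd$dx)
      lb <- layernorm_backward(hc$ln, dg)
      grads[[id]]$cls_ln_g <- lb$dgain
      grads[[id]]$cls_ln_b <- lb$doffset
      dh[[id]] <- gap_backward(hc$gap, lb$dX)
    } else {
      dout <- dlogits[[id]]                     # grad at 1x1-conv logits
      ob <- conv2d_backward(hc$outc, dout)
      grads[[id]]$out_W <- ob$dW; grads[[id]]$out_b <- ob$db
      df <- ob$dx
      plan <- seg_plan(enc)
      for (l in seq(nb, 1)) {
        dc <- cache$heads[[id]]$dec[[l]]
        drl <- relu_backward(dc$rl, df)
        cb <- conv2d_backward(dc$cv, drl)
        grads[[id]][[sprintf("dec%d_c_W", l)]] <- cb$dW
        grads[[id]][[sprintf("dec%d_c_b", l)]] <- cb$db
        d_tc <- cb$dx[, , , seq_len(dc$n_dec), drop = FALSE]
        d_skip <- cb$dx[, , , dc$n_dec + seq_len(dc$n_skip), drop = FALSE]
        blk <- nb - l + 1L
        dskips[[id]][[blk]] <- (dskips[[id]][[blk]] %||% 0) + d_skip
        tb <- tconv2_backward(dc$tc, d_tc)
        grads[[id]][[sprintf("dec%d_t_W", l)]] <- tb$dW
        grads[[id]][[sprintf("dec%d_t_b", l)]] <- tb$db
        df <- tb$dx
      }
      # back through token pathway
      dtok <- patchify_batch(df, att$patch_size)  # adjoint of unpatchify
      bpb <- dense_backward(hc$bp, dtok)
      grads[[id]]$proj_W <- bpb$dW; grads[[id]]$proj_b <- bpb$db
      ntok <- hc$ntok; N <- hc$N
      dXs <- vector("list", N)
      for (n in seq_len(N))
        dXs[[n]] <- bpb$dx[(n - 1L) * ntok + seq_len(ntok), , drop = FALSE]
      for (t in seq(att$n_tx_blocks, 1)) {
        pre <- sprintf("tx%d_", t)
        gacc <- NULL
        for (n in seq_len(N)) {
          tbb <- transformer_block_backward(hc$tx[[t]][[n]], dXs[[n]])
          dXs[[n]] <- tbb$dX
          if (is.null(gacc)) gacc <- tbb$grads
          else {
            for (nm in c("ln1_g", "ln1_b", "ln2_g", "ln2_b", "Wo", "bo",
                         "W1", "b1", "W2", "b2"))
              gacc[[nm]] <- gacc[[nm]] + tbb$grads[[nm]]
            for (h in seq_len(att$n_heads)) {
              gacc$Wq[[h]] <- gacc$Wq[[h]] + tbb$grads$Wq[[h]]
              gacc$Wk[[h]] <- gacc$Wk[[h]] + tbb$grads$Wk[[h]]
              gacc$Wv[[h]] <- gacc$Wv[[h]] + tbb$grads$Wv[[h]]
            }
          }
        }
        for (nm in c("ln1_g", "ln1_b", "ln2_g", "ln2_b", "Wo", "bo",
                     "W1", "b1", "W2", "b2"))
          grads[[id]][[paste0(pre, nm)]] <- gacc[[nm]]
        for (h in seq_len(att$n_heads)) {
          grads[[id]][[sprintf("%sWq%d", pre, h)]] <- gacc$Wq[[h]]
          grads[[id]][[sprintf("%sWk%d", pre, h)]] <- gacc$Wk[[h]]
          grads[[id]][[sprintf("%sWv%d", pre, h)]] <- gacc$Wv[[h]]
        }
      }
      dtok_in <- do.call(rbind, dXs)              # PE add: identity grad
      emb <- dense_backward(hc$emb, dtok_in)
      grads[[id]]$emb_W <- emb$dW; grads[[id]]$emb_b <- emb$db
      dh[[id]] <- unpatchify_batch(emb$dx, att$patch_size, hc$Hb, hc$Wb,
                                   hc$Cb, hc$N)
    }
  }

  # encoder blocks, deepest first, with the coupling-point adjoint
  for (bk in seq(nb, 1)) {
    live <- ids[!vapply(dh[ids], is.null, TRUE)]
    if (length(ids) > 1) {
      raw <- cache$mix_raw[[bk]]
      draw <- stats::setNames(vector("list", length(ids)), ids)
      for (q_id in ids) {
        acc <- NULL
        for (p_id in live) {
          w <- if (p_id == q_id) 1 else alpha[p_id, q_id]
          contrib <- w * dh[[p_id]]
          acc <- if (is.null(acc)) contrib else acc + contrib
          if (p_id != q_id) {
            a <- alpha[p_id, q_id]
            dbeta[p_id, q_id] <- dbeta[p_id, q_id] +
              sum(dh[[p_id]] * raw[[q_id]]) * a * (1 - a)
          }
        }
        draw[[q_id]] <- acc
      }
    } else {
      draw <- dh
    }
    for (id in ids) {
      ec <- cache$enc[[id]][[bk]]
      dpool <- draw[[id]]
      dskip <- dskips[[id]][[bk]]
      if (is.null(dpool) && is.null(dskip)) { dh[[id]] <- NULL; next }
      drl <- if (is.null(dpool)) 0 else maxpool2_backward(ec$pool, dpool)
      if (!is.null(dskip)) drl <- drl + dskip
      dz <- relu_backward(ec$rl, drl)
      if (enc$batchnorm) {
        bb <- batchnorm_backward(ec$bn, dz)
        grads[[id]] <- acc_grad(grads[[id]], sprintf("enc%d_bn_g", bk), bb$dgamma)
        grads[[id]] <- acc_grad(grads[[id]], sprintf("enc%d_bn_b", bk), bb$dbeta)
        dz <- bb$dx
      }
      cb <- conv2d_backward(ec$cv, dz, need_dx = bk > 1L)
      grads[[id]] <- acc_grad(grads[[id]], sprintf("enc%d_W", bk), cb$dW)
      grads[[id]] <- acc_grad(grads[[id]], sprintf("enc%d_b", bk), cb$db)
      dh[[id]] <- cb$dx
    }
  }
  list(grads = grads, dbeta = dbeta)
}

#' One TTC training step
#'
#' Runs the joint forward pass, computes each non-frozen task's loss D_p,
#' backpropagates the total cost sum_p D_p through the coupling points,
#' and applies W_{t+1} = W_t + V_{t+1} with V the optimizer transform of
#' the negative gradient.  Coupling parameters follow the chain rule
#' through alpha = sigmoid(beta) (factor alpha (1 - alpha)).  Frozen
#' subnetworks, their batch-norm state, and their beta rows never change.
#'
#' @param model A ttc_model.
#' @param batch list(x = H x W x C x N array, targets = named list:
#'   class-index vector for classification tasks, H x W x N mask array
#'   for segmentation tasks).  Targets are required for every non-frozen
#'   task.
#' @param loss_cfg Named list of [loss_config()] per task.
#' @param train_cfg [train_config()].
#' @param state Optimizer state from a previous step (NULL to start).
#' @return list(model, state, losses = per-task D_p).
#' @export
ttc_step <- function(model, batch, loss_cfg, train_cfg, state = NULL) {
  if (is.null(state)) state <- init_update_state(model)
  ids <- names(model$task_specs)
  unfrozen <- ids[!vapply(model$task_specs, `[[`, TRUE, "frozen")]
  for (id in unfrozen) {
    if (is.null(batch$targets[[id]]))
      stop_invalid("missing target for non-frozen task '%s'", id)
  }
  fw <- forward_full(model, batch$x, training = TRUE,
                     dropout_seed = train_cfg$seed + model$step)
  model$bn_state <- fw$bn_state
  losses <- list(); dlogits <- stats::setNames(vector("list", length(ids)), ids)
  for (id in unfrozen) {
    lg <- task_loss_grad(model$task_specs[[id]], loss_cfg[[id]],
                         fw$cache$heads[[id]], batch$targets[[id]])
    losses[[id]] <- lg$loss
    dlogits[[id]] <- lg$dlogits
  }
  bw <- backward_full(model, fw$cache, dlogits)
  t_new <- state$t + 1L
  Vrec <- list()
  for (id in unfrozen) {
    g <- bw$grads[[id]]
    for (nm in names(model$params[[id]])) {
      gv <- g[[nm]]
      if (is.null(gv)) next
      up <- optim_update(gv, state$m[[id]][[nm]], state$v[[id]][[nm]],
                         t_new, train_cfg)
      state$m[[id]][[nm]] <- up$m
      state$v[[id]][[nm]] <- up$v
      model$params[[id]][[nm]] <- model$params[[id]][[nm]] + up$V
      Vrec[[id]][[nm]] <- up$V
    }
  }
  # beta updates: entries (p, q), p unfrozen, p != q
  Vb <- model$ttc_beta * 0
  for (p_id in unfrozen) for (q_id in ids) {
    if (p_id == q_id || is.na(model$ttc_beta[p_id, q_id])) next
    up <- optim_update(bw$dbeta[p_id, q_id], state$mb[p_id, q_id],
                       state$vb[p_id, q_id], t_new, train_cfg)
    state$mb[p_id, q_id] <- up$m
    state$vb[p_id, q_id] <- up$v
    model$ttc_beta[p_id, q_id] <- model$ttc_beta[p_id, q_id] + up$V
    Vb[p_id, q_id] <- up$V
  }
  state$t <- t_new
  state$V <- Vrec
  state$V_beta <- Vb
  model$step <- model$step + 1L
  list(model = model, state = state, losses = losses)
}

samples_to_batch <- function(samples, task_specs) {
  d <- dim(samples[[1]]$image)
  N <- length(samples)
  x <- array(0, c(d[1], d[2], N, d[3]))      # internal [H, W, N, C]
  for (n in seq_len(N)) x[, , n, ] <- samples[[n]]$image
  targets <- list()
  cls <- smear_classes()
  for (id in names(task_specs)) {
    if (task_specs[[id]]$kind == "classification") {
      targets[[id]] <- vapply(samples, function(s) match(s$label, cls), 0L)
    } else {
      m <- array(0, c(d[1], d[2], N))
      for (n in seq_len(N)) m[, , n] <- samples[[n]]$mask
      targets[[id]] <- m
    }
  }
  list(x = x, targets = targets)
}

eval_split <- function(model, samples, batch_size = 32L, threshold = 0.5) {
  ids <- names(model$task_specs)
  cls <- smear_classes()
  res <- list()
  nb <- ceiling(length(samples) / batch_size)
  pred_lab <- c(); true_lab <- c(); dscs <- c(); ious <- c()
  for (b in seq_len(nb)) {
    idx <- ((b - 1L) * batch_size + 1L):min(b * batch_size, length(samples))
    bt <- samples_to_batch(samples[idx], model$task_specs)
    pr <- forward_full(model, bt$x, training = FALSE)$preds
    for (id in ids) {
      sp <- model$task_specs[[id]]
      if (sp$kind == "classification") {
        pl <- max.col(pr[[id]], ties.method = "first")
        res[[id]]$pred <- c(res[[id]]$pred, cls[pl])
        res[[id]]$true <- c(res[[id]]$true,
                            vapply(samples[idx], `[[`, "", "label"))
        res[[id]]$loss <- c(res[[id]]$loss,
                            categorical_ce(bt$targets[[id]], pr[[id]]))
      } else {
        for (j in seq_along(idx)) {
          pm <- prob_to_mask(pr[[id]][, , j], threshold)
          res[[id]]$dsc <- c(res[[id]]$dsc, dsc(pm, samples[[idx[j]]]$mask))
          res[[id]]$iou <- c(res[[id]]$iou, iou(pm, samples[[idx[j]]]$mask))
        }
        res[[id]]$loss <- c(res[[id]]$loss,
                            bce_loss(bt$targets[[id]],
                                     array(pr[[id]],
                                           dim = dim(bt$targets[[id]]))))
      }
    }
  }
  res
}

#' Fit a multi-task TTC model
#'
#' Epoch loop over shuffled mini-batches of [ttc_step()].  History
#' records per-epoch loss and metric (classification accuracy or mean
#' Dice) for the training and validation splits.  Deterministic given
#' `train_cfg$seed` in single-threaded BLAS.
#'
#' @param model A ttc_model.
#' @param dataset list(samples = list of SmearSample, split =
#'   [split_dataset()] output).
#' @param loss_cfg Named list of [loss_config()] per task.
#' @param train_cfg [train_config()].
#' @param state Optional optimizer state to resume.
#' @return list(model, history = data.frame(epoch, task_id, split, loss,
#'   metric), state).
#' @export
fit <- function(model, dataset, loss_cfg, train_cfg, state = NULL) {
  by_id <- stats::setNames(dataset$samples,
                           vapply(dataset$samples, `[[`, "", "sample_id"))
  train_s <- by_id[dataset$split$train_ids]
  val_s <- by_id[dataset$split$val_ids]
  if (length(train_s) == 0) stop_invalid("empty training split")
  if (is.null(state)) state <- init_update_state(model)
  hist <- list()
  ids <- names(model$task_specs)
  unfrozen <- ids[!vapply(model$task_specs, `[[`, TRUE, "frozen")]
  if (train_cfg$epochs == 0)
    return(list(model = model, history = data.frame(), state = state))
  for (ep in seq_len(train_cfg$epochs)) {
    ord <- with_seed(train_cfg$seed + 7919L * ep,
                     sample.int(length(train_s)))
    bs <- train_cfg$batch_size
    nb <- ceiling(length(train_s) / bs)
    ep_loss <- stats::setNames(numeric(length(unfrozen)), unfrozen)
    for (b in seq_len(nb)) {
      idx <- ((b - 1L) * bs + 1L):min(b * bs, length(train_s))
      batch <- samples_to_batch(train_s[ord[idx]], model$task_specs)
      st <- ttc_step(model, batch, loss_cfg, train_cfg, state)
      model <- st$model; state <- st$state
      for (id in unfrozen)
        ep_loss[id] <- ep_loss[id] + st$losses[[id]] * length(idx)
    }
    ep_loss <- ep_loss / length(train_s)
    model <- recalibrate_bn(model, train_s[ord], bs)
    vl <- if (length(val_s)) eval_split(model, val_s, bs) else NULL
    for (id in unfrozen) {
      sp <- model$task_specs[[id]]
      hist[[length(hist) + 1L]] <- data.frame(
        epoch = ep, task_id = id, split = "train",
        loss = unname(ep_loss[id]), metric = NA_real_)
      if (!is.null(vl)) {
        metric <- if (sp$kind == "classification")
          mean(vl[[id]]$pred == vl[[id]]$true) else mean(vl[[id]]$dsc)
        hist[[length(hist) + 1L]] <- data.frame(
          epoch = ep, task_id = id, split = "val",
          loss = mean(vl[[id]]$loss), metric = metric)
      }
    }
  }
  list(model = model, history = do.call(rbind, hist), state = state)
}

#' Train only the newest (non-frozen) task of a grown model
#'
#' After [add_task()], fits the model on the new task's data.  Frozen
#' subnetwork weights, optimizer state, and beta rows remain bit-identical
#' throughout.
#'
#' @param model A ttc_model with at least one frozen task and one
#'   non-frozen task.
#' @param new_task_dataset Dataset for the new task (same structure as
#'   in [fit()]).
#' @param loss_cfg Named list of [loss_config()] covering the new task.
#' @param train_cfg [train_config()].
#' @return list(model, history, state).
#' @export
incremental_fit <- function(model, new_task_dataset, loss_cfg, train_cfg) {
  frozen <- vapply(model$task_specs, `[[`, TRUE, "frozen")
  if (!any(frozen)) stop_invalid("no frozen task: use fit()")
  if (all(frozen)) stop("no unfrozen task to train", call. = FALSE)
  fit(model, new_task_dataset, loss_cfg, train_cfg)
}
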