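# Shared builders for desk-scale fixtures.  Everything is generated in
# code; no stored data.

tiny_encoder <- function(input_size = 16L, channels = c(3L, 4L),
                         dropout = 0, batchnorm = TRUE) {
  encoder_config(n_blocks = length(channels), channels = channels,
                 input_size = input_size, dropout = dropout,
                 batchnorm = batchnorm)
}

tiny_attention <- function(n_heads = 2L, head_dim = 3L) {
  attention_config(n_heads = n_heads, head_dim = head_dim, patch_size = 2L,
                   n_tx_blocks = 1L, ffn_dim = 8L)
}

two_task_specs <- function() {
  list(task_spec("classify", "classification", 4L),
       task_spec("segment", "segmentation"))
}

tiny_two_task_model <- function(seed = 7L, ttc_init_beta = 0.3, ...) {
  build_model(two_task_specs(), tiny_encoder(...), tiny_attention(),
              ttc_init_beta = ttc_init_beta, seed = seed)
}

random_batch <- function(size = 16L, n = 3L, seed = 42L) {
  withr::with_seed(seed, list(
    x = array(stats::runif(size * size * n * 3), c(size, size, n, 3L)),
    targets = list(
      classify = sample(1:4, n, replace = TRUE),
      segment = array(stats::rbinom(size * size * n, 1, 0.3),
                      c(size, size, n)))))
}

# nudge every parameter away from exact zeros so no ReLU sits on a kink
# when comparing analytic gradients with finite differences
jitter_params <- function(model, sd = 0.05, seed = 11L) {
  withr::with_seed(seed, {
    for (id in names(model$params)) {
      model$params[[id]] <- lapply(model$params[[id]], function(w)
        w + stats::rnorm(length(w), 0, sd))
    }
  })
  model
}

smear_dataset <- function(n = 40L, image_size = 32L, seed = 5L,
                          fractions = c(0.8, 0.1, 0.1)) {
  ds <- generate_dataset(synthetic_params(image_size = image_size,
                                          seed = seed), n)
  list(samples = ds$samples,
       split = split_dataset(ds$manifest$sample_id, fractions, seed = seed),
       manifest = ds$manifest)
}

param_checksums <- function(params) {
  vapply(params, function(w) sum(w) + sum(w * seq_along(w)), numeric(1))
}

joint_loss <- function(model, batch, lcfg) {
  fw <- forward_full(model, batch$x, training = TRUE, dropout_seed = 1)
  l <- 0
  for (id in names(model$task_specs))
    l <- l + task_loss_grad(model$task_specs[[id]], lcfg[[id]],
                            fw$cache$heads[[id]], batch$targets[[id]])$loss
  l
}

joint_grads <- function(model, batch, lcfg, only = NULL) {
  fw <- forward_full(model, batch$x, training = TRUE, dropout_seed = 1)
  dl <- list()
  ids <- if (is.null(only)) names(model$task_specs) else only
  for (id in ids)
    dl[[id]] <- task_loss_grad(model$task_specs[[id]], lcfg[[id]],
                               fw$cache$heads[[id]], batch$targets[[id]])$dlogits
  backward_full(model, fw$cache, dl)
}

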