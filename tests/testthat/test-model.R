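# Model assembly: TTC matrix, deterministic initialization, forward
# contracts, task addition, checkpoint round-trips.

test_that("ttc_alpha is the logistic transform with its landmarks", {
  expect_equal(ttc_alpha(0), 0.5)
  expect_equal(ttc_alpha(log(3)), 0.75)
  expect_gt(ttc_alpha(20), 0.999999)
  expect_lt(ttc_alpha(20), 1)
  expect_error(ttc_alpha(Inf), "finite")
})

test_that("build_model pins the TTC diagonal at 1 and is deterministic", {
  single <- build_model(list(task_spec("classify", "classification")),
                        tiny_encoder(), tiny_attention(), seed = 3)
  expect_equal(unname(ttc_matrix(single)), matrix(1, 1, 1))

  m <- tiny_two_task_model(seed = 5, ttc_init_beta = 0)
  a <- ttc_matrix(m)
  expect_equal(unname(diag(a)), c(1, 1))
  expect_equal(a["classify", "segment"], 0.5)

  m2 <- tiny_two_task_model(seed = 5, ttc_init_beta = 0)
  expect_identical(m$params, m2$params)

  expect_error(build_model(list(task_spec("a"), task_spec("a")),
                           tiny_encoder(), tiny_attention()), "duplicate")
})

test_that("forward predictions satisfy the output contracts", {
  m <- tiny_two_task_model()
  withr::with_seed(1, x <- array(runif(16 * 16 * 3 * 3), c(16, 16, 3, 3)))
  pr <- predict_tasks(m, x)
  expect_equal(rowSums(pr$classify), rep(1, 3), tolerance = 1e-6)
  expect_identical(dim(pr$segment), c(16L, 16L, 3L))
  expect_true(all(pr$segment > 0 & pr$segment < 1))

  one <- predict_tasks(m, x[, , , 1])
  expect_equal(one$classify[1, ], pr$classify[1, ], tolerance = 1e-12)

  expect_error(predict_tasks(m, array(0, c(8, 8, 3, 1))), "expected")
})

test_that("near-zero connectivity reproduces the single-task forward", {
  joint <- build_model(two_task_specs(), tiny_encoder(), tiny_attention(),
                       ttc_init_beta = -40, seed = 9)
  solo_c <- build_model(list(task_spec("classify", "classification")),
                        tiny_encoder(), tiny_attention(), seed = 9)
  solo_s <- build_model(list(task_spec("segment", "segmentation")),
                        tiny_encoder(), tiny_attention(), seed = 9)
  expect_identical(joint$params$classify, solo_c$params$classify)

  withr::with_seed(2, x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2)))
  pj <- predict_tasks(joint, x)
  expect_equal(pj$classify, predict_tasks(solo_c, x)$classify,
               tolerance = 1e-6)
  expect_equal(pj$segment, predict_tasks(solo_s, x)$segment,
               tolerance = 1e-6)
})

test_that("add_task freezes prior tasks and grows the TTC matrix", {
  m <- build_model(list(task_spec("classify", "classification")),
                   tiny_encoder(), tiny_attention(), ttc_init_beta = 0.2,
                   seed = 4)
  before <- param_checksums(m$params$classify)
  m2 <- add_task(m, task_spec("segment", "segmentation"))

  expect_length(m2$task_specs, 2)
  expect_true(m2$task_specs$classify$frozen)
  expect_false(m2$task_specs$segment$frozen)
  expect_identical(param_checksums(m2$params$classify), before)
  expect_identical(m2$params$classify, m$params$classify)

  a <- ttc_matrix(m2)
  expect_identical(dim(a), c(2L, 2L))
  expect_equal(unname(diag(a)), c(1, 1))
  expect_equal(a["segment", "classify"], ttc_alpha(0.2))

  expect_error(add_task(m2, task_spec("segment", "segmentation")),
               "duplicate")
})

test_that("checkpoints round-trip bit-exactly", {
  m <- tiny_two_task_model(seed = 2)
  ds <- smear_dataset(n = 12, image_size = 16L)
  lcfg <- list(classify = loss_config("categorical"),
               segment = loss_config("focal"))
  tcfg <- train_config(batch_size = 4L, epochs = 1L, seed = 1)
  m <- fit(m, ds, lcfg, tcfg)$model   # nontrivial weights and bn state

  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m2$params, m$params)
  expect_identical(m2$ttc_beta, m$ttc_beta)
  expect_identical(m2$bn_state, m$bn_state)

  withr::with_seed(3, x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2)))
  expect_identical(predict_tasks(m2, x), predict_tasks(m, x))

  expect_error(load_checkpoint(file.path(tempdir(), "absent.rds")),
               "not found")
})

test_that("hierarchical decision splits benign-vs-malignant before subtype", {
  # flat argmax would call this Benign (0.4 largest single class), but
  # the malignant mass 0.6 wins the first stage
  expect_equal(hierarchical_decision(c(0.4, 0.3, 0.2, 0.1)), "Early-B")
  expect_equal(hierarchical_decision(c(0.6, 0.2, 0.1, 0.1)), "Benign")
  probs <- rbind(c(0.5, 0.3, 0.1, 0.1), c(0.1, 0.2, 0.3, 0.4))
  expect_equal(hierarchical_decision(probs), c("Benign", "Pro-B"))
  expect_error(hierarchical_decision(c(0.5, 0.5)), "one column per class")
})
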