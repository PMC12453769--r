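# Training mechanics: gradient correctness against finite differences,
# update bookkeeping, descent, determinism, freezing.

test_that("analytic gradients match central finite differences", {
  m <- jitter_params(tiny_two_task_model())
  batch <- random_batch()
  lcfg <- list(classify = loss_config("categorical"),
               segment = loss_config("focal", class_weight = 2))
  bw <- joint_grads(m, batch, lcfg)
  h <- 1e-5
  withr::with_seed(21, {
    for (id in c("classify", "segment")) {
      nms <- sample(names(m$params[[id]]), 6)
      for (nm in nms) {
        i <- sample(length(m$params[[id]][[nm]]), 1)
        m2 <- m; m2$params[[id]][[nm]][i] <- m2$params[[id]][[nm]][i] + h
        m3 <- m; m3$params[[id]][[nm]][i] <- m3$params[[id]][[nm]][i] - h
        num <- (joint_loss(m2, batch, lcfg) - joint_loss(m3, batch, lcfg)) /
          (2 * h)
        expect_lt(abs(bw$grads[[id]][[nm]][i] - num), 1e-5,
                  label = sprintf("grad error %s/%s", id, nm))
      }
    }
  })
})

test_that("beta gradient follows the sigmoid chain rule (vs FD)", {
  m <- jitter_params(tiny_two_task_model())
  batch <- random_batch()
  lcfg <- list(classify = loss_config("categorical"),
               segment = loss_config("focal", class_weight = 2))
  bw <- joint_grads(m, batch, lcfg)
  h <- 1e-5
  for (p in c("classify", "segment")) for (q in c("classify", "segment")) {
    if (p == q) next
    m2 <- m; m2$ttc_beta[p, q] <- m2$ttc_beta[p, q] + h
    m3 <- m; m3$ttc_beta[p, q] <- m3$ttc_beta[p, q] - h
    num <- (joint_loss(m2, batch, lcfg) - joint_loss(m3, batch, lcfg)) /
      (2 * h)
    expect_lt(abs(bw$dbeta[p, q] - num), 1e-5)
  }
})

test_that("the applied update equals the stored V exactly", {
  m <- tiny_two_task_model()
  batch <- random_batch()
  lcfg <- list(classify = loss_config("categorical"),
               segment = loss_config("focal"))
  for (opt in c("adam", "sgd")) {
    tcfg <- train_config(optimizer = opt, batch_size = 3L, seed = 1)
    st <- ttc_step(m, batch, lcfg, tcfg)
    for (id in names(m$params)) for (nm in names(st$state$V[[id]])) {
      expect_identical(st$model$params[[id]][[nm]],
                       m$params[[id]][[nm]] + st$state$V[[id]][[nm]])
    }
    off <- which(row(m$ttc_beta) != col(m$ttc_beta))
    expect_identical(st$model$ttc_beta[off],
                     m$ttc_beta[off] + st$state$V_beta[off])
    expect_identical(st$state$t, 1L)
  }
})

test_that("a small plain-SGD step decreases the total cost", {
  m <- jitter_params(tiny_two_task_model())
  batch <- random_batch()
  lcfg <- list(classify = loss_config("categorical"),
               segment = loss_config("focal"))
  tcfg <- train_config(lr = 1e-3, optimizer = "sgd", seed = 1)
  l0 <- joint_loss(m, batch, lcfg)
  st <- ttc_step(m, batch, lcfg, tcfg)
  expect_lt(joint_loss(st$model, batch, lcfg), l0)
})

test_that("frozen subnetworks and their beta rows never change", {
  m <- tiny_two_task_model()
  m$task_specs$classify$frozen <- TRUE
  batch <- random_batch()
  batch$targets$classify <- NULL            # frozen task needs no target
  lcfg <- list(segment = loss_config("focal"))
  tcfg <- train_config(seed = 1)
  st <- ttc_step(m, batch, lcfg, tcfg)
  expect_identical(st$model$params$classify, m$params$classify)
  expect_identical(st$model$ttc_beta["classify", "segment"],
                   m$ttc_beta["classify", "segment"])
  expect_false(identical(st$model$params$segment, m$params$segment))
  expect_false(identical(st$model$ttc_beta["segment", "classify"],
                         m$ttc_beta["segment", "classify"]))
  expect_named(st$losses, "segment")
})

test_that("missing targets for non-frozen tasks are rejected", {
  m <- tiny_two_task_model()
  batch <- random_batch()
  batch$targets$segment <- NULL
  lcfg <- list(classify = loss_config("categorical"),
               segment = loss_config("focal"))
  expect_error(ttc_step(m, batch, lcfg, train_config(seed = 1)),
               "missing target")
})

test_that("fit is deterministic, epoch-0 is a no-op, and loss decreases", {
  ds <- smear_dataset(n = 48, image_size = 16L, seed = 6)
  m <- tiny_two_task_model(seed = 3)
  lcfg <- list(classify = loss_config("categorical"),
               segment = loss_config("focal"))

  r0 <- fit(m, ds, lcfg, train_config(epochs = 0L, seed = 1))
  expect_identical(r0$model$params, m$params)

  tcfg <- train_config(lr = 0.01, batch_size = 16L, epochs = 3L, seed = 1)
  r1 <- fit(m, ds, lcfg, tcfg)
  r2 <- fit(m, ds, lcfg, tcfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$model$params, r2$model$params)

  tr <- subset(r1$history, split == "train")
  for (id in c("classify", "segment")) {
    li <- tr$loss[tr$task_id == id]
    expect_lt(li[length(li)], li[1])
  }

  expect_error(fit(m, list(samples = ds$samples,
                           split = list(train_ids = character(0),
                                        val_ids = character(0),
                                        test_ids = character(0))),
                   lcfg, tcfg), "empty training split")
})

test_that("incremental fit trains only the new task", {
  ds <- smear_dataset(n = 32, image_size = 16L, seed = 8)
  lcfg <- list(classify = loss_config("categorical"),
               segment = loss_config("focal"))
  m <- build_model(list(task_spec("classify", "classification")),
                   tiny_encoder(), tiny_attention(), seed = 2)
  m <- fit(m, ds, lcfg["classify"],
           train_config(lr = 0.01, batch_size = 16L, epochs = 2L,
                        seed = 1))$model
  base_eval <- evaluate_model(m, ds$samples[1:8])

  m2 <- add_task(m, task_spec("segment", "segmentation"))
  frozen_before <- m2$params$classify
  r <- incremental_fit(m2, ds, lcfg,
                       train_config(lr = 0.01, batch_size = 16L,
                                    epochs = 2L, seed = 1))
  expect_identical(r$model$params$classify, frozen_before)

  tr <- subset(r$history, split == "train" & task_id == "segment")
  expect_lt(tr$loss[nrow(tr)], tr$loss[1])

  # the frozen task's evaluation is unchanged by the incremental fit
  after_eval <- evaluate_model(r$model, ds$samples[1:8])
  expect_identical(after_eval$classify$confusion, base_eval$classify$confusion)

  expect_error(incremental_fit(m, ds, lcfg, train_config(seed = 1)),
               "no frozen task")
})
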