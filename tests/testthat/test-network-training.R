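test_that("backpropagated gradients match numerical differentiation", {
  # segmenter covers dense-free path: conv, pool, upsample, skip concat
  set.seed(61)
  model <- tiny_segmenter(input_shape = c(6L, 6L, 1L), n_classes = 3L,
                          filters = 2L, init_seed = 5L)
  x <- array(rnorm(2 * 36), c(2, 6, 6, 1))
  y <- array(sample(0:2, 72, TRUE), c(2, 6, 6))
  masks <- mcdropconnect:::draw_network_masks(model, 42L, 7L)
  loss_at <- function(m) {
    fw <- mcdropconnect:::network_forward(m, x, masks)
    yy <- as.integer(y)
    -mean(log(pmax(fw$probs[cbind(seq_along(yy), yy + 1L)], 1e-12)))
  }
  fw <- mcdropconnect:::network_forward(model, x, masks, keep_cache = TRUE)
  yy <- as.integer(y)
  oh <- matrix(0, length(yy), 3); oh[cbind(seq_along(yy), yy + 1L)] <- 1
  grads <- mcdropconnect:::network_backward(model, fw$cache,
                                            (fw$probs - oh) / length(yy))
  for (i in mcdropconnect:::stochastic_node_idx(model)) {
    th <- model$nodes[[i]]$spec$theta
    probe <- sample(seq_along(th), min(12, length(th)))
    for (j in probe) {
      m2 <- model; m2$nodes[[i]]$spec$theta[j] <- th[j] + 1e-5
      m1 <- model; m1$nodes[[i]]$spec$theta[j] <- th[j] - 1e-5
      num <- (loss_at(m2) - loss_at(m1)) / 2e-5
      expect_equal(grads[[i]][j], num, tolerance = 1e-5)
    }
  }
})

test_that("the objective reduces to mean cross-entropy when weight decay is zero", {
  task <- generate_blob_task(n = 60, seed = 3)
  model <- tiny_mlp(hidden = 8L, init_seed = 3)
  probs <- pmax(deterministic_predict(model, task$features), 1e-12)
  ce <- -mean(log(probs[cbind(seq_len(60), task$labels + 1L)]))
  expect_equal(training_objective(model, task$features, task$labels,
                                  training_config(weight_decay = 0)),
               ce, tolerance = 1e-12)
  with_l2 <- training_objective(model, task$features, task$labels,
                                training_config(weight_decay = 0.01))
  expect_gt(with_l2, ce)
})

test_that("the L2 penalty contributes gradient 2 * lambda * theta", {
  # one SGD step from identical states with and without weight decay:
  # the first-step update difference is exactly -lr * 2 * lambda * theta
  task <- generate_blob_task(n = 100, seed = 5)
  lam <- 0.1; lr <- 0.02
  eff_lr <- lr * 0.01 # a one-epoch run sits in the last decay step
  m0 <- tiny_mlp(hidden = 8L, init_seed = 5)
  cfg0 <- training_config(weight_decay = 0, epochs = 1L, batch_size = 100L,
                          learning_rate = lr, seed = 9)
  cfg1 <- training_config(weight_decay = lam, epochs = 1L,
                          batch_size = 100L, learning_rate = lr, seed = 9)
  t0 <- train_model(m0, task$features, task$labels, cfg0)
  t1 <- train_model(m0, task$features, task$labels, cfg1)
  for (i in mcdropconnect:::stochastic_node_idx(m0)) {
    diff <- t1$nodes[[i]]$spec$theta - t0$nodes[[i]]$spec$theta
    expect_equal(diff, -eff_lr * 2 * lam * m0$nodes[[i]]$spec$theta,
                 tolerance = 1e-10)
  }
})

test_that("training is bit-reproducible under a fixed seed", {
  task <- generate_blob_task(n = 120, seed = 7)
  cfg <- training_config(epochs = 3L, seed = 11)
  run <- function() train_model(tiny_mlp(hidden = 8L, init_seed = 7),
                                task$features, task$labels, cfg)
  a <- run(); b <- run()
  for (i in mcdropconnect:::stochastic_node_idx(a)) {
    expect_identical(a$nodes[[i]]$spec$theta, b$nodes[[i]]$spec$theta)
  }
  expect_identical(a$loss_trace, b$loss_trace)
  # drop-free training is deterministic too
  cfg1 <- training_config(keep_prob = 1, epochs = 2L, seed = 11)
  m1 <- tiny_mlp(hidden = 8L, keep_prob = 1, init_seed = 7)
  expect_identical(
    train_model(m1, task$features, task$labels, cfg1)$loss_trace,
    train_model(m1, task$features, task$labels, cfg1)$loss_trace)
})

test_that("training failure on divergence carries the loss trace", {
  task <- generate_blob_task(n = 100, seed = 13)
  err <- tryCatch(
    train_model(tiny_mlp(hidden = 8L, init_seed = 13),
                task$features, task$labels,
                training_config(learning_rate = 1e200, epochs = 3L,
                                seed = 13)),
    mcdc_training_failure = function(e) e)
  expect_s3_class(err, "mcdc_training_failure")
})

test_that("training drives the loss down on the blob task", {
  fix <- trained_blob_model()
  tr <- fix$model$loss_trace
  expect_lt(tr$loss[nrow(tr)], tr$loss[1])
  g <- glance(fix$model)
  expect_true(g$trained)
  expect_equal(g$final_loss, tr$loss[nrow(tr)])
  td <- tidy(fix$model)
  expect_equal(nrow(td), 3)
  expect_true(all(td$keep_prob == 0.5))
})

test_that("invalid training configurations are rejected", {
  expect_error(training_config(weight_decay = -1),
               class = "mcdc_invalid_parameter")
  expect_error(training_config(keep_prob = 0),
               class = "mcdc_invalid_parameter")
})

test_that("reference models stay small and share shapes across mask modes", {
  refs <- reference_models()
  expect_named(refs, c("mlp_dropconnect", "mlp_dropout", "cnn_dropconnect",
                       "cnn_dropout", "segmenter_dropconnect",
                       "segmenter_dropout"))
  for (m in refs) expect_lt(n_parameters(m), 1e5)
  expect_identical(n_parameters(refs$mlp_dropconnect),
                   n_parameters(refs$mlp_dropout))
  expect_identical(n_parameters(refs$cnn_dropconnect),
                   n_parameters(refs$cnn_dropout))
  expect_identical(n_parameters(refs$segmenter_dropconnect),
                   n_parameters(refs$segmenter_dropout))
  # declared output shapes survive a forward pass
  x <- array(rnorm(2 * 16 * 16), c(2, 16, 16, 1))
  out <- deterministic_predict(refs$cnn_dropconnect, x)
  expect_equal(dim(out), c(2, 3))
  xs <- array(rnorm(2 * 24 * 24), c(2, 24, 24, 1))
  outs <- deterministic_predict(refs$segmenter_dropconnect, xs)
  expect_equal(dim(outs), c(2 * 24 * 24, 4))
  expect_equal(attr(outs, "spatial"), c(2, 24, 24))
})
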