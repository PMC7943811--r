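test_that("a drop-free model yields T identical samples equal to the deterministic pass", {
  model <- tiny_mlp(d_in = 4L, hidden = 8L, n_classes = 3L, keep_prob = 1,
                    init_seed = 2L)
  x <- matrix(rnorm(20), 5, 4)
  expect_warning(ms <- mc_predict(model, x, T = 5, seed = 1),
                 "no stochastic layers")
  det <- deterministic_predict(model, x)
  for (t in 1:5) expect_equal(ms$samples[t, , ], det, ignore_attr = TRUE)
  expect_equal(predictive_mean(ms), det, ignore_attr = TRUE)
})

test_that("MC prediction is reproducible and continuable across seed streams", {
  fix <- trained_blob_model()
  x <- fix$task$features[301:340, ]
  a <- mc_predict(fix$model, x, T = 6, seed = 5)
  b <- mc_predict(fix$model, x, T = 6, seed = 5)
  expect_identical(a$samples, b$samples)
  # continuation: T = 2 then T = 4 at offset 2 equals one T = 6 run
  h1 <- mc_predict(fix$model, x, T = 2, seed = 5)
  h2 <- mc_predict(fix$model, x, T = 4, seed = 5, draw_offset = 2)
  expect_identical(h1$samples, a$samples[1:2, , , drop = FALSE])
  expect_identical(h2$samples, a$samples[3:6, , , drop = FALSE])
})

test_that("sample rows stay on the probability simplex", {
  fix <- trained_blob_model()
  ms <- mc_predict(fix$model, fix$task$features[301:350, ], T = 8, seed = 3)
  sums <- apply(ms$samples, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  pm <- predictive_mean(ms)
  expect_true(all(abs(rowSums(pm) - 1) < 1e-6))
})

test_that("the predictive mean is the elementwise average of the passes", {
  s <- array(0, c(2, 1, 2))
  s[1, 1, ] <- c(1, 0); s[2, 1, ] <- c(0, 1)
  ms <- mcdropconnect:::new_mc_prediction_set(s)
  expect_equal(as.numeric(predictive_mean(ms)), c(0.5, 0.5))
  s3 <- array(0, c(3, 1, 2))
  s3[1, 1, ] <- c(0.9, 0.1); s3[2, 1, ] <- c(0.6, 0.4); s3[3, 1, ] <- c(0.6, 0.4)
  ms3 <- mcdropconnect:::new_mc_prediction_set(s3)
  expect_equal(as.numeric(predictive_mean(ms3)), c(0.7, 0.3))
  # idempotence on identical samples
  si <- array(rep(c(0.2, 0.8), each = 4), c(4, 1, 2))
  expect_equal(as.numeric(predictive_mean(mcdropconnect:::new_mc_prediction_set(si))),
               c(0.2, 0.8))
})

test_that("argmax labels break ties toward the lowest class index", {
  expect_identical(predicted_labels(rbind(c(0.5, 0.5), c(0.2, 0.8))),
                   c(0L, 1L))
  expect_identical(predicted_labels(matrix(1 / 3, 1, 3)), 0L)
})

test_that("the streaming moment accumulator matches the full sample path", {
  fix <- trained_blob_model()
  x <- fix$task$features[301:330, ]
  ms <- mc_predict(fix$model, x, T = 12, seed = 9)
  mo <- mc_predict_moments(fix$model, x, T = 12, seed = 9)
  expect_equal(predictive_mean(ms), mo$mean_probs, tolerance = 1e-12)
  sc_full <- uncertainty_scores(ms)
  sc_mom <- uncertainty_scores(mo)
  expect_equal(sc_full$mutual_information, sc_mom$mutual_information,
               tolerance = 1e-9)
})

test_that("invalid MC parameters are rejected", {
  fix <- trained_blob_model()
  expect_error(mc_predict(fix$model, fix$task$features[1:5, ], T = 0),
               class = "mcdc_invalid_parameter")
  expect_error(convergence_curve(fix$model, fix$task$features[1:5, ],
                                 fix$task$labels[1:5], integer(0)),
               class = "mcdc_invalid_parameter")
  expect_error(convergence_curve(fix$model, fix$task$features[1:5, ],
                                 fix$task$labels[1:5], c(4, 2)),
               class = "mcdc_invalid_parameter")
  expect_error(convergence_curve(fix$model, fix$task$features[1:5, ],
                                 fix$task$labels[1:5], c(2, 4),
                                 repetitions = 1),
               class = "mcdc_invalid_parameter")
})

test_that("convergence analysis defaults to 10 repetitions and degenerates cleanly", {
  expect_identical(eval(formals(convergence_curve)$repetitions), 10L)
  model <- tiny_mlp(d_in = 4L, hidden = 8L, n_classes = 3L, keep_prob = 1,
                    init_seed = 2L)
  x <- matrix(rnorm(40), 10, 4)
  y <- rep(0:2, length.out = 10)
  cc <- suppressWarnings(
    convergence_curve(model, x, y, c(1L, 4L), repetitions = 3, seed = 1))
  expect_equal(cc$sd_error, c(0, 0))
  expect_equal(cc$mean_error[1], cc$mean_error[2])
})

test_that("error variability shrinks as T grows", {
  fix <- trained_blob_model()
  x <- fix$task$features[301:500, ]
  y <- fix$task$labels[301:500]
  cc <- convergence_curve(fix$model, x, y, c(2L, 32L), repetitions = 10,
                          seed = 21)
  expect_lte(cc$sd_error[2], cc$sd_error[1])
  g <- glance(cc)
  expect_true(is.finite(g$deterministic_error))
  expect_true(g$first_T_within_sd %in% cc$T)
})
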