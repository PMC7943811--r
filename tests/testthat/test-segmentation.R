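test_that("segmentation scores match hand-computed confusion matrices", {
  perfect <- segmentation_scores(c(0, 1, 2, 0), c(0, 1, 2, 0), 3)
  expect_equal(perfect$pixel_accuracy, 1)
  expect_equal(perfect$mean_accuracy, 1)
  expect_equal(perfect$mean_iou, 1)
  # two-class confusion [[3,1],[1,3]]
  true <- c(rep(0, 4), rep(1, 4))
  pred <- c(0, 0, 0, 1, 1, 1, 1, 0)
  s <- segmentation_scores(pred, true, 2)
  expect_equal(s$pixel_accuracy, 0.75)
  expect_equal(s$mean_accuracy, 0.75)
  expect_equal(s$mean_iou, 0.6)
})

test_that("classes absent from the ground truth are excluded from class means", {
  true <- c(0, 0, 1, 1)
  pred <- c(0, 2, 1, 1)
  s <- segmentation_scores(pred, true, 3)
  expect_equal(s$n_classes_present, 2L)
  expect_equal(s$mean_accuracy, mean(c(0.5, 1)))
})

test_that("ignore-labelled pixels are excluded everywhere", {
  true <- c(0, 1, 255, 255)
  pred <- c(0, 0, 1, 0)
  s <- segmentation_scores(pred, true, 2)
  expect_equal(s$n_pixels, 2)
  expect_equal(s$pixel_accuracy, 0.5)
  expect_error(segmentation_scores(c(1, 1), c(255, 255), 2),
               class = "mcdc_invalid_input")
  expect_error(segmentation_scores(c(1, 1, 1), c(0, 1), 2),
               class = "mcdc_structural_error")
})

test_that("confusion-based scores equal a per-pixel loop oracle", {
  set.seed(47)
  for (rep in 1:40) {
    C <- sample(2:5, 1)
    n <- sample(30:120, 1)
    true <- sample(0:(C - 1), n, replace = TRUE)
    pred <- ifelse(runif(n) < 0.6, true, sample(0:(C - 1), n, replace = TRUE))
    s <- segmentation_scores(pred, true, C)
    cm <- matrix(0, C, C)
    for (i in seq_len(n)) cm[true[i] + 1, pred[i] + 1] <-
        cm[true[i] + 1, pred[i] + 1] + 1
    present <- rowSums(cm) > 0
    acc_i <- diag(cm)[present] / rowSums(cm)[present]
    iou_i <- diag(cm)[present] /
      (rowSums(cm)[present] + colSums(cm)[present] - diag(cm)[present])
    expect_equal(s$pixel_accuracy, sum(diag(cm)) / n)
    expect_equal(s$mean_accuracy, mean(acc_i))
    expect_equal(s$mean_iou, mean(iou_i))
  }
})

test_that("confidence-percentile accuracy keeps the most certain pixels", {
  i_norm <- (0:9) / 10
  correct <- i_norm < 0.5
  expect_equal(confidence_percentile_accuracy(i_norm, correct, 0),
               mean(correct))
  expect_equal(confidence_percentile_accuracy(i_norm, correct, 50), 1)
  # the 90th percentile retains the 10% most certain pixels
  expect_equal(confidence_percentile_accuracy(i_norm, correct, 90), 1)
  expect_equal(confidence_percentile_accuracy(i_norm, !correct, 90), 0)
  expect_error(confidence_percentile_accuracy(i_norm, correct, 100),
               class = "mcdc_invalid_parameter")
  # loop oracle on random data
  set.seed(53)
  i2 <- runif(57); c2 <- runif(57) < 0.7
  for (q in c(0, 25, 60, 90)) {
    k <- ceiling((100 - q) / 100 * 57)
    expect_equal(confidence_percentile_accuracy(i2, c2, q),
                 mean(c2[order(i2)][1:k]))
  }
})

test_that("rendered maps encode correctness and certainty as white", {
  pred <- matrix(c(0, 1, 1, 0), 2, 2)
  true <- matrix(c(0, 1, 0, 0), 2, 2)
  i_norm <- matrix(c(0.1, 0.2, 0.8, 0.9), 2, 2)
  maps <- render_maps(pred, true, i_norm, threshold = 0.5)
  expect_equal(sum(maps$correctness == 1), 3) # matches N_correct
  expect_equal(maps$confidence, matrix(c(1, 1, 0, 0), 2, 2))
  # threshold 0 blanks the confidence map (strict inequality)
  maps0 <- render_maps(pred, true, i_norm, threshold = 0)
  expect_true(all(maps0$confidence == 0))
  # perfect and fully certain renders all-white
  mp <- render_maps(true, true, i_norm * 0, threshold = 1)
  expect_true(all(mp$correctness == 1))
  expect_true(all(mp$confidence == 1))
  expect_error(render_maps(pred, true, i_norm, threshold = 2),
               class = "mcdc_invalid_parameter")
})

test_that("ignored pixels render neutral gray and PNGs are written", {
  pred <- matrix(0L, 4, 4)
  true <- matrix(0L, 4, 4); true[1, 1] <- 255L
  i_norm <- matrix(0.2, 4, 4)
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  maps <- render_maps(pred, true, i_norm, threshold = 0.5,
                      correctness_file = f1, confidence_file = f2)
  expect_equal(maps$correctness[1, 1], 0.5)
  expect_equal(maps$confidence[1, 1], 0.5)
  expect_true(file.exists(f1) && file.exists(f2))
  back <- png::readPNG(f1)
  expect_equal(dim(back), c(4, 4))
  expect_equal(back[1, 1], 0.5, tolerance = 1 / 255)
  unlink(c(f1, f2))
})

test_that("flat pixel vectors fold back into per-image maps", {
  vals <- seq_len(2 * 3 * 4)
  arr <- array(vals, c(2, 3, 4))
  maps <- as_label_maps(vals, c(2, 3, 4))
  expect_length(maps, 2)
  expect_equal(maps[[1]], matrix(arr[1, , ], 3, 4))
  expect_equal(maps[[2]], matrix(arr[2, , ], 3, 4))
})
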