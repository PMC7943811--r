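test_that("correctness maps are elementwise label agreement", {
  expect_identical(correctness_map(c(1, 2, 3), c(1, 0, 3)),
                   c(TRUE, FALSE, TRUE))
  expect_true(all(correctness_map(1:5, 1:5)))
  expect_false(any(correctness_map(1:5, 6:10)))
  expect_error(correctness_map(1:3, 1:4), class = "mcdc_structural_error")
})

test_that("certainty splits strictly below the threshold, ties uncertain", {
  expect_identical(certainty_split(c(0.1, 0.5, 0.9), 0.5),
                   c(TRUE, FALSE, FALSE))
  expect_false(any(certainty_split(c(0, 0.3, 1), 0)))
  expect_true(all(certainty_split(c(0.1, 0.5, 0.99), 1)))
  expect_error(certainty_split(c(0.5), 1.5),
               class = "mcdc_invalid_parameter")
})

test_that("four-way counts partition the items", {
  cnt <- confusion_counts(c(TRUE, TRUE, FALSE, FALSE),
                          c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(unname(cnt), c(1L, 1L, 1L, 1L))
  cnt2 <- confusion_counts(rep(TRUE, 7), rep(TRUE, 7))
  expect_identical(unname(cnt2), c(7L, 0L, 0L, 0L))
  set.seed(5)
  for (i in 1:50) {
    n <- sample(1:200, 1)
    cnt <- confusion_counts(runif(n) < 0.7, runif(n) < 0.4)
    expect_identical(sum(cnt), n)
  }
  expect_error(confusion_counts(c(TRUE), c(TRUE, FALSE)),
               class = "mcdc_structural_error")
})

test_that("ratio metrics follow the defining formulas with NA for 0/0", {
  r <- ratio_metrics(c(n_cc = 90, n_ic = 10, n_cu = 5, n_iu = 20))
  expect_equal(r$r_cc, 0.9)
  expect_equal(r$r_iu, 20 / 30)
  expect_equal(r$ua, 110 / 125)
  perfect <- ratio_metrics(c(n_cc = 50, n_ic = 0, n_cu = 0, n_iu = 0))
  expect_equal(perfect$r_cc, 1)
  expect_true(is.na(perfect$r_iu))
  expect_equal(perfect$ua, 1)
  all_unc <- ratio_metrics(c(n_cc = 0, n_ic = 0, n_cu = 3, n_iu = 2))
  expect_true(is.na(all_unc$r_cc))
  expect_equal(all_unc$r_iu, 1)
  expect_error(ratio_metrics(c(n_cc = 0, n_ic = 0, n_cu = 0, n_iu = 0)),
               class = "mcdc_invalid_input")
})

test_that("a constant-1 metric integrates to AUC 100 percent", {
  # all predictions correct and fully certain: r_cc is 1 wherever defined
  # and the undefined head is vacuously filled with 1
  mc <- metric_curves(rep(0, 20), rep(TRUE, 20))
  expect_equal(glance(mc)$r_cc_auc, 100)
})

test_that("a linear ramp integrates to AUC 50 percent", {
  # all incorrect with uniform uncertainties: ua(t) = 1 - F(t) ~ 1 - t
  n <- 2000
  i_norm <- (seq_len(n) - 0.5) / n
  mc <- metric_curves(i_norm, rep(FALSE, n))
  expect_lt(abs(glance(mc)$ua_auc - 50), 0.5)
})

test_that("threshold sweeps match a per-item brute-force loop exactly", {
  set.seed(17)
  ths <- seq(0, 1, length.out = 101)
  for (rep in 1:25) {
    n <- sample(20:150, 1)
    i_norm <- round(runif(n), 2) # ties on grid points exercise the boundary
    correct <- runif(n) < 0.8
    mc <- metric_curves(i_norm, correct, ths)
    for (k in sample(seq_along(ths), 12)) {
      th <- ths[k]
      ncc <- nic <- ncu <- niu <- 0L
      for (i in seq_len(n)) {
        cert <- i_norm[i] < th
        if (correct[i] && cert) ncc <- ncc + 1L
        else if (!correct[i] && cert) nic <- nic + 1L
        else if (correct[i]) ncu <- ncu + 1L
        else niu <- niu + 1L
      }
      expect_identical(c(mc$n_cc[k], mc$n_ic[k], mc$n_cu[k], mc$n_iu[k]),
                       as.numeric(c(ncc, nic, ncu, niu)))
      expect_equal(mc$ua[k], (ncc + niu) / n)
    }
  }
})

test_that("AUC is stable under grid refinement on smooth inputs", {
  set.seed(23)
  i_norm <- runif(4000)
  correct <- runif(4000) < plogis(3 - 6 * i_norm)
  a1 <- glance(metric_curves(i_norm, correct,
                             seq(0, 1, length.out = 101)))
  a2 <- glance(metric_curves(i_norm, correct,
                             seq(0, 1, length.out = 1001)))
  expect_lt(abs(a1$ua_auc - a2$ua_auc), 0.5)
  expect_lt(abs(a1$r_cc_auc - a2$r_cc_auc), 0.5)
  expect_lt(abs(a1$r_iu_auc - a2$r_iu_auc), 0.5)
})

test_that("grids must ascend strictly from 0 to 1", {
  expect_error(metric_curves(c(0.5), TRUE, seq(0.1, 1, length.out = 10)),
               class = "mcdc_invalid_parameter")
  expect_error(metric_curves(c(0.5), TRUE, c(0, 0.5, 0.5, 1)),
               class = "mcdc_invalid_parameter")
})

test_that("at threshold one, uncertainty accuracy reduces to accuracy", {
  set.seed(29)
  for (rep in 1:20) {
    n <- sample(10:100, 1)
    i_norm <- runif(n, 0, 0.99)
    correct <- runif(n) < 0.6
    te <- threshold_evaluation(i_norm, correct, 1)
    expect_equal(te$r_cc, mean(correct))
    expect_equal(te$ua, mean(correct))
    expect_true(is.na(te$r_iu) || te$r_iu == 0)
  }
})

test_that("KS separation matches CDF enumeration", {
  same <- c(0.1, 0.2, 0.3)
  expect_equal(ks_separation(same, same)$statistic, 0)
  expect_equal(ks_separation(c(0.1, 0.2), c(0.8, 0.9))$statistic, 1)
  expect_equal(ks_separation(c(0, 0, 1, 1), c(1, 1))$statistic, 0.5)
  expect_error(ks_separation(numeric(0), c(1)),
               class = "mcdc_invalid_input")
})
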