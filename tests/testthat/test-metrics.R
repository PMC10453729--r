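# frozen expected values: hand arithmetic / worked-example numbers checked
# against their closed forms before being asserted here
weak_counts <- function() counts_from_cells(tp = 0, fp = 5000, tn = 55000, fn = 0)

test_that("dsc matches hand-computed values and its definition gap", {
  expect_equal(dsc(counts_from_cells(100, 0, 0, 0))$value, 1.0)
  expect_equal(dsc(weak_counts())$value, 0.0)
  expect_equal(dsc(counts_from_cells(1, 1, 0, 1))$value, 0.5) # 2/(2+1+1)
  # completely true-negative prediction: denominator 0
  expect_true(is_undefined(dsc(counts_from_cells(0, 0, 9, 0))))
})

test_that("fpr and specificity are complements with a shared definition gap", {
  expect_equal(fpr(weak_counts())$value, 5000 / 60000)
  expect_equal(fpr(counts_from_cells(0, 6, 0, 0))$value, 1.0)
  expect_true(is_undefined(fpr(counts_from_cells(3, 0, 0, 2))))

  expect_equal(specificity(weak_counts())$value, 0.9167, tolerance = 5e-5 / 0.9167)
  expect_equal(specificity(counts_from_cells(0, 0, 10, 0))$value, 1.0)
  expect_true(is_undefined(specificity(counts_from_cells(4, 0, 0, 1))))

  set.seed(21)
  for (rep in 1:25) {
    c <- counts_from_cells(sample(0:9, 1), sample(1:9, 1), sample(0:9, 1),
                           sample(0:9, 1))
    expect_equal(specificity(c)$value, 1 - fpr(c)$value)
  }
})

test_that("weighted specificity reproduces the worked example and reduces to Spec at alpha = 0.5", {
  expect_equal(weighted_specificity(weak_counts(), alpha = 0.1)$value, 0.55)
  expect_equal(weighted_specificity(counts_from_cells(0, 0, 60000, 0),
                                    alpha = 0.37)$value, 1.0)
  expect_true(is_undefined(weighted_specificity(counts_from_cells(2, 0, 0, 3))))
  grid <- enumerate_counts(4)
  for (row in seq_len(nrow(grid))) {
    g <- grid[row, ]
    if (g$fp + g$tn == 0) next
    c <- counts_from_cells(g$tp, g$fp, g$tn, g$fn)
    expect_equal(weighted_specificity(c, alpha = 0.5)$value,
                 specificity(c)$value)
  }
})

test_that("alpha outside the open unit interval is rejected", {
  c <- weak_counts()
  for (bad in list(0, 1, -0.1, 1.5, NA_real_, c(0.1, 0.2))) {
    expect_error(weighted_specificity(c, alpha = bad), "alpha")
    expect_error(mism(c, alpha = bad), "alpha")
  }
})

test_that("mism routes to DSC for P > 0 and to wSpec for weak labels", {
  expect_equal(mism(weak_counts(), alpha = 0.1)$value, 0.55)
  expect_equal(mism(counts_from_cells(0, 0, 60000, 0), alpha = 0.1)$value, 1.0)
  c <- counts_from_cells(100, 20, 1000, 30)
  expect_identical(mism(c, alpha = 0.1)$value, dsc(c)$value) # same float path
})

test_that("accuracy and nmcc hit their anchor values", {
  expect_equal(accuracy(weak_counts())$value, 55000 / 60000)
  expect_equal(accuracy(counts_from_cells(3, 0, 4, 0))$value, 1.0)
  expect_equal(accuracy(counts_from_cells(0, 2, 0, 2))$value, 0.0)

  # inverted ground truth -> MCC = -1 -> nMCC = 0
  expect_equal(nmcc(counts_from_cells(0, 7, 0, 5))$value, 0.0)
  # perfect prediction with both classes -> MCC = 1 -> nMCC = 1
  expect_equal(nmcc(counts_from_cells(6, 0, 8, 0))$value, 1.0)
  # weak label with errors: a marginal sum is 0, MCC := 0 -> nMCC = 0.5
  expect_equal(nmcc(weak_counts())$value, 0.5)
})

test_that("defined metric values lie in [0,1] over exhaustively enumerated counts", {
  grid <- enumerate_counts(6)
  fns <- list(dsc, fpr, specificity, accuracy, nmcc,
              function(c) weighted_specificity(c, 0.1),
              function(c) mism(c, 0.1))
  for (row in seq_len(nrow(grid))) {
    g <- grid[row, ]
    c <- counts_from_cells(g$tp, g$fp, g$tn, g$fn)
    for (f in fns) {
      r <- f(c)
      if (!is_undefined(r)) {
        expect_gte(r$value, 0)
        expect_lte(r$value, 1)
      }
    }
  }
})

test_that("mism is total while dsc and specificity gaps match their characterizations", {
  grid <- enumerate_counts(6)
  for (row in seq_len(nrow(grid))) {
    g <- grid[row, ]
    c <- counts_from_cells(g$tp, g$fp, g$tn, g$fn)
    expect_false(is_undefined(mism(c, 0.1)))
    expect_identical(is_undefined(dsc(c)), g$tp == 0 && g$fp == 0 && g$fn == 0)
    expect_identical(is_undefined(specificity(c)), g$tn == 0 && g$fp == 0)
    if (positives(c) > 0) {
      expect_identical(mism(c, 0.1)$value, dsc(c)$value)
    } else {
      expect_identical(mism(c, 0.1)$value, weighted_specificity(c, 0.1)$value)
    }
  }
})

test_that("mism on weak labels decreases strictly in FP and increases in alpha", {
  n <- 40
  vals <- vapply(0:n, function(fp) {
    mism(counts_from_cells(0, fp, n - fp, 0), alpha = 0.1)$value
  }, 0)
  expect_equal(vals[1], 1.0)
  expect_equal(vals[n + 1], 0.0)
  expect_true(all(diff(vals) < 0))

  alphas <- c(0.05, 0.1, 0.3, 0.6, 0.9)
  by_alpha <- vapply(alphas, function(a) {
    mism(counts_from_cells(0, 10, 30, 0), alpha = a)$value
  }, 0)
  expect_true(all(diff(by_alpha) > 0))
})

test_that("evaluate_all computes every metric from one confusion matrix", {
  m <- random_mask(c(9, 9), p = 0.4)
  res <- evaluate_all(m, m)
  expect_named(res, c("DSC", "Spec", "wSpec", "FPR", "Acc", "nMCC", "MISm"))
  for (lab in c("DSC", "Spec", "wSpec", "Acc", "nMCC", "MISm")) {
    expect_equal(res[[lab]]$value, 1.0)
  }
  expect_equal(res$FPR$value, 0.0)

  # both masks empty: the weak-label edge case handled only by MISm
  e <- binary_mask(matrix(FALSE, 5, 5))
  res_e <- evaluate_all(e, e)
  expect_true(is_undefined(res_e$DSC))
  for (lab in c("Spec", "wSpec", "Acc", "MISm")) {
    expect_equal(res_e[[lab]]$value, 1.0)
  }

  # hand-enumerated pair with counts (1,1,1,1)
  truth <- binary_mask(matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE))
  pred <- binary_mask(matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE))
  res_h <- evaluate_all(truth, pred)
  expect_equal(res_h$DSC$value, 0.5)
  expect_equal(res_h$Acc$value, 0.5)
  expect_equal(res_h$MISm$value, 0.5)

  # complement pair with both classes present
  m2 <- binary_mask(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  res_c <- evaluate_all(m2, binary_mask(!unclass(m2)))
  expect_equal(res_c$DSC$value, 0)
  expect_equal(res_c$nMCC$value, 0)
  expect_equal(res_c$Acc$value, 0)

  expect_error(evaluate_all(m, m, metrics = c("dsc", "hausdorff")), "unknown metric")
})
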