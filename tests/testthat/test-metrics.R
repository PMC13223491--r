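test_that("pixel confusion counts match hand-counted toy masks", {
  t4 <- matrix(0, 4, 4); t4[1:2, 1:3] <- 1          # 6 positives
  p4 <- matrix(0, 4, 4); p4[1:2, 2:4] <- 1          # overlap 4
  cm <- confusion(p4, t4)
  expect_equal(cm$TP, 4); expect_equal(cm$FP, 2)
  expect_equal(cm$FN, 2); expect_equal(cm$TN, 8)
  same <- confusion(t4, t4)
  expect_equal(same$FP + same$FN, 0)
  inv <- confusion(1 - t4, t4)
  expect_equal(inv$TP + inv$TN, 0)
  expect_error(confusion(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("scores evaluate their formulas, flag undefined cases, and obey identities", {
  sc <- seg_scores(confusion_counts(TP = 3, FP = 1, FN = 3, TN = 9))
  expect_equal(sc$dsc, 0.6)
  expect_equal(sc$iou, 3 / 7)
  expect_equal(sc$accuracy, 12 / 16)
  expect_equal(sc$precision, 3 / 4)
  expect_equal(sc$sensitivity, 0.5)
  expect_equal(sc$specificity, 0.9)
  expect_equal(sc$f_score, 2 * 0.75 * 0.5 / 1.25)
  perfect <- seg_scores(confusion_counts(10, 20, 0, 0))
  expect_true(all(unlist(perfect) == 1))
  und <- seg_scores(confusion_counts(0, 5, 0, 0))
  expect_true(is.na(und$precision))
  expect_true("precision" %in% attr(und, "undefined"))
  set.seed(51)
  for (i in 1:1000) {
    cm <- confusion_counts(sample(0:50, 1), sample(0:50, 1),
                           sample(0:50, 1), sample(0:50, 1))
    sc <- seg_scores(cm)
    if (!is.na(sc$iou)) {
      expect_equal(sc$dsc, 2 * sc$iou / (1 + sc$iou), tolerance = 1e-12)
      expect_gte(sc$dsc, sc$iou)
    }
    ok <- unlist(sc)[!is.na(unlist(sc))]
    expect_true(all(ok >= 0 & ok <= 1))
    # swapping the positive/negative labelling swaps the paired scores
    swapped <- seg_scores(confusion_counts(cm$TP, cm$TN, FP = cm$FN, FN = cm$FP))
    expect_equal(swapped$precision, sc$sensitivity)
    expect_equal(swapped$sensitivity, sc$precision)
  }
})

test_that("PSNR follows its closed form and degrades with noise", {
  img <- matrix(runif(256), 16, 16)
  p <- psnr(img, img)
  expect_true(is.infinite(p) && isTRUE(attr(p, "identical")))
  a <- matrix(100, 8, 8); b <- a + 1
  expect_equal(psnr(a, b, peak = 255), 10 * log10(255^2), tolerance = 1e-12)
  expect_equal(10 * log10(255^2), 48.13, tolerance = 0.005)
  set.seed(52)
  ref <- matrix(runif(1024), 32, 32)
  ps <- sapply(c(0.01, 0.05, 0.1, 0.2), function(s)
    psnr(ref, ref + matrix(rnorm(1024, sd = s), 32, 32)))
  expect_true(all(diff(ps) < 0))
})

test_that("SSIM matches a direct per-window oracle to 1e-6", {
  set.seed(53)
  ref <- matrix(runif(24 * 24), 24, 24)
  noisy <- pmin(pmax(ref + matrix(rnorm(24 * 24, sd = 0.1), 24, 24), 0), 1)
  expect_equal(ssim(ref, ref), 1, tolerance = 1e-12)
  expect_lt(ssim(ref, matrix(0.5, 24, 24)), 1)
  expect_equal(ssim(ref, noisy), ssim_direct(ref, noisy), tolerance = 1e-6)
  blur <- (ref + ref[c(2:24, 24), ]) / 2
  expect_equal(ssim(ref, blur), ssim_direct(ref, blur), tolerance = 1e-6)
  expect_error(ssim(matrix(0, 5, 5), matrix(0, 5, 5)), "window")
})

test_that("mask-set evaluation averages per-image scores", {
  t1 <- matrix(0, 6, 6); t1[2:4, 2:4] <- 1
  p1 <- t1
  p2 <- matrix(0, 6, 6); p2[2:3, 2:4] <- 1
  ev <- evaluate_masks(list(p1, p2), list(t1, t1))
  expect_equal(ev$per_image[[1]]$dsc, 1)
  expect_equal(ev$mean[["dsc"]],
               mean(c(1, seg_scores(confusion(p2, t1))$dsc)))
})
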