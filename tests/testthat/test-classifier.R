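test_that("shape features recover analytic values on rasterised figures", {
  n <- 40
  d <- outer(1:n, 1:n, function(i, j) sqrt((i - n / 2)^2 + (j - n / 2)^2))
  disk <- (d <= 12) * 1
  img <- 0.5 - 0.3 * disk
  f <- extract_features(img, disk)
  expect_equal(unname(f["circularity"]), 1, tolerance = 0.05)
  expect_equal(unname(f["solidity"]), 1, tolerance = 0.05)
  expect_equal(unname(f["area_frac"]), sum(disk) / n^2)
  expect_lt(unname(f["interior_mean"]), 0.3)
  expect_lt(unname(f["contrast_ratio"]), 1)   # hypoechoic interior
  # convex square: solidity at 1 within tolerance
  sq <- matrix(0, n, n); sq[10:30, 10:30] <- 1
  fs <- extract_features(img, sq)
  expect_equal(unname(fs["solidity"]), 1, tolerance = 0.05)
  expect_error(extract_features(img, matrix(0, n, n)), "no lesion")
})

test_that("spiculated lesions score lower circularity than elliptical ones", {
  lower <- logical(30)
  for (i in 1:30) {
    pb <- phantom_generate(phantom_spec(size = 64, seed = 5000 + i))
    pm <- phantom_generate(phantom_spec(size = 64, lesion_class = "malignant",
                                        seed = 6000 + i))
    cb <- extract_features(pb$image, pb$mask)["circularity"]
    cm <- extract_features(pm$image, pm$mask)["circularity"]
    lower[i] <- cm < cb
  }
  expect_gte(mean(lower), 0.95)
})

test_that("the maximum-margin fit separates linearly separable toy data", {
  set.seed(61)
  x <- rbind(matrix(rnorm(40, mean = 0), ncol = 2),
             matrix(rnorm(40, mean = 4), ncol = 2))
  y <- rep(c(0, 1), each = 20)
  m <- psvm_fit(x, y)
  expect_equal(as.vector(psvm_predict(m, x)), y)
  # swapping class labels flips predictions but keeps the boundary geometry
  m2 <- psvm_fit(x, 1 - y)
  expect_equal(as.vector(psvm_predict(m2, x)), 1 - y)
  expect_error(psvm_fit(x, rep(0, 40)), "both classes")
})

test_that("predictions are deterministic and standardisation is internal", {
  set.seed(62)
  x <- rbind(matrix(rnorm(30, 0), ncol = 3), matrix(rnorm(30, 3), ncol = 3))
  y <- rep(c(0, 1), each = 10)
  m <- psvm_fit(x, y)
  p1 <- psvm_predict(m, x)
  p2 <- psvm_predict(m, x)
  expect_identical(p1, p2)
  expect_length(attr(p1, "margin"), 20)
  # scaling a feature column uniformly at fit time must not change predictions
  xs <- x; xs[, 2] <- xs[, 2] * 100
  ms <- psvm_fit(xs, y)
  expect_equal(as.vector(psvm_predict(ms, xs)), as.vector(p1))
})

test_that("lesion classification generalises on default-scale phantoms", {
  ph <- c(lapply(1:20, function(i)
            phantom_generate(phantom_spec(lesion_class = "benign", seed = 7000 + i))),
          lapply(1:20, function(i)
            phantom_generate(phantom_spec(lesion_class = "malignant", seed = 8000 + i))))
  lab <- rep(c(0, 1), each = 20)
  feats <- lapply(ph, function(p) extract_features(p$noisy, p$mask))
  tr <- c(1:14, 21:34); te <- setdiff(seq_along(ph), tr)
  m <- psvm_fit(feats[tr], lab[tr])
  acc <- mean(psvm_predict(m, feats[te]) == lab[te])
  expect_gte(acc, 0.9)
  # lesion-level confusion on the held-out set is computable
  pr <- psvm_predict(m, feats[te])
  cm <- confusion_counts(TP = sum(pr == 1 & lab[te] == 1),
                         TN = sum(pr == 0 & lab[te] == 0),
                         FP = sum(pr == 1 & lab[te] == 0),
                         FN = sum(pr == 0 & lab[te] == 1))
  expect_equal(cm$TP + cm$TN + cm$FP + cm$FN, length(te))
})
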