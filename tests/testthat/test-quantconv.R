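test_that("symmetric quantization follows the stated scale and bounds", {
  q0 <- quantize(array(0, c(2, 2)))
  expect_equal(as.vector(q0$levels), rep(0, 4))
  expect_equal(q0$scale, 1)
  q <- quantize(c(-1, 1), bits = 8)
  expect_equal(q$levels, c(-127, 127))
  expect_equal(q$scale, 1 / 127)
  expect_equal(q$zero_point, 0)
  set.seed(31)
  for (i in 1:200) {
    t <- rnorm(64) * 10^runif(1, -2, 2)
    for (bits in c(8, 16)) {
      q <- quantize(t, bits)
      expect_true(all(abs(q$levels) <= 2^(bits - 1) - 1))
      expect_true(all(abs(t - dequantize(q)) <= q$scale / 2 + 1e-12))
    }
  }
})

test_that("convolution matches hand-evaluated inner products", {
  x <- matrix(1, 3, 3)
  expect_equal(as.vector(conv2d(x, matrix(1, 3, 3), conv_spec(3, padding = 0))), 9)
  # 1x1 identity kernel
  set.seed(32)
  img <- matrix(runif(25), 5, 5)
  out <- conv2d(img, array(1, c(1, 1, 1, 1)), conv_spec(1, padding = 0))
  expect_equal(out[, , 1], img)
  # direct-convolution oracle on a random case, interior only
  x <- matrix(rnorm(49), 7, 7)
  k <- matrix(rnorm(9), 3, 3)
  out <- conv2d(x, k, conv_spec(3, padding = 0))[, , 1]
  for (i in 1:3) for (j in 1:3) {
    expect_equal(out[i, j], sum(x[i:(i + 2), j:(j + 2)] * k), tolerance = 1e-12)
  }
  expect_error(conv2d(matrix(1, 4, 4), array(1, c(3, 3, 2, 1)), conv_spec(3, 1, 1)),
               "channel|inconsistent")
})

test_that("exact convolution is linear and translation equivariant", {
  set.seed(33)
  k <- array(rnorm(9), c(3, 3, 1, 1))
  sp <- conv_spec(3, padding = 0)
  a <- matrix(rnorm(64), 8, 8); b <- matrix(rnorm(64), 8, 8)
  expect_equal(conv2d(2 * a + 3 * b, k, sp),
               2 * conv2d(a, k, sp) + 3 * conv2d(b, k, sp), tolerance = 1e-12)
  # shift input one pixel -> interior output shifts one pixel
  ash <- rbind(a[-1, ], 0)
  o1 <- conv2d(a, k, sp)[, , 1]
  o2 <- conv2d(ash, k, sp)[, , 1]
  expect_equal(o2[1:5, ], o1[2:6, ], tolerance = 1e-12)
})

test_that("emulated backends stay within the accumulated-ulp deviation bound", {
  set.seed(34)
  for (i in 1:10) {
    x <- array(runif(16 * 16) * 2 - 1, c(16, 16, 1))
    w <- array(rnorm(9), c(3, 3, 1, 1))
    ex <- conv2d(x, w, conv_spec(3, backend = "exact"))
    em <- conv2d(x, w, conv_spec(3, backend = "cutin_fp32"))
    bound <- conv_ulp_bound(x, w)
    expect_true(all(abs(em - ex) <= bound))
    em16 <- conv2d(x, w, conv_spec(3, backend = "cutin_fp16"))
    bound16 <- conv_ulp_bound(x, w, mbits = 10)
    expect_true(all(abs(em16 - ex) <= bound16))
  }
})

test_that("batch normalisation standardises and degenerates as expected", {
  set.seed(35)
  x <- array(rnorm(16 * 16 * 2, mean = 3, sd = 2), c(16, 16, 2))
  mu <- apply(x, 3, mean)
  v <- apply(x, 3, function(ch) mean((ch - mean(ch))^2))
  y <- batch_norm(x, mean = mu, var = v)
  expect_equal(apply(y, 3, mean), c(0, 0), tolerance = 1e-6)
  expect_equal(apply(y, 3, function(ch) var(as.vector(ch))), c(1, 1),
               tolerance = 1e-2)
  expect_equal(unique(as.vector(batch_norm(x, gamma = 0, beta = 7))), 7)
  expect_equal(batch_norm(x, mean = 0, var = 1 - 1e-5), x, tolerance = 1e-12)
})

test_that("relu zeroes negatives, keeps positives, and is idempotent", {
  x <- array(c(-2, -1, 0, 1, 2, -3), c(2, 3, 1))
  r <- relu(x)
  expect_equal(as.vector(r), c(0, 0, 0, 1, 2, 0))
  expect_identical(relu(r), r)
  expect_equal(dim(r), dim(x))
})
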