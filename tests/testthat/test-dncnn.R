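test_that("network structure matches its specification and counts parameters exactly", {
  net <- dncnn_build(network_spec(depth = 3, width = 8))
  expect_length(net$layers, 3)
  expect_false(isTRUE(net$layers[[1]]$bn))
  expect_true(isTRUE(net$layers[[2]]$bn))
  expect_false(isTRUE(net$layers[[3]]$bn))
  # closed-form parameter count: conv weights + biases + BN gamma/beta
  k <- 3
  expected <- (k * k * 1 * 8 + 8) + (k * k * 8 * 8 + 8 + 16) + (k * k * 8 * 1 + 1)
  expect_equal(net$n_params, expected)
  expect_error(dncnn_build(network_spec(depth = 2)), "depth")

  seg <- dncnn_build(network_spec(depth = 3, width = 4, head = "segment"))
  img <- matrix(runif(64), 8, 8)
  z <- dncnn_infer(seg, img)
  expect_equal(dim(z), dim(img))
  m <- dncnn_segment(seg, img, threshold = 0.5)
  expect_true(all(m %in% c(0, 1)))
})

test_that("zero learning rate freezes the loss trace and seeds reproduce it", {
  ds <- phantom_fixture()
  xs <- lapply(ds$train[1:6], `[[`, "noisy")
  ys <- lapply(ds$train[1:6], `[[`, "image")
  net <- dncnn_build(network_spec(depth = 3, width = 4))
  tr0 <- dncnn_train(net, xs, ys,
                     train_config(learning_rate = 1e-12, epochs = 4,
                                  batch_size = 6, seed = 2))$trace
  expect_lt(diff(range(tr0)), 1e-6)
  t1 <- dncnn_train(net, xs, ys, train_config(epochs = 3, seed = 5))$trace
  t2 <- dncnn_train(net, xs, ys, train_config(epochs = 3, seed = 5))$trace
  expect_identical(t1, t2)
  t3 <- dncnn_train(net, xs, ys, train_config(epochs = 3, seed = 6))$trace
  expect_false(identical(t1, t3))
})

test_that("training reduces the loss on a small denoising problem", {
  ds <- phantom_fixture()
  xs <- lapply(ds$train[1:10], `[[`, "noisy")
  ys <- lapply(ds$train[1:10], `[[`, "image")
  net <- dncnn_build(network_spec(depth = 4, width = 8))
  net <- dncnn_train(net, xs, ys,
                     train_config(learning_rate = 5e-3, epochs = 10,
                                  batch_size = 5, seed = 3))
  expect_lt(tail(net$trace, 1), net$trace[1])
  expect_true(net$trained)
})

test_that("residual mode denoises as input minus predicted noise", {
  ds <- phantom_fixture()
  p <- ds$test[[1]]
  net <- dncnn_build(network_spec(depth = 3, width = 4, residual = TRUE))
  net <- dncnn_train(net, lapply(ds$train[1:6], `[[`, "noisy"),
                     lapply(ds$train[1:6], `[[`, "image"),
                     train_config(epochs = 2, seed = 4))
  r <- dncnn_infer(net, p$noisy)
  expect_identical(dncnn_denoise(net, p$noisy),
                   pmin(pmax(p$noisy - r, 0), 1))
})

test_that("segmentation thresholds behave at their limits", {
  seg <- dncnn_build(network_spec(depth = 3, width = 4, head = "segment"))
  img <- matrix(runif(64), 8, 8)
  expect_true(all(dncnn_segment(seg, img, threshold = 0) == 1))
  expect_true(all(dncnn_segment(seg, img, threshold = 1) == 0))
})

test_that("morphological closing fills holes, is idempotent, and radius 0 is identity", {
  m <- matrix(0, 16, 16)
  m[5:12, 5:12] <- 1
  m[8, 8] <- 0                       # interior pinhole
  out <- postprocess_mask(m, 1)
  expect_equal(out[8, 8], 1)
  expect_identical(postprocess_mask(out, 1), out)
  expect_identical(postprocess_mask(m, 0), m)
  z <- matrix(0, 8, 8)
  expect_identical(postprocess_mask(z, 2), z)
})

test_that("emulated inference backends agree with exact on nearly all mask pixels", {
  ds <- phantom_fixture()
  xs <- lapply(ds$train[1:10], `[[`, "noisy")
  ms <- lapply(ds$train[1:10], `[[`, "mask")
  net <- dncnn_build(network_spec(depth = 3, width = 6, head = "segment"))
  net <- dncnn_train(net, xs, ms,
                     train_config(learning_rate = 5e-3, epochs = 12,
                                  batch_size = 5, seed = 8))
  p <- ds$test[[1]]
  me <- dncnn_segment(net, p$noisy, backend = "exact")
  mc <- dncnn_segment(net, p$noisy, backend = "cutin_fp32")
  expect_gte(mean(me == mc), 0.99)
})
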