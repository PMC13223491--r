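test_that("initialisation fills the bounds uniformly and deterministically", {
  b <- poa_bounds(c(-2, 0, 10), c(2, 1, 20))
  set.seed(41)
  X <- poa_initialize(b, 500)
  expect_true(all(sweep(X, 2, b$lower, `>=`)) && all(sweep(X, 2, b$upper, `<=`)))
  expect_gt(min(apply(X, 2, sd)), 0)
  set.seed(7); X1 <- poa_initialize(b, 20)
  set.seed(7); X2 <- poa_initialize(b, 20)
  expect_identical(X1, X2)
  # degenerate bounds limit: tiny interval pins all positions
  eps <- 1e-12
  bd <- poa_bounds(c(1, 1), c(1 + eps, 1 + eps))
  expect_equal(poa_initialize(bd, 10), matrix(1, 10, 2), tolerance = 1e-9)
  expect_error(poa_bounds(c(0, 1), c(1, 1)))
})

test_that("exploration with prey at the candidate leaves it unchanged and never worsens", {
  b <- poa_bounds(rep(-5, 3), rep(5, 3))
  set.seed(42)
  X <- poa_initialize(b, 8)
  fit <- apply(X, 1, poa_sphere)
  # prey identical to candidate 1 with equal fitness: displacement scale 0
  st <- poa_exploration(X[1, , drop = FALSE], fit[1], poa_sphere, b,
                        prey = X[1, ], prey_fit = fit[1])
  expect_equal(st$X[1, ], X[1, ])
  for (rep in 1:20) {
    st <- poa_exploration(X, fit, poa_sphere, b)
    expect_true(all(st$fit <= fit + 1e-12))
    X <- st$X; fit <- st$fit
    expect_true(all(X >= -5 & X <= 5))
  }
})

test_that("exploitation radius shrinks to zero and acceptance is greedy", {
  b <- poa_bounds(rep(-5, 3), rep(5, 3))
  set.seed(43)
  X <- poa_initialize(b, 10)
  fit <- apply(X, 1, poa_sphere)
  st <- poa_exploitation(X, fit, poa_sphere, b, t = 50, T = 50)
  expect_identical(st$X, X)             # zero-radius move at t = T
  st <- poa_exploitation(X, fit, poa_sphere, b, t = 1, T = 50)
  expect_true(all(st$fit <= fit + 1e-12))
  # dispersion of proposed moves shrinks with t (average |delta x| scale)
  disp <- function(t) {
    set.seed(99)
    mean(abs(0.2 * (1 - t / 50) * (2 * runif(300) - 1) * 3))
  }
  expect_lt(disp(25), disp(1))
})

test_that("sphere and rastrigin benchmarks are recovered with monotone traces", {
  best <- numeric(6)
  for (s in 1:6) {
    r <- poa_optimize(poa_sphere, poa_bounds(rep(-5.12, 5), rep(5.12, 5)),
                      poa_config(N = 20, T = 100, seed = s))
    expect_true(all(diff(r$trace) <= 0))
    expect_true(all(r$population$X >= -5.12 & r$population$X <= 5.12))
    best[s] <- r$best$fitness
  }
  expect_lt(median(best), 1e-3)
  rr <- sapply(1:6, function(s)
    poa_optimize(poa_rastrigin, poa_bounds(rep(-5.12, 2), rep(5.12, 2)),
                 poa_config(N = 20, T = 100, seed = s))$best$fitness)
  expect_lt(median(rr), 1.0)
})

test_that("constant and NaN fitness are handled as contracted", {
  b <- poa_bounds(rep(0, 2), rep(1, 2))
  r <- poa_optimize(function(x) 1, b, poa_config(N = 5, T = 10, seed = 2))
  expect_true(all(r$trace == 1))
  expect_true(all(r$best$position >= 0 & r$best$position <= 1))
  w <- capture_warnings(
    poa_optimize(function(x) if (x[1] > 0.5) NaN else sum(x), b,
                 poa_config(N = 5, T = 3, seed = 3)))
  expect_true(any(grepl("NaN", w)))
})

test_that("optimisation is fully deterministic under a fixed seed", {
  b <- poa_bounds(rep(-1, 3), rep(1, 3))
  r1 <- poa_optimize(poa_sphere, b, poa_config(N = 8, T = 20, seed = 11))
  r2 <- poa_optimize(poa_sphere, b, poa_config(N = 8, T = 20, seed = 11))
  expect_identical(r1, r2)
})

test_that("hyperparameter decoding clamps to the valid grid", {
  hp <- decode_hyper(c(-2.5, 5.4, 15.7, 0.5, 1.2))
  expect_equal(hp$learning_rate, 10^-2.5)
  expect_equal(hp$depth, 5L)
  expect_equal(hp$width, 16L)
  expect_equal(hp$radius, 1L)
  lohp <- decode_hyper(c(-9, 0, 0, 0, -5))
  expect_equal(lohp$learning_rate, 1e-4)
  expect_equal(lohp$depth, 3L)
  expect_equal(lohp$width, 8L)
  expect_equal(lohp$threshold, 0.2)
  expect_equal(lohp$radius, 0L)
})

test_that("segmentation fitness spans its trivial anchors", {
  ds <- phantom_fixture()
  val <- ds$test
  # oracle passthrough: perfect masks give fitness 0; empty masks give 1
  perfect <- sapply(val, function(p) {
    sc <- seg_scores(confusion(p$mask, p$mask))
    1 - 0.5 * sc$dsc - 0.5 * sc$iou
  })
  expect_equal(unname(perfect), rep(0, length(val)))
  empty <- sapply(val, function(p) {
    sc <- seg_scores(confusion(matrix(0, nrow(p$mask), ncol(p$mask)), p$mask))
    d <- ifelse(is.na(sc$dsc), 0, sc$dsc); i <- ifelse(is.na(sc$iou), 0, sc$iou)
    1 - 0.5 * d - 0.5 * i
  })
  expect_equal(unname(empty), rep(1, length(val)))
})
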