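# Independent oracles, kept free of the code paths they check.

# exact 64-bit product of two <= 32-bit integers via 16-bit limb long
# multiplication in doubles; returns a 16-digit hex string
mul64_hex <- function(a, b) {
  al <- a %% 65536; ah <- a %/% 65536
  bl <- b %% 65536; bh <- b %/% 65536
  p0 <- al * bl                       # < 2^32
  p1 <- al * bh + ah * bl             # < 2^33
  p2 <- ah * bh                       # < 2^32
  c0 <- p0 %% 65536
  t1 <- p0 %/% 65536 + p1 %% 65536
  c1 <- t1 %% 65536
  t2 <- p1 %/% 65536 + t1 %/% 65536 + p2 %% 65536
  c2 <- t2 %% 65536
  c3 <- p2 %/% 65536 + t2 %/% 65536
  paste0(sprintf("%04x", c3), sprintf("%04x", c2),
         sprintf("%04x", c1), sprintf("%04x", c0))
}

# brute-force working-base search (decimal), mirroring the stated selection
# rule but enumerated independently
brute_base_dec <- function(a, b) {
  cand <- unique(as.vector(outer(1:9, 10^(0:6))))
  d <- pmax(abs(cand - a), abs(cand - b))
  best <- min(d)
  min(cand[d == best])
}

# direct per-window SSIM: explicit double loop over every valid placement,
# Gaussian weights, population moments (independent of the package's
# separable-filter implementation)
ssim_direct <- function(ref, test, peak = 1, size = 11, sigma = 1.5) {
  h <- (size - 1) / 2
  w <- outer(-h:h, -h:h, function(x, y) exp(-(x^2 + y^2) / (2 * sigma^2)))
  w <- w / sum(w)
  C1 <- (0.01 * peak)^2; C2 <- (0.03 * peak)^2
  H <- nrow(ref); W <- ncol(ref)
  vals <- c()
  for (i in 1:(H - size + 1)) {
    for (j in 1:(W - size + 1)) {
      x <- ref[i:(i + size - 1), j:(j + size - 1)]
      y <- test[i:(i + size - 1), j:(j + size - 1)]
      mx <- sum(w * x); my <- sum(w * y)
      sxx <- sum(w * x * x) - mx^2
      syy <- sum(w * y * y) - my^2
      sxy <- sum(w * x * y) - mx * my
      vals <- c(vals, ((2 * mx * my + C1) * (2 * sxy + C2)) /
                        ((mx^2 + my^2 + C1) * (sxx + syy + C2)))
    }
  }
  mean(vals)
}

# seeded random normal-range fp32 / fp16 bit patterns whose products and
# sums (including partial cancellation, which can lower the exponent by up
# to the significand width) stay in the normal range
sample_fp_bits <- function(n, profile = "fp32") {
  if (profile == "fp32") {
    s <- sample(0:1, n, TRUE)
    e <- sample(90:160, n, TRUE)
    m <- floor(runif(n) * 2^23)
    s * 2^31 + e * 2^23 + m
  } else {
    s <- sample(0:1, n, TRUE)
    e <- sample(13:18, n, TRUE)
    m <- floor(runif(n) * 2^10)
    s * 2^15 + e * 2^10 + m
  }
}

# small shared phantom set, built once per test run
phantom_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_dataset(24, split_ratio = 0.75, seed = 42, size = 32)
    cache
  }
})
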