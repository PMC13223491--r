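test_that("decode extracts fields and classifies canonical patterns", {
  one <- fp_decode(0x3F800000)
  expect_equal(one$sign, 0)
  expect_equal(one$exponent, 127)
  expect_equal(one$mantissa, 0)
  expect_equal(one$value, 1)
  z <- fp_decode(0)
  expect_equal(z$class, "zero")
  m3 <- fp_decode(0xC0400000)
  expect_equal(m3$sign, 1)
  expect_equal(m3$exponent, 128)
  expect_equal(m3$value, -3)
  expect_equal(fp_decode(0x7F800000)$class, "inf")
  expect_equal(fp_decode(0x7FC00000)$class, "nan")
  expect_equal(fp_decode(0x3C00, "fp16")$value, 1)
})

test_that("encode(decode(x)) round-trips sampled bit patterns exactly", {
  set.seed(21)
  for (p in c("fp32", "fp16")) {
    bits <- sample_fp_bits(500, p)
    for (b in bits[1:50]) expect_equal(fp_encode(fp_decode(b, p)), b)
    # full vector round trip through value conversion
    expect_equal(float_to_bits(bits_to_float(bits, p), p), bits)
  }
})

test_that("emulated multiplication handles exact and identity cases", {
  for (rm in c("trunc", "rne")) {
    expect_equal(fp_multiply(float_to_bits(1.5), float_to_bits(2),
                             rounding = rm)$value, 3)
  }
  set.seed(22)
  xs <- sample_fp_bits(200)
  one <- float_to_bits(1)
  got <- fp_op_batch(xs, rep(one, 200), "mul", "fp32", "trunc")
  expect_equal(got, xs)
})

test_that("emulated arithmetic is commutative bit-for-bit", {
  set.seed(23)
  for (p in c("fp32", "fp16")) {
    a <- sample_fp_bits(2000, p); b <- sample_fp_bits(2000, p)
    for (op in c("mul", "add")) {
      expect_identical(fp_op_batch(a, b, op, p, "trunc"),
                       fp_op_batch(b, a, op, p, "trunc"))
    }
  }
})

test_that("emulation agrees with the host reference at the stated ulp bounds", {
  set.seed(24)
  n <- 5000
  for (p in c("fp32", "fp16")) {
    a <- sample_fp_bits(n, p); b <- sample_fp_bits(n, p)
    for (op in c("mul", "add")) {
      ref <- fp_ref_batch(a, b, op, p)
      expect_identical(fp_op_batch(a, b, op, p, "rne"), ref)
      expect_lte(max(ulp_diff(fp_op_batch(a, b, op, p, "trunc"), ref, p)), 1)
    }
  }
})

test_that("product magnitude is monotone in the first operand's magnitude", {
  y <- float_to_bits(1.37)
  xs <- float_to_bits(seq(0.1, 90, length.out = 200))
  vals <- abs(bits_to_float(fp_op_batch(xs, rep(y, 200), "mul", "fp32", "trunc")))
  expect_true(all(diff(vals) >= 0))
})

test_that("overflow saturates, underflow flushes, specials propagate", {
  big <- float_to_bits(3e38)
  r <- fp_multiply(big, big)
  expect_true(attr(r, "flags")$overflow)
  expect_equal(r$exponent, 254)                       # largest finite magnitude
  expect_equal(r$mantissa, 2^23 - 1)
  tiny <- float_to_bits(1e-30)
  u <- fp_multiply(tiny, tiny)
  expect_true(attr(u, "flags")$underflow)
  expect_equal(u$class, "zero")
  expect_equal(fp_multiply(0x7F800000, float_to_bits(2))$class, "inf")
  expect_equal(fp_multiply(0x7F800000, 0)$class, "nan")      # inf * 0
  expect_equal(fp_multiply(0x7FC00000, float_to_bits(2))$class, "nan")
  neg <- fp_multiply(float_to_bits(-2), float_to_bits(3))
  expect_equal(neg$value, -6)
})

test_that("emulated addition handles exact and neutral cases", {
  expect_equal(fp_add(float_to_bits(1), float_to_bits(1))$value, 2)
  set.seed(25)
  xs <- sample_fp_bits(200)
  got <- fp_op_batch(xs, rep(0, 200), "add", "fp32", "trunc")
  expect_equal(got, xs)
  # exact cancellation yields +0
  expect_equal(fp_add(float_to_bits(1.25), float_to_bits(-1.25))$class, "zero")
})
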