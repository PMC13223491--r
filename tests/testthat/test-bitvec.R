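test_that("bitvec construction enforces width and round-trips hex", {
  b <- bitvec(5, 3)
  expect_equal(b$width, 3L)
  expect_equal(bv_value(b), 5)
  expect_equal(bitvec("0xff", 8)$value, 255)
  expect_equal(bitvec(255, 8)$hex, "ff")
  expect_error(bitvec(8, 3), "does not fit")
  expect_error(bitvec("0x1ff", 8), "does not fit")
  expect_error(bitvec(-1, 4))
  wide <- bitvec("ffffffffffffffff", 64)
  expect_equal(wide$hex, "ffffffffffffffff")
})

test_that("vertical-crosswise multiplication matches exact products", {
  expect_equal(bv_value(ut_multiply(bitvec(5, 3), bitvec(3, 3))), 15)
  expect_equal(ut_multiply(bitvec(5, 3), bitvec(3, 3))$width, 6L)
  expect_equal(bv_value(ut_multiply(bitvec(0, 8), bitvec(173, 8))), 0)
  expect_equal(bv_value(ut_multiply(bitvec(1, 8), bitvec(173, 8))), 173)
  expect_error(ut_multiply(bitvec(1, 8), bitvec(1, 4)), "width mismatch")
  set.seed(11)
  for (i in 1:50) {
    a <- floor(runif(1) * 2^12); b <- floor(runif(1) * 2^12)
    expect_equal(bv_value(ut_multiply(bitvec(a, 12), bitvec(b, 12))), a * b)
  }
  tr <- attr(ut_multiply(bitvec(7, 3), bitvec(7, 3), trace = TRUE), "trace")
  expect_equal(tr$column, c(1, 2, 3, 2, 1, 0))   # partial products per column
})

test_that("working-base selection matches the brute-force oracle", {
  expect_equal(anurupyena_working_base(bitvec(48, 8), bitvec(52, 8))$base, 50)
  expect_equal(anurupyena_working_base(bitvec(98, 8), bitvec(97, 8))$base, 100)
  expect_equal(anurupyena_working_base(bitvec(1, 8), bitvec(1, 8))$base, 1)
  set.seed(5)
  for (i in 1:100) {
    a <- sample(1:5000, 1); b <- sample(1:5000, 1)
    got <- anurupyena_working_base(bitvec(a, 16), bitvec(b, 16))$base
    expect_equal(got, brute_base_dec(a, b))
  }
})

test_that("base-complement multiplication is exact on and off the base", {
  p <- nikhilam_multiply(bitvec(98, 8), bitvec(97, 8), trace = TRUE)
  expect_equal(bv_value(p), 9506)
  tr <- attr(p, "trace")
  expect_equal(tr$complement_a, 2)
  expect_equal(tr$complement_b, 3)
  expect_equal(tr$left_part, 95)
  expect_equal(tr$right_part, 6)
  # excess-over-base branch
  expect_equal(bv_value(nikhilam_multiply(bitvec(12, 8), bitvec(13, 8))), 156)
  # operand on the base: complement zero
  wb <- anurupyena_working_base(bitvec(100, 8), bitvec(73, 8))
  expect_equal(bv_value(nikhilam_multiply(bitvec(100, 8), bitvec(73, 8), wb)),
               7300)
  expect_error(nikhilam_multiply(bitvec(3, 4), bitvec(3, 4), base = list(base = 0)),
               "working_base")
  set.seed(6)
  for (mode in c("dec", "bin")) {
    for (i in 1:50) {
      a <- sample(1:250, 1); b <- sample(1:250, 1)
      expect_equal(bv_value(nikhilam_multiply(bitvec(a, 8), bitvec(b, 8),
                                              mode = mode)), a * b)
    }
  }
})

test_that("hybrid multiplication is exact, commutative, and agrees with UT/NAS", {
  expect_equal(bv_value(cutin_multiply(bitvec(2^7, 8), bitvec(2^7, 8))), 2^14)
  expect_error(cutin_multiply(bitvec(1, 12), bitvec(1, 12)), "power of two")
  set.seed(7)
  for (w in c(8, 16)) {
    for (i in 1:60) {
      a <- floor(runif(1) * 2^w); b <- floor(runif(1) * 2^w)
      pc <- cutin_multiply(bitvec(a, w), bitvec(b, w))
      expect_equal(bv_value(pc), a * b)
      expect_equal(pc$hex, cutin_multiply(bitvec(b, w), bitvec(a, w))$hex)
      expect_equal(pc$hex, ut_multiply(bitvec(a, w), bitvec(b, w))$hex)
      expect_equal(bv_value(nikhilam_multiply(bitvec(a, w), bitvec(b, w),
                                              mode = "bin")), a * b)
    }
  }
})

test_that("32-bit hybrid products match an independent limb-multiplication oracle", {
  set.seed(8)
  for (i in 1:40) {
    a <- floor(runif(1) * (2^32 - 1)); b <- floor(runif(1) * (2^32 - 1))
    expect_equal(cutin_multiply(bitvec(a, 32), bitvec(b, 32))$hex,
                 mul64_hex(a, b))
  }
})

test_that("staged 8x8 composition from 4x4 blocks is exact", {
  expect_equal(bv_value(multiply_8x8_staged(bitvec(255, 8), bitvec(255, 8))),
               65025)
  expect_equal(bv_value(multiply_8x8_staged(bitvec(16, 8), bitvec(16, 8))), 256)
  expect_error(multiply_8x8_staged(bitvec(1, 4), bitvec(1, 4)), "width")
  set.seed(9)
  for (i in 1:100) {
    a <- sample(0:255, 1); b <- sample(0:255, 1)
    expect_equal(bv_value(multiply_8x8_staged(bitvec(a, 8), bitvec(b, 8))), a * b)
  }
})

test_that("CSCGL addition equals integer addition with both carry-ins", {
  expect_equal(bv_value(cscgl_add(bitvec(0, 8), bitvec(0, 8), 0)), 0)
  expect_equal(bv_value(cscgl_add(bitvec(255, 8), bitvec(1, 8), 0)), 256)
  expect_equal(cscgl_add(bitvec(255, 8), bitvec(1, 8))$width, 9L)
  expect_error(cscgl_add(bitvec(1, 8), bitvec(1, 4)), "width mismatch")
  expect_equal(verify_cscgl(6), 0)     # exhaustive sweep, both carry-ins
})

test_that("carry-save reduction preserves the represented sum at every stage", {
  r <- csa_reduce(list(bitvec(5, 4), bitvec(3, 4), bitvec(9, 4)), trace = TRUE)
  expect_equal(bv_value(r$sum) + 2 * bv_value(r$carry), 17)
  for (st in r$stages) expect_equal(sum(st), 17)
  one <- csa_reduce(list(bitvec(12, 4)))
  expect_equal(bv_value(one$sum), 12)
  expect_equal(bv_value(one$carry), 0)
  zz <- csa_reduce(list(bitvec(0, 4), bitvec(0, 4), bitvec(0, 4)))
  expect_equal(bv_value(zz$sum) + bv_value(zz$carry), 0)
  expect_error(csa_reduce(list()), "at least one row")
  set.seed(10)
  for (i in 1:20) {
    vals <- sample(0:4095, sample(3:8, 1), replace = TRUE)
    offs <- sample(0:4, length(vals), replace = TRUE)
    total <- sum(vals * 2^offs)
    r <- csa_reduce(lapply(vals, bitvec, width = 12), offs, trace = TRUE)
    expect_equal(bv_value(r$sum) + 2 * bv_value(r$carry), total)
    for (st in r$stages) expect_equal(sum(st), total)
  }
})

test_that("test-vector files are well formed and exact", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_test_vectors(path, "cutin", width = 16, n = 50, seed = 3)
  lines <- readLines(path)
  expect_length(lines, 50)
  hex2num <- function(h) {
    d <- match(strsplit(h, "")[[1]], c(0:9, letters[1:6])) - 1
    Reduce(function(acc, x) acc * 16 + x, d, init = 0)
  }
  for (ln in lines[1:10]) {
    parts <- strsplit(ln, " ")[[1]]
    expect_equal(hex2num(parts[3]), hex2num(parts[1]) * hex2num(parts[2]))
  }
})
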