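#' Decode an IEEE-754 bit pattern
#'
#' Splits a 32-bit (`fp32`, 1/8/23, bias 127) or 16-bit (`fp16`, 1/5/10,
#' bias 15) pattern into sign, biased exponent and stored mantissa, with a
#' class label.
#'
#' @param bits non-negative integer-valued scalar, the raw pattern.
#' @param profile `"fp32"` or `"fp16"`.
#' @return Object of class `float_bits`: `sign`, `exponent`, `mantissa`,
#'   `profile`, `class` (one of `"zero"`, `"subnormal"`, `"normal"`,
#'   `"inf"`, `"nan"`) and `value` (the decoded double).
#' @examples
#' fp_decode(0x3F800000)           # 1.0
#' fp_decode(0xC0400000)$value     # -3.0
#' @export
fp_decode <- function(bits, profile = c("fp32", "fp16")) {
  profile <- match.arg(profile)
  fp16 <- profile == "fp16"
  eb <- if (fp16) 5L else 8L
  mb <- if (fp16) 10L else 23L
  stopifnot(bits >= 0, bits == floor(bits), bits < 2^(1 + eb + mb))
  m <- bits %% 2^mb
  e <- (bits %/% 2^mb) %% 2^eb
  s <- bits %/% 2^(eb + mb)
  emax <- 2^eb - 1
  cls <- if (e == emax && m != 0) "nan"
         else if (e == emax) "inf"
         else if (e == 0 && m == 0) "zero"
         else if (e == 0) "subnormal"
         else "normal"
  structure(list(sign = s, exponent = e, mantissa = m, profile = profile,
                 class = cls, value = cpp_bits_to_float(bits, fp16)),
            class = "float_bits")
}

#' @export
print.float_bits <- function(x, ...) {
  cat(sprintf("<%s> s=%d e=%d m=0x%x [%s] value=%g\n", x$profile, x$sign,
              x$exponent, x$mantissa, x$class, x$value))
  invisible(x)
}

#' Encode sign/exponent/mantissa fields into a bit pattern
#' @param x a `float_bits` object (or a list with the same fields).
#' @return The raw pattern as a double-held unsigned integer.
#' @export
fp_encode <- function(x) {
  eb <- if (x$profile == "fp16") 5L else 8L
  mb <- if (x$profile == "fp16") 10L else 23L
  stopifnot(x$exponent >= 0, x$exponent < 2^eb, x$mantissa >= 0, x$mantissa < 2^mb)
  x$sign * 2^(eb + mb) + x$exponent * 2^mb + x$mantissa
}

fp_bits_of <- function(x, profile) {
  if (inherits(x, "float_bits")) {
    stopifnot(x$profile == profile)
    return(fp_encode(x))
  }
  stopifnot(is.numeric(x))
  x
}

#' Emulated floating-point multiplication on the CUTIN datapath
#'
#' Multiplies two patterns of the same profile. The mantissa product (24x24
#' bits for fp32, 11x11 for fp16, zero-extended to the power-of-two CUTIN
#' width) is computed bit-level; the sign is the XOR of operand signs and
#' the exponent is the biased sum. If the product's leading bit is high the
#' mantissa window starts one bit higher and the exponent is incremented;
#' otherwise the window starts at the next position with the exponent
#' unchanged. Dropped low bits are truncated (hardware default) or rounded
#' to nearest-even. Subnormal inputs/results flush to signed zero
#' (`underflow` flag); exponent overflow saturates to the largest finite
#' magnitude (`overflow` flag); NaN/Inf propagate by IEEE rules.
#'
#' @param x,y bit patterns (doubles) or `float_bits` objects.
#' @param profile `"fp32"` or `"fp16"`.
#' @param rounding `"trunc"` or `"rne"`.
#' @return `float_bits` result with attribute `"flags"` (underflow/overflow).
#' @examples
#' fp_multiply(0x3FC00000, 0x40000000)$value    # 1.5 * 2 = 3
#' @export
fp_multiply <- function(x, y, profile = c("fp32", "fp16"),
                        rounding = c("trunc", "rne")) {
  profile <- match.arg(profile)
  rounding <- match.arg(rounding)
  res <- cpp_fp_op(fp_bits_of(x, profile), fp_bits_of(y, profile), "mul",
                   profile == "fp16", rounding)
  out <- fp_decode(res$bits, profile)
  attr(out, "flags") <- list(underflow = res$underflow, overflow = res$overflow)
  out
}

#' Emulated floating-point addition on the CSCGL datapath
#'
#' Standard align-add-normalize addition whose significand additions (and
#' complement subtractions) run through the CSCGL adder, with three guard
#' bits and a sticky. Rounding, flush-to-zero and saturation behave as in
#' [fp_multiply()].
#'
#' @inheritParams fp_multiply
#' @return `float_bits` result with attribute `"flags"`.
#' @export
fp_add <- function(x, y, profile = c("fp32", "fp16"),
                   rounding = c("trunc", "rne")) {
  profile <- match.arg(profile)
  rounding <- match.arg(rounding)
  res <- cpp_fp_op(fp_bits_of(x, profile), fp_bits_of(y, profile), "add",
                   profile == "fp16", rounding)
  out <- fp_decode(res$bits, profile)
  attr(out, "flags") <- list(underflow = res$underflow, overflow = res$overflow)
  out
}

#' Convert numeric values to IEEE bit patterns (host rounding)
#' @param v numeric vector.
#' @param profile `"fp32"` or `"fp16"`.
#' @return Vector of raw patterns as doubles.
#' @export
float_to_bits <- function(v, profile = c("fp32", "fp16")) {
  profile <- match.arg(profile)
  cpp_float_to_bits(as.numeric(v), profile == "fp16")
}

#' Convert IEEE bit patterns to numeric values
#' @param b vector of raw patterns.
#' @param profile `"fp32"` or `"fp16"`.
#' @return Numeric vector.
#' @export
bits_to_float <- function(b, profile = c("fp32", "fp16")) {
  profile <- match.arg(profile)
  cpp_bits_to_float(as.numeric(b), profile == "fp16")
}

#' Batch emulated float operations on bit patterns
#' @param xb,yb pattern vectors.
#' @param op `"mul"` or `"add"`.
#' @inheritParams fp_multiply
#' @return Vector of result patterns.
#' @export
fp_op_batch <- function(xb, yb, op = c("mul", "add"),
                        profile = c("fp32", "fp16"),
                        rounding = c("trunc", "rne")) {
  op <- match.arg(op); profile <- match.arg(profile)
  rounding <- match.arg(rounding)
  cpp_fp_op_batch(as.numeric(xb), as.numeric(yb), op, profile == "fp16", rounding)
}

#' Host-FPU reference for batch float operations
#'
#' Computes the same operation through the host floating-point unit (exact
#' double product/sum narrowed with round-to-nearest-even), independent of
#' the emulated datapath. Used as the conformance oracle.
#'
#' @inheritParams fp_op_batch
#' @return Vector of reference result patterns.
#' @export
fp_ref_batch <- function(xb, yb, op = c("mul", "add"),
                         profile = c("fp32", "fp16")) {
  op <- match.arg(op); profile <- match.arg(profile)
  cpp_fp_ref_batch(as.numeric(xb), as.numeric(yb), op, profile == "fp16")
}

#' Units-in-the-last-place distance between two patterns of one profile
#'
#' Both patterns are mapped to a monotone integer scale (sign-magnitude
#' folded around zero) and differenced; adjacent representable values are 1
#' ulp apart.
#'
#' @param a,b pattern vectors.
#' @param profile `"fp32"` or `"fp16"`.
#' @return Non-negative numeric vector of ulp distances.
#' @export
ulp_diff <- function(a, b, profile = c("fp32", "fp16")) {
  profile <- match.arg(profile)
  w <- if (profile == "fp16") 16 else 32
  fold <- function(p) {
    s <- p %/% 2^(w - 1)
    mag <- p %% 2^(w - 1)
    ifelse(s == 1, -mag, mag)
  }
  abs(fold(as.numeric(a)) - fold(as.numeric(b)))
}
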