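#' Vertical-crosswise (Urdhva Tiryagbhyam) multiplication
#'
#' Multiplies two equal-width [bitvec()] operands by forming every partial
#' product column `s_k = sum_{i+j=k} a_i b_j` simultaneously and propagating
#' the column carries upward - the Vedic "vertical and crosswise" scheme,
#' not repeated addition.
#'
#' @param a,b [bitvec()] operands of equal width.
#' @param trace if `TRUE`, attach the per-column partial-product counts,
#'   sum bits and carries as attribute `"trace"`.
#' @return A [bitvec()] of width `2 * width(a)` holding the exact product.
#' @examples
#' ut_multiply(bitvec(5, 3), bitvec(3, 3))   # 15
#' @export
ut_multiply <- function(a, b, trace = FALSE) {
  check_pair(a, b)
  out <- bv_from_hex(cpp_ut_mul(a$value, b$value, a$width), 2L * a$width)
  if (trace) attr(out, "trace") <- cpp_ut_mul_trace(a$value, b$value, a$width)
  out
}

#' Anurupyena working-base selection
#'
#' Chooses the scaled working base `m * B^k` ("proportionately" rule)
#' closest to both operands, minimising `max(|a - base|, |b - base|)`;
#' equidistant candidates break toward the smaller base. Decimal mode
#' (`B = 10`) scans ratios `m` in 1..9; binary mode (`B = 2`) scans
#' `m` in {1, 3} so scaled bases exist between adjacent powers of two.
#'
#' @param a,b positive [bitvec()] operands (widths may differ).
#' @param mode `"dec"` for powers of ten, `"bin"` for powers of two.
#' @return A list of class `working_base`: `base`, `ratio` (m), `power`
#'   (k) and `theoretical_base` (B).
#' @examples
#' anurupyena_working_base(bitvec(48, 8), bitvec(52, 8))$base   # 50
#' @export
anurupyena_working_base <- function(a, b, mode = c("dec", "bin")) {
  mode <- match.arg(mode)
  if (!is_bitvec(a) || !is_bitvec(b)) stop("operands must be bitvec objects")
  if (a$value <= 0 || b$value <= 0) stop("operands must be positive")
  out <- cpp_anurupyena_base(a$value, b$value, if (mode == "dec") 10L else 2L)
  class(out) <- "working_base"
  out
}

#' Nikhilam (base-complement) multiplication with Anurupyena scaling
#'
#' Multiplies via complements against a working base N: with
#' `ca = N - a`, `cb = N - b`, the product is
#' `(a - cb) * N + ca * cb` - "all from 9 and the last from 10". Operands
#' above the base yield negative complements (the excess branch). The
#' scaled-base and complement products run through the vertical-crosswise
#' datapath.
#'
#' @param a,b [bitvec()] operands.
#' @param base a `working_base` from [anurupyena_working_base()], or `NULL`
#'   to select one automatically in the given mode.
#' @param mode base mode used when `base` is `NULL`.
#' @param trace attach complements and left/right parts as attribute
#'   `"trace"`.
#' @return A [bitvec()] of width `2 * max(width(a), width(b))`.
#' @examples
#' bv_value(nikhilam_multiply(bitvec(98, 8), bitvec(97, 8)))   # 9506
#' @export
nikhilam_multiply <- function(a, b, base = NULL, mode = c("dec", "bin"),
                              trace = FALSE) {
  mode <- match.arg(mode)
  if (!is_bitvec(a) || !is_bitvec(b)) stop("operands must be bitvec objects")
  if (is.null(base)) base <- anurupyena_working_base(a, b, mode)
  if (!inherits(base, "working_base")) stop("base must be a working_base")
  if (base$base <= 0) stop("working base must be positive")
  res <- cpp_nikhilam_mul(a$value, b$value, base$base, base$ratio,
                          base$power, base$theoretical_base)
  w <- 2L * max(a$width, b$width)
  out <- bitvec(res$value, w)
  if (trace) attr(out, "trace") <- res[c("complement_a", "complement_b",
                                         "left_part", "right_part")]
  out
}

#' CUTIN hybrid multiplication
#'
#' The hybrid multiplier: an N-bit product is decomposed into four N/2-bit
#' sub-products combined crosswise. Each sub-product is routed to the
#' Nikhilam/Anurupyena complement path when both sub-operands lie within
#' `2^(w - nas_shift)` of the nearest binary working base (w the sub-operand
#' width), and otherwise recurses, bottoming out in direct vertical-crosswise
#' column sums at 4 bits. Cross partial products are reduced carry-save and
#' finalised by the CSCGL adder.
#'
#' @param a,b [bitvec()] operands of equal power-of-two width >= 4.
#' @param nas_shift closeness exponent for the complement-path dispatch
#'   (default 2, i.e. threshold `2^(w-2)`).
#' @return A [bitvec()] of double width; for 32-bit operands the numeric
#'   `value` may round but `$hex` is exact.
#' @examples
#' bv_value(cutin_multiply(bitvec(200, 8), bitvec(198, 8)))   # 39600
#' @export
cutin_multiply <- function(a, b, nas_shift = 2L) {
  check_pair(a, b)
  w <- a$width
  if (w < 4 || bitwAnd(w, w - 1L) != 0) stop("width must be a power of two >= 4")
  bv_from_hex(cpp_cutin_mul(a$value, b$value, w, as.integer(nas_shift)), 2L * w)
}

#' Staged 8x8 multiplication from 4x4 blocks
#'
#' Composes an 8x8 product from four 4x4 vertical-crosswise blocks with
#' staged carry insertion, commencing from a zero pre-carry: each phase
#' obtains a carry through the CSCGL adder and folds it into the next stage.
#'
#' @param a,b [bitvec()] operands of width 8.
#' @return A [bitvec()] of width 16.
#' @export
multiply_8x8_staged <- function(a, b) {
  check_pair(a, b)
  if (a$width != 8) stop("staged multiplier is defined for width 8")
  bv_from_hex(cpp_mul8x8_staged(a$value, b$value), 16L)
}

#' CSCGL addition
#'
#' Adder with clarified sum/carry generation logic: a partial-sum unit forms
#' `s0 = a XOR b` and `c0 = a AND b`, a carry unit derives the selected
#' carry into every position combinationally from `(s0, c0, cin)` - no
#' multiplexer, no duplicated conditional adders - and a final-sum unit
#' merges `s0` with the selected carries.
#'
#' @param a,b [bitvec()] operands of equal width.
#' @param cin carry-in bit (0 or 1).
#' @return A [bitvec()] of width `width(a) + 1` equal to `a + b + cin`.
#' @export
cscgl_add <- function(a, b, cin = 0L) {
  check_pair(a, b)
  stopifnot(cin %in% c(0L, 1L))
  bv_from_hex(cpp_cscgl_add(a$value, b$value, as.integer(cin), a$width),
              a$width + 1L)
}

#' Carry-save 3:2 reduction of a partial-product grid
#'
#' Reduces a list of addends (bit vectors with per-row left-shift offsets)
#' to a sum/carry pair by repeated 3:2 full-adder compression; the carry
#' vector is stored pre-shift, so the represented total is
#' `sum + 2 * carry`.
#'
#' @param rows list of [bitvec()] rows.
#' @param offsets integer left-shift applied to each row (default all 0).
#' @param trace if `TRUE`, include every intermediate stage (each a vector
#'   of row values whose plain sum is invariant).
#' @return List with `sum` and `carry` bitvecs and optionally `stages`.
#' @export
csa_reduce <- function(rows, offsets = NULL, trace = FALSE) {
  if (length(rows) < 1) stop("partial-product grid must contain at least one row")
  stopifnot(all(vapply(rows, is_bitvec, logical(1))))
  if (is.null(offsets)) offsets <- rep(0L, length(rows))
  stopifnot(length(offsets) == length(rows))
  vals <- vapply(rows, bv_value, numeric(1))
  res <- cpp_csa_reduce(vals, as.integer(offsets), trace)
  wmax <- max(vapply(seq_along(rows), function(i) rows[[i]]$width + offsets[i],
                     numeric(1))) + ceiling(log2(length(rows) + 1))
  out <- list(sum = bitvec(res$sum, wmax), carry = bitvec(res$carry, wmax))
  if (trace) out$stages <- res$stages
  out
}

#' Write plain-text multiplier test vectors
#'
#' Emits lines `a_hex b_hex product_hex` for external (e.g. HDL) checking.
#'
#' @param path output file.
#' @param algo one of `"ut"`, `"nas"`, `"cutin"`, `"staged"`.
#' @param width operand width in bits.
#' @param n number of seeded random vectors.
#' @param seed RNG seed.
#' @return Invisibly, the path.
#' @export
write_test_vectors <- function(path, algo = c("cutin", "ut", "nas", "staged"),
                               width = 8, n = 256, seed = 1) {
  algo <- match.arg(algo)
  id <- match(algo, c("ut", "nas", "cutin", "staged")) - 1L
  writeLines(cpp_test_vectors(id, as.integer(width), as.integer(n),
                              as.integer(seed)), path)
  invisible(path)
}

algo_id <- function(algo) {
  match(match.arg(algo, c("ut", "nas", "cutin", "staged")),
        c("ut", "nas", "cutin", "staged")) - 1L
}

#' Batch oracle check of a multiplier against machine integer multiplication
#'
#' Runs the selected bit-level multiplier over either the exhaustive 8-bit
#' operand space (`n = 0`) or `n` seeded random pairs at the given width,
#' comparing every product (and its operand-swapped twin) against the host
#' integer multiply. Intended for conformance sweeps.
#'
#' @param algo `"ut"`, `"nas"`, `"cutin"` or `"staged"`.
#' @param width operand width (8, 16 or 32).
#' @param n number of random pairs; 0 for the exhaustive 8-bit sweep.
#' @param seed PRNG seed for the sampled sweep.
#' @return Number of mismatching products (0 on conformance).
#' @export
verify_multiplier <- function(algo = "cutin", width = 8, n = 0, seed = 1) {
  cpp_verify_multiplier(algo_id(algo), as.integer(width), as.integer(n),
                        as.integer(seed))
}

#' Exhaustive oracle check of the CSCGL adder
#' @param width operand width (at most 12).
#' @return Number of mismatches against `a + b + cin` over all operands and
#'   both carry-ins.
#' @export
verify_cscgl <- function(width = 8) cpp_verify_cscgl_exhaustive(as.integer(width))

#' Sum-preservation check of carry-save reduction on random grids
#' @param n number of random grids.
#' @param seed PRNG seed.
#' @return Number of stages at which the invariant failed (0 on success).
#' @export
verify_csa <- function(n = 1e4, seed = 1) {
  cpp_verify_csa_random(as.integer(n), as.integer(seed))
}
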