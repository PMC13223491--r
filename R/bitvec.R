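#' Fixed-width unsigned binary operand
#'
#' A `bitvec` holds an unsigned integer confined to a fixed bit width, the
#' operand type of the emulated arithmetic units. Values up to 53 bits are
#' held exactly as doubles; wider results (e.g. 64-bit products of 32-bit
#' operands) carry an exact hexadecimal representation alongside the
#' (possibly rounded) numeric value.
#'
#' @param x non-negative integer-valued scalar, or a hex string (`"0x..."`
#'   or bare hex digits).
#' @param width positive integer number of bits.
#' @return An object of class `bitvec` with fields `width`, `value`
#'   (double; exact iff `width <= 53`) and `hex` (canonical, zero-padded).
#' @examples
#' bitvec(5, 3)
#' bitvec("0xff", 8)
#' @export
bitvec <- function(x, width) {
  stopifnot(length(width) == 1L, width >= 1, width == floor(width))
  if (is.character(x)) {
    hex <- tolower(sub("^0x", "", x))
    stopifnot(grepl("^[0-9a-f]+$", hex))
    hex <- sub("^0+(?=.)", "", hex, perl = TRUE)
    ndig <- ceiling(width / 4)
    r <- width %% 4
    top <- match(substr(hex, 1, 1), c(0:9, letters[1:6])) - 1
    if (nchar(hex) > ndig || (nchar(hex) == ndig && r > 0 && top >= 2^r))
      stop("value does not fit in ", width, " bits")
    hex <- paste0(strrep("0", ndig - nchar(hex)), hex)
    value <- hex_to_num(hex)
  } else {
    stopifnot(is.numeric(x), length(x) == 1L, x >= 0, x == floor(x))
    if (width <= 53 && x >= 2^width) stop("value does not fit in ", width, " bits")
    value <- as.numeric(x)
    hex <- num_to_hex(value, width)
  }
  structure(list(width = as.integer(width), value = value, hex = hex),
            class = "bitvec")
}

hex_to_num <- function(hex) {
  d <- match(strsplit(hex, "")[[1]], c(0:9, letters[1:6])) - 1
  Reduce(function(acc, x) acc * 16 + x, d, accumulate = FALSE, init = 0)
}

num_to_hex <- function(v, width) {
  ndig <- ceiling(width / 4)
  digs <- character(ndig)
  for (i in ndig:1) {
    digs[i] <- c(0:9, letters[1:6])[v %% 16 + 1]
    v <- v %/% 16
  }
  paste(digs, collapse = "")
}

#' @export
print.bitvec <- function(x, ...) {
  cat(sprintf("<bitvec %d-bit> 0x%s (%s)\n", x$width, x$hex,
              format(x$value, scientific = FALSE)))
  invisible(x)
}

#' @export
format.bitvec <- function(x, ...) sprintf("0x%s/%d", x$hex, x$width)

#' Integer value of a bitvec
#' @param x a [bitvec()].
#' @return double; exact when the width is at most 53 bits.
#' @export
bv_value <- function(x) {
  stopifnot(inherits(x, "bitvec"))
  x$value
}

is_bitvec <- function(x) inherits(x, "bitvec")

check_pair <- function(a, b) {
  if (!is_bitvec(a) || !is_bitvec(b)) stop("operands must be bitvec objects")
  if (a$width != b$width) stop("operand width mismatch: ", a$width, " vs ", b$width)
  invisible(TRUE)
}

bv_from_hex <- function(hex, width) {
  structure(list(width = as.integer(width), value = hex_to_num(hex), hex = hex),
            class = "bitvec")
}
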