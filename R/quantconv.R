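#' Symmetric quantization of a feature map
#'
#' Maps real values to signed integer levels with zero-point 0:
#' `scale = max(|t|) / (2^(bits-1) - 1)`, `levels = round(t / scale)`
#' clipped to the symmetric range. An all-zero tensor gets scale 1.
#'
#' @param t numeric array (any shape).
#' @param bits 8 or 16.
#' @return List with `levels` (same shape), `scale`, `zero_point` (always
#'   0) and `bits`.
#' @examples
#' q <- quantize(c(-1, 1), bits = 8)
#' q$levels                      # -127, 127
#' @export
quantize <- function(t, bits = 8) {
  stopifnot(bits %in% c(8, 16), all(is.finite(t)))
  qmax <- 2^(bits - 1) - 1
  m <- max(abs(t))
  scale <- if (m == 0) 1 else m / qmax
  levels <- pmin(pmax(round(t / scale), -qmax), qmax)
  if (!is.null(dim(t))) dim(levels) <- dim(t)
  list(levels = levels, scale = scale, zero_point = 0, bits = bits)
}

#' Reconstruct real values from quantized levels
#' @param q a list as returned by [quantize()].
#' @return Numeric array `levels * scale`.
#' @export
dequantize <- function(q) q$levels * q$scale

#' Convolution layer specification
#'
#' @param kernel odd kernel size k.
#' @param in_channels,out_channels positive channel counts.
#' @param stride positive stride.
#' @param padding non-negative zero-padding; `"same"` selects `(k-1)/2`.
#' @param backend `"exact"`, `"cutin_fp32"` or `"cutin_fp16"`.
#' @return A `conv_spec` list.
#' @export
conv_spec <- function(kernel = 3, in_channels = 1, out_channels = 1,
                      stride = 1, padding = "same",
                      backend = c("exact", "cutin_fp32", "cutin_fp16")) {
  backend <- match.arg(backend)
  stopifnot(kernel %% 2 == 1, kernel >= 1, in_channels >= 1, out_channels >= 1,
            stride >= 1)
  if (identical(padding, "same")) padding <- (kernel - 1) / 2
  stopifnot(padding >= 0)
  structure(list(kernel = as.integer(kernel), in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels), stride = as.integer(stride),
                 padding = as.integer(padding), backend = backend),
            class = "conv_spec")
}

as_hwc <- function(x) {
  if (is.null(dim(x))) stop("feature map must have dim attributes")
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 3)
  x
}

#' 2-D convolution through a selectable arithmetic backend
#'
#' Each output pixel is the inner product of an input patch vector and a
#' filter vector. The `exact` backend accumulates in host doubles; the
#' `cutin_fp32` / `cutin_fp16` backends route every scalar product through
#' the emulated IEEE multiplier and accumulate over a balanced binary tree
#' of emulated additions, mirroring the quantized-convolution datapath
#' (data buffer, processing elements, multiplier + adder tree).
#'
#' @param x H x W or H x W x C numeric array.
#' @param w kernel array `k x k x C x Cout` (a `k x k` matrix is promoted).
#' @param spec a [conv_spec()]; its channel counts must match `x` and `w`.
#' @param rounding rounding mode of the emulated backends.
#' @return `Ho x Wo x Cout` array.
#' @examples
#' x <- matrix(1, 3, 3)
#' conv2d(x, matrix(1, 3, 3), conv_spec(3, padding = 0))  # 9
#' @export
conv2d <- function(x, w, spec = conv_spec(), rounding = "trunc") {
  x <- as_hwc(x)
  if (length(dim(w)) == 2) dim(w) <- c(dim(w), 1L, 1L)
  stopifnot(length(dim(w)) == 4)
  if (dim(w)[1] != spec$kernel || dim(w)[3] != dim(x)[3])
    stop("kernel shape inconsistent with spec or input channels")
  out <- cpp_conv2d(as.numeric(x), as.integer(dim(x)),
                    as.numeric(w), as.integer(dim(w)),
                    spec$stride, spec$padding, spec$backend, rounding)
  out
}

#' Analytic deviation bound for emulated convolution backends
#'
#' Forward error bound for one convolution run through an emulated IEEE
#' backend with truncation: operand conversion and the truncated product
#' contribute at most 2 ulp of relative error per term, and each of the
#' `ceil(log2(n))` balanced-tree addition levels at most 1 ulp of the
#' accumulated magnitude, giving
#' `|err| <= (depth + 4) * 2^-mbits * (|x| * |w|) + n * minimum_normal`
#' per output pixel (the additive term covers flush-to-zero of tiny
#' products).
#'
#' @param x input feature map (H x W or H x W x C).
#' @param w kernel array.
#' @param mbits stored mantissa bits of the backend profile (23 for fp32,
#'   10 for fp16).
#' @param spec convolution geometry (defaults to same-padding with the
#'   kernel's shape).
#' @return Array of per-pixel bounds, same shape as the convolution output.
#' @export
conv_ulp_bound <- function(x, w, mbits = 23, spec = NULL) {
  x <- as_hwc(x)
  if (length(dim(w)) == 2) dim(w) <- c(dim(w), 1L, 1L)
  if (is.null(spec))
    spec <- conv_spec(dim(w)[1], dim(w)[3], dim(w)[4], backend = "exact")
  spec$backend <- "exact"
  S <- conv2d(abs(x), abs(w), spec)
  nterms <- dim(w)[1]^2 * dim(w)[3]
  depth <- ceiling(log2(nterms))
  min_normal <- if (mbits == 10) 2^-14 else 2^-126
  (depth + 4) * 2^-mbits * S + nterms * min_normal
}

#' Per-channel batch normalisation
#'
#' `(x - mean) / sqrt(var + eps) * gamma + beta`, parameters recycled per
#' channel.
#'
#' @param x H x W x C array.
#' @param mean,var,gamma,beta length-C numeric vectors (scalars recycle).
#' @param eps stabiliser.
#' @return Array of the same shape.
#' @export
batch_norm <- function(x, mean = 0, var = 1, gamma = 1, beta = 0, eps = 1e-5) {
  x <- as_hwc(x)
  C <- dim(x)[3]
  mean <- rep_len(mean, C); var <- rep_len(var, C)
  gamma <- rep_len(gamma, C); beta <- rep_len(beta, C)
  stopifnot(all(var >= 0))
  out <- x
  for (c in seq_len(C))
    out[, , c] <- (x[, , c] - mean[c]) / sqrt(var[c] + eps) * gamma[c] + beta[c]
  out
}

#' Rectified linear activation
#' @param x numeric array.
#' @return `pmax(x, 0)` with shape preserved; idempotent.
#' @export
relu <- function(x) {
  out <- pmax(x, 0)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}
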