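// 2-D convolution with selectable arithmetic backends.
//
// exact:       host double multiply-accumulate (reference datapath)
// cutin_fp32:  every scalar product through the emulated IEEE-754 fp32
//              multiplier; accumulation over a balanced binary tree of
//              emulated fp32 additions
// cutin_fp16:  same structure on the binary16 profile
//
// Tensors arrive from R as H x W x C arrays (column-major), kernels as
// k x k x C x Cout.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>

using namespace Rcpp;

// C entry points exported by float_emu.cpp
extern "C" {
  uint64_t vedicnn_fp_mul_bits(uint64_t, uint64_t, int, int);
  uint64_t vedicnn_fp_add_bits(uint64_t, uint64_t, int, int);
  uint64_t vedicnn_d2bits(double, int);
  double   vedicnn_bits2d(uint64_t, int);
}

static uint64_t emu_mul(uint64_t a, uint64_t b, bool fp16, int rm) {
  return vedicnn_fp_mul_bits(a, b, fp16 ? 1 : 0, rm);
}
static uint64_t emu_add(uint64_t a, uint64_t b, bool fp16, int rm) {
  return vedicnn_fp_add_bits(a, b, fp16 ? 1 : 0, rm);
}

// balanced binary adder tree over emulated sums
static uint64_t tree_sum(std::vector<uint64_t> &v, bool fp16, int rm) {
  if (v.empty()) return vedicnn_d2bits(0.0, fp16 ? 1 : 0);
  while (v.size() > 1) {
    std::vector<uint64_t> nxt;
    for (size_t i = 0; i + 1 < v.size(); i += 2)
      nxt.push_back(emu_add(v[i], v[i + 1], fp16, rm));
    if (v.size() & 1) nxt.push_back(v.back());
    v = nxt;
  }
  return v[0];
}

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, IntegerVector xdim,
                         NumericVector w, IntegerVector wdim,
                         int stride, int pad, std::string backend,
                         std::string rm) {
  int H = xdim[0], W = xdim[1], C = xdim[2];
  int k = wdim[0], Cin = wdim[2], Cout = wdim[3];
  if (Cin != C) stop("channel mismatch between input and kernel");
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("kernel larger than padded input");
  NumericVector out(Ho * Wo * Cout);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout);

  bool exact = (backend == "exact");
  bool fp16 = (backend == "cutin_fp16");
  int rmode = (rm == "rne") ? 1 : 0;

  // pre-quantize operands to the target profile once
  std::vector<uint64_t> xb, wb;
  if (!exact) {
    xb.resize(x.size()); wb.resize(w.size());
    for (int i = 0; i < x.size(); ++i) xb[i] = vedicnn_d2bits(x[i], fp16);
    for (int i = 0; i < w.size(); ++i) wb[i] = vedicnn_d2bits(w[i], fp16);
  }

  for (int co = 0; co < Cout; ++co) {
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        double acc = 0.0;
        std::vector<uint64_t> prods;
        for (int c = 0; c < C; ++c) {
          for (int kw = 0; kw < k; ++kw) {
            for (int kh = 0; kh < k; ++kh) {
              int ih = oh * stride + kh - pad;
              int iw = ow * stride + kw - pad;
              if (ih < 0 || ih >= H || iw < 0 || iw >= W) continue;  // zero pad
              int xi = ih + H * (iw + W * c);
              int wi = kh + k * (kw + k * (c + C * co));
              if (exact) acc += x[xi] * w[wi];
              else prods.push_back(emu_mul(xb[xi], wb[wi], fp16, rmode));
            }
          }
        }
        int oi = oh + Ho * (ow + Wo * co);
        if (exact) out[oi] = acc;
        else out[oi] = vedicnn_bits2d(tree_sum(prods, fp16, rmode), fp16);
      }
    }
  }
  return out;
}
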