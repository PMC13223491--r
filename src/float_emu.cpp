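// IEEE-754 multiply/add emulated on the Vedic integer datapath.
//
// fp32: 1/8/23 (bias 127), mantissa product 24x24 -> 48 bits on the 32-bit
// CUTIN datapath.  fp16: 1/5/10 (bias 15), 11x11 -> 22 bits on the 16-bit
// datapath.  Normalization follows the hardware rule: product MSB set ->
// mantissa window one bit higher and exponent incremented; else the window
// starts at the next position and the exponent is unchanged.  Rounding is
// either plain truncation of the dropped low bits (hardware default) or
// round-nearest-even with guard/sticky.  Subnormals flush to signed zero;
// exponent overflow saturates to the largest finite magnitude.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <cstring>

using namespace Rcpp;

uint64_t vedic_cutin_mul(uint64_t a, uint64_t b, int w);  // from vedic.cpp

struct Profile {
  int ebits, mbits, bias, cutin_w;
  uint64_t qnan, inf_mag, max_fin;
};

static Profile prof(int is16) {
  Profile p;
  if (is16) { p.ebits = 5;  p.mbits = 10; p.bias = 15;  p.cutin_w = 16; }
  else      { p.ebits = 8;  p.mbits = 23; p.bias = 127; p.cutin_w = 32; }
  uint64_t emax = (1ULL << p.ebits) - 1;
  p.inf_mag = emax << p.mbits;
  p.qnan = p.inf_mag | (1ULL << (p.mbits - 1));
  p.max_fin = ((emax - 1) << p.mbits) | ((1ULL << p.mbits) - 1);
  return p;
}

struct Fields { uint64_t s, e, m; };

static Fields split(uint64_t bits, const Profile &p) {
  Fields f;
  f.m = bits & ((1ULL << p.mbits) - 1);
  f.e = (bits >> p.mbits) & ((1ULL << p.ebits) - 1);
  f.s = bits >> (p.ebits + p.mbits);
  return f;
}

enum { RM_TRUNC = 0, RM_RNE = 1 };

// round a (mbits+1)-bit significand given dropped guard/sticky info
static uint64_t round_sig(uint64_t keep, uint64_t dropped, int drop_bits, int rm,
                          uint64_t &exp_bump) {
  exp_bump = 0;
  if (rm == RM_RNE && drop_bits > 0) {
    uint64_t g = (dropped >> (drop_bits - 1)) & 1ULL;
    uint64_t rest = drop_bits > 1 ? (dropped & ((1ULL << (drop_bits - 1)) - 1)) : 0;
    if (g && (rest || (keep & 1ULL))) ++keep;
  }
  return keep;
}

static uint64_t assemble(uint64_t s, int64_t e, uint64_t m, const Profile &p,
                         int &flag) {
  int64_t emax = (int64_t)((1ULL << p.ebits) - 1);
  if (e <= 0) { flag = 1; return s << (p.ebits + p.mbits); }           // underflow: flush
  if (e >= emax) { flag = 2; return (s << (p.ebits + p.mbits)) | p.max_fin; } // saturate
  return (s << (p.ebits + p.mbits)) | ((uint64_t)e << p.mbits) | m;
}

static uint64_t fp_mul_bits(uint64_t xb, uint64_t yb, int is16, int rm, int &flag) {
  Profile p = prof(is16);
  flag = 0;
  Fields x = split(xb, p), y = split(yb, p);
  uint64_t emax = (1ULL << p.ebits) - 1;
  uint64_t rs = x.s ^ y.s;
  bool xnan = (x.e == emax && x.m != 0), ynan = (y.e == emax && y.m != 0);
  bool xinf = (x.e == emax && x.m == 0), yinf = (y.e == emax && y.m == 0);
  if (x.e == 0) x.m = 0;  // flush subnormal input
  if (y.e == 0) y.m = 0;
  bool xzero = (x.e == 0), yzero = (y.e == 0);
  if (xnan || ynan) return p.qnan;
  if ((xinf && yzero) || (yinf && xzero)) return p.qnan;
  if (xinf || yinf) return (rs << (p.ebits + p.mbits)) | p.inf_mag;
  if (xzero || yzero) return rs << (p.ebits + p.mbits);

  uint64_t M1 = (1ULL << p.mbits) | x.m;   // implicit leading one
  uint64_t M2 = (1ULL << p.mbits) | y.m;
  uint64_t P = vedic_cutin_mul(M1, M2, p.cutin_w);   // 2*(mbits+1)-bit product
  int pw = 2 * (p.mbits + 1);
  int64_t e = (int64_t)x.e + (int64_t)y.e - p.bias;
  uint64_t keep, dropped; int drop_bits;
  if ((P >> (pw - 1)) & 1ULL) {            // product MSB high: higher window
    drop_bits = p.mbits + 1;
    keep = P >> drop_bits;                 // mbits+1 bits incl. leading one
    dropped = P & ((1ULL << drop_bits) - 1);
    e += 1;
  } else {                                 // window from position pw-2
    drop_bits = p.mbits;
    keep = P >> drop_bits;
    dropped = P & ((1ULL << drop_bits) - 1);
  }
  uint64_t bump;
  keep = round_sig(keep, dropped, drop_bits, rm, bump);
  if (keep >> (p.mbits + 1)) { keep >>= 1; e += 1; }   // rounding overflow
  return assemble(rs, e, keep & ((1ULL << p.mbits) - 1), p, flag);
}

// addition: align, add/subtract significands through the CSCGL datapath,
// normalize, round (3 extra working bits: guard/round/sticky)
uint64_t cscgl_add_for_fp(uint64_t a, uint64_t b, int w);

static uint64_t fp_add_bits(uint64_t xb, uint64_t yb, int is16, int rm, int &flag) {
  Profile p = prof(is16);
  flag = 0;
  Fields x = split(xb, p), y = split(yb, p);
  uint64_t emax = (1ULL << p.ebits) - 1;
  bool xnan = (x.e == emax && x.m != 0), ynan = (y.e == emax && y.m != 0);
  bool xinf = (x.e == emax && x.m == 0), yinf = (y.e == emax && y.m == 0);
  if (xnan || ynan) return p.qnan;
  if (xinf && yinf) return (x.s != y.s) ? p.qnan : xb;
  if (xinf) return xb;
  if (yinf) return yb;
  if (x.e == 0) x.m = 0;
  if (y.e == 0) y.m = 0;
  bool xzero = (x.e == 0), yzero = (y.e == 0);
  if (xzero && yzero)
    return ((x.s & y.s) << (p.ebits + p.mbits));   // -0 + -0 = -0, else +0
  if (xzero) return yb;
  if (yzero) return xb;

  uint64_t Mx = (1ULL << p.mbits) | x.m, My = (1ULL << p.mbits) | y.m;
  // order by magnitude (exponent, then mantissa)
  bool swap = (y.e > x.e) || (y.e == x.e && My > Mx);
  Fields big = swap ? y : x, small = swap ? x : y;
  uint64_t Mb = swap ? My : Mx, Ms = swap ? Mx : My;
  int64_t d = (int64_t)big.e - (int64_t)small.e;
  // working significands with 3 extra low bits
  uint64_t B = Mb << 3;
  uint64_t S;
  if (d >= (int64_t)(p.mbits + 4)) {
    S = (Ms != 0) ? 1 : 0;                 // pure sticky
  } else {
    uint64_t shifted = (Ms << 3) >> d;
    uint64_t lost = (d > 0) ? ((Ms << 3) & ((1ULL << d) - 1)) : 0;
    S = shifted | (lost ? 1ULL : 0ULL);
  }
  int64_t e = (int64_t)big.e;
  uint64_t sig;
  uint64_t sign = big.s;
  int addw = p.mbits + 5;
  if (x.s == y.s) {
    sig = cscgl_add_for_fp(B, S, addw);
    if (sig >> (p.mbits + 4)) {            // carry out: renormalize right
      sig = (sig >> 1) | (sig & 1ULL);
      e += 1;
    }
  } else {
    uint64_t comp = ((~S) + 1ULL) & ((1ULL << addw) - 1);   // two's complement
    sig = cscgl_add_for_fp(B, comp, addw) & ((1ULL << addw) - 1);
    if (sig == 0) return 0;                                  // exact cancel -> +0
    while (!((sig >> (p.mbits + 3)) & 1ULL)) { sig <<= 1; e -= 1; }
  }
  uint64_t bump;
  uint64_t keep = round_sig(sig >> 3, sig & 7ULL, 3, rm, bump);
  if (keep >> (p.mbits + 1)) { keep >>= 1; e += 1; }
  return assemble(sign, e, keep & ((1ULL << p.mbits) - 1), p, flag);
}

// thin wrapper so float code exercises the same CSCGL unit
#include <vector>
static uint64_t cscgl_unit(uint64_t a, uint64_t b, int w) {
  uint64_t s0 = a ^ b, c0 = a & b, carry = 0, sel = 0;
  for (int i = 0; i < w; ++i) {
    sel |= carry << i;
    carry = ((c0 >> i) & 1ULL) | (((s0 >> i) & 1ULL) & carry);
  }
  uint64_t sum = (s0 ^ sel) & ((w >= 64) ? ~0ULL : ((1ULL << w) - 1));
  if (w < 64) sum |= carry << w;
  return sum;
}
uint64_t cscgl_add_for_fp(uint64_t a, uint64_t b, int w) { return cscgl_unit(a, b, w); }

// ----------------------- host reference conversions ------------------------

static uint32_t f2b(float f) { uint32_t u; std::memcpy(&u, &f, 4); return u; }
static float b2f(uint32_t u) { float f; std::memcpy(&f, &u, 4); return f; }

// double -> binary16 bits, round to nearest even (reference path, frexp-based)
static uint16_t d2h(double v) {
  if (std::isnan(v)) return 0x7E00;
  uint16_t s = std::signbit(v) ? 0x8000 : 0;
  v = std::fabs(v);
  if (std::isinf(v) || v >= 65520.0) return s | 0x7C00;   // >= rounds to inf
  if (v < 0.5 * std::pow(2.0, -14)) return s;             // flush-to-zero regime
  if (v < std::pow(2.0, -14)) {
    // subnormal half range; callers avoid it, round anyway
    int lv = (int)std::lround(v / std::pow(2.0, -24));
    return s | (uint16_t)lv;
  }
  int e2; double fr = std::frexp(v, &e2);     // v = fr * 2^e2, fr in [0.5,1)
  int E = e2 - 1 + 15;
  double m = fr * 2.0 - 1.0;                  // in [0,1)
  double scaled = m * 1024.0;
  long lo = (long)std::floor(scaled);
  double rem = scaled - lo;
  if (rem > 0.5 || (rem == 0.5 && (lo & 1))) ++lo;
  if (lo == 1024) { lo = 0; ++E; }
  if (E >= 31) return s | 0x7C00;
  return s | (uint16_t)(E << 10) | (uint16_t)lo;
}

static double h2d(uint16_t h) {
  int s = (h >> 15) & 1, e = (h >> 10) & 31, m = h & 1023;
  double v;
  if (e == 31) v = m ? NAN : INFINITY;
  else if (e == 0) v = m * std::pow(2.0, -24);
  else v = (1.0 + m / 1024.0) * std::pow(2.0, e - 15);
  return s ? -v : v;
}

// plain-C entry points for the convolution backend (no R objects in the loop)
extern "C" {
uint64_t vedicnn_fp_mul_bits(uint64_t a, uint64_t b, int is16, int rm) {
  int flag; return fp_mul_bits(a, b, is16, rm, flag);
}
uint64_t vedicnn_fp_add_bits(uint64_t a, uint64_t b, int is16, int rm) {
  int flag; return fp_add_bits(a, b, is16, rm, flag);
}
uint64_t vedicnn_d2bits(double v, int is16) {
  return is16 ? (uint64_t)d2h(v) : (uint64_t)f2b((float)v);
}
double vedicnn_bits2d(uint64_t b, int is16) {
  return is16 ? h2d((uint16_t)b) : (double)b2f((uint32_t)b);
}
}

// ------------------------------ R interface --------------------------------

// [[Rcpp::export]]
List cpp_fp_op(double xbits, double ybits, std::string op, bool fp16, std::string rm) {
  int flag = 0;
  int r = (rm == "rne") ? RM_RNE : RM_TRUNC;
  uint64_t xb = (uint64_t)xbits, yb = (uint64_t)ybits;
  uint64_t res = (op == "mul") ? fp_mul_bits(xb, yb, fp16 ? 1 : 0, r, flag)
                               : fp_add_bits(xb, yb, fp16 ? 1 : 0, r, flag);
  return List::create(_["bits"] = (double)res,
                      _["underflow"] = (flag == 1), _["overflow"] = (flag == 2));
}

// [[Rcpp::export]]
NumericVector cpp_fp_op_batch(NumericVector xbits, NumericVector ybits,
                              std::string op, bool fp16, std::string rm) {
  int n = xbits.size(), flag;
  int r = (rm == "rne") ? RM_RNE : RM_TRUNC;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    uint64_t xb = (uint64_t)xbits[i], yb = (uint64_t)ybits[i];
    out[i] = (double)((op == "mul") ? fp_mul_bits(xb, yb, fp16 ? 1 : 0, r, flag)
                                    : fp_add_bits(xb, yb, fp16 ? 1 : 0, r, flag));
  }
  return out;
}

// host-FPU reference on the same bit patterns (independent of the emulation)
// [[Rcpp::export]]
NumericVector cpp_fp_ref_batch(NumericVector xbits, NumericVector ybits,
                               std::string op, bool fp16) {
  int n = xbits.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (fp16) {
      double x = h2d((uint16_t)xbits[i]), y = h2d((uint16_t)ybits[i]);
      double z = (op == "mul") ? x * y : x + y;   // exact in double for halves
      out[i] = (double)d2h(z);
    } else {
      double x = (double)b2f((uint32_t)xbits[i]);
      double y = (double)b2f((uint32_t)ybits[i]);
      double z = (op == "mul") ? x * y : x + y;
      out[i] = (double)f2b((float)z);             // RNE via host narrowing
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_float_to_bits(NumericVector v, bool fp16) {
  int n = v.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = fp16 ? (double)d2h(v[i]) : (double)f2b((float)v[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_bits_to_float(NumericVector b, bool fp16) {
  int n = b.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = fp16 ? h2d((uint16_t)b[i]) : (double)b2f((uint32_t)b[i]);
  return out;
}
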