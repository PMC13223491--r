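// Bit-level emulation of the Vedic multiplier family and the CSCGL adder.
//
// All routines operate on unsigned operand magnitudes held in uint64_t.
// Products of 32-bit operands occupy up to 64 bits, which exceeds the exact
// range of an R double (2^53), so product values cross the R boundary as hex
// strings; operands (<= 32 bits) travel as doubles.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

static uint64_t mask_bits(int w) {
  return (w >= 64) ? ~0ULL : ((1ULL << w) - 1ULL);
}

static uint64_t as_u64(double x) {
  if (x < 0 || x != std::floor(x))
    stop("operand must be a non-negative integer value");
  return (uint64_t)x;
}

static std::string to_hex(uint64_t v, int width_bits) {
  int digits = (width_bits + 3) / 4;
  if (digits < 1) digits = 1;
  std::string s(digits, '0');
  for (int i = digits - 1; i >= 0; --i) {
    s[i] = "0123456789abcdef"[v & 0xF];
    v >>= 4;
  }
  return s;
}

// ---------------------------------------------------------------------------
// Urdhva Tiryagbhyam: vertical-crosswise column sums with carry propagation.
// Column k collects sum_{i+j=k} a_i * b_j; the carry from each column feeds
// the next, so all partial products of one column are formed together.
// ---------------------------------------------------------------------------
static uint64_t ut_mul_u(uint64_t a, uint64_t b, int w) {
  uint64_t res = 0, carry = 0;
  for (int k = 0; k < 2 * w; ++k) {
    uint64_t col = carry;
    int ilo = k - (w - 1); if (ilo < 0) ilo = 0;
    int ihi = (k < w - 1) ? k : (w - 1);
    for (int i = ilo; i <= ihi; ++i)
      col += ((a >> i) & 1ULL) & ((b >> (k - i)) & 1ULL);
    res |= (col & 1ULL) << k;
    carry = col >> 1;
  }
  return res;
}

// ---------------------------------------------------------------------------
// CSCGL adder: partial-sum unit (PSU), carry unit (CU), final-sum unit (FSU).
// PSU forms s0 = a xor b and c0 = a and b in one level.  The CU derives the
// selected carry into every position purely combinationally from (s0, c0, cin)
// -- no duplicated conditional adders, no multiplexer.  The FSU merges s0 with
// the selected carries.  Result has width w + 1.
// ---------------------------------------------------------------------------
static uint64_t cscgl_add_u(uint64_t a, uint64_t b, int cin, int w) {
  uint64_t s0 = a ^ b;            // PSU partial sum
  uint64_t c0 = a & b;            // PSU partial carry
  uint64_t carry = (uint64_t)(cin & 1);
  uint64_t sel = 0;               // CU: selected carry into each bit position
  for (int i = 0; i < w; ++i) {
    sel |= carry << i;
    carry = ((c0 >> i) & 1ULL) | (((s0 >> i) & 1ULL) & carry);
  }
  uint64_t sum = (s0 ^ sel) & mask_bits(w);   // FSU
  if (w < 64) sum |= carry << w;
  return sum;
}

// 3:2 carry-save reduction of a list of addends down to (sum, carry),
// carry stored pre-shift (weight 2 lives in the invariant).
static void csa_reduce_u(std::vector<uint64_t> rows, uint64_t &sum, uint64_t &carry,
                         std::vector< std::vector<uint64_t> > *stages = nullptr) {
  if (stages) stages->push_back(rows);
  while (rows.size() > 2) {
    std::vector<uint64_t> next;
    size_t i = 0;
    for (; i + 2 < rows.size(); i += 3) {
      uint64_t x = rows[i], y = rows[i + 1], z = rows[i + 2];
      uint64_t s = x ^ y ^ z;
      uint64_t c = (x & y) | (x & z) | (y & z);
      next.push_back(s);
      next.push_back(c << 1);   // weight-2 carry re-enters as a shifted row
    }
    for (; i < rows.size(); ++i) next.push_back(rows[i]);
    rows = next;
    if (stages) stages->push_back(rows);
  }
  if (rows.size() == 1) { sum = rows[0]; carry = 0; return; }
  // final full-adder pass produces the canonical pre-shift carry vector
  uint64_t x = rows[0], y = rows[1];
  sum = x ^ y;
  carry = x & y;
  if (stages) {
    std::vector<uint64_t> fin; fin.push_back(sum); fin.push_back(carry << 1);
    stages->push_back(fin);
  }
}

// ---------------------------------------------------------------------------
// Anurupyena working-base selection: brute force over candidate bases m*B^k,
// minimizing max(|a - N|, |b - N|); ties break toward the smaller base.
// Decimal mode: B = 10, m in 1..9.  Binary mode: B = 2, m in {1, 3} so that
// scaled bases exist between adjacent powers of two.
// ---------------------------------------------------------------------------
static void anurupyena_u(uint64_t a, uint64_t b, int B,
                         uint64_t &best, int &best_m, int &best_k) {
  std::vector<int> ms;
  if (B == 10) { for (int m = 1; m <= 9; ++m) ms.push_back(m); }
  else { ms.push_back(1); ms.push_back(3); }
  uint64_t hi = (a > b) ? a : b;
  best = 1; best_m = 1; best_k = 0;
  uint64_t best_d = ~0ULL;
  for (size_t mi = 0; mi < ms.size(); ++mi) {
    uint64_t base = ms[mi];
    for (int k = 0; ; ++k) {
      uint64_t da = (base > a) ? base - a : a - base;
      uint64_t db = (base > b) ? base - b : b - base;
      uint64_t d = (da > db) ? da : db;
      if (d < best_d || (d == best_d && base < best)) {
        best_d = d; best = base; best_m = ms[mi]; best_k = k;
      }
      if (base > 2 * hi + 1) break;              // further bases only worsen
      if (base > (~0ULL) / (uint64_t)B) break;   // overflow guard
      base *= (uint64_t)B;
    }
  }
}

static int bits_needed(uint64_t x) {
  int w = 0;
  while (x) { ++w; x >>= 1; }
  return w < 1 ? 1 : w;
}

// Nikhilam with Anurupyena: complements against a working base N = m*B^k.
//   ca = N - a, cb = N - b (negative when the operand exceeds the base)
//   left  = a - cb  (== b - ca == a + b - N)
//   product = left * N + ca * cb
// The scaled-base multiply (left * m) and the complement product run through
// the UT datapath; the B^k factor is a digit/bit shift.
static uint64_t nikhilam_mul_u(uint64_t a, uint64_t b, uint64_t base, int m, int k, int B) {
  // 128-bit signed intermediates: left * base can exceed 2^63 for 32-bit
  // operands above the base even though the final product fits in 64 bits
  __int128 ca = (__int128)base - (__int128)a;
  __int128 cb = (__int128)base - (__int128)b;
  __int128 left = (__int128)a - cb;             // a + b - base
  uint64_t ua = (uint64_t)(ca < 0 ? -ca : ca), ub = (uint64_t)(cb < 0 ? -cb : cb);
  uint64_t cc = ut_mul_u(ua, ub, bits_needed(ua > ub ? ua : ub));
  __int128 right = ((ca < 0) != (cb < 0)) ? -(__int128)cc : (__int128)cc;
  uint64_t uleft = (uint64_t)(left < 0 ? -left : left);
  uint64_t lm = ut_mul_u(uleft, (uint64_t)m,
                         bits_needed(uleft > (uint64_t)m ? uleft : (uint64_t)m));
  __int128 scaled = (left < 0) ? -(__int128)lm : (__int128)lm;
  // multiply by B^k: bit shift in binary mode, repeated decimal shift otherwise
  __int128 shifted = scaled;
  if (B == 2) shifted = scaled << k;
  else for (int i = 0; i < k; ++i) shifted *= 10;
  __int128 prod = shifted + right;
  if (prod < 0) stop("nikhilam: internal negative product (invalid base)");
  return (uint64_t)prod;
}

// ---------------------------------------------------------------------------
// CUTIN hybrid multiplier.  N x N decomposes into four N/2 x N/2 sub-products
// combined crosswise; a sub-product is routed to the Nikhilam/Anurupyena path
// when both sub-operands sit within 2^(w-2) of the nearest binary working
// base, else it recurses on CUTIN (4-bit floor: direct UT column sums).
// Cross partial products are reduced carry-save and finalized by CSCGL.
// ---------------------------------------------------------------------------
static uint64_t cutin_mul_u(uint64_t a, uint64_t b, int w, int nas_shift) {
  if (w <= 4) return ut_mul_u(a, b, w);
  int h = w / 2;
  uint64_t al = a & mask_bits(h), ah = a >> h;
  uint64_t bl = b & mask_bits(h), bh = b >> h;
  uint64_t sub[4];
  const uint64_t xs[4] = { al, ah, al, ah };
  const uint64_t ys[4] = { bl, bl, bh, bh };
  uint64_t thr = 1ULL << (h - nas_shift > 0 ? h - nas_shift : 0);
  for (int i = 0; i < 4; ++i) {
    uint64_t x = xs[i], y = ys[i];
    uint64_t base; int m, k;
    anurupyena_u(x, y, 2, base, m, k);
    uint64_t dx = (base > x) ? base - x : x - base;
    uint64_t dy = (base > y) ? base - y : y - base;
    if (x > 0 && y > 0 && dx <= thr && dy <= thr)
      sub[i] = nikhilam_mul_u(x, y, base, m, k, 2);
    else
      sub[i] = cutin_mul_u(x, y, h, nas_shift);
  }
  // crosswise combination: pll + (plh + phl) << h + phh << 2h
  std::vector<uint64_t> rows;
  rows.push_back(sub[0]);
  rows.push_back(sub[1] << h);
  rows.push_back(sub[2] << h);
  rows.push_back(sub[3] << (2 * h));
  uint64_t s, c;
  csa_reduce_u(rows, s, c);
  return cscgl_add_u(s, c << 1, 0, 2 * w);
}

uint64_t vedic_cutin_mul(uint64_t a, uint64_t b, int w) {  // internal linkage hook
  return cutin_mul_u(a, b, w, 2);
}

// Staged 8x8 multiplier: four 4x4 UT blocks, zero pre-carry, carries obtained
// per phase via CSCGL and inserted into the next stage.
static uint64_t mul8x8_staged_u(uint64_t a, uint64_t b) {
  uint64_t al = a & 0xF, ah = a >> 4, bl = b & 0xF, bh = b >> 4;
  uint64_t pll = ut_mul_u(al, bl, 4);
  uint64_t plh = ut_mul_u(al, bh, 4);
  uint64_t phl = ut_mul_u(ah, bl, 4);
  uint64_t phh = ut_mul_u(ah, bh, 4);
  uint64_t low = pll & 0xF;
  uint64_t t1 = cscgl_add_u(plh, phl, 0, 8);          // stage 1, zero pre-carry
  uint64_t t2 = cscgl_add_u(t1, pll >> 4, 0, 9);      // stage 2, fold low carry
  uint64_t mid = t2 & 0xF;
  uint64_t t3 = cscgl_add_u(phh, t2 >> 4, 0, 8);      // stage 3, top block
  return low | (mid << 4) | (t3 << 8);
}

// ------------------------------ R interface --------------------------------

// [[Rcpp::export]]
String cpp_ut_mul(double a, double b, int width) {
  return to_hex(ut_mul_u(as_u64(a), as_u64(b), width), 2 * width);
}

// [[Rcpp::export]]
List cpp_ut_mul_trace(double a, double b, int width) {
  uint64_t ua = as_u64(a), ub = as_u64(b);
  IntegerVector cols(2 * width), sums(2 * width), carries(2 * width);
  uint64_t carry = 0;
  for (int k = 0; k < 2 * width; ++k) {
    uint64_t col = 0;
    int ilo = k - (width - 1); if (ilo < 0) ilo = 0;
    int ihi = (k < width - 1) ? k : (width - 1);
    for (int i = ilo; i <= ihi; ++i)
      col += ((ua >> i) & 1ULL) & ((ub >> (k - i)) & 1ULL);
    cols[k] = (int)col;
    col += carry;
    sums[k] = (int)(col & 1ULL);
    carry = col >> 1;
    carries[k] = (int)carry;
  }
  return List::create(_["column"] = cols, _["sum_bit"] = sums, _["carry_out"] = carries);
}

// [[Rcpp::export]]
List cpp_anurupyena_base(double a, double b, int B) {
  uint64_t base; int m, k;
  anurupyena_u(as_u64(a), as_u64(b), B, base, m, k);
  return List::create(_["base"] = (double)base, _["ratio"] = m, _["power"] = k,
                      _["theoretical_base"] = B);
}

// [[Rcpp::export]]
List cpp_nikhilam_mul(double a, double b, double base, int ratio, int power, int B) {
  uint64_t ua = as_u64(a), ub = as_u64(b), ubase = as_u64(base);
  uint64_t prod = nikhilam_mul_u(ua, ub, ubase, ratio, power, B);
  int64_t ca = (int64_t)ubase - (int64_t)ua;
  int64_t cb = (int64_t)ubase - (int64_t)ub;
  int w = bits_needed(ua > ub ? ua : ub);
  return List::create(_["hex"] = to_hex(prod, 2 * w),
                      _["value"] = (double)prod,
                      _["complement_a"] = (double)ca,
                      _["complement_b"] = (double)cb,
                      _["left_part"] = (double)((int64_t)ua - cb),
                      _["right_part"] = (double)(ca * cb));
}

// [[Rcpp::export]]
String cpp_cutin_mul(double a, double b, int width, int nas_shift) {
  return to_hex(cutin_mul_u(as_u64(a), as_u64(b), width, nas_shift), 2 * width);
}

// [[Rcpp::export]]
String cpp_mul8x8_staged(double a, double b) {
  return to_hex(mul8x8_staged_u(as_u64(a), as_u64(b)), 16);
}

// [[Rcpp::export]]
String cpp_cscgl_add(double a, double b, int cin, int width) {
  return to_hex(cscgl_add_u(as_u64(a), as_u64(b), cin, width), width + 1);
}

// [[Rcpp::export]]
List cpp_csa_reduce(NumericVector values, IntegerVector offsets, bool trace) {
  std::vector<uint64_t> rows;
  for (int i = 0; i < values.size(); ++i)
    rows.push_back(as_u64(values[i]) << offsets[i]);
  uint64_t s, c;
  std::vector< std::vector<uint64_t> > stages;
  csa_reduce_u(rows, s, c, trace ? &stages : nullptr);
  List out = List::create(_["sum"] = (double)s, _["carry"] = (double)c);
  if (trace) {
    List st(stages.size());
    for (size_t i = 0; i < stages.size(); ++i) {
      NumericVector v(stages[i].size());
      for (size_t j = 0; j < stages[i].size(); ++j) v[j] = (double)stages[i][j];
      st[i] = v;
    }
    out["stages"] = st;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Batch verification against the machine integer multiply/add oracle.
// algo: 0 = ut, 1 = nikhilam (auto binary base), 2 = cutin, 3 = staged 8x8
// n = 0 requests the exhaustive sweep (width 8 only).
// ---------------------------------------------------------------------------
static uint64_t run_algo(int algo, uint64_t a, uint64_t b, int width) {
  switch (algo) {
    case 0: return ut_mul_u(a, b, width);
    case 1: {
      uint64_t base; int m, k;
      anurupyena_u(a, b, 2, base, m, k);
      return nikhilam_mul_u(a, b, base, m, k, 2);
    }
    case 2: return cutin_mul_u(a, b, width, 2);
    case 3: return mul8x8_staged_u(a, b);
  }
  stop("unknown algorithm id");
}

// [[Rcpp::export]]
double cpp_verify_multiplier(int algo, int width, int n, int seed) {
  uint64_t mism = 0;
  if (n <= 0) {
    if (width != 8) stop("exhaustive sweep supported at width 8 only");
    for (uint64_t a = 0; a < 256; ++a)
      for (uint64_t b = 0; b < 256; ++b)
        if (run_algo(algo, a, b, 8) != a * b) ++mism;
  } else {
    // xorshift64 PRNG, fully determined by the seed
    uint64_t s = (uint64_t)seed * 2654435761ULL + 1442695040888963407ULL;
    uint64_t m = mask_bits(width);
    for (int i = 0; i < n; ++i) {
      s ^= s << 13; s ^= s >> 7; s ^= s << 17;
      uint64_t a = s & m;
      s ^= s << 13; s ^= s >> 7; s ^= s << 17;
      uint64_t b = s & m;
      if (run_algo(algo, a, b, width) != a * b) ++mism;
      if (run_algo(algo, a, b, width) != run_algo(algo, b, a, width)) ++mism;
    }
  }
  return (double)mism;
}

// [[Rcpp::export]]
double cpp_verify_cscgl_exhaustive(int width) {
  if (width > 12) stop("exhaustive adder sweep limited to width <= 12");
  uint64_t lim = 1ULL << width, mism = 0;
  for (uint64_t a = 0; a < lim; ++a)
    for (uint64_t b = 0; b < lim; ++b)
      for (int cin = 0; cin <= 1; ++cin)
        if (cscgl_add_u(a, b, cin, width) != a + b + (uint64_t)cin) ++mism;
  return (double)mism;
}

// [[Rcpp::export]]
double cpp_verify_csa_random(int n, int seed) {
  // n random grids; checks the sum-preservation invariant at every stage
  uint64_t s = (uint64_t)seed * 2654435761ULL + 88172645463325252ULL;
  uint64_t viol = 0;
  for (int g = 0; g < n; ++g) {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    int nrow = 1 + (int)(s % 8);
    std::vector<uint64_t> rows(nrow);
    uint64_t total = 0;
    for (int i = 0; i < nrow; ++i) {
      s ^= s << 13; s ^= s >> 7; s ^= s << 17;
      rows[i] = s & mask_bits(20);
      total += rows[i];
    }
    std::vector< std::vector<uint64_t> > stages;
    uint64_t sum, carry;
    csa_reduce_u(rows, sum, carry, &stages);
    for (size_t st = 0; st < stages.size(); ++st) {
      uint64_t t = 0;
      for (size_t j = 0; j < stages[st].size(); ++j) t += stages[st][j];
      if (t != total) ++viol;
    }
    if (sum + 2 * carry != total) ++viol;
  }
  return (double)viol;
}

// Plain-text test vectors `a_hex b_hex product_hex` for HDL cross-checks.
// [[Rcpp::export]]
CharacterVector cpp_test_vectors(int algo, int width, int n, int seed) {
  CharacterVector out(n);
  uint64_t s = (uint64_t)seed * 2654435761ULL + 1442695040888963407ULL;
  uint64_t m = mask_bits(width);
  for (int i = 0; i < n; ++i) {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    uint64_t a = s & m;
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    uint64_t b = s & m;
    uint64_t p = run_algo(algo, a, b, width);
    out[i] = to_hex(a, width) + " " + to_hex(b, width) + " " + to_hex(p, 2 * width);
  }
  return out;
}
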