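// Fan-Vercauteren somewhat-homomorphic scheme over Z_q[X]/(X^D + 1),
// q = 2^qbits (up to 2^192 here), t a small plaintext modulus.
//
// Coefficients are stored as little-endian 64-bit limbs holding the
// representative in [0, q); [.]_q centering is a bit mask because q is a
// power of two. Exact integer polynomial products (needed for the FV
// tensor-and-round multiplication) are computed by CRT over a fixed list of
// 59-bit NTT-friendly primes (p = 1 mod 8192, giving negacyclic transforms
// for every power-of-two D <= 4096) and reconstructed with Garner's
// algorithm into 512-bit integers. Ciphertexts remain elements of R_q x R_q;
// this is an internal multiplication technique, not an RNS scheme variant.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
#include <map>
#include <cmath>
#include <random>

using namespace Rcpp;

typedef uint64_t u64;
typedef int64_t i64;
typedef unsigned __int128 u128;

static const int NPRIMES = 8;          // 8 * 59 bits = 472-bit CRT range
static const u64 PRIMES[NPRIMES] = {
  576460752303415297ULL, 576460752303210497ULL, 576460752303185921ULL,
  576460752303136769ULL, 576460752303046657ULL, 576460752302596097ULL,
  576460752302579713ULL, 576460752302530561ULL};
static const u64 PROOTS[NPRIMES] = {5ULL, 3ULL, 6ULL, 3ULL, 5ULL, 3ULL, 5ULL, 13ULL};

static inline u64 addmod(u64 a, u64 b, u64 p) { u64 s = a + b; return s >= p ? s - p : s; }
static inline u64 submod(u64 a, u64 b, u64 p) { return a >= b ? a - b : a + p - b; }
static inline u64 mulmod(u64 a, u64 b, u64 p) { return (u64)((u128)a * b % p); }
static u64 powmod(u64 a, u64 e, u64 p) {
  u64 r = 1; a %= p;
  while (e) { if (e & 1) r = mulmod(r, a, p); a = mulmod(a, a, p); e >>= 1; }
  return r;
}
static u64 invmod(u64 a, u64 p) { return powmod(a, p - 2, p); }

// ---------------------------------------------------------------- 512-bit ints
// Two's-complement 512-bit integers, little-endian limbs.
struct I8 {
  u64 l[8];
  I8() { memset(l, 0, sizeof(l)); }
};
static inline void i8_add(I8 &a, const I8 &b) {
  u128 c = 0;
  for (int i = 0; i < 8; i++) { c += (u128)a.l[i] + b.l[i]; a.l[i] = (u64)c; c >>= 64; }
}
static inline void i8_sub(I8 &a, const I8 &b) {
  u128 borrow = 0;
  for (int i = 0; i < 8; i++) {
    u128 d = (u128)a.l[i] - b.l[i] - borrow;
    a.l[i] = (u64)d;
    borrow = (d >> 64) ? 1 : 0;
  }
}
static inline void i8_neg(I8 &a) {
  for (int i = 0; i < 8; i++) a.l[i] = ~a.l[i];
  for (int i = 0; i < 8; i++) { if (++a.l[i]) break; }
}
static inline bool i8_is_neg(const I8 &a) { return a.l[7] >> 63; }
// a += v * m for unsigned v, m (schoolbook, low 512 bits)
static inline void i8_addmul_u64(I8 &a, const I8 &m, u64 v) {
  u128 carry = 0;
  for (int i = 0; i < 8; i++) {
    u128 t = (u128)m.l[i] * v + a.l[i] + carry;
    a.l[i] = (u64)t;
    carry = t >> 64;
  }
}
// multiply in place by small unsigned scalar (mod 2^512, sign-safe)
static inline void i8_mul_u64(I8 &a, u64 v) {
  u128 carry = 0;
  for (int i = 0; i < 8; i++) {
    u128 t = (u128)a.l[i] * v + carry;
    a.l[i] = (u64)t;
    carry = t >> 64;
  }
}
// arithmetic shift right by k bits (0 < k < 512)
static inline void i8_sar(I8 &a, int k) {
  u64 fill = i8_is_neg(a) ? ~0ULL : 0ULL;
  int limb = k / 64, bit = k % 64;
  for (int i = 0; i < 8; i++) {
    u64 lo = (i + limb < 8) ? a.l[i + limb] : fill;
    u64 hi = (i + limb + 1 < 8) ? a.l[i + limb + 1] : fill;
    a.l[i] = bit ? ((lo >> bit) | (hi << (64 - bit))) : lo;
  }
}
static inline void i8_set_bit(I8 &a, int k) { a.l[k / 64] |= (1ULL << (k % 64)); }
static inline int i8_bitlen_abs(const I8 &a) {
  I8 t = a;
  if (i8_is_neg(t)) i8_neg(t);
  for (int i = 7; i >= 0; i--)
    if (t.l[i]) return i * 64 + 64 - __builtin_clzll(t.l[i]);
  return 0;
}
static inline double i8_log2_abs(const I8 &a) {
  I8 t = a;
  if (i8_is_neg(t)) i8_neg(t);
  int bl = i8_bitlen_abs(t);
  if (bl == 0) return -INFINITY;
  // top 64 bits as double for a fractional mantissa
  double top = 0;
  for (int i = 7; i >= 0; i--) top = top * 18446744073709551616.0 + (double)t.l[i];
  return std::log2(top);
}
// compare unsigned
static inline int i8_cmpu(const I8 &a, const I8 &b) {
  for (int i = 7; i >= 0; i--) {
    if (a.l[i] != b.l[i]) return a.l[i] < b.l[i] ? -1 : 1;
  }
  return 0;
}
static inline u64 i8_mod_u64(const I8 &a, u64 p) { // a interpreted unsigned
  u128 r = 0;
  for (int i = 7; i >= 0; i--) r = ((r << 64) | a.l[i]) % p;
  return (u64)r;
}

// --------------------------------------------------------------------- Garner
// pairwise inverses inv_pji[j][i] = p_j^{-1} mod p_i (j < i), prefix products
struct GarnerTab {
  u64 inv[NPRIMES][NPRIMES];
  I8 prefix[NPRIMES + 1]; // prefix[i] = prod_{j<i} p_j (unsigned)
  I8 ptot_half[NPRIMES + 1]; // prefix[i] / 2
};
static GarnerTab *g_garner = nullptr;
static void garner_init() {
  if (g_garner) return;
  g_garner = new GarnerTab();
  for (int i = 0; i < NPRIMES; i++)
    for (int j = 0; j < i; j++)
      g_garner->inv[j][i] = invmod(PRIMES[j] % PRIMES[i], PRIMES[i]);
  I8 acc; acc.l[0] = 1;
  g_garner->prefix[0] = acc;
  for (int i = 0; i < NPRIMES; i++) {
    i8_mul_u64(acc, PRIMES[i]);
    g_garner->prefix[i + 1] = acc;
    I8 h = acc; i8_sar(h, 1);
    g_garner->ptot_half[i + 1] = h;
  }
}
// reconstruct signed value from residues r[0..np) (centered range (-P/2, P/2])
static inline I8 garner_signed(const u64 *r, int np) {
  u64 v[NPRIMES];
  for (int i = 0; i < np; i++) {
    u64 t = r[i] % PRIMES[i];
    for (int j = 0; j < i; j++)
      t = mulmod(submod(t, v[j] % PRIMES[i], PRIMES[i]), g_garner->inv[j][i], PRIMES[i]);
    v[i] = t;
  }
  I8 x;
  for (int i = 0; i < np; i++) i8_addmul_u64(x, g_garner->prefix[i], v[i]);
  if (i8_cmpu(x, g_garner->ptot_half[np]) > 0) i8_sub(x, g_garner->prefix[np]);
  return x;
}

// ------------------------------------------------------------------ NTT plans
struct NttPlan {
  u64 p; int D;
  std::vector<u64> psi, ipsi;   // psi^i and psi^{-i} * Dinv baked separately
  std::vector<int> rev;
  std::vector<u64> wf, wi;      // stage twiddles, concatenated per stage
  u64 Dinv;
};
static std::map<std::pair<u64, int>, NttPlan> g_plans;

static NttPlan &get_plan(int pi, int D) {
  auto key = std::make_pair(PRIMES[pi], D);
  auto it = g_plans.find(key);
  if (it != g_plans.end()) return it->second;
  NttPlan pl;
  u64 p = PRIMES[pi];
  pl.p = p; pl.D = D;
  if ((8192 % (2 * D)) != 0) stop("ring degree not supported by NTT prime table");
  u64 psi = powmod(PROOTS[pi], (p - 1) / (u64)(2 * D), p); // order 2D
  u64 ipsi = invmod(psi, p);
  pl.psi.resize(D); pl.ipsi.resize(D);
  u64 a = 1, b = 1;
  for (int i = 0; i < D; i++) { pl.psi[i] = a; pl.ipsi[i] = b; a = mulmod(a, psi, p); b = mulmod(b, ipsi, p); }
  pl.Dinv = invmod((u64)D, p);
  pl.rev.resize(D);
  int lg = 0; while ((1 << lg) < D) lg++;
  for (int i = 0; i < D; i++) {
    int r = 0;
    for (int k = 0; k < lg; k++) if (i & (1 << k)) r |= 1 << (lg - 1 - k);
    pl.rev[i] = r;
  }
  u64 w = mulmod(psi, psi, p);      // order D
  u64 winv = invmod(w, p);
  pl.wf.resize(D); pl.wi.resize(D);
  int off = 0;
  for (int len = 2; len <= D; len <<= 1) {
    u64 wl = powmod(w, (u64)(D / len), p);
    u64 wli = powmod(winv, (u64)(D / len), p);
    u64 x = 1, y = 1;
    for (int j = 0; j < len / 2; j++) {
      pl.wf[off + j] = x; pl.wi[off + j] = y;
      x = mulmod(x, wl, p); y = mulmod(y, wli, p);
    }
    off += len / 2;
  }
  g_plans[key] = std::move(pl);
  return g_plans[key];
}

// in-place forward negacyclic NTT: input natural-order coeff residues
static void ntt_fwd(u64 *v, const NttPlan &pl) {
  int D = pl.D; u64 p = pl.p;
  std::vector<u64> tmp(D);
  for (int i = 0; i < D; i++) tmp[pl.rev[i]] = mulmod(v[i], pl.psi[i], p);
  memcpy(v, tmp.data(), D * sizeof(u64));
  int off = 0;
  for (int len = 2; len <= D; len <<= 1) {
    int half = len / 2;
    for (int i = 0; i < D; i += len)
      for (int j = 0; j < half; j++) {
        u64 u = v[i + j], x = mulmod(v[i + j + half], pl.wf[off + j], p);
        v[i + j] = addmod(u, x, p);
        v[i + j + half] = submod(u, x, p);
      }
    off += half;
  }
}
static void ntt_inv(u64 *v, const NttPlan &pl) {
  int D = pl.D; u64 p = pl.p;
  std::vector<u64> tmp(D);
  for (int i = 0; i < D; i++) tmp[pl.rev[i]] = v[i];
  memcpy(v, tmp.data(), D * sizeof(u64));
  int off = 0;
  for (int len = 2; len <= D; len <<= 1) {
    int half = len / 2;
    for (int i = 0; i < D; i += len)
      for (int j = 0; j < half; j++) {
        u64 u = v[i + j], x = mulmod(v[i + j + half], pl.wi[off + j], p);
        v[i + j] = addmod(u, x, p);
        v[i + j + half] = submod(u, x, p);
      }
    off += half;
  }
  for (int i = 0; i < D; i++) v[i] = mulmod(mulmod(v[i], pl.ipsi[i], p), pl.Dinv, p);
}

// ------------------------------------------------------------------ FV params
struct Params {
  int D, qbits, nl;   // nl limbs per coefficient
  u64 t;
  double sigma;
  int wbits, ell;     // relinearisation decomposition base 2^wbits, ell digits
};
static int limbs_for(int qbits) { return (qbits + 63) / 64; }
static int np_for_bits(double bits) {
  int np = (int)std::ceil((bits + 2.0) / 58.0);
  if (np < 1) np = 1;
  if (np > NPRIMES) stop("coefficient bound exceeds CRT range");
  return np;
}
static int log2i(int D) { int l = 0; while ((1 << l) < D) l++; return l; }

// polynomial with coefficients in [0, q), nl limbs each, length D
typedef std::vector<u64> PolyQ; // size D * nl

// q mod p and q/2 detection helpers
static inline bool coeff_top_half(const u64 *c, int qbits, int nl) {
  // true iff value >= 2^(qbits-1)
  int bit = (qbits - 1) % 64, limb = (qbits - 1) / 64;
  (void)nl;
  return (c[limb] >> bit) & 1;
}
// centered residue of coefficient mod p
static inline u64 coeff_res_centered(const u64 *c, int nl, int qbits, u64 p, u64 q_mod_p) {
  u128 r = 0;
  for (int i = nl - 1; i >= 0; i--) r = ((r << 64) | c[i]) % p;
  u64 v = (u64)r;
  if (coeff_top_half(c, qbits, nl)) v = submod(v, q_mod_p, p);
  return v;
}
static inline void mask_q(u64 *c, int qbits, int nl) {
  int rem = qbits % 64;
  if (rem) c[nl - 1] &= (~0ULL) >> (64 - rem);
  // limbs beyond nl-1 do not exist
}
// write low qbits of two's-complement I8 into limbs (value mod q)
static inline void i8_to_coeff(const I8 &v, u64 *c, int qbits, int nl) {
  for (int i = 0; i < nl; i++) c[i] = v.l[i];
  mask_q(c, qbits, nl);
}

// residues (centered) of a PolyQ for primes [0, np), NTT-transformed
static void poly_residues_ntt(const PolyQ &a, int D, int qbits, int nl,
                              int np, std::vector<std::vector<u64>> &out) {
  out.assign(np, std::vector<u64>(D));
  for (int pi = 0; pi < np; pi++) {
    u64 p = PRIMES[pi];
    u64 qmp = powmod(2, (u64)qbits, p);
    for (int i = 0; i < D; i++)
      out[pi][i] = coeff_res_centered(&a[(size_t)i * nl], nl, qbits, p, qmp);
    ntt_fwd(out[pi].data(), get_plan(pi, D));
  }
}

// ------------------------------------------------------------------ keys
struct Keys {
  Params par;
  bool has_sk;
  PolyQ s, pkb, pka;
  std::vector<PolyQ> rlkb, rlka;
  // cached NTT forms
  int np_enc, np_dec, np_rel;
  std::vector<std::vector<u64>> pkb_ntt, pka_ntt, s_ntt;
  std::vector<std::vector<std::vector<u64>>> rlkb_ntt, rlka_ntt; // [digit][prime]
};

static void build_caches(Keys &K) {
  const Params &P = K.par;
  int lD = log2i(P.D);
  double lt = std::log2((double)P.t);
  K.np_enc = np_for_bits(lD + P.qbits);                 // (q/2) * ternary products
  K.np_dec = np_for_bits(lD + P.qbits);
  K.np_rel = np_for_bits(lD + P.wbits + P.qbits + std::log2((double)std::max(1, P.ell)));
  (void)lt;
  poly_residues_ntt(K.pkb, P.D, P.qbits, P.nl, K.np_enc, K.pkb_ntt);
  poly_residues_ntt(K.pka, P.D, P.qbits, P.nl, K.np_enc, K.pka_ntt);
  if (K.has_sk) poly_residues_ntt(K.s, P.D, P.qbits, P.nl, K.np_dec, K.s_ntt);
  K.rlkb_ntt.resize(P.ell); K.rlka_ntt.resize(P.ell);
  for (int j = 0; j < P.ell; j++) {
    poly_residues_ntt(K.rlkb[j], P.D, P.qbits, P.nl, K.np_rel, K.rlkb_ntt[j]);
    poly_residues_ntt(K.rlka[j], P.D, P.qbits, P.nl, K.np_rel, K.rlka_ntt[j]);
  }
}

// ------------------------------------------------------------------ sampling
struct Rng {
  std::mt19937_64 g;
  explicit Rng(double seed) : g((u64)seed) {}
  u64 u() { return g(); }
  double unif01() { return ((g() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
  // rounded continuous Gaussian, truncated at 6 sigma
  i64 gauss(double sigma) {
    while (true) {
      double z = std::sqrt(-2.0 * std::log(unif01())) *
                 std::cos(2.0 * M_PI * unif01()) * sigma;
      if (std::fabs(z) <= 6.0 * sigma) return (i64)std::llround(z);
    }
  }
};

static void set_coeff_signed(PolyQ &a, int idx, i64 v, int qbits, int nl) {
  u64 *c = &a[(size_t)idx * nl];
  if (v >= 0) {
    c[0] = (u64)v;
    for (int i = 1; i < nl; i++) c[i] = 0;
  } else {
    c[0] = (u64)v; // sign-extended two's complement
    for (int i = 1; i < nl; i++) c[i] = ~0ULL;
  }
  mask_q(c, qbits, nl);
}
static PolyQ sample_ternary(Rng &rng, const Params &P) {
  PolyQ a((size_t)P.D * P.nl, 0);
  for (int i = 0; i < P.D; i++) {
    u64 r = rng.u() % 3;
    set_coeff_signed(a, i, (i64)r - 1, P.qbits, P.nl);
  }
  return a;
}
static PolyQ sample_gauss(Rng &rng, const Params &P) {
  PolyQ a((size_t)P.D * P.nl, 0);
  for (int i = 0; i < P.D; i++)
    set_coeff_signed(a, i, rng.gauss(P.sigma), P.qbits, P.nl);
  return a;
}
static PolyQ sample_uniform_q(Rng &rng, const Params &P) {
  PolyQ a((size_t)P.D * P.nl, 0);
  for (int i = 0; i < P.D; i++) {
    u64 *c = &a[(size_t)i * P.nl];
    for (int k = 0; k < P.nl; k++) c[k] = rng.u();
    mask_q(c, P.qbits, P.nl);
  }
  return a;
}

// ------------------------------------------------------------ poly arithmetic
static void poly_add_inplace(PolyQ &a, const PolyQ &b, const Params &P) {
  for (int i = 0; i < P.D; i++) {
    u64 *x = &a[(size_t)i * P.nl];
    const u64 *y = &b[(size_t)i * P.nl];
    u128 carry = 0;
    for (int k = 0; k < P.nl; k++) {
      carry += (u128)x[k] + y[k];
      x[k] = (u64)carry;
      carry >>= 64;
    }
    mask_q(x, P.qbits, P.nl);
  }
}
static void poly_neg_inplace(PolyQ &a, const Params &P) {
  for (int i = 0; i < P.D; i++) {
    u64 *x = &a[(size_t)i * P.nl];
    u128 borrow = 0;
    u64 tmp[4];
    for (int k = 0; k < P.nl; k++) { tmp[k] = ~x[k]; }
    // add 1
    u128 c = 1;
    for (int k = 0; k < P.nl; k++) { c += tmp[k]; x[k] = (u64)c; c >>= 64; }
    (void)borrow;
    mask_q(x, P.qbits, P.nl);
  }
}

// exact product of two mod-q polys (centered interpretation), reduced mod q
static PolyQ poly_mul_modq(const PolyQ &a, const PolyQ &b, const Params &P,
                           double bits_a, double bits_b) {
  garner_init();
  int np = np_for_bits(log2i(P.D) + bits_a + bits_b);
  std::vector<std::vector<u64>> ra, rb;
  poly_residues_ntt(a, P.D, P.qbits, P.nl, np, ra);
  poly_residues_ntt(b, P.D, P.qbits, P.nl, np, rb);
  std::vector<std::vector<u64>> rc(np, std::vector<u64>(P.D));
  for (int pi = 0; pi < np; pi++) {
    u64 p = PRIMES[pi];
    for (int i = 0; i < P.D; i++) rc[pi][i] = mulmod(ra[pi][i], rb[pi][i], p);
    ntt_inv(rc[pi].data(), get_plan(pi, P.D));
  }
  PolyQ out((size_t)P.D * P.nl, 0);
  u64 res[NPRIMES];
  for (int i = 0; i < P.D; i++) {
    for (int pi = 0; pi < np; pi++) res[pi] = rc[pi][i];
    I8 v = garner_signed(res, np);
    i8_to_coeff(v, &out[(size_t)i * P.nl], P.qbits, P.nl);
  }
  return out;
}

// Delta = floor(q / t) as I8 (q = 2^qbits)
static I8 delta_of(const Params &P) {
  u64 r = powmod(2 % P.t, (u64)P.qbits, P.t); // q mod t
  I8 q; i8_set_bit(q, P.qbits);
  I8 rr; rr.l[0] = r;
  i8_sub(q, rr); // q - (q mod t), divisible by t
  // divide by t (long division, unsigned)
  I8 out;
  u128 rem = 0;
  for (int i = 7; i >= 0; i--) {
    u128 cur = (rem << 64) | q.l[i];
    out.l[i] = (u64)(cur / P.t);
    rem = cur % P.t;
  }
  return out;
}

// Delta * m for centered small m, into PolyQ
static PolyQ delta_times_m(const IntegerVector &m, const Params &P) {
  I8 Delta = delta_of(P);
  PolyQ out((size_t)P.D * P.nl, 0);
  if (m.size() != P.D) stop("plaintext must have length D");
  for (int i = 0; i < P.D; i++) {
    int v = m[i];
    if (v == NA_INTEGER) stop("NA in plaintext");
    I8 x = Delta;
    i8_mul_u64(x, (u64)std::llabs((long long)v));
    if (v < 0) i8_neg(x);
    i8_to_coeff(x, &out[(size_t)i * P.nl], P.qbits, P.nl);
  }
  return out;
}

// ------------------------------------------------------------ raw conversion
static RawVector ct_to_raw(const PolyQ &c0, const PolyQ &c1, const Params &P) {
  size_t n = (size_t)P.D * P.nl * 8;
  RawVector out(2 * n);
  memcpy(RAW(out), c0.data(), n);
  memcpy(RAW(out) + n, c1.data(), n);
  return out;
}
static void raw_to_ct(const RawVector &r, PolyQ &c0, PolyQ &c1, const Params &P) {
  size_t n = (size_t)P.D * P.nl * 8;
  if ((size_t)r.size() != 2 * n) stop("ciphertext buffer has wrong size");
  c0.assign((size_t)P.D * P.nl, 0);
  c1.assign((size_t)P.D * P.nl, 0);
  memcpy(c0.data(), RAW(r), n);
  memcpy(c1.data(), RAW(r) + n, n);
}
static Params params_from_list(const List &par) {
  Params P;
  P.D = as<int>(par["D"]);
  P.qbits = as<int>(par["qbits"]);
  P.t = (u64)as<double>(par["t"]);
  P.sigma = as<double>(par["sigma"]);
  P.wbits = as<int>(par["relin_base_bits"]);
  P.nl = limbs_for(P.qbits);
  P.ell = (P.qbits + P.wbits - 1) / P.wbits;
  if (P.D < 4 || (P.D & (P.D - 1))) stop("D must be a power of two >= 4");
  if (8192 % (2 * P.D)) stop("D must be <= 4096");
  if (P.qbits < 20 || P.qbits > 192) stop("qbits must lie in [20, 192]");
  if (P.t < 2) stop("t must be >= 2");
  return P;
}

// ------------------------------------------------------------------ keygen
// [[Rcpp::export(name = ".fv_keygen_cpp")]]
SEXP fv_keygen_cpp(List par, double seed) {
  garner_init();
  Keys *K = new Keys();
  K->par = params_from_list(par);
  const Params &P = K->par;
  Rng rng(seed);
  K->has_sk = true;
  K->s = sample_ternary(rng, P);
  K->pka = sample_uniform_q(rng, P);
  PolyQ e = sample_gauss(rng, P);
  // b = -(a*s + e)
  PolyQ as = poly_mul_modq(K->pka, K->s, P, P.qbits - 1, 1);
  poly_add_inplace(as, e, P);
  poly_neg_inplace(as, P);
  K->pkb = as;
  // relinearisation keys: b_j = -(a_j s + e_j) + 2^(j*wbits) * s^2
  PolyQ s2 = poly_mul_modq(K->s, K->s, P, 1, 1);
  K->rlkb.resize(P.ell); K->rlka.resize(P.ell);
  for (int j = 0; j < P.ell; j++) {
    K->rlka[j] = sample_uniform_q(rng, P);
    PolyQ ej = sample_gauss(rng, P);
    PolyQ bj = poly_mul_modq(K->rlka[j], K->s, P, P.qbits - 1, 1);
    poly_add_inplace(bj, ej, P);
    poly_neg_inplace(bj, P);
    // + 2^(j*wbits) * s^2: shift s2 coefficients left j*wbits mod q
    PolyQ sh((size_t)P.D * P.nl, 0);
    for (int i = 0; i < P.D; i++) {
      I8 v;
      const u64 *c = &s2[(size_t)i * P.nl];
      for (int k = 0; k < P.nl; k++) v.l[k] = c[k];
      // interpret as unsigned [0,q): shifting mod q is fine either way
      int sb = j * P.wbits;
      // shift left: do it limb-wise into I8 (sb < 192)
      I8 w;
      int limb = sb / 64, bit = sb % 64;
      for (int k = 0; k + limb < 8; k++) {
        u128 t = ((u128)v.l[k]) << bit;
        w.l[k + limb] |= (u64)t;
        if (k + limb + 1 < 8) w.l[k + limb + 1] |= (u64)(t >> 64);
      }
      i8_to_coeff(w, &sh[(size_t)i * P.nl], P.qbits, P.nl);
    }
    poly_add_inplace(bj, sh, P);
    K->rlkb[j] = bj;
  }
  build_caches(*K);
  XPtr<Keys> ptr(K, true);
  return ptr;
}

// verification helper: [b + a*s]_q should be a small (error) polynomial
// [[Rcpp::export(name = ".fv_pk_noise_cpp")]]
double fv_pk_noise_cpp(SEXP keys) {
  XPtr<Keys> K(keys);
  const Params &P = K->par;
  PolyQ as = poly_mul_modq(K->pka, K->s, P, P.qbits - 1, 1);
  poly_add_inplace(as, K->pkb, P);
  // infinity norm of centered representatives
  double mx = 0;
  for (int i = 0; i < P.D; i++) {
    const u64 *c = &as[(size_t)i * P.nl];
    I8 v;
    for (int k = 0; k < P.nl; k++) v.l[k] = c[k];
    if (coeff_top_half(c, P.qbits, P.nl)) { // subtract q
      I8 q; i8_set_bit(q, P.qbits);
      i8_sub(v, q);
    }
    double b = i8_log2_abs(v);
    double mag = std::isfinite(b) ? std::pow(2.0, b) : 0.0;
    if (mag > mx) mx = mag;
  }
  return mx;
}

// [[Rcpp::export(name = ".fv_params_of_cpp")]]
List fv_params_of_cpp(SEXP keys) {
  XPtr<Keys> K(keys);
  const Params &P = K->par;
  return List::create(_["D"] = P.D, _["qbits"] = P.qbits, _["t"] = (double)P.t,
                      _["sigma"] = P.sigma, _["relin_base_bits"] = P.wbits,
                      _["ell"] = P.ell, _["has_sk"] = K->has_sk);
}

// ------------------------------------------------------------------ encrypt
// [[Rcpp::export(name = ".fv_encrypt_cpp")]]
RawVector fv_encrypt_cpp(SEXP keys, IntegerVector m, double seed) {
  XPtr<Keys> K(keys);
  const Params &P = K->par;
  Rng rng(seed);
  PolyQ u = sample_ternary(rng, P);
  PolyQ e1 = sample_gauss(rng, P);
  PolyQ e2 = sample_gauss(rng, P);
  // NTT of u on the enc prime set, multiply against cached pk transforms
  int np = K->np_enc;
  std::vector<std::vector<u64>> ru;
  poly_residues_ntt(u, P.D, P.qbits, P.nl, np, ru);
  PolyQ c0 = delta_times_m(m, P);
  PolyQ c1((size_t)P.D * P.nl, 0);
  u64 res[NPRIMES];
  std::vector<std::vector<u64>> t0(np, std::vector<u64>(P.D)), t1(np, std::vector<u64>(P.D));
  for (int pi = 0; pi < np; pi++) {
    u64 p = PRIMES[pi];
    for (int i = 0; i < P.D; i++) {
      t0[pi][i] = mulmod(ru[pi][i], K->pkb_ntt[pi][i], p);
      t1[pi][i] = mulmod(ru[pi][i], K->pka_ntt[pi][i], p);
    }
    ntt_inv(t0[pi].data(), get_plan(pi, P.D));
    ntt_inv(t1[pi].data(), get_plan(pi, P.D));
  }
  PolyQ bu((size_t)P.D * P.nl, 0), au((size_t)P.D * P.nl, 0);
  for (int i = 0; i < P.D; i++) {
    for (int pi = 0; pi < np; pi++) res[pi] = t0[pi][i];
    i8_to_coeff(garner_signed(res, np), &bu[(size_t)i * P.nl], P.qbits, P.nl);
    for (int pi = 0; pi < np; pi++) res[pi] = t1[pi][i];
    i8_to_coeff(garner_signed(res, np), &au[(size_t)i * P.nl], P.qbits, P.nl);
  }
  poly_add_inplace(c0, bu, P);
  poly_add_inplace(c0, e1, P);
  poly_add_inplace(c1, au, P);
  poly_add_inplace(c1, e2, P);
  return ct_to_raw(c0, c1, P);
}

// trivial (noiseless) lift of a plaintext to a ciphertext: (Delta*m, 0)
// [[Rcpp::export(name = ".fv_lift_cpp")]]
RawVector fv_lift_cpp(List par, IntegerVector m) {
  garner_init();
  Params P = params_from_list(par);
  PolyQ c0 = delta_times_m(m, P);
  PolyQ c1((size_t)P.D * P.nl, 0);
  return ct_to_raw(c0, c1, P);
}

// m~ = [c0 + c1 s]_q as centered I8 per coefficient
static std::vector<I8> phase_of(const Keys &K, const PolyQ &c0, const PolyQ &c1) {
  const Params &P = K.par;
  int np = K.np_dec;
  std::vector<std::vector<u64>> rc;
  poly_residues_ntt(c1, P.D, P.qbits, P.nl, np, rc);
  for (int pi = 0; pi < np; pi++) {
    u64 p = PRIMES[pi];
    for (int i = 0; i < P.D; i++) rc[pi][i] = mulmod(rc[pi][i], K.s_ntt[pi][i], p);
    ntt_inv(rc[pi].data(), get_plan(pi, P.D));
  }
  PolyQ c1s((size_t)P.D * P.nl, 0);
  u64 res[NPRIMES];
  for (int i = 0; i < P.D; i++) {
    for (int pi = 0; pi < np; pi++) res[pi] = rc[pi][i];
    i8_to_coeff(garner_signed(res, np), &c1s[(size_t)i * P.nl], P.qbits, P.nl);
  }
  poly_add_inplace(c1s, c0, P);
  std::vector<I8> out(P.D);
  I8 q; i8_set_bit(q, P.qbits);
  for (int i = 0; i < P.D; i++) {
    I8 v;
    const u64 *c = &c1s[(size_t)i * P.nl];
    for (int k = 0; k < P.nl; k++) v.l[k] = c[k];
    if (coeff_top_half(c, P.qbits, P.nl)) i8_sub(v, q);
    out[i] = v;
  }
  return out;
}

static IntegerVector decrypt_inner(const Keys &K, const PolyQ &c0, const PolyQ &c1) {
  const Params &P = K.par;
  std::vector<I8> ph = phase_of(K, c0, c1);
  IntegerVector m(P.D);
  for (int i = 0; i < P.D; i++) {
    I8 v = ph[i];
    i8_mul_u64(v, P.t);           // sign-safe mod 2^512
    I8 half; i8_set_bit(half, P.qbits - 1);
    i8_add(v, half);
    i8_sar(v, P.qbits);           // round(t * phase / q)
    i64 r = (i64)v.l[0];          // small now
    i64 t = (i64)P.t;
    r %= t; if (r < 0) r += t;
    if (r > t / 2) r -= t;
    m[i] = (int)r;
  }
  return m;
}

// [[Rcpp::export(name = ".fv_decrypt_cpp")]]
IntegerVector fv_decrypt_cpp(SEXP keys, RawVector ct) {
  XPtr<Keys> K(keys);
  if (!K->has_sk) stop("key material has no secret key");
  PolyQ c0, c1;
  raw_to_ct(ct, c0, c1, K->par);
  return decrypt_inner(*K, c0, c1);
}

// noise budget in bits: log2(Delta / (2 * ||e||_inf)), e = [c0+c1 s]_q - Delta*m
// [[Rcpp::export(name = ".fv_noise_budget_cpp")]]
double fv_noise_budget_cpp(SEXP keys, RawVector ct) {
  XPtr<Keys> K(keys);
  if (!K->has_sk) stop("key material has no secret key");
  const Params &P = K->par;
  PolyQ c0, c1;
  raw_to_ct(ct, c0, c1, P);
  std::vector<I8> ph = phase_of(*K, c0, c1);
  IntegerVector m = decrypt_inner(*K, c0, c1);
  I8 Delta = delta_of(P);
  double lmax = -INFINITY;
  I8 q; i8_set_bit(q, P.qbits);
  I8 qh; i8_set_bit(qh, P.qbits - 1);
  for (int i = 0; i < P.D; i++) {
    I8 dm = Delta;
    i8_mul_u64(dm, (u64)std::llabs((long long)m[i]));
    if (m[i] < 0) i8_neg(dm);
    I8 e = ph[i];
    i8_sub(e, dm);
    // recenter mod q: |ph| <= q/2 and |Delta*m| <= q/2, so one step suffices
    if (!i8_is_neg(e) && i8_cmpu(e, qh) > 0) {
      i8_sub(e, q);
    } else if (i8_is_neg(e)) {
      I8 t = e; i8_neg(t);
      if (i8_cmpu(t, qh) > 0) i8_add(e, q);
    }
    double b = i8_log2_abs(e);
    if (b > lmax) lmax = b;
  }
  double ld = i8_log2_abs(Delta);
  if (!std::isfinite(lmax)) return ld - 1.0; // exactly zero noise
  return ld - 1.0 - lmax;
}

// ------------------------------------------------------------------ add/neg
// [[Rcpp::export(name = ".fv_add_cpp")]]
RawVector fv_add_cpp(List par, RawVector a, RawVector b) {
  Params P = params_from_list(par);
  PolyQ a0, a1, b0, b1;
  raw_to_ct(a, a0, a1, P);
  raw_to_ct(b, b0, b1, P);
  poly_add_inplace(a0, b0, P);
  poly_add_inplace(a1, b1, P);
  return ct_to_raw(a0, a1, P);
}
// [[Rcpp::export(name = ".fv_neg_cpp")]]
RawVector fv_neg_cpp(List par, RawVector a) {
  Params P = params_from_list(par);
  PolyQ a0, a1;
  raw_to_ct(a, a0, a1, P);
  poly_neg_inplace(a0, P);
  poly_neg_inplace(a1, P);
  return ct_to_raw(a0, a1, P);
}

// ------------------------------------------------------------ multiplication
// plaintext multiplication: (c0*m, c1*m) reduced mod q
// [[Rcpp::export(name = ".fv_pt_mul_cpp")]]
RawVector fv_pt_mul_cpp(List par, RawVector a, IntegerVector m) {
  garner_init();
  Params P = params_from_list(par);
  if (m.size() != P.D) stop("plaintext must have length D");
  PolyQ a0, a1;
  raw_to_ct(a, a0, a1, P);
  PolyQ mp((size_t)P.D * P.nl, 0);
  double mmax = 1;
  for (int i = 0; i < P.D; i++) {
    set_coeff_signed(mp, i, m[i], P.qbits, P.nl);
    double am = std::fabs((double)m[i]);
    if (am > mmax) mmax = am;
  }
  double bm = std::log2(mmax) + 1;
  PolyQ r0 = poly_mul_modq(a0, mp, P, P.qbits - 1, bm);
  PolyQ r1 = poly_mul_modq(a1, mp, P, P.qbits - 1, bm);
  return ct_to_raw(r0, r1, P);
}

// full FV tensor multiplication with relinearisation
// [[Rcpp::export(name = ".fv_mul_cpp")]]
RawVector fv_mul_cpp(SEXP keys, RawVector a, RawVector b) {
  garner_init();
  XPtr<Keys> K(keys);
  const Params &P = K->par;
  PolyQ a0, a1, b0, b1;
  raw_to_ct(a, a0, a1, P);
  raw_to_ct(b, b0, b1, P);
  // exact tensor: d0 = a0 b0, d1 = a0 b1 + a1 b0, d2 = a1 b1 (scaled by t/q)
  int np = np_for_bits(log2i(P.D) + 2.0 * (P.qbits - 1) + std::log2((double)P.t) + 1);
  std::vector<std::vector<u64>> ra0, ra1, rb0, rb1;
  poly_residues_ntt(a0, P.D, P.qbits, P.nl, np, ra0);
  poly_residues_ntt(a1, P.D, P.qbits, P.nl, np, ra1);
  poly_residues_ntt(b0, P.D, P.qbits, P.nl, np, rb0);
  poly_residues_ntt(b1, P.D, P.qbits, P.nl, np, rb1);
  std::vector<std::vector<u64>> d0(np), d1(np), d2(np);
  for (int pi = 0; pi < np; pi++) {
    u64 p = PRIMES[pi];
    u64 tmodp = P.t % p;
    d0[pi].resize(P.D); d1[pi].resize(P.D); d2[pi].resize(P.D);
    for (int i = 0; i < P.D; i++) {
      u64 x00 = mulmod(ra0[pi][i], rb0[pi][i], p);
      u64 x01 = addmod(mulmod(ra0[pi][i], rb1[pi][i], p),
                       mulmod(ra1[pi][i], rb0[pi][i], p), p);
      u64 x11 = mulmod(ra1[pi][i], rb1[pi][i], p);
      d0[pi][i] = mulmod(x00, tmodp, p);   // scale by t before reconstruction
      d1[pi][i] = mulmod(x01, tmodp, p);
      d2[pi][i] = mulmod(x11, tmodp, p);
    }
    ntt_inv(d0[pi].data(), get_plan(pi, P.D));
    ntt_inv(d1[pi].data(), get_plan(pi, P.D));
    ntt_inv(d2[pi].data(), get_plan(pi, P.D));
  }
  PolyQ e0((size_t)P.D * P.nl, 0), e1((size_t)P.D * P.nl, 0), e2((size_t)P.D * P.nl, 0);
  u64 res[NPRIMES];
  I8 half; i8_set_bit(half, P.qbits - 1);
  for (int i = 0; i < P.D; i++) {
    std::vector<std::vector<u64>> *ds[3] = {&d0, &d1, &d2};
    PolyQ *es[3] = {&e0, &e1, &e2};
    for (int k = 0; k < 3; k++) {
      for (int pi = 0; pi < np; pi++) res[pi] = (*ds[k])[pi][i];
      I8 v = garner_signed(res, np);       // = t * conv (signed)
      i8_add(v, half);
      i8_sar(v, P.qbits);                  // round(t * conv / q)
      i8_to_coeff(v, &(*es[k])[(size_t)i * P.nl], P.qbits, P.nl);
    }
  }
  // relinearise e2: digits in base 2^wbits from the [0, q) representative
  int npr = K->np_rel;
  std::vector<std::vector<u64>> acc0(npr, std::vector<u64>(P.D, 0)),
                                acc1(npr, std::vector<u64>(P.D, 0));
  std::vector<u64> digits(P.D);
  for (int j = 0; j < P.ell; j++) {
    int sb = j * P.wbits;
    int limb = sb / 64, bit = sb % 64;
    u64 mask = (P.wbits == 64) ? ~0ULL : ((1ULL << P.wbits) - 1);
    for (int i = 0; i < P.D; i++) {
      const u64 *c = &e2[(size_t)i * P.nl];
      u64 lo = (limb < P.nl) ? c[limb] : 0;
      u64 hi = (limb + 1 < P.nl) ? c[limb + 1] : 0;
      u64 d = bit ? ((lo >> bit) | (hi << (64 - bit))) : lo;
      digits[i] = d & mask;
    }
    for (int pi = 0; pi < npr; pi++) {
      u64 p = PRIMES[pi];
      std::vector<u64> rd(P.D);
      for (int i = 0; i < P.D; i++) rd[i] = digits[i] % p;
      ntt_fwd(rd.data(), get_plan(pi, P.D));
      for (int i = 0; i < P.D; i++) {
        acc0[pi][i] = addmod(acc0[pi][i], mulmod(rd[i], K->rlkb_ntt[j][pi][i], p), p);
        acc1[pi][i] = addmod(acc1[pi][i], mulmod(rd[i], K->rlka_ntt[j][pi][i], p), p);
      }
    }
  }
  PolyQ r0((size_t)P.D * P.nl, 0), r1((size_t)P.D * P.nl, 0);
  for (int pi = 0; pi < npr; pi++) {
    ntt_inv(acc0[pi].data(), get_plan(pi, P.D));
    ntt_inv(acc1[pi].data(), get_plan(pi, P.D));
  }
  for (int i = 0; i < P.D; i++) {
    for (int pi = 0; pi < npr; pi++) res[pi] = acc0[pi][i];
    i8_to_coeff(garner_signed(res, npr), &r0[(size_t)i * P.nl], P.qbits, P.nl);
    for (int pi = 0; pi < npr; pi++) res[pi] = acc1[pi][i];
    i8_to_coeff(garner_signed(res, npr), &r1[(size_t)i * P.nl], P.qbits, P.nl);
  }
  poly_add_inplace(r0, e0, P);
  poly_add_inplace(r1, e1, P);
  return ct_to_raw(r0, r1, P);
}

// ---------------------------------------------------------- bit-packed serial
// payload: coefficients of c0 then c1, each packed at exactly qbits bits,
// little-endian bit order; total 2 * D * qbits bits
// [[Rcpp::export(name = ".fv_pack_cpp")]]
RawVector fv_pack_cpp(List par, RawVector ct) {
  Params P = params_from_list(par);
  PolyQ c0, c1;
  raw_to_ct(ct, c0, c1, P);
  size_t nbits = 2 * (size_t)P.D * P.qbits;
  RawVector out((nbits + 7) / 8);
  memset(RAW(out), 0, out.size());
  size_t pos = 0;
  const PolyQ *cs[2] = {&c0, &c1};
  for (int k = 0; k < 2; k++) {
    for (int i = 0; i < P.D; i++) {
      const u64 *c = &(*cs[k])[(size_t)i * P.nl];
      for (int b = 0; b < P.qbits; b++) {
        if ((c[b / 64] >> (b % 64)) & 1) RAW(out)[pos / 8] |= (1 << (pos % 8));
        pos++;
      }
    }
  }
  return out;
}
// [[Rcpp::export(name = ".fv_unpack_cpp")]]
RawVector fv_unpack_cpp(List par, RawVector payload) {
  Params P = params_from_list(par);
  size_t nbits = 2 * (size_t)P.D * P.qbits;
  if ((size_t)payload.size() != (nbits + 7) / 8)
    stop("packed ciphertext has wrong size (expected %d bytes, got %d)",
         (int)((nbits + 7) / 8), (int)payload.size());
  PolyQ c0((size_t)P.D * P.nl, 0), c1((size_t)P.D * P.nl, 0);
  size_t pos = 0;
  PolyQ *cs[2] = {&c0, &c1};
  for (int k = 0; k < 2; k++) {
    for (int i = 0; i < P.D; i++) {
      u64 *c = &(*cs[k])[(size_t)i * P.nl];
      for (int b = 0; b < P.qbits; b++) {
        if ((RAW(payload)[pos / 8] >> (pos % 8)) & 1) c[b / 64] |= (1ULL << (b % 64));
        pos++;
      }
    }
  }
  return ct_to_raw(c0, c1, P);
}

// ------------------------------------------------------------- key serialise
static void put_poly(std::vector<uint8_t> &buf, const PolyQ &p) {
  size_t n = p.size() * 8, at = buf.size();
  buf.resize(at + n);
  memcpy(buf.data() + at, p.data(), n);
}
// [[Rcpp::export(name = ".fv_keys_serialize_cpp")]]
RawVector fv_keys_serialize_cpp(SEXP keys, bool with_sk) {
  XPtr<Keys> K(keys);
  const Params &P = K->par;
  if (with_sk && !K->has_sk) stop("key material has no secret key");
  std::vector<uint8_t> buf;
  u64 hdr[8] = {0x5346484556464BULL /* "SFHEVFK" */, (u64)P.D, (u64)P.qbits,
                P.t, (u64)(P.sigma * 1048576.0), (u64)P.wbits, (u64)P.ell,
                (u64)(with_sk ? 1 : 0)};
  buf.resize(64);
  memcpy(buf.data(), hdr, 64);
  if (with_sk) put_poly(buf, K->s);
  put_poly(buf, K->pkb);
  put_poly(buf, K->pka);
  for (int j = 0; j < P.ell; j++) { put_poly(buf, K->rlkb[j]); put_poly(buf, K->rlka[j]); }
  RawVector out(buf.size());
  memcpy(RAW(out), buf.data(), buf.size());
  return out;
}
// [[Rcpp::export(name = ".fv_keys_deserialize_cpp")]]
SEXP fv_keys_deserialize_cpp(RawVector raw) {
  garner_init();
  if (raw.size() < 64) stop("truncated key file");
  u64 hdr[8];
  memcpy(hdr, RAW(raw), 64);
  if (hdr[0] != 0x5346484556464BULL) stop("not an sfhe key file");
  Keys *K = new Keys();
  K->par.D = (int)hdr[1]; K->par.qbits = (int)hdr[2]; K->par.t = hdr[3];
  K->par.sigma = (double)hdr[4] / 1048576.0;
  K->par.wbits = (int)hdr[5]; K->par.ell = (int)hdr[6];
  K->par.nl = limbs_for(K->par.qbits);
  K->has_sk = hdr[7] != 0;
  const Params &P = K->par;
  size_t npoly = (size_t)P.D * P.nl, nbytes = npoly * 8;
  size_t need = 64 + nbytes * ((K->has_sk ? 1 : 0) + 2 + 2 * (size_t)P.ell);
  if ((size_t)raw.size() != need) stop("key file has wrong size");
  size_t at = 64;
  auto get = [&](PolyQ &p) { p.assign(npoly, 0); memcpy(p.data(), RAW(raw) + at, nbytes); at += nbytes; };
  if (K->has_sk) get(K->s);
  get(K->pkb); get(K->pka);
  K->rlkb.resize(P.ell); K->rlka.resize(P.ell);
  for (int j = 0; j < P.ell; j++) { get(K->rlkb[j]); get(K->rlka[j]); }
  build_caches(*K);
  XPtr<Keys> ptr(K, true);
  return ptr;
}
// evaluation-only copy (drops the secret key)
// [[Rcpp::export(name = ".fv_strip_sk_cpp")]]
SEXP fv_strip_sk_cpp(SEXP keys) {
  XPtr<Keys> K(keys);
  Keys *E = new Keys(*K);
  E->has_sk = false;
  E->s.clear();
  E->s_ntt.clear();
  XPtr<Keys> ptr(E, true);
  return ptr;
}

// ----------------------------------------------------- small-modulus ring ops
// exact negacyclic product of two integer polynomials reduced centered mod t;
// used by the plaintext R_t circuit evaluator and as a fast path for tests
// [[Rcpp::export(name = ".ring_mul_cpp")]]
IntegerVector ring_mul_cpp(IntegerVector a, IntegerVector b, double t) {
  garner_init();
  int D = a.size();
  if (b.size() != D) stop("length mismatch");
  if (D < 1 || (D & (D - 1)) || D > 4096) stop("D must be a power of two <= 4096");
  double amax = 1, bmax = 1;
  for (int i = 0; i < D; i++) {
    amax = std::max(amax, std::fabs((double)a[i]));
    bmax = std::max(bmax, std::fabs((double)b[i]));
  }
  int np = np_for_bits(log2i(D) + std::log2(amax) + std::log2(bmax) + 2);
  std::vector<std::vector<u64>> ra(np, std::vector<u64>(D)), rb(np, std::vector<u64>(D));
  for (int pi = 0; pi < np; pi++) {
    u64 p = PRIMES[pi];
    for (int i = 0; i < D; i++) {
      i64 x = a[i]; ra[pi][i] = x >= 0 ? (u64)x % p : p - ((u64)(-x) % p);
      if (ra[pi][i] == p) ra[pi][i] = 0;
      i64 y = b[i]; rb[pi][i] = y >= 0 ? (u64)y % p : p - ((u64)(-y) % p);
      if (rb[pi][i] == p) rb[pi][i] = 0;
    }
    ntt_fwd(ra[pi].data(), get_plan(pi, D));
    ntt_fwd(rb[pi].data(), get_plan(pi, D));
    for (int i = 0; i < D; i++) ra[pi][i] = mulmod(ra[pi][i], rb[pi][i], p);
    ntt_inv(ra[pi].data(), get_plan(pi, D));
  }
  IntegerVector out(D);
  u64 res[NPRIMES];
  i64 tt = (i64)t;
  for (int i = 0; i < D; i++) {
    for (int pi = 0; pi < np; pi++) res[pi] = ra[pi][i];
    I8 v = garner_signed(res, np);
    // value fits comfortably in 128 bits here; fold to i64 via mod t
    bool neg = i8_is_neg(v);
    if (neg) i8_neg(v);
    u64 r = i8_mod_u64(v, (u64)tt);
    i64 c = (i64)r;
    if (neg) c = -c;
    c %= tt; if (c < 0) c += tt;
    if (c > tt / 2) c -= tt;
    out[i] = (int)c;
  }
  return out;
}
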