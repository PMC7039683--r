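// Gapped k-mer string kernel, SVM dual solver, and sequence scoring.
//
// The gkm kernel between two sequences is
//   K(A, B) = sum over l-mer pairs (u in A, v in B) of f(m(u, v))
// where m is the Hamming distance and f(m) = C(l - m, k) counts the gapped
// k-mers (k informative columns out of l) shared by two l-mers differing at
// m positions.  Two equivalent routes are implemented:
//
//  * a direct pairwise route (gkm_pair_kernel_cpp) using 2-bit packed l-mers,
//    XOR and popcount -- used for single pairs and as a cross-check;
//  * an explicit-feature route: for each of the C(l, k) position subsets,
//    count the 4^k gapped words per sequence and accumulate the Gram matrix
//    by BLAS rank-k updates (gkm_gram_cpp) -- used for training at scale.
//
// Counts are small integers, so the per-subset float GEMM is exact (all
// intermediate values < 2^24) and the double accumulator keeps the final
// Gram matrix integer-exact.
//
// Reverse-complement collapsing augments every sequence's l-mer multiset
// with the reverse complements, which makes scores strand-invariant.

#include <RcppArmadillo.h>
#include <cstdint>
#include <vector>
#include <string>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1; // N or anything else: l-mers containing it are skipped
  }
}

static inline uint32_t rc_code(uint32_t c, int l) {
  uint32_t r = 0;
  for (int i = 0; i < l; ++i) {
    r = (r << 2) | (3u - (c & 3u));
    c >>= 2;
  }
  return r;
}

// All valid (N-free) l-mer codes of a sequence; most-significant 2 bits =
// first base.  If add_rc, the reverse complement of each l-mer is appended.
static std::vector<uint32_t> lmer_codes(const std::string& s, int l, bool add_rc) {
  std::vector<uint32_t> out;
  const int n = (int)s.size();
  if (n < l) return out;
  out.reserve(add_rc ? 2 * (n - l + 1) : (n - l + 1));
  const uint32_t mask = (l == 16) ? 0xFFFFFFFFu : ((1u << (2 * l)) - 1u);
  uint32_t code = 0;
  int valid = 0; // number of consecutive valid bases ending here
  for (int i = 0; i < n; ++i) {
    int b = base_code(s[i]);
    if (b < 0) {
      valid = 0;
      code = 0;
      continue;
    }
    code = ((code << 2) | (uint32_t)b) & mask;
    if (++valid >= l) out.push_back(code);
  }
  if (add_rc) {
    const size_t m = out.size();
    for (size_t i = 0; i < m; ++i) out.push_back(rc_code(out[i], l));
  }
  return out;
}

// f(m) = C(l - m, k) for m <= l - k, else 0
static std::vector<double> mismatch_table(int l, int k) {
  std::vector<double> f(l + 1, 0.0);
  for (int m = 0; m <= l - k; ++m) f[m] = ::Rf_choose((double)(l - m), (double)k);
  return f;
}

// lexicographic position subsets of size k from {0, ..., l-1}
static std::vector<std::vector<int>> position_subsets(int l, int k) {
  std::vector<std::vector<int>> subs;
  std::vector<int> idx(k);
  for (int i = 0; i < k; ++i) idx[i] = i;
  while (true) {
    subs.push_back(idx);
    int i = k - 1;
    while (i >= 0 && idx[i] == l - k + i) --i;
    if (i < 0) break;
    ++idx[i];
    for (int j = i + 1; j < k; ++j) idx[j] = idx[j - 1] + 1;
  }
  return subs;
}

static inline uint32_t gapped_word(uint32_t code, const std::vector<int>& sub, int l) {
  uint32_t g = 0;
  for (size_t j = 0; j < sub.size(); ++j)
    g = (g << 2) | ((code >> (2 * (l - 1 - sub[j]))) & 3u);
  return g;
}

static inline int hamming_lmer(uint32_t a, uint32_t b, uint32_t oddmask) {
  uint32_t x = a ^ b;
  uint32_t y = (x | (x >> 1)) & oddmask;
  return __builtin_popcount(y);
}

// [[Rcpp::export]]
double gkm_pair_kernel_cpp(std::string a, std::string b, int l, int k, bool rc) {
  std::vector<uint32_t> ca = lmer_codes(a, l, rc);
  std::vector<uint32_t> cb = lmer_codes(b, l, rc);
  std::vector<double> f = mismatch_table(l, k);
  const uint32_t oddmask = [&]() {
    uint32_t m = 0;
    for (int i = 0; i < l; ++i) m |= (1u << (2 * i));
    return m;
  }();
  double s = 0.0;
  for (size_t i = 0; i < ca.size(); ++i)
    for (size_t j = 0; j < cb.size(); ++j)
      s += f[hamming_lmer(ca[i], cb[j], oddmask)];
  return s;
}

// [[Rcpp::export]]
NumericVector gkm_self_kernels_cpp(std::vector<std::string> seqs, int l, int k, bool rc) {
  const int n = (int)seqs.size();
  NumericVector out(n);
  std::vector<double> f = mismatch_table(l, k);
  uint32_t oddmask = 0;
  for (int i = 0; i < l; ++i) oddmask |= (1u << (2 * i));
  for (int s = 0; s < n; ++s) {
    std::vector<uint32_t> c = lmer_codes(seqs[s], l, rc);
    double acc = 0.0;
    for (size_t i = 0; i < c.size(); ++i)
      for (size_t j = 0; j < c.size(); ++j)
        acc += f[hamming_lmer(c[i], c[j], oddmask)];
    out[s] = acc;
  }
  return out;
}

extern "C" void ssyrk_(const char* uplo, const char* trans, const int* n,
                       const int* k, const float* alpha, const float* a,
                       const int* lda, const float* beta, float* c,
                       const int* ldc);

// Unnormalized Gram matrix over all sequence pairs, via the explicit
// gapped k-mer feature map (one BLAS float rank-k update per position
// subset; counts are small integers, so the float arithmetic is exact).
// [[Rcpp::export]]
arma::mat gkm_gram_cpp(std::vector<std::string> seqs, int l, int k, bool rc) {
  const int n = (int)seqs.size();
  std::vector<std::vector<uint32_t>> codes(n);
  for (int i = 0; i < n; ++i) codes[i] = lmer_codes(seqs[i], l, rc);
  std::vector<std::vector<int>> subs = position_subsets(l, k);
  const int d = 1 << (2 * k);
  arma::fmat Gf(n, n, arma::fill::zeros);
  arma::fmat X(n, d);
  const float one = 1.0f;
  for (size_t s = 0; s < subs.size(); ++s) {
    X.zeros();
    for (int i = 0; i < n; ++i)
      for (size_t t = 0; t < codes[i].size(); ++t)
        X(i, gapped_word(codes[i][t], subs[s], l)) += 1.0f;
    ssyrk_("U", "N", &n, &d, &one, X.memptr(), &n, &one, Gf.memptr(), &n);
    Rcpp::checkUserInterrupt();
  }
  arma::mat G(n, n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i <= j; ++i) {
      G(i, j) = (double)Gf(i, j);
      G(j, i) = G(i, j);
    }
  return G;
}

// Feature-space weight vector v (length C(l,k) * 4^k):
// v = sum_i beta_i * phi(seq_i), with phi the (rc-augmented) gapped k-mer
// count map.  beta already carries alpha_i * y_i / sqrt(K(sv_i, sv_i)).
// [[Rcpp::export]]
NumericVector gkm_weight_vector_cpp(std::vector<std::string> seqs, NumericVector beta,
                                    int l, int k, bool rc) {
  const int n = (int)seqs.size();
  std::vector<std::vector<int>> subs = position_subsets(l, k);
  const int d = 1 << (2 * k);
  NumericVector v((R_xlen_t)subs.size() * d);
  for (int i = 0; i < n; ++i) {
    if (beta[i] == 0.0) continue;
    std::vector<uint32_t> codes = lmer_codes(seqs[i], l, rc);
    for (size_t s = 0; s < subs.size(); ++s) {
      const size_t off = s * d;
      for (size_t t = 0; t < codes.size(); ++t)
        v[off + gapped_word(codes[t], subs[s], l)] += beta[i];
    }
  }
  return v;
}

// Unnormalized decision contribution of each sequence: <phi(seq), v>.
// [[Rcpp::export]]
NumericVector gkm_score_seqs_cpp(std::vector<std::string> seqs, NumericVector v,
                                 int l, int k, bool rc) {
  const int n = (int)seqs.size();
  std::vector<std::vector<int>> subs = position_subsets(l, k);
  const int d = 1 << (2 * k);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    std::vector<uint32_t> codes = lmer_codes(seqs[i], l, rc);
    double acc = 0.0;
    for (size_t s = 0; s < subs.size(); ++s) {
      const size_t off = s * d;
      for (size_t t = 0; t < codes.size(); ++t)
        acc += v[off + gapped_word(codes[t], subs[s], l)];
    }
    out[i] = acc;
  }
  return out;
}

// w(u) for every l-mer u (4^l values, indexed by 2-bit code).  With rc
// collapsing, w(u) = <phi(u) + phi(rc(u)), v>, so w(u) == w(rc(u)).
// [[Rcpp::export]]
NumericVector gkm_all_lmer_scores_cpp(NumericVector v, int l, int k, bool rc) {
  std::vector<std::vector<int>> subs = position_subsets(l, k);
  const int d = 1 << (2 * k);
  const size_t nl = (size_t)1 << (2 * l);
  std::vector<double> w0(nl, 0.0);
  for (size_t u = 0; u < nl; ++u) {
    double acc = 0.0;
    for (size_t s = 0; s < subs.size(); ++s)
      acc += v[s * d + gapped_word((uint32_t)u, subs[s], l)];
    w0[u] = acc;
  }
  NumericVector out(nl);
  for (size_t u = 0; u < nl; ++u)
    out[u] = rc ? w0[u] + w0[rc_code((uint32_t)u, l)] : w0[u];
  return out;
}

// [[Rcpp::export]]
CharacterVector decode_kmers_cpp(NumericVector codes, int l) {
  static const char bases[] = "ACGT";
  const int n = codes.size();
  CharacterVector out(n);
  std::string buf(l, 'A');
  for (int i = 0; i < n; ++i) {
    uint64_t c = (uint64_t)codes[i];
    for (int p = l - 1; p >= 0; --p) {
      buf[p] = bases[c & 3u];
      c >>= 2;
    }
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector encode_kmers_cpp(CharacterVector kmers, int l) {
  const int n = kmers.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(kmers[i]);
    if ((int)s.size() != l) stop("k-mer %d has length %d, expected %d", i + 1, (int)s.size(), l);
    uint64_t c = 0;
    for (int p = 0; p < l; ++p) {
      int b = base_code(s[p]);
      if (b < 0) stop("non-ACGT base in k-mer '%s'", s.c_str());
      c = (c << 2) | (uint64_t)b;
    }
    out[i] = (double)c;
  }
  return out;
}

// Soft-margin C-SVC dual solver (SMO with maximal-violating-pair working
// set, libsvm-style) on a precomputed kernel matrix.
// [[Rcpp::export]]
List smo_train_cpp(NumericMatrix K, IntegerVector y, double C, double tol, int max_iter) {
  const int n = K.nrow();
  std::vector<double> alpha(n, 0.0), grad(n, -1.0);
  int iter = 0;
  while (iter < max_iter) {
    // i: max  -y_t * grad_t over t allowed to increase alpha_t * y_t
    // j: min  -y_t * grad_t over t allowed to decrease
    int i = -1, j = -1;
    double gmax = -1e300, gmin = 1e300;
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * grad[t];
      bool up = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      bool dn = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      if (up && v > gmax) { gmax = v; i = t; }
      if (dn && v < gmin) { gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < tol) break;
    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta <= 0) eta = 1e-12;
    // minimize along the feasible pair direction, then clip (Platt-style)
    double ai = alpha[i], aj = alpha[j];
    double s = (double)(y[i] * y[j]);
    double gamma = ai + s * aj; // alpha_i + s * alpha_j is conserved
    double delta = (gmax - gmin) / eta; // step size along (y_i, -y_j) direction
    double nj = aj - y[j] * delta;
    double L, H;
    if (s > 0) { L = std::max(0.0, gamma - C); H = std::min(C, gamma); }
    else       { L = std::max(0.0, -gamma);    H = std::min(C, C - gamma); }
    if (nj > H) nj = H;
    if (nj < L) nj = L;
    double ni = gamma - s * nj;
    double dai = ni - ai, daj = nj - aj;
    if (std::abs(dai) < 1e-15 && std::abs(daj) < 1e-15) break;
    for (int t = 0; t < n; ++t)
      grad[t] += y[t] * (y[i] * K(t, i) * dai + y[j] * K(t, j) * daj);
    alpha[i] = ni;
    alpha[j] = nj;
    if (++iter % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  // bias from free support vectors; fall back to the violating-pair midpoint
  double bsum = 0.0;
  int bn = 0;
  double gmax = -1e300, gmin = 1e300;
  for (int t = 0; t < n; ++t) {
    double v = -y[t] * grad[t];
    bool up = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
    bool dn = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
    if (up && v > gmax) gmax = v;
    if (dn && v < gmin) gmin = v;
    if (alpha[t] > 1e-12 && alpha[t] < C - 1e-12) {
      bsum += v;
      ++bn;
    }
  }
  double b = bn > 0 ? bsum / bn : (gmax + gmin) / 2.0;
  return List::create(_["alpha"] = alpha, _["bias"] = b, _["iterations"] = iter,
                      _["converged"] = iter < max_iter);
}
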