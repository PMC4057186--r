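#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// State-space enumeration kernels for pairwise interaction models.
//
// A "component" is a set of m positions connected by active couplings; the
// 4^m states are enumerated with state s encoding digit i (letter at the
// i-th component position, 0..3) as (s >> 2i) & 3.  Energies are
//   E(s) = sum_i h(i, dig_i) + sum_k J_k(dig_{pi_k}, dig_{pj_k})
// and the model distribution is P(s) = exp(-E(s)) / Z.
//
// h:     m x 4 fields
// pairs: q x 2 zero-based component-position indices (i < j)
// J:     16 x q coupling blocks, column k stores J_k(a, b) at a + 4*b
// want:  w x 2 zero-based pairs for which joint marginals are requested

static const int MAX_ENUM = 14;   // 4^14 ~ 2.7e8 states, streamed
static const int MAX_STORE = 12;  // 4^12 doubles ~ 134 MB, materialized

static inline R_xlen_t pow4(int m) {
  R_xlen_t s = 1;
  for (int i = 0; i < m; ++i) s *= 4;
  return s;
}

// Safe shift so that exp(-E - shift) <= 1: shift = -(lower bound on E).
static double neg_energy_upper_bound(const std::vector<double>& hh, int m,
                                     const std::vector<double>& JJ, int q) {
  double b = 0.0;
  for (int i = 0; i < m; ++i) {
    double mx = -hh[i * 4];
    for (int a = 1; a < 4; ++a) mx = std::max(mx, -hh[i * 4 + a]);
    b += mx;
  }
  for (int k = 0; k < q; ++k) {
    double mx = -JJ[k * 16];
    for (int c = 1; c < 16; ++c) mx = std::max(mx, -JJ[k * 16 + c]);
    b += mx;
  }
  return b;
}

static void unpack(const NumericMatrix& h, const IntegerMatrix& pairs,
                   const NumericMatrix& J, std::vector<double>& hh,
                   std::vector<int>& pi, std::vector<int>& pj,
                   std::vector<double>& JJ) {
  const int m = h.nrow(), q = pairs.nrow();
  hh.resize(4 * m);
  for (int i = 0; i < m; ++i)
    for (int a = 0; a < 4; ++a) hh[i * 4 + a] = h(i, a);
  pi.resize(q); pj.resize(q); JJ.resize(16 * q);
  for (int k = 0; k < q; ++k) {
    pi[k] = pairs(k, 0);
    pj[k] = pairs(k, 1);
    for (int c = 0; c < 16; ++c) JJ[k * 16 + c] = J(c, k);
  }
}

// Single streamed sweep: accumulates Z (shifted), single marginals and the
// requested joint marginals. Returns shifted Z; marginals are normalized.
static double sweep(int m, const std::vector<double>& hh,
                    const std::vector<int>& pi, const std::vector<int>& pj,
                    const std::vector<double>& JJ, int q,
                    const std::vector<int>& wi, const std::vector<int>& wj,
                    int w, double shift, std::vector<double>& f1,
                    std::vector<double>& f2) {
  const R_xlen_t S = pow4(m);
  std::fill(f1.begin(), f1.end(), 0.0);
  std::fill(f2.begin(), f2.end(), 0.0);
  int dig[MAX_ENUM];
  double Z = 0.0;
  for (R_xlen_t s = 0; s < S; ++s) {
    R_xlen_t t = s;
    double e = 0.0;
    for (int i = 0; i < m; ++i) {
      dig[i] = (int)(t & 3);
      t >>= 2;
      e += hh[i * 4 + dig[i]];
    }
    for (int k = 0; k < q; ++k) e += JJ[k * 16 + dig[pi[k]] + 4 * dig[pj[k]]];
    const double p = std::exp(-e - shift);
    Z += p;
    for (int i = 0; i < m; ++i) f1[i * 4 + dig[i]] += p;
    for (int k = 0; k < w; ++k) f2[k * 16 + dig[wi[k]] + 4 * dig[wj[k]]] += p;
  }
  for (size_t i = 0; i < f1.size(); ++i) f1[i] /= Z;
  for (size_t i = 0; i < f2.size(); ++i) f2[i] /= Z;
  return Z;
}

// [[Rcpp::export]]
List cpp_enum_stats(NumericMatrix h, IntegerMatrix pairs, NumericMatrix J,
                    IntegerMatrix want) {
  const int m = h.nrow(), q = pairs.nrow(), w = want.nrow();
  if (m > MAX_ENUM) stop("component has %d positions; exact enumeration capped at %d", m, MAX_ENUM);
  std::vector<double> hh, JJ;
  std::vector<int> pi, pj;
  unpack(h, pairs, J, hh, pi, pj, JJ);
  std::vector<int> wi(w), wj(w);
  for (int k = 0; k < w; ++k) { wi[k] = want(k, 0); wj[k] = want(k, 1); }
  const double shift = neg_energy_upper_bound(hh, m, JJ, q);
  std::vector<double> f1(4 * m), f2(16 * w);
  const double Z = sweep(m, hh, pi, pj, JJ, q, wi, wj, w, shift, f1, f2);
  NumericMatrix f1m(m, 4);
  for (int i = 0; i < m; ++i)
    for (int a = 0; a < 4; ++a) f1m(i, a) = f1[i * 4 + a];
  NumericMatrix f2m(16, w);
  for (int k = 0; k < w; ++k)
    for (int c = 0; c < 16; ++c) f2m(c, k) = f2[k * 16 + c];
  return List::create(_["logZ"] = std::log(Z) + shift, _["f1"] = f1m,
                      _["f2"] = f2m);
}

// Marginal-matching gradient descent on one component:
//   h <- h - eta * gain * (f1_data - f1_model)
//   J <- J - eta * gain * (f2_data - f2_model)   (active pairs only)
// With adapt = true the per-parameter gain grows (x1.1) while the gradient
// sign persists and halves on a sign flip; adapt = false is the plain
// fixed-step schedule. Convergence: max |f_data - f_model| <= tol.
// [[Rcpp::export]]
List cpp_fit_component(NumericMatrix h0, IntegerMatrix pairs, NumericMatrix J0,
                       NumericMatrix f1d, NumericMatrix f2d, double eta,
                       double tol, int max_iter, bool adapt) {
  const int m = h0.nrow(), q = pairs.nrow();
  if (m > MAX_ENUM) stop("component has %d positions; exact enumeration capped at %d", m, MAX_ENUM);
  std::vector<double> hh, JJ;
  std::vector<int> pi, pj;
  unpack(h0, pairs, J0, hh, pi, pj, JJ);
  std::vector<double> d1(4 * m), d2(16 * q);
  for (int i = 0; i < m; ++i)
    for (int a = 0; a < 4; ++a) d1[i * 4 + a] = f1d(i, a);
  for (int k = 0; k < q; ++k)
    for (int c = 0; c < 16; ++c) d2[k * 16 + c] = f2d(c, k);

  std::vector<double> f1(4 * m), f2(16 * q);
  std::vector<double> gain1(4 * m, 1.0), gain2(16 * q, 1.0);
  std::vector<double> sgn1(4 * m, 0.0), sgn2(16 * q, 0.0);
  double res = R_PosInf;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    const double shift = neg_energy_upper_bound(hh, m, JJ, q);
    sweep(m, hh, pi, pj, JJ, q, pi, pj, q, shift, f1, f2);
    res = 0.0;
    for (int i = 0; i < 4 * m; ++i) res = std::max(res, std::fabs(d1[i] - f1[i]));
    for (int k = 0; k < 16 * q; ++k) res = std::max(res, std::fabs(d2[k] - f2[k]));
    if (res <= tol) break;
    for (int i = 0; i < 4 * m; ++i) {
      const double g = d1[i] - f1[i];
      if (adapt) {
        const double s = (g > 0) - (g < 0);
        gain1[i] = (s * sgn1[i] > 0) ? std::min(gain1[i] * 1.1, 1e4)
                                     : std::max(gain1[i] * 0.5, 1e-3);
        sgn1[i] = s;
      }
      hh[i] -= eta * gain1[i] * g;
    }
    for (int k = 0; k < 16 * q; ++k) {
      const double g = d2[k] - f2[k];
      if (adapt) {
        const double s = (g > 0) - (g < 0);
        gain2[k] = (s * sgn2[k] > 0) ? std::min(gain2[k] * 1.1, 1e4)
                                     : std::max(gain2[k] * 0.5, 1e-3);
        sgn2[k] = s;
      }
      JJ[k] -= eta * gain2[k] * g;
    }
  }
  NumericMatrix hout(m, 4);
  for (int i = 0; i < m; ++i)
    for (int a = 0; a < 4; ++a) hout(i, a) = hh[i * 4 + a];
  NumericMatrix Jout(16, q);
  for (int k = 0; k < q; ++k)
    for (int c = 0; c < 16; ++c) Jout(c, k) = JJ[k * 16 + c];
  return List::create(_["h"] = hout, _["J"] = Jout, _["iterations"] = it,
                      _["residual"] = res, _["converged"] = res <= tol);
}

// Energies of all 4^m states, in state-index order (materialized; m <= 12).
// [[Rcpp::export]]
NumericVector cpp_all_energies(NumericMatrix h, IntegerMatrix pairs,
                               NumericMatrix J) {
  const int m = h.nrow(), q = pairs.nrow();
  if (m > MAX_STORE) stop("cannot materialize 4^%d energies (max %d positions)", m, MAX_STORE);
  std::vector<double> hh, JJ;
  std::vector<int> pi, pj;
  unpack(h, pairs, J, hh, pi, pj, JJ);
  const R_xlen_t S = pow4(m);
  NumericVector out(S);
  int dig[MAX_STORE];
  for (R_xlen_t s = 0; s < S; ++s) {
    R_xlen_t t = s;
    double e = 0.0;
    for (int i = 0; i < m; ++i) {
      dig[i] = (int)(t & 3);
      t >>= 2;
      e += hh[i * 4 + dig[i]];
    }
    for (int k = 0; k < q; ++k) e += JJ[k * 16 + dig[pi[k]] + 4 * dig[pj[k]]];
    out[s] = e;
  }
  return out;
}
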