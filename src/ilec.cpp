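#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// One generation of the selfing-age-cohort (ILEC) recursion, operating on
// per-cohort genotype frequencies for the two locus types. Frequencies are
// stored as (p01, p11) per cohort; p00 is implicit. The final cohort class is
// absorbing. All arithmetic mirrors the R-level single-step operations
// (cohortMutation / cohortSelection / cohortReproduction) exactly.

namespace {

struct IlecState {
  std::vector<double> f, p01A, p11A, p01R, p11R;
};

inline void mutateType(std::vector<double>& p01, std::vector<double>& p11,
                       double mu) {
  if (mu <= 0.0) return;
  const double a = 1.0 - mu, b = mu;
  const double aa = a * a, bb = b * b, ab2 = 2.0 * a * b, ab = a * b;
  for (size_t i = 0; i < p01.size(); ++i) {
    double q01 = p01[i], q11 = p11[i], q00 = 1.0 - q01 - q11;
    p01[i] = q00 * ab2 + q01 * (aa + bb) + q11 * ab2;
    p11[i] = q00 * bb + q01 * ab + q11 * aa;
  }
}

// genotype weights (w00, w01, w11); returns per-cohort log-normalizer sum
inline void selectType(std::vector<double>& p01, std::vector<double>& p11,
                       double w00, double w01, double w11,
                       std::vector<double>& lognu) {
  for (size_t i = 0; i < p01.size(); ++i) {
    double q01 = p01[i], q11 = p11[i], q00 = 1.0 - q01 - q11;
    double nu = q00 * w00 + q01 * w01 + q11 * w11;
    p01[i] = q01 * w01 / nu;
    p11[i] = q11 * w11 / nu;
    lognu[i] = std::log(nu);
  }
}

inline void reproduceType(const std::vector<double>& g,
                          const std::vector<double>& p01,
                          const std::vector<double>& p11,
                          double rs, std::vector<double>& n01,
                          std::vector<double>& n11) {
  const size_t n = g.size();
  // pooled gamete frequency over fitness-weighted parents
  double q = 0.0;
  for (size_t i = 0; i < n; ++i) q += g[i] * (p11[i] + 0.5 * p01[i]);
  n01[0] = 2.0 * q * (1.0 - q);
  n11[0] = q * q;
  for (size_t i = 0; i + 1 < n; ++i) {  // Mendelian selfing: age i -> i+1
    n01[i + 1] = 0.5 * p01[i];
    n11[i + 1] = p11[i] + 0.25 * p01[i];
  }
  // pool the selfed offspring of the last two classes into the absorbing class
  if (n >= 2) {
    double wa = rs * g[n - 2], wb = rs * g[n - 1];
    double s01a = n01[n - 1], s11a = n11[n - 1];           // from cohort n-2
    double s01b = 0.5 * p01[n - 1], s11b = p11[n - 1] + 0.25 * p01[n - 1];
    if (wa + wb > 0.0) {
      n01[n - 1] = (wa * s01a + wb * s01b) / (wa + wb);
      n11[n - 1] = (wa * s11a + wb * s11b) / (wa + wb);
    } else {
      n01[n - 1] = s01b;
      n11[n - 1] = s11b;
    }
  }
}

inline double supDiff(const std::vector<double>& a,
                      const std::vector<double>& b) {
  double d = 0.0;
  for (size_t i = 0; i < a.size(); ++i)
    d = std::max(d, std::fabs(a[i] - b[i]));
  return d;
}

// Advance one full generation (mutation -> selection -> reproduction).
// Returns the sup-norm change between the old and new census state.
double ilecGeneration(IlecState& st, int LA, int LR, double muA, double muR,
                      double s, double h, double sTilde, bool island,
                      double rs) {
  const size_t n = st.f.size();
  IlecState nw = st;

  mutateType(nw.p01A, nw.p11A, muA);
  mutateType(nw.p01R, nw.p11R, muR);

  std::vector<double> lognuA(n, 0.0), lognuR(n, 0.0);
  // recessive "1" allele deleterious everywhere; additive "1" allele
  // disfavored in the source, favored on the island
  selectType(nw.p01R, nw.p11R, 1.0, std::exp(-h * s), std::exp(-s), lognuR);
  if (island)
    selectType(nw.p01A, nw.p11A, std::exp(-2.0 * sTilde), std::exp(-sTilde),
               1.0, lognuA);
  else
    selectType(nw.p01A, nw.p11A, 1.0, std::exp(-sTilde),
               std::exp(-2.0 * sTilde), lognuA);

  // parental weights g_i  (log-space to survive L ~ thousands)
  std::vector<double> logw(n), g(n);
  double mx = R_NegInf;
  for (size_t i = 0; i < n; ++i) {
    logw[i] = LA * lognuA[i] + LR * lognuR[i];
    if (nw.f[i] > 0.0) mx = std::max(mx, logw[i]);
  }
  double Z = 0.0;
  for (size_t i = 0; i < n; ++i) {
    g[i] = nw.f[i] * std::exp(logw[i] - mx);
    Z += g[i];
  }
  for (size_t i = 0; i < n; ++i) g[i] /= Z;

  IlecState out;
  out.f.assign(n, 0.0);
  out.p01A.assign(n, 0.0);
  out.p11A.assign(n, 0.0);
  out.p01R.assign(n, 0.0);
  out.p11R.assign(n, 0.0);

  out.f[0] = 1.0 - rs;
  for (size_t i = 0; i + 1 < n; ++i) out.f[i + 1] = rs * g[i];
  if (n >= 2) out.f[n - 1] += rs * g[n - 1];

  reproduceType(g, nw.p01A, nw.p11A, rs, out.p01A, out.p11A);
  reproduceType(g, nw.p01R, nw.p11R, rs, out.p01R, out.p11R);

  double d = supDiff(st.f, out.f);
  d = std::max(d, supDiff(st.p01A, out.p01A));
  d = std::max(d, supDiff(st.p11A, out.p11A));
  d = std::max(d, supDiff(st.p01R, out.p01R));
  d = std::max(d, supDiff(st.p11R, out.p11R));
  st = out;
  return d;
}

}  // namespace

// [[Rcpp::export]]
List cpp_ilec_solve(NumericVector f, NumericVector p01A, NumericVector p11A,
                    NumericVector p01R, NumericVector p11R, int LA, int LR,
                    double muA, double muR, double s, double h, double sTilde,
                    bool island, double rs, double tol, double maxIter) {
  IlecState st;
  st.f = as<std::vector<double>>(f);
  st.p01A = as<std::vector<double>>(p01A);
  st.p11A = as<std::vector<double>>(p11A);
  st.p01R = as<std::vector<double>>(p01R);
  st.p11R = as<std::vector<double>>(p11R);

  double d = R_PosInf;
  double iter = 0;
  while (iter < maxIter) {
    d = ilecGeneration(st, LA, LR, muA, muR, s, h, sTilde, island, rs);
    iter += 1;
    if (d < tol) break;
  }
  return List::create(
      _["f"] = wrap(st.f), _["p01A"] = wrap(st.p01A), _["p11A"] = wrap(st.p11A),
      _["p01R"] = wrap(st.p01R), _["p11R"] = wrap(st.p11R),
      _["iterations"] = iter, _["change"] = d, _["converged"] = (d < tol));
}
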