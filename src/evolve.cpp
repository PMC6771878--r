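#include <Rcpp.h>
#include <cmath>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Individual-based diploid simulator. Genotypes are stored as two haplotype
// matrices of 0/1 bytes with loci in rows (additive block first, then
// recessive block) and individuals in columns. All randomness goes through
// R's RNG so that set.seed() governs trajectories bit-for-bit.

namespace {

typedef std::vector<unsigned char> Hap;

inline uint32_t rand32() {
  return (uint32_t)(unif_rand() * 4294967296.0);
}

struct BitSource {
  uint32_t buf;
  int left;
  BitSource() : buf(0), left(0) {}
  inline int next() {
    if (left == 0) {
      buf = rand32();
      left = 32;
    }
    int b = buf & 1u;
    buf >>= 1;
    --left;
    return b;
  }
};

// flip each allele of a locus-type block independently with probability mu
void mutateBlock(Hap& h1, Hap& h2, int N, int L, int rowOff, int Lt,
                 double mu) {
  if (mu <= 0.0 || N == 0 || Lt == 0) return;
  const double M = 2.0 * N * Lt;
  int nflip = (int)R::rbinom(M, mu);
  if (nflip <= 0) return;
  std::unordered_set<long long> seen;
  int done = 0;
  while (done < nflip) {
    long long site = (long long)(unif_rand() * M);
    if (site >= (long long)M) continue;
    if (!seen.insert(site).second) continue;  // without replacement
    long long half = (long long)N * Lt;
    Hap& h = (site < half) ? h1 : h2;
    long long rem = site % half;
    int ind = (int)(rem / Lt);
    int loc = rowOff + (int)(rem % Lt);
    h[(size_t)ind * L + loc] ^= 1;
    ++done;
  }
}

// negative log fitness of one individual; island reverses the favored
// direction at additive loci
inline double loadOf(const unsigned char* g1, const unsigned char* g2, int LA,
                     int LR, double s, double h, double sTilde, bool island) {
  int add = 0, hom = 0, het = 0;
  for (int r = 0; r < LA; ++r) add += g1[r] + g2[r];
  for (int r = LA; r < LA + LR; ++r) {
    int a = g1[r] + g2[r];
    if (a == 2)
      ++hom;
    else if (a == 1)
      ++het;
  }
  double la = island ? sTilde * (2 * LA - add) : sTilde * add;
  return la + s * (hom + h * het);
}

void fitnessAll(const Hap& h1, const Hap& h2, int N, int L, int LA, int LR,
                double s, double h, double sTilde, bool island,
                std::vector<double>& w) {
  w.resize(N);
  for (int j = 0; j < N; ++j) {
    const unsigned char* g1 = &h1[(size_t)j * L];
    const unsigned char* g2 = &h2[(size_t)j * L];
    w[j] = std::exp(-loadOf(g1, g2, LA, LR, s, h, sTilde, island));
  }
}

inline int drawParent(const std::vector<double>& cumw, double total, int N) {
  double u = unif_rand() * total;
  int lo = 0, hi = N - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cumw[mid] < u)
      lo = mid + 1;
    else
      hi = mid;
  }
  return lo;
}

inline void makeGamete(const Hap& h1, const Hap& h2, int parent, int L,
                       unsigned char* dest, BitSource& bits) {
  const unsigned char* a = &h1[(size_t)parent * L];
  const unsigned char* b = &h2[(size_t)parent * L];
  for (int r = 0; r < L; ++r) dest[r] = bits.next() ? a[r] : b[r];
}

// one round of reproduction: produces Nout offspring from the current
// parents; returns realized selfing flags and selfing ages
void reproduce(const Hap& h1, const Hap& h2, const std::vector<double>& w,
               const std::vector<int>& age, int N, int L, double rs, int Nout,
               Hap& o1, Hap& o2, std::vector<int>& oage,
               std::vector<int>& oselfed) {
  std::vector<double> cumw(N);
  double total = 0.0;
  for (int j = 0; j < N; ++j) {
    total += w[j];
    cumw[j] = total;
  }
  o1.assign((size_t)Nout * L, 0);
  o2.assign((size_t)Nout * L, 0);
  oage.assign(Nout, 0);
  oselfed.assign(Nout, 0);
  BitSource bits;
  for (int j = 0; j < Nout; ++j) {
    bool selfed = unif_rand() < rs;
    int p1 = drawParent(cumw, total, N);
    int p2 = selfed ? p1 : drawParent(cumw, total, N);
    makeGamete(h1, h2, p1, L, &o1[(size_t)j * L], bits);
    makeGamete(h1, h2, p2, L, &o2[(size_t)j * L], bits);
    if (selfed) {
      oage[j] = (age.empty() ? 0 : age[p1]) + 1;
      oselfed[j] = 1;
    } else {
      oage[j] = 0;  // labelled outcrossed even if p2 happens to equal p1
      oselfed[j] = 0;
    }
  }
}

Hap rawToHap(const RawMatrix& m) {
  Hap h(m.size());
  for (R_xlen_t i = 0; i < m.size(); ++i) h[i] = m[i];
  return h;
}

RawMatrix hapToRaw(const Hap& h, int L, int N) {
  RawMatrix m(L, N);
  for (size_t i = 0; i < h.size(); ++i) m[i] = h[i];
  return m;
}

}  // namespace

// [[Rcpp::export]]
List cpp_evolve_source(RawMatrix hap1, RawMatrix hap2, IntegerVector age,
                       int LA, int LR, double muA, double muR, double s,
                       double h, double sTilde, bool island, double rs,
                       int nGen) {
  const int L = hap1.nrow(), N = hap1.ncol();
  Hap h1 = rawToHap(hap1), h2 = rawToHap(hap2);
  std::vector<int> ages = as<std::vector<int>>(age);
  std::vector<int> selfed(N, 0);
  std::vector<double> w;
  Hap o1, o2;
  std::vector<int> oage, oselfed;
  bool collapsed = false;

  for (int t = 0; t < nGen; ++t) {
    mutateBlock(h1, h2, N, L, 0, LA, muA);
    mutateBlock(h1, h2, N, L, LA, LR, muR);
    fitnessAll(h1, h2, N, L, LA, LR, s, h, sTilde, island, w);
    double total = 0.0;
    for (double x : w) total += x;
    if (total <= 0.0) {
      collapsed = true;
      break;
    }
    reproduce(h1, h2, w, ages, N, L, rs, N, o1, o2, oage, oselfed);
    h1.swap(o1);
    h2.swap(o2);
    ages.swap(oage);
    selfed.swap(oselfed);
  }

  return List::create(_["hap1"] = hapToRaw(h1, L, N),
                      _["hap2"] = hapToRaw(h2, L, N), _["age"] = wrap(ages),
                      _["selfed"] = wrap(selfed),
                      _["collapsed"] = collapsed);
}

// [[Rcpp::export]]
List cpp_establish(RawMatrix hap1, RawMatrix hap2, int LA, int LR, double muA,
                   double muR, double s, double h, double sTilde, bool island,
                   double rs, double r0, double K, int Tgen, double successN,
                   bool stopAtThreshold, int sfsGen, bool keepFinal) {
  const int L = hap1.nrow();
  int N = hap1.ncol();
  Hap h1 = rawToHap(hap1), h2 = rawToHap(hap2);
  std::vector<int> ages(N, 0), selfed(N, 0);
  std::vector<double> w;
  Hap o1, o2;
  std::vector<int> oage, oselfed;

  IntegerVector Ntraj(Tgen + 1, NA_INTEGER);
  NumericVector wbarTraj(Tgen + 1, NA_REAL);
  Ntraj[0] = N;
  NumericVector sfs(0);
  bool haveSfs = false;
  bool success = false;
  int extinctGen = NA_INTEGER;
  int tEnd = 0;

  for (int t = 1; t <= Tgen; ++t) {
    if (N == 0) break;
    mutateBlock(h1, h2, N, L, 0, LA, muA);
    mutateBlock(h1, h2, N, L, LA, LR, muR);
    fitnessAll(h1, h2, N, L, LA, LR, s, h, sTilde, island, w);
    double total = 0.0;
    for (double x : w) total += x;
    double wbar = total / N;
    wbarTraj[t - 1] = wbar;  // mean fitness of the generation-(t-1) parents
    int Nnext;
    if (total <= 0.0) {
      Nnext = 0;  // nobody can breed: extinction this generation
    } else {
      double dens = (K > 0) ? std::exp(r0 * (1.0 - (double)N / K))
                            : std::exp(r0);
      double mean = N * dens * wbar;
      Nnext = (int)R::rpois(mean);
    }
    if (Nnext == 0) {
      N = 0;
      Ntraj[t] = 0;
      extinctGen = t;
      tEnd = t;
      break;
    }
    reproduce(h1, h2, w, ages, N, L, rs, Nnext, o1, o2, oage, oselfed);
    h1.swap(o1);
    h2.swap(o2);
    ages.swap(oage);
    selfed.swap(oselfed);
    N = Nnext;
    Ntraj[t] = N;
    tEnd = t;
    if (sfsGen >= 0 && t == sfsGen && LA > 0) {
      sfs = NumericVector(LA);
      for (int j = 0; j < N; ++j)
        for (int r = 0; r < LA; ++r)
          sfs[r] += h1[(size_t)j * L + r] + h2[(size_t)j * L + r];
      for (int r = 0; r < LA; ++r) sfs[r] /= 2.0 * N;
      haveSfs = true;
    }
    if (stopAtThreshold && N >= successN) {
      success = true;
      break;
    }
  }
  if (!stopAtThreshold) success = (N > 0 && Ntraj[Tgen] != NA_INTEGER &&
                                   Ntraj[Tgen] >= successN);

  List out = List::create(
      _["success"] = success, _["N"] = Ntraj, _["wbar"] = wbarTraj,
      _["extinctGen"] = extinctGen, _["tEnd"] = tEnd,
      _["sfs"] = haveSfs ? sfs : NumericVector(0));
  if (keepFinal && N > 0) {
    out["hap1"] = hapToRaw(h1, L, N);
    out["hap2"] = hapToRaw(h2, L, N);
  }
  return out;
}
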