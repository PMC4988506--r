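// McCaskill-style partition function over RNA secondary structures with a
// simple per-pair energy model (no stacking): AU, GC and GU pairs with
// fixed energies and a minimum hairpin loop.  Inside quantities Z(i,j) and
// outside quantities Zhat(i,j) give exact base-pair and unpaired-stretch
// probabilities by the innermost-enclosing-pair decomposition.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// bases encoded 0=A, 1=C, 2=G, 3=U
static double pair_weight(int a, int b, double eAU, double eGC, double eGU,
                          double rt) {
  double e;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) e = eAU;
  else if ((a == 1 && b == 2) || (a == 2 && b == 1)) e = eGC;
  else if ((a == 2 && b == 3) || (a == 3 && b == 2)) e = eGU;
  else return 0.0;
  return std::exp(-e / rt);
}

struct PF {
  int n;
  std::vector<double> Z;     // (n+2) x (n+2); Z[i][j] = 1 for i > j
  std::vector<double> W;     // pair weights, 0 if unpairable
  std::vector<double> Zhat;  // outside values for pairable (i,j)
  double& z(int i, int j) { return Z[i * (n + 2) + j]; }
  double zv(int i, int j) const {
    return (i > j) ? 1.0 : Z[i * (n + 2) + j];
  }
  double& w(int i, int j) { return W[i * (n + 2) + j]; }
  double wv(int i, int j) const { return W[i * (n + 2) + j]; }
  double& zh(int i, int j) { return Zhat[i * (n + 2) + j]; }
  double zhv(int i, int j) const { return Zhat[i * (n + 2) + j]; }
};

static void compute_pf(const IntegerVector& s, double eAU, double eGC,
                       double eGU, double rt, int minloop, PF& pf) {
  int n = s.size();
  pf.n = n;
  pf.Z.assign((n + 2) * (n + 2), 0.0);
  pf.W.assign((n + 2) * (n + 2), 0.0);
  pf.Zhat.assign((n + 2) * (n + 2), 0.0);

  for (int i = 1; i <= n; ++i)
    for (int j = i + minloop + 1; j <= n; ++j)
      pf.w(i, j) = pair_weight(s[i - 1], s[j - 1], eAU, eGC, eGU, rt);

  // inside: Z(i,j) = Z(i,j-1) + sum_k Z(i,k-1) w(k,j) Z(k+1,j-1)
  for (int len = 1; len <= n; ++len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      double z = pf.zv(i, j - 1);
      for (int k = i; k <= j - minloop - 1; ++k) {
        double wkj = pf.wv(k, j);
        if (wkj > 0.0) z += pf.zv(i, k - 1) * wkj * pf.zv(k + 1, j - 1);
      }
      pf.z(i, j) = z;
    }
  }

  // outside, largest spans first:
  // Zhat(i,j) = Z(1,i-1) Z(j+1,n)
  //           + sum_{p<i, q>j} w(p,q) Zhat(p,q) Z(p+1,i-1) Z(j+1,q-1)
  for (int len = n; len >= minloop + 2; --len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      if (pf.wv(i, j) <= 0.0) continue;
      double acc = pf.zv(1, i - 1) * pf.zv(j + 1, n);
      for (int p = 1; p < i; ++p) {
        for (int q = j + 1; q <= n; ++q) {
          double wpq = pf.wv(p, q);
          if (wpq > 0.0) {
            acc += wpq * pf.zhv(p, q) * pf.zv(p + 1, i - 1) *
                   pf.zv(j + 1, q - 1);
          }
        }
      }
      pf.zh(i, j) = acc;
    }
  }
}

// probability that positions [a, b] (1-based, inclusive) are all unpaired
static double stretch_prob(const PF& pf, int a, int b) {
  int n = pf.n;
  double num = pf.zv(1, a - 1) * pf.zv(b + 1, n);
  for (int p = 1; p < a; ++p) {
    for (int q = b + 1; q <= n; ++q) {
      double wpq = pf.wv(p, q);
      if (wpq > 0.0) {
        num += wpq * pf.zhv(p, q) * pf.zv(p + 1, a - 1) * pf.zv(b + 1, q - 1);
      }
    }
  }
  return num / pf.zv(1, n);
}

// [[Rcpp::export]]
List pf_window(IntegerVector seq, int u, double eAU, double eGC, double eGU,
               double rt, int minloop) {
  int n = seq.size();
  if (n < 1) stop("empty sequence");
  PF pf;
  compute_pf(seq, eAU, eGC, eGU, rt, minloop, pf);

  NumericMatrix pair_prob(n, n);
  for (int i = 1; i <= n; ++i) {
    for (int j = i + minloop + 1; j <= n; ++j) {
      double wij = pf.wv(i, j);
      if (wij > 0.0) {
        double p = wij * pf.zv(i + 1, j - 1) * pf.zhv(i, j) / pf.zv(1, n);
        pair_prob(i - 1, j - 1) = p;
        pair_prob(j - 1, i - 1) = p;
      }
    }
  }
  int m = n - u + 1;
  NumericVector pu(m > 0 ? m : 0);
  for (int a = 1; a <= m; ++a) pu[a - 1] = stretch_prob(pf, a, a + u - 1);

  return List::create(_["Z"] = pf.zv(1, n), _["unpaired"] = pu,
                      _["pair_prob"] = pair_prob);
}

// mean unpaired-stretch probability per start, averaged over all sliding
// windows of width W that fully contain the stretch
// [[Rcpp::export]]
NumericVector pf_accessibility(IntegerVector seq, int W, int u, double eAU,
                               double eGC, double eGU, double rt,
                               int minloop) {
  int n = seq.size();
  if (u < 1 || n < u) stop("sequence shorter than the stretch length");
  int width = std::min(W, n);
  int nwin = n - width + 1;
  std::vector<double> acc(n - u + 1, 0.0);
  std::vector<int> cnt(n - u + 1, 0);
  PF pf;
  for (int w0 = 0; w0 < nwin; ++w0) {
    IntegerVector sub(seq.begin() + w0, seq.begin() + w0 + width);
    compute_pf(sub, eAU, eGC, eGU, rt, minloop, pf);
    for (int a = 1; a <= width - u + 1; ++a) {
      int ga = w0 + a - 1;  // 0-based global stretch start
      acc[ga] += stretch_prob(pf, a, a + u - 1);
      cnt[ga] += 1;
    }
  }
  NumericVector out(n - u + 1);
  for (int i = 0; i < (int)out.size(); ++i)
    out[i] = cnt[i] > 0 ? acc[i] / cnt[i] : NA_REAL;
  return out;
}
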