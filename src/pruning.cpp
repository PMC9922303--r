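#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// 4x4 transition matrix P(t) = U diag(exp(eigval * t)) Uinv for a
// reversible rate matrix decomposed in R. Column-major like R matrices.
static inline void ptrans4(const double* U, const double* Uinv,
                           const double* ev, double t, double* P) {
  double E[4];
  for (int k = 0; k < 4; ++k) E[k] = std::exp(ev[k] * t);
  for (int j = 0; j < 4; ++j) {
    for (int i = 0; i < 4; ++i) {
      double s = 0.0;
      for (int k = 0; k < 4; ++k)
        s += U[i + 4 * k] * E[k] * Uinv[k + 4 * j];
      // rounding can produce tiny negatives; probabilities must be >= 0
      P[i + 4 * j] = s > 0.0 ? s : 0.0;
    }
  }
}

// Felsenstein pruning with per-branch scaling, mixed over discrete-Gamma
// rate categories with equal weights. Edges must be in postorder
// (children before parents); node ids are 1-based ape conventions:
// tips 1..ntip, internals ntip+1..ntip+nint, root = parent of last edge.
//
// tippart: 4 x npat x ntip tip partial likelihoods (ambiguity-aware);
// wt: pattern weights. Returns the alignment log-likelihood.
// [[Rcpp::export]]
double cpp_alignment_loglik(IntegerVector parent, IntegerVector child,
                            NumericVector brlen, NumericVector scale,
                            NumericMatrix U, NumericMatrix Uinv,
                            NumericVector eigval, NumericVector basefreq,
                            NumericVector catrate, NumericVector tippart,
                            NumericVector wt, int npat, int ntip,
                            int nint) {
  const int nedge = parent.size();
  const int ncat = catrate.size();
  const double* Up = U.begin();
  const double* Uip = Uinv.begin();
  const double* evp = eigval.begin();
  const double* tp = tippart.begin();
  const int root = parent[nedge - 1];

  // per-internal-node partials (4 x npat), reused across categories
  std::vector<double> part((size_t)nint * 4 * npat);
  std::vector<double> logsc(npat);
  // per-pattern per-category site log-likelihoods
  std::vector<double> catll((size_t)npat * ncat);
  double P[16];

  for (int k = 0; k < ncat; ++k) {
    std::fill(part.begin(), part.end(), 1.0);
    std::fill(logsc.begin(), logsc.end(), 0.0);
    for (int e = 0; e < nedge; ++e) {
      const int ch = child[e];
      const int pa = parent[e];
      const double t = brlen[e] * scale[e] * catrate[k];
      ptrans4(Up, Uip, evp, t, P);
      const double* Lc;
      if (ch <= ntip) {
        Lc = tp + (size_t)4 * npat * (ch - 1);
      } else {
        Lc = part.data() + (size_t)4 * npat * (ch - ntip - 1);
      }
      double* Lp = part.data() + (size_t)4 * npat * (pa - ntip - 1);
      for (int s = 0; s < npat; ++s) {
        const double c0 = Lc[4 * s], c1 = Lc[4 * s + 1];
        const double c2 = Lc[4 * s + 2], c3 = Lc[4 * s + 3];
        double mx = 0.0;
        for (int i = 0; i < 4; ++i) {
          const double v = P[i] * c0 + P[i + 4] * c1 + P[i + 8] * c2 +
                           P[i + 12] * c3;
          const double w = Lp[4 * s + i] * v;
          Lp[4 * s + i] = w;
          if (w > mx) mx = w;
        }
        if (mx < 1e-200 && mx > 0.0) {  // rescale to avoid underflow
          const double f = 1.0 / mx;
          for (int i = 0; i < 4; ++i) Lp[4 * s + i] *= f;
          logsc[s] += std::log(mx);
        }
      }
    }
    const double* Lr = part.data() + (size_t)4 * npat * (root - ntip - 1);
    for (int s = 0; s < npat; ++s) {
      double lik = 0.0;
      for (int i = 0; i < 4; ++i) lik += basefreq[i] * Lr[4 * s + i];
      catll[(size_t)s * ncat + k] =
          (lik > 0.0 ? std::log(lik) : -1e308) + logsc[s];
    }
  }

  // mix categories with equal weights via log-sum-exp
  double total = 0.0;
  const double lw = -std::log((double)ncat);
  for (int s = 0; s < npat; ++s) {
    double mx = catll[(size_t)s * ncat];
    for (int k = 1; k < ncat; ++k)
      if (catll[(size_t)s * ncat + k] > mx) mx = catll[(size_t)s * ncat + k];
    double acc = 0.0;
    for (int k = 0; k < ncat; ++k)
      acc += std::exp(catll[(size_t)s * ncat + k] - mx);
    total += wt[s] * (mx + std::log(acc) + lw);
  }
  return total;
}
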