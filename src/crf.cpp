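// Linear-chain CRF internals: emission/transition scoring, forward
// normalizer, forward-backward gradient, and Viterbi decoding.
//
// Weight vector layout (length nfeat*nlab [+ nlab*nlab when use_trans]):
//   state weight for (feature f, label y): w[f*nlab + y]
//   transition weight (y_prev -> y):       w[nfeat*nlab + y_prev*nlab + y]
// A sentence is a list of integer vectors of active (0-based) feature ids
// per token.  Sequence score:
//   score(y) = sum_t sum_{f active at t} w[f, y_t]
//            + sum_{t>=2} w_trans[y_{t-1}, y_t]   (when use_trans)

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double logsumexp(const std::vector<double>& v) {
  double m = v[0];
  for (size_t i = 1; i < v.size(); ++i) if (v[i] > m) m = v[i];
  double s = 0.0;
  for (size_t i = 0; i < v.size(); ++i) s += std::exp(v[i] - m);
  return m + std::log(s);
}

// emission score matrix, row-major L x nlab
static std::vector<double> emissions(const NumericVector& w, const List& sent,
                                     int nlab) {
  int L = sent.size();
  std::vector<double> E((size_t)L * nlab, 0.0);
  for (int t = 0; t < L; ++t) {
    IntegerVector f = sent[t];
    for (int k = 0; k < f.size(); ++k) {
      const double* wf = &w[(R_xlen_t)f[k] * nlab];
      for (int y = 0; y < nlab; ++y) E[(size_t)t * nlab + y] += wf[y];
    }
  }
  return E;
}

// [[Rcpp::export]]
double crf_path_score_cpp(NumericVector w, List sent, IntegerVector y,
                          int nfeat, int nlab, bool use_trans) {
  int L = sent.size();
  double s = 0.0;
  const double* wt = use_trans ? &w[(R_xlen_t)nfeat * nlab] : nullptr;
  for (int t = 0; t < L; ++t) {
    IntegerVector f = sent[t];
    for (int k = 0; k < f.size(); ++k) s += w[(R_xlen_t)f[k] * nlab + y[t]];
    if (use_trans && t > 0) s += wt[(R_xlen_t)y[t - 1] * nlab + y[t]];
  }
  return s;
}

// [[Rcpp::export]]
double crf_logZ_cpp(NumericVector w, List sent, int nfeat, int nlab,
                    bool use_trans) {
  int L = sent.size();
  if (L == 0) return 0.0;
  std::vector<double> E = emissions(w, sent, nlab);
  const double* wt = use_trans ? &w[(R_xlen_t)nfeat * nlab] : nullptr;
  std::vector<double> alpha(nlab), prev(nlab), tmp(nlab);
  for (int y = 0; y < nlab; ++y) alpha[y] = E[y];
  for (int t = 1; t < L; ++t) {
    prev = alpha;
    for (int y = 0; y < nlab; ++y) {
      for (int yp = 0; yp < nlab; ++yp) {
        tmp[yp] = prev[yp] + (use_trans ? wt[(R_xlen_t)yp * nlab + y] : 0.0);
      }
      alpha[y] = logsumexp(tmp) + E[(size_t)t * nlab + y];
    }
  }
  return logsumexp(alpha);
}

// [[Rcpp::export]]
IntegerVector crf_viterbi_cpp(NumericVector w, List sent, int nfeat,
                              int nlab, bool use_trans) {
  int L = sent.size();
  IntegerVector path(L);
  if (L == 0) return path;
  std::vector<double> E = emissions(w, sent, nlab);
  const double* wt = use_trans ? &w[(R_xlen_t)nfeat * nlab] : nullptr;
  std::vector<double> delta(nlab), prev(nlab);
  std::vector<int> bp((size_t)L * nlab, 0);
  for (int y = 0; y < nlab; ++y) delta[y] = E[y];
  for (int t = 1; t < L; ++t) {
    prev = delta;
    for (int y = 0; y < nlab; ++y) {
      int best = 0;
      double bestv = prev[0] + (use_trans ? wt[0 * nlab + y] : 0.0);
      for (int yp = 1; yp < nlab; ++yp) {
        double v = prev[yp] + (use_trans ? wt[(R_xlen_t)yp * nlab + y] : 0.0);
        if (v > bestv) { bestv = v; best = yp; }  // ties keep smaller index
      }
      delta[y] = bestv + E[(size_t)t * nlab + y];
      bp[(size_t)t * nlab + y] = best;
    }
  }
  int best = 0;
  for (int y = 1; y < nlab; ++y) if (delta[y] > delta[best]) best = y;
  path[L - 1] = best;
  for (int t = L - 1; t > 0; --t) path[t - 1] = bp[(size_t)t * nlab + path[t]];
  return path;
}

// Penalized negative log-likelihood and gradient over a dataset.
// [[Rcpp::export]]
List crf_nll_grad_cpp(NumericVector w, List feats, List labels, int nfeat,
                      int nlab, bool use_trans, double lambda) {
  R_xlen_t nw = w.size();
  NumericVector grad(nw);
  double nll = 0.0;
  double* wt_grad = use_trans ? &grad[(R_xlen_t)nfeat * nlab] : nullptr;
  const double* wt = use_trans ? &w[(R_xlen_t)nfeat * nlab] : nullptr;

  for (int s = 0; s < feats.size(); ++s) {
    List sent = feats[s];
    IntegerVector y = labels[s];
    int L = sent.size();
    if (L == 0) continue;
    std::vector<double> E = emissions(w, sent, nlab);

    // forward (log alpha), backward (log beta)
    std::vector<double> la((size_t)L * nlab), lb((size_t)L * nlab);
    std::vector<double> tmp(nlab);
    for (int yy = 0; yy < nlab; ++yy) la[yy] = E[yy];
    for (int t = 1; t < L; ++t) {
      for (int yy = 0; yy < nlab; ++yy) {
        for (int yp = 0; yp < nlab; ++yp) {
          tmp[yp] = la[(size_t)(t - 1) * nlab + yp] +
                    (use_trans ? wt[(R_xlen_t)yp * nlab + yy] : 0.0);
        }
        la[(size_t)t * nlab + yy] = logsumexp(tmp) + E[(size_t)t * nlab + yy];
      }
    }
    for (int yy = 0; yy < nlab; ++yy) lb[(size_t)(L - 1) * nlab + yy] = 0.0;
    for (int t = L - 2; t >= 0; --t) {
      for (int yy = 0; yy < nlab; ++yy) {
        for (int yn = 0; yn < nlab; ++yn) {
          tmp[yn] = (use_trans ? wt[(R_xlen_t)yy * nlab + yn] : 0.0) +
                    E[(size_t)(t + 1) * nlab + yn] +
                    lb[(size_t)(t + 1) * nlab + yn];
        }
        lb[(size_t)t * nlab + yy] = logsumexp(tmp);
      }
    }
    std::vector<double> last(nlab);
    for (int yy = 0; yy < nlab; ++yy) last[yy] = la[(size_t)(L - 1) * nlab + yy];
    double logZ = logsumexp(last);

    // observed path score
    nll -= crf_path_score_cpp(w, sent, y, nfeat, nlab, use_trans);
    nll += logZ;

    // gradient: expected minus observed feature counts
    for (int t = 0; t < L; ++t) {
      IntegerVector f = sent[t];
      // state marginals
      for (int yy = 0; yy < nlab; ++yy) {
        double p = std::exp(la[(size_t)t * nlab + yy] +
                            lb[(size_t)t * nlab + yy] - logZ);
        if (p == 0.0) continue;
        for (int k = 0; k < f.size(); ++k) {
          grad[(R_xlen_t)f[k] * nlab + yy] += p;
        }
      }
      for (int k = 0; k < f.size(); ++k) grad[(R_xlen_t)f[k] * nlab + y[t]] -= 1.0;
      // transition marginals
      if (use_trans && t > 0) {
        for (int yp = 0; yp < nlab; ++yp) {
          double a = la[(size_t)(t - 1) * nlab + yp];
          for (int yy = 0; yy < nlab; ++yy) {
            double p = std::exp(a + wt[(R_xlen_t)yp * nlab + yy] +
                                E[(size_t)t * nlab + yy] +
                                lb[(size_t)t * nlab + yy] - logZ);
            wt_grad[(R_xlen_t)yp * nlab + yy] += p;
          }
        }
        wt_grad[(R_xlen_t)y[t - 1] * nlab + y[t]] -= 1.0;
      }
    }
  }

  // L2 penalty
  for (R_xlen_t i = 0; i < nw; ++i) {
    nll += 0.5 * lambda * w[i] * w[i];
    grad[i] += lambda * w[i];
  }
  return List::create(_["nll"] = nll, _["grad"] = grad);
}
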