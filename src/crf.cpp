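// Linear-chain CRF core: penalized negative log-likelihood with analytic
// gradient (forward-backward), Viterbi decoding and k-best decoding with
// exact joint probabilities. States are generic; order-2 models are
// realized in R by composing label pairs into product states and passing
// the corresponding transition/initial masks.
//
// Weight vector layout (R side must match):
//   state weights  w[(f-1)*nS + s]        f = 1..nF, s = 0..nS-1
//   transitions    w[offT + a*nS + b]     a,b = 0..nS-1
//   initial        w[offI + s]
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline double logsumexp(const std::vector<double>& v) {
  double m = R_NegInf;
  for (double x : v) if (x > m) m = x;
  if (!R_FINITE(m)) return R_NegInf;
  double s = 0.0;
  for (double x : v) if (R_FINITE(x)) s += std::exp(x - m);
  return m + std::log(s);
}

struct SeqView {
  const List& feats; // list of IntegerVector (1-based feature ids)
  int T;
  explicit SeqView(const List& f) : feats(f), T(f.size()) {}
};

// node potentials for one position: sum of state-feature weights
static inline void node_potentials(const NumericVector& w, const IntegerVector& fv,
                                   int nS, std::vector<double>& out) {
  std::fill(out.begin(), out.end(), 0.0);
  for (int k = 0; k < fv.size(); ++k) {
    int f = fv[k];
    if (f <= 0) continue;
    const double* base = &w[(size_t)(f - 1) * nS];
    for (int s = 0; s < nS; ++s) out[s] += base[s];
  }
}

// [[Rcpp::export]]
List crf_nll_grad_cpp(NumericVector w, List seq_feats, List seq_labels,
                      int nF, int nS, LogicalMatrix trans_mask,
                      LogicalVector init_mask, double sigma) {
  size_t offT = (size_t)nF * nS;
  size_t offI = offT + (size_t)nS * nS;
  size_t nW = offI + nS;
  NumericVector grad(nW);
  double nll = 0.0;
  int nSeq = seq_feats.size();
  std::vector<double> node_t(nS);

  for (int q = 0; q < nSeq; ++q) {
    List feats = seq_feats[q];
    IntegerVector labels = seq_labels[q];
    int T = feats.size();
    if (T == 0) continue;

    // precompute node potentials
    std::vector<std::vector<double>> node(T, std::vector<double>(nS));
    for (int t = 0; t < T; ++t) {
      IntegerVector fv = feats[t];
      node_potentials(w, fv, nS, node[t]);
    }

    // forward
    std::vector<std::vector<double>> alpha(T, std::vector<double>(nS, R_NegInf));
    for (int s = 0; s < nS; ++s) {
      if (init_mask[s]) alpha[0][s] = node[0][s] + w[offI + s];
    }
    std::vector<double> acc(nS);
    for (int t = 1; t < T; ++t) {
      for (int b = 0; b < nS; ++b) {
        for (int a = 0; a < nS; ++a) {
          acc[a] = (trans_mask(a, b) && R_FINITE(alpha[t-1][a]))
            ? alpha[t-1][a] + w[offT + (size_t)a * nS + b] : R_NegInf;
        }
        alpha[t][b] = node[t][b] + logsumexp(acc);
      }
    }
    double logZ = logsumexp(alpha[T-1]);

    // backward
    std::vector<std::vector<double>> beta(T, std::vector<double>(nS, 0.0));
    for (int t = T - 2; t >= 0; --t) {
      for (int a = 0; a < nS; ++a) {
        for (int b = 0; b < nS; ++b) {
          acc[b] = trans_mask(a, b)
            ? w[offT + (size_t)a * nS + b] + node[t+1][b] + beta[t+1][b]
            : R_NegInf;
        }
        beta[t][a] = logsumexp(acc);
      }
    }

    // gold score and empirical counts
    double gold = 0.0;
    for (int t = 0; t < T; ++t) {
      int y = labels[t] - 1;
      gold += node[t][y];
      IntegerVector fv = feats[t];
      for (int k = 0; k < fv.size(); ++k) {
        if (fv[k] > 0) grad[(size_t)(fv[k] - 1) * nS + y] -= 1.0;
      }
      if (t == 0) { gold += w[offI + y]; grad[offI + y] -= 1.0; }
      else {
        int yp = labels[t-1] - 1;
        gold += w[offT + (size_t)yp * nS + y];
        grad[offT + (size_t)yp * nS + y] -= 1.0;
      }
    }
    nll += logZ - gold;

    // expected counts
    for (int t = 0; t < T; ++t) {
      IntegerVector fv = feats[t];
      for (int s = 0; s < nS; ++s) {
        double g = alpha[t][s] + beta[t][s] - logZ;
        if (!R_FINITE(g)) continue;
        double p = std::exp(g);
        for (int k = 0; k < fv.size(); ++k) {
          if (fv[k] > 0) grad[(size_t)(fv[k] - 1) * nS + s] += p;
        }
        if (t == 0) grad[offI + s] += p;
      }
      if (t > 0) {
        for (int a = 0; a < nS; ++a) {
          if (!R_FINITE(alpha[t-1][a])) continue;
          for (int b = 0; b < nS; ++b) {
            if (!trans_mask(a, b)) continue;
            double lp = alpha[t-1][a] + w[offT + (size_t)a * nS + b] +
              node[t][b] + beta[t][b] - logZ;
            if (R_FINITE(lp)) grad[offT + (size_t)a * nS + b] += std::exp(lp);
          }
        }
      }
    }
  }

  // Gaussian prior: penalty ||w||^2 / (2 sigma)
  double pen = 0.0;
  for (size_t i = 0; i < nW; ++i) {
    pen += w[i] * w[i];
    grad[i] += w[i] / sigma;
  }
  nll += pen / (2.0 * sigma);
  return List::create(_["nll"] = nll, _["grad"] = grad);
}

// forward pass only -> log partition function
static double log_partition(const NumericVector& w,
                            const std::vector<std::vector<double>>& node,
                            int nS, const LogicalMatrix& trans_mask,
                            const LogicalVector& init_mask,
                            size_t offT, size_t offI) {
  int T = node.size();
  std::vector<double> prev(nS, R_NegInf), cur(nS), acc(nS);
  for (int s = 0; s < nS; ++s)
    if (init_mask[s]) prev[s] = node[0][s] + w[offI + s];
  for (int t = 1; t < T; ++t) {
    for (int b = 0; b < nS; ++b) {
      for (int a = 0; a < nS; ++a) {
        acc[a] = (trans_mask(a, b) && R_FINITE(prev[a]))
          ? prev[a] + w[offT + (size_t)a * nS + b] : R_NegInf;
      }
      cur[b] = node[t][b] + logsumexp(acc);
    }
    prev = cur;
  }
  return logsumexp(prev);
}

static std::vector<std::vector<double>> all_nodes(const NumericVector& w,
                                                  const List& feats, int nS) {
  int T = feats.size();
  std::vector<std::vector<double>> node(T, std::vector<double>(nS));
  for (int t = 0; t < T; ++t) {
    IntegerVector fv = feats[t];
    node_potentials(w, fv, nS, node[t]);
  }
  return node;
}

// [[Rcpp::export]]
List crf_viterbi_cpp(NumericVector w, List feats, int nF, int nS,
                     LogicalMatrix trans_mask, LogicalVector init_mask) {
  int T = feats.size();
  size_t offT = (size_t)nF * nS, offI = offT + (size_t)nS * nS;
  if (T == 0) {
    return List::create(_["path"] = IntegerVector(0), _["logscore"] = 0.0,
                        _["logZ"] = 0.0);
  }
  auto node = all_nodes(w, feats, nS);
  std::vector<std::vector<double>> delta(T, std::vector<double>(nS, R_NegInf));
  std::vector<std::vector<int>> back(T, std::vector<int>(nS, -1));
  for (int s = 0; s < nS; ++s)
    if (init_mask[s]) delta[0][s] = node[0][s] + w[offI + s];
  for (int t = 1; t < T; ++t) {
    for (int b = 0; b < nS; ++b) {
      double best = R_NegInf; int arg = -1;
      for (int a = 0; a < nS; ++a) {
        if (!trans_mask(a, b) || !R_FINITE(delta[t-1][a])) continue;
        double sc = delta[t-1][a] + w[offT + (size_t)a * nS + b];
        if (sc > best) { best = sc; arg = a; }
      }
      if (arg >= 0) { delta[t][b] = node[t][b] + best; back[t][b] = arg; }
    }
  }
  double best = R_NegInf; int arg = 0;
  for (int s = 0; s < nS; ++s)
    if (delta[T-1][s] > best) { best = delta[T-1][s]; arg = s; }
  IntegerVector path(T);
  int s = arg;
  for (int t = T - 1; t >= 0; --t) { path[t] = s + 1; s = (t > 0) ? back[t][s] : 0; }
  double logZ = log_partition(w, node, nS, trans_mask, init_mask, offT, offI);
  return List::create(_["path"] = path, _["logscore"] = best, _["logZ"] = logZ);
}

struct KBItem {
  double score;
  int next_state; // 0-based state at t+1, or -1 at the last position
  int next_rank;  // 0-based rank within (t+1, next_state)
};

struct KBCand {
  double score;
  int m; // tie-break key 1 (next/first state, ascending)
  int r; // tie-break key 2 (rank, ascending)
};

static inline bool cand_less(const KBCand& a, const KBCand& b) {
  if (a.score != b.score) return a.score > b.score;
  if (a.m != b.m) return a.m < b.m;
  return a.r < b.r;
}

// k-best suffix decoding: D[t][s] holds the k highest-scoring label
// suffixes starting at position t in state s, ties ordered so that the
// full output is lexicographic by label sequence among equal scores.
// [[Rcpp::export]]
List crf_nbest_cpp(NumericVector w, List feats, int n, int nF, int nS,
                   LogicalMatrix trans_mask, LogicalVector init_mask) {
  int T = feats.size();
  size_t offT = (size_t)nF * nS, offI = offT + (size_t)nS * nS;
  if (T == 0) {
    return List::create(_["paths"] = List::create(IntegerVector(0)),
                        _["logscores"] = NumericVector::create(0.0),
                        _["logZ"] = 0.0);
  }
  auto node = all_nodes(w, feats, nS);
  // D[t][s]: vector of KBItem sorted best-first
  std::vector<std::vector<std::vector<KBItem>>> D(
      T, std::vector<std::vector<KBItem>>(nS));
  for (int s = 0; s < nS; ++s)
    D[T-1][s].push_back({node[T-1][s], -1, -1});
  for (int t = T - 2; t >= 0; --t) {
    for (int s = 0; s < nS; ++s) {
      std::vector<KBCand> cands;
      for (int m = 0; m < nS; ++m) {
        if (!trans_mask(s, m)) continue;
        double tr = w[offT + (size_t)s * nS + m];
        const auto& lst = D[t+1][m];
        int lim = std::min<int>(lst.size(), n);
        for (int r = 0; r < lim; ++r) {
          double sc = node[t][s] + tr + lst[r].score;
          if (R_FINITE(sc)) cands.push_back({sc, m, r});
        }
      }
      std::stable_sort(cands.begin(), cands.end(), cand_less);
      int keep = std::min<int>(cands.size(), n);
      D[t][s].reserve(keep);
      for (int i = 0; i < keep; ++i)
        D[t][s].push_back({cands[i].score, cands[i].m, cands[i].r});
    }
  }
  // merge over starting states with initial weights
  std::vector<KBCand> final_cands;
  for (int s = 0; s < nS; ++s) {
    if (!init_mask[s]) continue;
    double in = w[offI + s];
    const auto& lst = D[0][s];
    int lim = std::min<int>(lst.size(), n);
    for (int r = 0; r < lim; ++r) {
      double sc = in + lst[r].score;
      if (R_FINITE(sc)) final_cands.push_back({sc, s, r});
    }
  }
  std::stable_sort(final_cands.begin(), final_cands.end(), cand_less);
  int keep = std::min<int>(final_cands.size(), n);
  List paths(keep);
  NumericVector scores(keep);
  for (int i = 0; i < keep; ++i) {
    IntegerVector path(T);
    int s = final_cands[i].m, r = final_cands[i].r;
    for (int t = 0; t < T; ++t) {
      path[t] = s + 1;
      if (t < T - 1) {
        const KBItem& item = D[t][s][r];
        s = item.next_state; r = item.next_rank;
      }
    }
    paths[i] = path;
    scores[i] = final_cands[i].score;
  }
  double logZ = log_partition(w, node, nS, trans_mask, init_mask, offT, offI);
  return List::create(_["paths"] = paths, _["logscores"] = scores,
                      _["logZ"] = logZ);
}
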