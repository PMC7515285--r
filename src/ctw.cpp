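#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Context-tree weighting with Krichevsky-Trofimov (add-1/2) estimators at
// every node and the canonical 1/2-1/2 mixture between a node's own KT
// estimate and the product of its children's weighted probabilities.
// Everything is kept in log2 domain so codelengths of 1e6-symbol
// sequences never underflow. Nodes are allocated lazily, so memory scales
// with the number of distinct contexts actually seen, not with m^depth.

namespace {

struct Node {
  double log_pe;         // log2 KT estimate over this node's subsequence
  double log_pw;         // log2 weighted probability
  double log_child_sum;  // sum over children of log_pw (absent child = 0)
  uint32_t cnt[4];
  int child[4];
  Node() : log_pe(0.0), log_pw(0.0), log_child_sum(0.0) {
    for (int i = 0; i < 4; ++i) { cnt[i] = 0; child[i] = -1; }
  }
};

inline double kt_increment(const Node &nd, int s, int m) {
  uint32_t tot = 0;
  for (int i = 0; i < m; ++i) tot += nd.cnt[i];
  return std::log2((nd.cnt[s] + 0.5) / (tot + 0.5 * m));
}

inline double mix_half(double a, double b) {
  // log2(0.5 * 2^a + 0.5 * 2^b), stable for large-magnitude a, b
  double mx = a > b ? a : b;
  return mx - 1.0 + std::log2(std::exp2(a - mx) + std::exp2(b - mx));
}

} // namespace

// [[Rcpp::export]]
double ctw_codelength_cpp(IntegerVector seq, int depth, int m) {
  const int n = seq.size();
  if (m != 2 && m != 4) stop("alphabet size must be 2 or 4");
  if (depth < 1) stop("depth must be >= 1");
  if (n <= depth) stop("sequence must be longer than the context depth");
  for (int i = 0; i < n; ++i) {
    if (seq[i] == NA_INTEGER || seq[i] < 0 || seq[i] >= m)
      stop("symbols must lie in {0, ..., alphabet_size - 1}");
  }

  std::vector<Node> pool;
  pool.reserve(1 << 14);
  pool.emplace_back(); // root
  std::vector<int> path(depth + 1);
  std::vector<double> old_pw(depth + 1);

  for (int t = depth; t < n; ++t) {
    const int s = seq[t];
    // walk the context path, most recent symbol first
    path[0] = 0;
    old_pw[0] = pool[0].log_pw;
    for (int d = 1; d <= depth; ++d) {
      const int c = seq[t - d];
      int slot = pool[path[d - 1]].child[c];
      if (slot < 0) {
        slot = static_cast<int>(pool.size());
        pool.emplace_back();
        pool[path[d - 1]].child[c] = slot;
      }
      path[d] = slot;
      old_pw[d] = pool[slot].log_pw;
    }
    // update the leaf, then propagate toward the root
    {
      Node &leaf = pool[path[depth]];
      leaf.log_pe += kt_increment(leaf, s, m);
      leaf.cnt[s]++;
      leaf.log_pw = leaf.log_pe;
    }
    for (int d = depth - 1; d >= 0; --d) {
      Node &nd = pool[path[d]];
      nd.log_child_sum += pool[path[d + 1]].log_pw - old_pw[d + 1];
      nd.log_pe += kt_increment(nd, s, m);
      nd.cnt[s]++;
      nd.log_pw = mix_half(nd.log_pe, nd.log_child_sum);
    }
  }
  return -pool[0].log_pw;
}

// State trajectory of the general history-dependent facilitation model.
// Four state variables: instantaneous probabilities (p, q) relaxing
// toward the limit probabilities (p_L, q_L) with time constants tau_L;
// the limits jump on spikes and decay toward baseline with the
// facilitation decay constants tau_f. Per bin, driven by the previous
// bin's input symbol: the limits jump (spike) or decay (quiescent), then
// p and q relax one bin toward the updated limits, then the release for
// the bin is drawn. Exponential steps use the exact per-bin factor
// exp(-bin_width / tau), so the limit trajectory is invariant to
// splitting a bin in two.
// [[Rcpp::export]]
List general_state_cpp(IntegerVector x, double p1, double q1,
                       double pmax, double qmax, double u, double v,
                       double bin_width, double tau_L_p, double tau_L_q,
                       double tau_f_p, double tau_f_q) {
  const int n = x.size();
  NumericVector p_out(n), q_out(n), pL_out(n), qL_out(n);
  const double eL_p = std::exp(-bin_width / tau_L_p);
  const double eL_q = std::exp(-bin_width / tau_L_q);
  const double ef_p = std::exp(-bin_width / tau_f_p);
  const double ef_q = std::exp(-bin_width / tau_f_q);

  double p = p1, q = q1, pL = p1, qL = q1;
  for (int i = 0; i < n; ++i) {
    if (i > 0) {
      if (x[i - 1] == 1) {
        pL += u * (pmax - pL);
        qL += v * (qmax - qL);
      } else {
        pL = p1 + (pL - p1) * ef_p;
        qL = q1 + (qL - q1) * ef_q;
      }
      p = pL + (p - pL) * eL_p;
      q = qL + (q - qL) * eL_q;
      pL_out[i] = pL;
      qL_out[i] = qL;
    } else {
      pL_out[i] = pL;
      qL_out[i] = qL;
    }
    p_out[i] = p;
    q_out[i] = q;
  }
  return List::create(_["p"] = p_out, _["q"] = q_out,
                      _["p_L"] = pL_out, _["q_L"] = qL_out);
}
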