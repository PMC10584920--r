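#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Degree-preserving double-edge-swap randomization of a bipartite edge list.
// A proposal picks two distinct edges (s1,d1),(s2,d2) and rewires to
// (s1,d2),(s2,d1); it is rejected if the edges share an endpoint (no-op) or
// if either rewired edge already exists (multi-edges forbidden). n_switches
// counts successful swaps. Uses R's RNG so results follow set.seed().

static inline int ridx(int n) { return (int)(unif_rand() * n) % n; }

// [[Rcpp::export]]
List edge_switch_cpp(IntegerVector src, IntegerVector dst, int n_src,
                     int n_tgt, double n_switches, double max_tries) {
  int m = src.size();
  std::vector<int> s(src.begin(), src.end()), d(dst.begin(), dst.end());
  std::vector<char> adj((size_t)n_src * n_tgt, 0);
  for (int i = 0; i < m; i++) adj[(size_t)(s[i] - 1) * n_tgt + (d[i] - 1)] = 1;
  double done = 0, tries = 0;
  while (done < n_switches && tries < max_tries) {
    tries += 1;
    int e1 = ridx(m), e2 = ridx(m);
    if (e1 == e2) continue;
    int s1 = s[e1], d1 = d[e1], s2 = s[e2], d2 = d[e2];
    if (s1 == s2 || d1 == d2) continue;
    size_t k12 = (size_t)(s1 - 1) * n_tgt + (d2 - 1);
    size_t k21 = (size_t)(s2 - 1) * n_tgt + (d1 - 1);
    if (adj[k12] || adj[k21]) continue;
    adj[(size_t)(s1 - 1) * n_tgt + (d1 - 1)] = 0;
    adj[(size_t)(s2 - 1) * n_tgt + (d2 - 1)] = 0;
    adj[k12] = 1;
    adj[k21] = 1;
    d[e1] = d2;
    d[e2] = d1;
    done += 1;
  }
  return List::create(_["src"] = IntegerVector(s.begin(), s.end()),
                      _["dst"] = IntegerVector(d.begin(), d.end()),
                      _["n_done"] = done, _["n_tries"] = tries);
}

// Generate n_networks randomizations (each restarted from the input
// network), score each against a source x target evidence-overlap matrix,
// and verify degree preservation and edge uniqueness per network.
// [[Rcpp::export]]
List randomize_overlap_cpp(IntegerVector src, IntegerVector dst, int n_src,
                           int n_tgt, LogicalMatrix okmat, int n_networks,
                           double n_switches, double max_tries) {
  int m = src.size();
  NumericVector overlaps(n_networks);
  std::vector<int> deg_s0(n_src, 0), deg_t0(n_tgt, 0);
  for (int i = 0; i < m; i++) { deg_s0[src[i] - 1]++; deg_t0[dst[i] - 1]++; }
  bool all_ok = true;
  double short_runs = 0;
  for (int r = 0; r < n_networks; r++) {
    List res = edge_switch_cpp(src, dst, n_src, n_tgt, n_switches, max_tries);
    IntegerVector s = res["src"], d = res["dst"];
    if (as<double>(res["n_done"]) < n_switches) short_runs += 1;
    std::vector<int> deg_s(n_src, 0), deg_t(n_tgt, 0);
    std::vector<char> seen((size_t)n_src * n_tgt, 0);
    double ov = 0;
    for (int i = 0; i < m; i++) {
      deg_s[s[i] - 1]++;
      deg_t[d[i] - 1]++;
      size_t k = (size_t)(s[i] - 1) * n_tgt + (d[i] - 1);
      if (seen[k]) all_ok = false;  // duplicate edge
      seen[k] = 1;
      if (okmat(s[i] - 1, d[i] - 1)) ov += 1;
    }
    if (deg_s != deg_s0 || deg_t != deg_t0) all_ok = false;
    overlaps[r] = ov;
  }
  return List::create(_["overlaps"] = overlaps, _["all_ok"] = all_ok,
                      _["short_runs"] = short_runs);
}
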