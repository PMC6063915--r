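#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Signed extremum of the weighted running sum for one gene set.
// pos: sorted 1-based hit positions; w: non-negative weights (|snr|^p) at
// those positions; N: length of the ranked list. Hits add w/W, misses
// subtract 1/(N-k). When all hit weights are zero the unweighted statistic
// (equal increments 1/k) is used. Ties between the positive and negative
// extremum resolve to the positive one.
static double es_from_hits(const std::vector<int>& pos,
                           const std::vector<double>& w, int N) {
  const int k = (int)pos.size();
  double W = 0.0;
  for (double x : w) W += x;
  bool unweighted = (W <= 0.0);
  if (unweighted) W = (double)k;
  const double miss = 1.0 / (double)(N - k);
  double cum = 0.0, maxv = R_NegInf, minv = 0.0;  // walk ends at 0
  for (int j = 0; j < k; ++j) {
    // value just before hit j (end of the preceding miss run)
    double before = cum / W - (double)(pos[j] - 1 - j) * miss;
    if (before < minv) minv = before;
    cum += unweighted ? 1.0 : w[j];
    double after = cum / W - (double)(pos[j] - (j + 1)) * miss;
    if (after > maxv) maxv = after;
  }
  // near-exact ties between the extrema resolve to the positive one
  return (maxv >= std::fabs(minv) - 1e-12) ? maxv : minv;
}

// [[Rcpp::export]]
double cpp_es(IntegerVector pos, NumericVector w, int N) {
  std::vector<int> p(pos.begin(), pos.end());
  std::vector<double> ww(w.begin(), w.end());
  return es_from_hits(p, ww, N);
}

// Null enrichment scores from nperm uniform random k-subsets of the ranked
// list (gene-set permutation). wfull holds |snr|^p for every position.
// Uses R's RNG so results are governed by set.seed().
// [[Rcpp::export]]
NumericVector cpp_es_null(int N, int k, NumericVector wfull, int nperm) {
  NumericVector out(nperm);
  std::vector<int> stamp(N + 1, -1);
  std::vector<int> pos(k);
  std::vector<double> w(k);
  for (int perm = 0; perm < nperm; ++perm) {
    // Floyd's algorithm: k distinct values in 1..N
    int m = 0;
    for (int j = N - k + 1; j <= N; ++j) {
      int t = (int)(unif_rand() * j) + 1;
      if (t > j) t = j;
      if (stamp[t] == perm) t = j;
      stamp[t] = perm;
      pos[m++] = t;
    }
    std::sort(pos.begin(), pos.end());
    for (int j = 0; j < k; ++j) w[j] = wfull[pos[j] - 1];
    out[perm] = es_from_hits(pos, w, N);
  }
  return out;
}

// Metropolis sampler over subsets of candidate links.
// cand_edges: per candidate, the 1-based ids of network edges it explains.
// Target density exp(beta * (coverage - lambda * n_selected)); proposals
// toggle one uniformly chosen candidate. Inclusion frequencies are
// accumulated over post-burn-in states taken every `thin` steps.
// [[Rcpp::export]]
List cpp_mcmc_bpn(List cand_edges, int n_edges, double lambda, double beta,
                  double burn_in, double n_steps, int thin) {
  const int K = cand_edges.size();
  std::vector< std::vector<int> > edges(K);
  for (int i = 0; i < K; ++i) {
    IntegerVector e = cand_edges[i];
    edges[i].assign(e.begin(), e.end());
  }
  std::vector<int> cover(n_edges + 1, 0);
  std::vector<char> state(K, 0), best_state(K, 0);
  std::vector<double> incl(K, 0.0);
  std::vector<double> on_since(K, 0.0);
  double coverage = 0.0, n_sel = 0.0;
  double score = 0.0, best_score = 0.0;
  double n_samples = 0.0, n_accept = 0.0;
  const double total = burn_in + n_steps;

  for (double s = 1.0; s <= total; s += 1.0) {
    int u = (int)(unif_rand() * K);
    if (u >= K) u = K - 1;
    double dcov = 0.0, dscore;
    if (!state[u]) {
      for (int e : edges[u]) if (cover[e] == 0) dcov += 1.0;
      dscore = dcov - lambda;
    } else {
      for (int e : edges[u]) if (cover[e] == 1) dcov += 1.0;
      dscore = lambda - dcov;
    }
    if (dscore >= 0.0 || unif_rand() < std::exp(beta * dscore)) {
      n_accept += 1.0;
      if (!state[u]) {
        for (int e : edges[u]) ++cover[e];
        coverage += dcov;
        n_sel += 1.0;
        state[u] = 1;
        on_since[u] = n_samples;
      } else {
        for (int e : edges[u]) --cover[e];
        coverage -= dcov;
        n_sel -= 1.0;
        state[u] = 0;
        incl[u] += n_samples - on_since[u];
      }
      score = coverage - lambda * n_sel;
      if (score > best_score) {
        best_score = score;
        for (int i = 0; i < K; ++i) best_state[i] = state[i];
      }
    }
    if (s > burn_in) {
      double t = s - burn_in;
      if (std::fmod(t, (double)thin) == 0.0) n_samples += 1.0;
    }
  }
  for (int i = 0; i < K; ++i)
    if (state[i]) incl[i] += n_samples - on_since[i];

  NumericVector prob(K);
  LogicalVector best(K);
  for (int i = 0; i < K; ++i) {
    prob[i] = (n_samples > 0.0) ? incl[i] / n_samples : NA_REAL;
    best[i] = best_state[i] != 0;
  }
  return List::create(_["probability"] = prob,
                      _["best_state"] = best,
                      _["best_score"] = best_score,
                      _["n_samples"] = n_samples,
                      _["acceptance_rate"] = n_accept / total);
}
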