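#include <Rcpp.h>
using namespace Rcpp;

// Objective F(P) over clusters c:
//   sum form:  sum_{i<j in c} (S_ij + gamma)            - penalty * [|c| == 1]
//   mean form: mean_{i<j in c} (S_ij) + gamma  (|c|>=2) - penalty * [|c| == 1]
// Higher is better. pairsum[c] tracks sum_{i<j in c} S_ij.

static inline double cluster_term(double pairsum, int size, double gamma,
                                  double penalty, bool mean_form) {
  if (size <= 0) return 0.0;
  if (size == 1) return -penalty;
  double npairs = 0.5 * size * (size - 1.0);
  if (mean_form) return pairsum / npairs + gamma;
  return pairsum + gamma * npairs;
}

// [[Rcpp::export]]
double chase_objective_cpp(NumericMatrix S, IntegerVector labels, double gamma,
                           double penalty, bool mean_form) {
  int n = S.nrow();
  int k = 0;
  for (int i = 0; i < n; ++i) if (labels[i] > k) k = labels[i];
  std::vector<double> pairsum(k, 0.0);
  std::vector<int> size(k, 0);
  for (int i = 0; i < n; ++i) size[labels[i] - 1]++;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (labels[i] == labels[j]) pairsum[labels[i] - 1] += S(i, j);
  double F = 0.0;
  for (int c = 0; c < k; ++c)
    F += cluster_term(pairsum[c], size[c], gamma, penalty, mean_form);
  return F;
}

// Stochastic shuffle optimizer. Each step proposes moving a uniformly
// random site to a uniformly random target among the non-empty clusters
// plus (when fewer than k are alive) the lowest-index dormant cluster.
// Greedy acceptance (delta > 0) by default; Metropolis acceptance with a
// geometrically cooled temperature when t0 > 0. Returns the best labelling
// ever visited, not the final state. Uses R's RNG (set.seed applies).
// [[Rcpp::export]]
List chase_optimize_cpp(NumericMatrix S, IntegerVector labels0, int k,
                        int n_shuffles, double gamma, double penalty,
                        double t0, double decay, bool mean_form) {
  int n = S.nrow();
  if (labels0.size() != n) stop("labels0 length must match S");
  std::vector<int> lab(n);
  std::vector<int> size(k, 0);
  std::vector<double> pairsum(k, 0.0);
  // M(c, i) = sum over members j of cluster c of S(j, i)
  NumericMatrix M(k, n);
  for (int i = 0; i < n; ++i) {
    int c = labels0[i] - 1;
    if (c < 0 || c >= k) stop("labels must lie in 1..k");
    lab[i] = c;
    size[c]++;
  }
  for (int i = 0; i < n; ++i) {
    int c = lab[i];
    for (int j = 0; j < n; ++j) M(c, j) += S(i, j);
  }
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (lab[i] == lab[j]) pairsum[lab[i]] += S(i, j);

  double F = 0.0;
  for (int c = 0; c < k; ++c)
    F += cluster_term(pairsum[c], size[c], gamma, penalty, mean_form);

  double bestF = F;
  std::vector<int> best(lab);
  double T = t0;
  long accepted = 0;
  std::vector<int> targets(k + 1);

  for (int step = 0; step < n_shuffles; ++step) {
    int i = (int)(unif_rand() * n);
    if (i >= n) i = n - 1;
    int a = lab[i];
    // candidate targets: alive clusters, plus lowest dormant if any room
    int nt = 0, dormant = -1;
    for (int c = 0; c < k; ++c) {
      if (size[c] > 0) targets[nt++] = c;
      else if (dormant < 0) dormant = c;
    }
    if (dormant >= 0) targets[nt++] = dormant;
    int b = targets[(int)(unif_rand() * nt)];
    if (b == a) { if (t0 > 0.0) T *= decay; continue; }

    double psa_new = pairsum[a] - (M(a, i) - S(i, i));
    double psb_new = pairsum[b] + M(b, i);
    double delta =
      cluster_term(psa_new, size[a] - 1, gamma, penalty, mean_form) +
      cluster_term(psb_new, size[b] + 1, gamma, penalty, mean_form) -
      cluster_term(pairsum[a], size[a], gamma, penalty, mean_form) -
      cluster_term(pairsum[b], size[b], gamma, penalty, mean_form);

    bool accept = delta > 0.0;
    if (!accept && t0 > 0.0 && T > 0.0)
      accept = unif_rand() < std::exp(delta / T);
    if (accept) {
      lab[i] = b;
      size[a]--; size[b]++;
      pairsum[a] = psa_new; pairsum[b] = psb_new;
      for (int j = 0; j < n; ++j) {
        double s = S(i, j);
        M(a, j) -= s;
        M(b, j) += s;
      }
      F += delta;
      ++accepted;
      if (F > bestF) { bestF = F; best = lab; }
    }
    if (t0 > 0.0) T *= decay;
  }

  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = best[i] + 1;
  return List::create(_["labels"] = out, _["objective"] = bestF,
                      _["accepted"] = accepted, _["final_objective"] = F);
}
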