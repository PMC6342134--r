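#include <Rcpp.h>
using namespace Rcpp;

// Simulated-annealing maximisation of weighted bipartite (Barber-type)
// modularity.  Bn is the pre-scaled modularity matrix
// (A - k d^T / F) / F, so that Q(partition) = sum over same-module
// row/column pairs of Bn(i, j).  Nodes 0..nr-1 are rows, nr..nr+nc-1
// columns; labels run 0..max_modules-1.  Moves are single-node
// relabellings plus occasional whole-module merges, cooled
// geometrically, followed by a greedy hill-climb to the local optimum.
// Uses R's RNG stream (RNGScope supplied by Rcpp attributes).

static double move_delta(const NumericMatrix &Bn, const IntegerVector &lab,
                         int node, int to, int nr, int nc) {
  int from = lab[node];
  double d = 0.0;
  if (node < nr) { // row node: interacts with columns
    for (int j = 0; j < nc; ++j) {
      int lj = lab[nr + j];
      if (lj == to) d += Bn(node, j);
      else if (lj == from) d -= Bn(node, j);
    }
  } else { // column node
    int j = node - nr;
    for (int i = 0; i < nr; ++i) {
      int li = lab[i];
      if (li == to) d += Bn(i, j);
      else if (li == from) d -= Bn(i, j);
    }
  }
  return d;
}

static double full_q(const NumericMatrix &Bn, const IntegerVector &lab,
                     int nr, int nc) {
  double q = 0.0;
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      if (lab[i] == lab[nr + j]) q += Bn(i, j);
  return q;
}

static int rand_int(int n) { // uniform on 0..n-1
  int v = (int)std::floor(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

// [[Rcpp::export]]
List anneal_modules_cpp(NumericMatrix Bn, int max_modules, double t0,
                        double cooling, double t_min, int steps_per_temp) {
  int nr = Bn.nrow(), nc = Bn.ncol(), n = nr + nc;
  IntegerVector lab(n), best_lab(n);
  for (int i = 0; i < n; ++i) lab[i] = rand_int(max_modules);
  double q = full_q(Bn, lab, nr, nc);
  std::copy(lab.begin(), lab.end(), best_lab.begin());
  double best_q = q;

  for (double temp = t0; temp > t_min; temp *= cooling) {
    for (int s = 0; s < steps_per_temp; ++s) {
      if (max_modules > 1 && unif_rand() < 0.1) { // merge two modules
        int a = rand_int(max_modules), b = rand_int(max_modules);
        if (a == b) continue;
        double d = 0.0;
        for (int i = 0; i < nr; ++i) {
          if (lab[i] != a && lab[i] != b) continue;
          for (int j = 0; j < nc; ++j) {
            int lj = lab[nr + j];
            if ((lab[i] == a && lj == b) || (lab[i] == b && lj == a))
              d += Bn(i, j);
          }
        }
        if (d > 0 || unif_rand() < std::exp(d / temp)) {
          for (int i = 0; i < n; ++i) if (lab[i] == a) lab[i] = b;
          q += d;
        }
      } else { // single-node move
        int node = rand_int(n);
        int to = rand_int(max_modules);
        if (to == lab[node]) continue;
        double d = move_delta(Bn, lab, node, to, nr, nc);
        if (d > 0 || unif_rand() < std::exp(d / temp)) {
          lab[node] = to;
          q += d;
        }
      }
      if (q > best_q) {
        best_q = q;
        std::copy(lab.begin(), lab.end(), best_lab.begin());
      }
    }
  }

  // greedy refinement of the best state found
  std::copy(best_lab.begin(), best_lab.end(), lab.begin());
  q = full_q(Bn, lab, nr, nc);
  bool improved = true;
  while (improved) {
    improved = false;
    for (int node = 0; node < n; ++node) {
      int arg = lab[node];
      double bestd = 0.0;
      for (int to = 0; to < max_modules; ++to) {
        if (to == lab[node]) continue;
        double d = move_delta(Bn, lab, node, to, nr, nc);
        if (d > bestd + 1e-15) { bestd = d; arg = to; }
      }
      if (arg != lab[node]) {
        lab[node] = arg;
        q += bestd;
        improved = true;
      }
    }
  }
  q = full_q(Bn, lab, nr, nc); // re-sync accumulated Q
  return List::create(_["labels"] = lab, _["q"] = q);
}
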