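// Gibbs sampler inner loop. Uses R's RNG (unif_rand) so set.seed() on the
// R side makes runs bit-reproducible.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// sample index in [0, n) proportional to w (w need not be normalized)
static int sample_prop(const std::vector<double>& w, double total) {
  double u = unif_rand() * total;
  double acc = 0.0;
  int n = (int)w.size();
  for (int k = 0; k < n; ++k) {
    acc += w[k];
    if (u <= acc) return k;
  }
  return n - 1; // numerical slack
}

// [[Rcpp::export]]
List gibbs_sample_cpp(IntegerVector unit_of, NumericVector prior,
                      IntegerMatrix bio_edges, IntegerMatrix add_edges,
                      int n_units, int n_iter, int burn_in,
                      double delta_bio, double delta_add,
                      bool random_scan) {
  const int n_cand = prior.size();
  std::vector<std::vector<int>> nb_bio(n_cand), nb_add(n_cand);
  for (int e = 0; e < bio_edges.nrow(); ++e) {
    int u = bio_edges(e, 0), v = bio_edges(e, 1);
    nb_bio[u].push_back(v);
    nb_bio[v].push_back(u);
  }
  for (int e = 0; e < add_edges.nrow(); ++e) {
    int u = add_edges(e, 0), v = add_edges(e, 1);
    nb_add[u].push_back(v);
    nb_add[v].push_back(u);
  }
  std::vector<std::vector<int>> cands(n_units);
  for (int c = 0; c < n_cand; ++c) cands[unit_of[c]].push_back(c);

  RNGScope scope;
  std::vector<int> nbio(n_cand, 0), nadd(n_cand, 0);
  std::vector<int> assign(n_units, -1);
  std::vector<double> w;
  // initial state: draw each unit from its prior
  for (int f = 0; f < n_units; ++f) {
    const std::vector<int>& cf = cands[f];
    w.assign(cf.size(), 0.0);
    double tot = 0.0;
    for (size_t k = 0; k < cf.size(); ++k) {
      w[k] = prior[cf[k]];
      tot += w[k];
    }
    assign[f] = cf[sample_prop(w, tot)];
  }
  for (int f = 0; f < n_units; ++f) {
    int a = assign[f];
    for (int v : nb_bio[a]) nbio[v]++;
    for (int v : nb_add[a]) nadd[v]++;
  }

  NumericVector visits(n_cand), visits1(n_cand), visits2(n_cand);
  double n_cond_evals = 0.0;
  const int n_rec = n_iter - burn_in;
  const int half = burn_in + n_rec / 2;
  for (int it = 0; it < n_iter; ++it) {
    for (int s = 0; s < n_units; ++s) {
      int f = random_scan ? (int)(unif_rand() * n_units) : s;
      if (f >= n_units) f = n_units - 1;
      const std::vector<int>& cf = cands[f];
      int old_c = assign[f];
      for (int v : nb_bio[old_c]) nbio[v]--;
      for (int v : nb_add[old_c]) nadd[v]--;
      w.assign(cf.size(), 0.0);
      double tot = 0.0;
      for (size_t k = 0; k < cf.size(); ++k) {
        int c = cf[k];
        w[k] = prior[c] * (nbio[c] + delta_bio) * (nadd[c] + delta_add);
        tot += w[k];
      }
      n_cond_evals += (double)cf.size();
      int new_c = cf[sample_prop(w, tot)];
      assign[f] = new_c;
      for (int v : nb_bio[new_c]) nbio[v]++;
      for (int v : nb_add[new_c]) nadd[v]++;
    }
    if (it >= burn_in) {
      for (int f = 0; f < n_units; ++f) {
        visits[assign[f]] += 1.0;
        if (it < half) visits1[assign[f]] += 1.0;
        else visits2[assign[f]] += 1.0;
      }
    }
  }
  const double d1 = std::max(1, n_rec / 2);
  const double d2 = std::max(1, n_rec - n_rec / 2);
  for (int c = 0; c < n_cand; ++c) {
    visits[c] /= (double)n_rec;
    visits1[c] /= d1;
    visits2[c] /= d2;
  }
  return List::create(
    _["posterior"] = visits,
    _["visits_first_half"] = visits1,
    _["visits_second_half"] = visits2,
    _["n_cond_evals"] = n_cond_evals);
}
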