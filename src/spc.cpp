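#include <Rcpp.h>
using namespace Rcpp;

// Union-find with path compression.
static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[rb] = ra;
}

// Swendsen-Wang simulation of a q-state Potts model on a fixed interaction
// graph, one temperature at a time. For each temperature the pairwise
// spin-spin coincidence frequency is accumulated over the post-burn-in
// sweeps; edges whose coincidence exceeds corr_threshold are linked and the
// connected components of the linked graph are the clusters at that
// temperature. Uses R's RNG so runs are reproducible under set.seed().
//
// edge_i / edge_j: 0-based endpoints; J: interaction strengths; temps:
// ascending temperatures. Returns a list with one integer assignment vector
// (1-based cluster ids, ordered by first occurrence) per temperature.
// [[Rcpp::export(name = ".spc_run")]]
List spc_run(int n, IntegerVector edge_i, IntegerVector edge_j,
             NumericVector J, NumericVector temps, int sweeps, int burnin,
             int q, double corr_threshold) {
  int m = edge_i.size();
  int n_temp = temps.size();
  List out(n_temp);

  std::vector<int> spin(n), parent(n);
  std::vector<double> coincide(m);
  std::vector<double> pfreeze(m);

  for (int t = 0; t < n_temp; ++t) {
    double T = temps[t];
    for (int e = 0; e < m; ++e)
      pfreeze[e] = (T <= 0.0) ? 1.0 : 1.0 - std::exp(-J[e] / T);
    for (int i = 0; i < n; ++i)
      spin[i] = (int)(unif_rand() * q);
    std::fill(coincide.begin(), coincide.end(), 0.0);

    for (int s = 0; s < sweeps; ++s) {
      // bond freezing between aligned spins, then cluster flip
      for (int i = 0; i < n; ++i) parent[i] = i;
      for (int e = 0; e < m; ++e) {
        int a = edge_i[e], b = edge_j[e];
        if (spin[a] == spin[b] && unif_rand() < pfreeze[e])
          uf_union(parent, a, b);
      }
      // assign a fresh random spin to every SW cluster
      std::vector<int> newspin(n, -1);
      for (int i = 0; i < n; ++i) {
        int r = uf_find(parent, i);
        if (newspin[r] < 0) newspin[r] = (int)(unif_rand() * q);
        spin[i] = newspin[r];
      }
      if (s >= burnin) {
        for (int e = 0; e < m; ++e)
          if (spin[edge_i[e]] == spin[edge_j[e]]) coincide[e] += 1.0;
      }
    }

    // link edges with high coincidence, take connected components
    double denom = (double)(sweeps - burnin);
    for (int i = 0; i < n; ++i) parent[i] = i;
    for (int e = 0; e < m; ++e)
      if (coincide[e] / denom > corr_threshold)
        uf_union(parent, edge_i[e], edge_j[e]);

    IntegerVector assign(n);
    std::vector<int> label(n, 0);
    int next = 0;
    for (int i = 0; i < n; ++i) {
      int r = uf_find(parent, i);
      if (label[r] == 0) label[r] = ++next;
      assign[i] = label[r];
    }
    out[t] = assign;
  }
  return out;
}
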