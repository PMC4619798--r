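#include <Rcpp.h>
using namespace Rcpp;

// Monte Carlo Prisoner's Dilemma on a multiplex with the homophily- and
// communicability-modified Fermi rule. Strategies are layer-major
// (S[a*N+x], 1 = cooperate, 0 = defect). Uses R's RNG so runs are
// reproducible from set.seed() in the calling R code.

static inline double layer_payoff_c(const std::vector<const int*>& ptr,
                                    const std::vector<const int*>& idx,
                                    const std::vector<int>& S,
                                    int x, int a, int N,
                                    double b, double cost) {
  const int* p = ptr[a];
  const int* nb = idx[a];
  int nC = 0;
  int deg = p[x + 1] - p[x];
  for (int k = p[x]; k < p[x + 1]; ++k) nC += S[a * N + nb[k]];
  double P = b * nC;
  if (S[a * N + x] == 1) P -= cost * deg;
  return P;
}

// [[Rcpp::export]]
List mc_run_cpp(List adj_ptr, List adj_idx, List delta_list,
                NumericMatrix G, IntegerVector S0,
                double b, double cost, double K,
                double eta_min, double eta_max,
                int N, int M, int rounds,
                bool beta_excludes_alpha, bool neighbor_focal,
                bool eta_all_layers,
                IntegerVector snapshot_rounds) {
  const int NM = N * M;
  std::vector<const int*> ptr(M), idx(M);
  std::vector<IntegerVector> keep_p(M), keep_i(M);
  for (int a = 0; a < M; ++a) {
    keep_p[a] = as<IntegerVector>(adj_ptr[a]);
    keep_i[a] = as<IntegerVector>(adj_idx[a]);
    ptr[a] = keep_p[a].begin();
    idx[a] = keep_i[a].begin();
  }
  std::vector<NumericMatrix> dmat;
  for (int i = 0; i < delta_list.size(); ++i)
    dmat.push_back(as<NumericMatrix>(delta_list[i]));
  const int ndelta = dmat.size();

  std::vector<int> S(S0.begin(), S0.end());

  NumericMatrix rho(rounds + 1, M + 2);  // total, per-layer, node-level
  std::set<int> snaps(snapshot_rounds.begin(), snapshot_rounds.end());
  List snapshots;
  CharacterVector snap_names;

  long skipped = 0;

  auto record = [&](int round) {
    int tot = 0;
    for (int a = 0; a < M; ++a) {
      int la = 0;
      for (int x = 0; x < N; ++x) la += S[a * N + x];
      rho(round, 1 + a) = (double)la / N;
      tot += la;
    }
    rho(round, 0) = (double)tot / NM;
    int full = 0;
    for (int x = 0; x < N; ++x) {
      int all = 1;
      for (int a = 0; a < M; ++a) if (S[a * N + x] == 0) { all = 0; break; }
      full += all;
    }
    rho(round, M + 1) = (double)full / N;
    if (snaps.count(round)) {
      snapshots.push_back(IntegerVector(S.begin(), S.end()));
      snap_names.push_back(std::to_string(round));
    }
  };

  record(0);

  for (int round = 1; round <= rounds; ++round) {
    for (int step = 0; step < NM; ++step) {
      int r = (int)(R::unif_rand() * NM);
      if (r >= NM) r = NM - 1;
      int x = r % N, a = r / N;

      // pick the comparison layer beta; the pool of candidate models must
      // be non-empty there, else redraw (at most M attempts)
      int bta = -1, deg = 0;
      const int* pool_p = 0; const int* pool_i = 0;
      for (int att = 0; att < M; ++att) {
        int cand;
        if (beta_excludes_alpha && M > 1) {
          cand = (int)(R::unif_rand() * (M - 1));
          if (cand >= M - 1) cand = M - 2;
          if (cand >= a) cand += 1;
        } else {
          cand = (int)(R::unif_rand() * M);
          if (cand >= M) cand = M - 1;
        }
        int src = neighbor_focal ? a : cand;
        const int* p = ptr[src];
        int d = p[x + 1] - p[x];
        if (d > 0) { bta = cand; deg = d; pool_p = p; pool_i = idx[src]; break; }
      }
      if (bta < 0) { ++skipped; continue; }

      int j = (int)(R::unif_rand() * deg);
      if (j >= deg) j = deg - 1;
      int y = pool_i[pool_p[x] + j];

      double Px = layer_payoff_c(ptr, idx, S, x, a, N, b, cost);
      double Py = layer_payoff_c(ptr, idx, S, y, bta, N, b, cost);

      // communicability scaling: counterpart of x plus its neighbors,
      // either on the selected layer beta only, or aggregated over every
      // other layer (communicability-weighted, so strongly coupled layers
      // dominate the scaling factor)
      int sx = S[a * N + x];
      double num = 0.0, den = 0.0;
      for (int b2 = 0; b2 < M; ++b2) {
        if (eta_all_layers) { if (b2 == a && M > 1) continue; }
        else if (b2 != bta) continue;
        double g0 = G(a * N + x, b2 * N + x);
        den += g0;
        if (S[b2 * N + x] == sx) num += g0;
        const int* p = ptr[b2];
        const int* nb = idx[b2];
        for (int k = p[x]; k < p[x + 1]; ++k) {
          int y2 = nb[k];
          double g = G(a * N + x, b2 * N + y2);
          den += g;
          if (S[b2 * N + y2] == sx) num += g;
        }
      }
      double eta = (den > 0.0)
                   ? eta_min + (eta_max - eta_min) * (1.0 - num / den)
                   : eta_max;

      const NumericMatrix& dm = dmat[(a < ndelta) ? a : 0];
      double dxy = dm(x, y);
      double prob;
      if (dxy == 0.0) {
        prob = (Py > Px) ? eta : ((Py == Px) ? eta / 2.0 : 0.0);
      } else {
        prob = eta / (1.0 + std::exp((Px - Py) / (dxy * K)));
      }
      if (R::unif_rand() < prob) S[a * N + x] = S[bta * N + y];
    }
    record(round);
  }

  if (snapshots.size() > 0) snapshots.attr("names") = snap_names;
  return List::create(_["rho"] = rho,
                      _["final_state"] = IntegerVector(S.begin(), S.end()),
                      _["snapshots"] = snapshots,
                      _["skipped"] = (double)skipped);
}
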