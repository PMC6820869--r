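#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double sinc(double x) {
  return (std::fabs(x) < 1e-8) ? 1.0 - x * x / 6.0 : std::sin(x) / x;
}

static inline double dist3(const double* x, const double* y, const double* z,
                           int i, int j) {
  double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// Debye pair sum S(q) = N + 2 * sum_{j<k} sinc(q d_jk) for identical beads.
// Exact double loop for small ensembles; distance-histogram acceleration
// (bin width passed from R, <= bead_radius/4) for large ones.
// [[Rcpp::export]]
NumericVector cpp_debye_sum(NumericMatrix coords, NumericVector q,
                            double bin_width, int exact_limit = 300) {
  const int n = coords.nrow(), nq = q.size();
  NumericVector out(nq);
  if (n == 0) return out;
  const double* x = &coords(0, 0);
  const double* y = &coords(0, 1);
  const double* z = &coords(0, 2);

  if (n <= exact_limit) {
    std::vector<double> d;
    d.reserve((size_t)n * (n - 1) / 2);
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) d.push_back(dist3(x, y, z, i, j));
    for (int k = 0; k < nq; ++k) {
      double s = 0.0;
      for (size_t m = 0; m < d.size(); ++m) s += sinc(q[k] * d[m]);
      out[k] = n + 2.0 * s;
    }
    return out;
  }

  double dmax = 0.0;
  for (int i = 0; i < n; ++i) {
    double r2 = x[i] * x[i] + y[i] * y[i] + z[i] * z[i];
    if (r2 > dmax) dmax = r2;
  }
  // sites are centred by the caller; 2*max radius bounds all pair distances
  dmax = 2.0 * std::sqrt(dmax) + bin_width;
  const int nb = (int)(dmax / bin_width) + 2;
  std::vector<double> hist(nb, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int b = (int)(dist3(x, y, z, i, j) / bin_width);
      if (b >= nb) b = nb - 1;
      hist[b] += 1.0;
    }
  for (int k = 0; k < nq; ++k) {
    double s = 0.0;
    for (int b = 0; b < nb; ++b)
      if (hist[b] > 0.0) s += hist[b] * sinc(q[k] * (b + 0.5) * bin_width);
    out[k] = n + 2.0 * s;
  }
  return out;
}

// For each row of A, squared distance to the nearest row of B.
// [[Rcpp::export]]
NumericVector cpp_min_dist2(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < nb; ++j) {
      double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = best;
  }
  return out;
}

// Neighbour lists (site pairs closer than cutoff), flattened CSR-style.
// [[Rcpp::export]]
List cpp_neighbors(NumericMatrix sites, double cutoff) {
  const int M = sites.nrow();
  const double* x = &sites(0, 0);
  const double* y = &sites(0, 1);
  const double* z = &sites(0, 2);
  const double c2 = cutoff * cutoff;
  std::vector<int> cnt(M, 0);
  for (int i = 0; i < M; ++i)
    for (int j = i + 1; j < M; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      if (dx * dx + dy * dy + dz * dz <= c2) { ++cnt[i]; ++cnt[j]; }
    }
  IntegerVector ptr(M + 1);
  for (int i = 0; i < M; ++i) ptr[i + 1] = ptr[i] + cnt[i];
  IntegerVector idx(ptr[M]);
  std::vector<int> fill(M, 0);
  for (int i = 0; i < M; ++i)
    for (int j = i + 1; j < M; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      if (dx * dx + dy * dy + dz * dz <= c2) {
        idx[ptr[i] + fill[i]++] = j;
        idx[ptr[j] + fill[j]++] = i;
      }
    }
  return List::create(_["ptr"] = ptr, _["idx"] = idx);
}

struct AnnealState {
  // occupancy flags plus a dense list of occupied site indices
  std::vector<char> occ;
  std::vector<int> occ_list;   // indices of occupied sites
  std::vector<int> occ_pos;    // position of site in occ_list, -1 if vacant
  std::vector<double> hist;    // pair-distance histogram of occupied beads
  std::vector<int> ncnt;       // occupied-neighbour count per site
  int n_occ;
  int iso;                     // occupied beads with no occupied neighbour
  long sum_ncnt;               // sum of ncnt over occupied sites
};

class Annealer {
public:
  const double *x, *y, *z;
  int M, nq, nb;
  std::vector<double> sinctab;  // nb x nq
  const double *qv, *It, *sg, *ff;
  double bw, w_compact;
  const int* nptr;   // neighbour list offsets (size M+1)
  const int* nidx;   // flattened neighbour indices (0-based)
  AnnealState st;

  double model_chi2(const std::vector<double>& hist, int count) const {
    // I_model(q) = ff(q) * (N + 2 sum_b h_b sinc(q d_b)); analytic LSQ scale
    double swmt = 0.0, swmm = 0.0;
    std::vector<double> Im(nq);
    for (int k = 0; k < nq; ++k) Im[k] = (double)count;
    for (int b = 0; b < nb; ++b) {
      double h = hist[b];
      if (h > 0.0) {
        const double* row = &sinctab[(size_t)b * nq];
        for (int k = 0; k < nq; ++k) Im[k] += 2.0 * h * row[k];
      }
    }
    for (int k = 0; k < nq; ++k) {
      Im[k] *= ff[k];
      double w = 1.0 / (sg[k] * sg[k]);
      swmt += w * Im[k] * It[k];
      swmm += w * Im[k] * Im[k];
    }
    double s = (swmm > 0) ? swmt / swmm : 0.0;
    double chi2 = 0.0;
    for (int k = 0; k < nq; ++k) {
      double r = (s * Im[k] - It[k]) / sg[k];
      chi2 += r * r;
    }
    return chi2 / nq;
  }

  double objective() const {
    double pen = 0.0;
    if (st.n_occ > 0)
      pen = (double)st.iso / st.n_occ +
            (1.0 - (double)st.sum_ncnt / (12.0 * st.n_occ));
    return model_chi2(st.hist, st.n_occ) + w_compact * pen;
  }

  void toggle(int s) {
    bool adding = !st.occ[s];
    // histogram update against all other occupied beads
    for (int m = 0; m < st.n_occ; ++m) {
      int j = st.occ_list[m];
      if (j == s) continue;
      int b = (int)(dist3(x, y, z, s, j) / bw);
      if (b >= nb) b = nb - 1;
      st.hist[b] += adding ? 1.0 : -1.0;
    }
    // neighbour bookkeeping
    if (adding) {
      int cnt = 0;
      for (int t = nptr[s]; t < nptr[s + 1]; ++t) {
        int j = nidx[t];
        if (st.occ[j]) {
          ++cnt;
          if (st.ncnt[j] == 0) --st.iso;
          ++st.ncnt[j];
          st.sum_ncnt += 1;
        }
      }
      st.ncnt[s] = cnt;
      st.sum_ncnt += cnt;
      if (cnt == 0) ++st.iso;
      st.occ[s] = 1;
      st.occ_pos[s] = st.n_occ;
      st.occ_list[st.n_occ++] = s;
    } else {
      st.occ[s] = 0;
      int p = st.occ_pos[s];
      int last = st.occ_list[--st.n_occ];
      st.occ_list[p] = last;
      st.occ_pos[last] = p;
      st.occ_pos[s] = -1;
      int cnt = st.ncnt[s];
      st.sum_ncnt -= cnt;
      if (cnt == 0) --st.iso;
      st.ncnt[s] = 0;
      for (int t = nptr[s]; t < nptr[s + 1]; ++t) {
        int j = nidx[t];
        if (st.occ[j]) {
          --st.ncnt[j];
          st.sum_ncnt -= 1;
          if (st.ncnt[j] == 0) ++st.iso;
        }
      }
    }
  }
};

// Metropolis single-bead-flip annealing of a bead occupancy against a target
// curve. Geometric cooling; stops when the acceptance rate drops below
// min_accept. Seeded through R's RNG (set.seed before calling).
// [[Rcpp::export]]
List cpp_anneal(NumericMatrix sites, IntegerVector neigh_ptr,
                IntegerVector neigh_idx, IntegerVector occ0, NumericVector q,
                NumericVector I_target, NumericVector sigma, NumericVector ff,
                double bin_width, double w_compact, double T0, double cooling,
                int moves_per_round, int max_rounds, double min_accept) {
  Annealer an;
  const int M = sites.nrow();
  an.x = &sites(0, 0); an.y = &sites(0, 1); an.z = &sites(0, 2);
  an.M = M; an.nq = q.size();
  an.qv = &q[0]; an.It = &I_target[0]; an.sg = &sigma[0]; an.ff = &ff[0];
  an.bw = bin_width; an.w_compact = w_compact;
  an.nptr = &neigh_ptr[0]; an.nidx = neigh_idx.size() ? &neigh_idx[0] : NULL;

  double dmax = 0.0;
  for (int i = 0; i < M; ++i) {
    double r2 = an.x[i] * an.x[i] + an.y[i] * an.y[i] + an.z[i] * an.z[i];
    if (r2 > dmax) dmax = r2;
  }
  dmax = 2.0 * std::sqrt(dmax) + bin_width;
  an.nb = (int)(dmax / bin_width) + 2;
  an.sinctab.assign((size_t)an.nb * an.nq, 0.0);
  for (int b = 0; b < an.nb; ++b) {
    double d = (b + 0.5) * bin_width;
    for (int k = 0; k < an.nq; ++k)
      an.sinctab[(size_t)b * an.nq + k] = sinc(q[k] * d);
  }

  AnnealState& st = an.st;
  st.occ.assign(M, 0);
  st.occ_list.assign(M, 0);
  st.occ_pos.assign(M, -1);
  st.hist.assign(an.nb, 0.0);
  st.ncnt.assign(M, 0);
  st.n_occ = 0; st.iso = 0; st.sum_ncnt = 0;
  for (int i = 0; i < M; ++i)
    if (occ0[i]) an.toggle(i);

  double E = an.objective();
  double bestE = E;
  std::vector<char> best_occ(st.occ);

  // calibrate T0 from typical move magnitudes when not supplied
  double T = T0;
  if (!(T > 0.0)) {
    double acc = 0.0;
    int ntrial = 50;
    for (int t = 0; t < ntrial; ++t) {
      int s = (int)(unif_rand() * M);
      if (s >= M) s = M - 1;
      if (st.occ[s] && st.n_occ <= 1) continue;
      an.toggle(s);
      double E2 = an.objective();
      acc += std::fabs(E2 - E);
      an.toggle(s);  // revert
    }
    T = acc / ntrial;
    if (!(T > 0.0)) T = 1.0;
  }

  std::vector<double> trace_obj, trace_acc, trace_T;
  int rounds_done = 0;
  for (int round = 0; round < max_rounds; ++round) {
    int accepted = 0;
    for (int mv = 0; mv < moves_per_round; ++mv) {
      int s = (int)(unif_rand() * M);
      if (s >= M) s = M - 1;
      if (st.occ[s] && st.n_occ <= 1) continue;  // never empty the model
      an.toggle(s);
      double E2 = an.objective();
      double dE = E2 - E;
      if (dE <= 0.0 || unif_rand() < std::exp(-dE / T)) {
        E = E2;
        ++accepted;
        if (E < bestE) { bestE = E; best_occ = st.occ; }
      } else {
        an.toggle(s);  // revert
      }
    }
    ++rounds_done;
    double rate = moves_per_round > 0 ? (double)accepted / moves_per_round : 0.0;
    trace_obj.push_back(E);
    trace_acc.push_back(rate);
    trace_T.push_back(T);
    T *= cooling;
    if (rate < min_accept) break;
  }

  // final chi2 of the best-ever configuration
  std::vector<double> hist(an.nb, 0.0);
  int cnt = 0;
  for (int i = 0; i < M; ++i) if (best_occ[i]) ++cnt;
  for (int i = 0; i < M; ++i) {
    if (!best_occ[i]) continue;
    for (int j = i + 1; j < M; ++j) {
      if (!best_occ[j]) continue;
      int b = (int)(dist3(an.x, an.y, an.z, i, j) / bin_width);
      if (b >= an.nb) b = an.nb - 1;
      hist[b] += 1.0;
    }
  }
  double best_chi2 = an.model_chi2(hist, cnt);

  IntegerVector occ_out(M);
  for (int i = 0; i < M; ++i) occ_out[i] = best_occ[i] ? 1 : 0;
  return List::create(_["occupancy"] = occ_out, _["best_objective"] = bestE,
                      _["best_chi2"] = best_chi2,
                      _["rounds"] = rounds_done,
                      _["trace_objective"] = wrap(trace_obj),
                      _["trace_acceptance"] = wrap(trace_acc),
                      _["trace_temperature"] = wrap(trace_T));
}
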