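// Structured-coalescent and sequence-evolution core.
//
// All randomness goes through R's RNG (RNGScope), so set.seed() at the R
// level makes every simulation bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Structured coalescent
//
// Populations are numbered 1..P. Demographic events (already sorted by time,
// ties kept in listed order) are rows (time, type, a, b, value) with
//   type 1 = merge : all lineages of pop a move to pop b
//   type 2 = admix : each lineage in pop a moves to pop b with prob `value`
//   type 3 = resize: pop a's haploid size becomes `value`
// Between events each pair of lineages within a population of size N
// coalesces at rate 1/N per generation (continuous-time approximation).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List sim_genealogy_cpp(IntegerVector sample_sizes, NumericVector pop_sizes,
                       NumericMatrix events) {
  const int P = sample_sizes.size();
  if (pop_sizes.size() != P) stop("sample_sizes and pop_sizes length mismatch");
  int n = 0;
  for (int p = 0; p < P; ++p) {
    if (sample_sizes[p] < 0) stop("negative sample size");
    n += sample_sizes[p];
  }
  if (n < 1) stop("at least one sampled lineage required");

  std::vector<double> N(pop_sizes.begin(), pop_sizes.end());
  for (int p = 0; p < P; ++p)
    if (sample_sizes[p] > 0 && N[p] <= 0) stop("nonpositive size in a sampled population");

  const int n_nodes = 2 * n - 1;
  IntegerVector parent(n_nodes, 0);        // 0 = root (no parent)
  NumericVector node_time(n_nodes, 0.0);
  IntegerVector tip_pop(n);

  std::vector<int> lin_node, lin_pop;      // active lineages
  lin_node.reserve(n); lin_pop.reserve(n);
  int id = 0;
  for (int p = 0; p < P; ++p)
    for (int k = 0; k < sample_sizes[p]; ++k) {
      tip_pop[id] = p + 1;
      lin_node.push_back(id + 1);          // 1-based node ids
      lin_pop.push_back(p);
      ++id;
    }

  RNGScope scope;
  double t = 0.0;
  int next_node = n + 1;
  int ei = 0;
  const int nE = events.nrow();
  std::vector<int> npop(P), members;

  while ((int)lin_node.size() > 1) {
    std::fill(npop.begin(), npop.end(), 0);
    for (size_t i = 0; i < lin_pop.size(); ++i) npop[lin_pop[i]]++;

    double total = 0.0;
    std::vector<double> rate(P, 0.0);
    for (int p = 0; p < P; ++p) {
      if (npop[p] >= 2) {
        if (N[p] <= 0) stop("nonpositive population size in an active epoch");
        rate[p] = 0.5 * npop[p] * (npop[p] - 1) / N[p];
        total += rate[p];
      }
    }

    double t_event = (ei < nE) ? events(ei, 0) : R_PosInf;
    double dt = (total > 0) ? exp_rand() / total : R_PosInf;

    if (t + dt < t_event) {
      // coalescence
      t += dt;
      double u = unif_rand() * total;
      int p = 0;
      while (p < P - 1 && u > rate[p]) { u -= rate[p]; ++p; }
      while (rate[p] <= 0) ++p;  // guard against fp edge
      members.clear();
      for (size_t i = 0; i < lin_pop.size(); ++i)
        if (lin_pop[i] == p) members.push_back((int)i);
      int m = (int)members.size();
      int i1 = (int)std::floor(unif_rand() * m); if (i1 == m) i1 = m - 1;
      int i2 = (int)std::floor(unif_rand() * (m - 1)); if (i2 == m - 1) i2 = m - 2;
      if (i2 >= i1) ++i2;
      int a = members[i1], b = members[i2];
      parent[lin_node[a] - 1] = next_node;
      parent[lin_node[b] - 1] = next_node;
      node_time[next_node - 1] = t;
      lin_node[a] = next_node;
      // remove lineage b (swap with back)
      lin_node[b] = lin_node.back(); lin_pop[b] = lin_pop.back();
      lin_node.pop_back(); lin_pop.pop_back();
      ++next_node;
    } else {
      if (!R_finite(t_event)) stop("lineages remain in populations that never merge");
      t = t_event;
      // apply every event scheduled at exactly this time, in listed order
      while (ei < nE && events(ei, 0) == t_event) {
        int type = (int)events(ei, 1);
        int a = (int)events(ei, 2) - 1;
        int b = (int)events(ei, 3) - 1;
        double v = events(ei, 4);
        if (a < 0 || a >= P) stop("event population index out of range");
        if (type == 1) {                   // merge a -> b
          if (b < 0 || b >= P) stop("merge destination out of range");
          for (size_t i = 0; i < lin_pop.size(); ++i)
            if (lin_pop[i] == a) lin_pop[i] = b;
        } else if (type == 2) {            // admixture pulse a -> b w.p. v
          if (b < 0 || b >= P) stop("admixture donor out of range");
          for (size_t i = 0; i < lin_pop.size(); ++i)
            if (lin_pop[i] == a && unif_rand() < v) lin_pop[i] = b;
        } else if (type == 3) {            // stepwise resize
          if (v <= 0) stop("resize to nonpositive population size");
          N[a] = v;
        } else stop("unknown event type");
        ++ei;
      }
    }
  }

  return List::create(_["n_tips"] = n, _["parent"] = parent,
                      _["node_time"] = node_time, _["tip_pop"] = tip_pop);
}

// ---------------------------------------------------------------------------
// Sequence evolution: HKY with per-site relative rates (0 = invariant site).
//
// The HKY generator is scaled so the stationary mean rate is 1 substitution
// per unit of (mu * site rate * time). Two exact samplers:
//  * equal base frequencies: the leaving rate is state-independent, so branch
//    mutation counts are Poisson and events are placed by the jump chain;
//  * general frequencies: per-branch Gillespie with state-dependent rates.
// Site rates are drawn once per dataset and shared across branches.
// ---------------------------------------------------------------------------

static inline int transition_partner(int b) { return b ^ 2; }  // A<->G, C<->T

// [[Rcpp::export]]
List evolve_cpp(IntegerVector parent, NumericVector node_time, int n_tips,
                NumericVector rates, double mu, double kappa,
                NumericVector freqs) {
  const int n_nodes = parent.size();
  const int L = rates.size();
  if (freqs.size() != 4) stop("freqs must have length 4");
  if (mu < 0) stop("mu must be nonnegative");
  if (kappa <= 0) stop("kappa must be positive");
  double fsum = freqs[0] + freqs[1] + freqs[2] + freqs[3];
  if (std::abs(fsum - 1.0) > 1e-9) stop("base frequencies must sum to 1");

  RNGScope scope;

  // root sequence over all L sites
  IntegerVector root_seq(L);
  double cf[4] = {freqs[0], freqs[0] + freqs[1], freqs[0] + freqs[1] + freqs[2], 1.0};
  for (int s = 0; s < L; ++s) {
    double u = unif_rand();
    int b = 0; while (b < 3 && u > cf[b]) ++b;
    root_seq[s] = b;
  }

  // variable (rate > 0) sites
  std::vector<int> vsite; std::vector<double> vrate;
  for (int s = 0; s < L; ++s)
    if (rates[s] > 0) { vsite.push_back(s + 1); vrate.push_back(rates[s]); }
  const int S = (int)vsite.size();

  IntegerMatrix tip_var(n_tips, S);
  if (S == 0 || n_nodes == 0) {
    return List::create(_["var_sites"] = wrap(vsite), _["tip_var"] = tip_var,
                        _["root_seq"] = root_seq);
  }

  // children lists and root
  std::vector<std::vector<int> > child(n_nodes);
  int root = -1;
  for (int i = 0; i < n_nodes; ++i) {
    if (parent[i] == 0) root = i;
    else child[parent[i] - 1].push_back(i);
  }
  if (root < 0) stop("genealogy has no root");

  // HKY scaling: mean stationary rate 1
  double mean_rate = 0.0;
  for (int i = 0; i < 4; ++i) {
    int ti = transition_partner(i);
    double out = kappa * freqs[ti];
    for (int j = 0; j < 4; ++j) if (j != i && j != ti) out += freqs[j];
    mean_rate += freqs[i] * out;
  }
  double csc = 1.0 / mean_rate;
  double dleave[4];
  for (int i = 0; i < 4; ++i) {
    int ti = transition_partner(i);
    double out = kappa * freqs[ti];
    for (int j = 0; j < 4; ++j) if (j != i && j != ti) out += freqs[j];
    dleave[i] = csc * out;
  }
  bool equal_freqs = true;
  for (int i = 0; i < 4; ++i)
    if (std::abs(freqs[i] - 0.25) > 1e-12) equal_freqs = false;

  // cumulative site-rate table for the Poisson path
  std::vector<double> cum_rate(S);
  double sum_rate = 0.0;
  for (int s = 0; s < S; ++s) { sum_rate += vrate[s]; cum_rate[s] = sum_rate; }

  // jump: mutate state b once, returning the new state
  auto jump = [&](int b) -> int {
    int ti = transition_partner(b);
    double w[4]; double tot = 0.0;
    for (int j = 0; j < 4; ++j) {
      if (j == b) { w[j] = 0.0; continue; }
      w[j] = (j == ti) ? kappa * freqs[j] : freqs[j];
      tot += w[j];
    }
    double u = unif_rand() * tot;
    int j = -1;
    for (int cand = 0; cand < 4; ++cand) {
      if (cand == b) continue;
      if (u <= w[cand]) { j = cand; break; }
      u -= w[cand];
    }
    if (j < 0) j = (b == 3) ? 2 : 3;  // floating-point edge
    return j;
  };

  // iterative preorder DFS carrying the variable-site states
  std::vector<std::vector<int> > seq_store(n_nodes);
  std::vector<int> stack; stack.push_back(root);
  {
    std::vector<int> rseq(S);
    for (int s = 0; s < S; ++s) rseq[s] = root_seq[vsite[s] - 1];
    seq_store[root] = rseq;
  }

  while (!stack.empty()) {
    int node = stack.back(); stack.pop_back();
    std::vector<int> &seq = seq_store[node];

    if (node != root) {
      double len = node_time[parent[node] - 1] - node_time[node];
      if (len < 0) stop("negative branch length");
      if (mu > 0 && len > 0) {
        if (equal_freqs) {
          // state-independent leaving rate (= 1 after scaling)
          double lam = mu * len * sum_rate;
          int nmut = (int)R::rpois(lam);
          for (int m = 0; m < nmut; ++m) {
            double u = unif_rand() * sum_rate;
            int lo = 0, hi = S - 1;
            while (lo < hi) { int mid = (lo + hi) / 2; if (cum_rate[mid] < u) lo = mid + 1; else hi = mid; }
            seq[lo] = jump(seq[lo]);
          }
        } else {
          // aggregated Gillespie over variable sites
          double lam = 0.0;
          std::vector<double> w(S);
          for (int s = 0; s < S; ++s) { w[s] = vrate[s] * dleave[seq[s]]; lam += w[s]; }
          lam *= mu;
          double tt = 0.0;
          while (lam > 0) {
            tt += exp_rand() / lam;
            if (tt > len) break;
            double u = unif_rand() * (lam / mu);
            int s = 0;
            while (s < S - 1 && u > w[s]) { u -= w[s]; ++s; }
            int nb = jump(seq[s]);
            lam += mu * vrate[s] * (dleave[nb] - dleave[seq[s]]);
            w[s] = vrate[s] * dleave[nb];
            seq[s] = nb;
          }
        }
      }
    }

    if (child[node].empty()) {
      for (int s = 0; s < S; ++s) tip_var(node, s) = seq[s];
    } else {
      for (size_t c = 0; c < child[node].size(); ++c) {
        seq_store[child[node][c]] = seq;
        stack.push_back(child[node][c]);
      }
    }
    seq_store[node].clear(); seq_store[node].shrink_to_fit();
  }

  return List::create(_["var_sites"] = wrap(vsite), _["tip_var"] = tip_var,
                      _["root_seq"] = root_seq);
}

// ---------------------------------------------------------------------------
// 12-statistic summary from a (tips x variable-sites) state matrix.
// Returns, for P populations: n_haplotypes (xP), segregating sites (xP),
// mean pairwise differences (xP), then Hudson F_ST = 1 - Hw/Hb for every
// unordered pair in order (1,2), (1,3), ..., (P-1,P).
// Invariant columns contribute nothing, so passing only variable sites is
// equivalent to passing the full alignment.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector sumstats_cpp(IntegerMatrix tipmat, IntegerVector pop, int n_pops) {
  const int n = tipmat.nrow(), S = tipmat.ncol(), P = n_pops;
  if (pop.size() != n) stop("pop labels must match rows");
  std::vector<int> npop(P, 0);
  for (int i = 0; i < n; ++i) {
    if (pop[i] < 1 || pop[i] > P) stop("population index out of range");
    npop[pop[i] - 1]++;
  }
  for (int p = 0; p < P; ++p)
    if (npop[p] < 2) stop("every population needs at least two sequences");

  // haplotype counts per population (exact row equality)
  NumericVector nhap(P);
  {
    std::vector<std::vector<std::vector<int> > > rows(P);
    for (int i = 0; i < n; ++i) {
      std::vector<int> r(S);
      for (int s = 0; s < S; ++s) r[s] = tipmat(i, s);
      rows[pop[i] - 1].push_back(r);
    }
    for (int p = 0; p < P; ++p) {
      std::sort(rows[p].begin(), rows[p].end());
      nhap[p] = (double)(std::unique(rows[p].begin(), rows[p].end()) - rows[p].begin());
    }
  }

  NumericVector segs(P), mpd(P);
  int n_pairs = P * (P - 1) / 2;
  std::vector<double> cross(n_pairs, 0.0);

  std::vector<std::vector<int> > cnt(P, std::vector<int>(8, 0));
  for (int s = 0; s < S; ++s) {
    for (int p = 0; p < P; ++p) std::fill(cnt[p].begin(), cnt[p].end(), 0);
    for (int i = 0; i < n; ++i) {
      int st = tipmat(i, s);
      if (st < 0 || st > 7) stop("sequence states must be small nonnegative integers");
      cnt[pop[i] - 1][st]++;
    }
    for (int p = 0; p < P; ++p) {
      int states = 0; double sq = 0.0;
      for (int a = 0; a < 8; ++a) {
        if (cnt[p][a] > 0) ++states;
        sq += (double)cnt[p][a] * cnt[p][a];
      }
      if (states >= 2) segs[p] += 1.0;
      mpd[p] += 0.5 * ((double)npop[p] * npop[p] - sq);
    }
    int k = 0;
    for (int p = 0; p < P; ++p)
      for (int q = p + 1; q < P; ++q, ++k) {
        double same = 0.0;
        for (int a = 0; a < 8; ++a) same += (double)cnt[p][a] * cnt[q][a];
        cross[k] += (double)npop[p] * npop[q] - same;
      }
  }
  for (int p = 0; p < P; ++p) mpd[p] /= 0.5 * npop[p] * (npop[p] - 1);

  NumericVector out(3 * P + n_pairs);
  for (int p = 0; p < P; ++p) { out[p] = nhap[p]; out[P + p] = segs[p]; out[2 * P + p] = mpd[p]; }
  int k = 0;
  for (int p = 0; p < P; ++p)
    for (int q = p + 1; q < P; ++q, ++k) {
      double hb = cross[k] / ((double)npop[p] * npop[q]);
      double hw = 0.5 * (mpd[p] + mpd[q]);
      out[3 * P + k] = (hb == 0.0) ? 0.0 : 1.0 - hw / hb;
    }
  return out;
}
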